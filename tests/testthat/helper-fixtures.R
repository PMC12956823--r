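# Shared fixture builders. Everything is generated in code; no data files.

# A small, fully valid society table (n rows, deterministic content).
make_table <- function(n = 8, seed = 1) {
  set.seed(seed)
  df <- data.frame(
    society_id = sprintf("s%02d", seq_len(n)),
    language_taxon = sprintf("L%03d", seq_len(n)),
    kava = rbinom(n, 1, 0.5),
    political_complexity = sample(0:4, n, replace = TRUE),
    social_stratification = sample(0:4, n, replace = TRUE),
    atoll_raw = sample(c(0, 0.5, 1), n, replace = TRUE, prob = c(.7, .1, .2)),
    latitude = runif(n, -25, 5),
    longitude = runif(n, 150, 180),
    stringsAsFactors = FALSE)
  society_table(df)
}

# Simulated table + tree pair on which the coevolution / signal models are
# exactly correctly specified.
make_ou_dataset <- function(n_tips = 40, params = ou_params(), seed = 1,
                            missing_kava = 0, missing_trait = 0) {
  tree <- simulate_tree(n_tips, seed = seed)
  eta <- simulate_ou_tips(tree, params, seed = seed + 1)
  obs <- latent_to_observed(eta, params$alpha,
                            missing_kava = missing_kava,
                            missing_trait = missing_trait, seed = seed + 2)
  set.seed(seed + 3)
  df <- data.frame(
    society_id = rownames(eta),
    language_taxon = rownames(eta),
    kava = obs$kava,
    political_complexity = obs$trait,
    social_stratification = sample(0:4, n_tips, replace = TRUE),
    atoll_raw = 0,
    latitude = runif(n_tips, -25, 5),
    longitude = runif(n_tips, 150, 180),
    stringsAsFactors = FALSE)
  list(table = society_table(df), tree = tree,
       trees = phylo_set(tree, kind = "summary"), eta = eta,
       params = params)
}

# Independent brute-force oracle: shared root-to-tip path length between
# two tips computed by explicit path traversal (no vcv machinery).
shared_path_oracle <- function(tree) {
  ntips <- length(tree$tip.label)
  root <- ntips + 1L
  parent <- integer(ntips + tree$Nnode)
  elen <- numeric(ntips + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    elen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  path_to_root <- function(node) {
    out <- integer(0)
    while (node != root) {
      out <- c(out, node)
      node <- parent[node]
    }
    out
  }
  M <- matrix(0, ntips, ntips,
              dimnames = list(tree$tip.label, tree$tip.label))
  depths <- numeric(ntips)
  for (i in seq_len(ntips)) depths[i] <- sum(elen[path_to_root(i)])
  for (i in seq_len(ntips)) {
    pi_ <- path_to_root(i)
    for (j in seq_len(ntips)) {
      shared <- intersect(pi_, path_to_root(j))
      M[i, j] <- sum(elen[shared])
    }
  }
  list(shared = M, depths = depths)
}
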