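#' Configuration for the synthetic-data generator
#'
#' The generator produces a world in which every other module's assumptions
#' hold exactly: a pure-birth tree (height normalized to 1), latent
#' bivariate OU trajectories simulated branchwise from the transition
#' moments, Bernoulli / cumulative-logit observation layers, island-cluster
#' geography with an optional Matern 3/2 Gaussian-process confounder added
#' to both traits' predictors, and explicit missingness.
#'
#' Seeds are split hierarchically (tree / latent / observation / geography)
#' so each component can be varied independently.
#'
#' @param n_tips Number of societies (tips); at least 3.
#' @param birth_rate Speciation rate of the pure-birth tree.
#' @param ou An [ou_params] ground truth.
#' @param gp_scale Scale of the spatial confounder (0 disables).
#' @param rho Spatial decay length of the confounder.
#' @param missing_kava,missing_trait Counts of values set missing.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_tips = 83, birth_rate = 1,
                       ou = ou_params(b = c(0.1, 0.575),
                                      A = matrix(c(-1, 0.75, 0.25, -1), 2),
                                      sigma = c(1.2, 1.2), r = 0.3,
                                      alpha = c(-2, -0.75, 0.5, 1.75),
                                      eta_anc = -2),
                       gp_scale = 0, rho = 0.02,
                       missing_kava = 0, missing_trait = 0,
                       seed = 1) {
  if (n_tips < 3) ct_config_error("n_tips must be at least 3")
  if (birth_rate <= 0) ct_config_error("birth_rate must be positive")
  if (missing_kava < 0 || missing_kava >= n_tips ||
      missing_trait < 0 || missing_trait >= n_tips) {
    ct_config_error("missing counts must be in [0, n_tips)")
  }
  structure(list(n_tips = n_tips, birth_rate = birth_rate, ou = ou,
                 gp_scale = gp_scale, rho = rho,
                 missing_kava = missing_kava,
                 missing_trait = missing_trait, seed = seed),
            class = "sim_config")
}

# Derive component sub-seeds (< 2^31) from the master seed.
split_seed <- function(seed, n = 6L) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

#' Simulate a pure-birth tree with unit height
#'
#' @param n_tips Number of tips (>= 3).
#' @param birth_rate Speciation rate.
#' @param seed Integer seed (reproducible).
#' @return A rooted ultrametric `phylo` with height 1 and tips `t1..tn`.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 3) ct_config_error("n_tips must be at least 3")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth_rate, death = 0)
  rescale_tree_height(tr)
}

#' Simulate latent OU trait values at the tips of a tree
#'
#' Recursively draws each node's bivariate latent state from the OU
#' transition moments given its parent, starting from a root draw
#' `N(eta_anc, 1)` per trait. This forward simulation uses the pure-R
#' moment functions, independently of the compiled likelihood used in
#' fitting.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param params An [ou_params] (stable `A`).
#' @param seed Integer seed.
#' @return `n_tips x 2` matrix of latent tip values (rows named by tip
#'   label), with the full node matrix attached as attribute `eta_nodes`.
#' @export
simulate_ou_tips <- function(tree, params, seed = NULL) {
  stopifnot(inherits(params, "ou_params"))
  if (!ou_is_stable(params$A)) ct_numeric_error("A is not stable")
  if (!is.null(seed)) set.seed(seed)
  ntips <- length(tree$tip.label)
  N <- ntips + tree$Nnode
  root <- ntips + 1L
  eta <- matrix(NA_real_, N, 2)
  eta[root, ] <- stats::rnorm(2, params$eta_anc, 1)
  # parents precede children in cladewise edge order
  tr <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    mo <- ou_transition_moments(params, tr$edge.length[e], eta[par, ])
    Lc <- t(chol(mo$cov + diag(1e-12, 2)))
    eta[ch, ] <- mo$mean + drop(Lc %*% stats::rnorm(2))
  }
  tips <- eta[seq_len(ntips), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  attr(tips, "eta_nodes") <- eta
  tips
}

#' Threshold latent values into observed binary and ordinal traits
#'
#' Binary trait: Bernoulli with `p = logistic(eta1)`. Ordinal trait: drawn
#' from the cumulative-logit category probabilities at `eta2` with ordered
#' cutpoints `alpha`. Missingness is injected by blanking a fixed number of
#' uniformly chosen entries.
#'
#' @param eta_tips `n x 2` latent matrix (optionally with spatial offsets
#'   already added).
#' @param alpha Ordered cutpoints.
#' @param missing_kava,missing_trait Number of entries set to `NA`.
#' @param seed Integer seed.
#' @return data.frame with columns `kava` and `trait` (integer 0..4).
#' @export
latent_to_observed <- function(eta_tips, alpha, missing_kava = 0,
                               missing_trait = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(eta_tips)
  kava <- stats::rbinom(n, 1, stats::plogis(eta_tips[, 1]))
  pr <- ordinal_category_probs(eta_tips[, 2], alpha)
  trait <- apply(pr, 1, function(p) sample(0:4, 1, prob = p))
  if (missing_kava > 0) kava[sample.int(n, missing_kava)] <- NA
  if (missing_trait > 0) trait[sample.int(n, missing_trait)] <- NA
  data.frame(kava = kava, trait = as.integer(trait))
}

#' Simulate island-cluster geography and a spatial confounder
#'
#' Coordinates are drawn around a handful of cluster centres inside a
#' Pacific-like bounding box (longitudes may wrap across the antimeridian).
#' When `gp_scale > 0`, a latent spatial effect is drawn from a Matern 3/2
#' Gaussian process over the Haversine distances and returned for addition
#' to both traits' predictors, inducing spurious spatial association.
#'
#' @param n Number of societies.
#' @param gp_scale Marginal SD of the spatial effect (0 disables).
#' @param rho Matern decay length on the normalized-distance scale.
#' @param n_clusters Number of island clusters.
#' @param seed Integer seed.
#' @return List with `latitude`, `longitude`, `spatial_effect` (length-n
#'   vector, zeros when disabled).
#' @export
simulate_geography <- function(n, gp_scale = 0, rho = 0.02,
                               n_clusters = 8, seed = NULL) {
  if (n < 2) ct_config_error("need at least 2 societies")
  if (!is.null(seed)) set.seed(seed)
  centers_lon <- stats::runif(n_clusters, 140, 230)
  centers_lat <- stats::runif(n_clusters, -25, 10)
  cl <- sample.int(n_clusters, n, replace = TRUE)
  lon <- centers_lon[cl] + stats::rnorm(n, 0, 1.5)
  lat <- pmin(pmax(centers_lat[cl] + stats::rnorm(n, 0, 1.5), -89), 89)
  lon <- ((lon + 180) %% 360) - 180
  eff <- rep(0, n)
  if (gp_scale > 0) {
    df <- data.frame(society_id = paste0("g", seq_len(n)),
                     language_taxon = paste0("g", seq_len(n)),
                     kava = 0, political_complexity = 0,
                     social_stratification = 0, atoll_raw = 0,
                     latitude = lat, longitude = lon)
    tab <- society_table(df)
    K <- matern32(normalize_distances(haversine_matrix(tab)),
                  kernel_config(rho = rho))
    eff <- gp_scale * drop(chol_jitter(K) %*% stats::rnorm(n))
  }
  list(latitude = lat, longitude = lon, spatial_effect = eff)
}

#' Simulate a complete synthetic study dataset
#'
#' The `"dataset-s1-like"` preset emulates the statistical shape of the
#' study data: 83 societies with binary kava, two 5-level ordinal traits,
#' atoll codes containing seven 0.5 ("almost atoll") values, island-cluster
#' coordinates, 5 missing kava values and 1 missing social-stratification
#' value, plus a posterior-style set of 100 trees of which the first is the
#' true generating history. Trees carry 12 extra language tips beyond the
#' 83 mapped societies, so pruning via the returned taxon map is exercised;
#' three societies are deliberately given a second plausible language to
#' emulate multi-language societies (the map picks one).
#'
#' Kava and political complexity are generated from the latent OU ground
#' truth; social stratification is derived from the same political-
#' complexity latent plus logistic noise, giving correlated ordinals
#' without a third OU dimension.
#'
#' @param preset Currently `"dataset-s1-like"` or `"custom"`.
#' @param cfg A [sim_config]; for the preset, its `n_tips`, missingness and
#'   spatial settings are overridden to the preset values.
#' @param n_trees Number of trees in the posterior-style sample.
#' @param seed Master seed (overrides `cfg$seed`).
#' @return List with `table` ([society_table]), `trees` (unpruned
#'   [phylo_set]), `map` ([taxon_map]), `pruned` (pruned, society-labelled
#'   [phylo_set]), and `truth` (generator ground truth).
#' @export
simulate_dataset <- function(preset = c("dataset-s1-like", "custom"),
                             cfg = sim_config(), n_trees = 100,
                             seed = NULL) {
  preset <- match.arg(preset)
  if (!is.null(seed)) cfg$seed <- seed
  if (preset == "dataset-s1-like") {
    cfg$n_tips <- 83L
    cfg$missing_kava <- 5L
    cfg$missing_trait <- 0L  # political complexity fully observed
  }
  s <- split_seed(cfg$seed, 6L)
  n <- cfg$n_tips
  n_extra <- 12L
  ids <- sprintf("s%02d", seq_len(n))
  taxa <- sprintf("L%03d", seq_len(n))

  # trees: the first is the generating history; the rest emulate posterior
  # topological uncertainty
  trees <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    tr <- simulate_tree(n + n_extra, cfg$birth_rate, seed = s[1] + i - 1L)
    tr$tip.label <- c(taxa, sprintf("X%03d", seq_len(n_extra)))[
      as.integer(sub("^t", "", tr$tip.label))]
    trees[[i]] <- tr
  }
  physet <- phylo_set(trees, kind = "posterior_sample")
  map <- taxon_map(ids, taxa)
  pruned <- prune_and_match(physet, map)

  eta <- simulate_ou_tips(pruned$trees[[1]], cfg$ou, seed = s[2])
  geo <- simulate_geography(n, gp_scale = cfg$gp_scale, rho = cfg$rho,
                            seed = s[4])
  eta_obs <- eta[match(ids, rownames(eta)), , drop = FALSE]
  eta_obs <- eta_obs + cbind(geo$spatial_effect, geo$spatial_effect)
  obs <- latent_to_observed(eta_obs, cfg$ou$alpha,
                            missing_kava = cfg$missing_kava,
                            missing_trait = cfg$missing_trait,
                            seed = s[3])

  set.seed(s[5])
  # social stratification: same latent axis plus logistic noise, own cuts
  ss_latent <- eta_obs[, 2] + stats::rlogis(n)
  ss_cuts <- cfg$ou$alpha * 1.4
  ss <- as.integer(cut(ss_latent, c(-Inf, ss_cuts, Inf))) - 1L
  if (preset == "dataset-s1-like") ss[sample.int(n, 1)] <- NA

  atoll_raw <- rep(0, n)
  n_atoll <- max(1L, round(0.15 * n))
  pick <- sample.int(n, n_atoll + if (preset == "dataset-s1-like") 7L
                     else max(1L, round(0.08 * n)))
  atoll_raw[pick[seq_len(n_atoll)]] <- 1
  atoll_raw[pick[-seq_len(n_atoll)]] <- 0.5
  # atolls suppress kava (environmentally unsuitable)
  set.seed(s[6])
  obs$kava[atoll_raw == 1 & !is.na(obs$kava)] <-
    stats::rbinom(sum(atoll_raw == 1 & !is.na(obs$kava)), 1, 0.05)

  table <- society_table(data.frame(
    society_id = ids, language_taxon = taxa, kava = obs$kava,
    political_complexity = obs$trait, social_stratification = ss,
    atoll_raw = atoll_raw, latitude = geo$latitude,
    longitude = geo$longitude, stringsAsFactors = FALSE))

  list(table = table, trees = physet, map = map, pruned = pruned,
       truth = list(ou = cfg$ou, eta_tips = eta_obs,
                    spatial_effect = geo$spatial_effect, cfg = cfg,
                    seeds = s))
}
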