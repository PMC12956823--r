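#' Parameters of the bivariate latent Ornstein-Uhlenbeck model
#'
#' The latent traits follow `d eta_t = (b + A eta_t) dt + G dW_t` along each
#' branch: `A` is the 2x2 selection matrix (diagonals: autoregressive
#' selection, must be nonpositive; off-diagonals: cross-trait selection),
#' `b` the continuous-time intercepts and `Q = G G'` the drift covariance,
#' parameterized by positive scales `sigma` and drift correlation `r`.
#' Observation layers: trait 1 is Bernoulli-logit, trait 2 cumulative-logit
#' with ordered cutpoints `alpha`. `eta_anc` is the root-state prior mean
#' (root states are drawn from `N(eta_anc, 1)` per trait).
#'
#' @param b Numeric 2-vector of intercepts.
#' @param A 2x2 selection matrix with nonpositive diagonal.
#' @param sigma Positive 2-vector of drift scales.
#' @param r Drift correlation in (-1, 1).
#' @param alpha Increasing cutpoint vector (length 4).
#' @param eta_anc Root-state prior mean (scalar, applied to both traits).
#' @return An `ou_params` object (includes the implied `Q`).
#' @export
ou_params <- function(b = c(0, 0), A = diag(-1, 2), sigma = c(1, 1),
                      r = 0, alpha = c(-1.5, -0.5, 0.5, 1.5),
                      eta_anc = 0) {
  A <- as.matrix(A)
  if (!all(dim(A) == c(2, 2))) ct_config_error("A must be 2x2")
  if (any(diag(A) > 0)) {
    ct_config_error("diagonal of A must be nonpositive (stationarity)")
  }
  if (length(sigma) != 2L || any(sigma <= 0)) {
    ct_config_error("sigma must be two positive scales")
  }
  if (abs(r) >= 1) ct_config_error("r must lie in (-1, 1)")
  if (is.unsorted(alpha, strictly = TRUE)) {
    ct_config_error("alpha must be strictly increasing")
  }
  Q <- diag(sigma) %*% matrix(c(1, r, r, 1), 2) %*% diag(sigma)
  structure(list(b = as.numeric(b), A = A, sigma = as.numeric(sigma), r = r,
                 Q = Q, alpha = as.numeric(alpha), eta_anc = eta_anc),
            class = "ou_params")
}

#' Equilibrium (stationary mean) of the OU process
#'
#' Solves `A theta + b = 0`, i.e. `theta = -A^{-1} b`.
#'
#' @param A Stable 2x2 selection matrix.
#' @param b Intercept 2-vector.
#' @return The equilibrium 2-vector.
#' @export
ou_equilibrium <- function(A, b) {
  A <- as.matrix(A)
  if (abs(det(A)) < 1e-12) {
    ct_numeric_error("A is singular: no unique equilibrium")
  }
  if (!ou_is_stable(A)) {
    ct_numeric_error("A is not stable (eigenvalues must have negative real part)")
  }
  drop(solve(A, -b))
}

# 2x2 stability: both eigenvalues have negative real part iff tr < 0, det > 0
ou_is_stable <- function(A) {
  (A[1, 1] + A[2, 2]) < 0 && (A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]) > 0
}

#' Stationary covariance of the OU process
#'
#' Solves the continuous Lyapunov equation `A S + S A' + Q = 0` by
#' vectorization.
#'
#' @param A Stable 2x2 selection matrix.
#' @param Q Drift covariance (2x2, PSD).
#' @return The stationary covariance matrix.
#' @export
ou_stationary_cov <- function(A, Q) {
  if (!ou_is_stable(A)) ct_numeric_error("A is not stable")
  M <- kronecker(diag(2), A) + kronecker(A, diag(2))
  S <- matrix(solve(M, -as.vector(Q)), 2, 2)
  (S + t(S)) / 2
}

#' Transition moments of the OU process over a branch
#'
#' Conditional on the parent state, the child state after time `dt` is
#' Gaussian with mean `theta + expm(A dt) (eta_parent - theta)` and
#' covariance `S - expm(A dt) S expm(A dt)'` where `S` is the stationary
#' covariance. The matrix exponential is evaluated with `Matrix::expm`
#' (independent of the compiled closed form used in fitting).
#'
#' @param params An [ou_params].
#' @param dt Nonnegative branch length.
#' @param eta_parent Parent latent state (2-vector).
#' @return List with `mean` (2-vector) and `cov` (2x2).
#' @export
ou_transition_moments <- function(params, dt, eta_parent) {
  stopifnot(inherits(params, "ou_params"))
  if (dt < 0) ct_config_error("dt must be nonnegative")
  if (!ou_is_stable(params$A)) ct_numeric_error("A is not stable")
  E <- as.matrix(Matrix::expm(params$A * dt))
  S <- ou_stationary_cov(params$A, params$Q)
  theta <- ou_equilibrium(params$A, params$b)
  list(mean = drop(theta + E %*% (eta_parent - theta)),
       cov = S - E %*% S %*% t(E))
}

# log density of a bivariate normal
ldmvn2 <- function(x, m, V) {
  dV <- V[1, 1] * V[2, 2] - V[1, 2]^2
  if (!is.finite(dV) || dV <= 0) return(-Inf)
  d <- x - m
  quad <- (V[2, 2] * d[1]^2 - 2 * V[1, 2] * d[1] * d[2] +
             V[1, 1] * d[2]^2) / dV
  -log(2 * pi) - 0.5 * log(dV) - 0.5 * quad
}

#' Joint log density of latent states and observations on a tree
#'
#' Reference (pure R) implementation of the model's unnormalized joint
#' density for fixed parameters and a full set of latent node states: the
#' sum of (i) the root prior `N(eta_anc, 1)` per trait, (ii) branchwise OU
#' transition log densities of each child given its parent, and (iii) tip
#' observation log likelihoods (Bernoulli-logit for the binary trait,
#' cumulative-logit for the ordinal trait). Missing tip observations
#' contribute nothing. Branch lengths should already be floored; zero-length
#' branches with differing parent/child states give `-Inf`.
#'
#' @param tree A rooted `phylo` whose tips are labelled by society id.
#' @param params An [ou_params].
#' @param eta Matrix `(n_tips + n_internal) x 2` of latent states in ape
#'   node numbering.
#' @param table A [society_table].
#' @param trait Name of the ordinal trait column.
#' @param spatial_effects Optional `n_tips x 2` matrix of per-society
#'   offsets added to the observational predictors.
#' @return The log density (scalar).
#' @export
tree_latent_loglik <- function(tree, params, eta, table,
                               trait = "political_complexity",
                               spatial_effects = NULL) {
  stopifnot(inherits(params, "ou_params"))
  ntips <- length(tree$tip.label)
  N <- ntips + tree$Nnode
  if (!is.matrix(eta) || nrow(eta) != N || ncol(eta) != 2) {
    ct_validation_error(paste0("eta must be a ", N, " x 2 matrix"))
  }
  root <- ntips + 1L
  ll <- sum(stats::dnorm(eta[root, ], params$eta_anc, 1, log = TRUE))
  S <- ou_stationary_cov(params$A, params$Q)
  theta <- ou_equilibrium(params$A, params$b)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    t_e <- tree$edge.length[e]
    if (t_e <= 0) {
      if (any(eta[ch, ] != eta[par, ])) return(-Inf)
      next
    }
    E <- as.matrix(Matrix::expm(params$A * t_e))
    m <- drop(theta + E %*% (eta[par, ] - theta))
    V <- S - E %*% S %*% t(E)
    ll <- ll + ldmvn2(eta[ch, ], m, V)
  }
  idx <- match(tree$tip.label, table$society_id)
  if (anyNA(idx)) {
    ct_alignment_error(paste0("table lacks society id(s): ",
      paste(tree$tip.label[is.na(idx)], collapse = ", ")))
  }
  off <- spatial_effects %||% matrix(0, ntips, 2)
  kava <- table$kava[idx]
  ordv <- table[[trait]][idx]
  for (i in seq_len(ntips)) {
    mu1 <- eta[i, 1] + off[i, 1]
    mu2 <- eta[i, 2] + off[i, 2]
    if (!is.na(kava[i])) {
      ll <- ll + kava[i] * mu1 - log1pexp(mu1)
    }
    if (!is.na(ordv[i])) {
      p <- ordinal_category_probs(mu2, params$alpha)[1, ordv[i] + 1L]
      ll <- ll + log(max(p, 1e-300))
    }
  }
  ll
}

#' Specification for a coevolution fit
#'
#' @param trait Ordinal trait name (the binary trait is always kava).
#' @param spatial_control Add Matern 3/2 Gaussian-process intercepts to the
#'   observational predictors of both traits.
#' @param rho Spatial decay length (normalized-distance scale), used when
#'   `spatial_control` is `TRUE`.
#' @param root_prior `"informed"` puts the root-state prior at
#'   `N(-2, 1)` per trait (ancestral societies unlikely to have either
#'   trait); `"default"` uses `N(0, 1)`.
#' @param fix_spatial_scale Optional fixed value for both spatial GP scales
#'   (e.g. 0 to verify that the controlled model collapses onto the
#'   uncontrolled one); `NULL` estimates them.
#' @return A `coevolution_spec`.
#' @export
coevolution_spec <- function(trait = "political_complexity",
                             spatial_control = FALSE, rho = 0.02,
                             root_prior = c("informed", "default"),
                             fix_spatial_scale = NULL) {
  root_prior <- match.arg(root_prior)
  structure(list(trait = trait, spatial_control = spatial_control,
                 rho = rho, root_prior = root_prior,
                 root_mean = if (root_prior == "informed") -2 else 0,
                 fix_spatial_scale = fix_spatial_scale),
            class = "coevolution_spec")
}

# BFS preorder plus parent/branch-length arrays for the compiled core.
# Rescales the tree to unit height and floors branch lengths at
# floor_frac of tree height to avoid singular transitions.
build_tree_arrays <- function(tree, floor_frac = 1e-6) {
  tree <- rescale_tree_height(tree)
  ntips <- length(tree$tip.label)
  N <- ntips + tree$Nnode
  root <- ntips + 1L
  parent <- integer(N); parent[root] <- root
  blen <- numeric(N)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    parent[ch] <- tree$edge[e, 1]
    blen[ch] <- max(tree$edge.length[e], floor_frac)
  }
  kids <- split(tree$edge[, 2], factor(tree$edge[, 1], levels = seq_len(N)))
  preorder <- integer(N); preorder[1] <- root
  head <- 1L; cnt <- 1L
  while (head <= cnt) {
    for (ch in kids[[preorder[head]]]) {
      cnt <- cnt + 1L
      preorder[cnt] <- ch
    }
    head <- head + 1L
  }
  list(parent = parent - 1L, blen = blen, preorder = preorder - 1L,
       ntips = ntips, N = N, tip_labels = tree$tip.label, tree = tree)
}

# Interleaved sampler for one tree: adaptive random-walk Metropolis on the
# global OU parameters, Hamiltonian updates (with step-size and diagonal
# mass adaptation) on the non-centered innovations, cutpoints and spatial
# innovations.
sample_coev_tree <- function(arr, obs, spec, sc, Lspat = NULL) {
  N <- arr$N; ntips <- arr$ntips
  spatial <- isTRUE(spec$spatial_control)
  dx <- 2L * N + 4L + if (spatial) 2L * ntips else 0L
  iu <- seq_len(2L * N)
  ic <- 2L * N + 1:4
  is_ <- if (spatial) 2L * N + 4L + seq_len(2L * ntips) else integer(0)
  fix_sg <- spec$fix_spatial_scale
  est_sg <- spatial && is.null(fix_sg)
  ng <- 9L + if (est_sg) 2L else 0L
  Lsp <- if (spatial) Lspat else matrix(0, 0, 0)

  g_constrain <- function(gv) {
    c(gv[1], gv[2], -exp(gv[3]), -exp(gv[4]), gv[5], gv[6],
      exp(gv[7]), exp(gv[8]), tanh(gv[9]))
  }
  prior_g <- function(gv) {
    r <- tanh(gv[9])
    lp <- -sum(gv[1:2]^2) / 2 -
      (exp(2 * gv[3]) + exp(2 * gv[4])) / 2 + gv[3] + gv[4] -
      sum(gv[5:6]^2) / 8 -
      (exp(2 * gv[7]) + exp(2 * gv[8])) / 2 + gv[7] + gv[8] +
      4 * log1p(-r^2)
    if (est_sg) {
      lp <- lp - (exp(2 * gv[10]) + exp(2 * gv[11])) / 2 + gv[10] + gv[11]
    }
    lp
  }

  eval_x <- function(x, gv, want_grad = TRUE) {
    raw <- x[ic]
    cuts <- cumsum(c(raw[1], exp(raw[-1])))
    sg <- if (est_sg) exp(gv[10:11])
          else if (spatial) rep(fix_sg, 2) else c(0, 0)
    res <- cpp_ou_eval(x[iu], cuts, g_constrain(gv), spec$root_mean,
                       arr$parent, arr$blen, arr$preorder,
                       obs$kava, obs$ordv, want_grad, Lsp,
                       if (spatial) x[is_] else numeric(0),
                       sg[1], sg[2], spatial)
    if (!isTRUE(res$stable)) return(list(lp = -Inf))
    lp <- res$ll - sum(x[iu]^2) / 2 - sum(cuts^2) / 8 + sum(raw[-1])
    if (spatial) lp <- lp - sum(x[is_]^2) / 2
    out <- list(lp = lp, eta_tips = res$eta_tips,
                eta_nodes = res$eta_nodes)
    if (want_grad) {
      g <- numeric(dx)
      g[iu] <- res$grad_u - x[iu]
      gc <- res$grad_cuts - cuts / 4
      gcut <- numeric(4)
      gcut[1] <- sum(gc)
      for (j in 2:4) gcut[j] <- exp(raw[j]) * sum(gc[j:4]) + 1
      g[ic] <- gcut
      if (spatial) g[is_] <- res$grad_uspat - x[is_]
      out$grad <- g
    }
    out
  }

  W <- sc$warmup; M <- sc$iter; Lf <- sc$leapfrog
  x <- stats::rnorm(dx, 0, 0.1)
  x[ic] <- c(-1.5, 0, 0, 0) + stats::rnorm(4, 0, 0.05)
  gv <- c(0, 0, log(0.7), log(0.7), 0, 0, log(0.7), log(0.7), 0,
          if (est_sg) c(log(0.3), log(0.3)))
  gv <- gv + stats::rnorm(ng, 0, 0.05)
  rwst <- rw_state_new(ng, scale = 0.05)
  rwst_c <- rw_state_new(9L, scale = 0.05)
  cur <- eval_x(x, gv, TRUE)
  if (!is.finite(cur$lp)) ct_numeric_error("bad initialization")

  step <- 0.05
  mu_da <- log(10 * step); H_bar <- 0; log_step_bar <- log(step)
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  inv_mass <- rep(1, dx)
  collect <- matrix(0, W, dx)
  m1 <- max(2L, floor(0.5 * W)); m2 <- max(3L, floor(0.9 * W))

  n_keep <- M
  glob_draws <- matrix(0, n_keep, 9 + if (spatial) 2 else 0)
  sg_fixed <- if (spatial && !is.null(fix_sg)) rep(fix_sg, 2) else NULL
  cut_draws <- matrix(0, n_keep, 4)
  eta_draws <- array(0, c(n_keep, ntips, 2))
  acc_h <- 0; n_div <- 0L

  for (it in seq_len(W + M)) {
    lp_g <- function(gg) {
      r <- eval_x(x, gg, want_grad = FALSE)
      r$lp + prior_g(gg)
    }
    lpg_cur <- cur$lp + prior_g(gv)
    for (rep in seq_len(sc$rw_reps)) {
      st <- rw_step(gv, lpg_cur, lp_g, rwst, adapt = it <= W)
      gv <- st$x; lpg_cur <- st$lp; rwst <- st$state
    }
    cur <- eval_x(x, gv, TRUE)

    one <- hmc_one(function(q) eval_x(q, gv, TRUE), x, cur, step,
                   inv_mass, Lf)
    x <- one$q; cur <- one$cur

    # interweaved (ASIS) centered update: move the OU globals with the
    # latent states held fixed, then map back to innovations so the
    # non-centered state stays consistent
    eta_nodes <- cur$eta_nodes
    lp_c_fn <- function(g9) {
      gg <- gv; gg[1:9] <- g9
      res <- cpp_ou_centered_ll(eta_nodes, g_constrain(gg),
                                spec$root_mean, arr$parent, arr$blen,
                                arr$preorder)
      if (!isTRUE(res$stable)) return(-Inf)
      res$ll + prior_g(gg)
    }
    lpc_cur <- lp_c_fn(gv[1:9])
    moved <- FALSE
    for (rep in seq_len(sc$rw_reps)) {
      st <- rw_step(gv[1:9], lpc_cur, lp_c_fn, rwst_c, adapt = it <= W)
      if (any(st$x != gv[1:9])) moved <- TRUE
      gv[1:9] <- st$x; lpc_cur <- st$lp; rwst_c <- st$state
    }
    if (moved) {
      x[iu] <- cpp_ou_u_from_eta(eta_nodes, g_constrain(gv),
                                 spec$root_mean, arr$parent, arr$blen,
                                 arr$preorder)
      cur <- eval_x(x, gv, TRUE)
    }

    if (it <= W) {
      frac <- 1 / (it + t0)
      H_bar <- (1 - frac) * H_bar + frac * (0.8 - one$alpha)
      log_step <- mu_da - sqrt(it) / gamma * H_bar
      step <- exp(log_step)
      eta_w <- it^(-kappa)
      log_step_bar <- eta_w * log_step + (1 - eta_w) * log_step_bar
      collect[it, ] <- x
      if (it == m1 || it == m2) {
        lo <- if (it == m1) max(1L, floor(0.15 * W)) else m1 + 1L
        if (it - lo > 10L) {
          v <- apply(collect[lo:it, , drop = FALSE], 2, stats::var)
          v[v <= 0 | !is.finite(v)] <- 1e-6
          inv_mass <- v
        }
        mu_da <- log(10 * exp(log_step_bar)); H_bar <- 0
      }
      if (it == W) step <- exp(log_step_bar)
    } else {
      k <- it - W
      gcon <- g_constrain(gv)
      glob_draws[k, seq_len(9)] <- gcon
      if (spatial) {
        glob_draws[k, 10:11] <- if (est_sg) exp(gv[10:11]) else sg_fixed
      }
      raw <- x[ic]
      cut_draws[k, ] <- cumsum(c(raw[1], exp(raw[-1])))
      eta_draws[k, , ] <- cur$eta_tips
      acc_h <- acc_h + one$alpha
      if (one$divergent) n_div <- n_div + 1L
    }
  }
  list(globals = glob_draws, cuts = cut_draws, eta = eta_draws,
       accept_hmc = acc_h / M,
       accept_rw = rwst$accepts / rwst$tries,
       n_divergent = n_div, step = step)
}

#' Fit the generalized dynamic phylogenetic (coevolution) model
#'
#' Latent bivariate OU coevolution along each tree with Bernoulli (kava) and
#' cumulative-logit (ordinal trait) observation layers. Priors follow the
#' printed model: `b ~ N(0,1)`, diagonal of `A` negative-half-Normal(0,1),
#' off-diagonals `N(0,2)`, `sigma ~ N+(0,1)`, drift correlation
#' `LKJ(4)`-equivalent, cutpoints `N(0,2)` ordered, root states
#' `N(eta_anc, 1)`. Trees are rescaled to unit height (rates are per tree
#' height) with a branch-length floor of 1e-6. The model is fitted per tree
#' and per-tree posteriors are pooled by concatenation with equal weight.
#'
#' Sampling alternates adaptive random-walk Metropolis updates of the global
#' OU parameters with Hamiltonian updates of the non-centered latent states
#' (and cutpoints / spatial innovations); divergent Hamiltonian transitions
#' are counted and reported.
#'
#' @param table A [society_table] containing `kava` and the ordinal trait.
#' @param trees A [phylo_set] with tips labelled by society id.
#' @param spec A [coevolution_spec].
#' @param sampler_cfg Named list overriding `warmup`, `iter`, `leapfrog`
#'   and `rw_reps` (Metropolis sub-steps of the global block per
#'   iteration).
#' @param n_trees Optional cap on the number of trees used.
#' @param seed Integer seed.
#' @return A `ct_coevolution_fit`: `draws` (data.frame of global
#'   parameters), `eta_tips` (draw x tip x trait array of latent tip
#'   states), `summary`, `diagnostics`, `spec`, `traits`.
#' @export
fit_coevolution <- function(table, trees, spec = coevolution_spec(),
                            sampler_cfg = list(), n_trees = NULL,
                            seed = NULL) {
  stopifnot(inherits(table, "society_table"), inherits(trees, "phylo_set"),
            inherits(spec, "coevolution_spec"))
  if (!is.null(seed)) set.seed(seed)
  sc <- utils::modifyList(list(warmup = 1000L, iter = 1000L, leapfrog = 12L,
                               rw_reps = 30L),
                          sampler_cfg)
  tree_list <- trees$trees
  if (!is.null(n_trees)) {
    tree_list <- tree_list[seq_len(min(n_trees, length(tree_list)))]
  }
  Lspat <- NULL
  seed0 <- if (is.null(seed)) 1L else seed
  pooled_g <- list(); pooled_c <- list(); pooled_e <- list()
  diags <- list()
  for (ti in seq_along(tree_list)) {
    set.seed(tree_seed(tree_list[[ti]], seed0))
    arr <- build_tree_arrays(tree_list[[ti]])
    idx <- match(arr$tip_labels, table$society_id)
    if (anyNA(idx)) {
      ct_alignment_error(paste0("tree ", ti, " has unknown tip(s): ",
        paste(arr$tip_labels[is.na(idx)], collapse = ", ")))
    }
    obs <- list(
      kava = ifelse(is.na(table$kava[idx]), -1L,
                    as.integer(table$kava[idx])),
      ordv = ifelse(is.na(table[[spec$trait]][idx]), -1L,
                    as.integer(table[[spec$trait]][idx])))
    if (isTRUE(spec$spatial_control)) {
      sub <- as.data.frame(table)[idx, , drop = FALSE]
      class(sub) <- c("society_table", "data.frame")
      Ks <- spatial_covariance(sub, kernel_config(rho = spec$rho))
      Lspat <- chol_jitter(Ks$matrix)
    }
    res <- sample_coev_tree(arr, obs, spec, sc, Lspat)
    pooled_g[[ti]] <- res$globals
    pooled_c[[ti]] <- res$cuts
    pooled_e[[ti]] <- res$eta
    diags[[ti]] <- data.frame(tree = ti, accept_hmc = res$accept_hmc,
                              accept_rw = res$accept_rw,
                              n_divergent = res$n_divergent,
                              step = res$step)
  }
  G <- do.call(rbind, pooled_g)
  cn <- c("b1", "b2", "A11", "A22", "A12", "A21", "sigma1", "sigma2", "r")
  if (isTRUE(spec$spatial_control)) cn <- c(cn, "sg1", "sg2")
  colnames(G) <- cn
  cuts <- do.call(rbind, pooled_c)
  colnames(cuts) <- paste0("cut", 1:4)
  n_tot <- nrow(G)
  ntips <- dim(pooled_e[[1]])[2]
  eta <- array(0, c(n_tot, ntips, 2))
  pos <- 0L
  for (ti in seq_along(pooled_e)) {
    k <- dim(pooled_e[[ti]])[1]
    eta[pos + seq_len(k), , ] <- pooled_e[[ti]]
    pos <- pos + k
  }
  diagnostics <- do.call(rbind, diags)
  if (mean(diagnostics$n_divergent) > 0.1 * sc$iter) {
    warning("convergence warning: >10% divergent Hamiltonian transitions")
  }
  draws <- as.data.frame(cbind(G, cuts))
  structure(list(draws = draws, eta_tips = eta,
                 summary = summarize_posterior(as.matrix(draws)),
                 diagnostics = diagnostics, spec = spec,
                 traits = c("kava", spec$trait),
                 tip_labels = build_tree_arrays(tree_list[[1]])$tip_labels,
                 sampler = sc, n_trees = length(tree_list)),
            class = "ct_coevolution_fit")
}

#' @export
print.ct_coevolution_fit <- function(x, ...) {
  cat("Dynamic phylogenetic coevolution fit:",
      paste(x$traits, collapse = " x "), "\n")
  cat(x$n_trees, "tree(s),", nrow(x$draws), "pooled draws; spatial control:",
      x$spec$spatial_control, "; root prior:", x$spec$root_prior, "\n")
  print(x$summary[x$summary$parameter %in%
                    c("A12", "A21", "sigma1", "sigma2", "r"), ], digits = 3)
  invisible(x)
}

#' Standardized equilibrium shift (delta-theta)
#'
#' For each posterior draw, the change in the equilibrium value of the
#' target trait when the source trait is held one standardized unit above
#' its equilibrium: `delta_theta = -A[to, from] * delta / A[to, to]`, where
#' `delta` is the robust scale (median absolute deviation by default) of
#' the source trait's latent tip states in that draw. The positive posterior
#' mass (PPM) is the fraction of draws above zero; if the cross-trait
#' selection is identically zero the PPM is reported as 0.5.
#'
#' @param fit A `ct_coevolution_fit`.
#' @param from Source trait: index (1 = binary, 2 = ordinal) or trait name.
#' @param to Target trait: index or name.
#' @param scale `"mad"` (median absolute deviation, consistency-scaled) or
#'   `"sd"`.
#' @return A `ct_delta_theta`: `draws`, `summary` (median, CI66, CI95),
#'   `ppm`, `direction`.
#' @export
delta_theta <- function(fit, from = 1, to = 2, scale = c("mad", "sd")) {
  stopifnot(inherits(fit, "ct_coevolution_fit"))
  scale <- match.arg(scale)
  if (is.character(from)) from <- match(from, fit$traits)
  if (is.character(to)) to <- match(to, fit$traits)
  if (anyNA(c(from, to)) || from == to) {
    ct_config_error("direction must name two distinct traits")
  }
  a_cross <- if (to == 2) fit$draws$A21 else fit$draws$A12
  a_self <- if (to == 2) fit$draws$A22 else fit$draws$A11
  n <- length(a_cross)
  delta <- vapply(seq_len(n), function(d) {
    v <- fit$eta_tips[d, , from]
    if (scale == "mad") stats::mad(v) else stats::sd(v)
  }, numeric(1))
  if (any(delta == 0)) {
    ct_numeric_error("degenerate latent scale: zero spread in tip states")
  }
  dtheta <- -a_cross * delta / a_self
  ppm <- if (all(a_cross == 0)) 0.5 else mean(dtheta > 0)
  nm <- paste0("dtheta_", fit$traits[from], "_to_", fit$traits[to])
  summ <- summarize_posterior(matrix(dtheta, ncol = 1,
                                     dimnames = list(NULL, nm)))
  summ$ppm <- ppm
  structure(list(draws = dtheta, summary = summ, ppm = ppm,
                 direction = c(from = fit$traits[from],
                               to = fit$traits[to]),
                 scale = scale),
            class = "ct_delta_theta")
}

#' @export
print.ct_delta_theta <- function(x, ...) {
  cat("delta-theta", x$direction["from"], "->", x$direction["to"],
      sprintf("| median %.3f, 95%% CI [%.3f, %.3f], PPM %.2f\n",
              x$summary$median, x$summary$ci95_lo, x$summary$ci95_hi,
              x$ppm))
  invisible(x)
}
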