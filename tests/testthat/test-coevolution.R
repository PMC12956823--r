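# Independent bivariate normal log density for the term-by-term oracle
# (deliberately not ldmvn2).
oracle_dmvn <- function(x, m, V) {
  as.numeric(-log(2 * pi) - 0.5 * log(det(V)) -
               0.5 * t(x - m) %*% solve(V) %*% (x - m))
}

rand_stable_A <- function() {
  repeat {
    A <- matrix(c(-runif(1, 0.3, 2), rnorm(1, 0, 0.8),
                  rnorm(1, 0, 0.8), -runif(1, 0.3, 2)), 2)
    if (coevotrait:::ou_is_stable(A)) return(A)
  }
}

test_that("ou_equilibrium solves A theta + b = 0", {
  expect_equal(ou_equilibrium(diag(-1, 2), c(0, 0)), c(0, 0))
  expect_equal(ou_equilibrium(diag(c(-1, -2)), c(2, 2)), c(2, 1))
  set.seed(1)
  for (i in 1:20) {
    A <- rand_stable_A(); b <- rnorm(2)
    th <- ou_equilibrium(A, b)
    expect_lt(sqrt(sum((A %*% th + b)^2)), 1e-10)
  }
  expect_error(ou_equilibrium(matrix(c(-1, 1, 1, -1), 2), c(1, 1)),
               class = "ct_numeric_error")  # singular
  expect_error(ou_equilibrium(matrix(c(-1, 3, 3, -1), 2), c(1, 1)),
               class = "ct_numeric_error")  # saddle (unstable)
})

test_that("ou_stationary_cov solves the Lyapunov equation", {
  expect_equal(ou_stationary_cov(diag(-1, 2), diag(2)), diag(0.5, 2))
  set.seed(2)
  for (i in 1:20) {
    A <- rand_stable_A()
    sig <- runif(2, 0.3, 2); r <- runif(1, -0.8, 0.8)
    Q <- diag(sig) %*% matrix(c(1, r, r, 1), 2) %*% diag(sig)
    S <- ou_stationary_cov(A, Q)
    expect_lt(max(abs(A %*% S + S %*% t(A) + Q)), 1e-10)
    expect_gt(min(eigen(S, symmetric = TRUE)$values), 0)
  }
})

test_that("ou_transition_moments limits and one Euler-Maruyama check", {
  p <- ou_params(b = c(0.5, -0.3), A = matrix(c(-1.2, 0.6, 0.3, -0.9), 2),
                 sigma = c(0.8, 1.1), r = 0.4)
  m0 <- ou_transition_moments(p, 0, c(1, -1))
  expect_equal(m0$mean, c(1, -1))
  expect_equal(m0$cov, matrix(0, 2, 2), tolerance = 1e-12)

  pI <- ou_params(b = c(0, 0), A = diag(-1, 2), sigma = c(1, 1), r = 0)
  mL <- ou_transition_moments(pI, 50, c(3, -3))
  expect_equal(mL$cov, diag(0.5, 2), tolerance = 1e-10)
  expect_equal(mL$mean, c(0, 0), tolerance = 1e-10)

  # simulation oracle at dt = 0.3 (full 50-set sweep in the acceptance suite)
  mo <- ou_transition_moments(p, 0.3, c(1, -1))
  set.seed(3)
  npath <- 4e4; h <- 1e-3
  eta <- matrix(rep(c(1, -1), each = npath), npath, 2)
  G <- t(chol(p$Q))
  for (s in seq_len(300)) {
    eta <- eta + (matrix(p$b, npath, 2, byrow = TRUE) + eta %*% t(p$A)) * h +
      sqrt(h) * matrix(rnorm(2 * npath), npath, 2) %*% t(G)
  }
  se_m <- apply(eta, 2, sd) / sqrt(npath)
  expect_true(all(abs(colMeans(eta) - mo$mean) < 3 * se_m))
  emp <- cov(eta)
  se_v <- sqrt((diag(mo$cov) %o% diag(mo$cov) + mo$cov^2) / npath)
  expect_true(all(abs(emp - mo$cov) < 3 * se_v))

  expect_error(ou_transition_moments(p, -1, c(0, 0)),
               class = "ct_config_error")
})

test_that("compiled core agrees with the R joint density exactly", {
  # change of variables: joint density of latent states equals the
  # non-centered observation term plus standard-normal innovation density
  # minus the log Jacobian of the innovation-to-state map
  set.seed(4)
  p <- ou_params(b = c(0.5, -0.3), A = matrix(c(-1.2, 0.6, 0.3, -0.9), 2),
                 sigma = c(0.8, 1.1), r = 0.4, eta_anc = -2)
  tree <- simulate_tree(12, seed = 5)
  arr <- coevotrait:::build_tree_arrays(tree)
  kava <- c(rep(c(0L, 1L), 5), -1L, 1L)
  ordv <- c(sample(0:4, 11, replace = TRUE), -1L)
  u <- rnorm(2 * arr$N, 0, 0.5)
  g <- c(p$b, diag(p$A), p$A[1, 2], p$A[2, 1], p$sigma, p$r)
  res <- coevotrait:::cpp_ou_eval(u, p$alpha, g, -2, arr$parent, arr$blen,
                                  arr$preorder, kava, ordv, FALSE,
                                  matrix(0, 0, 0), numeric(0), 0, 0, FALSE)
  tab <- society_table(data.frame(
    society_id = arr$tip_labels, language_taxon = arr$tip_labels,
    kava = ifelse(kava < 0, NA, kava),
    political_complexity = ifelse(ordv < 0, NA, ordv),
    social_stratification = 0L, atoll_raw = 0, latitude = 0,
    longitude = seq_len(12)))
  llR <- tree_latent_loglik(arr$tree, p, res$eta_nodes, tab,
                            trait = "political_complexity")
  S <- ou_stationary_cov(p$A, p$Q)
  logJ <- 0
  root <- 13L
  for (k in seq_len(arr$N)) {
    if (k == root) next
    E <- as.matrix(Matrix::expm(p$A * arr$blen[k]))
    V <- S - E %*% S %*% t(E)
    logJ <- logJ + 0.5 * determinant(V)$modulus
  }
  expect_equal(llR, as.numeric(res$ll + sum(dnorm(u, log = TRUE)) - logJ),
               tolerance = 1e-10)
})

test_that("compiled gradients match finite differences (incl. spatial)", {
  set.seed(6)
  tree <- simulate_tree(9, seed = 7)
  arr <- coevotrait:::build_tree_arrays(tree)
  kava <- c(0L, 1L, 1L, 0L, -1L, 1L, 0L, 1L, 0L)
  ordv <- c(0L, 2L, 4L, 1L, 3L, -1L, 2L, 0L, 4L)
  cuts <- c(-1, -0.3, 0.4, 1)
  g <- c(0.5, -0.3, -1.2, -0.9, 0.3, 0.6, 0.8, 1.1, 0.4)
  Lspat <- t(chol(matern32(as.matrix(dist(seq_len(9)) / 9),
                           kernel_config(rho = 0.3)) + diag(1e-9, 9)))
  u <- rnorm(2 * arr$N, 0, 0.5)
  uspat <- rnorm(18, 0, 0.5)
  ev <- function(uu, cc, us) {
    coevotrait:::cpp_ou_eval(uu, cc, g, -2, arr$parent, arr$blen,
                             arr$preorder, kava, ordv, FALSE, Lspat, us,
                             0.7, 0.5, TRUE)$ll
  }
  r0 <- coevotrait:::cpp_ou_eval(u, cuts, g, -2, arr$parent, arr$blen,
                                 arr$preorder, kava, ordv, TRUE, Lspat,
                                 uspat, 0.7, 0.5, TRUE)
  e <- 1e-6
  fd_u <- vapply(seq_along(u), function(i) {
    up <- u; up[i] <- up[i] + e; (ev(up, cuts, uspat) - r0$ll) / e
  }, numeric(1))
  expect_lt(max(abs(fd_u - r0$grad_u)), 1e-4)
  fd_c <- vapply(1:4, function(i) {
    cp <- cuts; cp[i] <- cp[i] + e; (ev(u, cp, uspat) - r0$ll) / e
  }, numeric(1))
  expect_lt(max(abs(fd_c - as.numeric(r0$grad_cuts))), 1e-4)
  fd_s <- vapply(seq_along(uspat), function(i) {
    sp <- uspat; sp[i] <- sp[i] + e; (ev(u, cuts, sp) - r0$ll) / e
  }, numeric(1))
  expect_lt(max(abs(fd_s - as.numeric(r0$grad_uspat))), 1e-4)
})

test_that("tree_latent_loglik equals a hand-assembled three-term sum", {
  tree <- ape::read.tree(
    text = "(((t1:0.3,t2:0.3):0.4,t3:0.7):0.3,(t4:0.5,t5:0.5):0.5);")
  p <- ou_params(b = c(0.2, -0.1), A = matrix(c(-1, 0.5, 0.2, -0.8), 2),
                 sigma = c(0.9, 1.2), r = 0.3,
                 alpha = c(-1, -0.2, 0.6, 1.4), eta_anc = -2)
  set.seed(8)
  eta <- matrix(rnorm(18, 0, 1), 9, 2)
  tab <- society_table(data.frame(
    society_id = paste0("t", 1:5), language_taxon = paste0("t", 1:5),
    kava = c(1L, 0L, NA, 1L, 0L),
    political_complexity = c(0L, 2L, 4L, NA, 3L),
    social_stratification = 0L, atoll_raw = 0, latitude = 0,
    longitude = 1:5))
  got <- tree_latent_loglik(tree, p, eta, tab)

  S <- ou_stationary_cov(p$A, p$Q)
  theta <- ou_equilibrium(p$A, p$b)
  # (i) root prior
  hand <- sum(dnorm(eta[6, ], -2, 1, log = TRUE))
  # (ii) branchwise transitions
  for (ed in seq_len(nrow(tree$edge))) {
    par <- tree$edge[ed, 1]; ch <- tree$edge[ed, 2]
    E <- as.matrix(Matrix::expm(p$A * tree$edge.length[ed]))
    m <- theta + E %*% (eta[par, ] - theta)
    V <- S - E %*% S %*% t(E)
    hand <- hand + oracle_dmvn(eta[ch, ], m, V)
  }
  # (iii) tip observations
  for (i in 1:5) {
    k <- tab$kava[i]; y <- tab$political_complexity[i]
    if (!is.na(k)) {
      pk <- plogis(eta[i, 1])
      hand <- hand + log(if (k == 1) pk else 1 - pk)
    }
    if (!is.na(y)) {
      cdf <- c(-Inf, p$alpha, Inf)
      hand <- hand + log(plogis(cdf[y + 2] - eta[i, 2]) -
                           plogis(cdf[y + 1] - eta[i, 2]))
    }
  }
  expect_equal(got, hand, tolerance = 1e-10)
})

test_that("degenerate trees are handled: zero branches and single tips", {
  p <- ou_params(sigma = c(1, 1))
  z <- ape::read.tree(text = "((A:0,B:1):1,C:2);")
  tab <- society_table(data.frame(
    society_id = c("A", "B", "C"), language_taxon = c("A", "B", "C"),
    kava = 1L, political_complexity = 2L, social_stratification = 0L,
    atoll_raw = 0, latitude = 0, longitude = 1:3))
  eta <- matrix(seq(-1, 1, length.out = 10), 5, 2)
  expect_identical(tree_latent_loglik(z, p, eta, tab), -Inf)
  # the fitting path floors branch lengths instead
  arr <- coevotrait:::build_tree_arrays(z)
  expect_true(all(arr$blen[-4] > 0))

  single <- ape::read.tree(text = "(A:1);")
  tabA <- tab[1, , drop = FALSE]
  class(tabA) <- c("society_table", "data.frame")
  etaA <- matrix(c(0.5, -1, 0.2, 0.3), 2, 2)
  got <- tree_latent_loglik(single, p, etaA, tabA)
  S <- ou_stationary_cov(p$A, p$Q)
  E <- as.matrix(Matrix::expm(p$A))
  m <- drop(E %*% etaA[2, ])  # theta = 0 here
  V <- S - E %*% S %*% t(E)
  hand <- sum(dnorm(etaA[2, ], 0, 1, log = TRUE)) +
    oracle_dmvn(etaA[1, ], m, V) +
    log(plogis(etaA[1, 1])) +
    log(plogis(p$alpha[3] - etaA[1, 2]) - plogis(p$alpha[2] - etaA[1, 2]))
  expect_equal(got, hand, tolerance = 1e-10)
})

test_that("delta_theta closed form, antisymmetry, and quantile oracle", {
  fake_fit <- function(a12, a21, eta_vals) {
    n <- length(a21)
    eta <- array(0, c(n, length(eta_vals), 2))
    for (d in seq_len(n)) { eta[d, , 1] <- eta_vals; eta[d, , 2] <- eta_vals }
    structure(list(
      draws = data.frame(b1 = 0, b2 = 0, A11 = -1, A22 = -1,
                         A12 = a12, A21 = a21, sigma1 = 1, sigma2 = 1,
                         r = 0),
      eta_tips = eta, traits = c("kava", "political_complexity"),
      spec = coevolution_spec()), class = "ct_coevolution_fit")
  }
  # delta = 1 exactly: mad(c(-x, x)) = 1.4826 x
  v <- c(-1, 1) / 1.4826
  f <- fake_fit(a12 = 0, a21 = 1, eta_vals = v)
  d12 <- delta_theta(f, 1, 2)
  expect_equal(d12$draws, 1, tolerance = 1e-12)
  expect_equal(d12$ppm, 1)
  # A_ji = 0 draws: delta identically 0 and PPM reported as 0.5
  f0 <- fake_fit(a12 = 0, a21 = 0, eta_vals = v)
  d0 <- delta_theta(f0, 1, 2)
  expect_true(all(d0$draws == 0))
  expect_equal(d0$ppm, 0.5)

  set.seed(9)
  a21 <- rnorm(1000)
  fplus <- fake_fit(0, a21, v)
  fminus <- fake_fit(0, -a21, v)
  expect_equal(delta_theta(fplus, 1, 2)$draws,
               -delta_theta(fminus, 1, 2)$draws, tolerance = 1e-12)

  # brute-force quantile oracle on the summary
  dd <- delta_theta(fplus, 1, 2)
  s <- sort(dd$draws)
  man_q <- function(p) {
    h <- (length(s) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  expect_equal(dd$summary$median, man_q(0.5), tolerance = 1e-12)
  expect_equal(dd$summary$ci95_lo, man_q(0.025), tolerance = 1e-12)
  expect_equal(dd$summary$ci66_hi, man_q(0.83), tolerance = 1e-12)

  expect_error(delta_theta(f, 1, 1), class = "ct_config_error")
})

test_that("fit_coevolution runs, pools over trees order-invariantly", {
  params <- ou_params(b = c(0, 0), A = matrix(c(-0.7, 1, 0, -0.7), 2),
                      sigma = c(2, 2), r = 0, eta_anc = 0)
  d <- make_ou_dataset(20, params, seed = 31)
  extra <- lapply(32:33, function(s) {
    tr <- simulate_tree(20, seed = s)
    tr$tip.label <- d$tree$tip.label
    tr
  })
  fwd <- phylo_set(c(list(d$tree), extra))
  bwd <- phylo_set(c(rev(extra), list(d$tree)))
  sc <- list(warmup = 150L, iter = 150L, leapfrog = 8L, rw_reps = 10L)
  f1 <- fit_coevolution(d$table, fwd, coevolution_spec(root_prior = "default"),
                        sampler_cfg = sc, seed = 11)
  f2 <- fit_coevolution(d$table, bwd, coevolution_spec(root_prior = "default"),
                        sampler_cfg = sc, seed = 11)
  expect_equal(f1$summary$median, f2$summary$median, tolerance = 1e-12)
  expect_equal(nrow(f1$draws), 450)
  expect_true(all(c("accept_hmc", "accept_rw", "n_divergent") %in%
                    names(f1$diagnostics)))
  expect_true(all(f1$draws$A11 < 0 & f1$draws$A22 < 0))
  expect_true(all(abs(f1$draws$r) < 1))
  expect_true(all(f1$draws$cut1 < f1$draws$cut2 &
                    f1$draws$cut2 < f1$draws$cut3 &
                    f1$draws$cut3 < f1$draws$cut4))
})

test_that("round trip: simulated coevolution data recover the generator", {
  # scaled down from the 20-replicate / 100-tip design for runtime: 4
  # replicates at 60 tips, requiring >= 80% CI coverage over b, diag(A),
  # sigma (24 checks)
  params <- ou_params(b = c(0.2, -0.2),
                      A = matrix(c(-0.8, 0.6, 0.2, -0.8), 2),
                      sigma = c(1.5, 1.5), r = 0.2, eta_anc = 0)
  hits <- 0L; total <- 0L
  for (i in 1:4) {
    d <- make_ou_dataset(60, params, seed = 40 + i)
    fit <- fit_coevolution(d$table, d$trees,
                           coevolution_spec(root_prior = "default"),
                           sampler_cfg = list(warmup = 600L, iter = 600L,
                                              leapfrog = 10L,
                                              rw_reps = 20L),
                           seed = 140 + i)
    s <- fit$summary
    truth <- c(b1 = params$b[1], b2 = params$b[2],
               A11 = params$A[1, 1], A22 = params$A[2, 2],
               sigma1 = params$sigma[1], sigma2 = params$sigma[2])
    for (nm in names(truth)) {
      row <- s[s$parameter == nm, ]
      hits <- hits + (row$ci95_lo <= truth[nm] &&
                        truth[nm] <= row$ci95_hi)
      total <- total + 1L
    }
  }
  expect_gte(hits / total, 0.8)
})

test_that("spatial control with scale fixed at zero matches no control", {
  params <- ou_params(b = c(0, 0), A = matrix(c(-0.7, 1, 0, -0.7), 2),
                      sigma = c(2, 2), r = 0, eta_anc = 0)
  d <- make_ou_dataset(20, params, seed = 61)
  sc <- list(warmup = 800L, iter = 6000L, leapfrog = 8L, rw_reps = 15L)
  f_un <- fit_coevolution(d$table, d$trees,
                          coevolution_spec(root_prior = "default"),
                          sampler_cfg = sc, seed = 7)
  f_sp <- fit_coevolution(d$table, d$trees,
                          coevolution_spec(root_prior = "default",
                                           spatial_control = TRUE,
                                           fix_spatial_scale = 0),
                          sampler_cfg = sc, seed = 8)
  idx <- seq(1, 6000, by = 10)
  ks <- suppressWarnings(
    stats::ks.test(delta_theta(f_un, 1, 2)$draws[idx],
                   delta_theta(f_sp, 1, 2)$draws[idx])$statistic)
  expect_lt(ks, 0.1)
})
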