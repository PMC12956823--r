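make_ordinal_data <- function(n = 83, slope = 1, alpha = c(-1.5, -0.5, 0.5, 1.5),
                              seed = 1) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  pr <- ordinal_category_probs(slope * x, alpha)
  y <- apply(pr, 1, function(p) sample(0:4, 1, prob = p))
  society_table(data.frame(
    society_id = sprintf("s%03d", seq_len(n)),
    language_taxon = sprintf("L%03d", seq_len(n)),
    kava = x, political_complexity = y, social_stratification = 0L,
    atoll_raw = 0, latitude = runif(n, -20, 0),
    longitude = runif(n, 150, 180), stringsAsFactors = FALSE))
}

test_that("ordinal_category_probs is a proper, correctly-placed distribution", {
  set.seed(2)
  for (i in 1:20) {
    alpha <- sort(rnorm(4, 0, 2))
    mu <- rnorm(5, 0, 3)
    p <- ordinal_category_probs(mu, alpha)
    expect_true(all(p >= 0))
    expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-12)
  }
  # symmetric cutpoints at mu = 0 -> symmetric probabilities
  p0 <- ordinal_category_probs(0, c(-1, -0.4, 0.4, 1))[1, ]
  expect_equal(p0, rev(p0), ignore_attr = TRUE)
  # hand evaluation of the four logistic terms
  mu <- 2; alpha <- c(-1, 0, 1, 2)
  expect_equal(
    unname(ordinal_category_probs(mu, alpha)[1, ]),
    c(plogis(-1 - 2),
      plogis(0 - 2) - plogis(-1 - 2),
      plogis(1 - 2) - plogis(0 - 2),
      plogis(2 - 2) - plogis(1 - 2),
      1 - plogis(2 - 2)),
    tolerance = 1e-14)
  expect_error(ordinal_category_probs(0, c(1, 0, 2, 3)),
               class = "ct_validation_error")
})

test_that("regression log posterior gradient matches finite differences", {
  tab <- make_ordinal_data(25, seed = 5)
  cov <- list(phylogenetic = phylo_correlation(simulate_tree(25, seed = 6)))
  cov$phylogenetic$labels <- tab$society_id
  rownames(cov$phylogenetic$matrix) <-
    colnames(cov$phylogenetic$matrix) <- tab$society_id
  for (fam_resp in list(c("political_complexity", "kava"),
                        c("kava", "atoll"))) {
    tab2 <- binarize_atolls(tab, "half_as_atoll")
    spec <- regression_spec(fam_resp[1], fam_resp[2],
                            random_structures = "phylogenetic")
    dat <- coevotrait:::build_regression_data(tab2, spec, cov)
    lpg <- coevotrait:::regression_lp_grad(dat, spec)
    set.seed(7)
    q <- rnorm(if (spec$family == "bernoulli_logit") 1 + 1 + 1 + dat$n
               else 1 + 4 + 1 + dat$n, 0, 0.4)
    r0 <- lpg(q)
    fd <- vapply(seq_along(q), function(i) {
      e <- 1e-6; qp <- q; qp[i] <- qp[i] + e
      (lpg(qp)$lp - r0$lp) / e
    }, numeric(1))
    expect_lt(max(abs(fd - r0$grad)), 1e-4)
  }
})

test_that("null data give PPM near 0.5 and CI covering zero", {
  # a single null dataset's PPM is roughly uniform (it tracks the realized
  # sample association), so the check averages over datasets
  ppms <- numeric(3); covers <- logical(3)
  for (i in 1:3) {
    tab <- make_ordinal_data(83, slope = 0, seed = 10 + i)
    spec <- regression_spec("political_complexity", "kava",
                            sampler_cfg = list(chains = 1L, warmup = 300L,
                                               iter = 500L))
    fit <- fit_structured_regression(tab, spec, seed = 20 + i)
    s <- fit$summary[fit$summary$parameter == "kava", ]
    ppms[i] <- s$ppm
    covers[i] <- s$ci95_lo < 0 && 0 < s$ci95_hi
  }
  expect_gt(mean(ppms), 0.2)
  expect_lt(mean(ppms), 0.8)
  expect_gte(sum(covers), 2)
})

test_that("structured model with scale fixed at zero matches unstructured", {
  tab <- make_ordinal_data(60, slope = 1, seed = 13)
  cov <- list(phylogenetic = {
    tr <- simulate_tree(60, seed = 14)
    tr$tip.label <- tab$society_id[as.integer(sub("t", "", tr$tip.label))]
    phylo_correlation(tr)
  })
  sc <- list(chains = 1L, warmup = 500L, iter = 4000L)
  f_un <- fit_structured_regression(
    tab, regression_spec("political_complexity", "kava",
                         sampler_cfg = sc), seed = 15)
  f_fx <- fit_structured_regression(
    tab, regression_spec("political_complexity", "kava",
                         random_structures = "phylogenetic",
                         sampler_cfg = sc),
    cov, seed = 16, fix_sigma = 0)
  # thin to quasi-independent draws before comparing distributions
  idx <- seq(1, 4000, by = 4)
  ks <- suppressWarnings(
    stats::ks.test(f_un$draws$beta[idx, "kava"],
                   f_fx$draws$beta[idx, "kava"])$statistic)
  expect_lt(ks, 0.1)
})

test_that("predicted_contrast equals hand-computed expectation difference", {
  # single-draw posterior with known cutpoints and slope
  X <- matrix(c(1, 0, 1), ncol = 1, dimnames = list(NULL, "kava"))
  alpha <- c(-1, -0.2, 0.6, 1.4)
  beta <- 0.9
  z <- c(0.2, -0.1, 0)
  fit <- structure(list(
    spec = regression_spec("political_complexity", "kava"),
    draws = list(beta = matrix(beta, 1, 1, dimnames = list(NULL, "kava")),
                 cutpoints = matrix(alpha, 1, 4),
                 z_total = matrix(z, 1, 3)),
    data = list(X = X)), class = "ct_regression_fit")
  con <- predicted_contrast(fit, "kava")
  expectation <- function(mu) sum(0:4 * ordinal_category_probs(mu, alpha)[1, ])
  hand <- mean(vapply(z, function(zi) {
    expectation(beta + zi) - expectation(0 + zi)
  }, numeric(1)))
  expect_equal(con$draws, hand, tolerance = 1e-12)

  fit$draws$beta[1, 1] <- 0
  expect_equal(predicted_contrast(fit, "kava")$draws, 0)
  expect_error(predicted_contrast(fit, "nope"), class = "ct_config_error")
})

test_that("prior predictive ordinal draws occupy all five categories", {
  set.seed(17)
  X <- matrix(rbinom(50, 1, 0.5), ncol = 1)
  spec <- regression_spec("political_complexity", "kava")
  draws <- prior_predictive_ordinal(X, spec, n_draws = 200)
  expect_setequal(sort(unique(as.vector(draws))), 0:4)
})

test_that("alignment and configuration errors are raised", {
  tab <- make_ordinal_data(20, seed = 18)
  spec <- regression_spec("political_complexity", "kava",
                          random_structures = "phylogenetic")
  expect_error(fit_structured_regression(tab, spec, cov = list()),
               class = "ct_config_error")
  wrong <- phylo_correlation(simulate_tree(20, seed = 19))  # t1..t20 labels
  expect_error(
    fit_structured_regression(tab, spec, cov = list(phylogenetic = wrong)),
    class = "ct_alignment_error")
  expect_error(rho_sensitivity(tab, spec, numeric(0)),
               class = "ct_config_error")
  expect_error(regression_spec("kava", random_structures = "roads"),
               class = "ct_config_error")
})

test_that("rho_sensitivity with one rho reduces to a single structured fit", {
  tab <- make_ordinal_data(40, slope = 1, seed = 20)
  spec <- regression_spec("political_complexity", "kava",
                          random_structures = "spatial",
                          sampler_cfg = list(chains = 1L, warmup = 200L,
                                             iter = 200L))
  rs <- suppressMessages(rho_sensitivity(tab, spec, 0.04, seed = 21))
  expect_equal(nrow(rs$table), 1)
  spec1 <- spec; spec1$kernel_cfg$rho <- 0.04
  direct <- suppressMessages(fit_structured_regression(
    tab, spec1, list(spatial = spatial_covariance(tab,
                                                  kernel_config(rho = 0.04))),
    seed = 22))
  s <- direct$summary[direct$summary$parameter == "kava", ]
  expect_equal(rs$table$mean, s$mean, tolerance = 1e-12)
})
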