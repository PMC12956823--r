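# Simulate data under the signal model itself: correlated phylogenetic
# random effects with known scales and cross-trait correlation.
make_signal_data <- function(n, r_true, s1 = 2, s2 = 2, seed = 1) {
  tree <- simulate_tree(n, seed = seed)
  K <- phylo_correlation(tree)$matrix
  L <- t(chol(K + diag(1e-9, n)))
  set.seed(seed + 1)
  v1 <- drop(L %*% rnorm(n)); v2 <- drop(L %*% rnorm(n))
  z1 <- s1 * v1
  z2 <- s2 * (r_true * v1 + sqrt(1 - r_true^2) * v2)
  kava <- rbinom(n, 1, plogis(z1))
  y <- apply(ordinal_category_probs(z2, c(-1.5, -0.5, 0.5, 1.5)), 1,
             function(p) sample(0:4, 1, prob = p))
  df <- data.frame(society_id = tree$tip.label,
                   language_taxon = tree$tip.label, kava = kava,
                   political_complexity = y, social_stratification = 0L,
                   atoll_raw = 0, latitude = 0,
                   longitude = seq_len(n) / 10)
  list(tab = society_table(df), tree = tree,
       trees = phylo_set(tree, kind = "summary"))
}

test_that("signal model gradient matches finite differences", {
  d <- make_signal_data(12, 0.5, seed = 2)
  tab <- d$tab
  tab$kava[3] <- NA; tab$political_complexity[7] <- NA
  K <- phylo_correlation(d$tree)$matrix
  L <- t(chol(K + diag(1e-9, 12)))
  lpg <- coevotrait:::signal_lp_grad(tab$kava, tab$political_complexity, L)
  set.seed(3)
  q <- rnorm(8 + 24, 0, 0.4)
  r0 <- lpg(q)
  fd <- vapply(seq_along(q), function(i) {
    e <- 1e-6; qp <- q; qp[i] <- qp[i] + e
    (lpg(qp)$lp - r0$lp) / e
  }, numeric(1))
  expect_lt(max(abs(fd - r0$grad)), 1e-4)
})

test_that("cross-trait phylogenetic correlation is recovered", {
  # scaled down from the 10-replicate design for runtime; the pooled
  # posterior median over replicates is the quantity checked
  pooled <- unlist(lapply(1:3, function(i) {
    d <- make_signal_data(150, 0.6, seed = 100 * i)
    fit <- fit_bivariate_latent(d$tab, "political_complexity", d$trees,
                                sampler_cfg = list(warmup = 600L,
                                                   iter = 600L,
                                                   leapfrog = 20L),
                                seed = i)
    fit$draws$r
  }))
  expect_gt(median(pooled), 0.3)
  expect_lt(median(pooled), 0.85)
})

test_that("independent traits give a correlation CI covering zero", {
  d <- make_signal_data(80, 0, seed = 55)
  fit <- fit_bivariate_latent(d$tab, "political_complexity", d$trees,
                              sampler_cfg = list(warmup = 400L,
                                                 iter = 400L), seed = 5)
  s <- fit$summary[fit$summary$parameter == "r", ]
  expect_true(s$ci95_lo < 0 && 0 < s$ci95_hi)
})

test_that("lambda concentrates high for heritable traits, low when permuted", {
  d <- make_signal_data(150, 0, s1 = 5, s2 = 1.5, seed = 21)
  fit <- fit_bivariate_latent(d$tab, "political_complexity", d$trees,
                              sampler_cfg = list(warmup = 600L,
                                                 iter = 600L), seed = 1)
  lam <- phylogenetic_signal(fit, "kava")
  expect_true(all(lam$draws >= 0 & lam$draws <= 1))
  expect_gt(mean(lam$draws > 0.7), 0.5)

  set.seed(2)
  dfp <- as.data.frame(d$tab)
  perm <- sample(nrow(dfp))
  dfp$kava <- dfp$kava[perm]
  dfp$political_complexity <- dfp$political_complexity[perm]
  fitp <- fit_bivariate_latent(society_table(dfp), "political_complexity",
                               d$trees,
                               sampler_cfg = list(warmup = 600L,
                                                  iter = 600L), seed = 3)
  expect_gt(mean(fitp$draws$lambda_kava < 0.3), 0.5)
})

test_that("lambda limits hold on constructed scale draws", {
  expect_equal(lambda_from_scales(0), 0)
  expect_equal(lambda_from_scales(1e8), 1, tolerance = 1e-12)
  expect_equal(lambda_from_scales(2, sigma_resid = 0), 1)
  draws <- abs(rnorm(100))
  expect_true(all(lambda_from_scales(draws) >= 0 &
                    lambda_from_scales(draws) <= 1))
})

test_that("pooling over trees is invariant to tree order", {
  d1 <- make_signal_data(25, 0.4, seed = 7)
  extra <- lapply(8:9, function(s) {
    tr <- simulate_tree(25, seed = s)
    tr$tip.label <- d1$tree$tip.label
    tr
  })
  fwd <- phylo_set(c(list(d1$tree), extra))
  rev_ <- phylo_set(c(rev(extra), list(d1$tree)))
  sc <- list(warmup = 150L, iter = 150L)
  f1 <- fit_bivariate_latent(d1$tab, "political_complexity", fwd,
                             sampler_cfg = sc, seed = 9)
  f2 <- fit_bivariate_latent(d1$tab, "political_complexity", rev_,
                             sampler_cfg = sc, seed = 9)
  expect_equal(f1$summary$median, f2$summary$median, tolerance = 1e-12)
  expect_equal(f1$summary$ci95_lo, f2$summary$ci95_lo, tolerance = 1e-12)
})

test_that("degenerate inputs raise errors", {
  d <- make_signal_data(10, 0.3, seed = 31)
  expect_error(fit_bivariate_latent(d$tab, "no_such_trait", d$trees),
               class = "ct_config_error")
  fit <- fit_bivariate_latent(d$tab, "political_complexity", d$trees,
                              sampler_cfg = list(warmup = 80L, iter = 80L),
                              seed = 1)
  expect_error(phylogenetic_signal(fit, "social_stratification"),
               class = "ct_config_error")
})
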