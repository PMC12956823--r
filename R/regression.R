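#' Specify a structured Bayesian regression
#'
#' Ordinal responses (five levels) are modelled with a cumulative-logit
#' likelihood: the observed category arises from thresholding a latent
#' logistic variable at four ordered cutpoints. Binary responses use a
#' Bernoulli-logit likelihood. Society-level random effects structured by a
#' phylogenetic correlation matrix and/or a spatial Matern 3/2 kernel enter
#' the latent predictor additively, each with its own scale.
#'
#' Priors (regularizing, logged with every fit): slopes and intercept
#' Normal(0, 2.5); cutpoints Normal(0, 4) subject to ordering; random-effect
#' scales half-Normal(0, 1).
#'
#' @param response One of `"political_complexity"`, `"social_stratification"`,
#'   `"kava"`, `"atoll"`.
#' @param predictors Character vector of predictor columns (binary), e.g.
#'   `"kava"`, `"atoll"`.
#' @param random_structures Subset of `c("phylogenetic", "spatial")`.
#' @param family `"auto"` picks cumulative-logit for ordinal responses and
#'   Bernoulli for binary ones.
#' @param kernel_cfg A [kernel_config] used when `"spatial"` is requested.
#' @param prior_cfg Named list overriding `slope_sd`, `cut_sd`, `sigma_sd`.
#' @param sampler_cfg Named list overriding `chains`, `warmup`, `iter`,
#'   `leapfrog`.
#' @return A `regression_spec` object.
#' @export
regression_spec <- function(response,
                            predictors = "kava",
                            random_structures = character(0),
                            family = c("auto", "cumulative_logit",
                                       "bernoulli_logit"),
                            kernel_cfg = kernel_config(),
                            prior_cfg = list(),
                            sampler_cfg = list()) {
  family <- match.arg(family)
  if (family == "auto") {
    family <- if (response %in% c("kava", "atoll")) "bernoulli_logit"
              else "cumulative_logit"
  }
  bad <- setdiff(random_structures, c("phylogenetic", "spatial"))
  if (length(bad) > 0L) {
    ct_config_error(paste0("unknown random structure(s): ",
                           paste(bad, collapse = ", ")))
  }
  prior <- utils::modifyList(
    list(slope_sd = 2.5, cut_sd = 4, sigma_sd = 1), prior_cfg)
  sampler <- utils::modifyList(
    list(chains = 2L, warmup = 400L, iter = 400L, leapfrog = 15L),
    sampler_cfg)
  structure(list(response = response, predictors = predictors,
                 random_structures = random_structures, family = family,
                 kernel_cfg = kernel_cfg, prior = prior, sampler = sampler),
            class = "regression_spec")
}

#' Cumulative-logit category probabilities
#'
#' Probability of each of the five ordinal categories given a latent mean
#' `mu` and four ordered cutpoints: `P(k) = F(alpha_{k+1} - mu) -
#' F(alpha_k - mu)` with `F` the logistic CDF and boundary cutpoints at
#' minus/plus infinity. Probabilities are nonnegative and sum to one.
#'
#' @param latent_mean Numeric vector of latent means (logit scale).
#' @param alpha Increasing numeric vector of cutpoints (length 4 for five
#'   categories).
#' @return Matrix `length(latent_mean) x (length(alpha) + 1)` of category
#'   probabilities, columns named by category 0..K-1.
#' @export
ordinal_category_probs <- function(latent_mean, alpha) {
  if (is.unsorted(alpha, strictly = TRUE)) {
    ct_validation_error("cutpoints must be strictly increasing")
  }
  cuts <- c(-Inf, alpha, Inf)
  cdf <- vapply(cuts, function(a) stats::plogis(a - latent_mean),
                numeric(length(latent_mean)))
  if (is.null(dim(cdf))) cdf <- matrix(cdf, nrow = 1)
  probs <- cdf[, -1, drop = FALSE] - cdf[, -ncol(cdf), drop = FALSE]
  colnames(probs) <- as.character(seq_len(ncol(probs)) - 1L)
  probs
}

# log(1 + exp(x)) computed stably
log1pexp <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

logistic_pdf <- function(x) { p <- stats::plogis(x); p * (1 - p) }

# Assemble complete-case data and Cholesky factors for a fit. Missing
# response or predictor rows are excluded (never imputed); counts are
# reported via message() so exclusions are always visible.
build_regression_data <- function(table, spec, cov) {
  stopifnot(inherits(table, "society_table"))
  cols <- c(spec$response, spec$predictors)
  absent <- setdiff(cols, names(table))
  if (length(absent) > 0L) {
    ct_config_error(paste0("table lacks column(s): ",
                           paste(absent, collapse = ", "),
                           " (did you forget binarize_atolls()?)"))
  }
  keep <- stats::complete.cases(as.data.frame(table)[, cols, drop = FALSE])
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message("excluding ", n_drop, " row(s) with missing ",
            paste(cols, collapse = "/"))
  }
  dat <- as.data.frame(table)[keep, , drop = FALSE]
  if (nrow(dat) < 5L) ct_validation_error("fewer than 5 complete rows")
  y <- dat[[spec$response]]
  X <- as.matrix(dat[, spec$predictors, drop = FALSE])
  L_list <- list()
  for (s in spec$random_structures) {
    cv <- cov[[s]]
    if (is.null(cv)) {
      ct_config_error(paste0("random structure '", s,
                             "' requested but no covariance supplied"))
    }
    K <- align_cov(cv, dat$society_id)
    L_list[[s]] <- chol_jitter(K)
  }
  list(y = y, X = X, ids = dat$society_id, L_list = L_list,
       n_dropped = n_drop, n = nrow(dat))
}

# Log posterior and gradient closure over the unconstrained parameter
# vector. Layout: [beta (p)] [intercept (bernoulli) | cut_raw (4)]
# [per structure: log_sigma, u (n)].
regression_lp_grad <- function(dat, spec, fix_sigma = NULL) {
  y <- dat$y; X <- dat$X; n <- dat$n; p <- ncol(X)
  fam <- spec$family
  K_ord <- 4L
  slope_sd <- spec$prior$slope_sd
  cut_sd <- spec$prior$cut_sd
  structures <- spec$random_structures
  S <- length(structures)
  n_core <- p + if (fam == "bernoulli_logit") 1L else K_ord
  d_total <- n_core + S * (1L + n)

  function(q) {
    beta <- q[seq_len(p)]
    grad <- numeric(d_total)
    lp <- -sum(beta^2) / (2 * slope_sd^2)
    grad[seq_len(p)] <- -beta / slope_sd^2

    mu <- drop(X %*% beta)
    z_parts <- vector("list", S)
    sig <- numeric(S)
    for (s in seq_len(S)) {
      off <- n_core + (s - 1L) * (1L + n)
      ls <- q[off + 1L]
      u <- q[off + 1L + seq_len(n)]
      sigma <- if (!is.null(fix_sigma)) fix_sigma else exp(ls)
      v <- drop(dat$L_list[[s]] %*% u)
      z_parts[[s]] <- v
      sig[s] <- sigma
      mu <- mu + sigma * v
      # priors: u std normal; sigma half-normal(0, sigma_sd) + log-Jacobian
      lp <- lp - sum(u^2) / 2
      grad[off + 1L + seq_len(n)] <- -u
      if (is.null(fix_sigma)) {
        lp <- lp - sigma^2 / (2 * spec$prior$sigma_sd^2) + ls
        grad[off + 1L] <- -sigma^2 / spec$prior$sigma_sd^2 + 1
      }
    }

    if (fam == "bernoulli_logit") {
      b0 <- q[p + 1L]
      mu_full <- mu + b0
      lp <- lp - b0^2 / (2 * slope_sd^2) +
        sum(y * mu_full - log1pexp(mu_full))
      g_mu <- y - stats::plogis(mu_full)
      grad[p + 1L] <- sum(g_mu) - b0 / slope_sd^2
    } else {
      raw <- q[p + seq_len(K_ord)]
      cuts <- cumsum(c(raw[1], exp(raw[-1])))
      yk <- y + 1L  # categories 1..5
      cU <- c(cuts, Inf)[yk] - mu
      cL <- c(-Inf, cuts)[yk] - mu
      P <- stats::plogis(cU) - stats::plogis(cL)
      P <- pmax(P, 1e-300)
      lp <- lp + sum(log(P))
      fU <- ifelse(is.finite(cU), logistic_pdf(cU), 0)
      fL <- ifelse(is.finite(cL), logistic_pdf(cL), 0)
      g_mu <- (fL - fU) / P
      # gradient wrt the cutpoints themselves
      g_c <- numeric(K_ord)
      for (k in seq_len(K_ord)) {
        g_c[k] <- sum((fU / P)[yk == k]) - sum((fL / P)[yk == k + 1L])
      }
      g_c <- g_c - cuts / cut_sd^2
      lp <- lp - sum(cuts^2) / (2 * cut_sd^2) + sum(raw[-1])
      grad[p + 1L] <- sum(g_c)
      for (j in 2:K_ord) {
        grad[p + j] <- exp(raw[j]) * sum(g_c[j:K_ord]) + 1
      }
    }

    grad[seq_len(p)] <- grad[seq_len(p)] + drop(crossprod(X, g_mu))
    for (s in seq_len(S)) {
      off <- n_core + (s - 1L) * (1L + n)
      grad[off + 1L + seq_len(n)] <- grad[off + 1L + seq_len(n)] +
        sig[s] * drop(crossprod(dat$L_list[[s]], g_mu))
      if (is.null(fix_sigma)) {
        grad[off + 1L] <- grad[off + 1L] +
          sig[s] * sum(z_parts[[s]] * g_mu)
      }
    }
    list(lp = lp, grad = grad)
  }
}

#' Fit a structured Bayesian regression
#'
#' Samples the posterior with Hamiltonian Monte Carlo (non-centered random
#' effects), running `chains` independent chains and reporting split R-hat
#' and effective sample size for the core parameters. A warning is raised if
#' any core-parameter R-hat exceeds 1.01.
#'
#' @param table A [society_table]; rows with missing response or predictor
#'   are excluded (complete-case) with a message.
#' @param spec A [regression_spec].
#' @param cov Named list of [covariance_spec] objects keyed
#'   `"phylogenetic"` / `"spatial"`; required for each requested structure.
#' @param seed Integer RNG seed.
#' @param fix_sigma Optional fixed value for all random-effect scales
#'   (e.g. 0 to disable structure while keeping the same code path).
#' @return A `ct_regression_fit` with elements `summary` (data.frame),
#'   `draws` (list: `beta`, `cutpoints` or `intercept`, `sigma`, `z_total`),
#'   `data`, `spec`, `diagnostics`.
#' @export
fit_structured_regression <- function(table, spec, cov = list(), seed = NULL,
                                      fix_sigma = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dat <- build_regression_data(table, spec, cov)
  lpg <- regression_lp_grad(dat, spec, fix_sigma = fix_sigma)
  p <- ncol(dat$X); n <- dat$n
  fam <- spec$family
  K_ord <- 4L
  n_core <- p + if (fam == "bernoulli_logit") 1L else K_ord
  S <- length(spec$random_structures)
  d <- n_core + S * (1L + n)

  sc <- spec$sampler
  chains <- sc$chains
  ch_draws <- vector("list", chains)
  diag_list <- list()
  for (ch in seq_len(chains)) {
    init <- stats::rnorm(d, 0, 0.2)
    if (fam == "cumulative_logit") {
      init[p + seq_len(K_ord)] <- c(-1.5, rep(log(1), 3)) +
        stats::rnorm(K_ord, 0, 0.1)
    }
    fit <- run_hmc(lpg, init, n_warmup = sc$warmup, n_iter = sc$iter,
                   L = sc$leapfrog)
    ch_draws[[ch]] <- fit$draws
    diag_list[[ch]] <- c(accept = fit$accept_rate, step = fit$step,
                         divergent = fit$n_divergent)
  }
  draws <- do.call(rbind, ch_draws)

  # constrained quantities
  beta <- draws[, seq_len(p), drop = FALSE]
  colnames(beta) <- colnames(dat$X)
  if (fam == "bernoulli_logit") {
    intercept <- draws[, p + 1L]
    cutpoints <- NULL
  } else {
    raw <- draws[, p + seq_len(K_ord), drop = FALSE]
    cutpoints <- t(apply(raw, 1, function(r) cumsum(c(r[1], exp(r[-1])))))
    colnames(cutpoints) <- paste0("cut", seq_len(K_ord))
    intercept <- NULL
  }
  sigma <- NULL
  z_total <- matrix(0, nrow(draws), n)
  if (S > 0) {
    sigma <- matrix(0, nrow(draws), S,
                    dimnames = list(NULL, spec$random_structures))
    for (s in seq_len(S)) {
      off <- n_core + (s - 1L) * (1L + n)
      sg <- if (!is.null(fix_sigma)) rep(fix_sigma, nrow(draws))
            else exp(draws[, off + 1L])
      sigma[, s] <- sg
      u <- draws[, off + 1L + seq_len(n), drop = FALSE]
      z_total <- z_total + sg * (u %*% t(dat$L_list[[s]]))
    }
  }

  core <- cbind(beta,
                if (!is.null(intercept)) cbind(intercept = intercept),
                cutpoints, if (!is.null(sigma))
                  `colnames<-`(sigma, paste0("sigma_", colnames(sigma))))
  summ <- summarize_posterior(core)
  # convergence diagnostics per core parameter across chains
  rhats <- vapply(seq_len(ncol(core)), function(j) {
    split_rhat(matrix(core[, j], ncol = chains))
  }, numeric(1))
  summ$rhat <- rhats
  summ$ess <- vapply(seq_len(ncol(core)), function(j) {
    ess_basic(matrix(core[, j], ncol = chains))
  }, numeric(1))
  if (any(rhats > 1.01, na.rm = TRUE)) {
    warning("convergence warning: split R-hat > 1.01 for ",
            paste(summ$parameter[rhats > 1.01], collapse = ", "))
  }

  structure(list(summary = summ, spec = spec,
                 draws = list(beta = beta, intercept = intercept,
                              cutpoints = cutpoints, sigma = sigma,
                              z_total = z_total),
                 data = dat,
                 prior = spec$prior,
                 diagnostics = do.call(rbind, diag_list)),
            class = "ct_regression_fit")
}

#' @export
print.ct_regression_fit <- function(x, ...) {
  cat("Structured", x$spec$family, "regression:",
      x$spec$response, "~", paste(x$spec$predictors, collapse = " + "), "\n")
  if (length(x$spec$random_structures) > 0) {
    cat("random structures:",
        paste(x$spec$random_structures, collapse = ", "), "\n")
  }
  cat(x$data$n, "societies (", x$data$n_dropped, "excluded )\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Expected change on the original ordinal scale
#'
#' For each posterior draw, predicts the expected value of the response on
#' its original 0..4 scale with the predictor set to 1 and to 0 for every
#' society in the fitted sample (keeping that society's fitted random
#' effects), and averages the difference over societies. This sample-average
#' marginal contrast is the model-based analogue of comparing fitted values
#' under presence versus absence of the predictor.
#'
#' @param fit A `ct_regression_fit` from a cumulative-logit model.
#' @param predictor Name of a fitted predictor column.
#' @return A `ct_contrast`: list with `draws` (vector) and `summary`.
#' @export
predicted_contrast <- function(fit, predictor) {
  stopifnot(inherits(fit, "ct_regression_fit"))
  if (fit$spec$family != "cumulative_logit") {
    ct_config_error("predicted_contrast requires a cumulative-logit fit")
  }
  if (!predictor %in% colnames(fit$draws$beta)) {
    ct_config_error(paste0("predictor '", predictor, "' not in the model"))
  }
  X <- fit$data$X
  n_draws <- nrow(fit$draws$beta)
  kvals <- 0:4
  out <- numeric(n_draws)
  X1 <- X; X1[, predictor] <- 1
  X0 <- X; X0[, predictor] <- 0
  for (dIdx in seq_len(n_draws)) {
    b <- fit$draws$beta[dIdx, ]
    al <- fit$draws$cutpoints[dIdx, ]
    z <- fit$draws$z_total[dIdx, ]
    mu1 <- drop(X1 %*% b) + z
    mu0 <- drop(X0 %*% b) + z
    e1 <- ordinal_category_probs(mu1, al) %*% kvals
    e0 <- ordinal_category_probs(mu0, al) %*% kvals
    out[dIdx] <- mean(e1 - e0)
  }
  structure(list(draws = out,
                 summary = summarize_posterior(matrix(out, ncol = 1,
                   dimnames = list(NULL, paste0("contrast_", predictor))))),
            class = "ct_contrast")
}

#' Sensitivity of the slope to the spatial decay length
#'
#' Refits the model over a grid of Matern decay lengths `rho` and tabulates
#' the posterior of the first predictor's slope for each, making visible how
#' the estimated effect attenuates as the assumed reach of spatial
#' dependence grows.
#'
#' @param table A [society_table].
#' @param spec A [regression_spec] including `"spatial"` among its random
#'   structures.
#' @param rhos Numeric vector of decay lengths (normalized-distance scale),
#'   e.g. `c(0.02, 0.04, 0.06, 0.08)`.
#' @param cov Optional named covariance list; the spatial entry is rebuilt
#'   for each `rho`, other entries are passed through.
#' @param seed Integer seed (one fit per rho, offset per element).
#' @return List with `table` (data.frame of slope summaries per rho) and
#'   `fits`.
#' @export
rho_sensitivity <- function(table, spec, rhos, cov = list(), seed = NULL) {
  if (length(rhos) == 0L) ct_config_error("empty rho grid")
  if (!"spatial" %in% spec$random_structures) {
    ct_config_error("rho_sensitivity requires spatial structure in the spec")
  }
  fits <- vector("list", length(rhos))
  rows <- vector("list", length(rhos))
  slope_name <- spec$predictors[1]
  for (i in seq_along(rhos)) {
    cfg <- spec$kernel_cfg; cfg$rho <- rhos[i]
    spec_i <- spec; spec_i$kernel_cfg <- cfg
    cov_i <- cov
    cov_i$spatial <- spatial_covariance(table, cfg)
    fits[[i]] <- fit_structured_regression(
      table, spec_i, cov_i,
      seed = if (is.null(seed)) NULL else seed + i)
    srow <- fits[[i]]$summary
    srow <- srow[srow$parameter == slope_name, , drop = FALSE]
    srow$rho <- rhos[i]
    rows[[i]] <- srow
  }
  list(table = do.call(rbind, rows), fits = fits)
}

#' Draw ordinal responses from the prior predictive distribution
#'
#' Used to check that the regularizing priors are not degenerate: draws of
#' cutpoints and slopes should generate all five response categories.
#'
#' @param X Predictor matrix.
#' @param spec A [regression_spec] (cumulative-logit).
#' @param n_draws Number of prior draws.
#' @return Integer matrix `n_draws x nrow(X)` of simulated categories 0..4.
#' @export
prior_predictive_ordinal <- function(X, spec, n_draws = 100) {
  out <- matrix(NA_integer_, n_draws, nrow(X))
  for (i in seq_len(n_draws)) {
    alpha <- sort(stats::rnorm(4, 0, spec$prior$cut_sd))
    beta <- stats::rnorm(ncol(X), 0, spec$prior$slope_sd)
    mu <- drop(X %*% beta)
    pr <- ordinal_category_probs(mu, alpha)
    out[i, ] <- apply(pr, 1, function(p) sample(0:4, 1, prob = p))
  }
  out
}
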