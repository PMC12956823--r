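# Gradient-based posterior samplers used by every model-fitting function in
# the package: a static Hamiltonian Monte Carlo sampler with dual-averaging
# step-size adaptation and diagonal mass-matrix estimation, and an adaptive
# multivariate random-walk Metropolis kernel for small parameter blocks whose
# gradients are not available in closed form.

# lp_grad(q) must return list(lp = scalar, grad = vector). Returns a list
# with draws (n_iter x d), lp, acceptance statistics and the adapted step.
run_hmc <- function(lp_grad, init, n_warmup = 400L, n_iter = 400L,
                    L = 12L, target_accept = 0.8, step_init = 0.1,
                    max_step = Inf) {
  d <- length(init)
  q <- init
  cur <- lp_grad(q)
  if (!is.finite(cur$lp)) ct_numeric_error("HMC initial point has non-finite density")

  # dual averaging state (Hoffman-Gelman constants)
  step <- step_init
  mu <- log(10 * step_init)
  log_step_bar <- log(step_init)
  H_bar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75

  inv_mass <- rep(1, d)
  # warmup schedule: [0, .15) step only; [.15, .9) also collect for mass;
  # mass recomputed at 50% and 90%, each time resetting dual averaging.
  m1 <- max(1L, floor(0.5 * n_warmup))
  m2 <- max(2L, floor(0.9 * n_warmup))
  collect <- matrix(0, n_warmup, d)

  draws <- matrix(0, n_iter, d)
  lps <- numeric(n_iter)
  n_div <- 0L
  acc_sum <- 0; acc_n <- 0

  total <- n_warmup + n_iter
  for (it in seq_len(total)) {
    p <- stats::rnorm(d) / sqrt(inv_mass)
    q_new <- q; g_new <- cur$grad
    H0 <- cur$lp - 0.5 * sum(p^2 * inv_mass)
    steps <- sample(max(1L, floor(0.5 * L)):ceiling(1.5 * L), 1L)
    p_half <- p + 0.5 * step * g_new
    diverged <- FALSE
    for (s in seq_len(steps)) {
      q_new <- q_new + step * inv_mass * p_half
      prop <- lp_grad(q_new)
      if (!is.finite(prop$lp)) { diverged <- TRUE; break }
      g_new <- prop$grad
      if (s < steps) p_half <- p_half + step * g_new
    }
    if (!diverged) {
      p_final <- p_half + 0.5 * step * g_new
      H1 <- prop$lp - 0.5 * sum(p_final^2 * inv_mass)
      dH <- H1 - H0
      if (!is.finite(dH) || dH < -1000) { diverged <- TRUE }
    }
    if (diverged) {
      alpha <- 0
      if (it > n_warmup) n_div <- n_div + 1L
    } else {
      alpha <- min(1, exp(dH))
      if (stats::runif(1) < alpha) { q <- q_new; cur <- prop }
    }

    if (it <= n_warmup) {
      # dual averaging update
      frac <- 1 / (it + t0)
      H_bar <- (1 - frac) * H_bar + frac * (target_accept - alpha)
      log_step <- mu - sqrt(it) / gamma * H_bar
      step <- min(exp(log_step), max_step)
      eta <- it^(-kappa)
      log_step_bar <- eta * log_step + (1 - eta) * log_step_bar
      collect[it, ] <- q
      if (it == m1 || it == m2) {
        lo <- if (it == m1) max(1L, floor(0.15 * n_warmup)) else m1 + 1L
        if (it - lo > 10L) {
          v <- apply(collect[lo:it, , drop = FALSE], 2, stats::var)
          v[v <= 0 | !is.finite(v)] <- 1e-6
          inv_mass <- v
        }
        mu <- log(10 * min(exp(log_step_bar), max_step))
        H_bar <- 0
      }
      if (it == n_warmup) step <- min(exp(log_step_bar), max_step)
    } else {
      draws[it - n_warmup, ] <- q
      lps[it - n_warmup] <- cur$lp
      acc_sum <- acc_sum + alpha; acc_n <- acc_n + 1
    }
  }
  list(draws = draws, lp = lps, accept_rate = acc_sum / max(1, acc_n),
       step = step, n_divergent = n_div)
}

# One Hamiltonian trajectory (jittered leapfrog count) from current state.
# cur must be lp_grad(q). Returns updated q/cur, the acceptance probability
# and a divergence flag.
hmc_one <- function(lp_grad, q, cur, step, inv_mass, L) {
  d <- length(q)
  p <- stats::rnorm(d) / sqrt(inv_mass)
  H0 <- cur$lp - 0.5 * sum(p^2 * inv_mass)
  steps <- sample(max(1L, floor(0.5 * L)):ceiling(1.5 * L), 1L)
  qn <- q; gn <- cur$grad
  ph <- p + 0.5 * step * gn
  div <- FALSE; prop <- NULL
  for (s in seq_len(steps)) {
    qn <- qn + step * inv_mass * ph
    prop <- lp_grad(qn)
    if (!is.finite(prop$lp)) { div <- TRUE; break }
    gn <- prop$grad
    if (s < steps) ph <- ph + step * gn
  }
  alpha <- 0
  if (!div) {
    pf <- ph + 0.5 * step * gn
    dH <- (prop$lp - 0.5 * sum(pf^2 * inv_mass)) - H0
    if (!is.finite(dH) || dH < -1000) {
      div <- TRUE
    } else {
      alpha <- min(1, exp(dH))
      if (stats::runif(1) < alpha) { q <- qn; cur <- prop }
    }
  }
  list(q = q, cur = cur, alpha = alpha, divergent = div)
}

# Adaptive multivariate random-walk Metropolis step state. Haario-style
# proposal covariance from the running empirical covariance, with
# Robbins-Monro scale adaptation targeting accept rate 0.23 during warmup.
rw_state_new <- function(d, scale = 0.1) {
  list(d = d, n = 0, mean = rep(0, d), m2 = matrix(0, d, d),
       log_scale = log(scale), chol = diag(d), accepts = 0, tries = 0)
}

rw_update_moments <- function(st, x) {
  st$n <- st$n + 1
  delta <- x - st$mean
  st$mean <- st$mean + delta / st$n
  st$m2 <- st$m2 + tcrossprod(delta, x - st$mean)
  if (st$n > 2 * st$d && st$n %% 25 == 0) {
    cv <- st$m2 / (st$n - 1) + diag(1e-8, st$d)
    ch <- tryCatch(t(chol(cv)), error = function(e) NULL)
    if (!is.null(ch)) st$chol <- ch
  }
  st
}

# One Metropolis update of x given log-posterior function; returns updated
# x, lp and state. Adaptation only while adapt = TRUE.
rw_step <- function(x, lp_x, lp_fn, st, adapt = TRUE) {
  z <- stats::rnorm(st$d)
  prop <- x + exp(st$log_scale) * drop(st$chol %*% z) * 2.38 / sqrt(st$d)
  lp_p <- lp_fn(prop)
  a <- if (is.finite(lp_p)) min(1, exp(lp_p - lp_x)) else 0
  acc <- stats::runif(1) < a
  if (acc) { x <- prop; lp_x <- lp_p }
  st$tries <- st$tries + 1; st$accepts <- st$accepts + as.numeric(acc)
  if (adapt) {
    st$log_scale <- st$log_scale + (a - 0.23) / sqrt(st$tries) * 2
    st <- rw_update_moments(st, x)
  }
  list(x = x, lp = lp_x, state = st)
}

#' Split-half R-hat convergence diagnostic
#'
#' Potential scale reduction computed after splitting each chain in half,
#' so within-chain drift inflates the statistic.
#'
#' @param x A matrix (iterations x chains) or vector of draws.
#' @return The split R-hat value.
#' @export
split_rhat <- function(x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  half <- floor(n / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  B <- half * stats::var(means)
  W <- mean(vars)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Effective sample size from autocorrelations
#'
#' Initial positive sequence estimator on pooled, centered chains.
#'
#' @param x Vector or matrix (iterations x chains) of draws.
#' @return Estimated effective sample size.
#' @export
ess_basic <- function(x) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  n <- nrow(x); m <- ncol(x)
  if (stats::var(as.vector(x)) == 0) return(n * m)
  rho <- rep(0, n - 1)
  for (ch in seq_len(m)) {
    a <- stats::acf(x[, ch], lag.max = min(n - 2, 200), plot = FALSE)$acf[-1]
    rho[seq_along(a)] <- rho[seq_along(a)] + a / m
  }
  s <- 0
  k <- 1
  while (k < length(rho)) {
    pair <- rho[k] + if (k + 1 <= length(rho)) rho[k + 1] else 0
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  max(1, n * m / (1 + 2 * s))
}
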