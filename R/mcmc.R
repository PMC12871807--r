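# Adaptive random-walk Metropolis sampler (Haario-style covariance
# adaptation with Robbins-Monro scale tuning during warmup only, so the
# post-warmup chain is a valid fixed-kernel Metropolis sampler).
#
# log_post: function(par) -> log posterior density (unnormalized)
# init: numeric start vector (unconstrained scale)
# Returns list(draws = matrix [n_draws x d], accept_rate, logpost).
adaptive_metropolis <- function(log_post, init, n_draws = 1000L,
                                warmup = 1000L, seed = 1L,
                                init_scale = 0.1) {
  d <- length(init)
  n_total <- warmup + n_draws
  with_seed(seed, {
    chain <- matrix(NA_real_, n_total, d)
    lp <- numeric(n_total)
    x <- init
    lx <- log_post(x)
    if (!is.finite(lx)) stop("log posterior not finite at the start value")
    cov_chol <- diag(init_scale, d)
    log_scale <- 0
    accept <- 0L
    for (t in seq_len(n_total)) {
      prop <- x + exp(log_scale) * drop(cov_chol %*% rnorm(d))
      lprop <- log_post(prop)
      alpha <- min(1, exp(lprop - lx))
      if (is.finite(lprop) && runif(1) < alpha) {
        x <- prop; lx <- lprop
        if (t > warmup) accept <- accept + 1L
      }
      chain[t, ] <- x
      lp[t] <- lx
      if (t <= warmup) {
        # scale toward 30% acceptance; refresh covariance periodically
        log_scale <- log_scale + (alpha - 0.3) / sqrt(t)
        if (t >= 100L && t %% 100L == 0L) {
          emp <- stats::cov(chain[max(1, t - 500):t, , drop = FALSE])
          emp <- emp * (2.38^2 / d) + diag(1e-10, d)
          ch <- tryCatch(chol(emp), error = function(e) NULL)
          if (!is.null(ch)) cov_chol <- t(ch)
        }
      }
    }
    list(draws = chain[(warmup + 1):n_total, , drop = FALSE],
         logpost = lp[(warmup + 1):n_total],
         accept_rate = accept / n_draws)
  })
}

# split-Rhat convergence diagnostic over a list of per-chain draw matrices
split_rhat <- function(chains) {
  halves <- list()
  for (ch in chains) {
    n <- nrow(ch)
    h <- floor(n / 2)
    halves <- c(halves, list(ch[1:h, , drop = FALSE],
                             ch[(h + 1):(2 * h), , drop = FALSE]))
  }
  m <- length(halves)
  n <- nrow(halves[[1]])
  d <- ncol(halves[[1]])
  vapply(seq_len(d), function(j) {
    means <- vapply(halves, function(h) mean(h[, j]), numeric(1))
    vars <- vapply(halves, function(h) var(h[, j]), numeric(1))
    W <- mean(vars)
    B <- n * var(means)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}
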