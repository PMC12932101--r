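# Adaptive random-walk Metropolis sampler used by the Bayesian fits.
#
# During warmup the proposal is a multivariate normal whose covariance is
# adapted from the chain history (Haario-style: 2.38^2/d times the running
# empirical covariance plus a small jitter), with a scalar step-size tuned
# toward ~25% acceptance. After warmup the proposal is frozen so the kept
# draws target the exact posterior.

run_metropolis <- function(log_post, init, n_warmup = 1000, n_keep = 2000,
                           n_chains = 4, thin = 1, seed = 1L) {
  d <- length(init[[1]])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  chains <- vector("list", n_chains)
  accept <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    theta <- init[[ch]]
    lp <- log_post(theta)
    if (!is.finite(lp)) {
      abort("Initial value has zero posterior density.")
    }
    scale <- 0.1
    cov_chol <- diag(d)
    hist_mat <- matrix(NA_real_, n_warmup, d)
    # warmup with adaptation
    for (i in seq_len(n_warmup)) {
      prop <- theta + scale * as.vector(cov_chol %*% rnorm(d))
      lpp <- log_post(prop)
      if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
        theta <- prop
        lp <- lpp
      }
      hist_mat[i, ] <- theta
      if (i %% 100 == 0) {
        acc <- mean(hist_mat[(i - 99):(i - 1), 1] != hist_mat[(i - 98):i, 1])
        scale <- scale * exp(acc - 0.25)
        if (i >= 300) {
          emp <- stats::cov(hist_mat[max(1, i - 999):i, , drop = FALSE])
          emp <- emp + diag(1e-8 + 1e-6 * diag(emp), d)
          ch_try <- tryCatch(t(chol(2.38^2 / d * emp)),
                             error = function(e) NULL)
          if (!is.null(ch_try)) cov_chol <- ch_try
        }
      }
    }
    # sampling with frozen proposal, keeping every `thin`-th state
    draws <- matrix(NA_real_, n_keep, d)
    n_acc <- 0L
    n_iter <- n_keep * thin
    for (i in seq_len(n_iter)) {
      prop <- theta + scale * as.vector(cov_chol %*% rnorm(d))
      lpp <- log_post(prop)
      if (is.finite(lpp) && log(runif(1)) < lpp - lp) {
        theta <- prop
        lp <- lpp
        n_acc <- n_acc + 1L
      }
      if (i %% thin == 0) draws[i %/% thin, ] <- theta
    }
    chains[[ch]] <- draws
    accept[ch] <- n_acc / n_iter
  }
  rhat <- vapply(seq_len(d), function(j) {
    split_rhat(lapply(chains, function(m) m[, j]))
  }, numeric(1))
  list(chains = chains, accept = accept, rhat = rhat)
}

# Split-chain potential scale reduction factor (each chain halved, then the
# standard between/within variance ratio).
split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  w <- mean(vars)
  b <- n * var(means)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}
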