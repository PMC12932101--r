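#' Cliff's delta effect size with bootstrap confidence interval
#'
#' Nonparametric effect size based on all pairwise comparisons between two
#' groups: with `greater` the number of (x, y) pairs where x > y, `lesser`
#' the reverse, and `total = n_x * n_y`, the statistic is
#' `abs(greater - lesser) / total` (ties count toward neither). It ranges
#' over \[0, 1\] (or \[-1, 1\] for the signed variant, `(greater - lesser) /
#' total`, which preserves direction): 0 means complete distributional
#' overlap, 1 complete separation. Magnitude bands follow the conventional
#' cutoffs: |delta| < 0.11 negligible, < 0.28 small, < 0.43 medium,
#' otherwise large. The 95% confidence interval is a percentile bootstrap,
#' resampling within each group independently.
#'
#' @param x,y Numeric samples (non-empty).
#' @param signed If `TRUE`, return the signed delta (positive when `x`
#'   tends to exceed `y`). Default `FALSE` (absolute value).
#' @param n_boot Bootstrap resamples for the CI (default 10000); set to 0
#'   to skip the CI.
#' @param conf Confidence level, default 0.95.
#' @param seed Integer seed for the bootstrap.
#' @return A one-row tibble: `delta`, `n_x`, `n_y`, `ci_low`, `ci_high`,
#'   `magnitude`.
#' @examples
#' cliffs_delta(c(5, 6, 7), c(1, 2, 3), n_boot = 100)  # complete separation
#' @export
cliffs_delta <- function(x, y, signed = FALSE, n_boot = 10000, conf = 0.95,
                         seed = 1L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) {
    abort("Both samples must be non-empty.")
  }
  stat <- function(x, y) {
    cmp <- sign(outer(x, y, "-"))
    d <- sum(cmp) / (length(x) * length(y))
    if (signed) d else abs(d)
  }
  delta <- stat(x, y)
  ci_low <- ci_high <- NA_real_
  if (n_boot > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(i) {
      stat(x[sample.int(length(x), replace = TRUE)],
           y[sample.int(length(y), replace = TRUE)])
    }, numeric(1))
    a <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(a, 1 - a)))
    ci_low <- ci[1]; ci_high <- ci[2]
  }
  mag <- abs(delta)
  magnitude <- if (mag < 0.11) "negligible" else if (mag < 0.28) {
    "small"
  } else if (mag < 0.43) "medium" else "large"
  tibble::tibble(delta = delta, n_x = length(x), n_y = length(y),
                 ci_low = ci_low, ci_high = ci_high, magnitude = magnitude)
}

#' Bayesian practical equivalence test on log2 ND50 values
#'
#' Decides whether two sets of log2-transformed ND50 titers differ by more
#' than a region of practical equivalence (ROPE). Each group's values are
#' modeled as Normal with its own mean and SD; the priors adapt to the
#' pooled data scale (mean ~ Normal(pooled mean, 2 x pooled SD), SD ~
#' half-Normal(0, 2 x pooled SD)). The posterior of the mean difference is
#' sampled by MCMC, and the groups are declared `different` exactly when
#' the posterior probability that |mean_a - mean_b| exceeds the ROPE
#' half-width (default 0.3 log2 units) is greater than `conf` (default
#' 0.95); otherwise the verdict is `not_different`.
#'
#' Alternatively, posterior draws of each group's log2 ND50 (e.g. from
#' [hill_nd50_draws()]) can be passed with `input = "draws"`; the rule is
#' then applied directly to the difference of the supplied draws.
#'
#' @param a,b Numeric vectors on the log2 scale: either >= 2 observed
#'   values per group (`input = "values"`) or >= 100 posterior draws per
#'   group (`input = "draws"`).
#' @param rope ROPE half-width in log2 units, default 0.3.
#' @param conf Posterior probability required to declare a difference,
#'   default 0.95.
#' @param input `"values"` or `"draws"`.
#' @param control MCMC settings for the values route (see
#'   [mcmc_control()]); the default uses 2 chains x 1500 kept draws.
#' @param seed Integer seed.
#' @return A one-row tibble: `mean_diff_log2` (posterior median of
#'   mean_a - mean_b), `prob_exceeds_rope`, `rope_halfwidth`, `verdict`.
#' @examples
#' equivalence_test(rnorm(20, 0, 0.2), rnorm(20, 3, 0.2))
#' @export
equivalence_test <- function(a, b, rope = 0.3, conf = 0.95,
                             input = c("values", "draws"),
                             control = mcmc_control(n_warmup = 500,
                                                    n_keep = 1500,
                                                    n_chains = 2, thin = 2),
                             seed = 1L) {
  input <- match.arg(input)
  a <- as.numeric(a); b <- as.numeric(b)
  if (rope < 0) abort("`rope` must be >= 0.")
  if (input == "draws") {
    if (length(a) < 100 || length(b) < 100) {
      abort("Posterior-draw input needs >= 100 draws per group.")
    }
    n <- min(length(a), length(b))
    if (length(a) != length(b)) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
      a <- a[sample.int(length(a), n)]
      b <- b[sample.int(length(b), n)]
    }
    diff <- a - b
  } else {
    if (length(a) < 2 || length(b) < 2) {
      abort(paste0("Each group needs >= 2 values (a single titer carries no ",
                   "dispersion information); pass posterior draws with ",
                   "input = \"draws\" instead."))
    }
    pooled_mean <- mean(c(a, b))
    pooled_sd <- sd(c(a, b))
    if (!is.finite(pooled_sd) || pooled_sd == 0) {
      abort("Degenerate input: pooled SD is zero.")
    }
    mu_a <- group_mean_draws(a, pooled_mean, pooled_sd, control, seed)
    mu_b <- group_mean_draws(b, pooled_mean, pooled_sd, control,
                             seed + 1L)
    diff <- mu_a - mu_b
  }
  prob <- if (rope == 0) mean(abs(diff) > 0) else mean(abs(diff) > rope)
  tibble::tibble(
    mean_diff_log2 = median(diff),
    prob_exceeds_rope = prob,
    rope_halfwidth = rope,
    verdict = ifelse(prob > conf, "different", "not_different")
  )
}

# Posterior draws of one group's mean under Normal(mu, sigma) likelihood,
# mu ~ Normal(m0, 2*s0), sigma ~ half-Normal(0, 2*s0); sampled on
# (mu, log sigma) with the shared Metropolis engine.
group_mean_draws <- function(x, m0, s0, control, seed) {
  log_post <- function(th) {
    mu <- th[1]; sigma <- exp(th[2])
    sum(dnorm(x, mu, sigma, log = TRUE)) +
      dnorm(mu, m0, 2 * s0, log = TRUE) +
      dnorm(sigma, 0, 2 * s0, log = TRUE) + th[2]
  }
  init <- lapply(seq_len(control$n_chains), function(k) {
    off <- k - (control$n_chains + 1) / 2
    c(mean(x) + 0.3 * s0 * off, log(max(sd(x), s0 / 10)) + 0.2 * off)
  })
  res <- run_metropolis(log_post, init, n_warmup = control$n_warmup,
                        n_keep = control$n_keep,
                        n_chains = control$n_chains,
                        thin = control$thin %||% 1L, seed = seed)
  unlist(lapply(res$chains, function(m) m[, 1]))
}
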