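#' Priors for the Bayesian four-parameter Hill fit
#'
#' Weakly-informative defaults reflecting how the assay is constructed:
#' normalized transduction has asymptotes near 0% (complete neutralization)
#' and 100% (the antibody-free control), the Hill slope is positive under
#' the orientation convention (transduction falls as serum content rises),
#' and the log2 ND50 is uniform over the tested dilution range padded by
#' `x50_pad` doublings on each side.
#'
#' @param bottom_mean,bottom_sd,bottom_min Normal prior (truncated at
#'   `bottom_min`) on the lower asymptote, in transduction %.
#' @param top_mean,top_sd Normal prior on the upper asymptote, in %.
#' @param slope_meanlog,slope_sdlog Lognormal prior on the Hill slope.
#' @param x50_pad Doublings added beyond the tested log2-dilution range for
#'   the uniform prior on log2 ND50.
#' @param sigma_scale Scale of the half-Normal prior on the residual SD (%).
#' @return A named list of prior settings.
#' @export
hill_priors <- function(bottom_mean = 0, bottom_sd = 20, bottom_min = -10,
                        top_mean = 100, top_sd = 20,
                        slope_meanlog = 0, slope_sdlog = 1,
                        x50_pad = 2, sigma_scale = 10) {
  list(bottom_mean = bottom_mean, bottom_sd = bottom_sd,
       bottom_min = bottom_min, top_mean = top_mean, top_sd = top_sd,
       slope_meanlog = slope_meanlog, slope_sdlog = slope_sdlog,
       x50_pad = x50_pad, sigma_scale = sigma_scale)
}

#' MCMC settings for the Bayesian fits
#'
#' @param n_warmup Adaptation iterations per chain (discarded).
#' @param n_keep Post-warmup draws kept per chain.
#' @param n_chains Number of chains.
#' @param thin Keep every `thin`-th post-warmup state; random-walk
#'   Metropolis draws are autocorrelated, and the default (5) brings the
#'   effective sample size of the kept draws close to their number.
#' @param rhat_max Convergence is flagged when any split-chain potential
#'   scale reduction factor exceeds this threshold.
#' @return A named list of sampler settings.
#' @export
mcmc_control <- function(n_warmup = 1500, n_keep = 2000, n_chains = 4,
                         thin = 5, rhat_max = 1.01) {
  list(n_warmup = as.integer(n_warmup), n_keep = as.integer(n_keep),
       n_chains = as.integer(n_chains), thin = as.integer(thin),
       rhat_max = rhat_max)
}

#' Bayesian four-parameter Hill fit of a neutralization curve
#'
#' Fits transduction % as a four-parameter Hill function of log2 dilution,
#' \deqn{y = bottom + (top - bottom) / (1 + 2^{slope (x - x_{50})}),}
#' with a Normal likelihood (fitted residual SD) via adaptive random-walk
#' Metropolis MCMC. `x50` is the log2 ND50: the dilution at which the curve
#' is halfway between its asymptotes. Replicate-level rows are used as-is.
#'
#' @param data A tibble with numeric columns `dilution` (fraction in (0,1))
#'   and `transduction_pct`; one row per replicate or per dilution mean
#'   (output of [normalize_wells()] or [normalize_plate()]).
#' @param priors From [hill_priors()].
#' @param control From [mcmc_control()].
#' @param seed Integer seed; fits are reproducible given the seed.
#' @return An object of class `hill_fit`: list with `draws` (tibble of
#'   posterior draws of `bottom`, `top`, `slope`, `x50`, `sigma` with chain
#'   and iteration indices), `data`, `diagnostics` (`rhat`, `accept`,
#'   `converged`), `priors`, `seed`.
#' @seealso [hill_nd50()], [fit_linear_nd50()], [tidy.hill_fit()]
#' @export
fit_hill <- function(data, priors = hill_priors(), control = mcmc_control(),
                     seed = 1L) {
  stopifnot(is.data.frame(data),
            all(c("dilution", "transduction_pct") %in% names(data)))
  data <- data[complete.cases(data[c("dilution", "transduction_pct")]), ]
  x <- log2(data$dilution)
  y <- data$transduction_pct
  if (length(unique(x)) < 4) {
    abort("Hill fit needs >= 4 distinct dilution points (one per parameter).")
  }
  x50_lo <- min(x) - priors$x50_pad
  x50_hi <- max(x) + priors$x50_pad

  log_post <- function(th) {
    bottom <- th[1]; top <- th[2]
    slope <- exp(th[3]); x50 <- th[4]; sigma <- exp(th[5])
    if (bottom < priors$bottom_min || bottom >= top ||
        x50 < x50_lo || x50 > x50_hi) {
      return(-Inf)
    }
    mu <- bottom + (top - bottom) / (1 + 2^(slope * (x - x50)))
    sum(dnorm(y, mu, sigma, log = TRUE)) +
      dnorm(bottom, priors$bottom_mean, priors$bottom_sd, log = TRUE) +
      dnorm(top, priors$top_mean, priors$top_sd, log = TRUE) +
      dnorm(th[3], priors$slope_meanlog, priors$slope_sdlog, log = TRUE) +
      dnorm(sigma, 0, priors$sigma_scale, log = TRUE) + th[5]
  }

  # deterministic, mildly dispersed data-driven inits per chain
  top0 <- min(max(max(y), 60), 140)
  bottom0 <- max(min(min(y), 40), priors$bottom_min + 1)
  if (bottom0 >= top0) bottom0 <- top0 - 10
  mid <- (top0 + bottom0) / 2
  x50_0 <- x[which.min(abs(y - mid))]
  x50_0 <- min(max(x50_0, x50_lo + 0.1), x50_hi - 0.1)
  sigma0 <- max(sd(y) / 2, 1)
  init <- lapply(seq_len(control$n_chains), function(k) {
    off <- (k - (control$n_chains + 1) / 2)
    c(bottom0, top0, log(1) + 0.2 * off,
      min(max(x50_0 + 0.3 * off, x50_lo + 0.05), x50_hi - 0.05),
      log(sigma0) + 0.1 * off)
  })

  res <- run_metropolis(log_post, init, n_warmup = control$n_warmup,
                        n_keep = control$n_keep,
                        n_chains = control$n_chains,
                        thin = control$thin %||% 1L, seed = seed)
  draws <- purrr::map_dfr(seq_along(res$chains), function(ch) {
    m <- res$chains[[ch]]
    tibble::tibble(chain = ch, iter = seq_len(nrow(m)),
                   bottom = m[, 1], top = m[, 2], slope = exp(m[, 3]),
                   x50 = m[, 4], sigma = exp(m[, 5]))
  })
  rhat <- setNames(res$rhat, c("bottom", "top", "log_slope", "x50",
                               "log_sigma"))
  converged <- all(is.finite(rhat)) && max(rhat) <= control$rhat_max
  if (!converged) {
    warn(paste0("Hill fit did not converge (max split R-hat = ",
                round(max(rhat), 3), "); result is flagged."))
  }
  structure(
    list(draws = draws, data = tibble::as_tibble(data),
         diagnostics = list(rhat = rhat, accept = res$accept,
                            converged = converged),
         priors = priors, control = control, seed = seed),
    class = "hill_fit"
  )
}

# Posterior-median Hill curve evaluated at log2 dilutions x.
hill_median_curve <- function(fit, x) {
  b <- median(fit$draws$bottom); t0 <- median(fit$draws$top)
  s <- median(fit$draws$slope); x50 <- median(fit$draws$x50)
  b + (t0 - b) / (1 + 2^(s * (x - x50)))
}

#' Extract the ND50 estimate from a Hill fit
#'
#' The ND50 point estimate is the posterior median of the log2 ND50
#' parameter (back-transformed to the dilution-fraction scale) with an
#' equal-tailed 95% credible interval. A fit whose posterior-median curve
#' never drops below 50% within the tested dilution range has no 50%
#' crossing (flat or non-identifiable curve) and is censored; censoring via
#' [apply_censoring()] also replaces estimates weaker than the strongest
#' tested dilution by the 1/1 placeholder titer.
#'
#' @param fit A `hill_fit`.
#' @param conf Credible level, default 0.95.
#' @return A one-row tibble: `nd50`, `ci_low`, `ci_high` (dilution
#'   fractions, `NA` when censored), `model = "hill"`, `censored`,
#'   `display_titer`, `converged`.
#' @export
hill_nd50 <- function(fit, conf = 0.95) {
  stopifnot(inherits(fit, "hill_fit"))
  a <- (1 - conf) / 2
  x50 <- fit$draws$x50
  tested <- sort(unique(fit$data$dilution))
  med_curve <- hill_median_curve(fit, log2(tested))
  no_crossing <- min(med_curve) >= 50
  out <- apply_censoring(
    nd50 = 2^median(x50),
    ci_low = 2^unname(quantile(x50, a)),
    ci_high = 2^unname(quantile(x50, 1 - a)),
    tested_dilutions = tested,
    no_crossing = no_crossing,
    model = "hill"
  )
  out$converged <- fit$diagnostics$converged
  out
}

#' Bayesian linear-model ND50 estimate
#'
#' The robust fallback used for serum samples whose curves are incomplete
#' or non-sigmoidal: a Bayesian simple linear regression of transduction %
#' on log2 dilution under the standard noninformative prior, whose
#' posterior is sampled exactly (Normal-inverse-chi-square conjugacy). The
#' ND50 is the dilution at which the fitted line crosses 50%, with the 95%
#' credible interval taken from the posterior of the crossing point. Draws
#' with a non-negative slope on the transduction scale carry no crossing
#' (no neutralization signal); if most draws have none, or the crossing
#' falls outside the censoring rule's range, the result is censored to the
#' 1/1 placeholder.
#'
#' @param data A tibble with columns `dilution` and `transduction_pct`
#'   (replicate-level rows preferred).
#' @param window `"all"` (default) fits all tested dilutions; `"flank"`
#'   restricts to the points bracketing the 50% crossing (the two dilution
#'   levels whose means flank 50%), when such a bracket exists.
#' @param n_draws Number of exact posterior draws, default 4000.
#' @param conf Credible level, default 0.95.
#' @param seed Integer seed.
#' @return A one-row tibble as in [hill_nd50()] with `model = "linear"`.
#' @examples
#' d <- tibble::tibble(dilution = c(1/4, 1/16), transduction_pct = c(40, 60))
#' fit_linear_nd50(d)  # crossing at 1/8
#' @export
fit_linear_nd50 <- function(data, window = c("all", "flank"),
                            n_draws = 4000, conf = 0.95, seed = 1L) {
  stopifnot(is.data.frame(data),
            all(c("dilution", "transduction_pct") %in% names(data)))
  window <- match.arg(window)
  data <- data[complete.cases(data[c("dilution", "transduction_pct")]), ]
  if (window == "flank") {
    means <- tapply(data$transduction_pct, data$dilution, mean)
    dil <- as.numeric(names(means))
    ord <- order(dil)
    means <- means[ord]; dil <- dil[ord]
    below <- which(means < 50)
    if (length(below) > 0 && min(below) > 1) {
      keep <- dil[c(min(below) - 1, min(below))]
      data <- data[data$dilution %in% keep, ]
    }
  }
  x <- log2(data$dilution)
  y <- data$transduction_pct
  if (length(unique(x)) < 2) {
    abort("Linear ND50 fit needs >= 2 distinct dilution points.")
  }
  if (var(x) == 0) abort("Zero variance in log2 dilution predictor.")
  n <- length(y)
  X <- cbind(1, x)
  fit <- lm(y ~ x)
  beta_hat <- coef(fit)
  tested <- sort(unique(data$dilution))

  if (n <= 2) {
    # saturated line: no residual information, use the exact crossing
    b <- unname(beta_hat[2])
    no_crossing <- !(b < 0)
    xc <- if (no_crossing) NA_real_ else unname((50 - beta_hat[1]) / b)
    return(apply_censoring(2^xc, 2^xc, 2^xc, tested, no_crossing, "linear"))
  }

  s2 <- sum(fit$residuals^2) / (n - 2)
  XtX_inv <- solve(crossprod(X))
  R <- chol(XtX_inv)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sigma2 <- (n - 2) * s2 / rchisq(n_draws, df = n - 2)
  z <- matrix(rnorm(2 * n_draws), n_draws, 2)
  beta <- matrix(beta_hat, n_draws, 2, byrow = TRUE) +
    (z %*% R) * sqrt(sigma2)
  slope_neg <- beta[, 2] < 0
  if (mean(slope_neg) < 0.5) {
    return(apply_censoring(NA_real_, NA_real_, NA_real_, tested,
                           no_crossing = TRUE, model = "linear"))
  }
  xc <- (50 - beta[slope_neg, 1]) / beta[slope_neg, 2]
  a <- (1 - conf) / 2
  apply_censoring(
    nd50 = 2^median(xc),
    ci_low = 2^unname(quantile(xc, a)),
    ci_high = 2^unname(quantile(xc, 1 - a)),
    tested_dilutions = tested,
    no_crossing = FALSE,
    model = "linear"
  )
}

#' Censor ND50 estimates outside the tested range
#'
#' Samples with minimal neutralization (an ND50 weaker than the strongest
#' tested serum dilution, e.g. a titer below 4 when testing from 1/4) or
#' with no 50% crossing at all are reported with the placeholder titer 1/1
#' rather than an extrapolated number.
#'
#' @param nd50,ci_low,ci_high Estimate and credible bounds on the
#'   dilution-fraction scale (`NA` allowed when there is no crossing).
#' @param tested_dilutions Dilution fractions actually tested.
#' @param no_crossing `TRUE` when the fitted curve never reaches 50% within
#'   the tested range.
#' @param model Fitting-model tag, `"hill"` or `"linear"`.
#' @return A one-row tibble: `nd50`, `ci_low`, `ci_high`, `model`,
#'   `censored`, `display_titer` (fraction string, "1/1" when censored).
#' @examples
#' apply_censoring(1/3, 1/5, 1/2, dilution_series())  # titer 3 < 4: censored
#' apply_censoring(1/8, 1/10, 1/6, dilution_series()) # pass-through
#' @export
apply_censoring <- function(nd50, ci_low = NA_real_, ci_high = NA_real_,
                            tested_dilutions, no_crossing = FALSE,
                            model = "linear") {
  strongest <- max(parse_dilution(tested_dilutions))
  censored <- isTRUE(no_crossing) || is.na(nd50) || nd50 > strongest
  if (censored) {
    tibble::tibble(nd50 = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                   model = model, censored = TRUE, display_titer = "1/1")
  } else {
    tibble::tibble(nd50 = nd50, ci_low = ci_low, ci_high = ci_high,
                   model = model, censored = FALSE,
                   display_titer = paste0("1/", max(1, round(1 / nd50))))
  }
}

#' Estimate ND50 for every curve in a normalized dataset
#'
#' Groups replicate-level normalized wells by (sample, serotype, format)
#' and fits each group's ND50. The `"auto"` policy follows the analysis
#' convention for this assay family: the four-parameter Hill fit for
#' monoclonal-antibody dilution series (rows whose `sample_type` is
#' `"mab"`), and the robust linear model for serum samples (everything
#' else) so both formats are compared on the same footing.
#'
#' @param normalized Output of [normalize_wells()] (or any tibble with
#'   `sample_id`, `serotype`, `format`, `dilution`, `transduction_pct`,
#'   optionally `sample_type`).
#' @param model `"auto"`, `"hill"` or `"linear"`.
#' @param seed Integer seed; per-group seeds are derived from it.
#' @param ... Passed to [fit_hill()] or [fit_linear_nd50()].
#' @return A tibble with one row per (sample_id, serotype, format):
#'   metadata plus the columns of [apply_censoring()].
#' @export
estimate_nd50 <- function(normalized, model = c("auto", "hill", "linear"),
                          seed = 1L, ...) {
  model <- match.arg(model)
  stopifnot(is.data.frame(normalized))
  keys <- c("sample_id", "serotype", "format")
  groups <- normalized |>
    dplyr::distinct(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
  purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    g <- dplyr::semi_join(normalized, groups[i, ], by = keys)
    use <- if (model == "auto") {
      if ("sample_type" %in% names(g) && any(g$sample_type == "mab")) {
        "hill"
      } else "linear"
    } else model
    g_seed <- (seed + i * 1009L) %% .Machine$integer.max
    res <- if (use == "hill") {
      hill_nd50(fit_hill(g, seed = g_seed, ...))
    } else {
      fit_linear_nd50(g, seed = g_seed, ...)
    }
    dplyr::bind_cols(groups[i, ], res)
  })
}

#' Posterior draws of the log2 ND50 from a Hill fit
#'
#' @param fit A `hill_fit`.
#' @return Numeric vector of posterior draws of log2 ND50, usable as a
#'   `draws` input to [equivalence_test()].
#' @export
hill_nd50_draws <- function(fit) {
  stopifnot(inherits(fit, "hill_fit"))
  fit$draws$x50
}

#' @export
print.hill_fit <- function(x, ...) {
  s <- hill_nd50(x)
  cat("Bayesian four-parameter Hill fit\n")
  cat(sprintf("  draws: %d (%d chains), max split R-hat %.3f%s\n",
              nrow(x$draws), max(x$draws$chain),
              max(x$diagnostics$rhat),
              if (x$diagnostics$converged) "" else " [NOT CONVERGED]"))
  if (s$censored) {
    cat("  ND50: censored (display titer 1/1)\n")
  } else {
    cat(sprintf("  ND50: %s (95%% CrI %s - %s)\n", s$display_titer,
                dilution_label(s$ci_low), dilution_label(s$ci_high)))
  }
  invisible(x)
}

#' Tidy posterior summaries of a Hill fit
#'
#' @param x A `hill_fit`.
#' @param conf.level Credible level for the interval columns.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per parameter (`bottom`, `top`,
#'   `slope`, `x50`, `sigma`): posterior median, SD, equal-tailed interval
#'   and split R-hat. `glance()`: a one-row tibble with the ND50 summary
#'   and diagnostics.
#' @method tidy hill_fit
#' @export
tidy.hill_fit <- function(x, conf.level = 0.95, ...) {
  a <- (1 - conf.level) / 2
  pars <- c("bottom", "top", "slope", "x50", "sigma")
  rhat <- x$diagnostics$rhat
  names(rhat) <- pars
  purrr::map_dfr(pars, function(p) {
    v <- x$draws[[p]]
    tibble::tibble(term = p, estimate = median(v), std.error = sd(v),
                   conf.low = unname(quantile(v, a)),
                   conf.high = unname(quantile(v, 1 - a)),
                   rhat = unname(rhat[p]))
  })
}

#' @rdname tidy.hill_fit
#' @method glance hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  s <- hill_nd50(x)
  tibble::tibble(nd50 = s$nd50, ci_low = s$ci_low, ci_high = s$ci_high,
                 censored = s$censored, display_titer = s$display_titer,
                 n_draws = nrow(x$draws),
                 max_rhat = max(x$diagnostics$rhat),
                 converged = x$diagnostics$converged)
}
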