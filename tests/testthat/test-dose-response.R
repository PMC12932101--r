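test_that("linear model crosses 50% where hand algebra says it should", {
  d <- tibble::tibble(dilution = c(1 / 4, 1 / 16),
                      transduction_pct = c(40, 60))
  res <- fit_linear_nd50(d)
  expect_equal(res$nd50, 1 / 8)
  expect_equal(res$display_titer, "1/8")
  expect_false(res$censored)
})

test_that("raising a line by a constant moves the crossing to stronger serum", {
  base <- tibble::tibble(dilution = c(1 / 4, 1 / 16),
                         transduction_pct = c(40, 60))
  prev <- fit_linear_nd50(base)$nd50
  for (shift in c(5, 10)) {
    shifted <- dplyr::mutate(base, transduction_pct = transduction_pct + shift)
    cur <- fit_linear_nd50(shifted)$nd50
    if (is.na(cur)) {
      # crossing pushed beyond the strongest tested dilution: censored
      expect_true(fit_linear_nd50(shifted)$censored)
    } else {
      expect_gt(cur, prev)
      prev <- cur
    }
  }
})

test_that("flat high curves are censored by the linear model", {
  set.seed(8)
  flat <- tibble::tibble(
    dilution = rep(dilution_series(), each = 3),
    transduction_pct = 95 + rnorm(18, 0, 2)
  )
  res <- fit_linear_nd50(flat)
  expect_true(res$censored)
  expect_equal(res$display_titer, "1/1")
  expect_true(is.na(res$nd50))
})

test_that("censoring applies the 1/1 placeholder rule", {
  tested <- dilution_series()
  weak <- apply_censoring(1 / 3, 1 / 5, 1 / 2, tested)
  expect_true(weak$censored)
  expect_equal(weak$display_titer, "1/1")
  ok <- apply_censoring(1 / 8, 1 / 12, 1 / 6, tested)
  expect_false(ok$censored)
  expect_equal(ok$nd50, 1 / 8)
  none <- apply_censoring(NA, tested_dilutions = tested, no_crossing = TRUE)
  expect_true(none$censored)
})

test_that("Hill fit recovers a noise-free sigmoid to within 0.1 log2", {
  nw <- noise_free_curve(1 / 16, hill_slope = 2)
  fit <- suppressWarnings(fit_hill(nw, seed = 4))
  res <- hill_nd50(fit)
  expect_false(res$censored)
  expect_lt(abs(log2(res$nd50) - log2(1 / 16)), 0.1)
})

test_that("Hill posterior median matches a least-squares oracle", {
  skip_if_not_installed("minpack.lm")
  tr <- simulation_truth(sample_profiles("s", 1 / 12, hill_slope = 1.8),
                         design = assay_design("CSC", noise_sigma = 0.03,
                                               seed = 21))
  nw <- normalize_wells(simulate_plate(tr))
  fit <- suppressWarnings(fit_hill(nw, seed = 13))
  nls_fit <- minpack.lm::nlsLM(
    transduction_pct ~ b + (t0 - b) / (1 + 2^(s * (log2(dilution) - x50))),
    data = nw, start = list(b = 0, t0 = 100, s = 2, x50 = -4)
  )
  expect_lt(abs(median(fit$draws$x50) - coef(nls_fit)[["x50"]]), 0.15)
})

test_that("Hill fits are deterministic given the seed and flag flat curves", {
  nw <- noise_free_curve(1 / 16)
  f1 <- suppressWarnings(fit_hill(nw, seed = 2))
  f2 <- suppressWarnings(fit_hill(nw, seed = 2))
  expect_identical(f1$draws, f2$draws)

  tr <- simulation_truth(sample_profiles("neg", NA),
                         design = assay_design("CSC", noise_sigma = 0.05,
                                               seed = 6))
  flat <- normalize_wells(simulate_plate(tr))
  res <- hill_nd50(suppressWarnings(fit_hill(flat, seed = 10)))
  expect_true(res$censored)
  expect_true(is.na(res$nd50))
  expect_equal(res$display_titer, "1/1")
})

test_that("Hill fit refuses underdetermined curves", {
  few <- tibble::tibble(dilution = c(1 / 4, 1 / 8, 1 / 16),
                        transduction_pct = c(30, 50, 70))
  expect_error(fit_hill(few), ">= 4 distinct")
  expect_error(fit_linear_nd50(few[1, ]), ">= 2 distinct")
})

test_that("Hill and linear fits agree on a locally linear mid-slope curve", {
  nw <- noise_free_curve(1 / 16, hill_slope = 0.8)
  hill <- hill_nd50(suppressWarnings(fit_hill(nw, seed = 5)))
  lin <- fit_linear_nd50(nw, seed = 5)
  expect_lt(abs(log2(hill$nd50) - log2(lin$nd50)), 0.2)
})

test_that("posterior-mean Hill curve is monotone in log2 dilution", {
  tr <- simulation_truth(sample_profiles("s", 1 / 16),
                         design = assay_design("CSC", noise_sigma = 0.05,
                                               seed = 14))
  nw <- normalize_wells(simulate_plate(tr))
  fit <- suppressWarnings(fit_hill(nw, seed = 3))
  expect_true(all(fit$draws$slope > 0))
  grid <- seq(-8, -1, length.out = 50)
  curve <- nabtiter:::hill_median_curve(fit, grid)
  expect_true(all(diff(curve) <= 0))
})

test_that("the auto model policy fits antibodies with Hill and sera linearly", {
  tr_mab <- simulation_truth(sample_profiles("ADK9", 1 / 16),
                             design = assay_design("CSC", noise_sigma = 0.02,
                                                   seed = 17))
  tr_ser <- simulation_truth(sample_profiles("donor1", 1 / 8),
                             design = assay_design("CSC", noise_sigma = 0.02,
                                                   seed = 18))
  nw <- dplyr::bind_rows(
    dplyr::mutate(normalize_wells(simulate_plate(tr_mab)),
                  sample_type = "mab"),
    dplyr::mutate(normalize_wells(simulate_plate(tr_ser)),
                  sample_type = "serum")
  )
  res <- suppressWarnings(estimate_nd50(nw, model = "auto", seed = 2))
  expect_equal(res$model[res$sample_id == "ADK9"], "hill")
  expect_equal(res$model[res$sample_id == "donor1"], "linear")
  forced <- suppressWarnings(estimate_nd50(nw, model = "hill", seed = 2))
  expect_equal(unique(forced$model), "hill")
})
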