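test_that("serum composition is constant under CSC and increasing under VSC", {
  d <- assay_design("CSC")
  expect_equal(serum_composition("CSC", 1 / 4, d), 0.10)
  expect_equal(serum_composition("CSC", 1 / 128, d), 0.10)
  expect_equal(serum_composition("VSC", 1e-9, d), d$vsc_medium_serum,
               tolerance = 1e-6)
  vsc <- serum_composition("VSC", dilution_series(), d)
  expect_true(all(diff(vsc) < 0))  # stronger dilution fraction => more serum
  expect_gt(serum_composition("VSC", 1 / 4, d),
            serum_composition("VSC", 1 / 128, d))
  expect_error(serum_composition("CSC", 1.5, d), "0, 1")
})

test_that("matrix-effect factors have the right shape and limits", {
  set.seed(42)
  for (i in 1:20) {
    m <- matrix_effect_model(
      enhance_amplitude = runif(1, 0, 10),
      enhance_halfsat = runif(1, 0.005, 0.5),
      inhibit_strength = runif(1, 0, 10),
      inhibit_shape = runif(1, 0.5, 3)
    )
    s <- sort(runif(20, 0, 1))
    expect_equal(enhancement_factor(0, m), 1)
    expect_equal(inhibition_factor(0, m), 1)
    expect_true(all(diff(enhancement_factor(s, m)) >= 0))
    expect_true(all(diff(inhibition_factor(s, m)) <= 0))
  }
})

test_that("noise-free CSC seronegative curves normalize to exactly 100%", {
  tr <- simulation_truth(sample_profiles("neg", NA),
                         design = assay_design("CSC", noise_sigma = 0))
  curves <- normalize_plate(simulate_plate(tr))
  expect_equal(curves$transduction_pct, rep(100, 6))
})

test_that("noise-free VSC seronegative curves inflate with serum content", {
  tr <- simulation_truth(sample_profiles("neg", NA),
                         design = assay_design("VSC", noise_sigma = 0))
  curves <- normalize_plate(simulate_plate(tr)) |>
    dplyr::arrange(dilution)
  expect_true(all(diff(curves$transduction_pct) > 0))
  expect_gt(curves$transduction_pct[curves$dilution == 1 / 4], 100)
})

test_that("seropositive Hill midpoint lands at the true ND50", {
  tr <- simulation_truth(sample_profiles("pos", 1 / 16, hill_slope = 2),
                         design = assay_design("CSC", noise_sigma = 0))
  curves <- normalize_plate(simulate_plate(tr))
  expect_equal(curves$transduction_pct[curves$dilution == 1 / 16], 50)
})

test_that("simulation is byte-identical given the same truth and seed", {
  tr <- simulation_truth(sample_profiles(c("a", "b"), c(NA, 1 / 8)),
                         design = assay_design("VSC", seed = 77))
  expect_identical(simulate_plate(tr), simulate_plate(tr))
  tr2 <- simulation_truth(sample_profiles(c("a", "b"), c(NA, 1 / 8)),
                          design = assay_design("VSC", seed = 78))
  expect_false(identical(simulate_plate(tr)$rlu, simulate_plate(tr2)$rlu))
})

test_that("replicate log-RLU dispersion matches noise_sigma", {
  tr <- simulation_truth(
    sample_profiles("s", NA),
    design = assay_design("CSC", dilutions = 1 / 4, replicates = 10000,
                          noise_sigma = 0.05, seed = 3)
  )
  w <- simulate_plate(tr)
  sd_log <- sd(log(w$rlu[w$role == "test"]))
  expect_equal(sd_log, 0.05, tolerance = 0.05)
})

test_that("the documented masking parameter set hides neutralization under VSC", {
  csc <- normalize_plate(simulate_plate(masking_truth("CSC")))
  vsc <- normalize_plate(simulate_plate(masking_truth("VSC")))
  expect_lt(min(csc$transduction_pct), 50)   # CSC crosses 50%
  expect_true(all(vsc$transduction_pct > 50))  # VSC never drops below 50%
})

test_that("serum titration isolates each matrix effect", {
  m <- matrix_effect_model()
  up <- simulate_serum_titration("on_aav", c(0, 0.01, 0.05, 0.1), m,
                                 noise_sigma = 0)
  expect_equal(up$transduction_pct[up$serum_level == 0], rep(100, 3))
  means_up <- tapply(up$transduction_pct, up$serum_level, mean)
  expect_true(all(diff(means_up) >= 0))
  expect_true(all(means_up >= 100))
  down <- simulate_serum_titration("on_cells", c(0, 0.01, 0.05, 0.1), m,
                                   noise_sigma = 0)
  means_down <- tapply(down$transduction_pct, down$serum_level, mean)
  expect_true(all(diff(means_down) <= 0))
  expect_true(all(means_down <= 100))
  expect_error(simulate_serum_titration("on_aav", c(0.01, 0.05)),
               "include 0")
})

test_that("invalid designs are rejected", {
  expect_error(assay_design(dilutions = c(1 / 4, 1 / 10)), "factor of 2")
  expect_error(assay_design(baseline_rlu = 0), "> 0")
  expect_error(assay_design(dilutions = numeric(0)), "non-empty")
  expect_error(sample_profiles("x", 2), "0, 1")
})
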