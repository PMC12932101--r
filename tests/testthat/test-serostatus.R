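curve_at_quarter <- function(pct, sample_id = "S1", format = "CSC") {
  tibble::tibble(sample_id = sample_id, serotype = "AAV9", format = format,
                 dilution = 1 / 4, transduction_pct = pct)
}

test_that("classification thresholds use strict inequalities", {
  expect_equal(classify_serostatus(curve_at_quarter(95),
                                   "pool_eligibility")$label, "seronegative")
  expect_equal(classify_serostatus(curve_at_quarter(90),
                                   "pool_eligibility")$label, "ineligible")
  expect_equal(classify_serostatus(curve_at_quarter(49),
                                   "neutralization")$label, "neutralizing")
  expect_equal(classify_serostatus(curve_at_quarter(50),
                                   "neutralization")$label, "non_neutralizing")
  expect_equal(classify_serostatus(curve_at_quarter(51),
                                   "neutralization")$label, "non_neutralizing")
})

test_that("classification requires the 1/4 dilution point", {
  off_grid <- tibble::tibble(sample_id = "S1", serotype = "AAV9",
                             format = "CSC", dilution = 1 / 8,
                             transduction_pct = 70)
  expect_error(classify_serostatus(off_grid, "neutralization"), "1/4")
})

test_that("classification uses the replicate mean at 1/4", {
  reps <- tibble::tibble(sample_id = "S1", serotype = "AAV9", format = "CSC",
                         dilution = 1 / 4,
                         transduction_pct = c(40, 45, 70))
  res <- classify_serostatus(reps, "neutralization")
  expect_equal(res$transduction_at_quarter, mean(c(40, 45, 70)))
  expect_equal(res$label, "non_neutralizing")
})

test_that("exact McNemar matches its closed form", {
  expect_equal(mcnemar_exact(7, 0), 2 * 0.5^7)
  expect_equal(mcnemar_exact(0, 0), 1)
  expect_equal(mcnemar_exact(3, 3), 1)  # doubling rule capped at 1
  # chi-square route approximates the exact one at larger counts
  expect_equal(mcnemar_exact(25, 10, exact = FALSE),
               mcnemar_exact(25, 10), tolerance = 0.05)
})

test_that("discordance tabulates paired labels and fractions", {
  n <- 46
  discordant <- 10
  ids <- paste0("s", seq_len(n))
  csc_labels <- c(rep("neutralizing", 20), rep("non_neutralizing", 26))
  vsc_labels <- csc_labels
  vsc_labels[1:discordant] <- "non_neutralizing"  # CSC detects, VSC misses
  cls <- dplyr::bind_rows(
    tibble::tibble(sample_id = ids, serotype = "AAV9", format = "CSC",
                   rule = "neutralization", transduction_at_quarter = 40,
                   label = csc_labels),
    tibble::tibble(sample_id = ids, serotype = "AAV9", format = "VSC",
                   rule = "neutralization", transduction_at_quarter = 60,
                   label = vsc_labels)
  )
  tab <- discordance(cls)
  expect_equal(tab$n, n)
  expect_equal(tab$n_discordant, discordant)
  expect_equal(tab$discordant_fraction, 100 * 10 / 46)  # 21.7%
  expect_equal(round(tab$discordant_fraction, 1), 21.7)
  expect_equal(tab$n_csc_pos_vsc_neg, 10)
  expect_equal(tab$p_value, mcnemar_oracle(10, 0))
  expect_equal(
    tab$n_csc_pos_vsc_pos + tab$n_csc_pos_vsc_neg +
      tab$n_csc_neg_vsc_pos + tab$n_csc_neg_vsc_neg,
    n
  )
})

test_that("zero discordance gives fraction 0 and p = 1", {
  ids <- paste0("s", 1:8)
  cls <- purrr::map_dfr(c("CSC", "VSC"), function(f) {
    tibble::tibble(sample_id = ids, serotype = "AAV1", format = f,
                   rule = "pool_eligibility", transduction_at_quarter = 95,
                   label = "seronegative")
  })
  tab <- discordance(cls)
  expect_equal(tab$discordant_fraction, 0)
  expect_equal(tab$p_value, 1)
})

test_that("unmatched sample sets are refused", {
  cls <- dplyr::bind_rows(
    tibble::tibble(sample_id = c("a", "b"), serotype = "AAV9", format = "CSC",
                   rule = "neutralization", transduction_at_quarter = 40,
                   label = "neutralizing"),
    tibble::tibble(sample_id = "a", serotype = "AAV9", format = "VSC",
                   rule = "neutralization", transduction_at_quarter = 60,
                   label = "non_neutralizing")
  )
  expect_error(discordance(cls), "both CSC and VSC")
})

test_that("classification is invariant to replicate order and RLU scale", {
  tr <- simulation_truth(sample_profiles(c("x", "y"), c(NA, 1 / 8)),
                         design = assay_design("CSC", seed = 12))
  wells <- simulate_plate(tr)
  base <- classify_serostatus(normalize_plate(wells), "neutralization")
  shuffled <- wells[sample.int(nrow(wells)), ]
  scaled <- dplyr::mutate(shuffled, rlu = rlu * 3.7)
  again <- classify_serostatus(normalize_plate(scaled), "neutralization")
  expect_equal(dplyr::arrange(again, sample_id),
               dplyr::arrange(base, sample_id))
})

test_that("under masking conditions VSC calls fewer neutralizers than CSC", {
  curves <- dplyr::bind_rows(
    normalize_plate(simulate_plate(masking_truth("CSC"))),
    normalize_plate(simulate_plate(masking_truth("VSC")))
  )
  cls <- classify_serostatus(curves, "neutralization")
  n_pos <- table(cls$format[cls$label == "neutralizing"])
  expect_gt(sum(cls$label == "neutralizing" & cls$format == "CSC"),
            sum(cls$label == "neutralizing" & cls$format == "VSC"))
  expect_true(all(cls$label[cls$format == "VSC"] == "non_neutralizing"))
})
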