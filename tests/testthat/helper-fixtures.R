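# Shared fixtures: tiny plate tables and independent oracles.

# Hand-built wells table: one sample, one dilution level, explicit controls.
tiny_wells <- function(test_rlu = 500, control_rlu = c(900, 1100),
                       dilution = 1 / 4, serotype = "AAV9", format = "CSC") {
  dplyr::bind_rows(
    tibble::tibble(
      plate_id = "p1", well = paste0("A", seq_along(test_rlu)),
      sample_id = "S1", role = "test", serotype = serotype, format = format,
      dilution = dilution, replicate = seq_along(test_rlu), rlu = test_rlu
    ),
    tibble::tibble(
      plate_id = "p1", well = paste0("H", seq_along(control_rlu)),
      sample_id = "control", role = "antibody_free_control",
      serotype = serotype, format = format, dilution = NA_real_,
      replicate = seq_along(control_rlu), rlu = control_rlu
    )
  )
}

# Noise-free normalized curve for direct fitting tests.
noise_free_curve <- function(true_nd50, hill_slope = 2, format = "CSC",
                             replicates = 3) {
  tr <- simulation_truth(
    sample_profiles("S1", true_nd50, hill_slope = hill_slope),
    design = assay_design(format, noise_sigma = 0, replicates = replicates)
  )
  normalize_wells(simulate_plate(tr))
}

# Brute-force Cliff's delta: explicit double loop, independent of the
# vectorized implementation.
cliffs_delta_brute <- function(x, y, signed = FALSE) {
  greater <- 0L
  lesser <- 0L
  for (xi in x) {
    for (yj in y) {
      if (xi > yj) greater <- greater + 1L
      if (xi < yj) lesser <- lesser + 1L
    }
  }
  d <- (greater - lesser) / (length(x) * length(y))
  if (signed) d else abs(d)
}

# Closed-form exact McNemar: explicit binomial tail sum from choose().
mcnemar_oracle <- function(b, c) {
  n <- b + c
  if (n == 0) return(1)
  k <- min(b, c)
  tail <- sum(choose(n, 0:k)) * 0.5^n
  min(1, 2 * tail)
}
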