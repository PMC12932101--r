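#' Normalize raw luminescence to the antibody-free control
#'
#' Converts each test well's RLU to transduction efficiency (%) relative to
#' the arithmetic mean of the antibody-free control wells in the *matched*
#' (plate, serotype, format) group; percent inhibition is its complement
#' (100 - transduction). Matching is strictly within-plate: a test group
#' with no control on its own plate is an error rather than being silently
#' pooled across plates. Blank wells are excluded; optionally their mean
#' RLU is first subtracted from all other wells on the plate.
#'
#' `normalize_wells()` returns one row per test well (replicate-level,
#' suitable for model fitting); `normalize_plate()` aggregates to curve
#' points with the replicate mean, SD and n per (sample, serotype, format,
#' dilution).
#'
#' @param wells A validated wells tibble (see [read_wells()] or
#'   [simulate_plate()]).
#' @param blank_subtract If `TRUE`, subtract the per-plate mean blank RLU
#'   from test and control wells before normalizing (clamped at 0).
#'   Default `FALSE`.
#' @return `normalize_wells()`: a tibble with the well columns plus
#'   `control_mean_rlu`, `transduction_pct` and `inhibition_pct`.
#'   `normalize_plate()`: a tibble with one row per curve point -
#'   `sample_id`, `serotype`, `format`, `dilution`, `transduction_pct`
#'   (replicate mean), `sd_pct`, `n`, `control_mean_rlu` - sorted by
#'   increasing serum content (decreasing dilution denominator) within
#'   curves.
#' @examples
#' tr <- simulation_truth(sample_profiles("S1", "1/16"),
#'                        design = assay_design("CSC", noise_sigma = 0))
#' normalize_plate(simulate_plate(tr))
#' @export
normalize_wells <- function(wells, blank_subtract = FALSE) {
  wells <- validate_wells(wells)
  if (blank_subtract) {
    wells <- wells |>
      dplyr::group_by(.data$plate_id) |>
      dplyr::mutate(rlu = pmax(
        .data$rlu - mean(.data$rlu[.data$role == "blank"]) *
          as.numeric(any(.data$role == "blank")),
        0
      )) |>
      dplyr::ungroup()
  }
  controls <- wells |>
    dplyr::filter(.data$role == "antibody_free_control") |>
    dplyr::group_by(.data$plate_id, .data$serotype, .data$format) |>
    dplyr::summarise(control_mean_rlu = mean(.data$rlu), .groups = "drop")
  if (any(controls$control_mean_rlu <= 0)) {
    abort("Control mean RLU is zero in at least one group; cannot normalize.")
  }
  out <- wells |>
    dplyr::filter(.data$role == "test") |>
    dplyr::left_join(controls, by = c("plate_id", "serotype", "format"))
  if (any(is.na(out$control_mean_rlu))) {
    abort("Test wells without a matched antibody-free control group.")
  }
  out |>
    dplyr::mutate(transduction_pct = 100 * .data$rlu / .data$control_mean_rlu,
                  inhibition_pct = 100 - .data$transduction_pct)
}

#' @rdname normalize_wells
#' @export
normalize_plate <- function(wells, blank_subtract = FALSE) {
  keys <- c("sample_id", "serotype", "format",
            intersect("sample_type", names(wells)))
  normalize_wells(wells, blank_subtract = blank_subtract) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "dilution")))) |>
    dplyr::summarise(
      mean_pct = mean(.data$transduction_pct),
      sd_pct = if (dplyr::n() > 1) sd(.data$transduction_pct) else 0,
      n = dplyr::n(),
      control_mean_rlu = mean(.data$control_mean_rlu),
      .groups = "drop"
    ) |>
    dplyr::rename(transduction_pct = "mean_pct") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)), .data$dilution)
}
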