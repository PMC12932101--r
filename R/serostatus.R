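#' Classify serostatus from the 1/4-dilution transduction readout
#'
#' Two stratification rules, both read off the replicate-mean transduction
#' at the strongest tested serum dilution (1/4 by default):
#'
#' * `pool_eligibility`: transduction strictly above `threshold` (default
#'   90%) labels the sample `seronegative`; anything else is `ineligible`
#'   for a reference serum pool. The stringent cutoff keeps low-level
#'   neutralizers out of antibody-free control pools.
#' * `neutralization`: transduction strictly below `threshold` (default
#'   50%) labels the sample `neutralizing`, otherwise `non_neutralizing`.
#'
#' Boundary values (exactly at the threshold) fall to the conservative
#' side (`ineligible` / `non_neutralizing`), matching the strict
#' inequalities "above 90%" and "less than 50%".
#'
#' @param curves Curve points from [normalize_plate()] (or any tibble with
#'   `sample_id`, `serotype`, `format`, `dilution`, `transduction_pct`).
#' @param rule `"pool_eligibility"` or `"neutralization"`.
#' @param threshold Transduction % threshold; defaults to 90 for the pool
#'   rule and 50 for the neutralization rule.
#' @param at Dilution fraction at which the rule is evaluated (default 1/4).
#' @return A tibble with one row per (sample_id, serotype, format): `rule`,
#'   `transduction_at_quarter` and `label`.
#' @examples
#' curves <- tibble::tibble(sample_id = "S1", serotype = "AAV9",
#'                          format = "CSC", dilution = 1/4,
#'                          transduction_pct = 95)
#' classify_serostatus(curves, "pool_eligibility")
#' @export
classify_serostatus <- function(curves,
                                rule = c("pool_eligibility", "neutralization"),
                                threshold = NULL, at = 1 / 4) {
  rule <- match.arg(rule)
  threshold <- threshold %||% if (rule == "pool_eligibility") 90 else 50
  stopifnot(is.data.frame(curves))
  keys <- c("sample_id", "serotype", "format")
  at_rows <- curves[!is.na(curves$dilution) &
                      abs(curves$dilution - at) < 1e-9, ]
  all_groups <- dplyr::distinct(curves, dplyr::across(dplyr::all_of(keys)))
  got <- dplyr::distinct(at_rows, dplyr::across(dplyr::all_of(keys)))
  missing <- dplyr::anti_join(all_groups, got, by = keys)
  if (nrow(missing) > 0) {
    abort(paste0("Curve(s) missing the ", dilution_label(at),
                 " dilution point: ",
                 paste(missing$sample_id, collapse = ", ")))
  }
  out <- at_rows |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(transduction_at_quarter = mean(.data$transduction_pct),
                     .groups = "drop")
  out$rule <- rule
  out$label <- if (rule == "pool_eligibility") {
    ifelse(out$transduction_at_quarter > threshold,
           "seronegative", "ineligible")
  } else {
    ifelse(out$transduction_at_quarter < threshold,
           "neutralizing", "non_neutralizing")
  }
  out[c(keys, "rule", "transduction_at_quarter", "label")]
}

#' Exact McNemar test for paired binary classifications
#'
#' Tests whether two paired classifiers (here CSC vs VSC on the same sera)
#' disagree symmetrically, using only the discordant pairs. The exact
#' two-sided p-value is the binomial sign test with doubling,
#' `2 * P(Binomial(b + c, 1/2) <= min(b, c))` capped at 1 (p = 1 when there
#' are no discordant pairs). The chi-square approximation (with continuity
#' correction) is available for cross-checking but is unreliable at the
#' small discordant counts typical of these panels.
#'
#' @param b,c Counts of the two discordant cells of the paired 2x2 table.
#' @param exact If `FALSE`, use the continuity-corrected chi-square
#'   approximation instead.
#' @return The two-sided p-value.
#' @examples
#' mcnemar_exact(7, 0)  # 2 * (1/2)^7 = 0.015625
#' @export
mcnemar_exact <- function(b, c, exact = TRUE) {
  stopifnot(b >= 0, c >= 0, b == round(b), c == round(c))
  n <- b + c
  if (n == 0) return(1)
  if (exact) {
    min(1, 2 * pbinom(min(b, c), n, 0.5))
  } else {
    stat <- (abs(b - c) - 1)^2 / n
    unname(pchisq(stat, df = 1, lower.tail = FALSE))
  }
}

#' Paired CSC/VSC classification discordance with McNemar testing
#'
#' Pairs each sample's CSC and VSC labels (same rule, same serotype),
#' tabulates the 2x2 agreement table, and reports the discordant fraction
#' with the exact McNemar p-value per (serotype, rule).
#'
#' @param classifications A tibble of [classify_serostatus()] rows covering
#'   both formats; every sample must appear under both CSC and VSC for each
#'   (serotype, rule).
#' @param exact Passed to [mcnemar_exact()].
#' @return A tibble with one row per (serotype, rule): `n` paired samples,
#'   the four paired counts (`n_csc_pos_vsc_pos` etc., where "pos" is the
#'   rule's detection label: `ineligible` or `neutralizing`),
#'   `n_discordant`, `discordant_fraction` (%), and `p_value`.
#' @export
discordance <- function(classifications, exact = TRUE) {
  stopifnot(is.data.frame(classifications),
            all(c("sample_id", "serotype", "format", "rule", "label") %in%
                  names(classifications)))
  wide <- classifications |>
    dplyr::select("sample_id", "serotype", "rule", "format", "label") |>
    tidyr::pivot_wider(names_from = "format", values_from = "label")
  if (!all(c("CSC", "VSC") %in% names(wide)) ||
      anyNA(wide$CSC) || anyNA(wide$VSC)) {
    abort("Every sample must be classified under both CSC and VSC.")
  }
  pos_label <- c(pool_eligibility = "ineligible",
                 neutralization = "neutralizing")
  wide |>
    dplyr::group_by(.data$serotype, .data$rule) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_csc_pos_vsc_pos = sum(.data$CSC == pos_label[.data$rule[1]] &
                                .data$VSC == pos_label[.data$rule[1]]),
      n_csc_pos_vsc_neg = sum(.data$CSC == pos_label[.data$rule[1]] &
                                .data$VSC != pos_label[.data$rule[1]]),
      n_csc_neg_vsc_pos = sum(.data$CSC != pos_label[.data$rule[1]] &
                                .data$VSC == pos_label[.data$rule[1]]),
      n_csc_neg_vsc_neg = sum(.data$CSC != pos_label[.data$rule[1]] &
                                .data$VSC != pos_label[.data$rule[1]]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_discordant = .data$n_csc_pos_vsc_neg + .data$n_csc_neg_vsc_pos,
      discordant_fraction = 100 * .data$n_discordant / .data$n,
      p_value = purrr::map2_dbl(.data$n_csc_pos_vsc_neg,
                                .data$n_csc_neg_vsc_pos,
                                mcnemar_exact, exact = exact)
    )
}
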