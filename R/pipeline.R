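#' Pipeline run configuration
#'
#' Collects the thresholds, model policy and seed of a full analysis run.
#' Every pipeline entry point writes the resolved configuration (including
#' the seed) next to its outputs so runs are reproducible.
#'
#' @param seed Integer seed for all stochastic steps.
#' @param pool_threshold Transduction % cutoff of the pool-eligibility rule
#'   (default 90).
#' @param neutralization_threshold Transduction % cutoff of the
#'   neutralization rule (default 50).
#' @param rope ROPE half-width of the equivalence test, log2 units
#'   (default 0.3).
#' @param conf Credible/confidence level (default 0.95).
#' @param model ND50 model policy: `"auto"` (Hill for monoclonal-antibody
#'   series, linear for serum samples), `"hill"` or `"linear"`.
#' @param blank_subtract Subtract per-plate blank means before
#'   normalization (default `FALSE`).
#' @return An object of class `nab_config` (a named list).
#' @export
nab_config <- function(seed = 1L, pool_threshold = 90,
                       neutralization_threshold = 50, rope = 0.3,
                       conf = 0.95, model = c("auto", "hill", "linear"),
                       blank_subtract = FALSE) {
  model <- match.arg(model)
  structure(
    list(seed = as.integer(seed), pool_threshold = pool_threshold,
         neutralization_threshold = neutralization_threshold,
         rope = rope, conf = conf, model = model,
         blank_subtract = blank_subtract),
    class = "nab_config"
  )
}

#' Default simulated study: seven sera in both assay formats
#'
#' Builds the ground truth for a desk-scale study mirroring a typical
#' serum panel: seven donors per serotype, of which three are seropositive
#' with true ND50 titers 1/8, 1/16 and 1/32 and four are seronegative,
#' measured under both CSC and VSC with the default matrix-effect model,
#' six two-fold dilutions and three replicates.
#'
#' @param seed Integer seed.
#' @param serotype Serotype label.
#' @param noise_sigma Measurement noise (log-scale SD), default 0.05.
#' @return Named list of two [simulation_truth()] objects (`CSC`, `VSC`).
#' @export
default_study_truth <- function(seed = 1L, serotype = "AAV9",
                                noise_sigma = 0.05) {
  profiles <- sample_profiles(
    paste0("S", 1:7),
    true_nd50 = c(NA, NA, NA, NA, 1 / 8, 1 / 16, 1 / 32),
    hill_slope = 2
  )
  list(
    CSC = simulation_truth(profiles, design = assay_design(
      "CSC", serotype = serotype, noise_sigma = noise_sigma, seed = seed)),
    VSC = simulation_truth(profiles, design = assay_design(
      "VSC", serotype = serotype, noise_sigma = noise_sigma,
      seed = seed + 1L))
  )
}

truth_to_list <- function(truth) {
  list(
    profiles = lapply(seq_len(nrow(truth$profiles)), function(i) {
      p <- truth$profiles[i, ]
      list(sample_id = p$sample_id,
           true_nd50 = if (is.na(p$true_nd50)) "none" else
             dilution_label(p$true_nd50),
           hill_slope = p$hill_slope,
           serostatus_truth = p$serostatus_truth)
    }),
    matrix = unclass(truth$matrix),
    design = local({
      d <- unclass(truth$design)
      d$dilutions <- dilution_label(d$dilutions)
      d
    })
  )
}

#' Simulate a study and write the wells CSV plus ground-truth sidecar
#'
#' @param out_dir Output directory (created if needed).
#' @param truths A list of [simulation_truth()] objects (one per format),
#'   default [default_study_truth()].
#' @param config A [nab_config()]; its seed is recorded alongside outputs.
#' @return Invisibly, a list with the combined `wells` tibble and the file
#'   paths written (`wells.csv`, `truth.yaml`, `config.yaml`).
#' @export
nab_simulate <- function(out_dir, truths = default_study_truth(),
                         config = nab_config()) {
  stopifnot(inherits(config, "nab_config"))
  if (inherits(truths, "simulation_truth")) truths <- list(truths)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wells <- purrr::imap_dfr(truths, function(tr, nm) {
    prefix <- if (is.character(nm) && nzchar(nm)) {
      paste0(tolower(nm), "_plate")
    } else "plate"
    simulate_plate(tr, plate_prefix = prefix)
  })
  wells_path <- file.path(out_dir, "wells.csv")
  readr::write_csv(
    dplyr::mutate(wells, dilution = dilution_label(.data$dilution)),
    wells_path
  )
  truth_path <- file.path(out_dir, "truth.yaml")
  yaml::write_yaml(lapply(truths, truth_to_list), truth_path)
  config_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), config_path)
  invisible(list(wells = wells,
                 paths = c(wells = wells_path, truth = truth_path,
                           config = config_path)))
}

#' Run the full analysis pipeline on a wells table
#'
#' Normalizes to antibody-free controls, estimates ND50 per (sample,
#' serotype, format) under the configured model policy with the censoring
#' rule, classifies serostatus under both rules, and - when both formats
#' are present for the same samples - tabulates CSC/VSC discordance with
#' exact McNemar p-values and the Cliff's delta between the formats'
#' normalized transduction values. When `out_dir` is given, each result
#' table is written as CSV along with the resolved configuration.
#'
#' @param wells A wells tibble ([read_wells()] / [simulate_plate()]) or a
#'   path to a wells CSV.
#' @param config A [nab_config()].
#' @param out_dir Optional output directory.
#' @return A list of tibbles: `curves`, `nd50`, `classifications`,
#'   `discordance` (`NULL` unless both formats are present), `format_effect`
#'   (Cliff's delta CSC vs VSC, `NULL` likewise).
#' @export
nab_analyze <- function(wells, config = nab_config(), out_dir = NULL) {
  stopifnot(inherits(config, "nab_config"))
  if (is.character(wells)) wells <- read_wells(wells)
  wells <- validate_wells(wells)
  normalized <- normalize_wells(wells, blank_subtract = config$blank_subtract)
  curves <- normalize_plate(wells, blank_subtract = config$blank_subtract)
  nd50 <- estimate_nd50(normalized, model = config$model, seed = config$seed)
  n_censored <- sum(nd50$censored)
  if (n_censored > 0) {
    message(n_censored, " ND50 estimate(s) censored to the 1/1 placeholder.")
  }
  classifications <- dplyr::bind_rows(
    classify_serostatus(curves, "pool_eligibility",
                        threshold = config$pool_threshold),
    classify_serostatus(curves, "neutralization",
                        threshold = config$neutralization_threshold)
  )
  both_formats <- all(c("CSC", "VSC") %in% wells$format)
  disc <- NULL
  fmt_effect <- NULL
  if (both_formats) {
    paired <- classifications |>
      dplyr::count(.data$serotype, .data$rule, .data$sample_id) |>
      dplyr::filter(.data$n == 2)
    if (nrow(paired) > 0) {
      keep <- dplyr::semi_join(classifications, paired,
                               by = c("serotype", "rule", "sample_id"))
      disc <- discordance(keep)
    }
    fmt_effect <- cliffs_delta(
      normalized$transduction_pct[normalized$format == "VSC"],
      normalized$transduction_pct[normalized$format == "CSC"],
      signed = TRUE, seed = config$seed
    )
  }
  results <- list(curves = curves, nd50 = nd50,
                  classifications = classifications, discordance = disc,
                  format_effect = fmt_effect)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(curves, file.path(out_dir, "curves.csv"))
    write_results(nd50, file.path(out_dir, "nd50.csv"))
    write_results(classifications, file.path(out_dir, "classifications.csv"))
    if (!is.null(disc)) {
      write_results(disc, file.path(out_dir, "discordance.csv"))
    }
    if (!is.null(fmt_effect)) {
      write_results(fmt_effect, file.path(out_dir, "format_effect.csv"))
    }
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  }
  results
}
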