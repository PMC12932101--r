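#' Serum matrix-effect model
#'
#' Serum influences AAV transduction through two antibody-independent
#' routes. Serum pre-incubated with the vector *enhances* transduction
#' (albumin and other components interact with the capsid), saturating at
#' a few percent serum; serum present in the cell-culture medium *inhibits*
#' transduction. The enhancement factor is a saturating hyperbola
#' \eqn{E(s) = 1 + a \, s / (s + k)} and the inhibition factor a Hill-type
#' decay \eqn{I(s) = 1 / (1 + b \, s^h)}, both equal to 1 at zero serum.
#'
#' @param enhance_amplitude Maximum fold-increase above baseline from serum
#'   pre-incubated with the vector (dimensionless, >= 0). Default 4, i.e. a
#'   plateau at five times the serum-free level.
#' @param enhance_halfsat Serum volume fraction at which enhancement is
#'   half-maximal, in (0, 1]. Default 0.05 (enhancement plateaus near 5%
#'   serum).
#' @param inhibit_strength Strength of the serum-on-cells inhibition
#'   (dimensionless, >= 0). Default 4.
#' @param inhibit_shape Shape exponent of the inhibition curve (> 0).
#'   Default 1.
#' @return An object of class `matrix_effect_model` (a named list).
#' @seealso [enhancement_factor()], [inhibition_factor()],
#'   [simulate_serum_titration()]
#' @examples
#' m <- matrix_effect_model()
#' enhancement_factor(c(0, 0.05, 0.5), m)
#' @export
matrix_effect_model <- function(enhance_amplitude = 4,
                                enhance_halfsat = 0.05,
                                inhibit_strength = 4,
                                inhibit_shape = 1) {
  if (enhance_amplitude < 0) abort("`enhance_amplitude` must be >= 0.")
  if (enhance_halfsat <= 0 || enhance_halfsat > 1) {
    abort("`enhance_halfsat` must be in (0, 1].")
  }
  if (inhibit_strength < 0) abort("`inhibit_strength` must be >= 0.")
  if (inhibit_shape <= 0) abort("`inhibit_shape` must be > 0.")
  structure(
    list(enhance_amplitude = enhance_amplitude,
         enhance_halfsat = enhance_halfsat,
         inhibit_strength = inhibit_strength,
         inhibit_shape = inhibit_shape),
    class = "matrix_effect_model"
  )
}

#' Matrix-effect factors
#'
#' @param s Serum volume fraction(s) in \[0, 1\].
#' @param model A [matrix_effect_model()].
#' @return Numeric vector of multiplicative factors on transduction;
#'   `enhancement_factor()` is monotone non-decreasing with E(0) = 1,
#'   `inhibition_factor()` monotone non-increasing with I(0) = 1.
#' @export
enhancement_factor <- function(s, model) {
  stopifnot(inherits(model, "matrix_effect_model"), all(s >= 0))
  1 + model$enhance_amplitude * s / (s + model$enhance_halfsat)
}

#' @rdname enhancement_factor
#' @export
inhibition_factor <- function(s, model) {
  stopifnot(inherits(model, "matrix_effect_model"), all(s >= 0))
  1 / (1 + model$inhibit_strength * s^model$inhibit_shape)
}

#' Ground-truth neutralization profiles for simulated samples
#'
#' @param sample_id Character vector of sample identifiers.
#' @param true_nd50 Dilution fraction in (0, 1] at which true neutralization
#'   is 50%, or `NA` for a seronegative sample (no neutralizing antibodies).
#'   Accepts "1/16"-style strings.
#' @param hill_slope Hill slope of the true neutralization curve (> 0).
#'   Recycled. Default 2.
#' @return A tibble with columns `sample_id`, `true_nd50`, `hill_slope`,
#'   `serostatus_truth` (`"seronegative"` iff `true_nd50` is `NA`).
#' @examples
#' sample_profiles(c("S1", "S2"), true_nd50 = c(NA, "1/16"))
#' @export
sample_profiles <- function(sample_id, true_nd50 = NA, hill_slope = 2) {
  true_nd50 <- parse_dilution(true_nd50)
  n <- length(sample_id)
  true_nd50 <- rep_len(true_nd50, n)
  hill_slope <- rep_len(hill_slope, n)
  if (anyDuplicated(sample_id)) abort("`sample_id` must be unique.")
  ok <- is.na(true_nd50) | (true_nd50 > 0 & true_nd50 <= 1)
  if (!all(ok)) abort("`true_nd50` must be in (0, 1] or NA (seronegative).")
  if (any(hill_slope <= 0)) abort("`hill_slope` must be > 0.")
  tibble::tibble(
    sample_id = as.character(sample_id),
    true_nd50 = true_nd50,
    hill_slope = hill_slope,
    serostatus_truth = ifelse(is.na(true_nd50), "seronegative", "seropositive")
  )
}

#' Assay plate design
#'
#' Describes one assay run: format, dilution series, serum-composition
#' constants, replication, noise level and baseline signal.
#'
#' In the CSC (constant serum concentration) format the test serum is
#' diluted in antibody-free serum so every well carries the same total
#' serum (`csc_total_serum`, default 10%). In the VSC (variable serum
#' concentration) format the test serum is diluted in medium, so total
#' serum per well grows as the test serum is less dilute, on top of the
#' serum contributed by the culture medium (`vsc_medium_serum`, default
#' 1.25%).
#'
#' @param format `"CSC"` or `"VSC"`.
#' @param dilutions Ordered dilution fractions of the test serum, strictly
#'   decreasing by a factor 2, all in (0, 1). Default 1/4 ... 1/128.
#' @param serotype Capsid serotype label. Default `"AAV9"`.
#' @param csc_total_serum Total serum volume fraction per well under CSC.
#'   Default 0.10.
#' @param vsc_medium_serum Serum volume fraction contributed by the culture
#'   medium under VSC. Default 0.0125.
#' @param vsc_test_serum_max Final volume fraction that undiluted test serum
#'   would occupy in a VSC well (the transduction mix is 20 uL into 100 uL
#'   total, so default 0.25 after the mix's own 2-fold step is folded into
#'   the dilution series).
#' @param replicates Wells per (sample, dilution) condition and number of
#'   antibody-free control wells per plate (>= 1). Default 3.
#' @param noise_sigma Log-scale standard deviation of the multiplicative
#'   lognormal measurement noise (>= 0). Default 0.05.
#' @param baseline_rlu Luminescence of an unperturbed well (> 0), in RLU.
#'   Default 1e5.
#' @param seed Integer seed making simulation deterministic.
#' @return An object of class `assay_design` (a named list).
#' @export
assay_design <- function(format = c("CSC", "VSC"),
                         dilutions = dilution_series(),
                         serotype = "AAV9",
                         csc_total_serum = 0.10,
                         vsc_medium_serum = 0.0125,
                         vsc_test_serum_max = 0.25,
                         replicates = 3,
                         noise_sigma = 0.05,
                         baseline_rlu = 1e5,
                         seed = 1L) {
  format <- match.arg(format)
  dilutions <- parse_dilution(dilutions)
  if (length(dilutions) == 0) abort("`dilutions` must be non-empty.")
  if (any(dilutions <= 0) || any(dilutions >= 1)) {
    abort("All dilutions must lie in (0, 1).")
  }
  if (length(dilutions) > 1) {
    ratio <- dilutions[-length(dilutions)] / dilutions[-1]
    if (any(abs(ratio - 2) > 1e-8)) {
      abort("`dilutions` must be strictly decreasing by a factor of 2.")
    }
  }
  if (csc_total_serum <= 0 || csc_total_serum > 1) {
    abort("`csc_total_serum` must be in (0, 1].")
  }
  if (vsc_medium_serum < 0 || vsc_medium_serum >= 1) {
    abort("`vsc_medium_serum` must be in [0, 1).")
  }
  if (vsc_test_serum_max <= 0 || vsc_test_serum_max > 1) {
    abort("`vsc_test_serum_max` must be in (0, 1].")
  }
  if (replicates < 1) abort("`replicates` must be >= 1.")
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  if (baseline_rlu <= 0) abort("`baseline_rlu` must be > 0.")
  structure(
    list(format = format, dilutions = dilutions, serotype = serotype,
         csc_total_serum = csc_total_serum,
         vsc_medium_serum = vsc_medium_serum,
         vsc_test_serum_max = vsc_test_serum_max,
         replicates = as.integer(replicates),
         noise_sigma = noise_sigma, baseline_rlu = baseline_rlu,
         seed = as.integer(seed)),
    class = "assay_design"
  )
}

#' Bundle profiles, matrix model and design into a simulation ground truth
#'
#' @param profiles A tibble from [sample_profiles()].
#' @param matrix A [matrix_effect_model()].
#' @param design An [assay_design()].
#' @return An object of class `simulation_truth`.
#' @export
simulation_truth <- function(profiles, matrix = matrix_effect_model(),
                             design = assay_design()) {
  stopifnot(is.data.frame(profiles),
            all(c("sample_id", "true_nd50", "hill_slope") %in% names(profiles)),
            inherits(matrix, "matrix_effect_model"),
            inherits(design, "assay_design"))
  structure(list(profiles = tibble::as_tibble(profiles),
                 matrix = matrix, design = design),
            class = "simulation_truth")
}

#' Total serum volume fraction in a well
#'
#' Under CSC the total serum is held constant regardless of the test-serum
#' dilution; under VSC the test serum adds to the fixed medium serum, so
#' total serum strictly increases as the test serum is less dilute.
#'
#' @param format `"CSC"` or `"VSC"`.
#' @param dilution Test-serum dilution fraction(s) in (0, 1).
#' @param design An [assay_design()] supplying the composition constants.
#' @return Total serum volume fraction per well.
#' @examples
#' d <- assay_design()
#' serum_composition("CSC", c(1/4, 1/128), d)  # both 0.10
#' serum_composition("VSC", c(1/4, 1/128), d)  # strictly decreasing with d
#' @export
serum_composition <- function(format, dilution, design = assay_design()) {
  stopifnot(inherits(design, "assay_design"))
  dilution <- parse_dilution(dilution)
  if (any(is.na(dilution)) || any(dilution <= 0) || any(dilution >= 1)) {
    abort("`dilution` must lie in (0, 1).")
  }
  format <- match.arg(format, c("CSC", "VSC"))
  if (format == "CSC") {
    rep(design$csc_total_serum, length(dilution))
  } else {
    design$vsc_medium_serum + dilution * design$vsc_test_serum_max
  }
}

# True neutralization survival: fraction of transduction surviving the
# sample's antibodies at test-serum dilution d. Four-parameter Hill with
# bottom 0 / top 1; H(true_nd50) = 0.5, decreasing as serum gets stronger.
hill_survival <- function(dilution, true_nd50, hill_slope) {
  if (is.na(true_nd50)) return(rep(1, length(dilution)))
  1 / (1 + (dilution / true_nd50)^hill_slope)
}

# Serum fraction in the cell medium (drives the inhibition factor):
# CSC seeds cells in serum-free medium; VSC medium carries vsc_medium_serum.
medium_serum <- function(design) {
  if (design$format == "CSC") 0 else design$vsc_medium_serum
}

# Serum fraction pre-incubated with vector in the antibody-free control:
# CSC controls are antibody-free serum at the full csc_total_serum; VSC
# controls are plain medium, so only the medium serum remains.
control_serum <- function(design) {
  if (design$format == "CSC") design$csc_total_serum else design$vsc_medium_serum
}

well_positions <- function(n) {
  rows <- LETTERS[1:8]
  all_wells <- as.vector(t(outer(rows, 1:12, paste0)))
  plates <- ceiling(n / 96)
  tibble::tibble(
    plate_index = rep(seq_len(plates), each = 96)[seq_len(n)],
    well = rep(all_wells, plates)[seq_len(n)]
  )
}

#' Simulate a plate run of the transduction-inhibition assay
#'
#' Generates one well-level luminescence record per (sample, dilution,
#' replicate) condition plus per-plate antibody-free control wells, under
#' the generative model: expected RLU = `baseline_rlu` x E(total serum) x
#' I(medium serum) x H(dilution), where E and I are the matrix-effect
#' factors of the design's format, H is the sample's true Hill
#' neutralization survival (identically 1 for seronegative samples), and
#' measurement noise is multiplicative lognormal with log-scale SD
#' `noise_sigma`. Output is deterministic given `design$seed`.
#'
#' @param truth A [simulation_truth()].
#' @param plate_prefix Prefix for generated plate identifiers.
#' @return A tibble of well records with columns `plate_id`, `well`,
#'   `sample_id`, `role` (`"test"` or `"antibody_free_control"`),
#'   `serotype`, `format`, `dilution` (fraction; `NA` for controls),
#'   `replicate`, `rlu`.
#' @examples
#' tr <- simulation_truth(sample_profiles("S1", "1/16"),
#'                        design = assay_design("CSC", noise_sigma = 0))
#' simulate_plate(tr)
#' @export
simulate_plate <- function(truth, plate_prefix = "plate") {
  stopifnot(inherits(truth, "simulation_truth"))
  design <- truth$design
  profiles <- truth$profiles

  grid <- tidyr::expand_grid(
    sample_id = profiles$sample_id,
    dilution = design$dilutions,
    replicate = seq_len(design$replicates)
  ) |>
    dplyr::left_join(profiles, by = "sample_id")

  s_total <- serum_composition(design$format, grid$dilution, design)
  s_med <- medium_serum(design)
  grid$expected <- design$baseline_rlu *
    enhancement_factor(s_total, truth$matrix) *
    inhibition_factor(s_med, truth$matrix) *
    mapply(function(d, nd, h) hill_survival(d, nd, h),
           grid$dilution, grid$true_nd50, grid$hill_slope)

  # lay test wells out on as many 96-well plates as needed, reserving
  # `replicates` control wells at the end of each plate
  per_plate <- 96 - design$replicates
  n_test <- nrow(grid)
  grid$plate_index <- (seq_len(n_test) - 1) %/% per_plate + 1

  controls <- tidyr::expand_grid(
    plate_index = unique(grid$plate_index),
    replicate = seq_len(design$replicates)
  )
  controls$expected <- design$baseline_rlu *
    enhancement_factor(control_serum(design), truth$matrix) *
    inhibition_factor(s_med, truth$matrix)

  wells <- dplyr::bind_rows(
    dplyr::mutate(grid[c("plate_index", "sample_id", "dilution",
                         "replicate", "expected")],
                  role = "test"),
    dplyr::mutate(controls, sample_id = "control", dilution = NA_real_,
                  role = "antibody_free_control")
  ) |>
    dplyr::arrange(.data$plate_index, .data$role == "antibody_free_control")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(design$seed)
  noise <- if (design$noise_sigma > 0) {
    rlnorm(nrow(wells), meanlog = 0, sdlog = design$noise_sigma)
  } else {
    rep(1, nrow(wells))
  }

  pos <- wells |>
    dplyr::group_by(.data$plate_index) |>
    dplyr::mutate(well = well_positions(96)$well[dplyr::row_number()]) |>
    dplyr::ungroup()

  tibble::tibble(
    plate_id = paste0(plate_prefix, pos$plate_index),
    well = pos$well,
    sample_id = pos$sample_id,
    role = pos$role,
    serotype = design$serotype,
    format = design$format,
    dilution = pos$dilution,
    replicate = as.integer(pos$replicate),
    rlu = pos$expected * noise
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate the serum pre-incubation titration experiment
#'
#' Emulates the calibration experiment that characterizes the two matrix
#' effects separately: antibody-free serum either pre-incubated with the
#' vector (`"on_aav"`, enhancement only) or added to the cell medium
#' (`"on_cells"`, inhibition only), titrated over `serum_levels`, with
#' readouts normalized to the 0% serum condition.
#'
#' @param mode `"on_aav"` or `"on_cells"`.
#' @param serum_levels Serum volume fractions; must include 0 (the
#'   normalization reference).
#' @param matrix A [matrix_effect_model()].
#' @param noise_sigma Log-scale SD of multiplicative lognormal noise.
#' @param replicates Wells per serum level.
#' @param baseline_rlu Baseline luminescence.
#' @param seed Integer seed.
#' @return A tibble with columns `mode`, `serum_level`, `replicate`,
#'   `rlu`, `transduction_pct` (normalized to the mean of the 0% wells).
#' @export
simulate_serum_titration <- function(mode = c("on_aav", "on_cells"),
                                     serum_levels = c(0, 0.01, 0.05, 0.10),
                                     matrix = matrix_effect_model(),
                                     noise_sigma = 0, replicates = 3,
                                     baseline_rlu = 1e5, seed = 1L) {
  mode <- match.arg(mode)
  if (!any(serum_levels == 0)) {
    abort("`serum_levels` must include 0 (the normalization reference).")
  }
  if (any(serum_levels < 0)) abort("`serum_levels` must be >= 0.")
  factor <- if (mode == "on_aav") {
    enhancement_factor(serum_levels, matrix)
  } else {
    inhibition_factor(serum_levels, matrix)
  }
  grid <- tidyr::expand_grid(serum_level = serum_levels,
                             replicate = seq_len(replicates))
  expected <- baseline_rlu * factor[match(grid$serum_level, serum_levels)]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  noise <- if (noise_sigma > 0) {
    rlnorm(nrow(grid), 0, noise_sigma)
  } else rep(1, nrow(grid))
  rlu <- expected * noise
  ref <- mean(rlu[grid$serum_level == 0])
  tibble::tibble(mode = mode, serum_level = grid$serum_level,
                 replicate = as.integer(grid$replicate), rlu = rlu,
                 transduction_pct = 100 * rlu / ref)
}

#' Documented parameter set where VSC masks a real neutralizer
#'
#' Returns a [simulation_truth()] for a single low-titer seropositive sample
#' (true ND50 = 1/6, Hill slope 2) under a matrix model with moderate
#' vector-enhancement (amplitude 4, half-saturation 5% serum). With these
#' values the noise-free CSC curve crosses 50% inside the tested range
#' while the VSC curve of the same sample stays above 50% at every tested
#' dilution, so the two formats disagree on its neutralization status: the
#' baseline inflation of the variable-serum format masks the partial
#' neutralization that the constant-serum format resolves.
#'
#' @param format `"CSC"` or `"VSC"`.
#' @param noise_sigma Measurement noise; default 0 (the masking statement
#'   is about expected curves).
#' @param seed Integer seed.
#' @return A [simulation_truth()].
#' @export
masking_truth <- function(format = c("CSC", "VSC"), noise_sigma = 0,
                          seed = 1L) {
  format <- match.arg(format)
  simulation_truth(
    profiles = sample_profiles("masked_low_titer", true_nd50 = 1 / 6,
                               hill_slope = 2),
    matrix = matrix_effect_model(enhance_amplitude = 4,
                                 enhance_halfsat = 0.05),
    design = assay_design(format, noise_sigma = noise_sigma, seed = seed)
  )
}
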