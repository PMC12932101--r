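#' Read well-level plate data
#'
#' Reads a long-format wells CSV (one row per well, columns `plate_id`,
#' `well`, `sample_id`, `role`, `serotype`, `format`, `dilution`,
#' `replicate`, `rlu`) or, when `plate_map` is given, a wide 8 x 12 plate
#' grid of raw luminescence whose per-well metadata come from a plate-map
#' YAML file. Well labels are normalized ("a01" becomes "A1") and the
#' result is validated: duplicated (plate, well) positions, negative RLU,
#' test wells without a dilution, and test groups lacking an antibody-free
#' control are all rejected with the offending item named.
#'
#' @param path Path to the CSV file.
#' @param plate_map Optional path to a plate-map YAML (see Details), which
#'   switches parsing to the wide-grid layout.
#' @details The plate-map YAML has top-level fields `plate_id`, optional
#'   defaults `serotype` and `format`, and a `wells` mapping from well
#'   label to the per-well fields (`sample_id`, `role`, `dilution`,
#'   `replicate`, and optionally `serotype`/`format` overriding the
#'   defaults). Dilutions may be written as "1/8"-style fractions. Grid
#'   cells without a plate-map entry are treated as empty and dropped.
#' @return A validated tibble of well records; `dilution` is the numeric
#'   dilution fraction (`NA` for control and blank wells). Row order of the
#'   input is preserved.
#' @seealso [write_results()], [validate_wells()]
#' @export
read_wells <- function(path, plate_map = NULL) {
  if (is.null(plate_map)) {
    raw <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
    required <- c("plate_id", "well", "sample_id", "role", "serotype",
                  "format", "dilution", "replicate", "rlu")
    missing <- setdiff(required, names(raw))
    if (length(missing) > 0) {
      abort(paste0("Wells file is missing required column(s): ",
                   paste(missing, collapse = ", ")))
    }
    wells <- tibble::tibble(
      plate_id = raw$plate_id,
      well = normalize_well(raw$well),
      sample_id = raw$sample_id,
      role = raw$role,
      serotype = raw$serotype,
      format = raw$format,
      dilution = parse_dilution(raw$dilution),
      replicate = as.integer(raw$replicate),
      rlu = as.numeric(raw$rlu)
    )
    if ("sample_type" %in% names(raw)) wells$sample_type <- raw$sample_type
  } else {
    wells <- read_wells_grid(path, plate_map)
  }
  validate_wells(wells)
}

read_wells_grid <- function(path, plate_map) {
  map <- tryCatch(yaml::read_yaml(plate_map), error = function(e) {
    abort(paste0("Malformed plate-map YAML: ", conditionMessage(e)))
  })
  if (is.null(map$plate_id) || is.null(map$wells)) {
    abort("Plate map must contain `plate_id` and `wells`.")
  }
  grid <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  rows <- toupper(trimws(grid[[1]]))
  long <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    cols <- names(grid)[-1]
    tibble::tibble(well = paste0(rows[i], sub("^[^0-9]*", "", cols)),
                   rlu = as.numeric(unlist(grid[i, -1])))
  })
  entries <- map$wells
  names(entries) <- normalize_well(names(entries))
  long$well <- normalize_well(long$well)
  long <- long[long$well %in% names(entries) & !is.na(long$rlu), ]
  meta <- purrr::map_dfr(long$well, function(w) {
    e <- entries[[w]]
    tibble::tibble(
      sample_id = as.character(e$sample_id %||% "control"),
      role = as.character(e$role %||% "test"),
      serotype = as.character(e$serotype %||% map$serotype %||% "unknown"),
      format = as.character(e$format %||% map$format %||% "CSC"),
      dilution = parse_dilution(e$dilution %||% NA),
      replicate = as.integer(e$replicate %||% 1L)
    )
  })
  tibble::tibble(plate_id = as.character(map$plate_id), well = long$well,
                 meta, rlu = long$rlu)
}

#' Normalize 96-well plate coordinates
#'
#' @param well Character vector of well labels, e.g. "a01", "B3".
#' @return Labels in canonical letter-row, 1-based-column form ("A1").
#' @export
normalize_well <- function(well) {
  well <- toupper(trimws(well))
  row <- substr(well, 1, 1)
  col <- suppressWarnings(as.integer(substring(well, 2)))
  bad <- !(row %in% LETTERS[1:8]) | is.na(col) | col < 1 | col > 12
  if (any(bad)) {
    abort(paste0("Invalid well label(s): ",
                 paste(unique(well[bad]), collapse = ", ")))
  }
  paste0(row, col)
}

#' Validate a wells table
#'
#' Enforces the structural contract of plate data: unique (plate, well)
#' positions, non-negative luminescence, roles among test /
#' antibody_free_control / blank, dilutions present exactly for test wells,
#' and at least one antibody-free control in every (serotype, format,
#' plate) group that contains test wells.
#'
#' @param wells A wells tibble (see [read_wells()] for columns).
#' @return `wells`, invisibly validated (returned unchanged).
#' @export
validate_wells <- function(wells) {
  stopifnot(is.data.frame(wells))
  dup <- duplicated(wells[c("plate_id", "well")])
  if (any(dup)) {
    abort(paste0("Duplicate well position(s): ",
                 paste(unique(paste0(wells$plate_id[dup], ":", wells$well[dup])),
                       collapse = ", ")))
  }
  if (any(is.na(wells$rlu)) || any(wells$rlu < 0)) {
    abort("RLU values must be present and >= 0.")
  }
  bad_role <- setdiff(unique(wells$role),
                      c("test", "antibody_free_control", "blank"))
  if (length(bad_role) > 0) {
    abort(paste0("Unknown well role(s): ", paste(bad_role, collapse = ", ")))
  }
  test <- wells$role == "test"
  if (any(test & is.na(wells$dilution))) {
    abort("Test wells must carry a dilution.")
  }
  ctrl <- wells$role == "antibody_free_control"
  if (any(ctrl & !is.na(wells$dilution))) {
    abort("Antibody-free control wells must not carry a dilution.")
  }
  groups <- wells |>
    dplyr::group_by(.data$plate_id, .data$serotype, .data$format) |>
    dplyr::summarise(
      has_test = any(.data$role == "test"),
      has_control = any(.data$role == "antibody_free_control"),
      .groups = "drop"
    )
  orphan <- groups[groups$has_test & !groups$has_control, ]
  if (nrow(orphan) > 0) {
    abort(paste0(
      "Test group(s) lacking an antibody-free control: ",
      paste(paste0("(", orphan$plate_id, ", ", orphan$serotype, ", ",
                   orphan$format, ")"), collapse = ", ")
    ))
  }
  wells
}

#' Write a results table to CSV
#'
#' Writes any results tibble (wells, curves, ND50 tables, classifications,
#' comparisons) with a stable column order. Columns holding dilution
#' fractions (`dilution`, `nd50`, `ci_low`, `ci_high`) gain a paired
#' `<column>_display` fraction string ("1/8") so titers stay human-readable
#' while the decimal remains the machine value; [read_results()] drops the
#' display columns again, so write/read round-trips losslessly.
#'
#' @param results A data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  stopifnot(is.data.frame(results))
  out <- tibble::as_tibble(results)
  for (col in intersect(c("dilution", "nd50", "ci_low", "ci_high"), names(out))) {
    if (is.numeric(out[[col]])) {
      disp <- paste0(col, "_display")
      pos <- match(col, names(out))
      out <- tibble::add_column(out, !!disp := dilution_label(out[[col]]),
                                .after = pos)
    }
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_results
#' @param ... Passed to [readr::read_csv()].
#' @export
read_results <- function(path, ...) {
  out <- readr::read_csv(path, show_col_types = FALSE, ...)
  out[!grepl("_display$", names(out))]
}
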