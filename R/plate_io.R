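# Reading, validating and joining plate-reader exports, layouts and metadata.
#
# Interchange dialect: comma-delimited UTF-8 with a header row. Grid files are
# one plate per file, row labels A-H in the first column, column headers 1-12.
# Long files may hold several plates (plate_id column). All parsing is strict:
# a malformed cell fails with an error naming the plate and well, never a
# silent NA.

#' Parse an 8 x 12 plate-reader grid export
#'
#' Reads a comma-delimited 96-well grid (rows A--H, columns 1--12) of relative
#' fluorescence units (RFU) into a long well table. Every well starts with
#' `role = "empty"`; roles and sample identities are attached later with
#' [join_layout()].
#'
#' @param file Path to a CSV file, or a character vector of CSV lines.
#' @param plate_id Label identifying the plate (one plate per grid file).
#' @return A tibble with one row per well: `plate_id`, `well`, `row`,
#'   `column`, `fluorescence`, `role`, `sample_id`, `gain`.
#' @export
#' @examples
#' lines <- c(paste(c("row", 1:12), collapse = ","),
#'            paste(c("A", rep(1000, 12)), collapse = ","))
#' # a full grid needs rows A-H; see parse_long_table() for partial plates
parse_plate_grid <- function(file, plate_id) {
  stopifnot(is.character(plate_id), length(plate_id) == 1)
  raw <- read_csv_strict(file)
  if (ncol(raw) < 13) {
    missing_cols <- setdiff(as.character(PLATE_COLS), colnames(raw))
    abort_grazekit(sprintf("grid for plate %s: column(s) %s absent", plate_id,
                           paste(missing_cols, collapse = ", ")),
                   class = "grazekit_parse_error")
  }
  hdr <- colnames(raw)[-1]
  if (!identical(hdr[1:12], as.character(PLATE_COLS))) {
    abort_grazekit(sprintf("grid for plate %s: column headers must be 1..12, got: %s",
                           plate_id, paste(utils::head(hdr, 12), collapse = ", ")),
                   class = "grazekit_parse_error")
  }
  row_labels <- toupper(trimws(raw[[1]]))
  absent <- setdiff(PLATE_ROWS, row_labels)
  if (length(absent) > 0) {
    abort_grazekit(sprintf("grid for plate %s: row %s absent", plate_id,
                           paste(absent, collapse = ", ")),
                   class = "grazekit_parse_error")
  }
  extra <- setdiff(row_labels, PLATE_ROWS)
  if (length(extra) > 0 || anyDuplicated(row_labels)) {
    abort_grazekit(sprintf("grid for plate %s: expected exactly rows A-H, got: %s",
                           plate_id, paste(row_labels, collapse = ", ")),
                   class = "grazekit_parse_error")
  }
  recs <- lapply(PLATE_ROWS, function(r) {
    vals <- as.character(unlist(raw[row_labels == r, 1 + PLATE_COLS]))
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(num))
    if (length(bad) > 0) {
      abort_grazekit(sprintf("grid for plate %s: non-numeric fluorescence at %s:%s (value '%s')",
                             plate_id, plate_id, well_string(r, bad[1]), vals[bad[1]]),
                     class = "grazekit_parse_error")
    }
    tibble::tibble(row = r, column = PLATE_COLS, fluorescence = num)
  })
  wells <- dplyr::bind_rows(recs)
  wells <- tibble::tibble(
    plate_id = plate_id,
    well = well_string(wells$row, wells$column),
    row = wells$row, column = wells$column,
    fluorescence = wells$fluorescence,
    role = "empty", sample_id = NA_character_, gain = NA_integer_
  )
  validate_wells(wells)
  wells
}

#' Parse a long-format well table
#'
#' Reads a comma-delimited table with columns `plate_id`, `well`,
#' `fluorescence` and optionally `role`, `sample_id`, `gain`. Duplicate
#' (plate, well) pairs and malformed well addresses are rejected.
#'
#' @inheritParams parse_plate_grid
#' @return A well tibble as for [parse_plate_grid()].
#' @export
parse_long_table <- function(file) {
  raw <- read_csv_strict(file)
  need <- c("plate_id", "well", "fluorescence")
  miss <- setdiff(need, colnames(raw))
  if (length(miss) > 0) {
    abort_grazekit(sprintf("long table: required column(s) absent: %s",
                           paste(miss, collapse = ", ")),
                   class = "grazekit_parse_error")
  }
  addr <- parse_well_string(raw$well)
  if (any(!addr$ok)) {
    bad <- raw$well[!addr$ok][1]
    abort_grazekit(sprintf("long table: invalid well address '%s' (expected A1..H12)", bad),
                   class = "grazekit_parse_error")
  }
  fl <- suppressWarnings(as.numeric(raw$fluorescence))
  if (any(is.na(fl))) {
    i <- which(is.na(fl))[1]
    abort_grazekit(sprintf("long table: non-numeric fluorescence at %s:%s (value '%s')",
                           raw$plate_id[i], raw$well[i], as.character(raw$fluorescence[i])),
                   class = "grazekit_parse_error")
  }
  key <- paste(raw$plate_id, toupper(trimws(raw$well)))
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    abort_grazekit(sprintf("long table: duplicate well(s): %s", paste(dups, collapse = ", ")),
                   class = "grazekit_parse_error")
  }
  wells <- tibble::tibble(
    plate_id = as.character(raw$plate_id),
    well = well_string(addr$row, addr$column),
    row = addr$row, column = addr$column,
    fluorescence = fl,
    role = if ("role" %in% colnames(raw)) as.character(raw$role) else "empty",
    sample_id = if ("sample_id" %in% colnames(raw)) as.character(raw$sample_id) else NA_character_,
    gain = if ("gain" %in% colnames(raw)) as.integer(raw$gain) else NA_integer_
  )
  wells$role[is.na(wells$role) | !nzchar(wells$role)] <- "empty"
  wells$sample_id[!is.na(wells$sample_id) & !nzchar(wells$sample_id)] <- NA_character_
  validate_wells(wells)
  wells
}

#' Convert a long well table back to an 8 x 12 grid
#'
#' Inverse of [parse_plate_grid()] for one complete plate; the grid-long-grid
#' round trip reproduces all 96 fluorescence values exactly.
#'
#' @param wells Well tibble holding the 96 wells of a single plate.
#' @return A data frame with a `row` column (A--H) and columns `1`..`12`.
#' @export
wells_to_grid <- function(wells) {
  plate <- unique(wells$plate_id)
  if (length(plate) != 1) {
    abort_grazekit("wells_to_grid expects the wells of exactly one plate")
  }
  if (nrow(wells) != 96 || anyDuplicated(wells$well) > 0) {
    abort_grazekit(sprintf("plate %s: grid output needs all 96 distinct wells, got %d",
                           plate, nrow(wells)))
  }
  mat <- matrix(NA_real_, 8, 12, dimnames = list(PLATE_ROWS, as.character(PLATE_COLS)))
  mat[cbind(wells$row, as.character(wells$column))] <- wells$fluorescence
  out <- data.frame(row = PLATE_ROWS, mat, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a plate grid CSV
#'
#' @param wells Well tibble for one plate (see [wells_to_grid()]).
#' @param file Output path.
#' @export
write_plate_grid <- function(wells, file) {
  utils::write.csv(wells_to_grid(wells), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Join a plate layout and sample metadata onto a well table
#'
#' Attaches a role (sample / control / stressor_control / blank) and, for
#' sample wells, the animal's identity, genotype, block and status to each
#' well. The two technical-replicate wells of one animal are linked through a
#' shared `sample_id`; the per-sample replicate count is recorded in
#' `n_tech_reps`. Fluorescence values are never altered.
#'
#' @param wells Well tibble from [parse_plate_grid()] or [parse_long_table()].
#' @param layout Tibble or CSV path with columns `plate_id`, `well`, `role`
#'   and (for samples) `sample_id`.
#' @param meta Tibble or CSV path with columns `sample_id`, `genotype`,
#'   `block`, `status`, and optional `volume_mL`, `hours`.
#' @return Annotated well tibble.
#' @export
join_layout <- function(wells, layout, meta) {
  if (is.character(layout)) layout <- read_layout(layout)
  if (is.character(meta)) meta <- read_sample_meta(meta)
  layout <- tibble::as_tibble(layout)
  meta <- tibble::as_tibble(meta)

  if (nrow(layout) == 0) {
    rlang::warn("empty layout: all wells keep role = 'empty'")
    wells$n_tech_reps <- NA_integer_
    return(annotate_meta(wells, meta))
  }
  need <- c("plate_id", "well", "role")
  miss <- setdiff(need, colnames(layout))
  if (length(miss) > 0) {
    abort_grazekit(sprintf("layout: required column(s) absent: %s", paste(miss, collapse = ", ")),
                   class = "grazekit_parse_error")
  }
  if (!"sample_id" %in% colnames(layout)) layout$sample_id <- NA_character_
  layout$sample_id[!is.na(layout$sample_id) & !nzchar(trimws(layout$sample_id))] <- NA_character_
  addr <- parse_well_string(layout$well)
  if (any(!addr$ok)) {
    abort_grazekit(sprintf("layout: invalid well address '%s'", layout$well[!addr$ok][1]),
                   class = "grazekit_parse_error")
  }
  layout$well <- well_string(addr$row, addr$column)

  key_wells <- paste(wells$plate_id, wells$well)
  key_layout <- paste(layout$plate_id, layout$well)
  if (anyDuplicated(key_layout)) {
    abort_grazekit(sprintf("layout: duplicate well(s): %s",
                           paste(unique(key_layout[duplicated(key_layout)]), collapse = ", ")),
                   class = "grazekit_parse_error")
  }
  absent <- setdiff(key_layout, key_wells)
  if (length(absent) > 0) {
    abort_grazekit(sprintf("layout names well(s) not present in the reads: %s",
                           paste(absent, collapse = ", ")),
                   class = "grazekit_parse_error")
  }
  bad_role <- setdiff(unique(layout$role), WELL_ROLES)
  if (length(bad_role) > 0) {
    abort_grazekit(sprintf("layout: unknown role(s): %s", paste(bad_role, collapse = ", ")),
                   class = "grazekit_parse_error")
  }

  idx <- match(key_wells, key_layout)
  hit <- !is.na(idx)
  wells$role[hit] <- layout$role[idx[hit]]
  wells$sample_id[hit] <- layout$sample_id[idx[hit]]
  validate_wells(wells)

  sample_ids <- unique(wells$sample_id[wells$role == "sample"])
  no_meta <- setdiff(sample_ids, meta$sample_id)
  if (length(no_meta) > 0) {
    abort_grazekit(sprintf("layout sample(s) without metadata: %s",
                           paste(no_meta, collapse = ", ")),
                   class = "grazekit_parse_error")
  }
  reps <- table(wells$sample_id[wells$role == "sample"])
  wells$n_tech_reps <- ifelse(wells$role == "sample",
                              as.integer(reps[wells$sample_id]), NA_integer_)
  annotate_meta(wells, meta)
}

annotate_meta <- function(wells, meta) {
  if (nrow(meta) > 0) {
    if (anyDuplicated(meta$sample_id)) {
      abort_grazekit("metadata: duplicate sample_id", class = "grazekit_parse_error")
    }
    parse_status(meta$status)  # validate flags early
    keep <- c("sample_id", "genotype", "block", "status",
              intersect(c("volume_mL", "hours"), colnames(meta)))
    wells <- dplyr::left_join(wells, meta[, keep], by = "sample_id")
  } else {
    wells$genotype <- NA_character_
    wells$block <- NA_character_
    wells$status <- NA_character_
  }
  for (col in c("genotype", "block", "status")) {
    if (!col %in% colnames(wells)) wells[[col]] <- NA_character_
  }
  if (!"volume_mL" %in% colnames(wells)) wells$volume_mL <- NA_real_
  if (!"hours" %in% colnames(wells)) wells$hours <- NA_real_
  tibble::as_tibble(wells)
}

#' Read a plate layout CSV
#' @param file Path to a CSV with columns `plate_id`, `well`, `role`, `sample_id`.
#' @return Layout tibble.
#' @export
read_layout <- function(file) {
  tibble::as_tibble(read_csv_strict(file))
}

#' Read a sample metadata CSV
#' @param file Path to a CSV with columns `sample_id`, `genotype`, `block`,
#'   `status` and optional `volume_mL`, `hours`.
#' @return Metadata tibble with validated columns.
#' @export
read_sample_meta <- function(file) {
  meta <- tibble::as_tibble(read_csv_strict(file))
  need <- c("sample_id", "genotype", "block", "status")
  miss <- setdiff(need, colnames(meta))
  if (length(miss) > 0) {
    abort_grazekit(sprintf("metadata: required column(s) absent: %s",
                           paste(miss, collapse = ", ")),
                   class = "grazekit_parse_error")
  }
  for (col in c("volume_mL", "hours")) {
    if (col %in% colnames(meta)) {
      meta[[col]] <- as.numeric(meta[[col]])
      if (any(!is.na(meta[[col]]) & meta[[col]] <= 0)) {
        abort_grazekit(sprintf("metadata: %s must be positive", col),
                       class = "grazekit_parse_error")
      }
    }
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta
}

#' Write the annotated well table
#' @param wells Annotated well tibble.
#' @param file Output CSV path.
#' @export
write_well_table <- function(wells, file) {
  utils::write.csv(wells, file, row.names = FALSE)
  invisible(file)
}

# strict CSV reader used by all parsers: everything as character, no coercion
read_csv_strict <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE, fileEncoding = "UTF-8")
  if (ncol(df) < 1) abort_grazekit("empty input file", class = "grazekit_parse_error")
  df
}

validate_wells <- function(wells) {
  if (any(!is.finite(wells$fluorescence))) {
    abort_grazekit("fluorescence must be finite", class = "grazekit_parse_error")
  }
  if (any(wells$fluorescence < 0)) {
    i <- which(wells$fluorescence < 0)[1]
    abort_grazekit(sprintf("negative fluorescence at %s:%s", wells$plate_id[i], wells$well[i]),
                   class = "grazekit_parse_error")
  }
  key <- paste(wells$plate_id, wells$well)
  if (anyDuplicated(key)) {
    abort_grazekit(sprintf("duplicate well(s): %s",
                           paste(unique(key[duplicated(key)]), collapse = ", ")),
                   class = "grazekit_parse_error")
  }
  samp <- wells$role == "sample"
  if (any(samp & is.na(wells$sample_id))) {
    i <- which(samp & is.na(wells$sample_id))[1]
    abort_grazekit(sprintf("sample well without sample_id at %s:%s",
                           wells$plate_id[i], wells$well[i]),
                   class = "grazekit_parse_error")
  }
  if (any(!samp & !is.na(wells$sample_id))) {
    i <- which(!samp & !is.na(wells$sample_id))[1]
    abort_grazekit(sprintf("non-sample well carries a sample_id at %s:%s",
                           wells$plate_id[i], wells$well[i]),
                   class = "grazekit_parse_error")
  }
  invisible(wells)
}

#' Assay configuration
#'
#' Bundles the assay constants and estimator options used throughout the
#' pipeline. Defaults follow the standard protocol: 10 mL of medium per tube
#' and a 7 hr assay.
#'
#' @param default_volume_mL Medium volume per tube (mL); per-sample overrides
#'   come from the metadata `volume_mL` column.
#' @param default_hours Assay duration (hr); overridable per sample.
#' @param output_units `"mL_per_hr"` (canonical) or `"L_per_day"`.
#' @param tech_rep_cv_warn Technical-replicate coefficient of variation above
#'   which a sample is flagged `high_tech_cv` (fraction, default 0.15).
#' @param bootstrap_B Number of bootstrap resamples for the percentile CI;
#'   0 disables the CI.
#' @param rng_seed Integer seed driving all randomness (required when
#'   `bootstrap_B > 0`).
#' @param blank_subtract If `TRUE`, the per-plate mean of `blank` wells is
#'   subtracted from every well before any ratio is formed. Default `FALSE`.
#' @param gain_range Accepted fluorometer gain range; reads outside it only
#'   warn.
#' @return An `assay_config` list.
#' @export
assay_config <- function(default_volume_mL = 10, default_hours = 7,
                         output_units = c("mL_per_hr", "L_per_day"),
                         tech_rep_cv_warn = 0.15, bootstrap_B = 2000,
                         rng_seed = NULL, blank_subtract = FALSE,
                         gain_range = c(112, 120)) {
  output_units <- match.arg(output_units)
  stopifnot(default_volume_mL > 0, default_hours > 0,
            tech_rep_cv_warn > 0, tech_rep_cv_warn < 1, bootstrap_B >= 0)
  if (bootstrap_B > 0 && is.null(rng_seed)) {
    abort_grazekit("rng_seed is required when bootstrap_B > 0",
                   class = "grazekit_config_error")
  }
  structure(list(default_volume_mL = default_volume_mL,
                 default_hours = default_hours,
                 output_units = output_units,
                 tech_rep_cv_warn = tech_rep_cv_warn,
                 bootstrap_B = as.integer(bootstrap_B),
                 rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed),
                 blank_subtract = isTRUE(blank_subtract),
                 gain_range = gain_range),
            class = "assay_config")
}

#' Read an assay configuration file
#'
#' YAML file whose keys mirror the [assay_config()] arguments.
#'
#' @param file Path to the YAML config.
#' @return An `assay_config` list.
#' @export
read_assay_config <- function(file) {
  vals <- yaml::read_yaml(file)
  known <- names(formals(assay_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort_grazekit(sprintf("config: unknown key(s): %s", paste(unknown, collapse = ", ")),
                   class = "grazekit_config_error")
  }
  do.call(assay_config, vals)
}

#' Warn when fluorometer gains fall outside the accepted range
#'
#' The detector gain changes the RFU scale, not within-plate ratios, so
#' out-of-range gains are reported as a warning rather than an error.
#'
#' @param wells Well tibble with a `gain` column.
#' @param config [assay_config()] holding `gain_range`.
#' @return Invisibly, the offending subset of wells.
#' @export
check_gain <- function(wells, config = assay_config(bootstrap_B = 0)) {
  g <- wells$gain
  bad <- !is.na(g) & (g < config$gain_range[1] | g > config$gain_range[2])
  if (any(bad)) {
    rlang::warn(sprintf("gain outside accepted range [%s, %s] on %d well(s), e.g. %s:%s",
                        config$gain_range[1], config$gain_range[2], sum(bad),
                        wells$plate_id[bad][1], wells$well[bad][1]))
  }
  invisible(wells[bad, ])
}
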