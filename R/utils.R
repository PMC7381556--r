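# Internal helpers shared across modules.

PLATE_ROWS <- LETTERS[1:8]
PLATE_COLS <- 1:12

QC_FLAGS <- c("negative_rate", "died", "male", "high_tech_cv")
EXCLUDING_FLAGS <- c("negative_rate", "died", "male")
WELL_ROLES <- c("sample", "control", "stressor_control", "blank", "empty")
UNIT_TOKENS <- c("mL_per_hr", "L_per_day")

#' @importFrom rlang abort warn inform
NULL

abort_grazekit <- function(msg, class = "grazekit_error") {
  rlang::abort(msg, class = c(class, "grazekit_error"))
}

# "A1".."H12" -> list(row, column); vectorized, NA for malformed input
parse_well_string <- function(well) {
  well <- toupper(trimws(well))
  ok <- grepl("^[A-H]([1-9]|1[0-2])$", well)
  row <- ifelse(ok, substr(well, 1, 1), NA_character_)
  col <- ifelse(ok, suppressWarnings(as.integer(substring(well, 2))), NA_integer_)
  list(row = row, column = as.integer(col), ok = ok)
}

well_string <- function(row, column) paste0(row, column)

# split "died;male" style status strings into a list of character vectors
parse_status <- function(status) {
  status[is.na(status) | !nzchar(trimws(status))] <- "ok"
  lapply(strsplit(status, "[;,+]"), function(s) {
    s <- tolower(trimws(s))
    s <- s[nzchar(s)]
    bad <- setdiff(s, c("alive", "died", "male", "ok"))
    if (length(bad) > 0) {
      abort_grazekit(sprintf("unknown status flag(s): %s", paste(bad, collapse = ", ")),
                     class = "grazekit_parse_error")
    }
    if (length(s) == 0) "ok" else s
  })
}

has_status <- function(status_list, flag) {
  vapply(status_list, function(s) flag %in% s, logical(1))
}

# deterministic child seeds below 2^31, derived from one master seed
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
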