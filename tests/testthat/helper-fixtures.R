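# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# Annotated well table for one or more plates, bypassing the CSV layer.
# controls/samples are per-plate: controls = numeric vector, samples = named
# list sample_id -> numeric replicate values.
toy_wells <- function(controls, samples, plate_id = "P1", genotype = "G1",
                      block = "B1", status = "ok", blanks = numeric(),
                      control_role = "control", volume_mL = NA_real_,
                      hours = NA_real_) {
  rows <- list()
  add <- function(fl, role, sid) {
    start <- sum(vapply(rows, nrow, integer(1)))
    idx <- start + seq_along(fl)
    tibble::tibble(
      plate_id = plate_id,
      well = paste0(LETTERS[(idx - 1) %/% 12 + 1], (idx - 1) %% 12 + 1),
      row = LETTERS[(idx - 1) %/% 12 + 1],
      column = as.integer((idx - 1) %% 12 + 1),
      fluorescence = fl, role = role, sample_id = sid, gain = NA_integer_
    )
  }
  rows[[length(rows) + 1]] <- add(controls, control_role, NA_character_)
  if (length(blanks) > 0) rows[[length(rows) + 1]] <- add(blanks, "blank", NA_character_)
  sids <- names(samples)
  if (is.null(sids)) sids <- character(0)
  geno <- rep_len(genotype, length(sids))
  blk <- rep_len(block, length(sids))
  stat <- rep_len(status, length(sids))
  for (i in seq_along(samples)) {
    rows[[length(rows) + 1]] <- add(samples[[i]], "sample", sids[i])
  }
  wells <- dplyr::bind_rows(rows)
  wells$n_tech_reps <- NA_integer_
  n_reps <- table(wells$sample_id[wells$role == "sample"])
  is_s <- wells$role == "sample"
  wells$n_tech_reps[is_s] <- as.integer(n_reps[wells$sample_id[is_s]])
  meta <- tibble::tibble(sample_id = sids, genotype = geno, block = blk, status = stat)
  wells <- dplyr::left_join(wells, meta, by = "sample_id")
  wells$volume_mL <- ifelse(is_s, volume_mL, NA_real_)
  wells$hours <- ifelse(is_s, hours, NA_real_)
  wells
}

# bind toy plates together
bind_plates <- function(...) dplyr::bind_rows(...)

# full 8x12 grid CSV text for one plate, constant or matrix values
grid_csv_lines <- function(values = 1000) {
  if (length(values) == 1) values <- matrix(values, 8, 12)
  c(paste(c("row", 1:12), collapse = ","),
    vapply(1:8, function(i) paste(c(LETTERS[i], values[i, ]), collapse = ","),
           character(1)))
}

write_tmp_csv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# an estimate tibble for the stats layer, generated directly
make_estimates <- function(means, n = 10, sd = 0, blocks = c("B1", "B2"),
                           block_effect = 0, seed = NULL, interaction = NULL) {
  gen <- function() {
    rows <- list()
    for (g in names(means)) {
      for (b in seq_along(blocks)) {
        mu <- means[[g]] + block_effect * (b - 1)
        if (!is.null(interaction)) mu <- mu + interaction[[g]][b]
        rows[[length(rows) + 1]] <- tibble::tibble(
          sample_id = paste0(g, "_", blocks[b], "_", seq_len(n)),
          genotype = g, block = blocks[b],
          f_value = mu + if (sd > 0) stats::rnorm(n, 0, sd) else
            rep_len(c(-0.01, 0, 0.01), n)  # fixed spread so residual SS > 0
        )
      }
    }
    dplyr::bind_rows(rows)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
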