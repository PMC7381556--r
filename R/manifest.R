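# Provenance manifest written next to every CLI output set.

#' Write a run manifest
#'
#' Records the command, configuration snapshot, MD5 digests of every input
#' file, the seed, package version and a timestamp as `manifest.json` in the
#' output directory. Reruns with identical manifest inputs reproduce
#' identical outputs for deterministic commands.
#'
#' @param dir Output directory.
#' @param command Subcommand name.
#' @param inputs Character vector of input file paths.
#' @param config Configuration list (stored as-is).
#' @param seed Integer seed or `NULL`.
#' @return Invisibly, the manifest path.
#' @export
write_run_manifest <- function(dir, command, inputs = character(),
                               config = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- inputs[!is.na(inputs)]
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(normalizePath(inputs)))
  } else list()
  manifest <- list(
    command = command,
    config = if (is.null(config)) NULL else unclass(config),
    input_digests = digests,
    seed = seed,
    package_version = as.character(utils::packageVersion("grazekit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
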