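#' Write a run manifest
#'
#' Records everything needed to reproduce a run — resolved configuration,
#' input file digests, seed, package version and a timestamp — as JSON.
#' Intended to be written before any computation output.
#'
#' @param path Output JSON path.
#' @param config An [ldra_control()] configuration.
#' @param inputs Character vector of input file paths (digested with MD5).
#' @param extra Optional named list merged into the manifest.
#' @return Invisibly, the manifest list.
#' @export
write_run_manifest <- function(path, config, inputs = character(0),
                               extra = list()) {
  digests <- lapply(inputs, function(p) {
    list(path = p,
         md5 = if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_)
  })
  manifest <- c(list(
    tool = "ldra",
    version = as.character(utils::packageVersion("ldra")),
    created_utc = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    seed = config$seed,
    config = unclass(config),
    inputs = digests
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
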