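# Run manifest: a JSON snapshot tying a training run to its inputs and
# outputs so a run can be reproduced and checked byte-for-byte.

#' Write a run manifest
#'
#' Records the full configuration, the MD5 digests of the input files, the
#' output paths and the final structure report as JSON. Written atomically
#' (temp file + rename). Re-running the pipeline with the same inputs and
#' seed reproduces an identical manifest apart from nothing: no timestamps
#' are stored.
#'
#' @param path output JSON path.
#' @param config a [train_config()].
#' @param inputs named character vector of input file paths to digest.
#' @param outputs named character vector of output file paths.
#' @param report optional [structure_report()].
#' @return Invisibly, the manifest list.
#' @export
write_run_manifest <- function(path, config, inputs, outputs, report = NULL) {
  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    input_digests = as.list(tools::md5sum(inputs)),
    outputs = as.list(outputs))
  if (!is.null(report)) manifest$structure_report <- unclass(report)
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  file.rename(tmp, path)
  invisible(manifest)
}
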