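#' Write a selection report
#'
#' JSON reports carry the full result — selected feature names and
#' indices, subset size, reduction rate, final accuracy, fitness
#' trajectory, config echo and seed — and round-trip losslessly through
#' [read_report()]. The TSV variant lists one selected feature per line
#' (name and original index).
#'
#' @param result An `hfia_result` from [run_hfia()].
#' @param path Output file path.
#' @param format `"json"` (default) or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("json", "tsv")) {
  stopifnot(inherits(result, "hfia_result"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(result), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    readr::write_tsv(tidy(result), path, col_names = TRUE, progress = FALSE)
  }
  invisible(path)
}

#' Read back a JSON selection report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return An `hfia_result`.
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$selected_features <- as.integer(raw$selected_features)
  structure(raw, class = "hfia_result")
}
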