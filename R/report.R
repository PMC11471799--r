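# JSON serialization of model-comparison reports. Deterministic output
# (fixed key order, full-precision numbers, no timestamps), so identical
# runs write byte-identical files; the provenance block records everything
# needed to re-run the comparison.

#' Write a model-comparison report to JSON
#'
#' @param report a \code{\link{compare_variants}} result.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "model_comparison_report"))
  x <- unclass(report)
  x$nll <- as.list(x$nll)
  x$theta_hat <- lapply(x$theta_hat, as.list)
  x$key_cells_inside <- as.list(x$key_cells_inside)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read a model-comparison report from JSON
#'
#' Inverse of \code{\link{write_report}}: restores the named vectors, the
#' coverage data frames and the class, so a written report round-trips
#' unchanged.
#'
#' @param path JSON file written by \code{\link{write_report}}.
#' @return A \code{model_comparison_report}.
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$nll <- unlist(x$nll)
  x$theta_hat <- lapply(x$theta_hat, unlist)
  x$key_cells_inside <- unlist(x$key_cells_inside)
  x$within_ci <- lapply(x$within_ci, function(cols) {
    df <- as.data.frame(cols)
    df
  })
  structure(x, class = "model_comparison_report")
}
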