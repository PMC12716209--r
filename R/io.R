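# Plain-text I/O: per-cell tables as CSV, model audits as JSON. CSVs are
# written without row names and without quoting numerics, so repeated runs
# with the same seed are byte-identical.

#' Write / read a per-cell table as CSV
#'
#' Used for both truth tables and measured cell records. The documented
#' header for truth tables is `cell_id, condition, well, timepoint_h,
#' true_label, lamin_a, lamin_b1`, followed by any marker channel columns.
#'
#' @param cells a `data.frame`.
#' @param path file path.
#' @return `write_cells_csv` returns `path` invisibly; `read_cells_csv`
#'   returns a `data.frame`.
#' @export
write_cells_csv <- function(cells, path) {
  write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @param required columns that must be present.
#' @rdname write_cells_csv
#' @export
read_cells_csv <- function(path, required = c("cell_id", "lamin_a", "lamin_b1")) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  out <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(out))
  if (length(miss)) stop_input("%s lacks column(s): %s", path, toString(miss))
  out
}

#' Serialize a control model to JSON for audit
#'
#' All scalar model fields (slope, intercept, R-squared, residual scale,
#' band moments, thresholds, correction flags) are written; the per-cell
#' `kept` vector is summarized as the number of trimmed cells.
#'
#' @param model a [fit_control_model()] result.
#' @param path JSON file path.
#' @return `path`, invisibly. `read_control_model()` returns a
#'   `control_model`.
#' @export
write_control_model <- function(model, path) {
  .check_fitted(model)
  fields <- model[setdiff(names(model), "kept")]
  fields$n_trimmed <- sum(!model$kept)
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_control_model
#' @export
read_control_model <- function(path) {
  if (!file.exists(path)) stop_input("no such file: %s", path)
  fields <- jsonlite::read_json(path, simplifyVector = TRUE)
  fields$n_trimmed <- NULL
  fields$kept <- rep(TRUE, fields$n_control)
  class(fields) <- "control_model"
  .check_fitted(fields)
  fields
}
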