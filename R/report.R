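#' Write a machine-readable run report
#'
#' Collects the artifacts of a screening run into plain JSON + CSV
#' summaries: per-condition senescent fractions, a control-model audit
#' (slope, intercept, R-squared, residual scale, thresholds, correction
#' flags), marker thresholds and stratified fractions when supplied, and
#' confusion counts / accuracy when ground truth is available. Reruns with
#' identical inputs produce byte-identical files.
#'
#' @param screen a [screen_experiment()] result, a
#'   [screen_timecourse()] result, or a bare `screen_result`.
#' @param dir output directory (created if needed).
#' @param markers optional named list of [score_positivity()] results.
#' @param stratified optional `data.frame` from [stratify()].
#' @param truth optional truth table (`cell_id`, `true_label`) to evaluate
#'   the classifier against.
#' @param seed,config optional provenance recorded in the report log.
#' @return (invisibly) a list with the `summary` list written to
#'   `report.json` and the paths of all written files.
#' @export
report <- function(screen, dir, markers = NULL, stratified = NULL,
                   truth = NULL, seed = NULL, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  if (inherits(screen, "screen_result")) {
    cells <- screen$cells
    summary_df <- screen$summary
    models <- list(control = screen$model)
  } else if (!is.null(screen$result) && inherits(screen$result, "screen_result")) {
    cells <- screen$result$cells
    summary_df <- screen$result$summary
    models <- list(control = screen$model)
  } else if (!is.null(screen$by_well)) {   # timecourse
    cells <- screen$cells
    summary_df <- screen$by_well
    models <- screen$models
  } else {
    ss_stop("senoscreen_dependency_error",
            "screen must be a completed screening result")
  }

  audit <- lapply(models, function(m) {
    f <- m[setdiff(names(m), "kept")]
    f$n_trimmed <- sum(!m$kept)
    f
  })

  summary <- list(
    package = "senoscreen",
    version = as.character(utils::packageVersion("senoscreen")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = config,
    n_cells = nrow(cells),
    control_models = audit,
    fractions = summary_df
  )
  if (!is.null(markers)) {
    summary$marker_thresholds <- lapply(markers, function(m) {
      thr <- m$threshold
      list(channel = thr$channel, control_mean = thr$control_mean,
           control_sd = thr$control_sd, threshold = thr$threshold,
           n_control = thr$n_control, fraction_positive = m$fraction_positive)
    })
  }
  if (!is.null(stratified)) summary$stratified <- stratified
  if (!is.null(truth)) {
    if (!all(c("cell_id", "true_label") %in% names(truth))) {
      stop_input("truth needs 'cell_id' and 'true_label'")
    }
    m <- match(cells$cell_id, truth$cell_id)
    if (anyNA(m)) stop_join("truth does not cover all classified cells")
    cc <- confusion_counts(truth$true_label[m], cells$label)
    summary$confusion <- cc[c("TP", "TN", "FP", "FN")]
    summary$accuracy <- accuracy(cc)
  }

  paths <- c(
    json = file.path(dir, "report.json"),
    per_cell = file.path(dir, "per_cell.csv"),
    summary = file.path(dir, "summary.csv")
  )
  jsonlite::write_json(summary, paths[["json"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  write_cells_csv(cells, paths[["per_cell"]])
  write_cells_csv(summary_df, paths[["summary"]])
  invisible(list(summary = summary, paths = paths))
}
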