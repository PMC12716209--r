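#' Mean + 2 SD marker-positivity threshold
#'
#' The positivity threshold for a marker channel is computed from the
#' experiment's own control population: `control_mean + 2 * control_sd`,
#' with the sample SD (n - 1 denominator). Cells strictly above the
#' threshold are positive; a cell exactly at the threshold is negative.
#'
#' @param control numeric vector of control intensities, or a `data.frame`
#'   of cell records (then `channel` selects the column).
#' @param channel marker channel name; required when `control` is a
#'   `data.frame`, otherwise used only as the stored name.
#' @return an object of class `marker_threshold` with fields `channel`,
#'   `control_mean`, `control_sd`, `threshold`, `n_control`.
#' @export
marker_threshold <- function(control, channel = "marker") {
  vals <- if (is.data.frame(control)) {
    if (!channel %in% names(control)) {
      stop_input("channel '%s' not present in control records", channel)
    }
    control[[channel]]
  } else {
    as.numeric(control)
  }
  vals <- vals[is.finite(vals)]
  if (length(vals) < 10L) {
    stop_control("need at least 10 finite control values, got %d", length(vals))
  }
  m <- mean(vals)
  s <- sd(vals)
  structure(
    list(channel = channel, control_mean = m, control_sd = s,
         threshold = m + 2 * s, n_control = length(vals)),
    class = "marker_threshold"
  )
}

#' @export
print.marker_threshold <- function(x, ...) {
  cat(sprintf("<marker_threshold> %s: positive iff value > %.6g (= %.6g + 2 * %.6g, n = %d)\n",
              x$channel, x$threshold, x$control_mean, x$control_sd, x$n_control))
  invisible(x)
}

#' Score per-cell marker positivity
#'
#' Applies a [marker_threshold()] (strict `>`) to every cell and aggregates
#' positive fractions per field of view and per condition. Both aggregations
#' are emitted: per-FOV fractions (one value per image, mirroring
#' dot-per-FOV plots) and cell-pooled per-condition fractions.
#'
#' @param cells cell records containing the threshold's channel column;
#'   `fov_id` and `condition` columns are used for aggregation when present
#'   (missing ones fall back to a single pseudo-group).
#' @param thr a [marker_threshold()].
#' @return an object of class `positivity_result`: list with `cells` (input
#'   plus logical `<channel>_positive`), `by_fov`, `by_condition`, and
#'   `fraction_positive` (overall pooled fraction).
#' @export
score_positivity <- function(cells, thr) {
  if (!inherits(thr, "marker_threshold")) {
    stop_input("thr must be a marker_threshold")
  }
  ch <- thr$channel
  if (!ch %in% names(cells)) {
    stop_input("cells lack marker channel column '%s'", ch)
  }
  pos <- cells[[ch]] > thr$threshold
  out <- cells
  out[[paste0(ch, "_positive")]] <- pos

  agg_by <- function(key) {
    g <- if (key %in% names(out)) out[[key]] else rep("all", nrow(out))
    a <- aggregate(pos, by = list(group = g),
                   FUN = function(z) c(n = length(z), n_positive = sum(z)))
    res <- data.frame(group = a$group,
                      n = as.integer(a$x[, "n"]),
                      n_positive = as.integer(a$x[, "n_positive"]))
    names(res)[1] <- key
    res$fraction_positive <- res$n_positive / res$n
    res[order(res[[key]]), , drop = FALSE]
  }
  structure(
    list(
      cells = out,
      channel = ch,
      threshold = thr,
      by_fov = agg_by("fov_id"),
      by_condition = agg_by("condition"),
      fraction_positive = mean(pos)
    ),
    class = "positivity_result"
  )
}

#' Stratify marker positivity by screening label
#'
#' Cross-tabulates per-cell marker status against senescent/non-senescent
#' screening labels: the overall positive fraction and the marker-positive /
#' -negative fractions within the senescent and the non-senescent
#' sub-populations, per group. Within each sub-population the +/- fractions
#' sum to 1, and the overall fraction is exactly the population-size-weighted
#' mixture of the within-population fractions.
#'
#' @param marker per-cell marker scores: the `cells` element of a
#'   [score_positivity()] result (or any `data.frame` with `cell_id` and the
#'   `<channel>_positive` column).
#' @param screen per-cell screening labels: a `screen_result`, or a
#'   `data.frame` with `cell_id` and `label`.
#' @param channel marker channel name (identifies the positivity column).
#' @param by grouping columns taken from the screen labels (default
#'   `"condition"` when present).
#' @return a `data.frame` with, per group: cell counts, overall
#'   `fraction_positive`, `frac_pos_in_senescent`, `frac_neg_in_senescent`,
#'   `frac_pos_in_non_senescent`, `frac_neg_in_non_senescent`.
#' @export
stratify <- function(marker, screen, channel, by = NULL) {
  if (inherits(marker, "positivity_result")) marker <- marker$cells
  if (inherits(screen, "screen_result")) screen <- screen$cells
  pcol <- paste0(channel, "_positive")
  if (!all(c("cell_id", pcol) %in% names(marker))) {
    stop_input("marker records need 'cell_id' and '%s'", pcol)
  }
  if (!all(c("cell_id", "label") %in% names(screen))) {
    stop_input("screen records need 'cell_id' and 'label'")
  }
  if (!setequal(marker$cell_id, screen$cell_id) ||
      anyDuplicated(marker$cell_id) || anyDuplicated(screen$cell_id)) {
    stop_join("marker and screen labels must cover the same unique cell_ids")
  }
  m <- marker[match(screen$cell_id, marker$cell_id), , drop = FALSE]
  by <- by %||% intersect("condition", names(screen))
  g <- if (length(by)) {
    interaction(screen[by], drop = TRUE, lex.order = TRUE)
  } else {
    factor(rep("all", nrow(screen)))
  }

  rows <- lapply(levels(g), function(lv) {
    ix <- g == lv
    pos <- m[[pcol]][ix]
    sen <- screen$label[ix] == "senescent"
    one <- function(sel) if (any(sel)) mean(pos[sel]) else NA_real_
    data.frame(
      group = lv,
      n = sum(ix),
      n_senescent = sum(sen),
      fraction_positive = mean(pos),
      frac_pos_in_senescent = one(sen),
      frac_neg_in_senescent = if (any(sen)) 1 - one(sen) else NA_real_,
      frac_pos_in_non_senescent = one(!sen),
      frac_neg_in_non_senescent = if (any(!sen)) 1 - one(!sen) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
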