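#' Fit the proliferating-control lamin model
#'
#' Ordinary least squares of lamin B1 on lamin A over the control cells,
#' together with everything classification needs: the residual scale and
#' moments for the prediction band, the per-channel mean + 2 SD high-intensity
#' thresholds, and R-squared as a heterogeneity measure. If
#' `r_squared < r2_min`, the fit is corrected by iterative trimming: cells
#' with |internally studentized residual| > 2 are removed and the model
#' refitted, up to `max_iter` rounds or until R-squared reaches `r2_min`.
#' A trimming round removes the cells the screening rules themselves would
#' flag against the current fit: |internally studentized residual| > 2
#' (off the correlation) or intensity above the current subset's mean + 2 SD
#' in either channel (high lamin). Untreated controls typically contain a
#' small spontaneously senescent fraction (e.g. over-confluent cultures);
#' trimming excludes it from the proliferating reference. Thresholds and
#' band parameters always come from the post-correction control subset.
#'
#' @param control cell records of the control condition; needs columns
#'   `lamin_a` and `lamin_b1`, at least 10 rows, strictly positive
#'   intensities.
#' @param alpha prediction-band level (default 0.05 for a 95% band).
#' @param r2_min R-squared below which the heterogeneity correction runs.
#' @param max_iter maximum trimming rounds.
#' @return an object of class `control_model` with fields `slope`,
#'   `intercept`, `n_control`, `r_squared`, `resid_sd`, `x_mean`, `sxx`,
#'   `alpha`, `mean_a`, `sd_a`, `mean_b1`, `sd_b1`, `thr_a`, `thr_b1`,
#'   `correction_applied`, `correction_iterations`, `heterogeneous`
#'   (TRUE when trimming never reached `r2_min`), and `kept` (logical vector
#'   marking the retained control cells).
#' @examples
#' ctrl <- simulate_population(population_spec(500, resid_sd = 2, seed = 1))
#' m <- fit_control_model(ctrl)
#' c(m$slope, m$r_squared)
#' @export
fit_control_model <- function(control, alpha = 0.05, r2_min = 0.95,
                              max_iter = 5L) {
  if (!all(c("lamin_a", "lamin_b1") %in% names(control))) {
    stop_input("control records need 'lamin_a' and 'lamin_b1' columns")
  }
  if (nrow(control) < 10L) {
    stop_control("need at least 10 control cells, got %d", nrow(control))
  }
  if (any(control$lamin_a <= 0) || any(control$lamin_b1 <= 0)) {
    stop_input("control intensities must be strictly positive")
  }
  if (alpha <= 0 || alpha >= 1) stop_param("alpha must lie in (0, 1)")
  if (var(control$lamin_a) == 0) {
    stop_degenerate("zero variance in control lamin_a: fit undefined")
  }

  keep <- rep(TRUE, nrow(control))
  iters <- 0L
  repeat {
    dat <- control[keep, , drop = FALSE]
    fit <- lm(lamin_b1 ~ lamin_a, data = dat)
    # suppressed: "essentially perfect fit" on zero-residual controls
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= r2_min || iters >= max_iter) break
    rs <- rstandard(fit)
    flagged <- abs(rs) > 2 |
      dat$lamin_a > mean(dat$lamin_a) + 2 * sd(dat$lamin_a) |
      dat$lamin_b1 > mean(dat$lamin_b1) + 2 * sd(dat$lamin_b1)
    drop_ix <- which(flagged)
    if (!length(drop_ix) || sum(keep) - length(drop_ix) < 10L) break
    keep[which(keep)[drop_ix]] <- FALSE
    iters <- iters + 1L
  }

  dat <- control[keep, , drop = FALSE]
  n <- nrow(dat)
  s <- suppressWarnings(summary(fit)$sigma)   # sqrt(SSE / (n - 2))
  if (!is.finite(s)) s <- 0
  model <- list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    n_control = n,
    r_squared = r2,
    resid_sd = s,
    x_mean = mean(dat$lamin_a),
    sxx = sum((dat$lamin_a - mean(dat$lamin_a))^2),
    alpha = alpha,
    mean_a = mean(dat$lamin_a),
    sd_a = sd(dat$lamin_a),
    mean_b1 = mean(dat$lamin_b1),
    sd_b1 = sd(dat$lamin_b1),
    correction_applied = iters > 0L,
    correction_iterations = iters,
    heterogeneous = r2 < r2_min,
    kept = keep
  )
  model$thr_a <- model$mean_a + 2 * model$sd_a
  model$thr_b1 <- model$mean_b1 + 2 * model$sd_b1
  class(model) <- "control_model"
  model
}

#' @export
print.control_model <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<control_model> B1 = %.4g * A + %.4g  (n = %d, R^2 = %.4f, s = %.4g)\n",
      "  thresholds: A > %.4g, B1 > %.4g; band alpha = %g\n",
      "  heterogeneity correction: %s (%d iteration(s))%s\n"
    ),
    x$slope, x$intercept, x$n_control, x$r_squared, x$resid_sd,
    x$thr_a, x$thr_b1, x$alpha,
    if (x$correction_applied) "applied" else "not needed",
    x$correction_iterations,
    if (x$heterogeneous) "; control still heterogeneous (R^2 < target)" else ""
  ))
  invisible(x)
}

.check_fitted <- function(model) {
  if (!inherits(model, "control_model") || is.null(model$slope) ||
      !is.finite(model$slope)) {
    stop_state("model must be a fitted control_model")
  }
  invisible(model)
}

#' Prediction band of the control lamin correlation
#'
#' Two-sided `1 - alpha` prediction interval for the lamin B1 intensity of a
#' single new cell with lamin A intensity `a`:
#' `yhat(a) +/- t(1 - alpha/2, n - 2) * s * sqrt(1 + 1/n + (a - x_mean)^2 / sxx)`.
#' A prediction band (not a mean-response confidence band) is used because by
#' construction it contains about `1 - alpha` of control cells regardless of
#' control size; its half-width is minimal at `a = x_mean`.
#'
#' @param model a fitted [fit_control_model()] result.
#' @param a vector of lamin A intensities.
#' @return a `data.frame` with columns `fit`, `lower`, `upper`.
#' @export
prediction_band <- function(model, a) {
  .check_fitted(model)
  tq <- qt(1 - model$alpha / 2, df = model$n_control - 2L)
  hw <- tq * model$resid_sd *
    sqrt(1 + 1 / model$n_control + (a - model$x_mean)^2 / model$sxx)
  fit <- model$slope * a + model$intercept
  data.frame(fit = fit, lower = fit - hw, upper = fit + hw)
}

#' Classify cells as senescent or non-senescent
#'
#' A cell is senescent iff any of three rules fires against the control
#' model: `lamin_a > thr_a` (high lamin A, mean + 2 SD), `lamin_b1 > thr_b1`
#' (high lamin B1), or `lamin_b1` outside the control prediction band at its
#' `lamin_a` (deviation from the linear correlation, two-sided). Otherwise it
#' is non-senescent: within the normal intensity range and on the control
#' correlation.
#'
#' @param cells cell records with `lamin_a` and `lamin_b1` columns.
#' @param model a fitted [fit_control_model()] result.
#' @return an object of class `screen_result`: list with `cells` (input plus
#'   `label`, reason flags `high_a`, `high_b1`, `off_line`, and
#'   `off_line_side` in `{"above", "below", NA}`), and `summary` (per-group
#'   counts and `fraction_senescent`, grouped by whichever of `condition`,
#'   `well`, `timepoint_h` are present).
#' @export
classify_cells <- function(cells, model) {
  .check_fitted(model)
  if (!all(c("lamin_a", "lamin_b1") %in% names(cells))) {
    stop_input("cells need 'lamin_a' and 'lamin_b1' columns")
  }
  band <- prediction_band(model, cells$lamin_a)
  high_a <- cells$lamin_a > model$thr_a
  high_b1 <- cells$lamin_b1 > model$thr_b1
  above <- cells$lamin_b1 > band$upper
  below <- cells$lamin_b1 < band$lower
  off_line <- above | below
  senescent <- high_a | high_b1 | off_line

  out <- cells
  out$label <- ifelse(senescent, "senescent", "non_senescent")
  out$high_a <- high_a
  out$high_b1 <- high_b1
  out$off_line <- off_line
  out$off_line_side <- ifelse(above, "above", ifelse(below, "below", NA))
  structure(
    list(cells = out, summary = summarize_screen(out), model = model),
    class = "screen_result"
  )
}

# Per-group counts/fractions over whichever grouping columns are present.
summarize_screen <- function(cells) {
  keys <- intersect(c("condition", "well", "timepoint_h"), names(cells))
  if (!length(keys)) {
    cells$condition <- "all"
    keys <- "condition"
  }
  agg <- aggregate(
    cells$label == "senescent",
    by = cells[keys],
    FUN = function(z) c(n = length(z), n_senescent = sum(z))
  )
  counts <- agg$x
  agg$x <- NULL
  agg$n <- as.integer(counts[, "n"])
  agg$n_senescent <- as.integer(counts[, "n_senescent"])
  agg$n_non_senescent <- agg$n - agg$n_senescent
  agg$fraction_senescent <- agg$n_senescent / agg$n
  ord <- do.call(order, agg[keys])
  agg <- agg[ord, , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d cells\n", nrow(x$cells)))
  print(x$summary)
  invisible(x)
}

#' Screen an experiment against its own control condition
#'
#' Fits one control model on the stated control condition and classifies
#' every condition (the control included) against it, as in an endpoint
#' screen where each experiment carries its own proliferating control.
#'
#' @param cells cell records for all conditions (single `data.frame` with a
#'   `condition` column) or a named list of per-condition tables.
#' @param control_condition name of the control condition.
#' @param alpha,r2_min,max_iter passed to [fit_control_model()].
#' @return list with `model` (the control [fit_control_model()]) and
#'   `result` (a `screen_result` over all cells).
#' @examples
#' ctrl <- simulate_population(population_spec(500, resid_sd = 2, seed = 1))
#' trt <- simulate_population(
#'   population_spec(500, frac_senescent = 0.6, resid_sd = 2, seed = 2),
#'   condition = "irradiated"
#' )
#' scr <- screen_experiment(rbind(ctrl, trt), "control")
#' scr$result$summary
#' @export
screen_experiment <- function(cells, control_condition, alpha = 0.05,
                              r2_min = 0.95, max_iter = 5L) {
  if (is.list(cells) && !is.data.frame(cells)) {
    if (is.null(names(cells))) stop_config("per-condition list must be named")
    cells <- do.call(rbind, lapply(names(cells), function(nm) {
      tab <- cells[[nm]]
      tab$condition <- nm
      tab
    }))
  }
  if (!"condition" %in% names(cells)) {
    stop_config("cells need a 'condition' column")
  }
  if (!control_condition %in% cells$condition) {
    stop_config("control condition '%s' not present", control_condition)
  }
  ctrl <- cells[cells$condition == control_condition, , drop = FALSE]
  model <- fit_control_model(ctrl, alpha = alpha, r2_min = r2_min,
                             max_iter = max_iter)
  list(model = model, result = classify_cells(cells, model))
}

#' Screen a live-imaging time course with per-well t = 0 controls
#'
#' High-content variant: instead of a separate untreated condition, every
#' well's own first timepoint (`t = 0 h`) serves as its proliferating
#' control. A control model is fitted per well on the `t = 0` cells and all
#' of the well's timepoints are classified against it.
#'
#' @param cells cell records with `well` and `timepoint_h` columns (and
#'   optionally `condition`).
#' @param control_timepoint the control time (default 0).
#' @param alpha,r2_min,max_iter passed to [fit_control_model()].
#' @return list with `models` (per-well control models), `cells` (classified
#'   records), `by_well` (fraction senescent per well and timepoint) and
#'   `by_condition` (mean fraction across wells per condition and timepoint,
#'   when `condition` is present).
#' @export
screen_timecourse <- function(cells, control_timepoint = 0, alpha = 0.05,
                              r2_min = 0.95, max_iter = 5L) {
  if (!all(c("well", "timepoint_h") %in% names(cells))) {
    stop_config("cells need 'well' and 'timepoint_h' columns")
  }
  wells <- unique(cells$well)
  models <- list()
  classified <- vector("list", length(wells))
  for (i in seq_along(wells)) {
    w <- wells[i]
    wc <- cells[cells$well == w, , drop = FALSE]
    ctrl <- wc[wc$timepoint_h == control_timepoint, , drop = FALSE]
    if (!nrow(ctrl)) {
      stop_config("well '%s' has no t = %g control cells", w, control_timepoint)
    }
    models[[w]] <- fit_control_model(ctrl, alpha = alpha, r2_min = r2_min,
                                     max_iter = max_iter)
    classified[[i]] <- classify_cells(wc, models[[w]])$cells
  }
  allcells <- do.call(rbind, classified)
  by_well <- summarize_screen(allcells)
  by_condition <- NULL
  if ("condition" %in% names(allcells)) {
    by_condition <- aggregate(
      fraction_senescent ~ condition + timepoint_h,
      data = by_well, FUN = mean
    )
    by_condition <- by_condition[order(by_condition$condition,
                                       by_condition$timepoint_h), ]
    rownames(by_condition) <- NULL
  }
  list(models = models, cells = allcells, by_well = by_well,
       by_condition = by_condition)
}

#' Per-cell lamin B1 / lamin A intensity ratio
#'
#' The ratio drops the line's intercept but tracks the same decorrelation
#' signal the classifier uses: senescent cells with elevated or decorrelated
#' lamin B1 shift the ratio distribution upward relative to control.
#'
#' @param cells cell records with `lamin_a` (> 0) and `lamin_b1` columns.
#' @return numeric vector of per-cell ratios, named by `cell_id` when
#'   available.
#' @export
lamin_ratio <- function(cells) {
  if (!all(c("lamin_a", "lamin_b1") %in% names(cells))) {
    stop_input("cells need 'lamin_a' and 'lamin_b1' columns")
  }
  if (any(cells$lamin_a <= 0)) {
    stop_input("lamin_a must be strictly positive to form the ratio")
  }
  setNames(cells$lamin_b1 / cells$lamin_a,
           if ("cell_id" %in% names(cells)) cells$cell_id else NULL)
}
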