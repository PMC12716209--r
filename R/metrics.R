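#' Confusion counts for classifier validation
#'
#' Exact 2x2 tabulation of predicted against true senescence labels,
#' with `"senescent"` as the positive class.
#'
#' @param truth,predicted equal-length character vectors with values
#'   `"senescent"` / `"non_senescent"`.
#' @return an object of class `confusion_counts` with fields `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop_input("truth and predicted must have equal length")
  }
  ok <- c("senescent", "non_senescent")
  bad <- setdiff(unique(c(truth, predicted)), ok)
  if (length(bad)) stop_input("unknown label value(s): %s", toString(bad))
  tpos <- truth == "senescent"
  ppos <- predicted == "senescent"
  structure(
    list(
      TP = sum(tpos & ppos), TN = sum(!tpos & !ppos),
      FP = sum(!tpos & ppos), FN = sum(tpos & !ppos)
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d (accuracy %.4f)\n",
              x$TP, x$TN, x$FP, x$FN, accuracy(x)))
  invisible(x)
}

#' Classification accuracy
#'
#' `(TN + TP) / (TN + TP + FP + FN)`.
#'
#' @param counts a [confusion_counts()] object (or a list with fields
#'   `TP`, `TN`, `FP`, `FN`).
#' @return accuracy in \[0, 1\].
#' @export
accuracy <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (is.na(total) || total <= 0) stop_domain("total count must be > 0")
  (counts$TN + counts$TP) / total
}

#' Sensitivity and specificity
#'
#' @inheritParams accuracy
#' @return named vector `c(sensitivity, specificity)`.
#' @export
sens_spec <- function(counts) {
  c(
    sensitivity = counts$TP / (counts$TP + counts$FN),
    specificity = counts$TN / (counts$TN + counts$FP)
  )
}

#' Rule-of-70 doubling time
#'
#' `70 / growth_rate`, with the growth rate in percent per unit time — the
#' common rule-of-70 reading under which the formula approximates
#' `ln(2) / rate`. The exact value `100 * ln(2) / rate` differs by under
#' 1.1% for rates up to 10% per unit time.
#'
#' @param growth_rate growth rate in percent per unit time (> 0).
#' @return doubling time in the unit time of the rate.
#' @export
doubling_time <- function(growth_rate) {
  if (any(!is.finite(growth_rate)) || any(growth_rate <= 0)) {
    stop_domain("growth_rate must be > 0")
  }
  70 / growth_rate
}

#' Fit a growth curve on semi-log scale
#'
#' OLS slope of `ln(count)` against time, converted to a percent growth rate
#' (x 100) so the rule-of-70 applies, plus the resulting doubling time. The
#' exact doubling time `ln(2) / slope` is reported alongside.
#'
#' @param times timepoints (hours or any consistent unit); at least 3.
#' @param counts live-cell counts (> 0), same length.
#' @return an object of class `growth_series` with `times`, `counts`,
#'   `ln_slope` (per unit time), `growth_rate` (percent per unit time),
#'   `doubling_time` (rule of 70) and `doubling_time_exact`
#'   (`ln(2) / ln_slope`).
#' @examples
#' g <- fit_growth(c(0, 24, 48), c(1000, 2000, 4000))
#' c(g$growth_rate, g$doubling_time)  # 2.888 %/h, 24.24 h
#' @export
fit_growth <- function(times, counts) {
  if (length(times) != length(counts) || length(times) < 3L) {
    stop_input("need >= 3 aligned (time, count) pairs")
  }
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop_domain("counts must be strictly positive")
  }
  b <- unname(coef(lm(log(counts) ~ times))[2])
  rate <- 100 * b
  structure(
    list(
      times = times, counts = counts, ln_slope = b, growth_rate = rate,
      doubling_time = doubling_time(rate),     # domain error when rate <= 0
      doubling_time_exact = log(2) / b
    ),
    class = "growth_series"
  )
}

#' @export
print.growth_series <- function(x, ...) {
  cat(sprintf(
    "<growth_series> rate %.4g %%/unit time; doubling %.4g (rule of 70), %.4g (exact)\n",
    x$growth_rate, x$doubling_time, x$doubling_time_exact
  ))
  invisible(x)
}
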