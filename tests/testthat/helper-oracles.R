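# Independent oracles, written against the rule definitions rather than the
# package implementation, plus shared fixture generators.

# Brute-force per-cell re-evaluation of the three senescence rules.
# Deliberately scalar and loop-based; only reads plain model fields.
oracle_classify <- function(cells, model) {
  n <- model$n_control
  tq <- stats::qt(1 - model$alpha / 2, n - 2)
  thr_a <- model$mean_a + 2 * model$sd_a
  thr_b1 <- model$mean_b1 + 2 * model$sd_b1
  out <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    a <- cells$lamin_a[i]
    b <- cells$lamin_b1[i]
    predicted <- model$intercept + model$slope * a
    half <- tq * model$resid_sd *
      sqrt(1 + 1 / n + (a - model$x_mean)^2 / model$sxx)
    senescent <- FALSE
    if (a > thr_a) senescent <- TRUE
    if (b > thr_b1) senescent <- TRUE
    if (b > predicted + half) senescent <- TRUE
    if (b < predicted - half) senescent <- TRUE
    out[i] <- if (senescent) "senescent" else "non_senescent"
  }
  out
}

# Brute-force confusion tabulation by explicit looping.
oracle_confusion <- function(truth, predicted) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == "senescent" && predicted[i] == "senescent") tp <- tp + 1L
    if (truth[i] == "non_senescent" && predicted[i] == "non_senescent") tn <- tn + 1L
    if (truth[i] == "non_senescent" && predicted[i] == "senescent") fp <- fp + 1L
    if (truth[i] == "senescent" && predicted[i] == "non_senescent") fn <- fn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# Deterministic 64x64 image used to freeze the Li threshold against an
# independent reference implementation (value in test-imageops.R).
li_fixture_image <- function() {
  set.seed(421)
  img <- matrix(rnorm(64 * 64, 20, 3), 64, 64)
  rr <- matrix(seq_len(64), 64, 64)
  cc <- t(rr)
  img[(rr - 32)^2 + (cc - 32)^2 <= 100] <- 150
  img
}

# Synthetic image with hard-edged disks on a flat background; used for seed
# and watershed tests where analytic ground truth is wanted.
disk_image <- function(shape, centers, radius, bg = 10, fg = 100) {
  img <- matrix(bg, shape[1], shape[2])
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  for (k in seq_len(nrow(centers))) {
    img[(rr - centers[k, 1])^2 + (cc - centers[k, 2])^2 <= radius^2] <- fg
  }
  img
}

# On-model ("pure control") population spec used across screening tests:
# the configuration the classifier assumes, with residual scale small enough
# that the population R^2 exceeds the heterogeneity-correction trigger.
on_model_spec <- function(n, seed, frac = 0, ...) {
  population_spec(n, frac_senescent = frac, resid_sd = 2, seed = seed, ...)
}
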