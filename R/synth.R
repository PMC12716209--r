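#' Specify a simulated two-channel lamin population
#'
#' A population spec encodes the statistical world the screening classifier
#' assumes: proliferating ("non_senescent") cells whose per-nucleus mean lamin
#' B1 intensity follows a linear law in lamin A with Gaussian residuals, plus
#' an optional senescent sub-population with multiplicatively elevated
#' intensities and/or a broken B1~A correlation.
#'
#' For proliferating cells, `lamin_a ~ N(lamin_a_mean, lamin_a_sd)` and
#' `lamin_b1 = slope * lamin_a + intercept + N(0, resid_sd)`. Senescent cells
#' take a proliferating draw and multiply both channels by `senescent_fold`;
#' a `decorrelate_prob` subset of them instead draws lamin B1 from the
#' *marginal* control B1 distribution (times `senescent_fold`), independent of
#' their lamin A, which breaks the correlation without changing the marginals.
#' All intensities are redrawn until strictly positive (at most 100 rounds).
#'
#' Default numeric values are package calibration choices for testability, not
#' measured constants.
#'
#' @param n_cells number of cells to simulate.
#' @param frac_senescent true senescent fraction in \[0, 1\]. The realized count
#'   is deterministic: `floor(n_cells * frac_senescent)`, with membership
#'   assigned by a seeded shuffle.
#' @param lamin_a_mean,lamin_a_sd control lamin A distribution (intensity units).
#' @param slope,intercept control linear law `B1 = slope * A + intercept`.
#' @param resid_sd residual SD of B1 about the control line.
#' @param senescent_fold multiplicative intensity elevation for senescent
#'   cells (>= 1).
#' @param decorrelate_prob fraction of senescent cells whose B1 is drawn
#'   independently of A (deterministic count, same policy as above).
#' @param seed RNG seed for [simulate_population()]; `NULL` uses the current
#'   RNG stream.
#' @return an object of class `population_spec`.
#' @seealso [simulate_population()]
#' @export
population_spec <- function(n_cells,
                            frac_senescent = 0,
                            lamin_a_mean = 100,
                            lamin_a_sd = 20,
                            slope = 0.8,
                            intercept = 5,
                            resid_sd = 4,
                            senescent_fold = 3,
                            decorrelate_prob = 0.5,
                            seed = NULL) {
  spec <- list(
    n_cells = as.integer(n_cells), frac_senescent = frac_senescent,
    lamin_a_mean = lamin_a_mean, lamin_a_sd = lamin_a_sd,
    slope = slope, intercept = intercept, resid_sd = resid_sd,
    senescent_fold = senescent_fold, decorrelate_prob = decorrelate_prob,
    seed = seed
  )
  class(spec) <- "population_spec"
  validate_population_spec(spec)
  spec
}

validate_population_spec <- function(spec) {
  with(spec, {
    if (is.na(n_cells) || n_cells < 0) stop_param("n_cells must be >= 0")
    if (frac_senescent < 0 || frac_senescent > 1) {
      stop_param("frac_senescent must lie in [0, 1], got %g", frac_senescent)
    }
    if (lamin_a_sd <= 0) stop_param("lamin_a_sd must be > 0")
    if (resid_sd < 0) stop_param("resid_sd must be >= 0")
    if (senescent_fold < 1) stop_param("senescent_fold must be >= 1")
    if (decorrelate_prob < 0 || decorrelate_prob > 1) {
      stop_param("decorrelate_prob must lie in [0, 1]")
    }
    if (lamin_a_mean <= 0) stop_param("lamin_a_mean must be > 0")
  })
  invisible(spec)
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf(
    "<population_spec> n=%d, frac_senescent=%g, B1 = %g*A + %g (resid_sd %g), fold=%g\n",
    x$n_cells, x$frac_senescent, x$slope, x$intercept, x$resid_sd, x$senescent_fold
  ))
  invisible(x)
}

# Draw one proliferating-control population of size n on the current stream.
.draw_control <- function(n, spec) {
  a <- rnorm_pos(n, spec$lamin_a_mean, spec$lamin_a_sd)
  b1 <- spec$slope * a + spec$intercept + rnorm(n, 0, spec$resid_sd)
  bad <- b1 <= 0
  for (i in seq_len(100L)) {
    if (!any(bad)) break
    b1[bad] <- spec$slope * a[bad] + spec$intercept +
      rnorm(sum(bad), 0, spec$resid_sd)
    bad <- b1 <= 0
  }
  if (any(bad)) stop_param("could not draw strictly positive lamin B1 in 100 redraws")
  list(a = a, b1 = b1)
}

#' Simulate a per-cell lamin intensity table with known ground truth
#'
#' Draws one population as described in [population_spec()] and returns a
#' truth table: one row per cell with identifiers, the true label, and the
#' two lamin channel intensities. Deterministic given `spec$seed`.
#'
#' @param spec a [population_spec()].
#' @param condition,well,timepoint_h identifiers copied into every row.
#' @param id_prefix prefix for the generated unique `cell_id`s; defaults to a
#'   combination of `condition`, `well` and `timepoint_h`.
#' @return a `data.frame` with columns `cell_id`, `condition`, `well`,
#'   `timepoint_h`, `true_label` (`"senescent"` / `"non_senescent"`),
#'   `lamin_a`, `lamin_b1`.
#' @examples
#' tt <- simulate_population(population_spec(200, frac_senescent = 0.25, seed = 1))
#' table(tt$true_label)
#' @export
simulate_population <- function(spec, condition = "control", well = "w1",
                                timepoint_h = 0, id_prefix = NULL) {
  validate_population_spec(spec)
  n <- spec$n_cells
  id_prefix <- id_prefix %||%
    paste(condition, well, paste0("t", timepoint_h), sep = "_")
  if (n == 0L) {
    return(data.frame(
      cell_id = character(0), condition = character(0), well = character(0),
      timepoint_h = numeric(0), true_label = character(0),
      lamin_a = numeric(0), lamin_b1 = numeric(0), stringsAsFactors = FALSE
    ))
  }
  with_seed(spec$seed, {
    n_sen <- det_count(n, spec$frac_senescent)
    order_ix <- if (n > 0) sample.int(n) else integer(0)
    sen_ix <- order_ix[seq_len(n_sen)]
    label <- rep("non_senescent", n)
    label[sen_ix] <- "senescent"

    ctrl <- .draw_control(n, spec)
    a <- ctrl$a
    b1 <- ctrl$b1
    if (n_sen > 0) {
      a[sen_ix] <- spec$senescent_fold * a[sen_ix]
      b1[sen_ix] <- spec$senescent_fold * b1[sen_ix]
      # decorrelated subset: B1 independent of A, marginal control law * fold
      n_dec <- det_count(n_sen, spec$decorrelate_prob)
      dec_ix <- sen_ix[seq_len(n_dec)]
      if (n_dec > 0) {
        b1[dec_ix] <- spec$senescent_fold * .draw_control(n_dec, spec)$b1
      }
    }
    data.frame(
      cell_id = sprintf("%s_c%05d", id_prefix, seq_len(n)),
      condition = condition, well = well, timepoint_h = timepoint_h,
      true_label = label, lamin_a = a, lamin_b1 = b1,
      stringsAsFactors = FALSE
    )
  })
}

.check_truth <- function(truth) {
  need <- c("cell_id", "true_label", "lamin_a", "lamin_b1")
  miss <- setdiff(need, names(truth))
  if (length(miss)) stop_input("truth table lacks columns: %s", toString(miss))
  if (anyDuplicated(truth$cell_id)) stop_input("cell_id values must be unique")
  invisible(truth)
}

#' Attach a marker channel with population-specific positive fractions
#'
#' Adds a marker intensity column (e.g. an IL6 promoter reporter, geminin,
#' CDT1, or H3K9me3 staining) to a truth table. Marker-negative cells draw
#' `N(neg_mean, neg_sd)`; marker-positive cells draw
#' `N(pos_fold * neg_mean, neg_sd)`. How many cells of each true label are
#' positive is deterministic (`floor(n_label * pos_frac)`, seeded shuffle),
#' so count-based tests are exact. The true marker state is recorded in
#' `<channel>_pos`.
#'
#' @param truth a truth table from [simulate_population()] and friends.
#' @param channel marker channel name (becomes the new column name).
#' @param pos_frac_by_label named list/vector mapping true labels
#'   (`"senescent"`, `"non_senescent"`) to positive fractions; labels not
#'   named default to 0.
#' @param neg_mean,neg_sd negative-population intensity distribution.
#' @param pos_fold multiplicative mean shift of positives (> 1).
#' @param seed RNG seed (`NULL`: current stream).
#' @return `truth` with columns `<channel>` (numeric) and `<channel>_pos`
#'   (logical) appended.
#' @export
attach_marker <- function(truth, channel, pos_frac_by_label,
                          neg_mean = 50, neg_sd = 5, pos_fold = 10,
                          seed = NULL) {
  .check_truth(truth)
  if (neg_mean <= 0 || neg_sd <= 0) stop_param("neg_mean and neg_sd must be > 0")
  if (pos_fold <= 1) stop_param("pos_fold must be > 1")
  labs <- names(pos_frac_by_label)
  unknown <- setdiff(labs, c("senescent", "non_senescent"))
  if (length(unknown)) stop_param("unknown label key: %s", toString(unknown))
  fr <- unlist(pos_frac_by_label)
  if (any(fr < 0 | fr > 1)) stop_param("positive fractions must lie in [0, 1]")

  with_seed(seed, {
    n <- nrow(truth)
    positive <- logical(n)
    for (lab in c("senescent", "non_senescent")) {
      ix <- which(truth$true_label == lab)
      frac <- if (lab %in% labs) fr[[lab]] else 0
      n_pos <- det_count(length(ix), frac)
      if (n_pos > 0) positive[sample(ix)[seq_len(n_pos)]] <- TRUE
    }
    vals <- numeric(n)
    vals[!positive] <- rnorm_pos(sum(!positive), neg_mean, neg_sd)
    vals[positive] <- rnorm_pos(sum(positive), pos_fold * neg_mean, neg_sd)
    truth[[channel]] <- vals
    truth[[paste0(channel, "_pos")]] <- positive
    truth
  })
}

#' Simulate virtually sorted senescent / non-senescent populations
#'
#' Emulates re-analysis of FACS-sorted populations: draws, without
#' replacement, a "sorted senescent" table with a stated purity of truly
#' senescent cells and a "sorted non-senescent" table with a stated purity of
#' truly non-senescent cells. Composition is deterministic:
#' `floor(size * purity)` cells of the intended label, the remainder of the
#' other label.
#'
#' @param truth source truth table containing both labels.
#' @param purity_sen,purity_nsen purity of the two sorted tables, in \[0, 1\].
#' @param sizes integer vector of length 2: sizes of the sorted-senescent and
#'   sorted-non-senescent tables.
#' @param seed RNG seed (`NULL`: current stream).
#' @return a list with elements `sorted_senescent` and `sorted_non_senescent`,
#'   each a truth table whose `condition` records the sort.
#' @export
simulate_sorted_populations <- function(truth, purity_sen = 1, purity_nsen = 1,
                                        sizes = c(100L, 100L), seed = NULL) {
  .check_truth(truth)
  if (purity_sen < 0 || purity_sen > 1 || purity_nsen < 0 || purity_nsen > 1) {
    stop_param("purities must lie in [0, 1]")
  }
  if (length(sizes) != 2L || any(sizes < 0)) {
    stop_param("sizes must be two non-negative counts")
  }
  sen_pool <- which(truth$true_label == "senescent")
  nsen_pool <- which(truth$true_label == "non_senescent")

  take <- function(pool_main, pool_other, size, purity, what) {
    n_main <- det_count(size, purity)
    n_other <- size - n_main
    if (n_main > length(pool_main)) {
      stop_capacity(
        "sorted-%s table needs %d truly %s cells but the source has only %d",
        what, n_main, what, length(pool_main)
      )
    }
    if (n_other > length(pool_other)) {
      stop_capacity(
        "sorted-%s table needs %d contaminant cells but the source has only %d",
        what, n_other, length(pool_other)
      )
    }
    c(
      if (n_main > 0) sample(pool_main, n_main) else integer(0),
      if (n_other > 0) sample(pool_other, n_other) else integer(0)
    )
  }

  with_seed(seed, {
    ix_sen <- take(sen_pool, nsen_pool, sizes[[1]], purity_sen, "senescent")
    # sample the non-senescent sort from cells not already taken
    sen_pool2 <- setdiff(sen_pool, ix_sen)
    nsen_pool2 <- setdiff(nsen_pool, ix_sen)
    ix_nsen <- take(nsen_pool2, sen_pool2, sizes[[2]], purity_nsen, "non_senescent")
    out_sen <- truth[ix_sen, , drop = FALSE]
    out_nsen <- truth[ix_nsen, , drop = FALSE]
    out_sen$condition <- "sort_senescent"
    out_nsen$condition <- "sort_non_senescent"
    rownames(out_sen) <- rownames(out_nsen) <- NULL
    list(sorted_senescent = out_sen, sorted_non_senescent = out_nsen)
  })
}

#' Logistic senescence-induction kinetics
#'
#' `frac(t) = base + (plateau - base) / (1 + exp(-k * (t - t50)))`. At
#' `t = t50` the fraction is the midpoint `(base + plateau) / 2`; for
#' `k * t50 >> 1` the value at `t = 0` is approximately `base`, and a dose
#' with `plateau == base` is constant over time.
#'
#' @param t time (hours).
#' @param base baseline senescent fraction.
#' @param plateau asymptotic senescent fraction, in \[0, 1\].
#' @param k logistic rate (per hour).
#' @param t50 midpoint time (hours).
#' @export
logistic_fraction <- function(t, base, plateau, k, t50) {
  if (plateau < 0 || plateau > 1) stop_param("plateau must lie in [0, 1]")
  if (base < 0 || base > 1) stop_param("base must lie in [0, 1]")
  base + (plateau - base) / (1 + exp(-k * (t - t50)))
}

#' Simulate a dose/time-resolved senescence-induction series
#'
#' For every dose, well and timepoint, draws an independent population whose
#' true senescent fraction follows the dose's logistic kinetics
#' ([logistic_fraction()]). Each well carries its own `t = 0` population, the
#' control the per-well screening mode uses. Wells and timepoints get
#' distinct RNG sub-streams derived from `spec$seed` by fixed offsets.
#'
#' @param doses vector of dose labels (numeric or character).
#' @param timepoints vector of times in hours; must include 0.
#' @param kinetics named list (by dose label) of lists with elements `base`,
#'   `plateau`, `k`, `t50`.
#' @param spec a [population_spec()]; `n_cells` is the per-(dose, well,
#'   timepoint) population size and its distributional parameters define both
#'   populations. `spec$frac_senescent` is ignored (kinetics supply it).
#' @param n_wells replicate wells per dose.
#' @return one combined truth table; `condition` is `dose_<dose>`.
#' @export
simulate_timecourse <- function(doses, timepoints, kinetics, spec, n_wells = 2) {
  if (!0 %in% timepoints) stop_param("timepoints must include 0")
  validate_population_spec(spec)
  miss <- setdiff(as.character(doses), names(kinetics))
  if (length(miss)) stop_param("kinetics missing for dose(s): %s", toString(miss))

  out <- list()
  counter <- 0L
  for (d in as.character(doses)) {
    kp <- kinetics[[d]]
    for (par in c("base", "plateau", "k", "t50")) {
      if (is.null(kp[[par]])) stop_param("kinetics for dose %s lacks '%s'", d, par)
    }
    for (w in seq_len(n_wells)) {
      for (t in timepoints) {
        counter <- counter + 1L
        frac <- logistic_fraction(t, kp$base, kp$plateau, kp$k, kp$t50)
        sp <- spec
        sp$frac_senescent <- frac
        sp$seed <- if (is.null(spec$seed)) NULL else spec$seed + 1000L * counter
        out[[counter]] <- simulate_population(
          sp,
          condition = paste0("dose_", d),
          well = sprintf("%s_w%d", d, w),
          timepoint_h = t
        )
      }
    }
  }
  do.call(rbind, out)
}
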