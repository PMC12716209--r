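test_that("a perfectly linear control is fitted exactly", {
  a <- seq(60, 140, length.out = 50)
  ctrl <- data.frame(lamin_a = a, lamin_b1 = 0.8 * a + 5)
  m <- fit_control_model(ctrl)
  expect_equal(m$slope, 0.8)
  expect_equal(m$intercept, 5)
  expect_equal(m$r_squared, 1)
  expect_false(m$correction_applied)
  expect_equal(m$resid_sd, 0, tolerance = 1e-10)
  # threshold identity: thr - mean == 2 * sd exactly
  expect_equal(m$thr_a - m$mean_a, 2 * m$sd_a)
  expect_equal(m$thr_b1 - m$mean_b1, 2 * m$sd_b1)
})

test_that("control fit errors are classed", {
  expect_error(
    fit_control_model(data.frame(lamin_a = 1:5, lamin_b1 = 1:5)),
    class = "senoscreen_insufficient_control_error"
  )
  expect_error(
    fit_control_model(data.frame(lamin_a = rep(10, 20),
                                 lamin_b1 = rnorm(20, 10))),
    class = "senoscreen_degenerate_error"
  )
  expect_error(
    fit_control_model(data.frame(lamin_a = c(-1, rnorm(19, 100)),
                                 lamin_b1 = rnorm(20, 85))),
    class = "senoscreen_input_error"
  )
})

test_that("OLS recovers the generator law within sampling error", {
  hits <- 0
  for (seed in 1:20) {
    tt <- simulate_population(on_model_spec(500, seed))
    m <- fit_control_model(tt)
    fit <- lm(lamin_b1 ~ lamin_a, data = tt)
    se <- coef(summary(fit))["lamin_a", "Std. Error"]
    if (abs(m$slope - 0.8) <= 3 * se) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("heterogeneity correction recovers the clean-subset fit", {
  for (seed in 1:5) {
    clean <- simulate_population(on_model_spec(950, seed))
    contam <- simulate_population(
      population_spec(50, frac_senescent = 1, resid_sd = 2,
                      senescent_fold = 3, decorrelate_prob = 1,
                      seed = 100 + seed),
      condition = "contaminant"
    )
    mixed <- rbind(clean, contam)
    m <- fit_control_model(mixed)
    raw_fit <- lm(lamin_b1 ~ lamin_a, data = mixed)
    expect_lt(summary(raw_fit)$r.squared, 0.95)  # contamination breaks R^2
    expect_true(m$correction_applied)
    expect_gte(m$r_squared, 0.95)
    # post-correction slope within 3 SE of the known clean-subset OLS
    clean_fit <- lm(lamin_b1 ~ lamin_a, data = clean)
    se <- coef(summary(clean_fit))["lamin_a", "Std. Error"]
    expect_lt(abs(m$slope - coef(clean_fit)[2]), 3 * se)
  }
})

test_that("prediction band follows the textbook formula", {
  ctrl <- simulate_population(on_model_spec(200, 7))
  m <- fit_control_model(ctrl)

  # direct formula evaluation as oracle at a synthetic parameterization
  m2 <- m
  m2$n_control <- 100L
  m2$resid_sd <- 2
  m2$x_mean <- 100
  m2$sxx <- 40000
  band <- prediction_band(m2, 150)
  hw_oracle <- qt(0.975, 98) * 2 * sqrt(1 + 0.01 + 2500 / 40000)
  expect_equal(band$upper - band$fit, hw_oracle)
  expect_equal(band$fit - band$lower, hw_oracle)
  expect_equal(band$fit, m2$slope * 150 + m2$intercept)

  # half-width is minimized at a = x_mean
  aa <- seq(m$x_mean - 80, m$x_mean + 80, length.out = 101)
  hw <- (prediction_band(m, aa)$upper - prediction_band(m, aa)$lower) / 2
  expect_equal(aa[which.min(hw)], m$x_mean, tolerance = 2)
  expect_equal(min(hw),
               qt(1 - m$alpha / 2, m$n_control - 2) * m$resid_sd *
                 sqrt(1 + 1 / m$n_control))

  # degenerate: zero residual scale collapses the band onto the line
  line <- data.frame(lamin_a = seq(60, 140, 2))
  line$lamin_b1 <- 0.8 * line$lamin_a + 5
  m0 <- fit_control_model(line)
  b0 <- prediction_band(m0, c(80, 120))
  expect_equal(b0$lower, b0$fit, tolerance = 1e-8)
  expect_equal(b0$upper, b0$fit, tolerance = 1e-8)

  expect_error(prediction_band(structure(list(), class = "control_model"), 1),
               class = "senoscreen_state_error")
})

test_that("classification applies the three rules with reason flags", {
  ctrl <- simulate_population(on_model_spec(1000, 17))
  m <- fit_control_model(ctrl)
  probe <- data.frame(
    cell_id = c("mid", "high_b1", "high_a", "below"),
    lamin_a = c(m$mean_a, m$mean_a, m$mean_a + 4 * m$sd_a, m$mean_a),
    lamin_b1 = c(m$slope * m$mean_a + m$intercept,
                 m$mean_b1 + 3 * m$sd_b1,
                 m$slope * (m$mean_a + 4 * m$sd_a) + m$intercept,
                 (m$slope * m$mean_a + m$intercept) / 3)
  )
  res <- classify_cells(probe, m)$cells
  expect_equal(res$label,
               c("non_senescent", "senescent", "senescent", "senescent"))
  expect_true(res$high_b1[2])
  expect_true(res$high_a[3])
  expect_true(res$off_line[4])
  expect_equal(res$off_line_side[4], "below")
  expect_error(classify_cells(data.frame(lamin_a = 1), m),
               class = "senoscreen_input_error")
})

test_that("classification equals the brute-force oracle on mixed populations", {
  ctrl <- simulate_population(on_model_spec(2000, 23))
  m <- fit_control_model(ctrl)
  cells <- simulate_population(on_model_spec(2000, 24, frac = 0.5))
  got <- classify_cells(cells, m)$cells$label
  expect_identical(got, oracle_classify(cells, m))
})

test_that("screen_experiment uses one control model for all conditions", {
  tabs <- list(
    control = simulate_population(on_model_spec(2000, 31)),
    same1 = simulate_population(on_model_spec(2000, 32)),
    same2 = simulate_population(on_model_spec(2000, 33))
  )
  scr <- screen_experiment(tabs, "control")
  fr <- scr$result$summary$fraction_senescent
  # identically distributed conditions: fractions within 3 percentage points
  expect_lt(max(fr) - min(fr), 0.03)

  induced <- simulate_population(on_model_spec(1000, 34, frac = 0.9))
  scr2 <- screen_experiment(
    list(control = tabs$control, irradiated = induced), "control"
  )
  s <- scr2$result$summary
  expect_gte(s$fraction_senescent[s$condition == "irradiated"], 0.85)

  expect_error(screen_experiment(tabs, "missing"),
               class = "senoscreen_config_error")
})

test_that("per-well time-course screening classifies against each t0", {
  spec <- population_spec(800, resid_sd = 2, seed = 40)
  kin <- list(
    `0` = list(base = 0.05, plateau = 0.05, k = 0.1, t50 = 84),
    `50` = list(base = 0.02, plateau = 0.9, k = 0.1, t50 = 84)
  )
  tc <- simulate_timecourse(c(0, 50), c(0, 84, 156), kin, spec, n_wells = 2)
  res <- screen_timecourse(tc)
  expect_equal(sort(names(res$models)), sort(unique(tc$well)))

  bw <- res$by_well
  # induced wells end far above their start; null wells stay flat
  for (w in unique(bw$well[bw$condition == "dose_50"])) {
    traj <- bw[bw$well == w, ]
    expect_gte(traj$fraction_senescent[traj$timepoint_h == 156],
               traj$fraction_senescent[traj$timepoint_h == 0])
  }
  null_traj <- bw[bw$condition == "dose_0", ]
  expect_lt(max(null_traj$fraction_senescent) -
              min(null_traj$fraction_senescent), 0.05)
  # replicate wells with identical kinetics agree at every timepoint
  d50 <- bw[bw$condition == "dose_50", ]
  spread <- tapply(d50$fraction_senescent, d50$timepoint_h,
                   function(z) max(z) - min(z))
  expect_true(all(spread < 0.05))

  expect_error(screen_timecourse(tc[tc$timepoint_h > 0, ]),
               class = "senoscreen_config_error")
})

test_that("lamin ratio exposes the decorrelation signal", {
  expect_equal(unname(lamin_ratio(data.frame(lamin_a = 100, lamin_b1 = 80))),
               0.8)
  # intercept-free noise-free cells: ratio equals the slope everywhere
  a <- seq(50, 150, 5)
  onl <- data.frame(lamin_a = a, lamin_b1 = 0.8 * a)
  expect_equal(unname(lamin_ratio(onl)), rep(0.8, length(a)))

  ctrl <- simulate_population(on_model_spec(2000, 55))
  dec <- simulate_population(
    population_spec(2000, frac_senescent = 1, resid_sd = 2,
                    decorrelate_prob = 1, seed = 56)
  )
  # decorrelated senescent B1 is drawn from the scaled marginal, so the mean
  # ratio strictly exceeds the control mean ratio
  expect_gt(mean(lamin_ratio(dec)), mean(lamin_ratio(ctrl)))
  expect_error(lamin_ratio(data.frame(lamin_a = 0, lamin_b1 = 1)),
               class = "senoscreen_input_error")
})
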