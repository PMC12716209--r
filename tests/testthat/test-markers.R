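test_that("marker threshold is exact mean + 2 * sample SD", {
  expect_equal(marker_threshold(rep(10, 12))$threshold, 10)
  # constructed mean 100, sample SD 20
  vals <- c(rep(80, 5), rep(120, 5))
  vals <- (vals - mean(vals)) / sd(vals) * 20 + 100
  thr <- marker_threshold(vals)
  expect_equal(thr$threshold, 140)
  expect_equal(thr$n_control, 10L)
  expect_error(marker_threshold(1:5),
               class = "senoscreen_insufficient_control_error")
})

test_that("marker threshold converges to mu + 2 sigma at large n", {
  set.seed(61)
  thr <- marker_threshold(rnorm(1e5, 50, 5))
  expect_lt(abs(thr$threshold - 60), 0.1)
})

test_that("positivity is strict and calibrated on its own control", {
  # a cell exactly at the threshold is negative
  thr <- marker_threshold(rep(c(10, 30), 6), channel = "mk")
  at <- data.frame(cell_id = "x", mk = thr$threshold)
  expect_false(score_positivity(at, thr)$cells$mk_positive)

  # negative population scored against its own mean + 2 SD: upper-tail at
  # z = 2 is 0.02275 (self-thresholding perturbs it only at O(1/sqrt(n)))
  set.seed(62)
  vals <- rnorm(1e4, 50, 5)
  thr2 <- marker_threshold(vals, channel = "mk")
  pos <- score_positivity(data.frame(cell_id = as.character(seq_along(vals)),
                                     mk = vals), thr2)
  expect_lt(abs(pos$fraction_positive - 0.02275), 0.005)
})

test_that("generator positive fractions are recovered", {
  tt <- simulate_population(population_spec(2000, frac_senescent = 0.5,
                                            seed = 63))
  tt <- attach_marker(tt, "il6_gfp",
                      list(senescent = 0.8, non_senescent = 0.1),
                      neg_mean = 50, neg_sd = 2, pos_fold = 10, seed = 64)
  ctrl_vals <- tt$il6_gfp[!tt$il6_gfp_pos & tt$true_label == "non_senescent"]
  thr <- marker_threshold(ctrl_vals, channel = "il6_gfp")
  pos <- score_positivity(tt, thr)
  frac_true <- mean(tt$il6_gfp_pos)
  expect_lt(abs(pos$fraction_positive - frac_true), 0.03)
  expect_error(score_positivity(data.frame(cell_id = "a", other = 1), thr),
               class = "senoscreen_input_error")
})

test_that("per-FOV aggregation conserves condition-level counts", {
  tt <- simulate_population(population_spec(900, frac_senescent = 0.5, seed = 65))
  tt <- attach_marker(tt, "mk", list(senescent = 0.6), seed = 66)
  tt$fov_id <- rep(sprintf("fov%d", 1:9), each = 100)
  thr <- marker_threshold(tt$mk[tt$true_label == "non_senescent"], "mk")
  pos <- score_positivity(tt, thr)
  expect_equal(sum(pos$by_fov$n_positive), sum(pos$by_condition$n_positive))
  expect_equal(sum(pos$by_fov$n), nrow(tt))
})

test_that("stratified fractions recombine exactly and flag id mismatches", {
  tt <- simulate_population(population_spec(2000, frac_senescent = 0.5, seed = 67))
  tt <- attach_marker(tt, "mk", list(senescent = 0.8, non_senescent = 0.1),
                      seed = 68)
  screen <- data.frame(cell_id = tt$cell_id, condition = tt$condition,
                       label = tt$true_label)
  marker <- data.frame(cell_id = tt$cell_id, mk_positive = tt$mk_pos)
  st <- stratify(marker, screen, "mk")

  expect_equal(st$frac_pos_in_senescent + st$frac_neg_in_senescent, 1)
  expect_equal(st$frac_pos_in_non_senescent + st$frac_neg_in_non_senescent, 1)
  # mixture recombination: overall = weighted within-population fractions
  w_sen <- st$n_senescent / st$n
  expect_equal(
    st$fraction_positive,
    w_sen * st$frac_pos_in_senescent + (1 - w_sen) * st$frac_pos_in_non_senescent
  )
  # generator fractions recovered
  expect_lt(abs(st$frac_pos_in_senescent - 0.8), 0.05)
  expect_lt(abs(st$frac_pos_in_non_senescent - 0.1), 0.05)

  expect_error(stratify(marker[-1, ], screen, "mk"),
               class = "senoscreen_join_error")
})

test_that("markers independent of senescence stratify evenly", {
  tt <- simulate_population(population_spec(4000, frac_senescent = 0.5, seed = 69))
  tt <- attach_marker(tt, "mk",
                      list(senescent = 0.3, non_senescent = 0.3), seed = 70)
  screen <- data.frame(cell_id = tt$cell_id, label = tt$true_label)
  marker <- data.frame(cell_id = tt$cell_id, mk_positive = tt$mk_pos)
  st <- stratify(marker, screen, "mk", by = character(0))
  mc_se <- sqrt(0.3 * 0.7 / 2000)
  expect_lt(abs(st$frac_pos_in_senescent - st$fraction_positive), 3 * mc_se)
})
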