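test_that("simulate_population honours the deterministic count policy", {
  for (case in list(
    list(n = 100L, frac = 0, expected = 0L),
    list(n = 100L, frac = 1, expected = 100L),
    list(n = 100L, frac = 0.29, expected = 29L),
    list(n = 10L, frac = 0.25, expected = 2L),
    list(n = 57L, frac = 0.5, expected = 28L)
  )) {
    tt <- simulate_population(
      population_spec(case$n, frac_senescent = case$frac, seed = 11)
    )
    expect_equal(nrow(tt), case$n)
    expect_equal(sum(tt$true_label == "senescent"), case$expected)
    expect_setequal(unique(tt$true_label),
                    intersect(c("senescent", "non_senescent"), tt$true_label))
  }
})

test_that("generated tables satisfy the truth-table invariants", {
  for (seed in 1:5) {
    tt <- simulate_population(
      population_spec(300, frac_senescent = 0.4, seed = seed)
    )
    expect_false(anyDuplicated(tt$cell_id) > 0)
    expect_true(all(tt$lamin_a > 0))
    expect_true(all(tt$lamin_b1 > 0))
    expect_true(all(tt$true_label %in% c("senescent", "non_senescent")))
  }
})

test_that("control populations reproduce the closed-form lamin correlation", {
  # linear-plus-noise model: r = slope * sd_a / sqrt(slope^2 sd_a^2 + resid_sd^2)
  spec <- population_spec(10000, frac_senescent = 0, slope = 0.8,
                          intercept = 5, resid_sd = 2, lamin_a_sd = 20,
                          seed = 1)
  tt <- simulate_population(spec)
  r_expected <- 0.8 * 20 / sqrt(0.64 * 400 + 4)
  expect_lt(abs(cor(tt$lamin_a, tt$lamin_b1) - r_expected), 0.01)
})

test_that("simulation is bit-identical under a fixed seed", {
  spec <- population_spec(200, frac_senescent = 0.3, seed = 77)
  expect_identical(simulate_population(spec), simulate_population(spec))
  spec2 <- spec
  spec2$seed <- 78
  expect_false(identical(simulate_population(spec),
                         simulate_population(spec2)))
})

test_that("population_spec rejects invalid parameters", {
  expect_error(population_spec(10, frac_senescent = 1.2),
               class = "senoscreen_parameter_error")
  expect_error(population_spec(10, resid_sd = -1),
               class = "senoscreen_parameter_error")
  expect_error(population_spec(10, senescent_fold = 0.5),
               class = "senoscreen_parameter_error")
  expect_error(population_spec(10, lamin_a_sd = 0),
               class = "senoscreen_parameter_error")
})

test_that("attach_marker realizes exact deterministic positive counts", {
  tt <- simulate_population(
    population_spec(2000, frac_senescent = 0.5, seed = 3)
  )
  marked <- attach_marker(tt, "il6_gfp",
                          list(senescent = 0.8, non_senescent = 0.1),
                          seed = 4)
  sen <- marked$true_label == "senescent"
  expect_equal(sum(marked$il6_gfp_pos[sen]), 800L)  # floor(1000 * 0.8)
  expect_equal(sum(marked$il6_gfp_pos[!sen]), 100L)

  none <- attach_marker(tt, "m", list(senescent = 0, non_senescent = 0),
                        seed = 5)
  expect_false(any(none$m_pos))

  # labels omitted from the map default to fraction 0
  sen_only <- attach_marker(tt, "m2", list(senescent = 0.8), seed = 6)
  expect_equal(sum(sen_only$m2_pos[!sen]), 0L)
})

test_that("attach_marker separates populations at high fold", {
  tt <- simulate_population(population_spec(500, frac_senescent = 0.5, seed = 8))
  marked <- attach_marker(tt, "mk", list(senescent = 1, non_senescent = 0),
                          neg_mean = 50, neg_sd = 1, pos_fold = 10, seed = 9)
  sen <- marked$true_label == "senescent"
  expect_gt(min(marked$mk[sen]), max(marked$mk[!sen]))
  expect_error(
    attach_marker(tt, "mk2", list(apoptotic = 0.5)),
    class = "senoscreen_parameter_error"
  )
})

test_that("virtual sorting has exact composition and detects capacity limits", {
  tt <- simulate_population(population_spec(1000, frac_senescent = 0.5, seed = 2))
  sorted <- simulate_sorted_populations(tt, purity_sen = 0.96,
                                        purity_nsen = 0.88,
                                        sizes = c(100L, 200L), seed = 3)
  expect_equal(nrow(sorted$sorted_senescent), 100L)
  expect_equal(sum(sorted$sorted_senescent$true_label == "senescent"), 96L)
  expect_equal(nrow(sorted$sorted_non_senescent), 200L)
  expect_equal(sum(sorted$sorted_non_senescent$true_label == "non_senescent"),
               176L)  # floor(200 * 0.88)
  # sampling without replacement: no cell in both sorts
  expect_length(
    intersect(sorted$sorted_senescent$cell_id,
              sorted$sorted_non_senescent$cell_id),
    0
  )

  pure <- simulate_sorted_populations(tt, 1, 1, sizes = c(50L, 50L), seed = 4)
  expect_true(all(pure$sorted_senescent$true_label == "senescent"))
  expect_true(all(pure$sorted_non_senescent$true_label == "non_senescent"))

  no_sen <- simulate_population(population_spec(100, frac_senescent = 0, seed = 5))
  expect_error(
    simulate_sorted_populations(no_sen, 1, 1, sizes = c(10L, 10L), seed = 6),
    class = "senoscreen_capacity_error"
  )
})

test_that("logistic induction kinetics hit their midpoint and limits", {
  # midpoint: frac(t50) = (base + plateau) / 2
  expect_equal(logistic_fraction(84, base = 0.02, plateau = 0.9,
                                 k = 0.1, t50 = 84), 0.46)
  expect_equal(logistic_fraction(1e6, 0.02, 0.9, 0.1, 84), 0.9)
  expect_equal(logistic_fraction(10, 0.05, 0.05, 0.1, 84), 0.05)
  expect_error(logistic_fraction(0, 0.02, 1.4, 0.1, 84),
               class = "senoscreen_parameter_error")
})

test_that("simulate_timecourse builds per-well series with logistic truth", {
  spec <- population_spec(400, seed = 10)
  kin <- list(
    `0` = list(base = 0.05, plateau = 0.05, k = 0.1, t50 = 84),
    `50` = list(base = 0.02, plateau = 0.9, k = 0.1, t50 = 84)
  )
  tc <- simulate_timecourse(c(0, 50), c(0, 84, 156), kin, spec, n_wells = 2)
  expect_true(all(c("dose_0", "dose_50") %in% tc$condition))
  # every well carries its own t = 0 population
  for (w in unique(tc$well)) {
    expect_true(0 %in% tc$timepoint_h[tc$well == w])
  }
  # null kinetics: constant true fraction (deterministic counts)
  d0 <- tc[tc$condition == "dose_0", ]
  fr0 <- tapply(d0$true_label == "senescent",
                list(d0$well, d0$timepoint_h), mean)
  expect_true(all(fr0 == 0.05))
  # induced dose: true fraction at the midpoint timepoint is 0.46 exactly
  d50 <- tc[tc$condition == "dose_50" & tc$timepoint_h == 84, ]
  fr50 <- tapply(d50$true_label == "senescent", d50$well, mean)
  expect_true(all(fr50 == 0.46))  # floor(400 * 0.46) / 400
  expect_error(simulate_timecourse(c(0), c(84), kin, spec),
               class = "senoscreen_parameter_error")
})
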