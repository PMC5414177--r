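test_that("sizer corrects an uneven division; timer never does", {
  ps <- wt_one_transition()
  ex <- uneven_division_experiment(ps, 30, 10)
  expect_false(is.na(ex$convergence_cycles))
  expect_lte(ex$convergence_cycles, 10)
  expect_equal(ex$steady_birth, 20, tolerance = 0.01)

  pt <- timer_params()
  ext <- uneven_division_experiment(pt, 30, 10)
  expect_true(is.na(ext$convergence_cycles))
  # the size ratio between the two timer lineages never shrinks
  big <- ext$trajectories[ext$trajectories$cell == "big", "birth_size"]
  small <- ext$trajectories[ext$trajectories$cell == "small", "birth_size"]
  expect_equal(big / small, rep(3, length(big)), tolerance = 1e-9)
})

test_that("birth-size deviations roughly halve per generation at exponent 1", {
  tpl <- model_params(pCDK = 1, T_division = 100, g_mean = wt_growth_rate,
                      dt = 0.1)
  p <- calibrate_one_transition(template = tpl)
  traj <- simulate_lineage(p, 30, n_cycles = 4)$birth_size
  dev <- abs(traj - 20)
  ratios <- dev[-1] / dev[-length(dev)]
  expect_true(all(ratios > 0.35 & ratios < 0.65))
})

test_that("growth rate sets division size and cycle length in the sizer", {
  ps <- wt_one_transition()
  g <- wt_growth_rate
  res <- rgr_experiment(ps, g * c(0.5, 1, 1.5))
  expect_true(all(res$stability == "STABLE"))
  expect_true(all(diff(res$division_size) > 0))
  expect_true(all(diff(res$cycle_length) < 0))
  # continuous limit: division size roughly proportional to g
  expect_equal(res$division_size[3] / res$division_size[2], 1.5,
               tolerance = 0.1)
  # timer: off-doubling growth rates lose stability
  rt <- rgr_experiment(timer_params(), g * c(0.8, 1.2))
  expect_true(all(rt$stability == "LOST"))
})

test_that("pCDK sets cell size but not cycle length; g sets both", {
  p <- with_observed_noise(wt_one_transition())
  res <- pcdk_mutant_experiment(p, fold_changes = c(0.5, 1, 2),
                                g_factors = 1.5, duration = 600, seed = 5)
  wt <- res[res$parameter == "pCDK" & res$factor == 1, ]
  halved <- res[res$parameter == "pCDK" & res$factor == 0.5, ]
  doubled <- res[res$parameter == "pCDK" & res$factor == 2, ]
  # size moves opposite to pCDK, ~inversely in the continuous limit
  expect_equal(halved$division_size_mean / wt$division_size_mean, 2,
               tolerance = 0.15)
  expect_equal(doubled$division_size_mean / wt$division_size_mean, 0.5,
               tolerance = 0.15)
  # cycle length is untouched within sampling error
  expect_lt(abs(halved$cycle_length_mean - wt$cycle_length_mean) /
              wt$cycle_length_mean, 0.05)
  expect_lt(abs(doubled$cycle_length_mean - wt$cycle_length_mean) /
              wt$cycle_length_mean, 0.05)
  # the g comparator moves both size and cycle length
  faster <- res[res$parameter == "g", ]
  expect_gt(faster$division_size_mean / wt$division_size_mean, 1.2)
  expect_lt(faster$cycle_length_mean / wt$cycle_length_mean, 0.8)
})

test_that("weaker size feedback needs more cycles to recover, but stays stable", {
  res <- exponent_variant_experiment()
  expect_equal(res$alpha, c(1, 0.67, 0.34))
  expect_true(all(res$stability == "STABLE"))
  expect_true(all(diff(res$convergence_cycles) >= 0))
  expect_gt(res$convergence_cycles[3], res$convergence_cycles[1])
})

test_that("fold scans record additive phases and guard their inputs", {
  pA <- with_observed_noise(wt_two_transition(sizer_at_g1s = TRUE,
                                              sizer_at_g2m = FALSE))
  scan <- two_transition_fold_scan(pA, which = "pCDK_M",
                                   sizer_config = "G1S_only",
                                   folds = c(1, 1.5), duration = 300,
                                   seed = 41)
  expect_s3_class(scan, "cdk_scan_result")
  # phase additivity: mean G1 + mean S-G2-M = mean cycle length
  expect_equal(scan$g1_mean + scan$sgm_mean, scan$cycle_mean,
               tolerance = 1e-9)
  expect_true(all(scan$fold >= 1))
  expect_error(two_transition_fold_scan(pA, which = "pCDK_M",
                                        sizer_config = "both",
                                        folds = c(1, 2)),
               "sizer flags")
  expect_error(two_transition_fold_scan(pA, which = "pCDK_M",
                                        sizer_config = "G1S_only",
                                        folds = c(0.5, 1)),
               ">= 1")
})
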