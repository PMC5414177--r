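test_that("RGR formula and its inverse agree with direct evaluation", {
  expect_equal(compute_rgr(20, 40, 0, 24), log(2) / 24)
  expect_equal(compute_rgr(33, 33, 5, 29), 0)
  expect_equal(compute_rgr(25, 30, 0, 24), log(1.2) / 24)
  expect_equal(infer_interval_length(20, 40, log(2) / 24), 24)
  expect_equal(infer_interval_length(12, 12, 0.05), 0)
  expect_equal(infer_interval_length(20, 30, 0.0289), log(1.5) / 0.0289)
  expect_error(compute_rgr(-1, 10, 0, 1), "positive")
  expect_error(compute_rgr(10, 10, 5, 5), "t1 > t0")
  expect_error(infer_interval_length(10, 20, 0), "positive")
  # mutual inverses through the growth update, across random cases
  set.seed(8)
  for (i in 1:20) {
    a0 <- runif(1, 5, 80)
    g <- runif(1, 0.01, 0.08)
    t <- runif(1, 1, 60)
    expect_equal(infer_interval_length(a0, grow_step(a0, g, t), g), t)
    expect_equal(compute_rgr(a0, grow_step(a0, g, t), 0, t), g)
  }
})

test_that("sister pairs are paired, signed and flagged correctly", {
  tab <- data.frame(
    cell_id = 1:8,
    parent_id = c(NA, 1, 1, NA, 4, 4, NA, 7),
    birth_time = c(0, 25, 25, 0, 25, 25, 0, 25),
    division_time = c(25, 49, 55, 25, 50, 50, 25, NA),
    birth_area = c(20, 30, 24, 20, 21, 21, 20, 26),
    division_area = c(54, 58, 55, 42, 42, 42, 52, NA))
  pairs <- sister_pair_table(tab, sync_resolution = 3)
  # parent 7's second daughter never completed a cycle: pair excluded
  expect_equal(sort(pairs$parent_id), c(1, 4))
  p1 <- pairs[pairs$parent_id == 1, ]
  expect_equal(p1$delta_birth, 6)
  expect_true(p1$asymmetric)                  # 6 > 5 um^2
  expect_equal(p1$delta_cycle, (49 - 25) - (55 - 25))
  expect_false(p1$synchronous)                # |6| h >= 3 h resolution
  expect_equal(p1$delta_growth, (58 - 30) - (55 - 24))
  p4 <- pairs[pairs$parent_id == 4, ]
  expect_equal(p4$delta_birth, 0)
  expect_true(p4$synchronous)
  expect_false(p4$asymmetric)
  # convergence flag: |58 - 55| = 3 < 6 at birth
  expect_true(p1$closer_at_division)
  expect_equal(nrow(sister_pair_table(tab[1, ])), 0L)   # empty output is fine
})

test_that("p1 synchrony respects the resolution argument", {
  tab <- data.frame(cell_id = 1:3, parent_id = c(NA, 1, 1),
                    birth_time = c(0, 25, 25),
                    division_time = c(25, 49, 55),
                    birth_area = c(20, 30, 24),
                    division_area = c(54, 58, 55))
  expect_true(sister_pair_table(tab, sync_resolution = 8)$synchronous)
  expect_false(sister_pair_table(tab, sync_resolution = 3)$synchronous)
})

test_that("strict binomial tail matches exhaustive enumeration", {
  # independent oracle: enumerate all 2^n outcomes, n <= 12
  set.seed(5)
  for (i in 1:12) {
    n <- sample(1:12, 1)
    k <- sample(0:n, 1)
    p <- runif(1, 0.1, 0.9)
    expect_equal(binomial_tail_greater(k, n, p),
                 enumerate_tail_greater(k, n, p), tolerance = 1e-12)
  }
  expect_equal(binomial_tail_greater(0, 1, 0.5), 0.5)
  expect_equal(binomial_tail_greater(3, 4, 0.5), 0.0625)
  expect_equal(binomial_tail_greater(7, 7, 0.5), 0)
  # large-n cross-check against the distribution-function route
  expect_equal(binomial_tail_greater(72, 105, 0.5),
               stats::pbinom(72, 105, 0.5, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(binomial_tail_greater(5, 4, 0.5), "k <= n")
  expect_error(binomial_tail_greater(1, 4, 1), "p must")
})

test_that("convergence test counts asymmetric pairs under the strict tail", {
  pairs <- data.frame(asymmetric = c(rep(TRUE, 10), rep(FALSE, 4)),
                      closer_at_division = c(rep(FALSE, 10), rep(TRUE, 4)))
  res <- convergence_test(pairs)
  expect_equal(res$n_asymmetric, 10)
  expect_equal(res$k_closer, 0)
  expect_equal(res$p_value, 1 - 0.5^10)   # ~1: no convergence signal
  expect_error(convergence_test(pairs[11:14, ]), "no asymmetric")
})

test_that("marker combinations map onto cell-cycle phases", {
  expect_equal(classify_phase_from_markers(FALSE, FALSE), "G1")
  expect_equal(classify_phase_from_markers(TRUE, TRUE), "S")
  expect_equal(classify_phase_from_markers(FALSE, TRUE), "G2_M")
  expect_equal(classify_phase_from_markers(TRUE, FALSE), "INCONSISTENT")
  expect_equal(classify_phase_from_markers(c(TRUE, FALSE), c(TRUE, TRUE)),
               c("S", "G2_M"))
  expect_error(classify_phase_from_markers(NA, TRUE), "defined")
})

test_that("zone summary reduces to global means for a single zone", {
  run <- run_population(population_config(
    with_observed_noise(wt_one_transition()), duration = 200, seed = 31))
  tab <- run$lineage
  tab$zone <- "CZ"
  zs <- zone_summary(tab)
  expect_equal(nrow(zs), 1L)
  expect_equal(zs$birth_size_mean, mean(tab$birth_area))
  expect_equal(zs$cycle_length_mean,
               mean(tab$division_time - tab$birth_time))
  expect_error(zone_summary(tab[, -ncol(tab)], zone_col = "zone"), "zone")
})

test_that("larger daughters divide first in the simulated sizer population", {
  run <- run_population(population_config(
    with_observed_noise(wt_one_transition()), duration = 600, seed = 9))
  sp <- sister_pair_table(run$lineage, sync_resolution = 1)
  asyn <- sp[!sp$synchronous & sp$delta_birth > 0, ]
  expect_gt(nrow(asyn), 100)
  expect_gt(mean(asyn$delta_cycle < 0), 0.9)
})
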