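test_that("exponential growth update is exact", {
  expect_equal(grow_step(20, log(2) / 24, 24), 40)
  expect_equal(grow_step(33.7, 0, 5), 33.7)
  # closed-form value frozen from an independent high-precision evaluation
  expect_equal(grow_step(30, 0.05, 1), 31.5381328913, tolerance = 1e-10)
  expect_error(grow_step(-1, 0.05, 1), "positive")
  expect_error(grow_step(20, 0.05, 0), "positive")
})

test_that("production rate follows the selected size-dependence mode", {
  p_none <- model_params(pCDK = 3, T_division = 100,
                         size_dependence = "NONE")
  expect_equal(cdk_production_rate(c(5, 20, 80), p_none, "single"),
               rep(3, 3))
  p1 <- model_params(pCDK = 3, T_division = 100)
  expect_equal(cdk_production_rate(40, p1, "single"),
               2 * cdk_production_rate(20, p1, "single"))
  p67 <- model_params(pCDK = 3, T_division = 100, size_exponent = 0.67)
  expect_equal(cdk_production_rate(8 * 20, p67, "single") /
                 cdk_production_rate(20, p67, "single"),
               8^0.67, tolerance = 1e-12)
  pinv <- model_params(pCDK = 3, T_division = 100,
                       size_dependence = "PCDK_INV_SIZE")
  expect_equal(cdk_production_rate(40, pinv, "single"), 3 * 20 / 40)
  expect_error(cdk_production_rate(0, p1, "single"), "positive")
})

test_that("effective threshold follows the selected size-dependence mode", {
  pinv <- model_params(pCDK = 3, T_division = 100,
                       size_dependence = "THRESHOLD_INV_SIZE")
  expect_equal(effective_threshold(20, pinv, "single"), 100)
  expect_equal(effective_threshold(40, pinv, "single"), 50)
  pprop <- model_params(pCDK = 3, T_division = 100,
                        size_dependence = "THRESHOLD_PROP_SIZE")
  expect_equal(effective_threshold(10, pprop, "single"), 50)
  p1 <- model_params(pCDK = 3, T_division = 100)
  expect_equal(effective_threshold(77, p1, "single"), 100)
})

test_that("timer cell divides when accumulation strictly exceeds threshold", {
  # T = 24, pCDK = 1, dt = 1: 25 steps to exceed 24 strictly, 1 mitosis step
  p <- model_params(pCDK = 1, T_division = 24, size_dependence = "NONE")
  cell <- cell_state(20, g = wt_growth_rate)
  r24 <- advance_cell(cell, p, n_steps = 24)
  expect_equal(r24$event, "NONE")
  expect_equal(r24$cell$cdk, 24)          # tie: waits one more step
  r25 <- advance_cell(r24$cell, p, n_steps = 1)
  expect_equal(r25$event, "DIVISION_TRIGGERED")
  r26 <- advance_cell(r25$cell, p, n_steps = 1)
  expect_equal(r26$event, "DIVIDED")
  expect_equal(r26$cell$age, 26)
  # zero steps leave the state untouched
  expect_identical(advance_cell(cell, p, n_steps = 0)$cell, cell)
})

test_that("division splits the parent area exactly by the division ratio", {
  p <- model_params(pCDK = 1, T_division = 24, size_dependence = "NONE")
  make_ready <- function(size, d) {
    cell <- cell_state(size, g = wt_growth_rate, d = d)
    cell$phase <- "MITOSIS"
    cell$mitosis_left <- 0L
    cell
  }
  dd <- divide_cell(make_ready(40, 50), p)
  expect_equal(dd[[1]]$size, 20)
  expect_equal(dd[[2]]$size, 20)
  dd <- divide_cell(make_ready(40, 60), p)
  expect_equal(dd[[1]]$size, 24)
  expect_equal(dd[[2]]$size, 16)
  # mass conservation to machine precision across random cases
  set.seed(1)
  for (i in 1:25) {
    size <- runif(1, 5, 200)
    d <- runif(1, 5, 95)
    dd <- divide_cell(make_ready(size, d), p)
    expect_identical(dd[[1]]$size + dd[[2]]$size, size)
    expect_equal(dd[[1]]$cdk, 0)
    expect_equal(dd[[2]]$phase, "G1")
  }
  expect_error(divide_cell(cell_state(20, g = 0.03), p), "mitosis")
})

test_that("scalar lineage engine matches the vectorised cell engine", {
  configs <- list(
    model_params(pCDK = 3.1, T_division = 100, g_mean = wt_growth_rate),
    model_params(pCDK = 4, T_division = 100, size_dependence = "NONE",
                 g_mean = wt_growth_rate),
    wt_two_transition(),
    wt_two_transition(sizer_at_g1s = TRUE, sizer_at_g2m = FALSE))
  for (p in configs) {
    traj <- simulate_lineage(p, 23, n_cycles = 2)
    cell <- cell_state(23, g = p$g_mean, d = p$d_mean)
    res <- list(cell = cell, event = "NONE")
    while (res$event != "DIVIDED") res <- advance_cell(res$cell, p, 1)
    expect_equal(res$cell$size, traj$division_size[1])
    expect_equal(res$cell$age, traj$cycle_length[1])
    if (p$two_transition)
      expect_equal(res$cell$g1s_time, traj$g1s_time[1])
  }
})

test_that("interphase length responds monotonically to pCDK and T", {
  interphase <- function(pCDK, T_division) {
    p <- model_params(pCDK = pCDK, T_division = T_division,
                      g_mean = wt_growth_rate)
    simulate_lineage(p, 20, n_cycles = 1)$cycle_length
  }
  lens_p <- vapply(seq(2, 6, by = 0.5), interphase,
                   numeric(1), T_division = 100)
  expect_true(all(diff(lens_p) <= 0))
  lens_t <- vapply(seq(60, 180, by = 15), function(T)
    interphase(3, T), numeric(1))
  expect_true(all(diff(lens_t) >= 0))
})

test_that("discrete sizer converges to the continuous adder increment", {
  # closed form: area added per cycle = g * T * size_ref / pCDK
  g <- wt_growth_rate
  closed <- g * 100 * 20 / 2.7726
  errs <- vapply(c(1, 0.1, 0.01), function(dt) {
    p <- model_params(pCDK = 2.7726, T_division = 100, g_mean = g, dt = dt)
    ss <- steady_state_lineage(p, 20, max_cycles = 300)
    abs(ss$division_size - ss$birth_size - closed) / closed
  }, numeric(1))
  expect_true(all(diff(errs) < 0))        # first-order shrinkage
  expect_lt(errs[2], 0.02)
  expect_lt(errs[3], 0.002)
})

test_that("invalid parameterisations are rejected", {
  expect_error(model_params(pCDK = 3, T_division = 100, dt = 0), "dt")
  expect_error(model_params(pCDK = -1, T_division = 100), "positive")
  expect_error(model_params(pCDK = 3, T_division = 100, d_mean = 100),
               "d_mean")
  expect_error(model_params(two_transition = TRUE, pCDK_S = 1), "pCDK_M")
  expect_error(cell_state(20, g = 0.03, d = 0), "d must")
  expect_error(cell_state(-5, g = 0.03), "positive")
})
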