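## Scalar one-cycle simulator. Replicates the per-step semantics of
## .step_cells exactly (grow, accumulate at start-of-step size, strict
## threshold comparison, one-step-minimum phases, growth during mitosis with
## CDK frozen) but on plain scalars, because calibration bisections call it
## thousands of times. Equivalence with the vectorised engine is pinned by a
## test.
.sim_cycle <- function(params, b, g, t0, max_steps = 1e5) {
  dt <- params$dt
  size <- b
  cdk <- 0
  t <- t0
  g1s_time <- NA_real_
  g1s_size <- NA_real_
  two <- params$two_transition
  phase <- 1L                      # 1 G1/interphase, 2 S_G2_M, 3 mitosis
  mitosis_left <- 0L
  steps <- 0L
  slope <- params$rgr_size_slope
  repeat {
    steps <- steps + 1L
    if (steps > max_steps)
      stop("cell failed to divide within ", max_steps,
           " steps; degenerate parameters?")
    s0 <- size
    g_eff <- if (slope != 0) g + slope * (s0 - params$size_ref) else g
    size <- s0 * exp(g_eff * dt)
    t <- t + dt
    if (phase == 3L) {
      mitosis_left <- mitosis_left - 1L
      if (mitosis_left <= 0L) break
    } else if (two) {
      if (phase == 1L) {
        cdk <- cdk + cdk_production_rate(s0, params, "S") * dt
        if (cdk > effective_threshold(s0, params, "G1S")) {
          g1s_time <- t
          g1s_size <- size
          phase <- 2L
          cdk <- 0
        }
      } else {
        cdk <- cdk + cdk_production_rate(s0, params, "M") * dt
        if (cdk > effective_threshold(s0, params, "G2M")) {
          phase <- 3L
          mitosis_left <- params$mitosis_steps
        }
      }
    } else {
      cdk <- cdk + cdk_production_rate(s0, params, "single") * dt
      if (cdk > effective_threshold(s0, params, "single")) {
        phase <- 3L
        mitosis_left <- params$mitosis_steps
      }
    }
  }
  list(birth_time = t0, birth_size = b, g1s_time = g1s_time,
       g1s_size = g1s_size, division_time = t, division_size = size)
}

#' Simulate a single cell lineage
#'
#' Follows one cell through successive cycles, always keeping the first
#' daughter after each division. With `g_sd = 0` and `d_sd = 0` this is the
#' deterministic single-cell trajectory used by the calibration routines and
#' the perturbation experiments; with noise switched on, fresh `g` and `d`
#' are drawn at each birth as in the population simulator.
#'
#' @param params A [model_params()] object.
#' @param birth_size Size at birth of the founding cell (um^2).
#' @param n_cycles Number of complete division cycles to simulate.
#' @param t0 Time (h) at which the founder is born.
#' @param max_steps_per_cycle Safety cap; exceeding it aborts with an error
#'   (a cycle that long indicates a degenerate parameterisation).
#' @return A data frame with one row per completed cycle: `cycle`,
#'   `birth_time`, `birth_size`, `g1s_time`, `g1s_size`, `division_time`,
#'   `division_size`, `cycle_length`, `g1_length`, `sgm_length`, `g`, `d`.
#' @examples
#' p <- model_params(pCDK = 3.05, T_division = 100)
#' simulate_lineage(p, 20, n_cycles = 3)
#' @export
simulate_lineage <- function(params, birth_size, n_cycles = 10L, t0 = 0,
                             max_steps_per_cycle = 1e5) {
  validate_model_params(params)
  if (!is.finite(birth_size) || birth_size <= 0)
    stop("birth_size must be positive")
  n_cycles <- as.integer(n_cycles)
  b <- birth_size
  g <- .draw_g(1L, params)
  d <- .draw_d(1L, params)
  t <- t0
  out <- vector("list", n_cycles)
  for (cyc in seq_len(n_cycles)) {
    cy <- .sim_cycle(params, b, g, t, max_steps = max_steps_per_cycle)
    out[[cyc]] <- data.frame(
      cycle = cyc, birth_time = cy$birth_time, birth_size = cy$birth_size,
      g1s_time = cy$g1s_time, g1s_size = cy$g1s_size,
      division_time = cy$division_time, division_size = cy$division_size,
      cycle_length = cy$division_time - cy$birth_time,
      g1_length = cy$g1s_time - cy$birth_time,
      sgm_length = cy$division_time - cy$g1s_time,
      g = g, d = d)
    b <- cy$division_size * d / 100    # follow daughter 1
    t <- cy$division_time
    g <- .draw_g(1L, params)
    d <- .draw_d(1L, params)
  }
  do.call(rbind, out)
}

#' Noiseless steady state of a single lineage
#'
#' Iterates single-cell cycles (deterministic `g = g_mean`, `d = d_mean`)
#' until the lineage reaches its attractor. Two kinds of attractor occur on
#' the discrete time grid: a fixed point (consecutive birth sizes agree to
#' `tol`), and - whenever the doubling time `ln 2 / g` is not a whole number
#' of steps - a bounded limit cycle in which the birth size alternates
#' between step-grid bands. The latter is detected by comparing windowed
#' means of the birth-size series; in that case the reported sizes and
#' durations are means over the final window. A timer model away from its
#' fixed point drifts without bound and reports `converged = FALSE`.
#'
#' @inheritParams simulate_lineage
#' @param tol Relative tolerance on consecutive birth sizes (must be > 0).
#' @param max_cycles Cycle budget before attractor detection falls back to
#'   the windowed test.
#' @param window Window length (cycles) for limit-cycle detection; two
#'   adjacent windows whose mean birth sizes agree to 0.5% count as
#'   converged.
#' @return A list: `converged`, `attractor` (`"fixed_point"`,
#'   `"limit_cycle"` or `"none"`), `birth_size`, `division_size`,
#'   `cycle_length`, `g1_length`, `sgm_length`, `n_cycles`, and the vector
#'   of per-cycle `birth_sizes`.
#' @export
steady_state_lineage <- function(params, birth_size, tol = 1e-3,
                                 max_cycles = 200L, window = 12L) {
  validate_model_params(params)
  if (!is.finite(tol) || tol <= 0)
    stop("tol must be a positive relative tolerance")
  g <- params$g_mean
  d <- params$d_mean
  b <- birth_size
  t <- 0
  cycles <- vector("list", max_cycles)
  births <- numeric(max_cycles)
  fixed_at <- NA_integer_
  n_done <- 0L
  for (cyc in seq_len(max_cycles)) {
    births[cyc] <- b
    cy <- .sim_cycle(params, b, g, t)
    cycles[[cyc]] <- cy
    n_done <- cyc
    b_next <- cy$division_size * d / 100
    t <- cy$division_time
    if (abs(b_next - b) < tol * b) {
      fixed_at <- cyc
      b <- b_next
      break
    }
    b <- b_next
  }
  births <- births[seq_len(n_done)]
  stat <- function(f) vapply(cycles[seq_len(n_done)], f, numeric(1))
  if (!is.na(fixed_at)) {
    cy <- cycles[[fixed_at]]
    return(list(converged = TRUE, attractor = "fixed_point",
                birth_size = cy$birth_size,
                division_size = cy$division_size,
                cycle_length = cy$division_time - cy$birth_time,
                g1_length = cy$g1s_time - cy$birth_time,
                sgm_length = cy$division_time - cy$g1s_time,
                n_cycles = fixed_at, birth_sizes = births))
  }
  ## windowed limit-cycle detection over the final two windows
  ok <- FALSE
  if (n_done >= 2L * window) {
    w1 <- mean(births[(n_done - window + 1L):n_done])
    w0 <- mean(births[(n_done - 2L * window + 1L):(n_done - window)])
    ok <- abs(w1 - w0) < 0.005 * w1
  }
  tail_idx <- (max(1L, n_done - window + 1L)):n_done
  div <- stat(function(c) c$division_size)
  cyc_len <- stat(function(c) c$division_time - c$birth_time)
  g1_len <- stat(function(c) c$g1s_time - c$birth_time)
  sgm_len <- stat(function(c) c$division_time - c$g1s_time)
  list(converged = ok, attractor = if (ok) "limit_cycle" else "none",
       birth_size = mean(births[tail_idx]),
       division_size = mean(div[tail_idx]),
       cycle_length = mean(cyc_len[tail_idx]),
       g1_length = mean(g1_len[tail_idx]),
       sgm_length = mean(sgm_len[tail_idx]),
       n_cycles = n_done, birth_sizes = births)
}
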