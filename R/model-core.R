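#' Exponential growth update
#'
#' Advances a cell's outer surface area by one interval of exponential growth
#' at relative growth rate `g`: `size * exp(g * dt)`. This is the exact
#' solution of dS/dt = g S, matching the log-linear growth observed in
#' tracked meristem cells, so the update carries no time-discretisation error
#' of its own.
#'
#' @param size Cell size in um^2 (> 0). Vectorised.
#' @param g Relative growth rate in h^-1.
#' @param dt Interval in hours (> 0).
#' @return The size after `dt` hours.
#' @examples
#' grow_step(20, log(2) / 24, 24)  # doubles to 40
#' @export
grow_step <- function(size, g, dt) {
  if (any(!is.finite(size)) || any(size <= 0)) stop("size must be positive")
  if (any(!is.finite(dt)) || any(dt <= 0)) stop("dt must be positive")
  size * exp(g * dt)
}

## Which size-dependence mode applies to a given accumulator: in the
## two-transition model the mode is gated by the per-transition sizer flags.
.mode_for <- function(params, which) {
  if (!params$two_transition) return(params$size_dependence)
  flag <- switch(which,
                 S = , G1S = params$sizer_at_g1s,
                 M = , G2M = params$sizer_at_g2m,
                 single = TRUE)
  if (flag) params$size_dependence else "NONE"
}

.base_rate <- function(params, which) {
  r <- switch(which,
              single = params$pCDK,
              S = params$pCDK_S,
              M = params$pCDK_M,
              stop("unknown accumulator: ", which))
  if (is.null(r)) stop("production rate not set for accumulator ", which)
  r
}

.base_threshold <- function(params, which) {
  t <- switch(which,
              single = params$T_division,
              G1S = params$T_g1s,
              G2M = params$T_g2m,
              stop("unknown threshold: ", which))
  if (is.null(t)) stop("threshold not set for ", which)
  t
}

#' CDK production rate at a given cell size
#'
#' The instantaneous production rate of the selected CDK accumulator. In
#' `PCDK_PROP_SIZE` mode the base rate is scaled by
#' `(size / size_ref)^size_exponent`, in `PCDK_INV_SIZE` by
#' `size_ref / size`; threshold-dilution modes and `NONE` leave the rate at
#' its base value.
#'
#' @param size Cell size in um^2 (> 0). Vectorised.
#' @param params A [model_params()] object.
#' @param which `"single"` (one-transition), `"S"` or `"M"`.
#' @return Production rate in a.u. h^-1 (strictly positive).
#' @examples
#' p <- model_params(pCDK = 3, T_division = 100)
#' cdk_production_rate(40, p, "single") / cdk_production_rate(20, p, "single")
#' @export
cdk_production_rate <- function(size, params, which = "single") {
  if (any(!is.finite(size)) || any(size <= 0)) stop("size must be positive")
  base <- .base_rate(params, which)
  switch(.mode_for(params, which),
         NONE = ,
         THRESHOLD_INV_SIZE = ,
         THRESHOLD_PROP_SIZE = rep_len(base, length(size)),
         PCDK_PROP_SIZE = base * (size / params$size_ref)^params$size_exponent,
         PCDK_INV_SIZE = base * params$size_ref / size,
         stop("unknown size_dependence mode"))
}

#' Effective CDK threshold at a given cell size
#'
#' The threshold the selected accumulator is compared against. In
#' `THRESHOLD_INV_SIZE` mode (inhibitor dilution) the base threshold is
#' scaled by `size_ref / size`, in `THRESHOLD_PROP_SIZE` by
#' `size / size_ref`; production-rate modes and `NONE` leave it unchanged.
#'
#' @inheritParams cdk_production_rate
#' @param which `"single"`, `"G1S"` or `"G2M"`.
#' @return Threshold in a.u.
#' @export
effective_threshold <- function(size, params, which = "single") {
  if (any(!is.finite(size)) || any(size <= 0)) stop("size must be positive")
  base <- .base_threshold(params, which)
  switch(.mode_for(params, if (which == "single") "single" else which),
         NONE = ,
         PCDK_PROP_SIZE = ,
         PCDK_INV_SIZE = rep_len(base, length(size)),
         THRESHOLD_INV_SIZE = base * params$size_ref / size,
         THRESHOLD_PROP_SIZE = base * size / params$size_ref,
         stop("unknown size_dependence mode"))
}

## One synchronous time step over a population data frame (vectorised).
##
## Order of events within a step, for every cell in parallel:
##   1. grow exponentially for dt (growth never pauses, including mitosis);
##      the effective rate is g + rgr_size_slope * (size - size_ref),
##      evaluated at start-of-step size;
##   2. accumulate CDK, with the production rate and any size-dependent
##      threshold both evaluated at the start-of-step size;
##   3. compare: strictly exceeding the G1/S threshold records the
##      transition (time and end-of-step size), switches to S_G2_M and
##      resets the accumulator; strictly exceeding the division threshold
##      enters MITOSIS (CDK frozen from then on);
##   4. cells that entered MITOSIS on an earlier step count down; reaching
##      zero marks them ready to divide at the end of this step.
##
## Returns list(cells = survivors still cycling, ready = cells whose mitosis
## completed this step). `t` is the time at the start of the step.
.step_cells <- function(cells, params, t) {
  dt <- params$dt
  s0 <- cells$size
  g_eff <- cells$g + params$rgr_size_slope * (s0 - params$size_ref)
  cells$size <- s0 * exp(g_eff * dt)
  cells$age <- cells$age + dt

  in_mitosis <- cells$phase == "MITOSIS"
  g1 <- cells$phase == "G1"
  sgm <- cells$phase == "S_G2_M"

  if (params$two_transition) {
    if (any(g1))
      cells$cdk[g1] <- cells$cdk[g1] +
        cdk_production_rate(s0[g1], params, "S") * dt
    if (any(sgm))
      cells$cdk[sgm] <- cells$cdk[sgm] +
        cdk_production_rate(s0[sgm], params, "M") * dt
    cross_g1s <- g1 & cells$cdk > effective_threshold(s0, params, "G1S")
    if (any(cross_g1s)) {
      cells$g1s_time[cross_g1s] <- t + dt
      cells$g1s_size[cross_g1s] <- cells$size[cross_g1s]
      cells$phase[cross_g1s] <- "S_G2_M"
      cells$cdk[cross_g1s] <- 0
    }
    trigger <- sgm & cells$cdk > effective_threshold(s0, params, "G2M")
  } else {
    if (any(g1))
      cells$cdk[g1] <- cells$cdk[g1] +
        cdk_production_rate(s0[g1], params, "single") * dt
    trigger <- g1 & cells$cdk > effective_threshold(s0, params, "single")
  }
  if (any(trigger)) {
    cells$phase[trigger] <- "MITOSIS"
    cells$mitosis_left[trigger] <- params$mitosis_steps
  }
  if (any(in_mitosis))
    cells$mitosis_left[in_mitosis] <- cells$mitosis_left[in_mitosis] - 1L
  done <- cells$phase == "MITOSIS" & cells$mitosis_left <= 0L & in_mitosis
  list(cells = cells[!done, , drop = FALSE],
       ready = cells[done, , drop = FALSE])
}

#' Advance a single cell by time steps
#'
#' Applies the per-step update rules (grow, accumulate CDK, compare against
#' the effective threshold, count down mitosis) to one cell. Mitosis is
#' triggered when the accumulated activity strictly exceeds the effective
#' threshold and takes `params$mitosis_steps` further steps, during which the
#' cell grows but CDK is frozen; completion is signalled by the `"DIVIDED"`
#' event, after which the caller divides the cell with [divide_cell()].
#'
#' @param cell A [cell_state()] row.
#' @param params A [model_params()] object.
#' @param n_steps Number of steps of `params$dt` hours to take (0 returns the
#'   cell unchanged). Stepping stops early when mitosis completes.
#' @param t Absolute time (h) at the start of the first step; defaults to
#'   `birth_time + age` of the cell.
#' @return `list(cell = updated cell, event = one of "NONE",
#'   "DIVISION_TRIGGERED", "DIVIDED")`. `"DIVISION_TRIGGERED"` reports that
#'   the cell is currently in mitosis.
#' @examples
#' p <- model_params(pCDK = 1, T_division = 24, size_dependence = "NONE")
#' cell <- cell_state(20, g = log(2) / 25, d = 50)
#' res <- advance_cell(cell, p, n_steps = 26)
#' res$event  # "DIVIDED" at t = 26 h
#' @export
advance_cell <- function(cell, params, n_steps = 1L, t = NULL) {
  stopifnot(is.data.frame(cell), nrow(cell) == 1)
  validate_model_params(params)
  n_steps <- as.integer(n_steps)
  if (n_steps < 0) stop("n_steps must be >= 0")
  if (is.null(t)) t <- cell$birth_time + cell$age
  event <- if (cell$phase == "MITOSIS") "DIVISION_TRIGGERED" else "NONE"
  if (n_steps == 0) return(list(cell = cell, event = event))
  for (i in seq_len(n_steps)) {
    st <- .step_cells(cell, params, t)
    t <- t + params$dt
    if (nrow(st$ready)) {
      cell <- st$ready
      return(list(cell = cell, event = "DIVIDED"))
    }
    cell <- st$cells
  }
  event <- if (cell$phase == "MITOSIS") "DIVISION_TRIGGERED" else "NONE"
  list(cell = cell, event = event)
}

## Truncated-normal draws for per-cell parameters. g is truncated to > 0,
## d to [5, 95] percent (extreme asymmetries are never observed and would
## produce near-zero daughters). Plain resampling; the truncated mass is
## negligible at realistic noise levels.
.draw_g <- function(n, params) {
  if (params$g_sd == 0) return(rep_len(params$g_mean, n))
  g <- stats::rnorm(n, params$g_mean, params$g_sd)
  bad <- g <= 0
  while (any(bad)) {
    g[bad] <- stats::rnorm(sum(bad), params$g_mean, params$g_sd)
    bad <- g <= 0
  }
  g
}

.draw_d <- function(n, params) {
  if (params$d_sd == 0) return(rep_len(params$d_mean, n))
  d <- stats::rnorm(n, params$d_mean, params$d_sd)
  bad <- d < 5 | d > 95
  while (any(bad)) {
    d[bad] <- stats::rnorm(sum(bad), params$d_mean, params$d_sd)
    bad <- d < 5 | d > 95
  }
  d
}

## Vectorised division of cells that completed mitosis. Daughter 1 receives
## d percent of the parent area, daughter 2 the remainder (areas sum exactly
## to the parent area). Both daughters reset CDK, re-enter G1 at age 0 and
## draw fresh g and d. Consumes the RNG stream.
.divide_cells <- function(ready, params, t, next_id) {
  n <- nrow(ready)
  if (n == 0)
    return(list(daughters = ready[0, , drop = FALSE], next_id = next_id))
  s1 <- ready$size * ready$d / 100
  s2 <- ready$size - s1
  ids <- next_id + seq_len(2L * n) - 1L
  daughters <- data.frame(
    cell_id = ids,
    parent_id = rep(ready$cell_id, 2L),
    size = c(s1, s2),
    cdk = 0,
    phase = "G1",
    mitosis_left = 0L,
    age = 0,
    g = .draw_g(2L * n, params),
    d = .draw_d(2L * n, params),
    birth_size = c(s1, s2),
    birth_time = t,
    g1s_time = NA_real_,
    g1s_size = NA_real_,
    zone = rep(ready$zone, 2L),
    stringsAsFactors = FALSE)
  list(daughters = daughters, next_id = next_id + 2L * n)
}

#' Divide a cell that has completed mitosis
#'
#' Splits the parent area according to its preassigned division ratio `d`:
#' the first daughter receives `d` percent of the parent area, the second the
#' remainder, so the daughter areas sum exactly to the parent area. Both
#' daughters start in G1 with CDK reset to zero, age zero, and freshly drawn
#' `g` and `d`.
#'
#' @param cell A cell whose mitosis has completed (phase `"MITOSIS"`,
#'   countdown exhausted), e.g. the cell returned by [advance_cell()] with a
#'   `"DIVIDED"` event.
#' @param params A [model_params()] object (supplies the `g` and `d`
#'   distributions for the daughters).
#' @param t Birth time to record for the daughters (defaults to the parent's
#'   `birth_time + age`).
#' @return A list of two `cell_state` rows.
#' @export
divide_cell <- function(cell, params, t = NULL) {
  stopifnot(is.data.frame(cell), nrow(cell) == 1)
  if (cell$phase != "MITOSIS" || cell$mitosis_left > 0L)
    stop("cell has not completed mitosis; cannot divide")
  if (is.null(t)) t <- cell$birth_time + cell$age
  res <- .divide_cells(cell, params, t, next_id = cell$cell_id + 1L)
  d <- res$daughters
  class(d) <- c("cdk_cell_state", "data.frame")
  list(d[1, , drop = FALSE], d[2, , drop = FALSE])
}
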