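#' Configuration for the synthetic lineage-table generator
#'
#' The generator emulates the statistical structure of cell-tracking tables
#' from a dividing meristem surface: exponential single-cell growth, uneven
#' divisions, zone-dependent growth rates, and additive measurement noise on
#' recorded areas. Latent dynamics come from the CDK cell-cycle engine
#' (dual-sizer two-transition model for `SIZER`, the same rates with size
#' feedback disabled for `TIMER`), so the generated tables satisfy every
#' lineage-table invariant exactly when `noise_sd = 0`.
#'
#' The default division-ratio spread (`d_sd = 12`) is chosen so that about
#' 60% of divisions produce daughters differing by more than 5 um^2 at birth
#' at wild-type sizes (at a 40 um^2 division size the birth difference is
#' `0.8 * |d - 50|` um^2, so `P(diff > 5) = P(|d - 50| > 6.25) ~= 0.60` at
#' s.d. 12), the asymmetry level reported for meristem divisions. Note that
#' under `TIMER` dynamics absolute birth-size differences are amplified (not
#' preserved) by exponential growth, so timer tables show almost no
#' convergence of sister sizes - which is precisely what makes them a useful
#' null for the convergence test.
#'
#' @param n_founders Number of founder cells.
#' @param n_generations Generations of the recorded binary tree per founder.
#' @param recording_interval Imaging interval in hours; carried in the
#'   config for downstream synchrony resolution (event times themselves are
#'   recorded at simulation resolution so that noise-free tables satisfy the
#'   table invariants exactly).
#' @param zones Data frame with columns `label`, `g_mean`, `g_sd`; founders
#'   are assigned to zones round-robin. Defaults to a central zone /
#'   peripheral zone / primordium gradient of increasing growth rate.
#' @param d_mean,d_sd Division-ratio distribution (percent).
#' @param noise_sd Additive Gaussian measurement noise on recorded areas
#'   (um^2; latent dynamics stay exact).
#' @param dynamics `"SIZER"` or `"TIMER"`.
#' @param seed Integer seed.
#' @param g_ref Reference growth rate at which the latent model is
#'   calibrated (h^-1).
#' @param latent_exponent Size-sensing exponent of the latent sizer
#'   (default 2). With production exactly proportional to size (exponent 1)
#'   each daughter adds the same area per cycle, so absolute sister-size
#'   differences are preserved within a cycle (adder behaviour); tracked
#'   meristem sisters instead converge in size before dividing (the larger
#'   daughter adds less), which requires superlinear size sensing. An
#'   exponent of 2 gives approximate critical-size behaviour and reproduces
#'   the observed majority of asymmetric pairs being closer at division.
#' @param burn_in_cycles Unrecorded cycles run before the recorded tree, so
#'   founders start near their zone's steady state.
#' @return An object of class `cdk_synth_config`.
#' @export
synth_config <- function(n_founders = 24L, n_generations = 3L,
                         recording_interval = 8,
                         zones = data.frame(
                           label = c("CZ", "PZ", "P"),
                           g_mean = c(log(2) / 25, 0.033, 0.040),
                           g_sd = c(0.08, 0.08, 0.08) *
                             c(log(2) / 25, 0.033, 0.040),
                           stringsAsFactors = FALSE),
                         d_mean = 50, d_sd = 12, noise_sd = 0.5,
                         dynamics = c("SIZER", "TIMER"), seed = 1L,
                         g_ref = log(2) / 25, latent_exponent = 2,
                         burn_in_cycles = 3L) {
  dynamics <- match.arg(dynamics)
  if (recording_interval <= 0) stop("recording_interval must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  stopifnot(is.data.frame(zones),
            all(c("label", "g_mean", "g_sd") %in% names(zones)))
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              recording_interval = recording_interval, zones = zones,
              d_mean = d_mean, d_sd = d_sd, noise_sd = noise_sd,
              dynamics = dynamics, seed = as.integer(seed), g_ref = g_ref,
              latent_exponent = latent_exponent,
              burn_in_cycles = as.integer(burn_in_cycles))
  class(cfg) <- "cdk_synth_config"
  cfg
}

## Latent model for the generator: dual-sizer two-transition wild type
## calibrated at g_ref; TIMER keeps the calibrated rates but removes the
## size feedback at both transitions.
.synth_params <- function(config) {
  tpl <- model_params(two_transition = TRUE, pCDK_S = 1, pCDK_M = 1,
                      T_g1s = 100, T_g2m = 200, g_mean = config$g_ref,
                      size_exponent = config$latent_exponent)
  p <- calibrate_two_transition(g = config$g_ref, template = tpl)
  p$d_mean <- config$d_mean
  p$d_sd <- 0                # d is drawn per cell by the generator
  p$g_sd <- 0
  if (config$dynamics == "TIMER") {
    p$sizer_at_g1s <- FALSE
    p$sizer_at_g2m <- FALSE
  }
  p
}

.noisy <- function(x, sd) {
  if (sd == 0) return(x)
  pmax(x + stats::rnorm(length(x), 0, sd), 0.1)
}

#' Generate a synthetic lineage table
#'
#' Simulates `n_founders` binary lineage trees under the configured
#' dynamics, records every cell that completes a cycle (birth, G1/S and
#' division times and areas, parentage, zone), and adds measurement noise
#' to the recorded areas only. Deterministic given the seed.
#'
#' @param config A [synth_config()].
#' @return A lineage table data frame (columns as in
#'   [write_lineage_table()]), with one row per completed cell cycle.
#' @examples
#' tab <- generate_lineage_table(synth_config(n_founders = 4, seed = 7))
#' head(tab)
#' @export
generate_lineage_table <- function(config) {
  stopifnot(inherits(config, "cdk_synth_config"))
  set.seed(config$seed)
  params <- .synth_params(config)
  zones <- config$zones
  rows <- list()
  next_id <- 1L
  for (f in seq_len(config$n_founders)) {
    z <- zones[((f - 1L) %% nrow(zones)) + 1L, ]
    draw_gz <- function() {
      g <- stats::rnorm(1L, z$g_mean, z$g_sd)
      while (g <= 0) g <- stats::rnorm(1L, z$g_mean, z$g_sd)
      g
    }
    ## unrecorded burn-in so the founder starts near its zone's steady state
    b <- params$size_ref
    t <- 0
    for (k in seq_len(config$burn_in_cycles)) {
      cy <- .sim_cycle(params, b, draw_gz(), t)
      b <- cy$division_size / 2
      t <- 0                        # burn-in consumes no recorded time
    }
    queue <- list(list(b = b, t = 0, gen = 1L, parent = NA_integer_))
    while (length(queue)) {
      cell <- queue[[1L]]
      queue <- queue[-1L]
      g <- draw_gz()
      d <- .draw_d(1L, list(d_mean = config$d_mean, d_sd = config$d_sd))
      cy <- .sim_cycle(params, cell$b, g, cell$t)
      id <- next_id
      next_id <- next_id + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = id, parent_id = cell$parent,
        birth_time = cy$birth_time, division_time = cy$division_time,
        birth_area = .noisy(cy$birth_size, config$noise_sd),
        division_area = .noisy(cy$division_size, config$noise_sd),
        g1s_time = cy$g1s_time,
        g1s_area = .noisy(cy$g1s_size, config$noise_sd),
        zone = z$label, stringsAsFactors = FALSE)
      if (cell$gen < config$n_generations) {
        s1 <- cy$division_size * d / 100
        queue <- c(queue,
                   list(list(b = s1, t = cy$division_time,
                             gen = cell$gen + 1L, parent = id),
                        list(b = cy$division_size - s1,
                             t = cy$division_time,
                             gen = cell$gen + 1L, parent = id)))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate sister-pair records
#'
#' Produces exactly `n_pairs` divisions in which the parent and both
#' daughters complete full cycles, ready for [sister_pair_table()]. Each
#' pair descends from an independent founder of the first configured zone.
#'
#' @param config A [synth_config()].
#' @param n_pairs Number of tracked divisions.
#' @return A lineage table with `3 * n_pairs` rows (parent and two
#'   daughters per pair).
#' @export
generate_sister_pairs <- function(config, n_pairs) {
  stopifnot(inherits(config, "cdk_synth_config"))
  set.seed(config$seed)
  params <- .synth_params(config)
  z <- config$zones[1L, ]
  draw_gz <- function() {
    g <- stats::rnorm(1L, z$g_mean, z$g_sd)
    while (g <= 0) g <- stats::rnorm(1L, z$g_mean, z$g_sd)
    g
  }
  rows <- vector("list", 3L * n_pairs)
  for (i in seq_len(n_pairs)) {
    b <- params$size_ref
    t <- 0
    for (k in seq_len(config$burn_in_cycles)) {
      cy <- .sim_cycle(params, b, draw_gz(), t)
      b <- cy$division_size / 2
      t <- 0
    }
    d <- .draw_d(1L, list(d_mean = config$d_mean, d_sd = config$d_sd))
    parent <- .sim_cycle(params, b, draw_gz(), 0)
    pid <- 3L * (i - 1L) + 1L
    rows[[pid]] <- data.frame(
      cell_id = pid, parent_id = NA_integer_,
      birth_time = parent$birth_time, division_time = parent$division_time,
      birth_area = .noisy(parent$birth_size, config$noise_sd),
      division_area = .noisy(parent$division_size, config$noise_sd),
      g1s_time = parent$g1s_time,
      g1s_area = .noisy(parent$g1s_size, config$noise_sd),
      zone = z$label, stringsAsFactors = FALSE)
    s1 <- parent$division_size * d / 100
    sizes <- c(s1, parent$division_size - s1)
    for (j in 1:2) {
      cy <- .sim_cycle(params, sizes[j], draw_gz(), parent$division_time)
      rows[[pid + j]] <- data.frame(
        cell_id = pid + j, parent_id = pid,
        birth_time = cy$birth_time, division_time = cy$division_time,
        birth_area = .noisy(cy$birth_size, config$noise_sd),
        division_area = .noisy(cy$division_size, config$noise_sd),
        g1s_time = cy$g1s_time,
        g1s_area = .noisy(cy$g1s_size, config$noise_sd),
        zone = z$label, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
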