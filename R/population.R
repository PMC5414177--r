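#' Configuration for a population simulation
#'
#' @param params A [model_params()] object.
#' @param n_init Number of founding cells (default 100).
#' @param cap Maximum population size; when a step ends with more cells,
#'   randomly selected cells are removed down to the cap (default 100).
#' @param duration Simulated time in hours.
#' @param burn_in Hours excluded from summary statistics, so that the
#'   initialisation transient does not contaminate reported distributions.
#'   Defaults to three mean cycle lengths (`3 * ln 2 / g_mean`).
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param record_timeseries Keep the per-timepoint population summary
#'   (always cheap; default `TRUE`).
#' @return An object of class `cdk_population_config`.
#' @export
population_config <- function(params, n_init = 100L, cap = 100L,
                              duration = 600, burn_in = NULL, seed = 1L,
                              record_timeseries = TRUE) {
  validate_model_params(params)
  if (is.null(burn_in)) burn_in <- 3 * log(2) / params$g_mean
  n_init <- as.integer(n_init)
  cap <- as.integer(cap)
  if (n_init < 1L) stop("n_init must be >= 1")
  if (n_init > cap) stop("n_init must not exceed cap")
  if (!(duration > burn_in) || burn_in < 0)
    stop("need duration > burn_in >= 0")
  cfg <- list(params = params, n_init = n_init, cap = cap,
              duration = duration, burn_in = burn_in,
              seed = as.integer(seed),
              record_timeseries = isTRUE(record_timeseries))
  class(cfg) <- "cdk_population_config"
  cfg
}

#' Initialise an asynchronous population
#'
#' Draws `n_init` cells spread over the cycle: sizes log-uniform between the
#' nominal birth size (`size_ref`) and the nominal division size
#' (`2 * size_ref`), with the CDK accumulator(s) set proportionally to the
#' cell's progress through the cycle, and per-cell `g` and `d` drawn from
#' their truncated normal distributions. Deterministic given the seed set by
#' the caller.
#'
#' @param config A [population_config()] object.
#' @return A data frame of cells (one [cell_state()] row each).
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "cdk_population_config"))
  p <- config$params
  n <- config$n_init
  b <- p$size_ref
  size <- exp(stats::runif(n, log(b), log(2 * b)))
  progress <- log(size / b) / log(2)     # 0 at birth, 1 at division
  g <- .draw_g(n, p)
  d <- .draw_d(n, p)
  cells <- data.frame(
    cell_id = seq_len(n),
    parent_id = NA_integer_,
    size = size,
    cdk = 0,
    phase = "G1",
    mitosis_left = 0L,
    age = 0,
    g = g,
    d = d,
    birth_size = size,
    birth_time = 0,
    g1s_time = NA_real_,
    g1s_size = NA_real_,
    zone = NA_character_,
    stringsAsFactors = FALSE)
  if (p$two_transition) {
    ## assume the nominal 60/40 split of the cycle between G1 and S-G2-M
    frac <- 0.6
    in_g1 <- progress < frac
    cells$cdk[in_g1] <- progress[in_g1] / frac * p$T_g1s
    cells$phase[!in_g1] <- "S_G2_M"
    cells$cdk[!in_g1] <- (progress[!in_g1] - frac) / (1 - frac) * p$T_g2m
  } else {
    cells$cdk <- progress * p$T_division
  }
  cells
}

#' Run a capped asynchronous population simulation
#'
#' Advances all cells synchronously in steps of `params$dt`, appending both
#' daughters at each division and culling uniformly at random down to `cap`
#' whenever the population exceeds it (culling happens after all divisions
#' of a step). Every completed cycle of a cell born during the run is
#' recorded in a lineage table.
#'
#' @param config A [population_config()] object.
#' @return An object of class `cdk_population_run`: a list with
#'   \describe{
#'     \item{`lineage`}{lineage table of completed cycles (`cell_id`,
#'       `parent_id`, `birth_time`, `division_time`, `birth_area`,
#'       `division_area`, `g1s_time`, `g1s_area`, `g`, `d`, `zone`).}
#'     \item{`timeseries`}{per-timepoint `time`, `n`, `mean_size`,
#'       `sd_size`.}
#'     \item{`summary`}{a [summarize_population()] of the post-burn-in
#'       lineage table (`NULL` if too few completed cycles).}
#'     \item{`config`}{the input configuration.}
#'   }
#' @examples
#' p <- model_params(pCDK = 3.05, T_division = 100, g_sd = 0.2 * log(2) / 25,
#'                   d_sd = 5)
#' run <- run_population(population_config(p, duration = 150, seed = 42))
#' nrow(run$lineage)
#' @export
run_population <- function(config) {
  stopifnot(inherits(config, "cdk_population_config"))
  p <- config$params
  set.seed(config$seed)
  cells <- init_population(config)
  next_id <- config$n_init + 1L
  n_steps <- floor(config$duration / p$dt + 1e-9)
  records <- vector("list", 256L)
  n_rec <- 0L
  ts_time <- numeric(n_steps + 1L)
  ts_n <- integer(n_steps + 1L)
  ts_mean <- numeric(n_steps + 1L)
  ts_sd <- numeric(n_steps + 1L)
  ts_time[1L] <- 0
  ts_n[1L] <- nrow(cells)
  ts_mean[1L] <- mean(cells$size)
  ts_sd[1L] <- stats::sd(cells$size)
  t <- 0
  for (k in seq_len(n_steps)) {
    st <- .step_cells(cells, p, t)
    t <- t + p$dt
    cells <- st$cells
    ready <- st$ready
    if (nrow(ready)) {
      n_rec <- n_rec + 1L
      if (n_rec > length(records)) records <- c(records, vector("list", length(records)))
      records[[n_rec]] <- data.frame(
        cell_id = ready$cell_id, parent_id = ready$parent_id,
        birth_time = ready$birth_time, division_time = t,
        birth_area = ready$birth_size, division_area = ready$size,
        g1s_time = ready$g1s_time, g1s_area = ready$g1s_size,
        g = ready$g, d = ready$d, zone = ready$zone,
        stringsAsFactors = FALSE)
      div <- .divide_cells(ready, p, t, next_id)
      next_id <- div$next_id
      cells <- rbind(cells, div$daughters)
    }
    if (nrow(cells) == 0L)
      stop("population went extinct at t = ", t, " h")
    if (nrow(cells) > config$cap) {
      keep <- sample.int(nrow(cells), config$cap)
      cells <- cells[keep, , drop = FALSE]
    }
    ts_time[k + 1L] <- t
    ts_n[k + 1L] <- nrow(cells)
    ts_mean[k + 1L] <- mean(cells$size)
    ts_sd[k + 1L] <- stats::sd(cells$size)
  }
  lineage <- if (n_rec) do.call(rbind, records[seq_len(n_rec)]) else
    data.frame(cell_id = integer(), parent_id = integer(),
               birth_time = numeric(), division_time = numeric(),
               birth_area = numeric(), division_area = numeric(),
               g1s_time = numeric(), g1s_area = numeric(),
               g = numeric(), d = numeric(), zone = character(),
               stringsAsFactors = FALSE)
  rownames(lineage) <- NULL
  ts <- data.frame(time = ts_time, n = ts_n, mean_size = ts_mean,
                   sd_size = ts_sd)
  post <- lineage[lineage$birth_time >= config$burn_in, , drop = FALSE]
  summ <- if (nrow(post) >= 2L) summarize_population(post) else NULL
  out <- list(lineage = lineage,
              timeseries = if (config$record_timeseries) ts else NULL,
              summary = summ, config = config)
  class(out) <- "cdk_population_run"
  out
}

#' @export
print.cdk_population_run <- function(x, ...) {
  cat(sprintf("Population run: %g h, %d completed cycles recorded\n",
              x$config$duration, nrow(x$lineage)))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Summary statistics of a lineage table
#'
#' Means and standard deviations of birth size, division size, cycle length
#' and (when the G1/S transition is recorded) phase lengths, plus the
#' least-squares slope and correlation of cycle length against log birth
#' size. A sizer population shows a negative slope (larger-born cells cycle
#' faster); the reversed variants show a positive one.
#'
#' @param table A lineage table (as in `cdk_population_run$lineage`) with at
#'   least two completed cycles.
#' @return An object of class `cdk_population_summary` (a list of named
#'   statistics: `n_cycles`, `birth_size_mean/sd`, `division_size_mean/sd`,
#'   `cycle_length_mean/sd`, `g1_length_mean/sd`, `sgm_length_mean/sd`,
#'   `size_cycle_slope`, `size_cycle_cor`).
#' @export
summarize_population <- function(table) {
  if (!is.data.frame(table) || nrow(table) < 2L)
    stop("need a lineage table with at least 2 completed cycles")
  cyc <- table$division_time - table$birth_time
  g1 <- table$g1s_time - table$birth_time
  sgm <- table$division_time - table$g1s_time
  fit <- stats::lm(cyc ~ log(table$birth_area))
  out <- list(
    n_cycles = nrow(table),
    birth_size_mean = mean(table$birth_area),
    birth_size_sd = stats::sd(table$birth_area),
    division_size_mean = mean(table$division_area),
    division_size_sd = stats::sd(table$division_area),
    cycle_length_mean = mean(cyc),
    cycle_length_sd = stats::sd(cyc),
    g1_length_mean = if (all(is.na(g1))) NA_real_ else mean(g1, na.rm = TRUE),
    g1_length_sd = if (all(is.na(g1))) NA_real_ else stats::sd(g1, na.rm = TRUE),
    sgm_length_mean = if (all(is.na(sgm))) NA_real_ else mean(sgm, na.rm = TRUE),
    sgm_length_sd = if (all(is.na(sgm))) NA_real_ else stats::sd(sgm, na.rm = TRUE),
    size_cycle_slope = unname(stats::coef(fit)[2L]),
    size_cycle_cor = if (stats::sd(cyc) == 0) 0 else
      stats::cor(log(table$birth_area), cyc))
  class(out) <- "cdk_population_summary"
  out
}

#' @export
print.cdk_population_summary <- function(x, ...) {
  cat(sprintf("  %d cycles | birth %.2f +/- %.2f um^2 | division %.2f +/- %.2f um^2\n",
              x$n_cycles, x$birth_size_mean, x$birth_size_sd,
              x$division_size_mean, x$division_size_sd))
  cat(sprintf("  cycle %.2f +/- %.2f h", x$cycle_length_mean, x$cycle_length_sd))
  if (!is.na(x$g1_length_mean))
    cat(sprintf(" | G1 %.2f h | S-G2-M %.2f h", x$g1_length_mean,
                x$sgm_length_mean))
  cat(sprintf("\n  cycle ~ ln(birth size): slope %.3f h, r = %.3f\n",
              x$size_cycle_slope, x$size_cycle_cor))
  invisible(x)
}
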