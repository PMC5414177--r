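#' Uneven-division recovery experiment
#'
#' Starts one large and one small cell (no noise) and follows each lineage,
#' asking whether and how fast their birth sizes return to the steady state.
#' A sizer corrects the perturbation within a few cycles (for the
#' size-proportional production model the birth-size deviation roughly
#' halves each generation); a timer never does.
#'
#' @param params A (typically calibrated) [model_params()] object.
#' @param size_big,size_small Birth sizes of the two founders (um^2).
#' @param n_cycles Number of cycles to follow each lineage.
#' @param conv_frac Convergence band: both birth sizes must come within this
#'   relative distance of the steady-state birth size (default 0.05). Note
#'   that the discrete trigger leaves a neutral band of birth sizes in which
#'   a lineage comes to rest; the band widens as the size feedback weakens
#'   (roughly as `(1 + g dt)^(1/alpha)`), so weak-feedback variants should
#'   be run at a finer `dt` than the default 1 h for this criterion to be
#'   meaningful (see [exponent_variant_experiment()]).
#' @return A list: `trajectories` (data frame with `cell` in
#'   `{"big","small"}`, per-cycle birth/division sizes and cycle lengths),
#'   `steady_birth` (steady-state birth size, `NA` if the model has none),
#'   and `convergence_cycles` (first generation at which both lineages are
#'   within the band; `NA` for non-convergence).
#' @export
uneven_division_experiment <- function(params, size_big, size_small,
                                       n_cycles = 30L, conv_frac = 0.05) {
  validate_model_params(params)
  p <- params
  p$g_sd <- 0
  p$d_sd <- 0
  ss <- steady_state_lineage(p, p$size_ref, max_cycles = 100L)
  steady_birth <- if (ss$converged) ss$birth_size else NA_real_
  big <- simulate_lineage(p, size_big, n_cycles = n_cycles)
  small <- simulate_lineage(p, size_small, n_cycles = n_cycles)
  big$cell <- "big"
  small$cell <- "small"
  traj <- rbind(big, small)
  conv <- NA_integer_
  if (!is.na(steady_birth)) {
    ok <- abs(big$birth_size - steady_birth) <= conv_frac * steady_birth &
      abs(small$birth_size - steady_birth) <= conv_frac * steady_birth
    if (any(ok)) conv <- which(ok)[1L]
  }
  list(trajectories = traj, steady_birth = steady_birth,
       convergence_cycles = conv)
}

#' Growth-rate perturbation experiment
#'
#' Runs the noiseless model at several relative growth rates. A sizer yields
#' a larger division size and a shorter cycle at higher `g`; a timer's
#' division size diverges whenever its fixed cycle length differs from the
#' doubling time `ln 2 / g`.
#'
#' @param params A (typically calibrated) [model_params()] object.
#' @param g_values Growth rates to test (h^-1).
#' @param max_cycles Steady-state search budget per rate.
#' @return A data frame with one row per rate: `g`, `division_size`,
#'   `cycle_length`, `stability` (`"STABLE"` if a steady state was reached,
#'   else `"LOST"`).
#' @export
rgr_experiment <- function(params, g_values, max_cycles = 200L) {
  validate_model_params(params)
  rows <- lapply(g_values, function(gv) {
    p <- params
    p$g_mean <- gv
    p$g_sd <- 0
    p$d_sd <- 0
    ss <- steady_state_lineage(p, p$size_ref, max_cycles = max_cycles)
    data.frame(g = gv,
               division_size = if (ss$converged) ss$division_size else NA_real_,
               cycle_length = ss$cycle_length,
               stability = if (ss$converged) "STABLE" else "LOST",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' CDK-production mutant experiment
#'
#' Scales the production rate of the one-transition model (emulating mutants
#' with reduced or increased CDK synthesis) and, for comparison, the growth
#' rate, then measures population distributions. Changing pCDK moves mean
#' cell size (opposite in direction) but leaves cycle length unchanged;
#' changing `g` moves both.
#'
#' @param params Calibrated one-transition sizer parameters (noise fields
#'   `g_sd`/`d_sd` are used as given).
#' @param fold_changes Multipliers applied to pCDK (e.g. `c(0.5, 1, 2)`).
#' @param g_factors Optional multipliers applied to `g` for comparator runs.
#' @param duration,seed Population-run settings; run `i` uses `seed + i`.
#'   The first half of each run is treated as burn-in, so a perturbed
#'   population has re-equilibrated to its new steady size distribution
#'   before its statistics are recorded.
#' @return A data frame: `parameter` (`"pCDK"` or `"g"`), `factor`,
#'   `division_size_mean/sd`, `cycle_length_mean/sd`, `n_cycles`.
#' @export
pcdk_mutant_experiment <- function(params, fold_changes = c(0.5, 1, 2),
                                   g_factors = NULL, duration = 600,
                                   seed = 1L) {
  validate_model_params(params)
  if (params$two_transition)
    stop("pcdk_mutant_experiment uses the one-transition model")
  runs <- c(lapply(fold_changes, function(f) list(parameter = "pCDK", factor = f)),
            lapply(g_factors, function(f) list(parameter = "g", factor = f)))
  rows <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    p <- params
    if (r$parameter == "pCDK") p$pCDK <- p$pCDK * r$factor
    else p$g_mean <- p$g_mean * r$factor
    run <- run_population(population_config(p, duration = duration,
                                            burn_in = duration / 2,
                                            seed = seed + i))
    s <- run$summary
    rows[[i]] <- data.frame(
      parameter = r$parameter, factor = r$factor,
      division_size_mean = s$division_size_mean,
      division_size_sd = s$division_size_sd,
      cycle_length_mean = s$cycle_length_mean,
      cycle_length_sd = s$cycle_length_sd,
      n_cycles = s$n_cycles, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Size-exponent variant experiment
#'
#' Calibrates the size-proportional production model for each exponent
#' (production scaling with Size, Size^0.67 or Size^0.34), so all variants
#' share the same steady state, then measures how many cycles each needs to
#' recover from the same uneven division. Weaker size feedback (smaller
#' exponent) needs more cycles; all variants remain stable.
#'
#' @param alphas Exponents to test.
#' @param T_division,g Calibration inputs (see
#'   [calibrate_one_transition()]).
#' @param target A [calibration_target()].
#' @param perturbation Relative sizes of the two founders as multiples of
#'   the steady-state birth size (default 1.5 and 0.5).
#' @param n_cycles Cycles to follow after the perturbation.
#' @param dt Integration step (h) for this experiment, default 0.25.
#'   Convergence efficiency is a continuous-limit property; on the coarse
#'   1 h grid the weak-feedback variants come to rest inside a neutral band
#'   of the discrete trigger that is wider than the convergence criterion,
#'   masking the effect the experiment measures.
#' @return A data frame: `alpha`, `pCDK`, `convergence_cycles`,
#'   `stability`.
#' @export
exponent_variant_experiment <- function(alphas = c(1, 0.67, 0.34),
                                        T_division = 100, g = log(2) / 25,
                                        target = calibration_target(),
                                        perturbation = c(1.5, 0.5),
                                        n_cycles = 60L, dt = 0.25) {
  rows <- lapply(alphas, function(a) {
    tpl <- model_params(pCDK = 1, T_division = T_division, g_mean = g,
                        size_dependence = "PCDK_PROP_SIZE", size_exponent = a,
                        dt = dt)
    p <- calibrate_one_transition(T_division, g, target, template = tpl)
    b <- attr(p, "report")$birth_size
    ex <- uneven_division_experiment(p, perturbation[1] * b,
                                     perturbation[2] * b,
                                     n_cycles = n_cycles)
    data.frame(alpha = a, pCDK = p$pCDK,
               convergence_cycles = ex$convergence_cycles,
               stability = if (is.na(ex$convergence_cycles)) "LOST" else "STABLE",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fold-reduction scan of the two-transition model
#'
#' Reduces `pCDK_S` or `pCDK_M` by each fold in `folds` (thresholds held
#' fixed), runs a capped noisy population for each, and records phase
#' lengths, sizes and a stability classification. With size control at G1/S
#' only, moderate `pCDK_M` reductions lengthen S-G2-M but G1 shrinks to
#' compensate, leaving total cycle length unchanged - until G1 hits its
#' one-step floor and size control is lost. The G2/M-only configuration
#' mirrors this with a narrower stable range (S-G2-M is the shorter phase);
#' the dual-sizer configuration stays stable throughout, at increased size.
#'
#' @param params Calibrated two-transition parameters whose sizer flags
#'   match `sizer_config`; noise fields (`g_sd`, `d_sd`) are used as given.
#' @param which `"pCDK_M"` or `"pCDK_S"`: the rate to reduce.
#' @param sizer_config `"G1S_only"`, `"G2M_only"` or `"both"`; checked
#'   against the sizer flags of `params`.
#' @param folds Fold reductions (>= 1) to scan; include 1 for the reference.
#' @param duration,seed,cap Population-run settings; fold `i` uses
#'   `seed + i`. The first half of each run is treated as burn-in: a
#'   perturbed population passes through a transient while its size
#'   distribution moves to the new steady state, and cycles during that
#'   climb are systematically longer than at the steady state, so
#'   summarising them would confound the phase-length comparison.
#' @param cycle_tol Relative band around the fold-1 mean cycle length within
#'   which cycle length counts as unchanged (default 0.05).
#' @return A data frame of class `cdk_scan_result`: `fold`, `g1_mean/sd`,
#'   `sgm_mean/sd`, `cycle_mean/sd`, `division_size_mean/sd`, `stability`,
#'   `cycle_unchanged`.
#' @export
two_transition_fold_scan <- function(params,
                                     which = c("pCDK_M", "pCDK_S"),
                                     sizer_config = c("G1S_only", "G2M_only",
                                                      "both"),
                                     folds = c(1, 1.2, 1.4, 1.5, 1.7, 2, 2.5, 3),
                                     duration = 600, seed = 1L, cap = 100L,
                                     cycle_tol = 0.05) {
  which <- match.arg(which)
  sizer_config <- match.arg(sizer_config)
  validate_model_params(params)
  if (!params$two_transition)
    stop("two_transition_fold_scan needs calibrated two-transition params")
  want <- switch(sizer_config,
                 G1S_only = c(TRUE, FALSE),
                 G2M_only = c(FALSE, TRUE),
                 both = c(TRUE, TRUE))
  if (!identical(c(params$sizer_at_g1s, params$sizer_at_g2m), want))
    stop("params sizer flags do not match sizer_config '", sizer_config,
         "'; calibrate the matching configuration first")
  if (any(folds < 1)) stop("folds are reductions and must be >= 1")
  rows <- vector("list", length(folds))
  for (i in seq_along(folds)) {
    f <- folds[i]
    p <- params
    p[[which]] <- params[[which]] / f
    run <- run_population(population_config(p, cap = cap, n_init = cap,
                                            duration = duration,
                                            burn_in = duration / 2,
                                            seed = seed + i))
    s <- run$summary
    stab <- classify_stability(run$timeseries,
                               cycle_length = log(2) / p$g_mean)
    rows[[i]] <- data.frame(
      fold = f,
      g1_mean = if (is.null(s)) NA_real_ else s$g1_length_mean,
      g1_sd = if (is.null(s)) NA_real_ else s$g1_length_sd,
      sgm_mean = if (is.null(s)) NA_real_ else s$sgm_length_mean,
      sgm_sd = if (is.null(s)) NA_real_ else s$sgm_length_sd,
      cycle_mean = if (is.null(s)) NA_real_ else s$cycle_length_mean,
      cycle_sd = if (is.null(s)) NA_real_ else s$cycle_length_sd,
      division_size_mean = if (is.null(s)) NA_real_ else s$division_size_mean,
      division_size_sd = if (is.null(s)) NA_real_ else s$division_size_sd,
      n_cycles = if (is.null(s)) 0L else s$n_cycles,
      stability = stab, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  ref <- out$cycle_mean[out$fold == 1][1L]
  out$cycle_unchanged <- is.finite(out$cycle_mean) & is.finite(ref) &
    abs(out$cycle_mean - ref) <= cycle_tol * ref
  class(out) <- c("cdk_scan_result", "data.frame")
  out
}

#' Stability boundary of a fold scan
#'
#' Convenience summary of a [two_transition_fold_scan()]: the largest
#' scanned fold that is size-stable with unchanged cycle length, and the
#' smallest scanned fold classified as loss of size control. Boundaries are
#' reported at the scanned grid, not interpolated.
#'
#' @param scan A `cdk_scan_result`.
#' @return A list: `max_stable_unchanged`, `max_stable`, `min_lost` (each
#'   `NA` if the scan contains no such fold).
#' @export
scan_boundary <- function(scan) {
  stopifnot(inherits(scan, "cdk_scan_result"))
  ok <- scan$stability == "STABLE" & scan$cycle_unchanged
  stable <- scan$stability == "STABLE"
  lost <- scan$stability == "LOST"
  list(max_stable_unchanged = if (any(ok)) max(scan$fold[ok]) else NA_real_,
       max_stable = if (any(stable)) max(scan$fold[stable]) else NA_real_,
       min_lost = if (any(lost)) min(scan$fold[lost]) else NA_real_)
}
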