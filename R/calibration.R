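#' Calibration targets for the wild-type cycle
#'
#' The wild-type parameterisation grows cells from 20 to 40 um^2 per cycle;
#' in the two-transition model G1 additionally occupies 60% of the cycle.
#'
#' @param birth_size_target Steady-state birth size (um^2, default 20).
#' @param division_size_target Steady-state division size (um^2, default 40;
#'   must equal twice the birth target under symmetric division).
#' @param g1_fraction_target G1 length as a fraction of cycle length
#'   (default 0.60; two-transition calibration only).
#' @param tolerance Relative tolerance used both for steady-state detection
#'   and for the calibration stopping rule (default 1e-3, > 0).
#' @return An object of class `cdk_calibration_target`.
#' @export
calibration_target <- function(birth_size_target = 20,
                               division_size_target = 40,
                               g1_fraction_target = 0.60,
                               tolerance = 1e-3) {
  if (!is.finite(tolerance) || tolerance <= 0)
    stop("tolerance must be > 0 (a zero tolerance can never be met)")
  if (abs(division_size_target - 2 * birth_size_target) >
      1e-9 * birth_size_target)
    stop("division_size_target must be 2 * birth_size_target ",
         "(symmetric division doubles per cycle)")
  if (g1_fraction_target <= 0 || g1_fraction_target >= 1)
    stop("g1_fraction_target must lie in (0, 1)")
  t <- list(birth_size_target = birth_size_target,
            division_size_target = division_size_target,
            g1_fraction_target = g1_fraction_target,
            tolerance = tolerance)
  class(t) <- "cdk_calibration_target"
  t
}

#' Continuous-limit production rate for a target size increment
#'
#' In the size-proportional production model (`PCDK_PROP_SIZE`, exponent 1)
#' the continuous-time dynamics add a fixed area per cycle: integrating
#' dCDK/dt = pCDK * S/size_ref with S = S0 exp(g t) up to the threshold `T`
#' gives an added area of `g * T * size_ref / pCDK`, independent of birth
#' size (adder behaviour). Inverting for a target increment gives the rate
#' used to seed the discrete-time calibration search.
#'
#' @param T_threshold Division threshold (a.u.).
#' @param g Relative growth rate (h^-1).
#' @param delta_size Target area added per cycle (um^2).
#' @param size_ref Normalisation size (um^2).
#' @return Production rate pCDK in a.u. h^-1.
#' @examples
#' adder_closed_form_pcdk(100, log(2) / 24, 20, 20)  # 100 * ln2 / 24
#' @export
adder_closed_form_pcdk <- function(T_threshold, g, delta_size, size_ref) {
  stopifnot(T_threshold > 0, g > 0, delta_size > 0, size_ref > 0)
  g * T_threshold * size_ref / delta_size
}

## Bisection on a nonincreasing staircase response. f(x) is the measured
## quantity; we search for x whose response lies within +/- tol_abs of
## target. The response takes discrete values, so the stopping rule is
## "response close enough", backed by an interval-width floor.
.bisect_staircase <- function(f, lo, hi, target, tol_abs, max_iter = 200L,
                              label = "calibration") {
  f_lo <- f(lo)
  f_hi <- f(hi)
  if (abs(f_lo - target) <= tol_abs) return(lo)
  if (abs(f_hi - target) <= tol_abs) return(hi)
  if (!(f_lo > target && f_hi < target))
    stop(label, " failed: search interval [", signif(lo, 6), ", ",
         signif(hi, 6), "] does not bracket the target (responses ",
         signif(f_lo, 6), ", ", signif(f_hi, 6), " vs target ",
         signif(target, 6), ")")
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    if (abs(f_mid - target) <= tol_abs) return(mid)
    if (f_mid > target) lo <- mid else hi <- mid
    if ((hi - lo) < 1e-12 * hi)
      stop(label, " failed: interval collapsed without meeting the target; ",
           "closest response ", signif(f_mid, 6), " vs target ",
           signif(target, 6))
  }
  stop(label, " failed to converge in ", max_iter, " iterations")
}

#' Calibrate the one-transition sizer model
#'
#' Reproduces the wild-type parameterisation procedure: the threshold
#' `T_division` is fixed at an arbitrary value and the production rate
#' `pCDK` is solved so that the noiseless, symmetric-division steady state
#' grows cells from the target birth size to the target division size per
#' cycle. The search is a bisection on `pCDK` seeded by
#' [adder_closed_form_pcdk()]; each evaluation simulates a single lineage to
#' its steady state.
#'
#' @param T_division Division threshold (a.u., default 100 - the scale is
#'   arbitrary, only the pCDK/T ratio matters).
#' @param g Relative growth rate used for calibration (h^-1).
#' @param target A [calibration_target()].
#' @param template A [model_params()]-like template whose size-dependence
#'   mode/exponent, `size_ref`, `dt` and `mitosis_steps` are retained
#'   (default: size-proportional production, exponent 1). Must be a sizer
#'   configuration (`size_dependence != "NONE"`).
#' @return A calibrated `cdk_model_params` object with attribute `"report"`
#'   (a list with the solved rate, achieved steady-state sizes and search
#'   diagnostics).
#' @examples
#' p <- calibrate_one_transition()
#' attr(p, "report")$division_size
#' @export
calibrate_one_transition <- function(T_division = 100, g = log(2) / 25,
                                     target = calibration_target(),
                                     template = NULL) {
  if (is.null(template))
    template <- model_params(pCDK = 1, T_division = T_division, g_mean = g)
  if (template$size_dependence == "NONE")
    stop("calibration requires a sizer mode (size_dependence != 'NONE'); ",
         "a timer has no size feedback to calibrate")
  params <- template
  params$two_transition <- FALSE
  params$T_division <- T_division
  params$g_mean <- g
  params$g_sd <- 0
  params$d_sd <- 0
  delta <- target$division_size_target - target$birth_size_target
  seed <- adder_closed_form_pcdk(T_division, g, delta, params$size_ref)
  evals <- 0L
  div_of <- function(pcdk) {
    evals <<- evals + 1L
    params$pCDK <- pcdk
    steady_state_lineage(params, target$birth_size_target,
                         tol = target$tolerance)$division_size
  }
  tol_abs <- target$tolerance * target$division_size_target
  pcdk <- .bisect_staircase(div_of, seed / 8, seed * 8,
                            target$division_size_target, tol_abs,
                            label = "one-transition calibration")
  params$pCDK <- pcdk
  ss <- steady_state_lineage(params, target$birth_size_target,
                             tol = target$tolerance)
  attr(params, "report") <- list(
    model = "one_transition", T_division = T_division, g = g,
    pCDK = pcdk, pCDK_seed = seed,
    birth_size = ss$birth_size, division_size = ss$division_size,
    cycle_length = ss$cycle_length, evaluations = evals,
    target = unclass(target))
  params
}

#' Calibrate the two-transition model
#'
#' Solves `(pCDK_S, pCDK_M)` so that the noiseless, symmetric-division
#' steady state starts cycles at the target birth size, divides at the
#' target division size, and spends the target fraction of the cycle in G1.
#' Thresholds are held fixed; their ratio encodes the relative CDK activity
#' at the two checkpoints. The G1 dynamics from the target birth size do not
#' depend on `pCDK_M`, so the solve proceeds as two bisections: first
#' `pCDK_S` against the target G1 length, then `pCDK_M` against the
#' remaining S-G2-M length (so that the full cycle meets the doubling time
#' and the division-size target).
#'
#' Any sizer configuration can be calibrated: set `sizer_at_g1s` /
#' `sizer_at_g2m` in the template to select where size feeds back (at least
#' one must be on); the other transition behaves as a timer phase.
#'
#' @param T_g1s,T_g2m Checkpoint thresholds (a.u.; defaults 100 and 200,
#'   i.e. a 1:2 ratio - a configurable assumption, not a measured value).
#' @param g Relative growth rate used for calibration (h^-1).
#' @param target A [calibration_target()].
#' @param template Optional `cdk_model_params` template (size-dependence
#'   mode, sizer flags, `size_ref`, `dt`, `mitosis_steps` retained).
#' @return A calibrated `cdk_model_params` with attribute `"report"`.
#' @examples
#' p <- calibrate_two_transition()
#' rep <- attr(p, "report")
#' c(rep$g1_fraction, rep$division_size)
#' @export
calibrate_two_transition <- function(T_g1s = 100, T_g2m = 200,
                                     g = log(2) / 25,
                                     target = calibration_target(),
                                     template = NULL) {
  if (is.null(template))
    template <- model_params(two_transition = TRUE, pCDK_S = 1, pCDK_M = 1,
                             T_g1s = T_g1s, T_g2m = T_g2m, g_mean = g)
  if (!template$sizer_at_g1s && !template$sizer_at_g2m)
    stop("at least one sizer flag must be set to calibrate a size controller")
  if (template$size_dependence == "NONE")
    stop("calibration requires a sizer mode (size_dependence != 'NONE')")
  params <- template
  params$two_transition <- TRUE
  params$T_g1s <- T_g1s
  params$T_g2m <- T_g2m
  params$g_mean <- g
  params$g_sd <- 0
  params$d_sd <- 0
  b0 <- target$birth_size_target
  cycle_target <- log(2) / g          # doubling time; forced by symmetry
  g1_target <- target$g1_fraction_target * cycle_target
  dt <- params$dt

  ## Stage 1: pCDK_S from the G1 length measured on the first cycle started
  ## at the target birth size (independent of pCDK_M). The measured length
  ## is quantised to the step grid, so the match is to within half a step.
  params$pCDK_M <- .base_rate(params, "M")   # placeholder, not used in G1
  evals <- 0L
  g1_of <- function(ps) {
    evals <<- evals + 1L
    params$pCDK_S <- ps
    params$pCDK_M <- 1e6                    # immediate G2/M; G1 unaffected
    cy <- .sim_cycle(params, b0, g, 0)
    cy$g1s_time
  }
  seed_s <- adder_closed_form_pcdk(T_g1s, g,
                                   b0 * (exp(g * g1_target) - 1),
                                   params$size_ref)
  tol_t <- max(dt / 2, target$tolerance * cycle_target)
  pS <- .bisect_staircase(g1_of, seed_s / 8, seed_s * 8, g1_target, tol_t,
                          label = "two-transition calibration (pCDK_S)")
  params$pCDK_S <- pS
  g1_achieved <- g1_of(pS)
  params$pCDK_S <- pS

  ## Stage 2: pCDK_M so that S-G2-M fills the rest of the doubling time,
  ## which lands division exactly on the division-size target.
  sgm_target <- cycle_target - g1_achieved
  if (sgm_target < 2 * dt)
    stop("infeasible targets: S-G2-M would need ", signif(sgm_target, 4),
         " h, below the ", 2 * dt, " h floor (one accumulation step plus ",
         "mitosis)")
  sgm_of <- function(pm) {
    evals <<- evals + 1L
    params$pCDK_M <- pm
    cy <- .sim_cycle(params, b0, g, 0)
    cy$division_time - cy$g1s_time
  }
  s_g1s <- b0 * exp(g * g1_achieved)
  seed_m <- adder_closed_form_pcdk(T_g2m, g,
                                   s_g1s * (exp(g * sgm_target) - 1),
                                   params$size_ref)
  pM <- .bisect_staircase(sgm_of, seed_m / 8, seed_m * 8, sgm_target, tol_t,
                          label = "two-transition calibration (pCDK_M)")
  params$pCDK_M <- pM
  ss <- steady_state_lineage(params, b0, tol = target$tolerance)
  g1_frac <- ss$g1_length / ss$cycle_length
  attr(params, "report") <- list(
    model = "two_transition", T_g1s = T_g1s, T_g2m = T_g2m, g = g,
    pCDK_S = pS, pCDK_M = pM,
    sizer_at_g1s = params$sizer_at_g1s, sizer_at_g2m = params$sizer_at_g2m,
    birth_size = ss$birth_size, division_size = ss$division_size,
    cycle_length = ss$cycle_length, g1_length = ss$g1_length,
    sgm_length = ss$sgm_length, g1_fraction = g1_frac,
    evaluations = evals, target = unclass(target))
  params
}

#' Classify a size time series as stable or as loss of size control
#'
#' Operationalises "loss of cell size control": the run is `STABLE` iff the
#' log-linear trend of mean size over the final half of the series drifts by
#' less than `drift_per_cycle` (default 5%) per mean cycle length, and mean
#' size never exceeds `bound_factor` (default 10) times its initial value.
#' Anything else - systematic growth or shrinkage of the population mean, or
#' unbounded sizes - is `LOST`.
#'
#' @param timeseries Data frame with columns `time` (h) and `mean_size`
#'   (um^2), e.g. `cdk_population_run$timeseries`; must span at least ten
#'   mean cycle lengths.
#' @param cycle_length Mean cycle length (h) used to scale the drift
#'   criterion (default 25, the wild-type doubling time).
#' @param drift_per_cycle Maximum tolerated relative change of mean size per
#'   cycle over the final half (default 0.05).
#' @param bound_factor Maximum tolerated ratio of mean size to its initial
#'   value (default 10).
#' @return `"STABLE"` or `"LOST"`.
#' @export
classify_stability <- function(timeseries, cycle_length = 25,
                               drift_per_cycle = 0.05, bound_factor = 10) {
  if (!is.data.frame(timeseries) ||
      !all(c("time", "mean_size") %in% names(timeseries)))
    stop("timeseries must have columns time and mean_size")
  span <- max(timeseries$time) - min(timeseries$time)
  if (span < 10 * cycle_length)
    stop("timeseries too short: need >= 10 mean cycle lengths, got ",
         signif(span / cycle_length, 3))
  init <- mean(timeseries$mean_size[seq_len(min(5L, nrow(timeseries)))])
  if (!all(is.finite(timeseries$mean_size)) ||
      max(timeseries$mean_size) > bound_factor * init)
    return("LOST")
  half <- timeseries[timeseries$time >=
                       (min(timeseries$time) + max(timeseries$time)) / 2, ]
  fit <- stats::lm(log(mean_size) ~ time, data = half)
  slope <- unname(stats::coef(fit)[2L])
  if (abs(slope) * cycle_length < log(1 + drift_per_cycle)) "STABLE" else "LOST"
}
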