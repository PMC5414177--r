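#' Model parameters for the CDK-accumulation cell-cycle models
#'
#' Bundles every constant of the single-cell update rules: the time step, the
#' growth-rate and division-ratio distributions, CDK production rates and
#' thresholds, and the way size feeds back on cycle progression.
#'
#' In the one-transition model a single CDK activity accumulates at rate
#' `pCDK` and triggers mitosis when it strictly exceeds `T_division`. In the
#' two-transition model (`two_transition = TRUE`) a first activity accumulates
#' at `pCDK_S` towards `T_g1s` (the G1/S checkpoint); crossing it starts a
#' second accumulator at `pCDK_M` towards `T_g2m` (the G2/M checkpoint), whose
#' crossing triggers mitosis.
#'
#' Size dependence is selected with `size_dependence`:
#' \describe{
#'   \item{`NONE`}{timer: rates and thresholds ignore cell size.}
#'   \item{`PCDK_PROP_SIZE`}{activator accumulation sizer: production rate is
#'     scaled by `(size / size_ref)^size_exponent`.}
#'   \item{`THRESHOLD_INV_SIZE`}{inhibitor-dilution sizer: the threshold is
#'     scaled by `size_ref / size`.}
#'   \item{`PCDK_INV_SIZE`, `THRESHOLD_PROP_SIZE`}{the reversed variants,
#'     which invert the size / cycle-length relationship.}
#' }
#' In the two-transition model the mode is applied at the G1/S accumulator
#' only if `sizer_at_g1s` is `TRUE` and at the G2/M accumulator only if
#' `sizer_at_g2m` is `TRUE`; a transition without its sizer flag behaves as a
#' timer phase.
#'
#' @param dt Time step in hours (default 1).
#' @param g_mean,g_sd Mean and s.d. of the per-cell relative growth rate
#'   (h^-1), drawn once at birth and truncated to positive values. The default
#'   mean corresponds to a 25 h doubling time.
#' @param d_mean,d_sd Mean and s.d. of the division ratio `d` (percent of the
#'   parent area given to the first daughter), drawn at birth and truncated to
#'   \[5, 95\].
#' @param pCDK,T_division Production rate (a.u. h^-1) and division threshold
#'   (a.u.) of the one-transition model.
#' @param size_dependence One of `"NONE"`, `"PCDK_PROP_SIZE"`,
#'   `"THRESHOLD_INV_SIZE"`, `"PCDK_INV_SIZE"`, `"THRESHOLD_PROP_SIZE"`.
#' @param size_exponent Exponent `alpha` applied in `PCDK_PROP_SIZE` mode
#'   (1, 0.67 or 0.34 in the scanned variants; any positive value accepted).
#' @param size_ref Normalisation size in um^2 for all size-dependent terms
#'   (default 20, the wild-type birth size), so production rates keep rate
#'   units for every exponent.
#' @param two_transition Logical; use the two-checkpoint model.
#' @param pCDK_S,pCDK_M,T_g1s,T_g2m Rates and thresholds of the G1/S and G2/M
#'   accumulators (two-transition model only).
#' @param sizer_at_g1s,sizer_at_g2m Apply the size-dependence mode at the
#'   respective transition.
#' @param mitosis_steps Number of time steps mitosis occupies (default 1).
#'   Growth continues during mitosis; CDK does not accumulate.
#' @param rgr_size_slope Optional size-dependent growth term: the effective
#'   growth rate of a cell is `g + rgr_size_slope * (size - size_ref)`
#'   (h^-1 um^-2, default 0).
#'
#' @return An object of class `cdk_model_params` (a validated list).
#' @examples
#' p <- model_params(pCDK = 3, T_division = 100)
#' p2 <- model_params(two_transition = TRUE, pCDK_S = 7, pCDK_M = 22,
#'                    T_g1s = 100, T_g2m = 200)
#' @export
model_params <- function(dt = 1,
                         g_mean = log(2) / 25, g_sd = 0,
                         d_mean = 50, d_sd = 0,
                         pCDK = NULL, T_division = NULL,
                         size_dependence = c("PCDK_PROP_SIZE", "NONE",
                                             "THRESHOLD_INV_SIZE",
                                             "PCDK_INV_SIZE",
                                             "THRESHOLD_PROP_SIZE"),
                         size_exponent = 1,
                         size_ref = 20,
                         two_transition = FALSE,
                         pCDK_S = NULL, pCDK_M = NULL,
                         T_g1s = NULL, T_g2m = NULL,
                         sizer_at_g1s = TRUE, sizer_at_g2m = TRUE,
                         mitosis_steps = 1L,
                         rgr_size_slope = 0) {
  size_dependence <- match.arg(size_dependence)
  p <- list(dt = dt, g_mean = g_mean, g_sd = g_sd,
            d_mean = d_mean, d_sd = d_sd,
            pCDK = pCDK, T_division = T_division,
            size_dependence = size_dependence,
            size_exponent = size_exponent, size_ref = size_ref,
            two_transition = isTRUE(two_transition),
            pCDK_S = pCDK_S, pCDK_M = pCDK_M,
            T_g1s = T_g1s, T_g2m = T_g2m,
            sizer_at_g1s = isTRUE(sizer_at_g1s),
            sizer_at_g2m = isTRUE(sizer_at_g2m),
            mitosis_steps = as.integer(mitosis_steps),
            rgr_size_slope = rgr_size_slope)
  class(p) <- "cdk_model_params"
  validate_model_params(p)
  p
}

#' @rdname model_params
#' @param params Object to validate.
#' @export
validate_model_params <- function(params) {
  stopifnot(inherits(params, "cdk_model_params"))
  p <- params
  if (!is.numeric(p$dt) || length(p$dt) != 1 || !is.finite(p$dt) || p$dt <= 0)
    stop("dt must be a positive number (hours)")
  if (p$g_sd < 0 || p$d_sd < 0) stop("g_sd and d_sd must be >= 0")
  if (p$d_mean <= 0 || p$d_mean >= 100) stop("d_mean must lie in (0, 100)")
  if (p$size_ref <= 0) stop("size_ref must be positive")
  if (p$size_exponent <= 0) stop("size_exponent must be positive")
  if (p$mitosis_steps < 1) stop("mitosis_steps must be >= 1")
  if (p$two_transition) {
    for (f in c("pCDK_S", "pCDK_M", "T_g1s", "T_g2m")) {
      v <- p[[f]]
      if (is.null(v) || !is.finite(v) || v <= 0)
        stop("two-transition model requires positive ", f)
    }
  } else {
    for (f in c("pCDK", "T_division")) {
      v <- p[[f]]
      if (is.null(v) || !is.finite(v) || v <= 0)
        stop("one-transition model requires positive ", f)
    }
  }
  invisible(params)
}

#' @export
print.cdk_model_params <- function(x, ...) {
  cat(if (x$two_transition) "Two-transition" else "One-transition",
      "CDK cell-cycle model parameters\n")
  cat(sprintf("  dt = %g h, g ~ N(%.5g, %.3g) h^-1, d ~ N(%g, %g) %%\n",
              x$dt, x$g_mean, x$g_sd, x$d_mean, x$d_sd))
  if (x$two_transition) {
    cat(sprintf("  pCDK_S = %.5g (T_G1/S = %g, sizer %s), pCDK_M = %.5g (T_G2/M = %g, sizer %s)\n",
                x$pCDK_S, x$T_g1s, ifelse(x$sizer_at_g1s, "on", "off"),
                x$pCDK_M, x$T_g2m, ifelse(x$sizer_at_g2m, "on", "off")))
  } else {
    cat(sprintf("  pCDK = %.5g, T_division = %g\n", x$pCDK, x$T_division))
  }
  cat(sprintf("  size dependence: %s (alpha = %g, size_ref = %g um^2)\n",
              x$size_dependence, x$size_exponent, x$size_ref))
  invisible(x)
}

#' Construct a single simulated cell
#'
#' A cell carries its current outer surface area (um^2), the level of the
#' currently accumulating CDK activity, its phase, age, the growth rate `g`
#' and division ratio `d` it was assigned at birth, and bookkeeping fields
#' shared with lineage tables. Phases are `"G1"` (interphase in the
#' one-transition model), `"S_G2_M"` and `"MITOSIS"`.
#'
#' @param size Current size (um^2, > 0).
#' @param g Relative growth rate (h^-1).
#' @param d Division ratio in percent, in (0, 100).
#' @param cdk Current CDK level (a.u., >= 0), reset to 0 at each phase entry.
#' @param phase `"G1"`, `"S_G2_M"` or `"MITOSIS"`.
#' @param age Hours since birth.
#' @param birth_size,birth_time Size and time at birth.
#' @param cell_id,parent_id Integer identifiers (`NA` parent for founders).
#' @param zone Optional developmental-zone label.
#' @return A one-row data frame of class `cdk_cell_state`.
#' @examples
#' cell_state(size = 20, g = log(2) / 25, d = 50)
#' @export
cell_state <- function(size, g, d = 50, cdk = 0, phase = "G1", age = 0,
                       birth_size = size, birth_time = 0,
                       cell_id = 1L, parent_id = NA_integer_,
                       zone = NA_character_) {
  if (!is.finite(size) || size <= 0) stop("size must be positive")
  if (!is.finite(cdk) || cdk < 0) stop("cdk must be non-negative")
  if (!phase %in% c("G1", "S_G2_M", "MITOSIS")) stop("unknown phase: ", phase)
  if (!is.finite(d) || d <= 0 || d >= 100) stop("d must lie in (0, 100)")
  cells <- data.frame(cell_id = as.integer(cell_id),
                      parent_id = as.integer(parent_id),
                      size = size, cdk = cdk, phase = phase,
                      mitosis_left = 0L, age = age, g = g, d = d,
                      birth_size = birth_size, birth_time = birth_time,
                      g1s_time = NA_real_, g1s_size = NA_real_,
                      zone = zone, stringsAsFactors = FALSE)
  class(cells) <- c("cdk_cell_state", "data.frame")
  cells
}
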