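#' Relative growth rate from two area measurements
#'
#' `RGR = (ln A1 - ln A0) / (t1 - t0)`, the exponential rate constant of a
#' cell's outer surface area.
#'
#' @param a0,a1 Areas (um^2, > 0) at times `t0` and `t1`. Vectorised.
#' @param t0,t1 Times in hours, `t1 > t0`.
#' @return RGR in h^-1.
#' @examples
#' compute_rgr(20, 40, 0, 24)  # ln2/24
#' @export
compute_rgr <- function(a0, a1, t0, t1) {
  if (any(!is.finite(a0)) || any(a0 <= 0) ||
      any(!is.finite(a1)) || any(a1 <= 0))
    stop("areas must be positive")
  if (any(t1 <= t0)) stop("need t1 > t0")
  (log(a1) - log(a0)) / (t1 - t0)
}

#' Time to grow between two sizes at a given RGR
#'
#' Inverts the RGR formula: the time needed to grow from `area_start` to
#' `area_end` at exponential rate `rgr` is
#' `(ln area_end - ln area_start) / rgr`. Applied to (mean birth size, mean
#' division size) it infers cycle length; to (birth, G1/S size) G1 length;
#' to (G1/S size, division size) S-G2-M length - each with the stem-mean
#' RGR.
#'
#' @param area_start,area_end Areas (um^2, > 0). Vectorised.
#' @param rgr Relative growth rate (h^-1, > 0).
#' @return Interval length in hours.
#' @examples
#' infer_interval_length(20, 40, log(2) / 24)  # 24 h
#' @export
infer_interval_length <- function(area_start, area_end, rgr) {
  if (any(!is.finite(area_start)) || any(area_start <= 0) ||
      any(!is.finite(area_end)) || any(area_end <= 0))
    stop("areas must be positive")
  if (any(!is.finite(rgr)) || any(rgr <= 0)) stop("rgr must be positive")
  (log(area_end) - log(area_start)) / rgr
}

#' Sister-pair statistics from a lineage table
#'
#' For every division where both daughters completed a full cycle, compares
#' the two sisters: the difference in birth size, in cycle length and in
#' added area (each signed as larger-at-birth minus smaller-at-birth), plus
#' the asymmetry, synchrony and convergence flags used to test size
#' correction.
#'
#' @param table A lineage table (columns `cell_id`, `parent_id`,
#'   `birth_time`, `division_time`, `birth_area`, `division_area`).
#' @param asym_threshold Pairs with a birth-area difference above this are
#'   flagged `asymmetric` (um^2; default 5).
#' @param sync_resolution Sisters are `synchronous` when their cycle lengths
#'   differ by less than this (h; default 8, one recording interval of a
#'   96-h course - use 3 for a 30-h course).
#' @return A data frame with one row per qualifying pair: `parent_id`,
#'   `delta_birth` (>= 0), `delta_cycle`, `delta_growth`, `asymmetric`,
#'   `synchronous`, `closer_at_division` (absolute division-area difference
#'   smaller than the birth-area difference). Empty if no pair qualifies.
#' @export
sister_pair_table <- function(table, asym_threshold = 5,
                              sync_resolution = 8) {
  stopifnot(is.data.frame(table))
  done <- table[!is.na(table$division_time) & !is.na(table$parent_id), ,
                drop = FALSE]
  counts <- table(done$parent_id)
  pids <- as.integer(names(counts)[counts == 2L])
  rows <- lapply(pids, function(pid) {
    sisters <- done[done$parent_id == pid, ]
    o <- order(sisters$birth_area, decreasing = TRUE)
    big <- sisters[o[1L], ]
    small <- sisters[o[2L], ]
    cyc_big <- big$division_time - big$birth_time
    cyc_small <- small$division_time - small$birth_time
    delta_birth <- big$birth_area - small$birth_area
    delta_cycle <- cyc_big - cyc_small
    data.frame(parent_id = pid,
               delta_birth = delta_birth,
               delta_cycle = delta_cycle,
               delta_growth = (big$division_area - big$birth_area) -
                 (small$division_area - small$birth_area),
               asymmetric = delta_birth > asym_threshold,
               synchronous = abs(delta_cycle) < sync_resolution,
               closer_at_division =
                 abs(big$division_area - small$division_area) < delta_birth)
  })
  if (!length(rows))
    return(data.frame(parent_id = integer(), delta_birth = numeric(),
                      delta_cycle = numeric(), delta_growth = numeric(),
                      asymmetric = logical(), synchronous = logical(),
                      closer_at_division = logical()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exact strictly-greater binomial tail
#'
#' `P(X > k)` for `X ~ Binomial(n, p)`, by direct summation of the exact
#' probability mass over `k+1, ..., n`. This strict (greater-than) tail is
#' the convention under which the published sister-pair convergence
#' statistic is reported; note it differs from the greater-or-equal tail of
#' common `binom.test` defaults by one term.
#'
#' @param k Observed count (0 <= k <= n).
#' @param n Number of trials.
#' @param p Success probability (0 < p < 1).
#' @return `P(X > k)`.
#' @examples
#' binomial_tail_greater(72, 105, 0.5)
#' @export
binomial_tail_greater <- function(k, n, p = 0.5) {
  if (length(k) != 1 || length(n) != 1 || k != round(k) || n != round(n))
    stop("k and n must be single integers")
  if (k < 0 || k > n || n < 1) stop("need 0 <= k <= n with n >= 1")
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  if (k == n) return(0)
  sum(stats::dbinom((k + 1):n, n, p))
}

#' Sister-pair convergence test
#'
#' Tests whether asymmetric sister pairs (birth-area difference above the
#' asymmetry threshold) tend to be closer in size at division than at birth,
#' against the null of no size correction (each pair closer or not with
#' probability one half). Reports the exact strictly-greater binomial tail
#' `P(X > k)` for the observed count `k` of converging pairs among the `n`
#' asymmetric pairs.
#'
#' @param pairs A [sister_pair_table()] data frame with at least one
#'   asymmetric pair.
#' @return A list: `k_closer`, `n_asymmetric`, `p_value`.
#' @examples
#' \dontrun{convergence_test(sister_pair_table(tab))}
#' @export
convergence_test <- function(pairs) {
  stopifnot(is.data.frame(pairs),
            all(c("asymmetric", "closer_at_division") %in% names(pairs)))
  asym <- pairs[pairs$asymmetric, , drop = FALSE]
  n <- nrow(asym)
  if (n < 1L) stop("no asymmetric pairs: convergence test undefined")
  k <- sum(asym$closer_at_division)
  list(k_closer = k, n_asymmetric = n,
       p_value = binomial_tail_greater(k, n, 0.5))
}

#' Cell-cycle phase from EdU and S-G2-M reporter markers
#'
#' Classifies a cell from a thymidine-analogue (EdU) incorporation flag and
#' an S-G2-M fluorescent reporter flag (switched on at G1/S, degraded at
#' mitosis): neither marker is G1, both is S, reporter-only is G2-M, and
#' EdU-only is inconsistent with the reporter dynamics (DNA synthesis with
#' no reporter) and flagged as such.
#'
#' @param edu,venus Logical flags (vectorised, equal length).
#' @return A character vector over `{"G1", "S", "G2_M", "INCONSISTENT"}`.
#' @examples
#' classify_phase_from_markers(c(FALSE, TRUE, FALSE, TRUE),
#'                             c(FALSE, TRUE, TRUE, FALSE))
#' @export
classify_phase_from_markers <- function(edu, venus) {
  if (length(edu) != length(venus)) stop("edu and venus must match in length")
  if (any(is.na(edu)) || any(is.na(venus)))
    stop("marker flags must be defined (no NA)")
  ifelse(!edu & !venus, "G1",
         ifelse(edu & venus, "S",
                ifelse(!edu & venus, "G2_M", "INCONSISTENT")))
}

#' Per-zone summary of a lineage table
#'
#' Groups cells by developmental zone (central zone, peripheral zone,
#' incipient primordia, primordia, ...) and reports mean and s.d. of birth
#' size, division size, cycle length, RGR and - where the G1/S transition is
#' recorded - phase lengths. Zone labels are taken as given; unknown labels
#' simply form their own group. By the recording convention the zone column
#' reflects the zone at birth.
#'
#' @param table A lineage table with a `zone` column.
#' @param zone_col Name of the grouping column (default `"zone"`).
#' @return A data frame with one row per zone: `zone`, `n`,
#'   `birth_size_mean/sd`, `division_size_mean`, `cycle_length_mean/sd`,
#'   `rgr_mean/sd`, `g1_length_mean`, `sgm_length_mean`.
#' @export
zone_summary <- function(table, zone_col = "zone") {
  stopifnot(is.data.frame(table))
  if (!zone_col %in% names(table))
    stop("no '", zone_col, "' column in table")
  zones <- split(table, table[[zone_col]])
  rows <- lapply(names(zones), function(z) {
    d <- zones[[z]]
    cyc <- d$division_time - d$birth_time
    rgr <- compute_rgr(d$birth_area, d$division_area, d$birth_time,
                       d$division_time)
    g1 <- d$g1s_time - d$birth_time
    sgm <- d$division_time - d$g1s_time
    data.frame(zone = z, n = nrow(d),
               birth_size_mean = mean(d$birth_area),
               birth_size_sd = stats::sd(d$birth_area),
               division_size_mean = mean(d$division_area),
               cycle_length_mean = mean(cyc),
               cycle_length_sd = stats::sd(cyc),
               rgr_mean = mean(rgr), rgr_sd = stats::sd(rgr),
               g1_length_mean = if (all(is.na(g1))) NA_real_ else
                 mean(g1, na.rm = TRUE),
               sgm_length_mean = if (all(is.na(sgm))) NA_real_ else
                 mean(sgm, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
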