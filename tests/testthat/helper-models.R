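## Shared fixtures: wild-type calibrations and the observed-variation noise
## level (g sd at 20% of the mean, division-ratio sd 5 percentage points).

wt_growth_rate <- log(2) / 25

with_observed_noise <- function(params) {
  params$g_sd <- 0.2 * params$g_mean
  params$d_sd <- 5
  params
}

wt_one_transition <- function(...) calibrate_one_transition(...)

wt_two_transition <- function(sizer_at_g1s = TRUE, sizer_at_g2m = TRUE) {
  tpl <- model_params(two_transition = TRUE, pCDK_S = 1, pCDK_M = 1,
                      T_g1s = 100, T_g2m = 200, g_mean = wt_growth_rate,
                      sizer_at_g1s = sizer_at_g1s,
                      sizer_at_g2m = sizer_at_g2m)
  calibrate_two_transition(template = tpl)
}

timer_params <- function(pCDK = 4, g_mean = wt_growth_rate) {
  model_params(pCDK = pCDK, T_division = 100, size_dependence = "NONE",
               g_mean = g_mean)
}

## Independent oracle: exact binomial tail by exhaustive enumeration of all
## 2^n Bernoulli outcome vectors (feasible for n <= 12). Deliberately brute
## force and independent of dbinom.
enumerate_tail_greater <- function(k, n, p) {
  outcomes <- expand.grid(rep(list(c(0L, 1L)), n))
  counts <- rowSums(outcomes)
  probs <- apply(outcomes, 1L, function(x) prod(ifelse(x == 1L, p, 1 - p)))
  sum(probs[counts > k])
}
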