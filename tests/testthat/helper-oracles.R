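# Independent oracles used to freeze expected values.

# Two-point straight line evaluated at x, written without reference to
# build_trend's internals.
line_eval <- function(x0, y0, x1, y1, x) {
  y0 + (y1 - y0) * (x - x0) / (x1 - x0)
}

# Brute-force attributable fraction from a synthetic 2x2 cohort: exposure
# prevalence p, baseline risk i0, risk ratio rr.  Fraction of cases in
# excess of the all-unexposed counterfactual.
par_cohort_oracle <- function(p, rr, i0 = 0.01, n = 1e6) {
  cases <- n * (1 - p) * i0 + n * p * i0 * rr
  counterfactual <- n * i0
  (cases - counterfactual) / cases
}

# A default-parameter synthetic bundle, shared across tests.
default_bundle <- function(seed = 1L, ...) {
  generate_bundle(generator_params(random_seed = seed, ...))
}

# Per-stratum, per-cycle person balance from a run result: living at the
# cycle start minus deaths must equal the pre-rescale living total.
conservation_error <- function(result) {
  st <- result$states
  fl <- result$flows
  key <- paste(st$year, st$sex, st$age_band)
  living_start <- (st$healthy + st$obese + st$smokers + st$diabetes)[
    match(paste(fl$year, fl$sex, fl$age_band), key)]
  expected_end <- living_start - fl$deaths_other - fl$deaths_diabetes
  abs(expected_end - fl$living_end) / pmax(living_start, 1)
}
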