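## Uncertainty and scenario procedures: analysis of extremes (all
## epidemiological parameters shifted +/- a common factor) and the
## capped-obesity scenario comparison.

## Internal: scale every epidemiological input (baseline prevalence,
## survey/trend prevalences, incidence, case fatality, total mortality,
## relative risks) by `mult`; population structure is never scaled.
## Scaled proportions are clamped to [0, 1]; scaled RRs floored at 1.
scale_inputs <- function(inputs, mult) {
  out <- inputs
  out$baseline$prevalence <- clamp(inputs$baseline$prevalence * mult)
  if (!is.null(inputs$surveys))
    out$surveys$prevalence <- clamp(inputs$surveys$prevalence * mult)
  if (!is.null(inputs$trends))
    out$trends$value <- clamp(inputs$trends$value * mult)
  rt <- inputs$hazards$rates
  rt$incidence <- rt$incidence * mult
  rt$case_fatality <- rt$case_fatality * mult
  rt$total_mortality <- rt$total_mortality * mult
  rr <- inputs$hazards$rr
  rr$rr_obese <- pmax(1, rr$rr_obese * mult)
  rr$rr_smoker <- pmax(1, rr$rr_smoker * mult)
  out$hazards <- hazard_table(rt, rr)
  out
}

#' Analysis-of-extremes uncertainty band
#'
#' Runs the projection three times: at the base parameter values, with every
#' epidemiological parameter (baseline prevalence, risk-factor prevalences,
#' incidence, case fatality, total mortality, relative risks -- but never
#' the population structure) scaled down by `1 - factor`, and scaled up by
#' `1 + factor`.  Scaled proportions are clamped to \[0, 1\] and scaled
#' relative risks floored at 1.  The per-year band is the aggregated
#' prevalence of the three runs.
#'
#' @param config a [model_config()]; `config$extremes_factor` is used when
#'   `factor` is not given.
#' @param inputs input bundle as for [run_model()].
#' @param factor proportional shift, in (0, 1); default 0.20.
#' @return An `"uncertainty_band"` data.frame with columns `year`, `low`,
#'   `base`, `high` (prevalence proportions), plus the three full runs in
#'   attribute `"runs"`.
#' @export
analysis_of_extremes <- function(config, inputs,
                                 factor = config$extremes_factor) {
  assert_that(factor > 0 && factor < 1, "extremes factor must lie in (0, 1)")
  runs <- list(low = run_model(config, scale_inputs(inputs, 1 - factor)),
               base = run_model(config, inputs),
               high = run_model(config, scale_inputs(inputs, 1 + factor)))
  band <- data.frame(year = runs$base$prevalence$year,
                     low = runs$low$prevalence$total,
                     base = runs$base$prevalence$total,
                     high = runs$high$prevalence$total)
  structure(band, class = c("uncertainty_band", "data.frame"), runs = runs)
}

#' Capped versus uncapped obesity scenarios
#'
#' Scenario 1 extrapolates the obesity trends linearly without limit;
#' scenario 2 caps each sex's obesity trend at `config$cap_male` /
#' `config$cap_female` (smoking is never capped).  Both runs share every
#' other input.
#'
#' @param config a [model_config()].
#' @param inputs input bundle as for [run_model()].
#' @return List with the two `"dfm_result"` runs (`uncapped`, `capped`) and
#'   `difference`, a data.frame of per-year total prevalence under each
#'   scenario and their difference (uncapped minus capped).
#' @export
run_scenarios <- function(config, inputs) {
  cfg1 <- config; cfg1$scenario <- "uncapped"
  cfg2 <- config; cfg2$scenario <- "capped"
  r1 <- run_model(cfg1, inputs)
  r2 <- run_model(cfg2, inputs)
  diff <- data.frame(year = r1$prevalence$year,
                     scenario1 = r1$prevalence$total,
                     scenario2 = r2$prevalence$total,
                     difference = r1$prevalence$total - r2$prevalence$total)
  list(uncapped = r1, capped = r2, difference = diff)
}
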