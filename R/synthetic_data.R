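## Synthetic input bundles.
##
## The generator emulates the structure of the study data: linear
## risk-factor trends observed at sparse survey years (three obesity
## surveys, two smoking surveys), a growing age/sex-stratified adult
## population, an age-increasing baseline diabetes surface, and the default
## transition-hazard table.  It is the test bed for every other module; it
## does not reconstruct any real survey microdata.

#' Default transition-hazard table
#'
#' The published age- and sex-specific transition hazards: diabetes
#' incidence and total mortality (per 1000 population per year, stored as
#' per-person proportions), diabetes case fatality (percent per year,
#' stored as a proportion), and the per-sex relative risks of diabetes for
#' the obese (6.74 men, 12.41 women) and for smokers (1.44 both sexes).
#'
#' @return A [hazard_table()].
#' @export
#' @examples
#' default_hazard_table()$rates
default_hazard_table <- function() {
  s <- all_strata()
  rates <- data.frame(
    s,
    incidence = c(12.90, 17.70, 18.90, 20.70, 22.40, 26.70,
                  12.90, 15.00, 15.90, 16.70, 19.70, 30.70) / 1000,
    case_fatality = c(0.15, 0.39, 0.67, 1.20, 1.35, 2.10,
                      0.16, 0.43, 0.62, 0.96, 1.90, 4.62) / 100,
    total_mortality = c(0.10, 0.50, 1.10, 2.50, 3.30, 6.10,
                        0.10, 0.50, 1.00, 1.80, 4.10, 11.60) / 1000)
  rr <- data.frame(sex = sexes(), rr_obese = c(6.74, 12.41),
                   rr_smoker = c(1.44, 1.44))
  hazard_table(rates, rr)
}

#' Parameters of the synthetic-bundle generator
#'
#' Defaults place the synthetic data in the study's regime: model years
#' 1992-2022; obesity surveyed in 1992, 1997 and 2005 and smoking in 1992
#' and 2005; male obesity peaking at 34.5% in the 35-44 band and female
#' obesity at 58.8% in the 45-54 band at the 2005 survey; a baseline
#' diabetes surface rescaled so the population-weighted 1992 aggregate is
#' 8.5%; and 6.5 million adults aged 25+ at start, growing 3% per year.
#'
#' @param start_year,end_year model period.
#' @param obesity_survey_years,smoking_survey_years calendar years of the
#'   emulated surveys (must lie within the model period).
#' @param obesity_start,obesity_slope named per-sex peak-band obesity
#'   prevalence at `start_year` and its annual increase.
#' @param smoking_start,smoking_slope same for current smoking.
#' @param obesity_gradient,smoking_gradient named per-sex vectors of six
#'   age-band multipliers applied to the peak-band line.
#' @param baseline_shape vector of six age-band relative levels of the
#'   start-year diabetes prevalence surface (shared by both sexes).
#' @param baseline_total population-weighted aggregate diabetes prevalence
#'   the surface is rescaled to at `start_year` (default 0.085).
#' @param pop_start total adults aged 25+ at `start_year`.
#' @param pop_growth annual population growth rate (> -1).
#' @param pop_band_weights vector of six age-band population weights.
#' @param male_share share of males in each band.
#' @param noise_sd standard deviation of the survey-point jitter, on the
#'   prevalence scale (truncated to \[0, 1\]); 0 puts points exactly on the
#'   configured lines.
#' @param random_seed integer seed; bundles are deterministic given it.
#' @return A list of parameters with class `"generator_params"`.
#' @export
generator_params <- function(start_year = 1992L, end_year = 2022L,
                             obesity_survey_years = c(1992L, 1997L, 2005L),
                             smoking_survey_years = c(1992L, 2005L),
                             obesity_start = c(male = 0.200, female = 0.300),
                             obesity_slope = c(male = (0.345 - 0.200) / 13,
                                               female = (0.588 - 0.300) / 13),
                             smoking_start = c(male = 0.250, female = 0.050),
                             smoking_slope = c(male = 0.0015, female = 0.0008),
                             obesity_gradient = list(
                               male = c(0.80, 1.00, 0.95, 0.88, 0.75, 0.55),
                               female = c(0.60, 0.90, 1.00, 0.95, 0.85, 0.65)),
                             smoking_gradient = list(
                               male = c(1.00, 1.10, 1.00, 0.90, 0.70, 0.50),
                               female = c(1.00, 1.00, 1.00, 1.00, 0.80, 0.60)),
                             baseline_shape = c(0.025, 0.065, 0.13, 0.19,
                                                0.23, 0.25),
                             baseline_total = 0.085,
                             pop_start = 6.5e6, pop_growth = 0.03,
                             pop_band_weights = c(0.34, 0.26, 0.18, 0.12,
                                                  0.07, 0.03),
                             male_share = 0.52,
                             noise_sd = 0, random_seed = 1L) {
  assert_that(pop_growth > -1, "population growth rate must exceed -1")
  assert_that(all(c(obesity_survey_years, smoking_survey_years) >= start_year &
                  c(obesity_survey_years, smoking_survey_years) <= end_year),
              "survey years must lie within the model period")
  structure(as.list(environment()), class = "generator_params")
}

#' Generate a complete synthetic input bundle
#'
#' Builds an internally consistent input set -- population trajectory,
#' survey points, baseline diabetes prevalence, hazard table and model
#' configuration -- that passes [validate_inputs()] with zero violations and
#' runs end-to-end through [run_model()], [analysis_of_extremes()] and
#' [run_scenarios()].  Deterministic given `params$random_seed`.
#'
#' @param params a [generator_params()].
#' @return A list with elements `hazards`, `baseline`, `population`,
#'   `surveys` and `config`, class `"input_bundle"`.
#' @export
#' @examples
#' b <- generate_bundle(generator_params(noise_sd = 0))
#' nrow(validate_inputs(b$hazards, b$baseline, b$population, b$surveys,
#'                      b$config))  # 0
generate_bundle <- function(params = generator_params()) {
  p <- params
  s <- all_strata()
  years <- p$start_year:p$end_year
  set.seed(p$random_seed)

  ## survey points on the configured lines, plus truncated-normal jitter
  line_value <- function(factor_name, sex, band_i, year) {
    start <- if (factor_name == "obesity") p$obesity_start else p$smoking_start
    slope <- if (factor_name == "obesity") p$obesity_slope else p$smoking_slope
    grad <- if (factor_name == "obesity") p$obesity_gradient else p$smoking_gradient
    (start[[sex]] + slope[[sex]] * (year - p$start_year)) * grad[[sex]][band_i]
  }
  rows <- list()
  for (f in c("obesity", "smoking")) {
    yrs <- if (f == "obesity") p$obesity_survey_years else p$smoking_survey_years
    for (i in seq_len(nrow(s))) {
      bi <- match(s$age_band[i], age_bands())
      for (y in yrs) {
        v <- line_value(f, s$sex[i], bi, y)
        if (v < 0 || v > 1)
          stop(sprintf("generator line gives prevalence %.3f outside [0, 1] for %s %s %s in %d",
                       v, f, s$sex[i], s$age_band[i], y), call. = FALSE)
        if (p$noise_sd > 0) v <- clamp(v + stats::rnorm(1, 0, p$noise_sd))
        rows[[length(rows) + 1L]] <- data.frame(
          sex = s$sex[i], age_band = s$age_band[i], factor = f,
          year = as.integer(y), prevalence = v)
      }
    }
  }
  surveys <- survey_points(do.call(rbind, rows))

  ## population trajectory: fixed band/sex structure, geometric growth
  band_w <- p$pop_band_weights / sum(p$pop_band_weights)
  sex_w <- ifelse(s$sex == "male", p$male_share, 1 - p$male_share)
  stratum_w <- sex_w * band_w[match(s$age_band, age_bands())]
  pop <- do.call(rbind, lapply(seq_along(years), function(t) {
    data.frame(year = years[t], s,
               population = p$pop_start * (1 + p$pop_growth)^(t - 1) * stratum_w)
  }))
  population <- population_trajectory(pop)

  ## baseline diabetes surface, rescaled to the target aggregate
  shape <- p$baseline_shape[match(s$age_band, age_bands())]
  w0 <- pop$population[pop$year == p$start_year]
  agg <- sum(shape * w0) / sum(w0)
  prev <- clamp(shape * (p$baseline_total / agg))
  baseline <- baseline_prevalence(data.frame(s, prevalence = prev))

  structure(list(hazards = default_hazard_table(), baseline = baseline,
                 population = population, surveys = surveys,
                 config = model_config(start_year = p$start_year,
                                       end_year = p$end_year,
                                       random_seed = p$random_seed)),
            class = "input_bundle")
}

#' Deterministic closed-cohort trajectory
#'
#' Iterates [step_stratum()] on a single closed cohort (no population
#' renewal, no re-anchoring of exposure pools) with fixed hazards and fixed
#' incidence among the healthy.  This is the deterministic counterpart the
#' microsimulation oracle is compared against.
#'
#' @param state named list with `healthy`, `obese`, `smokers`, `diabetes`.
#' @param hazards named list with `case_fatality`, `total_mortality`.
#' @param rr_obese,rr_smoker relative risks, >= 1.
#' @param I_h incidence among the healthy, per person-year.
#' @param years number of annual cycles to run.
#' @param mode rate-to-probability conversion.
#' @return data.frame with one row per year (0..years) and columns
#'   `healthy`, `obese`, `smokers`, `diabetes`, `dead_other`,
#'   `dead_diabetes` (cumulative deaths).
#' @export
project_cohort <- function(state, hazards, rr_obese, rr_smoker, I_h, years,
                           mode = c("exponential", "direct")) {
  mode <- match.arg(mode)
  comp <- c("healthy", "obese", "smokers", "diabetes")
  out <- matrix(0, years + 1L, 6,
                dimnames = list(NULL, c(comp, "dead_other", "dead_diabetes")))
  cur <- state
  dead_o <- dead_d <- 0
  out[1, ] <- c(unlist(cur[comp]), dead_o, dead_d)
  for (t in seq_len(years)) {
    st <- step_stratum(cur, hazards, rr_obese, rr_smoker, I_h, mode)
    cur <- st$state
    dead_o <- dead_o + st$flows$deaths_other
    dead_d <- dead_d + st$flows$deaths_diabetes
    out[t + 1L, ] <- c(unlist(cur[comp]), dead_o, dead_d)
  }
  data.frame(year = 0:years, out)
}

#' Stochastic microsimulation oracle
#'
#' Simulates `n_individuals` through the same per-cycle transition
#' probabilities as [step_stratum()] (individual Bernoulli transitions,
#' drawn compartment-wise), providing an independent stochastic check of
#' the deterministic engine.  Because every individual's state at year `t`
#' is an independent draw, each compartment count is binomial around the
#' deterministic trajectory, giving exact Monte-Carlo standard errors.
#'
#' @param state initial compartments (`healthy`, `obese`, `smokers`,
#'   `diabetes`), used as proportions to allocate the `n_individuals`.
#' @param hazards named list with `case_fatality`, `total_mortality`.
#' @param rr_obese,rr_smoker relative risks.
#' @param I_h incidence among the healthy.
#' @param n_individuals cohort size (>= 1).
#' @param years number of annual cycles.
#' @param seed integer seed; same seed, same trajectory.
#' @param mode rate-to-probability conversion.
#' @return List with `counts` (simulated compartment counts per year),
#'   `expected` (the deterministic trajectory scaled to `n_individuals`)
#'   and `se` (binomial standard errors of each count).
#' @export
microsim_oracle <- function(state, hazards, rr_obese, rr_smoker, I_h,
                            n_individuals, years, seed = 1L,
                            mode = c("exponential", "direct")) {
  mode <- match.arg(mode)
  assert_that(n_individuals >= 1, "need at least one individual")
  comp <- c("healthy", "obese", "smokers", "diabetes")
  tot <- sum(unlist(state[comp]))
  assert_that(tot > 0, "initial state is empty")

  ## largest-remainder allocation of individuals to compartments
  target <- unlist(state[comp]) / tot * n_individuals
  n <- floor(target)
  rem <- n_individuals - sum(n)
  if (rem > 0) {
    ord <- order(target - floor(target), decreasing = TRUE)
    n[ord[seq_len(rem)]] <- n[ord[seq_len(rem)]] + 1L
  }

  ## deterministic expectation on the same allocation
  det <- project_cohort(as.list(n), hazards, rr_obese, rr_smoker, I_h,
                        years, mode)

  f <- hazards[["case_fatality"]]
  m <- hazards[["total_mortality"]]
  p_h <- transition_probs(c(I_h, m), mode)            # -> diabetes, dead_other
  p_o <- transition_probs(c(I_h * rr_obese, m), mode)
  p_s <- transition_probs(c(I_h * rr_smoker, m), mode)
  p_d <- transition_probs(c(f, m), mode)              # -> dead_diab, dead_other

  set.seed(seed)
  cur <- c(n, dead_other = 0, dead_diabetes = 0)
  counts <- matrix(0L, years + 1L, 6,
                   dimnames = list(NULL, names(cur)))
  counts[1, ] <- cur
  draw <- function(n, p) {
    # exits to the two destinations, remainder stays
    if (n == 0) return(c(0L, 0L))
    as.integer(stats::rmultinom(1, n, c(p, 1 - sum(p)))[1:2])
  }
  for (t in seq_len(years)) {
    eh <- draw(cur[["healthy"]], p_h)
    eo <- draw(cur[["obese"]], p_o)
    es <- draw(cur[["smokers"]], p_s)
    ed <- draw(cur[["diabetes"]], p_d)
    cur[["healthy"]] <- cur[["healthy"]] - sum(eh)
    cur[["obese"]] <- cur[["obese"]] - sum(eo)
    cur[["smokers"]] <- cur[["smokers"]] - sum(es)
    cur[["diabetes"]] <- cur[["diabetes"]] - sum(ed) + eh[1] + eo[1] + es[1]
    cur[["dead_diabetes"]] <- cur[["dead_diabetes"]] + ed[1]
    cur[["dead_other"]] <- cur[["dead_other"]] + eh[2] + eo[2] + es[2] + ed[2]
    counts[t + 1L, ] <- cur
  }

  expected <- as.matrix(det[, names(cur)])
  prop <- expected / n_individuals
  se <- sqrt(n_individuals * prop * (1 - prop))
  list(counts = data.frame(year = 0:years, counts),
       expected = data.frame(year = 0:years, expected),
       se = data.frame(year = 0:years, se))
}
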