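## Input data model: constructors with invariant checks, annual trend
## construction from sparse survey points, and the capping transform.

#' Survey points of risk-factor prevalence
#'
#' A table of sparse survey measurements of obesity or current-smoking
#' prevalence, by stratum and calendar year.  These are the raw inputs from
#' which annual trend series are built by linear interpolation and
#' extrapolation.
#'
#' @param df data.frame with columns `sex`, `age_band`, `factor`
#'   (`"obesity"` or `"smoking"`), `year` (integer) and `prevalence`
#'   (proportion in \[0, 1\]).
#' @return The validated data.frame with class `"survey_points"`.
#' @export
survey_points <- function(df) {
  need <- c("sex", "age_band", "factor", "year", "prevalence")
  assert_that(all(need %in% names(df)),
              paste("survey points need columns:", paste(need, collapse = ", ")))
  assert_that(all(df$sex %in% sexes()), "unknown sex label in survey points")
  assert_that(all(df$age_band %in% age_bands()),
              "unknown age band label in survey points")
  assert_that(all(df$factor %in% c("obesity", "smoking")),
              "factor must be 'obesity' or 'smoking'")
  assert_that(all(df$prevalence >= 0 & df$prevalence <= 1),
              "survey prevalences must lie in [0, 1]")
  key <- paste(df$sex, df$age_band, df$factor, df$year)
  assert_that(!anyDuplicated(key) > 0,
              "duplicate survey year for the same stratum and factor")
  df <- df[order(df$factor, match(df$sex, sexes()),
                 match(df$age_band, age_bands()), df$year), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("survey_points", "data.frame"))
}

#' Build an annual trend series from sparse survey points
#'
#' Connects the survey points of one stratum and risk factor piecewise
#' linearly; before the first survey year values are back-extrapolated with
#' the first segment's slope, and after the last survey year they are
#' extrapolated with the overall observed slope between the first and last
#' survey points.  All values are clamped to \[0, 1\].  A single survey
#' point yields a constant series.
#'
#' @param points data.frame with columns `year` and `prevalence`, one row per
#'   survey, for a single stratum and factor.  At least one row; years unique.
#' @param years integer vector of model years the series must cover.
#' @return A `"trend_series"` data.frame with columns `year` and `value`.
#' @export
#' @examples
#' pts <- data.frame(year = c(1992, 2002), prevalence = c(0.20, 0.30))
#' tr <- build_trend(pts, 1992:2012)
#' tr$value[tr$year == 2012]  # 0.40
build_trend <- function(points, years) {
  assert_that(nrow(points) >= 1, "at least one survey point is required")
  assert_that(!anyDuplicated(points$year) > 0,
              "duplicate survey years for the same stratum and factor")
  assert_that(all(points$prevalence >= 0 & points$prevalence <= 1),
              "survey prevalences must lie in [0, 1]")
  points <- points[order(points$year), , drop = FALSE]
  yr <- as.numeric(points$year)
  pv <- as.numeric(points$prevalence)
  n <- length(yr)
  x <- as.numeric(years)

  if (n == 1L) {
    val <- rep(pv, length(x))
  } else {
    # interior: piecewise linear through the survey points
    val <- stats::approx(yr, pv, xout = x, rule = 1)$y
    # before first survey: first segment's slope, carried backwards
    s_first <- (pv[2] - pv[1]) / (yr[2] - yr[1])
    pre <- x < yr[1]
    val[pre] <- pv[1] + s_first * (x[pre] - yr[1])
    # beyond last survey: overall observed slope (last vs first survey)
    s_overall <- (pv[n] - pv[1]) / (yr[n] - yr[1])
    post <- x > yr[n]
    val[post] <- pv[n] + s_overall * (x[post] - yr[n])
  }

  structure(data.frame(year = as.integer(years), value = clamp(val)),
            class = c("trend_series", "data.frame"))
}

#' Cap a trend series at a maximum prevalence
#'
#' Replaces every value above `cap` by `cap`; values at or below the cap are
#' unchanged.  Used for the capped-obesity scenario, where projected obesity
#' prevalence is not allowed to exceed the highest observed value.
#'
#' @param series a `"trend_series"` (or any data.frame with a `value` column).
#' @param cap maximum allowed prevalence, in (0, 1\].
#' @return The series with values capped.
#' @export
apply_cap <- function(series, cap) {
  assert_that(is.numeric(cap) && length(cap) == 1 && cap > 0 && cap <= 1,
              "cap must be a single proportion in (0, 1]")
  series$value <- pmin(series$value, cap)
  series
}

#' Transition hazards by stratum
#'
#' Holds the annual diabetes incidence, diabetes case-fatality and total
#' (background) mortality rates for each stratum, together with per-sex
#' relative risks of diabetes for the obese and smoker states.  All rates are
#' stored as per-person-per-year proportions (printed per-1000 rates divided
#' by 1000, printed percentages divided by 100): one canonical unit avoids
#' silent thousand-fold errors.
#'
#' @param rates data.frame with columns `sex`, `age_band`, `incidence`,
#'   `case_fatality`, `total_mortality`, one row per stratum (12 rows).
#' @param rr data.frame with columns `sex`, `rr_obese`, `rr_smoker`
#'   (one row per sex); both relative risks must be >= 1.
#' @return A list with elements `rates` and `rr`, class `"hazard_table"`.
#' @export
hazard_table <- function(rates, rr) {
  rates <- order_strata(rates, "hazard table")
  for (f in c("incidence", "case_fatality", "total_mortality")) {
    assert_that(all(rates[[f]] >= 0), sprintf("%s rates must be >= 0", f))
  }
  assert_that(all(sexes() %in% rr$sex), "relative risks needed for both sexes")
  assert_that(all(rr$rr_obese >= 1) && all(rr$rr_smoker >= 1),
              "relative risks must be >= 1 (protective exposures out of scope)")
  rr <- rr[match(sexes(), rr$sex), c("sex", "rr_obese", "rr_smoker")]
  rownames(rr) <- NULL
  structure(list(rates = rates, rr = rr), class = "hazard_table")
}

#' Baseline diabetes prevalence by stratum
#'
#' Start-year prevalence of diagnosed plus undiagnosed type 2 diabetes in
#' each stratum, as a proportion of the living stratum population.
#'
#' @param df data.frame with columns `sex`, `age_band`, `prevalence`.
#' @return Validated data.frame with class `"baseline_prevalence"`.
#' @export
baseline_prevalence <- function(df) {
  df <- order_strata(df, "baseline prevalence")
  assert_that(all(df$prevalence >= 0 & df$prevalence <= 1),
              "baseline prevalences must lie in [0, 1]")
  structure(df[, c("sex", "age_band", "prevalence")],
            class = c("baseline_prevalence", "data.frame"))
}

#' Exogenous population trajectory
#'
#' Annual person counts per stratum over the model years.  The engine
#' rescales (or, in `band_shift` mode, shifts and rescales) compartments so
#' that each stratum's living total follows this trajectory.
#'
#' @param df data.frame with columns `year`, `sex`, `age_band`, `population`.
#' @return Validated data.frame with class `"population_trajectory"`.
#' @export
population_trajectory <- function(df) {
  need <- c("year", "sex", "age_band", "population")
  assert_that(all(need %in% names(df)),
              paste("population table needs columns:", paste(need, collapse = ", ")))
  assert_that(all(df$population >= 0), "population counts must be >= 0")
  df <- df[order(df$year, match(df$sex, sexes()),
                 match(df$age_band, age_bands())), need]
  rownames(df) <- NULL
  structure(df, class = c("population_trajectory", "data.frame"))
}

#' Model configuration
#'
#' Scalar settings of a projection run.
#'
#' @param start_year,end_year first and last modelled calendar years.
#' @param extremes_factor proportional parameter shift used by the analysis
#'   of extremes (default 0.20).
#' @param scenario `"uncapped"` (trends extrapolated freely) or `"capped"`
#'   (obesity trends capped at `cap_male` / `cap_female`).
#' @param cap_male,cap_female obesity prevalence caps (defaults 0.35, 0.60,
#'   the highest observed values rounded up).
#' @param aging_mode `"closed_strata"` (default: strata rescaled to the
#'   exogenous population, no inter-band flow) or `"band_shift"` (a
#'   1/duration fraction of each band moves up one band each cycle).
#' @param rate_conversion `"exponential"` (default, prob = 1 - exp(-rate))
#'   or `"direct"`.
#' @param incidence_anchor `"start_year"` (default) decomposes the overall
#'   incidence into the healthy-state incidence once, from the start-year
#'   exposure shares, and holds it fixed -- so overall incidence rises as
#'   the exposed pools grow, the mechanism by which risk-factor trends
#'   drive the projection; `"every_cycle"` re-decomposes from each cycle's
#'   shares, which pins overall incidence to the input value regardless of
#'   the trends.
#' @param entrant_diabetes_prev diabetes prevalence among new 25-34 entrants
#'   under `band_shift` aging (default 0).
#' @param random_seed integer seed, used only by synthetic-data generation.
#' @return A list of settings with class `"model_config"`.
#' @export
model_config <- function(start_year = 1992L, end_year = 2022L,
                         extremes_factor = 0.20,
                         scenario = c("uncapped", "capped"),
                         cap_male = 0.35, cap_female = 0.60,
                         aging_mode = c("closed_strata", "band_shift"),
                         rate_conversion = c("exponential", "direct"),
                         incidence_anchor = c("start_year", "every_cycle"),
                         entrant_diabetes_prev = 0,
                         random_seed = 1L) {
  scenario <- match.arg(scenario)
  aging_mode <- match.arg(aging_mode)
  rate_conversion <- match.arg(rate_conversion)
  incidence_anchor <- match.arg(incidence_anchor)
  assert_that(start_year < end_year, "start_year must precede end_year")
  assert_that(extremes_factor > 0 && extremes_factor < 1,
              "extremes_factor must lie in (0, 1)")
  assert_that(cap_male > 0 && cap_male <= 1 && cap_female > 0 && cap_female <= 1,
              "caps must lie in (0, 1]")
  structure(list(start_year = as.integer(start_year),
                 end_year = as.integer(end_year),
                 extremes_factor = extremes_factor,
                 scenario = scenario,
                 cap_male = cap_male, cap_female = cap_female,
                 aging_mode = aging_mode,
                 rate_conversion = rate_conversion,
                 incidence_anchor = incidence_anchor,
                 entrant_diabetes_prev = entrant_diabetes_prev,
                 random_seed = as.integer(random_seed)),
            class = "model_config")
}

#' Validate an input bundle
#'
#' Checks the structural invariants of a full input set -- stratum and year
#' coverage, value ranges, relative-risk bounds -- and reports violations
#' instead of throwing, so all problems surface at once.
#'
#' @param hazards a `"hazard_table"` (or equivalent list).
#' @param baseline a `"baseline_prevalence"` data.frame.
#' @param population a `"population_trajectory"` data.frame.
#' @param surveys a `"survey_points"` data.frame.
#' @param config a `"model_config"`.
#' @return A data.frame of violations with columns `component`, `where`,
#'   `message`; zero rows when every invariant holds.
#' @export
validate_inputs <- function(hazards, baseline, population, surveys, config) {
  v <- list()
  note <- function(component, where, message) {
    v[[length(v) + 1L]] <<- data.frame(component = component, where = where,
                                       message = message)
  }
  s <- all_strata()
  keys <- stratum_key(s$sex, s$age_band)
  years <- config$start_year:config$end_year

  ## hazards: coverage and ranges
  hk <- stratum_key(hazards$rates$sex, hazards$rates$age_band)
  for (k in setdiff(keys, hk)) note("hazards", k, "stratum missing")
  for (f in c("incidence", "case_fatality", "total_mortality")) {
    bad <- which(hazards$rates[[f]] < 0)
    for (i in bad) note("hazards", hk[i], sprintf("%s is negative (%g)", f,
                                                  hazards$rates[[f]][i]))
  }
  for (i in seq_len(nrow(hazards$rr))) {
    if (hazards$rr$rr_obese[i] < 1)
      note("hazards", hazards$rr$sex[i], "rr_obese below 1")
    if (hazards$rr$rr_smoker[i] < 1)
      note("hazards", hazards$rr$sex[i], "rr_smoker below 1")
  }

  ## baseline: coverage and range
  bk <- stratum_key(baseline$sex, baseline$age_band)
  for (k in setdiff(keys, bk)) note("baseline", k, "stratum missing")
  bad <- which(baseline$prevalence < 0 | baseline$prevalence > 1)
  for (i in bad) note("baseline", bk[i], sprintf("prevalence %g outside [0, 1]",
                                                 baseline$prevalence[i]))

  ## population: full (year, stratum) grid, non-negative
  pk <- paste(population$year, stratum_key(population$sex, population$age_band))
  grid <- as.vector(outer(years, keys, paste))
  for (k in setdiff(grid, pk)) note("population", k, "year x stratum missing")
  bad <- which(population$population < 0)
  for (i in bad) note("population", pk[i], sprintf("count %g is negative",
                                                   population$population[i]))

  ## surveys: at least one point per stratum x factor, in range, no duplicates
  for (f in c("obesity", "smoking")) {
    sub <- surveys[surveys$factor == f, , drop = FALSE]
    sk <- stratum_key(sub$sex, sub$age_band)
    for (k in setdiff(keys, sk))
      note("surveys", paste(f, k), "no survey point for stratum")
    bad <- which(sub$prevalence < 0 | sub$prevalence > 1)
    for (i in bad) note("surveys", paste(f, sk[i]),
                        sprintf("prevalence %g outside [0, 1]", sub$prevalence[i]))
    dup <- duplicated(paste(sk, sub$year))
    for (i in which(dup)) note("surveys", paste(f, sk[i]),
                               sprintf("duplicate survey year %d", sub$year[i]))
    out <- which(sub$year < config$start_year | sub$year > config$end_year)
    for (i in out) note("surveys", paste(f, sk[i]),
                        sprintf("survey year %d outside model years", sub$year[i]))
  }

  if (length(v) == 0)
    return(data.frame(component = character(), where = character(),
                      message = character()))
  do.call(rbind, v)
}
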