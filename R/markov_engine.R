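## Annual-cycle Markov engine.
##
## Each cycle: re-anchor the exposure compartments to the exogenous trend
## prevalences, decompose overall incidence into incidence among the
## healthy, apply competing-risk transitions, then advance the population
## to the next year's exogenous size.  Iteration order is fixed (years
## outer, strata inner, canonical order) and person counts stay fractional
## until report formatting, so runs are bit-reproducible.

#' Convert an annual rate to a one-cycle transition probability
#'
#' @param rate annual hazard rate, >= 0 (per person-year).
#' @param mode `"exponential"` (default): `1 - exp(-rate)`, the constant-
#'   hazard conversion; `"direct"`: `min(rate, 1)`.
#' @return Transition probability in \[0, 1\].  Vectorised over `rate`.
#' @export
#' @examples
#' rate_to_probability(0.0129)            # 0.012817
#' rate_to_probability(0.0129, "direct")  # 0.0129
rate_to_probability <- function(rate, mode = c("exponential", "direct")) {
  mode <- match.arg(mode)
  if (any(rate < 0)) stop("negative rate", call. = FALSE)
  if (mode == "exponential") 1 - exp(-rate) else pmin(rate, 1)
}

## Internal: competing exits from one compartment.  `rates` are additive
## hazards to the destinations; the joint exit probability is converted
## once and split proportionally, avoiding order-of-operations artifacts
## of sequential subtraction.
competing_exits <- function(n, rates, mode) {
  total <- sum(rates)
  if (total <= 0 || n <= 0) return(rep(0, length(rates)))
  n * rate_to_probability(total, mode) * rates / total
}

## Internal: per-destination one-cycle probabilities (same split as
## competing_exits); shared with the microsimulation oracle so both routes
## use identical numbers.
transition_probs <- function(rates, mode) {
  total <- sum(rates)
  if (total <= 0) return(rep(0, length(rates)))
  rate_to_probability(total, mode) * rates / total
}

#' Advance one stratum through a single annual cycle
#'
#' Applies the competing-risk transitions: Healthy, Obese and Smokers can
#' develop diabetes (at `I_h`, `I_h * rr_obese`, `I_h * rr_smoker`) or die
#' of other causes (total mortality `m`); the Diabetes compartment loses
#' members to diabetes-related death (case fatality `f`) and other-cause
#' death (`m`).  There is no remission: nothing leaves Diabetes except
#' death.  Persons are conserved: inflows minus deaths account for every
#' change.
#'
#' @param state named list/vector with `healthy`, `obese`, `smokers`,
#'   `diabetes` (person counts >= 0).
#' @param hazards named list/vector with `case_fatality` (`f`) and
#'   `total_mortality` (`m`) for the stratum, per person-year.
#' @param rr_obese,rr_smoker relative risks of diabetes, >= 1.
#' @param I_h incidence among the healthy, per person-year, >= 0.
#' @param mode rate-to-probability conversion, see [rate_to_probability()].
#' @return List with `state` (the compartments after the cycle, before any
#'   population rescaling) and `flows` (`new_cases`, `deaths_other`,
#'   `deaths_diabetes`).
#' @export
step_stratum <- function(state, hazards, rr_obese, rr_smoker, I_h,
                         mode = c("exponential", "direct")) {
  mode <- match.arg(mode)
  assert_that(I_h >= 0, "incidence among healthy must be >= 0")
  f <- hazards[["case_fatality"]]
  m <- hazards[["total_mortality"]]

  ex_h <- competing_exits(state[["healthy"]],  c(I_h,            m), mode)
  ex_o <- competing_exits(state[["obese"]],    c(I_h * rr_obese, m), mode)
  ex_s <- competing_exits(state[["smokers"]],  c(I_h * rr_smoker, m), mode)
  ex_d <- competing_exits(state[["diabetes"]], c(f,              m), mode)

  new_cases <- ex_h[1] + ex_o[1] + ex_s[1]
  deaths_other <- ex_h[2] + ex_o[2] + ex_s[2] + ex_d[2]
  deaths_diabetes <- ex_d[1]

  list(state = list(healthy = state[["healthy"]] - sum(ex_h),
                    obese = state[["obese"]] - sum(ex_o),
                    smokers = state[["smokers"]] - sum(ex_s),
                    diabetes = state[["diabetes"]] - sum(ex_d) + new_cases),
       flows = list(new_cases = new_cases, deaths_other = deaths_other,
                    deaths_diabetes = deaths_diabetes))
}

#' Advance stepped compartments to the next year's exogenous population
#'
#' In `closed_strata` mode each stratum's living compartments are rescaled
#' by one common factor so the living total matches next year's exogenous
#' count; compartment shares (hence prevalence) are preserved.  In
#' `band_shift` mode a 1/10 fraction of each band (1/15 for the 15-year-wide
#' 75+ band, which exits the modelled population) first moves up one band
#' carrying its compartment mix; entrants closing any remaining gap in the
#' 25-34 band arrive with the supplied risk-factor mix and
#' `entrant_diabetes_prev` diabetes prevalence, and other bands are rescaled.
#'
#' @param states data.frame with columns `sex`, `age_band`, `healthy`,
#'   `obese`, `smokers`, `diabetes` -- the compartments after [step_stratum()].
#' @param next_pop data.frame with columns `sex`, `age_band`, `population`:
#'   the exogenous living totals for the next year.
#' @param aging_mode `"closed_strata"` or `"band_shift"`.
#' @param entrant_mix data.frame with columns `sex`, `obesity_prev`,
#'   `smoking_prev`: risk-factor mix of new 25-34 entrants (band_shift only;
#'   defaults to zeros).
#' @param entrant_diabetes_prev diabetes prevalence among entrants
#'   (band_shift only, default 0).
#' @return The `states` data.frame advanced to the next year.
#' @export
advance_population <- function(states, next_pop,
                               aging_mode = c("closed_strata", "band_shift"),
                               entrant_mix = data.frame(sex = sexes(),
                                                        obesity_prev = 0,
                                                        smoking_prev = 0),
                               entrant_diabetes_prev = 0) {
  aging_mode <- match.arg(aging_mode)
  states <- order_strata(states, "states")
  next_pop <- order_strata(next_pop, "next-year population")
  assert_that(!anyNA(next_pop$population), "missing next-year population")
  comp <- c("healthy", "obese", "smokers", "diabetes")
  M <- as.matrix(states[, comp])

  if (aging_mode == "band_shift") {
    bands <- age_bands()
    nb <- length(bands)
    out_frac <- c(rep(1 / 10, nb - 1), 1 / 15)  # 75+ exits the model
    for (sx in sexes()) {
      idx <- which(states$sex == sx)  # ascending bands by canonical order
      out <- M[idx, , drop = FALSE] * out_frac
      M[idx, ] <- M[idx, , drop = FALSE] - out
      M[idx[-1], ] <- M[idx[-1], , drop = FALSE] +
        out[-nb, , drop = FALSE]
      # entrants to the youngest band close any deficit with the entrant mix
      i1 <- idx[1]
      deficit <- next_pop$population[i1] - sum(M[i1, ])
      if (deficit > 0) {
        mi <- match(sx, entrant_mix$sex)
        o <- entrant_mix$obesity_prev[mi]
        s_only <- smoker_only_prevalence(entrant_mix$smoking_prev[mi], o)
        d <- entrant_diabetes_prev
        M[i1, ] <- M[i1, ] + deficit *
          c(max(0, 1 - d - o * (1 - d) - s_only * (1 - d)),
            o * (1 - d), s_only * (1 - d), d)
      }
    }
  }

  living <- rowSums(M)
  fac <- ifelse(living > 0, next_pop$population / living, 0)
  M <- M * fac
  # strata that died out restart from the exogenous count, all healthy
  empty <- living <= 0 & next_pop$population > 0
  M[empty, "healthy"] <- next_pop$population[empty]
  states[, comp] <- M
  states
}

#' Run the Markov projection
#'
#' Executes the full annual-cycle projection over all strata and model
#' years: builds (and, under the capped scenario, caps) the risk-factor
#' trend series, partitions each stratum into compartments, decomposes
#' incidence, applies the competing-risk transitions, and advances the
#' population.  The start-year aggregated prevalence equals the aggregated
#' baseline input exactly.
#'
#' @param config a [model_config()].
#' @param inputs list (or `"input_bundle"`) with elements `hazards`
#'   ([hazard_table()]), `baseline` ([baseline_prevalence()]), `population`
#'   ([population_trajectory()]) and `surveys` ([survey_points()]); a
#'   pre-built `trends` data.frame (`year`, `sex`, `age_band`, `factor`,
#'   `value`) may be supplied instead of `surveys`.
#' @return A `"dfm_result"` list with `states` (per year and stratum:
#'   compartments plus cumulative deaths), `flows` (per cycle:
#'   `new_cases`, `deaths_other`, `deaths_diabetes`, and `living_end`, the
#'   pre-rescale living total), `prevalence` (per year: `male`, `female`,
#'   `total` aggregated prevalence proportions) and the `config` used.
#' @export
run_model <- function(config, inputs) {
  years <- config$start_year:config$end_year
  ny <- length(years)
  s <- all_strata()
  ns <- nrow(s)

  hz <- inputs$hazards
  rates <- order_strata(hz$rates, "hazard table")
  rr_o <- hz$rr$rr_obese[match(s$sex, hz$rr$sex)]
  rr_s <- hz$rr$rr_smoker[match(s$sex, hz$rr$sex)]

  trends <- build_all_trends(config, inputs, years)
  obesity <- trends$obesity   # ns x ny matrices
  smoking <- trends$smoking

  pop <- order_population(inputs$population, s, years)  # ns x ny
  base <- order_strata(as.data.frame(inputs$baseline), "baseline prevalence")

  comp <- c("healthy", "obese", "smokers", "diabetes")
  st_arr <- array(0, dim = c(ns, ny, length(comp)),
                  dimnames = list(NULL, NULL, comp))
  cum_dead_other <- matrix(0, ns, ny)
  cum_dead_diab <- matrix(0, ns, ny)
  fl_new <- fl_do <- fl_dd <- fl_live <- matrix(0, ns, max(ny - 1L, 1L))

  D <- base$prevalence * pop[, 1]
  I_h_anchor <- rep(NA_real_, ns)

  for (t in seq_len(ny)) {
    N <- pop[, t]
    D <- pmin(D, N)
    next_state <- matrix(0, ns, length(comp))
    for (i in seq_len(ns)) {
      p <- partition_stratum(N[i], D[i], obesity[i, t], smoking[i, t],
                             rr_o[i], rr_s[i])
      st_arr[i, t, ] <- c(p$healthy, p$obese, p$smokers, p$diabetes)
      if (t < ny) {
        nd <- p$healthy + p$obese + p$smokers
        if (nd > 0) {
          shares <- list(p_healthy = p$healthy / nd, p_obese = p$obese / nd,
                         p_smoker = p$smokers / nd)
          I_h <- decompose_incidence(rates$incidence[i], shares,
                                     rr_o[i], rr_s[i])
        } else {
          I_h <- 0
        }
        # under the start-year anchor the healthy-state incidence is fixed
        # at its first-cycle value; overall incidence then follows the pools
        if (config$incidence_anchor == "start_year") {
          if (is.na(I_h_anchor[i]) && nd > 0) I_h_anchor[i] <- I_h
          if (!is.na(I_h_anchor[i])) I_h <- I_h_anchor[i]
        }
        stepped <- step_stratum(p,
                                list(case_fatality = rates$case_fatality[i],
                                     total_mortality = rates$total_mortality[i]),
                                rr_o[i], rr_s[i], I_h,
                                mode = config$rate_conversion)
        next_state[i, ] <- unlist(stepped$state[comp])
        fl_new[i, t] <- stepped$flows$new_cases
        fl_do[i, t] <- stepped$flows$deaths_other
        fl_dd[i, t] <- stepped$flows$deaths_diabetes
        fl_live[i, t] <- sum(next_state[i, ])
      }
    }
    if (t < ny) {
      cum_dead_other[, t + 1] <- cum_dead_other[, t] + fl_do[, t]
      cum_dead_diab[, t + 1] <- cum_dead_diab[, t] + fl_dd[, t]
      nx <- data.frame(s, next_state)
      names(nx) <- c("sex", "age_band", comp)
      young <- stratum_index(sexes(), rep("25-34", 2))
      adv <- advance_population(
        nx, data.frame(s, population = pop[, t + 1]),
        aging_mode = config$aging_mode,
        entrant_mix = data.frame(sex = sexes(),
                                 obesity_prev = obesity[young, t + 1],
                                 smoking_prev = smoking[young, t + 1]),
        entrant_diabetes_prev = config$entrant_diabetes_prev)
      D <- adv$diabetes
    }
  }

  states <- data.frame(year = rep(years, each = ns),
                       sex = rep(s$sex, ny), age_band = rep(s$age_band, ny),
                       healthy = as.vector(st_arr[, , "healthy"]),
                       obese = as.vector(st_arr[, , "obese"]),
                       smokers = as.vector(st_arr[, , "smokers"]),
                       diabetes = as.vector(st_arr[, , "diabetes"]),
                       dead_other = as.vector(cum_dead_other),
                       dead_diabetes = as.vector(cum_dead_diab))

  cyc <- years[-ny]
  flows <- data.frame(year = rep(cyc, each = ns),
                      sex = rep(s$sex, ny - 1L),
                      age_band = rep(s$age_band, ny - 1L),
                      new_cases = as.vector(fl_new[, seq_len(ny - 1L)]),
                      deaths_other = as.vector(fl_do[, seq_len(ny - 1L)]),
                      deaths_diabetes = as.vector(fl_dd[, seq_len(ny - 1L)]),
                      living_end = as.vector(fl_live[, seq_len(ny - 1L)]))

  male <- s$sex == "male"
  diab <- st_arr[, , "diabetes"]
  living <- st_arr[, , "healthy"] + st_arr[, , "obese"] +
    st_arr[, , "smokers"] + diab
  prevalence <- data.frame(
    year = years,
    male = colSums(diab[male, , drop = FALSE]) /
      colSums(living[male, , drop = FALSE]),
    female = colSums(diab[!male, , drop = FALSE]) /
      colSums(living[!male, , drop = FALSE]),
    total = colSums(diab) / colSums(living))
  rownames(prevalence) <- NULL

  structure(list(states = states, flows = flows, prevalence = prevalence,
                 config = config),
            class = "dfm_result")
}

## Internal: ns x ny matrices of obesity and smoking prevalence, built from
## survey points (or taken from a pre-built `trends` table), capped under
## the capped scenario.
build_all_trends <- function(config, inputs, years) {
  s <- all_strata()
  ns <- nrow(s)
  ny <- length(years)
  obesity <- matrix(NA_real_, ns, ny)
  smoking <- matrix(NA_real_, ns, ny)
  if (!is.null(inputs$trends)) {
    tr <- inputs$trends
    for (i in seq_len(ns)) {
      for (f in c("obesity", "smoking")) {
        sub <- tr[tr$sex == s$sex[i] & tr$age_band == s$age_band[i] &
                    tr$factor == f, ]
        v <- sub$value[match(years, sub$year)]
        assert_that(!anyNA(v), sprintf("trend table misses years for %s %s %s",
                                       s$sex[i], s$age_band[i], f))
        if (f == "obesity") obesity[i, ] <- v else smoking[i, ] <- v
      }
    }
  } else {
    sv <- inputs$surveys
    for (i in seq_len(ns)) {
      for (f in c("obesity", "smoking")) {
        sub <- sv[sv$sex == s$sex[i] & sv$age_band == s$age_band[i] &
                    sv$factor == f, c("year", "prevalence")]
        tsr <- build_trend(sub, years)
        if (f == "obesity") obesity[i, ] <- tsr$value else smoking[i, ] <- tsr$value
      }
    }
  }
  if (config$scenario == "capped") {
    cap <- ifelse(s$sex == "male", config$cap_male, config$cap_female)
    obesity <- pmin(obesity, cap)
  }
  list(obesity = obesity, smoking = smoking)
}

## Internal: population trajectory as an ns x ny matrix in canonical order.
order_population <- function(population, s, years) {
  ns <- nrow(s)
  out <- matrix(NA_real_, ns, length(years))
  pk <- paste(population$year, stratum_key(population$sex, population$age_band))
  for (t in seq_along(years)) {
    idx <- match(paste(years[t], stratum_key(s$sex, s$age_band)), pk)
    assert_that(!anyNA(idx),
                sprintf("population table misses strata for year %d", years[t]))
    out[, t] <- population$population[idx]
  }
  out
}

#' Aggregate diabetes prevalence from a run result
#'
#' Population-weighted diabetes share of the living population, grouped as
#' requested.  The total is consistent with the sex-specific values
#' recombined with the same population weights.
#'
#' @param result a `"dfm_result"` from [run_model()].
#' @param by `"total"`, `"sex"` or `"stratum"`.
#' @return data.frame with `year`, grouping columns, and `prevalence`
#'   (proportion).
#' @export
aggregate_prevalence <- function(result, by = c("total", "sex", "stratum")) {
  by <- match.arg(by)
  st <- result$states
  living <- st$healthy + st$obese + st$smokers + st$diabetes
  if (by == "total") {
    num <- tapply(st$diabetes, st$year, sum)
    den <- tapply(living, st$year, sum)
    out <- data.frame(year = as.integer(names(num)),
                      prevalence = as.vector(num / den))
  } else if (by == "sex") {
    num <- tapply(st$diabetes, list(st$year, st$sex), sum)
    den <- tapply(living, list(st$year, st$sex), sum)
    out <- expand.grid(year = as.integer(rownames(num)), sex = colnames(num),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    out$prevalence <- as.vector(num / den)
  } else {
    out <- data.frame(year = st$year, sex = st$sex, age_band = st$age_band,
                      prevalence = st$diabetes / living)
  }
  assert_that(nrow(out) > 0, "empty grouping")
  rownames(out) <- NULL
  out
}
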