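## On-disk interfaces: input bundles as long-format CSV plus a YAML/JSON
## config, results as tidy CSV plus a summary JSON.  Round-trip readers are
## provided for both.

MEASURES <- c("population", "obesity_prev", "smoking_prev", "diabetes_prev",
              "incidence", "case_fatality", "total_mortality")

#' Write an input bundle to a directory
#'
#' Writes `inputs.csv` in long format (columns `year`, `sex`, `age_band`,
#' `measure`, `value`; measures `population`, `obesity_prev`,
#' `smoking_prev`, `diabetes_prev`, `incidence`, `case_fatality`,
#' `total_mortality`) and `config.yaml` holding the scalar settings and the
#' per-sex relative risks.
#'
#' @param bundle an `"input_bundle"` as from [generate_bundle()] or
#'   [read_bundle()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  start <- cfg$start_year

  pop <- data.frame(year = bundle$population$year,
                    sex = bundle$population$sex,
                    age_band = bundle$population$age_band,
                    measure = "population",
                    value = bundle$population$population)
  sv <- data.frame(year = bundle$surveys$year, sex = bundle$surveys$sex,
                   age_band = bundle$surveys$age_band,
                   measure = ifelse(bundle$surveys$factor == "obesity",
                                    "obesity_prev", "smoking_prev"),
                   value = bundle$surveys$prevalence)
  bl <- data.frame(year = start, sex = bundle$baseline$sex,
                   age_band = bundle$baseline$age_band,
                   measure = "diabetes_prev",
                   value = bundle$baseline$prevalence)
  rt <- bundle$hazards$rates
  hz <- do.call(rbind, lapply(
    c("incidence", "case_fatality", "total_mortality"),
    function(f) data.frame(year = start, sex = rt$sex, age_band = rt$age_band,
                           measure = f, value = rt[[f]])))
  utils::write.csv(rbind(pop, sv, bl, hz),
                   file.path(dir, "inputs.csv"), row.names = FALSE)

  rr <- bundle$hazards$rr
  cfg_out <- unclass(cfg)
  cfg_out$relative_risks <- stats::setNames(
    lapply(seq_len(nrow(rr)),
           function(i) list(obese = rr$rr_obese[i], smoker = rr$rr_smoker[i])),
    rr$sex)
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read an input bundle from a directory
#'
#' Counterpart of [write_bundle()]: reads `inputs.csv` and `config.yaml`
#' (or `config.json`) and reconstructs the typed inputs.
#'
#' @param dir directory holding `inputs.csv` and `config.yaml`/`config.json`.
#' @return An `"input_bundle"` list.
#' @export
read_bundle <- function(dir) {
  f_csv <- file.path(dir, "inputs.csv")
  assert_that(file.exists(f_csv), sprintf("no inputs.csv in %s", dir))
  raw <- utils::read.csv(f_csv, stringsAsFactors = FALSE)
  need <- c("year", "sex", "age_band", "measure", "value")
  assert_that(all(need %in% names(raw)),
              paste("inputs.csv needs columns:", paste(need, collapse = ", ")))
  bad <- setdiff(unique(raw$measure), MEASURES)
  assert_that(length(bad) == 0,
              paste("unknown measures in inputs.csv:", paste(bad, collapse = ", ")))

  f_yaml <- file.path(dir, "config.yaml")
  f_json <- file.path(dir, "config.json")
  cfg_raw <- if (file.exists(f_yaml)) {
    yaml::read_yaml(f_yaml)
  } else if (file.exists(f_json)) {
    jsonlite::read_json(f_json, simplifyVector = TRUE)
  } else {
    stop(sprintf("no config.yaml or config.json in %s", dir), call. = FALSE)
  }
  rrs <- cfg_raw$relative_risks
  assert_that(!is.null(rrs), "config lacks relative_risks")
  keep <- intersect(names(cfg_raw), names(formals(model_config)))
  config <- do.call(model_config, cfg_raw[keep])

  take <- function(m) raw[raw$measure == m, , drop = FALSE]
  pop <- take("population")
  population <- population_trajectory(
    data.frame(year = pop$year, sex = pop$sex, age_band = pop$age_band,
               population = pop$value))
  sv <- rbind(
    within(take("obesity_prev"), factor <- "obesity"),
    within(take("smoking_prev"), factor <- "smoking"))
  surveys <- survey_points(
    data.frame(sex = sv$sex, age_band = sv$age_band, factor = sv$factor,
               year = sv$year, prevalence = sv$value))
  bl <- take("diabetes_prev")
  baseline <- baseline_prevalence(
    data.frame(sex = bl$sex, age_band = bl$age_band, prevalence = bl$value))

  key <- function(df) stratum_key(df$sex, df$age_band)
  inc <- take("incidence"); cf <- take("case_fatality"); tm <- take("total_mortality")
  rates <- data.frame(sex = inc$sex, age_band = inc$age_band,
                      incidence = inc$value,
                      case_fatality = cf$value[match(key(inc), key(cf))],
                      total_mortality = tm$value[match(key(inc), key(tm))])
  rr <- data.frame(sex = names(rrs),
                   rr_obese = vapply(rrs, function(x) x$obese, numeric(1)),
                   rr_smoker = vapply(rrs, function(x) x$smoker, numeric(1)))
  hazards <- hazard_table(rates, rr)

  structure(list(hazards = hazards, baseline = baseline,
                 population = population, surveys = surveys, config = config),
            class = "input_bundle")
}

#' Write a run result to a directory
#'
#' Writes `states.csv` and `flows.csv` in tidy long format (`year`, `sex`,
#' `age_band`, `compartment`/`flow`, `value`) and `summary.json` with the
#' per-year male/female/total prevalence and diabetes counts.
#'
#' @param result a `"dfm_result"` from [run_model()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- function(df, id, what) {
    vars <- setdiff(names(df), id)
    out <- do.call(rbind, lapply(vars, function(v)
      data.frame(df[id], name = v, value = df[[v]])))
    names(out)[names(out) == "name"] <- what
    out
  }
  id <- c("year", "sex", "age_band")
  utils::write.csv(long(result$states, id, "compartment"),
                   file.path(dir, "states.csv"), row.names = FALSE)
  utils::write.csv(long(result$flows, id, "flow"),
                   file.path(dir, "flows.csv"), row.names = FALSE)

  st <- result$states
  diab <- tapply(st$diabetes, st$year, sum)
  summary <- list(year = result$prevalence$year,
                  prevalence_male = result$prevalence$male,
                  prevalence_female = result$prevalence$female,
                  prevalence_total = result$prevalence$total,
                  diabetes_count = as.vector(diab))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       digits = NA, auto_unbox = FALSE)
  invisible(dir)
}

#' Read a run result from a directory
#'
#' Counterpart of [write_result()]; reconstructs a `"dfm_result"` (without
#' the original config).
#'
#' @param dir directory holding `states.csv`, `flows.csv`, `summary.json`.
#' @return A `"dfm_result"` list.
#' @export
read_result <- function(dir) {
  wide <- function(file, what) {
    df <- utils::read.csv(file.path(dir, file), stringsAsFactors = FALSE)
    out <- stats::reshape(df, idvar = c("year", "sex", "age_band"),
                          timevar = what, direction = "wide")
    names(out) <- sub("^value\\.", "", names(out))
    rownames(out) <- NULL
    out
  }
  states <- wide("states.csv", "compartment")
  flows <- wide("flows.csv", "flow")
  sm <- jsonlite::read_json(file.path(dir, "summary.json"),
                            simplifyVector = TRUE)
  prevalence <- data.frame(year = sm$year, male = sm$prevalence_male,
                           female = sm$prevalence_female,
                           total = sm$prevalence_total)
  structure(list(states = states, flows = flows, prevalence = prevalence,
                 config = NULL),
            class = "dfm_result")
}
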