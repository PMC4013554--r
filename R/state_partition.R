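## Partition of a stratum's living population into the model compartments.
##
## Survey prevalences are whole-population proportions (surveys measure them
## that way, diabetics included).  The obese-smoker overlap is assigned to
## the Obese state, and diabetes cases attributable to each exposure are
## removed from the exposure pools via Levin's population attributable risk,
## so the Obese and Smoker compartments contain only non-diabetic people.

#' Prevalence of smoking without obesity
#'
#' Obese smokers are assigned to the Obese state; the Smokers state keeps
#' only non-obese smokers.  Assuming independence of the two exposures, the
#' overlap is the product of the two prevalences.
#'
#' @param smoking_prev,obesity_prev whole-population prevalences in \[0, 1\].
#' @return `smoking_prev * (1 - obesity_prev)`.
#' @export
#' @examples
#' smoker_only_prevalence(0.20, 0.30)  # 0.14
smoker_only_prevalence <- function(smoking_prev, obesity_prev) {
  assert_that(all(smoking_prev >= 0 & smoking_prev <= 1) &&
              all(obesity_prev >= 0 & obesity_prev <= 1),
              "prevalences must lie in [0, 1]")
  smoking_prev * (1 - obesity_prev)
}

#' Population attributable risk (Levin's formula)
#'
#' Fraction of disease cases attributable to an exposure with prevalence
#' `p_exposed` and relative risk `rr`:
#' `PAR = p (rr - 1) / (1 + p (rr - 1))`.
#' Used to remove attributable diabetes cases from the exposure pools.
#'
#' @param p_exposed exposure prevalence in \[0, 1\].
#' @param rr relative risk, >= 1.
#' @return The attributable fraction, in \[0, 1).  Monotone increasing in
#'   both arguments.
#' @export
#' @examples
#' levin_par(0.345, 6.74)
levin_par <- function(p_exposed, rr) {
  assert_that(all(p_exposed >= 0 & p_exposed <= 1),
              "exposure prevalence must lie in [0, 1]")
  if (any(rr < 1))
    stop("relative risk below 1: protective exposures are out of scope",
         call. = FALSE)
  x <- p_exposed * (rr - 1)
  x / (1 + x)
}

#' Partition one stratum into model compartments
#'
#' Splits the living population of a stratum-year into Healthy, Obese
#' (non-diabetic), Smoker (non-obese, non-diabetic) and Diabetes
#' compartments.  Exposure pools start from the whole-population prevalences,
#' then lose the diabetes cases attributed to each exposure by
#' [levin_par()].  If the pools would overrun the non-diabetic population
#' (large diabetes count, small prevalence), they are shrunk proportionally
#' so Healthy is floored at zero; negative pools are floored at zero with
#' Healthy absorbing the residual.
#'
#' @param living_pop living persons in the stratum.
#' @param diabetes_count persons with diabetes (must not exceed `living_pop`).
#' @param obesity_prev,smoking_prev whole-population prevalences in \[0, 1\].
#' @param rr_obese,rr_smoker relative risks of diabetes, >= 1.
#' @return Named list with `healthy`, `obese`, `smokers`, `diabetes`; the
#'   four compartments sum to `living_pop` and are all >= 0.
#' @export
#' @examples
#' partition_stratum(1000, 0, 0.30, 0.20, 6.74, 1.44)
partition_stratum <- function(living_pop, diabetes_count,
                              obesity_prev, smoking_prev,
                              rr_obese, rr_smoker) {
  assert_that(diabetes_count <= living_pop,
              "diabetes count exceeds living population")
  assert_that(living_pop >= 0 && diabetes_count >= 0,
              "counts must be >= 0")
  smk_only <- smoker_only_prevalence(smoking_prev, obesity_prev)
  obese <- max(0, obesity_prev * living_pop -
                  levin_par(obesity_prev, rr_obese) * diabetes_count)
  smokers <- max(0, smk_only * living_pop -
                    levin_par(smk_only, rr_smoker) * diabetes_count)
  non_diab <- living_pop - diabetes_count
  pool <- obese + smokers
  if (pool > non_diab && pool > 0) {
    shrink <- non_diab / pool
    obese <- obese * shrink
    smokers <- smokers * shrink
  }
  healthy <- non_diab - obese - smokers
  # guard against floating-point dust
  healthy <- max(0, healthy)
  list(healthy = healthy, obese = obese, smokers = smokers,
       diabetes = diabetes_count)
}

#' Decompose overall incidence into incidence among the healthy
#'
#' The overall diabetes incidence applies to the whole susceptible
#' (non-diabetic) population.  Treating it as the share-weighted sum of the
#' state-specific incidences -- `I_h` for Healthy, `I_h * rr_obese` for
#' Obese, `I_h * rr_smoker` for Smokers -- and solving for `I_h`:
#' `I_h = I / (p_h + p_o * rr_obese + p_s * rr_smoker)`.
#'
#' @param overall_incidence annual incidence rate (per person-year), >= 0.
#' @param shares named list or vector with `p_healthy`, `p_obese`,
#'   `p_smoker`: shares of the non-diabetic population in each state
#'   (each in \[0, 1\], summing to 1).
#' @param rr_obese,rr_smoker relative risks, >= 1.
#' @return Incidence rate among the healthy, `I_h`.
#' @export
#' @examples
#' decompose_incidence(0.0129, list(p_healthy = 1, p_obese = 0, p_smoker = 0),
#'                     6.74, 1.44)
decompose_incidence <- function(overall_incidence, shares,
                                rr_obese, rr_smoker) {
  assert_that(overall_incidence >= 0, "incidence must be >= 0")
  p_h <- shares[["p_healthy"]]; p_o <- shares[["p_obese"]]
  p_s <- shares[["p_smoker"]]
  assert_that(all(c(p_h, p_o, p_s) >= 0) && all(c(p_h, p_o, p_s) <= 1),
              "shares must lie in [0, 1]")
  assert_that(abs(p_h + p_o + p_s - 1) < 1e-8, "shares must sum to 1")
  denom <- p_h + p_o * rr_obese + p_s * rr_smoker
  if (denom <= 0) stop("degenerate exposure shares: zero denominator",
                       call. = FALSE)
  overall_incidence / denom
}
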