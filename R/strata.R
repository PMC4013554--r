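#' @keywords internal
"_PACKAGE"

## Stratum layout: 2 sexes x 6 ten-year age bands (open-ended 75+), adults 25+.
## Band labels are part of the external interface and must match bit-exactly.

#' Age-band labels used throughout the model
#'
#' Six ordered ten-year bands covering adults aged 25 and over; the last band
#' is open-ended.
#'
#' @return Character vector of the six band labels, in ascending age order.
#' @export
#' @examples
#' age_bands()
age_bands <- function() {
  c("25-34", "35-44", "45-54", "55-64", "65-74", "75+")
}

#' Sex labels used throughout the model
#'
#' @return Character vector `c("male", "female")`.
#' @export
sexes <- function() c("male", "female")

#' Enumerate the twelve model strata
#'
#' A stratum is one sex by age-band cell; the model always operates on the
#' full set of twelve, in a fixed order (males first, bands ascending) so
#' results are bit-reproducible.
#'
#' @return A data.frame with columns `sex` and `age_band`, twelve rows.
#' @export
#' @examples
#' all_strata()
all_strata <- function() {
  out <- expand.grid(age_band = age_bands(), sex = sexes(),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("sex", "age_band")]
  rownames(out) <- NULL
  out
}

## Internal: canonical ordering key "sex:band" and index lookup.
stratum_key <- function(sex, age_band) paste(sex, age_band, sep = ":")

stratum_index <- function(sex, age_band) {
  s <- all_strata()
  match(stratum_key(sex, age_band), stratum_key(s$sex, s$age_band))
}

## Internal: reorder a per-stratum data.frame into canonical stratum order,
## checking completeness. `df` must have sex and age_band columns.
order_strata <- function(df, what = "table") {
  s <- all_strata()
  idx <- match(stratum_key(s$sex, s$age_band), stratum_key(df$sex, df$age_band))
  if (anyNA(idx)) {
    missing <- stratum_key(s$sex, s$age_band)[is.na(idx)]
    stop(sprintf("%s is missing strata: %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  out <- df[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Internal: clamp numeric vector to [lo, hi].
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

## Internal: stopifnot-with-message helper.
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
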