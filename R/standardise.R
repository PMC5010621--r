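#' Person-years from stratified mid-period populations
#'
#' Each quinquennium contributes `population x 5` person-years, the population
#' being the mid-period estimate for that stratum.
#'
#' @param strata long-format data frame with columns `area_id`, `age_group`,
#'   `sex`, `period`, `population` (and optionally `deaths`).
#' @return the input with a `person_years` column appended.
#' @export
person_years <- function(strata) {
  stopifnot(all(c("area_id", "age_group", "sex", "period", "population")
                %in% names(strata)))
  if (any(strata$population < 0)) stop("populations must be non-negative")
  strata$person_years <- strata$population * 5
  strata
}

check_strata_complete <- function(strata) {
  ag <- unique(strata$age_group)
  sx <- unique(strata$sex)
  pd <- unique(strata$period)
  if (length(ag) != 18L) {
    stop("expected 18 age groups, found ", length(ag))
  }
  if (length(sx) != 2L || length(pd) != 2L) {
    stop("expected 2 sexes and 2 periods, found ",
         length(sx), " and ", length(pd))
  }
  invisible(TRUE)
}

#' Reference rates pooled over all areas ("national" rates)
#'
#' Computes, for each of the 18 age groups x 2 sexes x 2 periods strata, the
#' pooled death rate `sum(deaths) / sum(person-years)` over every area in the
#' study. Strata with zero person-years get rate 0 with a warning.
#'
#' @param strata long-format table with `deaths` and `population` columns.
#' @return a `rate_table` data frame (`age_group`, `sex`, `period`, `rate`).
#' @export
national_rates <- function(strata) {
  stopifnot("deaths" %in% names(strata))
  check_strata_complete(strata)
  strata <- person_years(strata)
  agg <- aggregate(cbind(deaths, person_years) ~ age_group + sex + period,
                   data = strata, FUN = sum)
  if (all(agg$person_years == 0)) {
    stop("all strata have zero person-years; rates undefined")
  }
  empty <- agg$person_years == 0
  if (any(empty)) {
    warning(sum(empty), " strata have zero person-years; their rate set to 0")
  }
  agg$rate <- ifelse(empty, 0, agg$deaths / agg$person_years)
  out <- agg[, c("age_group", "sex", "period", "rate")]
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Expected deaths per area by indirect standardisation
#'
#' For each area and sex, `E_i = sum over strata of rate x person-years`,
#' using the supplied reference rate table. Every stratum present in the data
#' must be covered by the rate table.
#'
#' @param strata long-format population table (with or without `deaths`).
#' @param rates a `rate_table` from [national_rates()] (or external rates with
#'   the same columns).
#' @return data frame `area_id`, `sex`, `expected`.
#' @export
expected_cases <- function(strata, rates) {
  strata <- person_years(strata)
  key <- paste(strata$age_group, strata$sex, strata$period)
  rkey <- paste(rates$age_group, rates$sex, rates$period)
  idx <- match(key, rkey)
  if (anyNA(idx)) {
    miss <- unique(key[is.na(idx)])
    stop("rate table does not cover strata: ",
         paste(head(miss, 5), collapse = "; "))
  }
  strata$expected <- rates$rate[idx] * strata$person_years
  agg <- aggregate(expected ~ area_id + sex, data = strata, FUN = sum)
  agg[order(agg$sex, agg$area_id), ]
}

#' Indirectly standardise a study universe in place
#'
#' Derives pooled reference rates from the universe's own strata table and
#' attaches per-sex expected deaths (`expected_men`, `expected_women`) to the
#' areas table. With internally derived rates the standardisation is
#' conservative: total expected equals total observed deaths within each sex.
#'
#' @param universe a `study_universe`.
#' @param rates optional external `rate_table`; internal pooled rates if NULL.
#' @return the universe with expected-death columns filled and the rate table
#'   stored as `universe$rates_used`.
#' @export
standardise_universe <- function(universe, rates = NULL) {
  if (is.null(rates)) rates <- national_rates(universe$strata)
  ec <- expected_cases(universe$strata, rates)
  for (sx in unique(ec$sex)) {
    sel <- ec$sex == sx
    ord <- match(universe$areas$id, ec$area_id[sel])
    universe$areas[[paste0("expected_", sx)]] <- ec$expected[sel][ord]
  }
  universe$rates_used <- rates
  universe
}
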