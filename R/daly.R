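# Discounted healthy-year streams underlying YLL and YLD.
#
# A constant stream of one healthy year per year over L years, discounted
# continuously at rate r, integrates to (1 - exp(-r L)) / r; the limit at
# r = 0 is L.  Age weighting is off by default (flag kept for symmetry
# with the standard DALY formulation; only the unweighted form is
# implemented).

discounted_years <- function(duration, discount_rate) {
  ifelse(discount_rate == 0,
         duration,
         (1 - exp(-discount_rate * duration)) / discount_rate)
}

#' Years of life lost to premature mortality (YLL)
#'
#' @param deaths number of deaths (N).
#' @param residual_life_expectancy years of life remaining at the age of
#'   death (L).
#' @param discount_rate annual discount rate r (continuous discounting);
#'   0 gives the undiscounted `N * L`.
#' @param age_weighting must be `FALSE`; uniform age weights are the only
#'   implemented form.
#' @return YLL in years: `N * (1 - exp(-r L)) / r`, or `N * L` when r = 0.
#' @export
#' @examples
#' yll(1, 30, 0)     # 30
#' yll(1, 30, 0.03)  # 19.78
yll <- function(deaths, residual_life_expectancy, discount_rate = 0.03,
                age_weighting = FALSE) {
  if (isTRUE(age_weighting)) {
    stop("age weighting is not implemented; use age_weighting = FALSE")
  }
  if (any(deaths < 0) || any(residual_life_expectancy < 0) ||
      any(discount_rate < 0)) {
    stop("deaths, residual_life_expectancy and discount_rate must be non-negative")
  }
  deaths * discounted_years(residual_life_expectancy, discount_rate)
}

#' Years lived with disability (YLD)
#'
#' @param incident_cases incident cases per year (I).
#' @param disability_weight disability weight in \[0, 1\] (DW); 0 = full
#'   health, 1 = equivalent to death.
#' @param duration mean duration of the condition in years.
#' @param discount_rate annual discount rate r; 0 gives the undiscounted
#'   `I * DW * duration`.
#' @inheritParams yll
#' @return YLD in years: `I * DW * (1 - exp(-r * duration)) / r`.
#' @export
#' @examples
#' yld(100, 0.5, 2, 0)  # 100
yld <- function(incident_cases, disability_weight, duration,
                discount_rate = 0.03, age_weighting = FALSE) {
  if (isTRUE(age_weighting)) {
    stop("age weighting is not implemented; use age_weighting = FALSE")
  }
  if (any(disability_weight < 0) || any(disability_weight > 1)) {
    stop("disability_weight must lie in [0, 1]")
  }
  if (any(incident_cases < 0) || any(duration < 0) || any(discount_rate < 0)) {
    stop("incident_cases, duration and discount_rate must be non-negative")
  }
  incident_cases * disability_weight * discounted_years(duration, discount_rate)
}

#' Disability-adjusted life years
#'
#' One DALY is one lost year of healthy life; the burden of a condition is
#' the sum of its mortality (YLL) and morbidity (YLD) components.
#'
#' @param yll_years,yld_years component values, e.g. from [yll()] and
#'   [yld()].
#' @return `yll_years + yld_years`.
#' @export
daly <- function(yll_years, yld_years) {
  yll_years + yld_years
}
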