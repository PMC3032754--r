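#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used wherever a rate or ratio is
#' reported at a fixed precision.  Base `round()` rounds half to even,
#' which would turn e.g. 0.625 into 0.62 where the reported tables print
#' 0.63.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` places.
#' @export
#' @examples
#' round_half_up(0.625, 2) # 0.63
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small epsilon absorbs binary representation error in x * p
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' The six denominator classes used for provision rates
#'
#' Every service rate is expressed per 1000 persons of one of these
#' sub-populations.
#'
#' @return Character vector of class names.
#' @export
denominator_classes <- function() {
  c("total", "live_births", "under5", "over5", "adult15plus", "female15to45")
}

#' Normalize intervention names for joining
#'
#' Joins across tables use the intervention name as key.  Matching is
#' exact after trimming, whitespace squashing and case-folding, with an
#' optional alias map for known variants (names = variant, values =
#' canonical; both sides are normalized before lookup).
#'
#' @param x character vector of names.
#' @param aliases optional named character vector mapping variant names to
#'   canonical names.
#' @return Normalized character vector.
#' @export
normalize_intervention <- function(x, aliases = NULL) {
  out <- tolower(trimws(gsub("\\s+", " ", x)))
  if (!is.null(aliases)) {
    key <- tolower(trimws(gsub("\\s+", " ", names(aliases))))
    val <- tolower(trimws(gsub("\\s+", " ", unname(aliases))))
    hit <- match(out, key)
    out[!is.na(hit)] <- val[hit[!is.na(hit)]]
  }
  out
}

#' Alias map linking HMIS data-element names to EHP intervention names
#'
#' The routine-reporting tables label services by HMIS data element
#' (e.g. "Acute Respiratory Infections under 5 years - new") while the
#' gap table uses EHP intervention names ("ARI in under-5s").  This map
#' covers the variants appearing in the packaged fixtures.
#'
#' @return Named character vector suitable for the `aliases` argument of
#'   [normalize_intervention()].
#' @export
ehp_intervention_aliases <- function() {
  c(
    "Acute Respiratory Infections under 5 years - new" = "ARI in under-5s",
    "Malaria under 5 years - new"                      = "Malaria - under 5",
    "Malaria 5 years and older - new"                  = "Malaria - 5 and over",
    "Diarrhoea non-bloody under 5 years - new"         = "Treatment of Dehydration in U5s",
    "Dysentery - new"                                  = "Case management of Dysentery",
    "Delivery by skilled personnel"                    = "Normal Delivery",
    "Antenatal total visits"                           = "Antenatal Care",
    "Abortion complications treated"                   = "Abortion Complications"
  )
}

# fiscal-year labels: "2002/03" <-> starting calendar year 2002
fy_label <- function(start_year) {
  sprintf("%d/%02d", start_year, (start_year + 1) %% 100)
}

fy_start <- function(label) {
  as.integer(sub("/.*$", "", label))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
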