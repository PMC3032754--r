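#' Classify cost-effectiveness against a $/DALY threshold
#'
#' An intervention is cost-effective when it averts a DALY for strictly
#' less than the threshold (default $150/DALY, the conventional cutoff
#' for low-income settings); `NA` values are classed `unknown`.
#'
#' @param usd_per_daly dollars per DALY averted; NA where no estimate
#'   exists.
#' @param threshold positive $/DALY cutoff.
#' @return Character vector in
#'   `{cost_effective, not_cost_effective, unknown}`.
#' @export
#' @examples
#' classify_ce(c(7, 298, NA))  # cost_effective, not_cost_effective, unknown
classify_ce <- function(usd_per_daly, threshold = 150) {
  if (threshold <= 0) stop("threshold must be positive")
  if (any(usd_per_daly <= 0, na.rm = TRUE)) {
    stop("usd_per_daly must be positive where present")
  }
  ifelse(is.na(usd_per_daly), "unknown",
         ifelse(usd_per_daly < threshold, "cost_effective",
                "not_cost_effective"))
}

# upper bound of a (low, high) estimate pair; both ends must clear the
# threshold for the intervention to count as cost-effective
ce_upper <- function(estimates) {
  if ("usd_per_daly" %in% names(estimates)) return(estimates$usd_per_daly)
  if (all(c("usd_per_daly_low", "usd_per_daly_high") %in% names(estimates))) {
    return(pmax(estimates$usd_per_daly_low, estimates$usd_per_daly_high))
  }
  stop("estimates need 'usd_per_daly' or 'usd_per_daly_low'/'usd_per_daly_high'")
}

#' Cross-classify interventions by cost-effectiveness, EHP membership and
#' burden rank
#'
#' Screens every intervention against the $/DALY threshold and crosses
#' the result with whether it is already in the EHP and whether it
#' targets one of the leading diseases by burden.  Range estimates
#' ("$3-12/DALY") are judged by their upper bound.  The summary counts
#' are: EHP members that are cost-effective / not cost-effective /
#' unknown, and non-EHP candidates (cost-effective and targeting a
#' top-ranked disease).
#'
#' @param estimates data frame with columns `intervention`, `in_ehp`
#'   (logical), either `usd_per_daly` or `usd_per_daly_low` +
#'   `usd_per_daly_high` (NA where no estimate exists), and either a
#'   logical `targets_top20` or a `target_disease` column resolved
#'   against `top20`.
#' @param top20 optional character vector of leading disease names (from
#'   [top_diseases()]) used to derive `targets_top20`.
#' @param threshold $/DALY cutoff, default 150.
#' @return An `ehp_ce_screen`: list with the classified `table` (adds
#'   `threshold_class` and `targets_top20`) and `counts`
#'   (`ehp_cost_effective`, `ehp_not_cost_effective`, `ehp_unknown`,
#'   `candidates`).
#' @export
cross_classify <- function(estimates, top20 = NULL, threshold = 150) {
  if (nrow(estimates) == 0) stop("'estimates' must be non-empty")
  if (anyDuplicated(normalize_intervention(estimates$intervention))) {
    stop("duplicate intervention names in estimates")
  }
  if (!"in_ehp" %in% names(estimates)) stop("estimates need an 'in_ehp' column")

  tab <- tibble::as_tibble(estimates)
  if (!"targets_top20" %in% names(tab)) {
    if (is.null(top20) || !"target_disease" %in% names(tab)) {
      stop("supply a 'targets_top20' column, or 'target_disease' plus 'top20'")
    }
    tab$targets_top20 <- normalize_intervention(tab$target_disease) %in%
      normalize_intervention(top20)
  }
  tab$threshold_class <- classify_ce(ce_upper(tab), threshold)

  counts <- list(
    ehp_cost_effective     = sum(tab$in_ehp & tab$threshold_class == "cost_effective"),
    ehp_not_cost_effective = sum(tab$in_ehp & tab$threshold_class == "not_cost_effective"),
    ehp_unknown            = sum(tab$in_ehp & tab$threshold_class == "unknown"),
    candidates             = sum(!tab$in_ehp & tab$targets_top20 &
                                   tab$threshold_class == "cost_effective")
  )
  structure(list(table = tab, counts = counts, threshold = threshold),
            class = "ehp_ce_screen")
}

#' @export
print.ehp_ce_screen <- function(x, ...) {
  c <- x$counts
  cat(sprintf("CE screen at $%g/DALY over %d interventions\n",
              x$threshold, nrow(x$table)))
  cat(sprintf("  in EHP: %d cost-effective, %d not, %d unknown\n",
              c$ehp_cost_effective, c$ehp_not_cost_effective, c$ehp_unknown))
  cat(sprintf("  candidates outside EHP (cost-effective, top-burden): %d\n",
              c$candidates))
  invisible(x)
}

#' Ranked candidate interventions not yet in the EHP
#'
#' Cost-effective interventions outside the current package that target a
#' leading-burden disease, sorted ascending by $/DALY (ranges by their
#' midpoint, reported as the (low, high) pair).
#'
#' @param screen an `ehp_ce_screen` from [cross_classify()].
#' @return Tibble `intervention`, `usd_per_daly_low`, `usd_per_daly_high`,
#'   sorted by midpoint.
#' @export
candidate_report <- function(screen) {
  stopifnot(inherits(screen, "ehp_ce_screen"))
  tab <- screen$table
  sel <- !tab$in_ehp & tab$targets_top20 & tab$threshold_class == "cost_effective"
  out <- tab[sel, , drop = FALSE]
  if (!"usd_per_daly_low" %in% names(out)) {
    out$usd_per_daly_low <- out$usd_per_daly
    out$usd_per_daly_high <- out$usd_per_daly
  }
  mid <- (out$usd_per_daly_low + out$usd_per_daly_high) / 2
  out <- out[order(mid), c("intervention", "usd_per_daly_low", "usd_per_daly_high")]
  tibble::as_tibble(out)
}
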