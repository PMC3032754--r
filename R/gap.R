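#' Provision-to-need rate ratio
#'
#' The coverage achieved for one intervention: provision per 1000 divided
#' by need per 1000 (the gap table's b/a).  Below 1 the service is
#' underprovided; above 1, overprovided.
#'
#' @param need_a need in cases per 1000 population; must be positive.
#' @param provision_b provision in cases per 1000 population.
#' @param digits decimal places for the reported ratio (reports use 2);
#'   `NA` for the unrounded value.
#' @return `provision_b / need_a`.
#' @export
#' @examples
#' gap_ratio(140, 68.1)  # 0.49
gap_ratio <- function(need_a, provision_b, digits = 2) {
  if (any(need_a <= 0)) stop("need_a must be positive (coverage undefined)")
  if (any(provision_b < 0, na.rm = TRUE)) stop("provision_b must be non-negative")
  r <- provision_b / need_a
  if (is.na(digits)) r else round_half_up(r, digits)
}

#' Build a gap table from need and provision rates
#'
#' Joins needs to provisions by intervention name (exact after
#' normalization, with optional aliases), computes per-row ratios and the
#' totals-based aggregate gap `sum(b) / sum(a)`.  The aggregate weights
#' interventions by their totals; it is not the mean of the row ratios.
#' Interventions present on only one side are excluded from the totals and
#' listed in the `exclusions` attribute rather than silently dropped.
#'
#' @param needs data frame with columns `intervention` and
#'   `need_per_1000` (or `need_a`).
#' @param provisions data frame with columns `intervention` and
#'   `rate_per_1000` (or `provision_b`).
#' @param aliases optional alias map, see [normalize_intervention()].
#' @return A `gap_table`: tibble with `intervention`, `need_a`,
#'   `provision_b` and the unrounded `ratio`, in the needs' input order;
#'   attributes `total_need`, `total_provision`, `aggregate_gap`
#'   (unrounded) and `exclusions` (tibble of unmatched names with the
#'   side they came from).
#' @export
build_gap_table <- function(needs, provisions, aliases = NULL) {
  need_col <- intersect(c("need_per_1000", "need_a"), names(needs))[1]
  prov_col <- intersect(c("rate_per_1000", "provision_b"), names(provisions))[1]
  if (is.na(need_col) || is.na(prov_col)) {
    stop("needs require a 'need_per_1000' column and provisions a 'rate_per_1000' column")
  }
  nkey <- normalize_intervention(needs$intervention, aliases)
  pkey <- normalize_intervention(provisions$intervention, aliases)
  if (anyDuplicated(nkey)) stop("duplicate intervention names in needs")
  if (anyDuplicated(pkey)) stop("duplicate intervention names in provisions")

  idx <- match(nkey, pkey)
  prov <- provisions[[prov_col]][idx]
  matched <- !is.na(idx) & !is.na(prov)

  needs_only <- needs$intervention[!matched]
  prov_only <- provisions$intervention[is.na(match(pkey, nkey))]
  exclusions <- tibble::tibble(
    intervention = c(needs_only, prov_only),
    side = c(rep("needs_only", length(needs_only)),
             rep("provision_only", length(prov_only)))
  )
  if (nrow(exclusions) > 0) {
    warning(nrow(exclusions),
            " intervention(s) without a need/provision match excluded from totals: ",
            paste(utils::head(exclusions$intervention, 5), collapse = ", "),
            if (nrow(exclusions) > 5) ", ..." else "")
  }

  rows <- tibble::tibble(
    intervention = needs$intervention[matched],
    need_a       = needs[[need_col]][matched],
    provision_b  = prov[matched]
  )
  rows$ratio <- gap_ratio(rows$need_a, rows$provision_b, digits = NA)

  structure(rows,
            class = c("gap_table", class(rows)),
            total_need      = sum(rows$need_a),
            total_provision = sum(rows$provision_b),
            aggregate_gap   = sum(rows$provision_b) / sum(rows$need_a),
            exclusions      = exclusions)
}

#' Totals and aggregate gap of a gap table
#'
#' @param x a `gap_table` from [build_gap_table()].
#' @return List with `total_need`, `total_provision`, `aggregate_gap`
#'   (unrounded) and the `exclusions` tibble.
#' @export
gap_totals <- function(x) {
  stopifnot(inherits(x, "gap_table"))
  list(total_need      = attr(x, "total_need"),
       total_provision = attr(x, "total_provision"),
       aggregate_gap   = attr(x, "aggregate_gap"),
       exclusions      = attr(x, "exclusions"))
}

#' @export
print.gap_table <- function(x, digits = 2, ...) {
  t <- gap_totals(x)
  cat("Gap analysis:", nrow(x), "interventions\n")
  shown <- tibble::as_tibble(x)
  shown$ratio <- round_half_up(shown$ratio, digits)
  print(shown, ...)
  cat(sprintf("Total need %.1f, total provision %.1f per 1000; aggregate gap %.2f\n",
              t$total_need, t$total_provision,
              round_half_up(t$aggregate_gap, digits)))
  if (nrow(t$exclusions) > 0) {
    cat("Excluded (unmatched):", paste(t$exclusions$intervention, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify each intervention as over-, exactly, or under-provided
#'
#' Classification uses the ratio rounded to `digits` decimal places, so a
#' service whose unrounded ratio is 1.004 counts as exactly met, matching
#' how published tables report a ratio of 1.00.
#'
#' @param x a `gap_table`, or a numeric vector of ratios.
#' @param digits rounding applied before comparison (default 2).
#' @return For a vector, a character vector in
#'   `{overprovided, met, underprovided}`; for a `gap_table`, the table
#'   with a `class` column appended.
#' @export
classify_provision <- function(x, digits = 2) {
  if (inherits(x, "gap_table")) {
    x$class <- classify_provision(x$ratio, digits = digits)
    return(x)
  }
  r <- round_half_up(x, digits)
  ifelse(r > 1, "overprovided", ifelse(r == 1, "met", "underprovided"))
}

#' Interventions with severe provision gaps
#'
#' @param x a `gap_table`.
#' @param threshold ratio cutoff in \[0, 1); rows whose rounded ratio is
#'   at or below it are returned (0 flags only services with no provision
#'   at all).
#' @param digits rounding applied before comparison.
#' @return Tibble of flagged rows sorted ascending by ratio.
#' @export
flag_severe_gaps <- function(x, threshold = 0.5, digits = 2) {
  stopifnot(inherits(x, "gap_table"))
  if (threshold < 0 || threshold >= 1) stop("threshold must lie in [0, 1)")
  r <- round_half_up(x$ratio, digits)
  out <- tibble::as_tibble(x)[r <= threshold, , drop = FALSE]
  out[order(out$ratio), , drop = FALSE]
}
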