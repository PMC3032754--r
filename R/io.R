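# CSV schema readers.  All tables are UTF-8, comma-delimited, with a
# mandatory header row and "." decimal separator; empty fields are
# missing values, distinct from 0.

read_schema <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(d))
  if (length(miss) > 0) {
    stop(what, " file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  }
  d
}

check_complete <- function(d, cols, what) {
  for (col in cols) {
    bad <- which(is.na(d[[col]]))
    if (length(bad) > 0) {
      stop(what, ": missing '", col, "' in row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  invisible(d)
}

#' Read pipeline input tables
#'
#' Schema-checked CSV readers for the assessment inputs.  Missing
#' required columns, or missing values in key fields, raise errors naming
#' the offending column and rows.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @name readers
NULL

#' @describeIn readers need table: `intervention`, `need_per_1000`,
#'   optional `incidence`.
#' @export
read_need_table <- function(path) {
  d <- read_schema(path, c("intervention", "need_per_1000"), "need table")
  check_complete(d, c("intervention", "need_per_1000"), "need table")
}

#' @describeIn readers HMIS counts: `intervention`, `fiscal_year`,
#'   `denominator_class`, and `raw_count` or `rate_per_1000`.
#' @export
read_hmis_table <- function(path) {
  d <- read_schema(path, c("intervention", "fiscal_year",
                           "denominator_class"), "HMIS table")
  if (!any(c("raw_count", "rate_per_1000") %in% names(d))) {
    stop("HMIS table ", path, " needs a 'raw_count' or 'rate_per_1000' column")
  }
  check_complete(d, c("intervention", "fiscal_year", "denominator_class"),
                 "HMIS table")
}

#' @describeIn readers population denominators: `fiscal_year` plus
#'   denominator-class columns.
#' @export
read_denominator_table <- function(path) {
  read_schema(path, c("fiscal_year", "total"), "denominator table")
}

#' @describeIn readers CE estimates: `intervention`, `in_ehp`, and
#'   `usd_per_daly` or `usd_per_daly_low`/`usd_per_daly_high`.
#' @export
read_ce_table <- function(path) {
  d <- read_schema(path, c("intervention", "in_ehp"), "CE table")
  if (!"usd_per_daly" %in% names(d) &&
      !all(c("usd_per_daly_low", "usd_per_daly_high") %in% names(d))) {
    stop("CE table ", path,
         " needs 'usd_per_daly' or 'usd_per_daly_low'/'usd_per_daly_high'")
  }
  d
}

#' @describeIn readers funding series: `fiscal_year`, `expenditure_pc`,
#'   `required_pc`, `scope`.
#' @export
read_funding_table <- function(path) {
  read_schema(path, c("fiscal_year", "expenditure_pc", "required_pc",
                      "scope"), "funding table")
}

#' @describeIn readers burden table: `disease`, `stratum`, `dalys`.
#' @export
read_burden_table <- function(path) {
  d <- read_schema(path, c("disease", "stratum", "dalys"), "burden table")
  check_complete(d, c("disease", "dalys"), "burden table")
}

#' Write a gap table to CSV with its totals row
#'
#' Rounds ratios to the reporting precision and appends a `Total` row
#' carrying the column sums and the totals-based aggregate gap.
#'
#' @param x a `gap_table` (ideally after [classify_provision()]).
#' @param path output CSV path.
#' @param digits ratio rounding (need and provision are written as
#'   stored).
#' @return `path`, invisibly.
#' @export
write_gap_table <- function(x, path, digits = 2) {
  stopifnot(inherits(x, "gap_table"))
  t <- gap_totals(x)
  out <- tibble::as_tibble(x)
  out$ratio <- round_half_up(out$ratio, digits)
  total <- tibble::tibble(
    intervention = "Total",
    need_a = t$total_need,
    provision_b = t$total_provision,
    ratio = round_half_up(t$aggregate_gap, digits)
  )
  if ("class" %in% names(out)) total$class <- NA_character_
  readr::write_csv(dplyr::bind_rows(out, total), path, na = "")
  invisible(path)
}

#' Read a run configuration
#'
#' A YAML (or JSON) file naming the input tables and analysis settings:
#' paths `needs`, `hmis`, `denominators`, `ce`, `funding`, optional
#' `burden`; settings `year`, `threshold` (default 150), `top_n`
#' (default 20), `outdir`, optional `aliases` (variant: canonical map).
#'
#' @param path YAML file path.
#' @return A named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$threshold <- cfg$threshold %||% 150
  cfg$top_n <- cfg$top_n %||% 20
  if (is.null(cfg$year)) stop("run config must set 'year'")
  for (f in c("needs", "hmis", "ce", "funding")) {
    if (is.null(cfg[[f]])) stop("run config must name a '", f, "' file")
  }
  cfg
}

#' Run the full EHP assessment
#'
#' Orchestrates the pipeline end to end: provision rates for the report
#' year, the provision-to-need gap table with over/under-provision
#' classes, the cost-effectiveness screen crossed with burden rank, and
#' the funding summary.  Writes `gap.csv`, `ce_classification.csv`,
#' `funding_summary.csv` and a machine-readable `headline.json` to the
#' output directory.  The outputs are pure functions of the inputs and
#' configuration.
#'
#' @param config a list as returned by [read_run_config()], or a path to
#'   a YAML configuration.
#' @return Invisibly, a list with `gap` (classified gap table), `ce`
#'   (`ehp_ce_screen`), `funding` (summary tibble) and `headline` (the
#'   statistics written to JSON).
#' @export
run_full_assessment <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config$threshold <- config$threshold %||% 150
  config$top_n <- config$top_n %||% 20
  outdir <- config$outdir %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  aliases <- if (!is.null(config$aliases)) unlist(config$aliases)

  message("reading inputs")
  needs <- read_need_table(config$needs)
  hmis <- read_hmis_table(config$hmis)
  denominators <- if (!is.null(config$denominators)) {
    read_denominator_table(config$denominators)
  }
  ce <- read_ce_table(config$ce)
  funding <- read_funding_table(config$funding)
  message("  ", nrow(needs), " needs, ", nrow(hmis), " HMIS records, ",
          nrow(ce), " CE estimates")

  message("building provision rates for ", config$year)
  provision <- build_provision_table(hmis, denominators, config$year)

  message("gap analysis")
  gap <- build_gap_table(needs, provision, aliases = aliases)
  gap <- classify_provision(gap)
  totals <- gap_totals(gap)

  message("cost-effectiveness screen at $", config$threshold, "/DALY")
  top20 <- NULL
  if (!is.null(config$burden)) {
    burden <- read_burden_table(config$burden)
    ranked <- rank_diseases(burden, stratum = "persons")
    top20 <- top_diseases(ranked, config$top_n)
  }
  screen <- cross_classify(ce, top20 = top20, threshold = config$threshold)

  message("funding summary")
  fsum <- funding_summary(funding)

  class_counts <- table(factor(gap$class, levels = c("overprovided", "met",
                                                     "underprovided")))
  headline <- list(
    year = config$year,
    total_need = totals$total_need,
    total_provision = totals$total_provision,
    aggregate_gap = round_half_up(totals$aggregate_gap, 2),
    n_interventions = nrow(gap),
    n_excluded = nrow(totals$exclusions),
    n_overprovided = unname(class_counts[["overprovided"]]),
    n_met = unname(class_counts[["met"]]),
    n_underprovided = unname(class_counts[["underprovided"]]),
    ce_counts = screen$counts,
    funding = as.list(stats::setNames(fsum$mean_coverage, fsum$scope))
  )

  write_gap_table(gap, file.path(outdir, "gap.csv"))
  readr::write_csv(screen$table, file.path(outdir, "ce_classification.csv"),
                   na = "")
  readr::write_csv(fsum, file.path(outdir, "funding_summary.csv"), na = "")
  jsonlite::write_json(headline, file.path(outdir, "headline.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message("wrote gap.csv, ce_classification.csv, funding_summary.csv, ",
          "headline.json to ", outdir)

  invisible(list(gap = gap, ce = screen, funding = fsum, headline = headline))
}
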