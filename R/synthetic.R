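#' Configuration for the synthetic EHP data generator
#'
#' Defines the study conditions the generator emulates: a national
#' population split into the six denominator classes, per-intervention
#' true coverage fractions that drive HMIS counts, $/DALY values spread
#' around the screening threshold, and a funding series with a known
#' growth rate.  Defaults mirror the Malawi 2008 assessment: a
#' 13.07-million population, 20 ranked diseases, 49 EHP interventions,
#' coverage ratios spanning 0.05–1.45 (under- through over-provision),
#' a log-normal $/DALY distribution with about 73% of its mass below
#' $150 (the published 33-of-45 known-value split), 18% of estimates
#' missing (10 of 55), and six fiscal years of per-capita SWAp funding
#' growing from $7.9 at 11.3%/year (reaching $13.5 by year six).
#'
#' @param seed integer RNG seed; a fixed seed gives byte-identical
#'   generator output.
#' @param n_diseases number of diseases in the burden table.
#' @param n_interventions number of EHP interventions.
#' @param population_total national population in the reference (final)
#'   fiscal year.
#' @param denominator_fractions named fractions of the total population
#'   in each denominator class (each in (0, 1]; `total` must be 1).
#' @param true_coverage_range (low, high) range of true provision-to-need
#'   coverage fractions, within (0, 2] so over-provision is generatable.
#' @param ce_log_mean,ce_log_sd log-scale mean and sd of the $/DALY
#'   distribution.
#' @param ce_missing_prob probability an intervention has no $/DALY
#'   estimate.
#' @param n_years number of fiscal years.
#' @param start_year first fiscal year's starting calendar year.
#' @param funding_start per-capita SWAp expenditure (USD) in the first
#'   year.
#' @param funding_growth annual growth fraction of per-capita
#'   expenditure.
#' @param funding_required_start,funding_required_end per-capita required
#'   cost (USD) in the first and last years (interpolated linearly).
#' @param pop_growth annual population growth fraction (years before the
#'   reference year are scaled down accordingly).
#' @param total_dalys total disease burden (DALYs) to distribute.
#' @param count_noise dispersion of service counts: 0 for Poisson,
#'   > 0 for negative-binomial with variance `mu + count_noise * mu^2`.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_diseases = 20,
                             n_interventions = 49,
                             population_total = 13066000,
                             denominator_fractions = c(
                               total = 1, live_births = 0.045, under5 = 0.17,
                               over5 = 0.83, adult15plus = 0.52,
                               female15to45 = 0.22),
                             true_coverage_range = c(0.05, 1.45),
                             ce_log_mean = log(67),
                             ce_log_sd = 1.3,
                             ce_missing_prob = 10 / 55,
                             n_years = 6,
                             start_year = 2002,
                             funding_start = 7.9,
                             funding_growth = 0.113,
                             funding_required_start = 17.3,
                             funding_required_end = 28.6,
                             pop_growth = 0.028,
                             total_dalys = 7.5e6,
                             count_noise = 0) {
  if (any(denominator_fractions <= 0) || any(denominator_fractions > 1)) {
    stop("denominator fractions must lie in (0, 1]")
  }
  if (!all(denominator_classes() %in% names(denominator_fractions))) {
    stop("denominator_fractions must name all of: ",
         paste(denominator_classes(), collapse = ", "))
  }
  if (length(true_coverage_range) != 2 ||
      true_coverage_range[1] <= 0 || true_coverage_range[2] > 2 ||
      diff(true_coverage_range) < 0) {
    stop("true_coverage_range must be an increasing pair within (0, 2]")
  }
  if (ce_missing_prob < 0 || ce_missing_prob > 1) {
    stop("ce_missing_prob must lie in [0, 1]")
  }
  if (n_diseases < 1 || n_interventions < 1 || n_years < 1) {
    stop("n_diseases, n_interventions and n_years must be at least 1")
  }
  if (count_noise < 0) stop("count_noise must be non-negative")
  if (population_total <= 0) stop("population_total must be positive")
  structure(
    list(seed = as.integer(seed), n_diseases = n_diseases,
         n_interventions = n_interventions,
         population_total = population_total,
         denominator_fractions = denominator_fractions,
         true_coverage_range = true_coverage_range,
         ce_log_mean = ce_log_mean, ce_log_sd = ce_log_sd,
         ce_missing_prob = ce_missing_prob,
         n_years = n_years, start_year = start_year,
         funding_start = funding_start, funding_growth = funding_growth,
         funding_required_start = funding_required_start,
         funding_required_end = funding_required_end,
         pop_growth = pop_growth, total_dalys = total_dalys,
         count_noise = count_noise),
    class = "synthetic_config"
  )
}

# independent RNG stream per generator so results do not depend on the
# order the gen_* functions are called in
with_gen_seed <- function(config, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((config$seed * 131L + offset) %% 2147483647L)
  expr
}

#' Generate population denominators by fiscal year
#'
#' Deterministic given the configuration: the final year's total equals
#' `population_total`, earlier years are discounted by the annual
#' population growth rate, and each denominator class is its configured
#' fraction of that year's total.
#'
#' @param config a [synthetic_config()].
#' @return Tibble with one row per fiscal year and one column per
#'   denominator class (all counts positive).
#' @export
gen_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  years <- config$start_year + seq_len(config$n_years) - 1
  scale <- (1 + config$pop_growth)^(seq_along(years) - config$n_years)
  totals <- round(config$population_total * scale)
  out <- tibble::tibble(fiscal_year = fy_label(years))
  for (cls in denominator_classes()) {
    out[[cls]] <- round(totals * config$denominator_fractions[[cls]])
  }
  out
}

#' Generate a disease burden table with known true incidence
#'
#' DALY shares follow a jittered power-law (a few diseases dominate, as
#' in observed national burden tables), split into male and female strata
#' with a random share, with per-disease annual incidence drawn on a
#' scale loosely tied to burden.  The true incidences are retained as
#' ground truth and must never be fed to the pipeline under test.
#'
#' @param config a [synthetic_config()].
#' @return List with `burden` (tibble `disease`, `stratum`, `dalys`,
#'   `incidence`; strata persons/males/females, persons = males +
#'   females) and `truth` (named vector of true incidences).
#' @export
gen_burden_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_gen_seed(config, 1L, {
    n <- config$n_diseases
    disease <- sprintf("disease_%02d", seq_len(n))
    share <- seq_len(n)^-1.4 * exp(stats::rnorm(n, 0, 0.2))
    share <- share / sum(share)
    dalys <- config$total_dalys * share
    male_frac <- stats::runif(n, 0.35, 0.65)
    incidence <- dalys * exp(stats::rnorm(n, -0.7, 0.5))
    burden <- tibble::tibble(
      disease   = rep(disease, 3),
      stratum   = rep(c("persons", "males", "females"), each = n),
      dalys     = c(dalys, dalys * male_frac, dalys * (1 - male_frac)),
      incidence = c(incidence, incidence * male_frac,
                    incidence * (1 - male_frac))
    )
    list(burden = burden, truth = stats::setNames(incidence, disease))
  })
}

#' Generate an EHP intervention registry with true coverage fractions
#'
#' Each intervention is linked to a disease (cyclically), assigned a
#' denominator class, and given a need rate per 1000 of that class
#' derived from the disease's true incidence.  True coverage fractions
#' are drawn uniformly over the configured range and retained as ground
#' truth.
#'
#' @param config a [synthetic_config()].
#' @param burden output of [gen_burden_table()].
#' @return List with `needs` (tibble `intervention`, `disease`,
#'   `denominator_class`, `need_per_1000`, need expressed per 1000 of the
#'   intervention's own denominator class) and `truth` (named vector of
#'   true coverage fractions).
#' @export
gen_intervention_registry <- function(config, burden) {
  stopifnot(inherits(config, "synthetic_config"))
  with_gen_seed(config, 2L, {
    n <- config$n_interventions
    intervention <- sprintf("intervention_%02d", seq_len(n))
    disease <- sprintf("disease_%02d", (seq_len(n) - 1) %% config$n_diseases + 1)
    cls <- sample(denominator_classes(), n, replace = TRUE)
    pop <- gen_population(config)
    ref <- pop[nrow(pop), , drop = FALSE]
    denom <- vapply(cls, function(k) ref[[k]][1], numeric(1))
    incidence <- burden$truth[disease]
    # an intervention typically addresses a fraction of the disease's cases
    caseload <- incidence * stats::runif(n, 0.2, 1)
    needs <- tibble::tibble(
      intervention = intervention,
      disease = disease,
      denominator_class = cls,
      need_per_1000 = 1000 * caseload / denom
    )
    coverage <- stats::runif(n, config$true_coverage_range[1],
                             config$true_coverage_range[2])
    list(needs = needs, truth = stats::setNames(coverage, intervention))
  })
}

#' Generate HMIS service counts from true coverage
#'
#' Expected count for an intervention-year is
#' `true_coverage * need_per_1000 * denominator / 1000`; realised counts
#' are Poisson around that expectation (negative-binomial with dispersion
#' `count_noise` when `count_noise > 0`), or the rounded expectation
#' itself with `noise = "none"`.
#'
#' @param config a [synthetic_config()].
#' @param needs needs tibble from [gen_intervention_registry()] (columns
#'   `intervention`, `denominator_class`, `need_per_1000`).
#' @param truth named vector of true coverage fractions per intervention.
#' @param noise noise model; the default follows the configuration
#'   (`poisson` when `count_noise` is 0, else `negbin`).
#' @return Tibble `intervention`, `fiscal_year`, `denominator_class`,
#'   `raw_count` (non-negative integers).
#' @export
gen_hmis_counts <- function(config, needs, truth,
                            noise = c("auto", "poisson", "negbin", "none")) {
  stopifnot(inherits(config, "synthetic_config"))
  noise <- match.arg(noise)
  if (noise == "auto") {
    noise <- if (config$count_noise > 0) "negbin" else "poisson"
  }
  if (any(needs$need_per_1000 < 0)) stop("needs must be non-negative")
  pop <- gen_population(config)
  with_gen_seed(config, 3L, {
    grid <- expand.grid(i = seq_len(nrow(needs)), y = seq_len(nrow(pop)),
                        KEEP.OUT.ATTRS = FALSE)
    denom <- mapply(function(i, y) pop[[needs$denominator_class[i]]][y],
                    grid$i, grid$y)
    mu <- truth[needs$intervention[grid$i]] * needs$need_per_1000[grid$i] *
      denom / 1000
    count <- switch(noise,
      none    = round(mu),
      poisson = stats::rpois(length(mu), mu),
      negbin  = stats::rnbinom(length(mu), mu = mu,
                               size = 1 / config$count_noise)
    )
    tibble::tibble(
      intervention      = needs$intervention[grid$i],
      fiscal_year       = pop$fiscal_year[grid$y],
      denominator_class = needs$denominator_class[grid$i],
      raw_count         = as.numeric(count)
    )
  })
}

#' Generate a cost-effectiveness table around the screening threshold
#'
#' $/DALY values are log-normal with the configured parameters; a
#' configured fraction is missing (no published estimate); each
#' intervention carries EHP-membership and top-20-disease flags.
#'
#' @param config a [synthetic_config()].
#' @param n number of interventions (defaults to `n_interventions`).
#' @return Tibble `intervention`, `usd_per_daly` (NA where missing),
#'   `in_ehp`, `targets_top20`.
#' @export
gen_ce_table <- function(config, n = config$n_interventions) {
  stopifnot(inherits(config, "synthetic_config"))
  with_gen_seed(config, 4L, {
    usd <- stats::rlnorm(n, config$ce_log_mean, config$ce_log_sd)
    usd[stats::runif(n) < config$ce_missing_prob] <- NA_real_
    tibble::tibble(
      intervention  = sprintf("intervention_%02d", seq_len(n)),
      usd_per_daly  = usd,
      in_ehp        = stats::runif(n) < 0.8,
      targets_top20 = stats::runif(n) < 0.5
    )
  })
}

#' Generate a per-capita funding series with a known growth rate
#'
#' Deterministic: expenditure grows geometrically from `funding_start` at
#' `funding_growth` per year; required cost interpolates linearly between
#' its start and end values.
#'
#' @param config a [synthetic_config()].
#' @return List with `funding` (tibble `fiscal_year`, `expenditure_pc`,
#'   `required_pc`, `scope`) and `truth` (the growth rate).
#' @export
gen_funding_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  years <- config$start_year + seq_len(config$n_years) - 1
  k <- seq_along(years) - 1
  req <- if (config$n_years == 1) config$funding_required_start else {
    config$funding_required_start +
      k / (config$n_years - 1) *
        (config$funding_required_end - config$funding_required_start)
  }
  funding <- tibble::tibble(
    fiscal_year    = fy_label(years),
    expenditure_pc = config$funding_start * (1 + config$funding_growth)^k,
    required_pc    = req,
    scope          = "swap_ehp"
  )
  list(funding = funding, truth = config$funding_growth)
}

#' Generate and write a complete synthetic input bundle
#'
#' Runs every generator and writes the pipeline's CSV inputs plus a
#' `ground_truth.csv` (which must never be fed to the pipeline under
#' test) to `outdir`.
#'
#' @param config a [synthetic_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the generated tables, the ground truth
#'   and the written file paths.
#' @export
simulate_ehp_inputs <- function(config, outdir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pop <- gen_population(config)
  bt <- gen_burden_table(config)
  reg <- gen_intervention_registry(config, bt)
  hmis <- gen_hmis_counts(config, reg$needs, reg$truth)
  ce <- gen_ce_table(config)
  fund <- gen_funding_series(config)

  truth <- tibble::tibble(
    kind = c(rep("coverage", length(reg$truth)),
             rep("incidence", length(bt$truth)),
             "funding_growth"),
    name = c(names(reg$truth), names(bt$truth), "funding_growth"),
    value = c(unname(reg$truth), unname(bt$truth), fund$truth)
  )

  paths <- c(
    population = file.path(outdir, "population.csv"),
    burden     = file.path(outdir, "burden.csv"),
    needs      = file.path(outdir, "needs.csv"),
    hmis       = file.path(outdir, "hmis.csv"),
    ce         = file.path(outdir, "ce.csv"),
    funding    = file.path(outdir, "funding.csv"),
    truth      = file.path(outdir, "ground_truth.csv")
  )
  readr::write_csv(pop, paths[["population"]])
  readr::write_csv(bt$burden, paths[["burden"]])
  readr::write_csv(reg$needs, paths[["needs"]])
  readr::write_csv(hmis, paths[["hmis"]])
  readr::write_csv(ce, paths[["ce"]])
  readr::write_csv(fund$funding, paths[["funding"]])
  readr::write_csv(truth, paths[["truth"]])

  invisible(list(population = pop, burden = bt$burden, needs = reg$needs,
                 hmis = hmis, ce = ce, funding = fund$funding,
                 truth = list(coverage = reg$truth, incidence = bt$truth,
                              funding_growth = fund$truth),
                 paths = paths))
}
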