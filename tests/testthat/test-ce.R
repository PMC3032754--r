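test_that("threshold classification matches the published examples", {
  expect_equal(classify_ce(7), "cost_effective")       # DTP/measles
  expect_equal(classify_ce(298), "not_cost_effective") # pentavaccine
  expect_equal(classify_ce(1060), "not_cost_effective")
  expect_equal(classify_ce(922), "not_cost_effective") # ART
  expect_equal(classify_ce(NA), "unknown")
  # strict inequality: exactly $150/DALY is not below the cutoff
  expect_equal(classify_ce(150), "not_cost_effective")
  expect_equal(classify_ce(149.99), "cost_effective")
  expect_error(classify_ce(-5), "positive")
  expect_error(classify_ce(10, threshold = 0), "positive")
})

test_that("classification is monotone in the threshold and partitions input", {
  vals <- c(3, 12, 39, 129, 150, 225, 298, 922, 1060, NA)
  for (th in c(50, 150, 500, 2000)) {
    cls <- classify_ce(vals, th)
    expect_equal(sum(cls == "cost_effective") +
                   sum(cls == "not_cost_effective") +
                   sum(cls == "unknown"), length(vals))
  }
  # raising the threshold never demotes an intervention
  lo <- classify_ce(vals, 150)
  hi <- classify_ce(vals, 500)
  expect_false(any(lo == "cost_effective" & hi == "not_cost_effective"))
})

test_that("cross-classification screens the published quoted values", {
  ce <- ehp_fixture("ce")
  s <- cross_classify(ce)
  tab <- s$table
  expect_equal(tab$threshold_class[tab$intervention == "DTP and measles vaccines"],
               "cost_effective")
  expect_equal(tab$threshold_class[tab$intervention == "Antiretroviral therapy"],
               "not_cost_effective")
  # the ART flag marks external funding but does not change its class
  expect_true(tab$externally_funded[tab$intervention == "Antiretroviral therapy"])
  # range $3-12 is judged by its upper bound, still under $150
  expect_equal(tab$threshold_class[tab$intervention == "IPPT of malaria in children"],
               "cost_effective")
  expect_equal(s$counts$ehp_cost_effective +
                 s$counts$ehp_not_cost_effective + s$counts$ehp_unknown,
               sum(tab$in_ehp))

  expect_error(cross_classify(ce[c(1, 1, 2), ]), "duplicate")
})

test_that("candidates are the cost-effective non-EHP interventions, ranked", {
  ce <- ehp_fixture("ce")
  rep <- candidate_report(cross_classify(ce))
  expect_true("IPPT of malaria in children" %in% rep$intervention)
  expect_true("Home made ORS" %in% rep$intervention)
  # range kept as a (low, high) pair
  ippt <- rep[rep$intervention == "IPPT of malaria in children", ]
  expect_equal(c(ippt$usd_per_daly_low, ippt$usd_per_daly_high), c(3, 12))
  # supplementary feeding ($225) is over threshold, never a candidate
  expect_false("Supplementary feeding for children" %in% rep$intervention)
  # sorted ascending by midpoint
  mids <- (rep$usd_per_daly_low + rep$usd_per_daly_high) / 2
  expect_true(all(diff(mids) >= 0))

  none <- candidate_report(cross_classify(ce[ce$in_ehp, ]))
  expect_equal(nrow(none), 0)
})

test_that("all-missing estimates all classify unknown", {
  est <- tibble::tibble(intervention = letters[1:4],
                        usd_per_daly = NA_real_,
                        in_ehp = TRUE, targets_top20 = FALSE)
  s <- cross_classify(est)
  expect_equal(s$counts$ehp_unknown, 4)
  expect_equal(s$counts$ehp_cost_effective, 0)
  expect_equal(s$counts$candidates, 0)
})

test_that("synthetic CE tables recover the log-normal cost-effective share", {
  cfg <- synthetic_config(seed = 11, n_interventions = 1e4,
                          ce_missing_prob = 0)
  ce <- gen_ce_table(cfg)
  frac <- mean(classify_ce(ce$usd_per_daly) == "cost_effective")
  expect_equal(frac, plnorm(150, cfg$ce_log_mean, cfg$ce_log_sd),
               tolerance = 0.02)

  # degenerate spreads behave as configured
  flat <- gen_ce_table(synthetic_config(seed = 3, n_interventions = 50,
                                        ce_log_sd = 0, ce_missing_prob = 0))
  expect_true(all(flat$usd_per_daly == exp(log(67))))
  gone <- gen_ce_table(synthetic_config(seed = 3, n_interventions = 50,
                                        ce_missing_prob = 1))
  expect_true(all(classify_ce(gone$usd_per_daly) == "unknown"))
})
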