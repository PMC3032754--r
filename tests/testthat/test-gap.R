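test_that("gap ratio matches published spot values", {
  expect_equal(gap_ratio(140, 68.1), 0.49)
  expect_equal(gap_ratio(9.8, 0.8), 0.08)
  expect_equal(gap_ratio(77.7, 77.7), 1)
  expect_error(gap_ratio(0, 5), "positive")
  expect_error(gap_ratio(-1, 5), "positive")
  expect_error(gap_ratio(10, -1), "non-negative")
})

test_that("gap table reproduces published totals and the totals-based aggregate", {
  inp <- fixture_gap_inputs()
  g <- build_gap_table(inp$needs, inp$provisions)
  t <- gap_totals(g)
  expect_equal(nrow(g), 49)
  expect_equal(t$total_need, 1931.6, tolerance = 1e-9)
  expect_equal(t$total_provision, 1311.3, tolerance = 1e-9)
  expect_equal(round_half_up(t$aggregate_gap, 2), 0.68)
  # the aggregate weights by totals; the mean of row ratios differs
  expect_equal(round_half_up(mean(g$ratio), 2), 0.66)

  single <- build_gap_table(
    data.frame(intervention = "x", need_per_1000 = 10),
    data.frame(intervention = "x", rate_per_1000 = 5))
  st <- gap_totals(single)
  expect_equal(c(st$total_need, st$total_provision, st$aggregate_gap),
               c(10, 5, 0.5))
})

test_that("aggregate gap is invariant to row order and common rescaling", {
  inp <- fixture_gap_inputs()
  base <- gap_totals(build_gap_table(inp$needs, inp$provisions))$aggregate_gap

  perm <- sample(nrow(inp$needs))
  shuffled <- gap_totals(build_gap_table(inp$needs[perm, ],
                                         inp$provisions))$aggregate_gap
  expect_equal(shuffled, base)

  scaled_needs <- inp$needs
  scaled_prov <- inp$provisions
  scaled_needs$need_per_1000 <- scaled_needs$need_per_1000 * 3.7
  scaled_prov$rate_per_1000 <- scaled_prov$rate_per_1000 * 3.7
  gs <- build_gap_table(scaled_needs, scaled_prov)
  expect_equal(gap_totals(gs)$aggregate_gap, base)
  expect_equal(gs$ratio, build_gap_table(inp$needs, inp$provisions)$ratio)
})

test_that("unmatched interventions are excluded from totals and reported", {
  needs <- data.frame(intervention = c("a", "b", "ghost"),
                      need_per_1000 = c(10, 20, 5))
  prov <- data.frame(intervention = c("a", "b", "orphan"),
                     rate_per_1000 = c(5, 10, 1))
  expect_warning(g <- build_gap_table(needs, prov), "ghost")
  ex <- gap_totals(g)$exclusions
  expect_setequal(ex$intervention, c("ghost", "orphan"))
  expect_equal(gap_totals(g)$total_need, 30)
  expect_error(
    suppressWarnings(build_gap_table(rbind(needs, needs[1, ]), prov)),
    "duplicate")
})

test_that("provision classes partition the fixture as published", {
  inp <- fixture_gap_inputs()
  g <- classify_provision(build_gap_table(inp$needs, inp$provisions))
  counts <- table(g$class)
  expect_equal(sum(counts), nrow(g))

  # exactly the two malaria treatment services are overprovided
  over <- g$intervention[g$class == "overprovided"]
  expect_length(over, 2)
  expect_setequal(over, c("Malaria - under 5", "Malaria - 5 and over"))

  # growth monitoring is 1.0044 unrounded but reports as met
  gm <- g[g$intervention == "Growth Monitoring of U5 Children", ]
  expect_gt(gm$ratio, 1)
  expect_equal(gm$class, "met")
  expect_equal(unname(counts["met"]), 7)
  expect_equal(unname(counts["underprovided"]), 40)
})

test_that("severe-gap flagging returns the worst-served interventions", {
  inp <- fixture_gap_inputs()
  g <- build_gap_table(inp$needs, inp$provisions)

  worst <- flag_severe_gaps(g, 0.10)
  expect_equal(worst$intervention,
               c("Prevention of MTC transmission", "Newborn Complications",
                 "Treatment of Dehydration in U5s"))

  half <- flag_severe_gaps(g, 0.52)
  expect_true(all(c("Normal Delivery", "ARI in under-5s") %in%
                    half$intervention))
  expect_true(all(diff(half$ratio) >= 0))
  expect_equal(nrow(flag_severe_gaps(g, 0)), 0)
  expect_error(flag_severe_gaps(g, 1), "\\[0, 1\\)")
})
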