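# independent oracle for time-discounted year streams: brute-force
# numerical integration of exp(-r t) over (0, L)
discount_oracle <- function(n, duration, rate) {
  n * stats::integrate(function(t) exp(-rate * t), 0, duration,
                       rel.tol = 1e-10)$value
}

# the packaged gap table split into the pipeline's two input tables
fixture_gap_inputs <- function() {
  gap <- ehp_fixture("gap")
  list(
    needs = data.frame(intervention = gap$intervention,
                       incidence = gap$incidence,
                       need_per_1000 = gap$need_a),
    provisions = data.frame(intervention = gap$intervention,
                            rate_per_1000 = gap$provision_b),
    printed_ratio = gap$ratio
  )
}

# multi-year pooled coverage estimate: total counts over all years
# divided by the counts expected at full coverage
pooled_coverage_estimate <- function(config, needs, hmis) {
  pop <- gen_population(config)
  totals <- stats::aggregate(raw_count ~ intervention, hmis, sum)
  denom_sum <- vapply(needs$denominator_class,
                      function(k) sum(pop[[k]]), numeric(1))
  expected_full <- needs$need_per_1000 * denom_sum / 1000
  est <- totals$raw_count[match(needs$intervention, totals$intervention)] /
    expected_full
  stats::setNames(est, needs$intervention)
}
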