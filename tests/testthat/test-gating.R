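test_that("FMO threshold follows the exact tail-count rule", {
  # distinct values 1..10000 at q = 3e-4: cutoff 9997, exactly 3 above
  expect_equal(calibrate_fmo_threshold(1:10000), 9997)
  expect_equal(sum(1:10000 > 9997), 3)
  # tie-saturated input: cutoff is the common value, nothing above
  expect_equal(calibrate_fmo_threshold(rep(5, 4000)), 5)
  # order must not matter
  expect_equal(calibrate_fmo_threshold(sample(1:10000)), 9997)
  expect_error(calibrate_fmo_threshold(numeric(0)), class = "gating_error")
  expect_error(calibrate_fmo_threshold(1:100, q = 0.5),
               class = "gating_error")
  expect_warning(calibrate_fmo_threshold(1:100, q = 3e-4), "recommended")
})

test_that("the calibrated cutoff admits at most q of its own sample, for arbitrary ties", {
  withr::local_seed(21)
  for (i in 1:50) {
    n <- sample(3400:20000, 1)
    x <- switch(1 + i %% 3,
                rnorm(n),
                round(rlnorm(n, 5, 1)),            # heavy ties
                sample(1:20, n, replace = TRUE))   # massive ties
    q <- 3e-4
    cut <- calibrate_fmo_threshold(x, q)
    expect_lte(sum(x > cut) / n, q)
    # cutoff is the smallest event value satisfying the contract
    smaller <- unique(x[x < cut])
    if (length(smaller) > 0)
      expect_gt(sum(x > max(smaller)) / n, q)
  }
})

test_that("doublet exclusion removes geometry outliers, not singlets", {
  sc0 <- clean_scenario(n = 20000, doublet_rate = 0)
  s0 <- simulate_sample(sc0, "4T1", 7, "rep1")
  kept <- exclude_doublets(s0$events)
  expect_gte(nrow(kept$values) / 20000, 0.99)

  sc <- clean_scenario(n = 20000, doublet_rate = 0.10)
  s <- simulate_sample(sc, "4T1", 7, "rep1")
  filt <- exclude_doublets(s$events)
  removed <- !attr(filt, "kept")
  expect_gte(mean(removed), 0.08)
  expect_lte(mean(removed), 0.12)
  # at least 90% of what was removed is truly a doublet
  expect_gte(mean(s$truth$doublet[removed]), 0.90)
  expect_lte(nrow(filt$values), nrow(s$events$values))
})

test_that("viability and lineage gates retain the configured fractions", {
  sc <- clean_scenario(n = 20000, dead_fraction = 0.2)
  s <- simulate_sample(sc, "4T1", 7, "rep1")
  cut <- calibrate_negative_cutoff(
    simulate_unstained(sc, seed = 1L), "viability")
  live <- viability_gate(s$events, cut)
  expect_lt(abs(nrow(live$values) / 20000 - 0.8), 0.02)
  expect_equal(nrow(viability_gate(s$events, Inf)$values), 20000)

  sc0 <- clean_scenario(n = 20000)
  s0 <- simulate_sample(sc0, "4T1", 7, "rep1")
  expect_gte(nrow(viability_gate(s0$events,
                                 cut)$values) / 20000, 0.99)

  # 30% lineage-positive contaminants
  scl <- scenario_config(
    populations = list(population_template("fc", c("FAPa", "CD26")),
                       population_template("lin", lineage_positive = TRUE)),
    abundance = data.frame(tumour_type = "4T1", day = 7,
                           population = c("fc", "lin"),
                           fraction = c(0.7, 0.3)),
    doublet_rate = 0, dead_fraction = 0, events_per_sample = 20000)
  sl <- simulate_sample(scl, "4T1", 7, "rep1")
  lcut <- calibrate_negative_cutoff(
    simulate_unstained(scl, seed = 2L), "lineage_dump")
  linneg <- lineage_gate(sl$events, lcut)
  expect_lt(abs(nrow(linneg$values) / 20000 - 0.7), 0.02)
  expect_lte(nrow(linneg$values), nrow(sl$events$values))
})

test_that("marker calls agree with ground truth for a bright two-marker template", {
  sc <- clean_scenario(n = 20000, spillover = default_spillover())
  spill <- sc$spillover
  fmos <- simulate_fmo_set(sc)
  thr <- calibrate_fmo_set(fmos, spill = spill)
  s <- simulate_sample(sc, "4T1", 7, "rep1")
  comp <- apply_compensation(s$events, spill)
  calls <- call_markers(comp, thr)
  exact <- calls[, "FAPa"] & calls[, "CD26"] &
    rowSums(calls[, c("aSMA", "PDGFRa", "PDGFRb", "PDPN")]) == 0
  expect_gte(mean(exact), 0.95)

  # degenerate cutoffs
  zero <- event_table(matrix(0, 5, nrow(sc$panel),
                             dimnames = list(NULL, sc$panel$detector)),
                      sc$panel)
  expect_false(any(call_markers(zero, thr$cutoffs)))
  low <- setNames(rep(-1, 6), caf_markers())
  expect_true(all(call_markers(zero, low)))
})

test_that("the gating tree nests monotonically and partitions Lin- into CAF+/CAF-", {
  sc <- default_scenario(events_per_sample = 20000)
  spill <- sc$spillover
  uns <- apply_compensation(simulate_unstained(sc), spill)
  thr <- calibrate_fmo_set(simulate_fmo_set(sc), spill = spill)
  s <- simulate_sample(sc, "4T1", 14, "rep1")
  g <- apply_gating_tree(apply_compensation(s$events, spill), thr,
                         viability_cutoff =
                           calibrate_negative_cutoff(uns, "viability"),
                         lineage_cutoff =
                           calibrate_negative_cutoff(uns, "lineage_dump"))
  cnt <- setNames(g$summary$count, g$summary$population)
  expect_true(all(diff(cnt[c("cells", "singlets", "live", "lin_neg")]) <= 0))
  expect_identical(cnt[["caf_pos"]] + cnt[["caf_neg"]], cnt[["lin_neg"]])
  expect_false(any(g$membership[, "caf_pos"] & g$membership[, "caf_neg"]))
  expect_equal(nrow(g$marker_calls), cnt[["lin_neg"]])

  # uncompensated input is refused unless explicitly allowed
  expect_error(apply_gating_tree(s$events, thr, Inf, Inf),
               class = "gating_error")
  expect_s3_class(apply_gating_tree(s$events, thr, Inf, Inf,
                                    allow_uncompensated = TRUE),
                  "gating_result")
})

test_that("all-negative fibroblasts yield under 1% CAF+ of Lin-", {
  sc <- scenario_config(
    populations = list(population_template("neg")),
    abundance = data.frame(tumour_type = "4T1", day = 7,
                           population = "neg", fraction = 1),
    doublet_rate = 0, dead_fraction = 0, events_per_sample = 20000)
  thr <- calibrate_fmo_set(simulate_fmo_set(sc))
  s <- simulate_sample(sc, "4T1", 7, "rep1")
  g <- apply_gating_tree(s$events, thr, Inf, Inf,
                         allow_uncompensated = TRUE)
  caf_pct <- with(g$summary, pct_of_parent[population == "caf_pos"])
  expect_lte(caf_pct, 1)
})
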