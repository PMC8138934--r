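test_that("subset enumeration is complete, ordered and bijective", {
  s6 <- enumerate_subsets(caf_markers())
  expect_equal(nrow(s6), 63)
  expect_equal(s6$index, 1:63)
  expect_equal(anyDuplicated(s6$label), 0)
  # label <-> bits bijection: rebuild the index from the bits
  bits <- as.matrix(s6[caf_markers()])
  expect_equal(as.integer(bits %*% 2^(0:5)), s6$index)
  expect_equal(s6$label[1], "aSMA+")
  expect_equal(s6$label[32], "PDPN+")  # bit 6 alone = 32
  expect_equal(nrow(enumerate_subsets("FAPa")), 1)
  expect_equal(nrow(enumerate_subsets(c("a", "b", "c"))), 7)
  expect_error(enumerate_subsets(character(0)),
               class = "composition_error")
})

test_that("subset assignment partitions calls and matches brute-force cross-tabulation", {
  expect_equal(assign_subset(rep(FALSE, 6)), 0L)  # CAF- sentinel
  expect_equal(assign_subset(c(TRUE, rep(FALSE, 5))), 1L)
  expect_equal(enumerate_subsets()$label[1], "aSMA+")

  withr::local_seed(8)
  calls <- matrix(runif(10000 * 6) < 0.35, ncol = 6,
                  dimnames = list(NULL, caf_markers()))
  idx <- assign_subset(calls)
  expect_equal(length(idx), 10000)
  # oracle: 6-way cross-tabulation, tallied independently
  key <- apply(calls, 1, function(r) paste(as.integer(r), collapse = ""))
  oracle <- table(key)
  for (k in names(oracle)) {
    bits <- as.logical(as.integer(strsplit(k, "")[[1]]))
    expect_equal(sum(idx == assign_subset(bits)),
                 as.integer(oracle[[k]]))
  }
})

make_profile <- function(calls, meta = sample_meta("p1", "4T1", 7, "rep1"),
                         n_other_lin = 10) {
  g <- structure(list(
    membership = NULL,
    summary = data.frame(
      population = c("cells", "singlets", "live", "lin_neg", "caf_pos",
                     "caf_neg"),
      count = c(nrow(calls) + n_other_lin + 20,
                nrow(calls) + n_other_lin + 10,
                nrow(calls) + n_other_lin + 5, nrow(calls) + n_other_lin,
                sum(rowSums(calls) > 0),
                nrow(calls) + n_other_lin - sum(rowSums(calls) > 0)),
      parent_count = 1, pct_of_parent = 1, pct_of_live = 1),
    marker_calls = calls, n_events = nrow(calls) + 30,
    sample_meta = meta), class = "gating_result")
  composition_profile(g)
}

test_that("composition profiles satisfy the partition and marker-marginal identities", {
  withr::local_seed(9)
  calls <- matrix(runif(5000 * 6) < 0.3, ncol = 6,
                  dimnames = list(NULL, caf_markers()))
  p <- make_profile(calls)
  expect_equal(sum(p$subset_fractions), 1, tolerance = 1e-9)
  expect_equal(sum(p$subset_counts) ,
               sum(assign_subset(calls) > 0))
  subs <- enumerate_subsets()
  for (m in caf_markers())
    expect_identical(p$per_marker_of_caf_pos[[m]],
                     sum(p$subset_fractions[subs[[m]]]))
  expect_true(all(p$subset_fractions >= 0 & p$subset_fractions <= 1))
})

test_that("a pure single-subset sample concentrates its profile on that subset", {
  calls <- matrix(FALSE, 100, 6, dimnames = list(NULL, caf_markers()))
  calls[, "FAPa"] <- TRUE
  p <- make_profile(calls)
  expect_equal(unname(p$subset_fractions[["FAPa+"]]), 1)
  expect_equal(sum(p$subset_fractions > 0), 1)
})

test_that("a configured 50/30/20 mixture is recovered within 1 percentage point", {
  sc <- scenario_config(
    populations = list(population_template("a", "FAPa"),
                       population_template("b", c("FAPa", "CD26")),
                       population_template("c", "PDGFRb")),
    abundance = data.frame(tumour_type = "4T1", day = 7,
                           population = c("a", "b", "c"),
                           fraction = c(0.5, 0.3, 0.2)),
    doublet_rate = 0, dead_fraction = 0, events_per_sample = 50000)
  thr <- calibrate_fmo_set(simulate_fmo_set(sc))
  s <- simulate_sample(sc, "4T1", 7, "rep1")
  g <- apply_gating_tree(s$events, thr, Inf, Inf,
                         allow_uncompensated = TRUE)
  p <- composition_profile(g)
  expect_lt(abs(p$subset_fractions[["FAPa+"]] - 0.5), 0.01)
  expect_lt(abs(p$subset_fractions[["FAPa+CD26+"]] - 0.3), 0.01)
  expect_lt(abs(p$subset_fractions[["PDGFRb+"]] - 0.2), 0.01)
})

test_that("zero-CAF+ samples are flagged and excluded from group summaries with a warning", {
  calls <- matrix(FALSE, 50, 6, dimnames = list(NULL, caf_markers()))
  p0 <- make_profile(calls)
  expect_equal(p0$n_caf_pos, 0)
  expect_true(all(is.na(p0$subset_fractions)))
  withr::local_seed(10)
  ok <- make_profile(matrix(runif(300) < 0.4, ncol = 6,
                            dimnames = list(NULL, caf_markers())))
  expect_warning(rk <- abundance_ranking(list(ok, p0)), "excluded")
  expect_equal(nrow(rk), 63)
})

test_that("abundance ranking orders by group mean with SEM and monotone top-k coverage", {
  withr::local_seed(11)
  mk <- function(id, bias) {
    calls <- matrix(runif(2000 * 6) < bias, ncol = 6,
                    dimnames = list(NULL, caf_markers()))
    make_profile(calls, sample_meta(id, "4T1", 7, "rep1"))
  }
  profs <- list(mk("a", 0.4), mk("b", 0.4), mk("c", 0.4))
  rk <- abundance_ranking(profs)
  expect_equal(rk$rank, 1:63)
  expect_true(all(diff(rk$mean_pct) <= 1e-12))
  expect_true(all(diff(rk$cum_pct) >= -1e-12))
  expect_lte(max(rk$cum_pct), 100 + 1e-9)
  expect_gte(rk$cum_pct[5], rk$cum_pct[1])
  # identical profiles give SEM 0
  same <- list(mk("a", 0.4), mk("a", 0.4))
  same[[2]] <- same[[1]]
  expect_equal(max(abundance_ranking(same)$sem_pct), 0)
  # a one-subset group has top-1 coverage 100%
  single <- make_profile(matrix(rep(c(TRUE, rep(FALSE, 5)), each = 50),
                                50, 6,
                                dimnames = list(NULL, caf_markers())))
  rk1 <- abundance_ranking(list(single, single))
  expect_equal(rk1$cum_pct[1], 100)
})

test_that("heatmap matrix is consistent with the profiles and sums to 100 per sample", {
  withr::local_seed(12)
  profs <- lapply(1:4, function(i) {
    calls <- matrix(runif(1200) < 0.4, ncol = 6,
                    dimnames = list(NULL, caf_markers()))
    make_profile(calls, sample_meta(paste0("s", i),
                                    c("4T1", "4T07")[1 + i %% 2],
                                    7, "rep1"))
  })
  hm <- heatmap_matrix(profs)
  expect_equal(dim(hm$matrix), c(63L, 4L))
  expect_equal(unname(colSums(hm$matrix)), rep(100, 4), tolerance = 1e-6)
  for (p in profs)
    expect_equal(unname(hm$matrix[, p$sample_id]),
                 unname(100 * p$subset_fractions))
})

test_that("pie slices sum to 1 and marker arcs equal the mean marker marginals", {
  withr::local_seed(13)
  profs <- lapply(1:3, function(i)
    make_profile(matrix(runif(1800) < 0.35, ncol = 6,
                        dimnames = list(NULL, caf_markers())),
                 sample_meta(paste0("s", i), "4T1", 7, "rep1")))
  pie <- pie_arc_data(profs)
  expect_equal(sum(pie$slices), 1, tolerance = 1e-9)
  mean_marg <- colMeans(do.call(rbind, lapply(profs, function(p)
    p$per_marker_of_caf_pos)))
  for (m in caf_markers())
    expect_equal(pie$arcs[[m]]$total, mean_marg[[m]], tolerance = 1e-9)
  # arcs of a single-subset profile cover only that slice
  single <- make_profile(matrix(rep(c(TRUE, TRUE, rep(FALSE, 4)),
                                    each = 40), 40, 6, byrow = FALSE,
                                dimnames = list(NULL, caf_markers())))
  pie1 <- pie_arc_data(list(single))
  on <- which(pie1$slices > 0)
  expect_equal(unname(on), 3L)  # aSMA+FAPa+ has index 3
  expect_equal(pie1$arcs[["aSMA"]]$total, 1)
  expect_equal(pie1$arcs[["CD26"]]$total, 0)
})

test_that("composition_table flattens profiles with subset and marker columns", {
  withr::local_seed(14)
  profs <- lapply(1:2, function(i)
    make_profile(matrix(runif(1200) < 0.4, ncol = 6,
                        dimnames = list(NULL, caf_markers())),
                 sample_meta(paste0("s", i), "4T1", 14, "rep2")))
  tab <- composition_table(profs)
  expect_equal(nrow(tab), 2)
  expect_true(all(sprintf("S%d", 1:63) %in% names(tab)))
  expect_equal(rowSums(tab[sprintf("S%d", 1:63)]), c(100, 100),
               tolerance = 1e-9)
})
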