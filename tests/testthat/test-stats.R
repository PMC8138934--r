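test_that("permutation test returns p = 1 for identical groups", {
  prof <- matrix(rep(c(0.5, 0.3, 0.2), each = 3), nrow = 3)
  res <- composition_permutation_test(prof, prof, n_perm = 1000)
  expect_equal(res$observed_statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("exhaustive 3-vs-3 mode matches an independent brute-force enumeration", {
  withr::local_seed(15)
  A <- matrix(runif(3 * 5), 3)
  B <- matrix(runif(3 * 5), 3)
  res <- composition_permutation_test(A, B, n_perm = 1000)
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, 20)  # C(6,3)

  # oracle: enumerate all 20 splits with nested loops
  X <- rbind(A, B)
  t_obs <- sum(abs(colMeans(A) - colMeans(B)))
  tnull <- c()
  for (i in 1:4) for (j in (i + 1):5) for (k in (j + 1):6) {
    ia <- c(i, j, k)
    tnull <- c(tnull, sum(abs(colMeans(X[ia, , drop = FALSE]) -
                                colMeans(X[-ia, , drop = FALSE]))))
  }
  expect_equal(sort(res$null_statistics), sort(tnull))
  expect_equal(res$p_value, mean(tnull >= t_obs - 1e-12))
})

test_that("sampled and exhaustive p-values agree within Monte Carlo error", {
  withr::local_seed(16)
  A <- matrix(runif(4 * 8), 4)
  B <- matrix(runif(4 * 8), 4) + 0.08
  ex <- composition_permutation_test(A, B, n_perm = 10000)
  expect_true(ex$exhaustive)
  sam <- composition_permutation_test(A, B, n_perm = 4000,
                                      exhaustive = FALSE, seed = 2L)
  se <- sqrt(ex$p_value * (1 - ex$p_value) / 4000)
  expect_lt(abs(sam$p_value - ex$p_value), 3 * se + 1 / 4000)
  # sampled p can never be zero
  expect_gte(sam$p_value, 1 / 4001)
})

test_that("permutation test validates group sizes and budget", {
  prof <- matrix(runif(9), 3)
  expect_error(composition_permutation_test(prof[1, , drop = FALSE], prof),
               class = "stats_error")
  expect_warning(composition_permutation_test(prof, prof, n_perm = 50),
                 "coarse")
})

test_that("Welch statistics match t.test and reduce to Student's t under equal n and variance", {
  withr::local_seed(17)
  x <- rnorm(12, 1, 2); y <- rnorm(9, 0, 3)
  w <- cafcyto:::welch_test(x, y)
  ref <- t.test(x, y)
  expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(w$p, ref$p.value, tolerance = 1e-12)

  # equal variance and n: Welch df = classical df, statistic identical
  x2 <- rnorm(10); y2 <- x2 + 1 - mean(x2) # equal sample variance
  y2 <- y2 * sd(x2) / sd(y2)
  st <- t.test(x2, y2, var.equal = TRUE)
  we <- cafcyto:::welch_test(x2, y2)
  expect_equal(we$statistic, unname(st$statistic), tolerance = 1e-10)

  # identical constant groups: statistic 0, p 1, no discovery
  d <- data.frame(comparison = "c1", group = rep(c("a", "b"), each = 3),
                  value = rep(5, 6))
  tab <- welch_t_fdr(d)
  expect_equal(tab$statistic, 0)
  expect_false(tab$discovery)
})

test_that("a 5-sigma effect is discovered even alone at Q = 1%", {
  withr::local_seed(18)
  d <- data.frame(comparison = "c1", group = rep(c("a", "b"), each = 10),
                  value = c(rnorm(10, 0, 1), rnorm(10, 5, 1)))
  expect_true(welch_t_fdr(d)$discovery)
})

test_that("two-stage FDR is monotone in Q and never rejects less than BH at the same level", {
  withr::local_seed(19)
  for (i in 1:20) {
    p <- c(runif(20), runif(5, 0, 0.002))
    qs <- c(0.001, 0.005, 0.01, 0.05, 0.1)
    n_disc <- vapply(qs, function(q) sum(fdr_two_stage(p, q)), 0L)
    expect_true(all(diff(n_disc) >= 0))
    bh <- sum(stats::p.adjust(p, "BH") <= 0.01)
    expect_gte(sum(fdr_two_stage(p, 0.01)), bh)
  }
  expect_identical(fdr_two_stage(numeric(0)), logical(0))
})

test_that("type III two-way ANOVA matches a from-scratch sums-of-squares oracle (balanced)", {
  # balanced 2x3 design with hand-computable cell means
  d <- expand.grid(rep = 1:4, day = c(7, 14, 21),
                   type = c("4T1", "4T07"))
  withr::local_seed(20)
  d$y <- 10 + 2 * (d$day == 14) + 3 * (d$type == "4T07") +
    1.5 * (d$day == 21) * (d$type == "4T07") + rnorm(nrow(d))
  res <- two_way_anova_tukey(d$y, d$day, d$type)

  # oracle: classical balanced decomposition
  n <- nrow(d); a <- 3; b <- 2; r <- 4
  gm <- mean(d$y)
  mA <- tapply(d$y, d$day, mean)
  mB <- tapply(d$y, d$type, mean)
  mAB <- tapply(d$y, list(d$day, d$type), mean)
  ssA <- b * r * sum((mA - gm)^2)
  ssB <- a * r * sum((mB - gm)^2)
  ssAB <- r * sum((mAB - outer(mA - gm, mB - gm, "+") - gm)^2)
  ssE <- sum((d$y - mAB[cbind(as.character(d$day),
                              as.character(d$type))])^2)
  ssT <- sum((d$y - gm)^2)
  expect_equal(ssA + ssB + ssAB + ssE, ssT, tolerance = 1e-9)
  f_oracle <- c(ssA / (a - 1), ssB / (b - 1),
                ssAB / ((a - 1) * (b - 1))) / (ssE / (n - a * b))
  got <- setNames(res$anova$statistic, res$anova$effect)
  expect_equal(unname(got[c("day", "tumour_type", "day:tumour_type")]),
               f_oracle, tolerance = 1e-9)
})

test_that("zero-noise equal means give F = 0; empty cells are named in the error", {
  d <- expand.grid(rep = 1:3, day = c(7, 14), type = c("4T1", "4T07"))
  res <- two_way_anova_tukey(rep(4, nrow(d)), d$day, d$type)
  expect_equal(res$anova$statistic, rep(0, 3))
  expect_equal(res$anova$p, rep(1, 3))
  d2 <- d[!(d$day == 14 & d$type == "4T07"), ]
  expect_error(two_way_anova_tukey(rnorm(nrow(d2)), d2$day, d2$type),
               "day 14")
})

test_that("Tukey-Kramer comparisons cover day pairs within each tumour type", {
  withr::local_seed(22)
  d <- expand.grid(rep = 1:5, day = c(7, 14, 21), type = c("4T1", "4T07"))
  d$y <- rnorm(nrow(d)) + 4 * (d$day == 21 & d$type == "4T1")
  res <- two_way_anova_tukey(d$y, d$day, d$type)
  expect_equal(nrow(res$comparisons), 6)  # 3 day pairs x 2 types
  sig <- res$comparisons[res$comparisons$discovery, "comparison"]
  expect_true(any(grepl("4T1.*21", sig)))
})

test_that("noiseless lines are interpolated exactly and a shared line gives F = 0", {
  day <- rep(c(7, 14, 21), each = 4)
  type <- rep(c("4T1", "4T07"), 6)
  y <- 2 * day + 5
  fit <- linear_trend_fit(y, day, type)
  expect_equal(fit$groups$slope, c(2, 2), tolerance = 1e-12)
  expect_equal(fit$groups$intercept, c(5, 5), tolerance = 1e-12)
  expect_equal(fit$shared_line_F, 0)
  expect_equal(fit$shared_line_p, 1)
  expect_error(linear_trend_fit(y[day != 21], day[day != 21],
                                type[day != 21]),
               class = "stats_error")
})

test_that("opposite slopes are detected by the shared-line test (power over replicates)", {
  withr::local_seed(23)
  hits <- 0
  for (i in 1:60) {
    day <- rep(c(7, 14, 21), length.out = 40)
    type <- rep(c("4T1", "4T07"), each = 20)
    y <- ifelse(type == "4T1", 10 + 0.5 * day, 17 - 0.5 * day) +
      rnorm(40, 0, 2)
    fit <- linear_trend_fit(y, day, type)
    hits <- hits + (fit$shared_line_p < 0.05)
  }
  expect_gte(hits / 60, 0.9)
  # the extra-sum-of-squares F agrees with anova()'s model comparison
  day <- rep(c(7, 14, 21), length.out = 24)
  type <- rep(c("4T1", "4T07"), each = 12)
  y <- 5 + 0.3 * day + rnorm(24)
  fit <- linear_trend_fit(y, day, type)
  ref <- anova(lm(y ~ day), lm(y ~ day * factor(type)))
  expect_equal(fit$shared_line_F, ref$F[2], tolerance = 1e-10)
  expect_equal(fit$shared_line_p, ref$`Pr(>F)`[2], tolerance = 1e-10)
})

test_that("one-way trend contrast matches the direct formula and degenerates correctly", {
  withr::local_seed(24)
  day <- rep(c(7, 14, 21), each = 5)
  y <- rnorm(15, mean = day / 7)
  res <- one_way_trend(y, day)
  cc <- c(-7, 0, 7)
  means <- tapply(y, day, mean)
  mse <- sum(resid(aov(y ~ factor(day)))^2) / 12
  est <- sum(cc * means)
  se <- sqrt(mse * sum(cc^2 / 5))
  expect_equal(res$linear_contrast$estimate, est, tolerance = 1e-12)
  expect_equal(res$linear_contrast$se, se, tolerance = 1e-12)
  expect_equal(res$linear_contrast$p,
               2 * pt(-abs(est / se), 12), tolerance = 1e-12)
  # equal means, zero noise
  res0 <- one_way_trend(rep(3, 15), day)
  expect_equal(res0$linear_contrast$estimate, 0)
  expect_equal(res0$F, 0)
  # strictly increasing noise-free means: p below machine-tiny threshold
  res1 <- one_way_trend(day * 1.0 + rnorm(15, 0, 1e-8), day)
  expect_lt(res1$linear_contrast$p, 1e-10)
})

test_that("significance stars follow the reporting convention", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 0.0009, 0.00009)),
               c("", "*", "**", "***", "****"))
})

test_that("reference normalisation gives mean 1 per batch and preserves single-batch ranks", {
  withr::local_seed(25)
  d <- expand.grid(rep = 1:4, day = c(7, 14, 21),
                   tumour_type = c("4T1", "4T07"), batch = "rep1",
                   marker = c("FAPa", "CD26"))
  d$sample_id <- seq_len(nrow(d))
  d$value <- rnorm(nrow(d), 20, 2)
  bc <- batch_effect_check(d)
  for (m in unique(d$marker)) {
    ref <- bc$normalized$norm_value[bc$normalized$marker == m &
                                      bc$normalized$tumour_type == "4T1" &
                                      bc$normalized$day == 7]
    expect_equal(mean(ref), 1, tolerance = 1e-12)
  }
  # single batch: normalisation is a per-marker rescaling, so F ranks and
  # p-values of the ANOVA are unchanged
  expect_equal(bc$comparisons$p_raw, bc$comparisons$p_norm,
               tolerance = 1e-9)
  expect_equal(bc$concordance, 1)
  # empty reference group is an error
  d2 <- d[!(d$tumour_type == "4T1" & d$day == 7), ]
  expect_error(batch_effect_check(d2), class = "stats_error")
})
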