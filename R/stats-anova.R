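#' Two-way ANOVA with Tukey-Kramer post-tests
#'
#' Fits `value ~ day * tumour_type` (both as factors) with sum-to-zero
#' contrasts, reports Type III sums of squares for the two main effects
#' and the interaction (matching the conventions of mainstream commercial
#' software for unbalanced designs), and runs Tukey-Kramer pairwise
#' comparisons across time within each tumour type, valid for unequal
#' group sizes.
#'
#' @param values numeric response, one per sample (percentages in this
#'   pipeline, so contrasts are in percentage points).
#' @param day,tumour_type factors (coerced) identifying the design cell
#'   of each value.
#' @return A `two_way_anova` object: `anova` (effect, sum_sq, df,
#'   statistic, p), `comparisons` (a `comparison_table` of Tukey-Kramer
#'   contrasts), and the fitted `model`.
#' @export
#' @examples
#' d <- expand.grid(day = c(7, 14, 21), type = c("4T1", "4T07"),
#'                  rep = 1:4)
#' y <- 10 + 2 * (d$day == 21) + rnorm(nrow(d))
#' two_way_anova_tukey(y, d$day, d$type)
two_way_anova_tukey <- function(values, day, tumour_type) {
  df <- data.frame(value = values, day = factor(day),
                   tumour_type = factor(tumour_type))
  cells <- table(df$day, df$tumour_type)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    abort2("empty design cell(s): ",
           paste(sprintf("(day %s, %s)", rownames(cells)[empty[, 1]],
                         colnames(cells)[empty[, 2]]), collapse = ", "),
           class = "stats_error")
  }
  if (sum(cells >= 2) < 2)
    abort2("need at least two cells with two or more replicates",
           class = "stats_error")
  fit <- stats::lm(value ~ day * tumour_type, data = df,
                   contrasts = list(day = "contr.sum",
                                    tumour_type = "contr.sum"))
  rss <- sum(stats::resid(fit)^2)
  if (rss <= 1e-10 * max(1, sum(df$value^2)))
    return(zero_residual_anova(fit, df))
  a3 <- car::Anova(fit, type = 3, singular.ok = FALSE)
  rows <- !rownames(a3) %in% c("(Intercept)", "Residuals")
  res_ms <- a3["Residuals", "Sum Sq"] / a3["Residuals", "Df"]
  fstat <- a3[rows, "Sum Sq"] / a3[rows, "Df"] / res_ms
  pval <- stats::pf(fstat, a3[rows, "Df"], a3["Residuals", "Df"],
                    lower.tail = FALSE)
  # zero-residual designs: an effect with zero sum of squares is absent
  zero <- a3[rows, "Sum Sq"] < 1e-12
  fstat[zero] <- 0; pval[zero] <- 1
  anova_tab <- data.frame(effect = rownames(a3)[rows],
                          sum_sq = a3[rows, "Sum Sq"],
                          df = a3[rows, "Df"],
                          statistic = fstat, p = pval, row.names = NULL)
  emm <- emmeans::emmeans(fit, ~ day | tumour_type)
  cmp <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "tukey"))
  comparisons <- data.frame(
    comparison = paste0(cmp$tumour_type, ": ", cmp$contrast),
    estimate = cmp$estimate, statistic = cmp$t.ratio, df = cmp$df,
    p = cmp$p.value, discovery = cmp$p.value < 0.05,
    method = "tukey-kramer", stringsAsFactors = FALSE)
  class(comparisons) <- c("comparison_table", "data.frame")
  structure(list(anova = anova_tab, comparisons = comparisons,
                 model = fit),
            class = "two_way_anova")
}

# Degenerate designs with zero residual variance (e.g. constant synthetic
# inputs): Type III sums of squares come from direct model-matrix column
# drops, an effect with zero SS gets F = 0 / p = 1 and a nonzero one
# F = Inf / p = 0; Tukey contrasts reduce to cell-mean differences.
zero_residual_anova <- function(fit, df) {
  mm <- stats::model.matrix(fit)
  asgn <- attr(mm, "assign")
  terms_lab <- attr(stats::terms(fit), "term.labels")
  y <- df$value
  rss_full <- sum(stats::resid(fit)^2)
  anova_tab <- do.call(rbind, lapply(seq_along(terms_lab), function(i) {
    red <- mm[, asgn != i, drop = FALSE]
    ss <- sum(stats::lsfit(red, y, intercept = FALSE)$residuals^2) -
      rss_full
    data.frame(effect = terms_lab[i], sum_sq = max(ss, 0),
               df = sum(asgn == i),
               statistic = if (ss > 1e-10) Inf else 0,
               p = if (ss > 1e-10) 0 else 1)
  }))
  cm <- tapply(df$value, list(df$day, df$tumour_type), mean)
  days <- rownames(cm)
  pairs <- utils::combn(days, 2)
  comparisons <- do.call(rbind, lapply(colnames(cm), function(tt) {
    est <- cm[pairs[1, ], tt] - cm[pairs[2, ], tt]
    data.frame(
      comparison = paste0(tt, ": day", pairs[1, ], " - day", pairs[2, ]),
      estimate = est,
      statistic = ifelse(est == 0, 0, sign(est) * Inf),
      df = stats::df.residual(fit),
      p = ifelse(est == 0, 1, 0), discovery = est != 0,
      method = "tukey-kramer", stringsAsFactors = FALSE)
  }))
  rownames(comparisons) <- NULL
  class(comparisons) <- c("comparison_table", "data.frame")
  structure(list(anova = anova_tab, comparisons = comparisons,
                 model = fit),
            class = "two_way_anova")
}

#' @export
print.two_way_anova <- function(x, ...) {
  cat("<two_way_anova> Type III effects:\n")
  print(transform(x$anova, sum_sq = signif(sum_sq, 5),
                  statistic = signif(statistic, 5), p = signif(p, 4)))
  cat("Tukey-Kramer comparisons (day within tumour type):\n")
  print(transform(x$comparisons, estimate = round(estimate, 3),
                  statistic = round(statistic, 3), p = signif(p, 4)),
        row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA over time with a linear-trend contrast
#'
#' Pools all samples (used when tumour type is not a significant factor),
#' tests the overall effect of day by one-way ANOVA, and tests for a
#' linear trend with a contrast whose coefficients are the centred day
#' values (proportional to -1, 0, +1 for days 7/14/21).
#'
#' @param values numeric response per sample.
#' @param day day of each sample (numeric; used both as the grouping
#'   factor and to build the contrast coefficients).
#' @return A list with `F`, `p`, and `linear_contrast` (`estimate` on the
#'   centred-day scale, `se`, `statistic`, `p`).
#' @export
one_way_trend <- function(values, day) {
  day_num <- as.numeric(as.character(day))
  f <- factor(day_num)
  if (nlevels(f) < 2)
    abort2("need at least two day groups", class = "stats_error")
  fit <- stats::aov(values ~ f)
  s <- summary(fit)[[1]]
  lev <- as.numeric(levels(f))
  cc <- lev - mean(lev)
  ng <- tabulate(f)
  means <- tapply(values, f, mean)
  mse <- s["Residuals", "Mean Sq"]
  est <- sum(cc * means)
  se <- sqrt(mse * sum(cc^2 / ng))
  df <- s["Residuals", "Df"]
  # zero residual variance: a nonzero contrast is then exact evidence
  tstat <- if (se > 0) est / se else if (est == 0) 0 else sign(est) * Inf
  ss_f <- s[1, "Sum Sq"]
  fstat <- if (ss_f < 1e-12) 0 else if (mse == 0) Inf else s[1, "F value"]
  list(F = fstat,
       p = if (ss_f < 1e-12) 1 else if (mse == 0) 0 else s[1, "Pr(>F)"],
       linear_contrast = list(estimate = est, se = se, statistic = tstat,
                              p = 2 * stats::pt(-abs(tstat), df)))
}

#' Per-group linear fits over time with a shared-line test
#'
#' Ordinary least squares of the response on day within each tumour
#' type, plus the extra-sum-of-squares F test comparing one pooled line
#' (2 parameters) against separate lines per group (4 parameters): a
#' small p indicates that slope and/or intercept differ between the
#' groups. 95 percent confidence bands come from the per-group fit
#' covariance.
#'
#' @param values numeric response per sample (percent).
#' @param day numeric day per sample; at least 3 distinct days per group.
#' @param tumour_type group of each sample (two or more levels).
#' @return A `trend_fit` object: per-group `slope` (percent per day),
#'   `intercept`, `slope_p` (slope-nonzero t-test), `shared_line_F`,
#'   `shared_line_p`, the per-group models and a `cb95` band table.
#' @export
linear_trend_fit <- function(values, day, tumour_type) {
  df <- data.frame(value = values, day = as.numeric(day),
                   group = factor(tumour_type))
  for (g in levels(df$group)) {
    if (length(unique(df$day[df$group == g])) < 3)
      abort2("group ", g, " has fewer than 3 distinct days",
             class = "stats_error")
  }
  pooled <- stats::lm(value ~ day, data = df)
  separate <- stats::lm(value ~ day * group, data = df)
  rss1 <- sum(stats::resid(pooled)^2)
  rss2 <- sum(stats::resid(separate)^2)
  df1 <- stats::df.residual(pooled)
  df2 <- stats::df.residual(separate)
  if (df2 <= 0)
    abort2("no residual degrees of freedom for the two-line model",
           class = "stats_error")
  if (rss1 - rss2 < 1e-12) {
    fstat <- 0; pval <- 1
  } else {
    fstat <- ((rss1 - rss2) / (df1 - df2)) / (rss2 / df2)
    pval <- stats::pf(fstat, df1 - df2, df2, lower.tail = FALSE)
  }
  fits <- lapply(split(df, df$group), function(d)
    stats::lm(value ~ day, data = d))
  groups <- data.frame(
    group = names(fits),
    slope = vapply(fits, function(f) stats::coef(f)[["day"]], 0),
    intercept = vapply(fits, function(f) stats::coef(f)[["(Intercept)"]], 0),
    slope_p = vapply(fits, function(f) {
      # perfect fits emit a reliability warning; the NA below covers them
      sm <- suppressWarnings(summary(f))$coefficients
      if ("day" %in% rownames(sm) && nrow(sm) > 1 &&
          is.finite(sm["day", 4])) sm["day", 4] else NA_real_
    }, 0), row.names = NULL)
  grid <- do.call(rbind, lapply(names(fits), function(g) {
    days <- seq(min(df$day[df$group == g]), max(df$day[df$group == g]),
                length.out = 25)
    pr <- stats::predict(fits[[g]], data.frame(day = days),
                         interval = "confidence", level = 0.95)
    data.frame(group = g, day = days, fit = pr[, "fit"],
               lwr = pr[, "lwr"], upr = pr[, "upr"])
  }))
  structure(list(groups = groups, shared_line_F = fstat,
                 shared_line_p = pval, models = fits, cb95 = grid),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("<trend_fit> per-group lines:\n")
  print(transform(x$groups, slope = round(slope, 4),
                  intercept = round(intercept, 3),
                  slope_p = signif(slope_p, 4)), row.names = FALSE)
  cat(sprintf("shared-line test: F = %.4g, p = %.4g\n",
              x$shared_line_F, x$shared_line_p))
  invisible(x)
}

#' Significance stars
#'
#' The reporting convention: `*` p < 0.05, `**` p < 0.01, `***`
#' p < 0.001, `****` p < 0.0001.
#'
#' @param p p-values.
#' @return Character vector of stars (empty string when p >= 0.05).
#' @export
significance_stars <- function(p) {
  cut_points <- c(1e-4, 1e-3, 1e-2, 5e-2)
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    strrep("*", sum(pi < cut_points))
  }, "")
}
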