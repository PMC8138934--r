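#' Batch-effect check by reference-group normalisation
#'
#' Repeats of a staining experiment carry multiplicative batch effects
#' (antibody lots, instrument drift). The check: within each batch,
#' divide every sample's marker percentage by that batch's mean in a
#' fixed reference group (default the 4T1 day-7 tumours), re-run the
#' two-way ANOVA with Tukey-Kramer post-tests on the ratios, and compare
#' the significance calls with the analysis of the raw percentages. High
#' concordance means the batch effect does not drive the conclusions.
#'
#' @param data data frame with columns `tumour_type`, `day`, `batch`,
#'   `marker`, `value` (marker percentage per sample); or a list of
#'   [composition_profile()]s, which is converted to the per-marker
#'   percentages of CAF+.
#' @param reference_type,reference_day the reference group; must be
#'   non-empty in every batch.
#' @param alpha significance threshold for the concordance calls.
#' @return A `batch_check` object: `normalized` (the input with a
#'   `norm_value` column), `comparisons` (per marker and contrast: raw
#'   and normalized adjusted p and significance calls), and `concordance`
#'   (fraction of comparisons whose call is unchanged).
#' @export
batch_effect_check <- function(data, reference_type = "4T1",
                               reference_day = 7, alpha = 0.05) {
  if (!is.data.frame(data)) data <- profiles_to_marker_table(data)
  req <- c("tumour_type", "day", "batch", "marker", "value")
  if (!all(req %in% names(data)))
    abort2("data needs columns ", paste(req, collapse = ", "),
           class = "stats_error")
  data$norm_value <- NA_real_
  for (b in unique(data$batch)) {
    in_b <- data$batch == b
    for (m in unique(data$marker)) {
      ref <- data$value[in_b & data$marker == m &
                          data$tumour_type == reference_type &
                          data$day == reference_day]
      if (length(ref) == 0)
        abort2("reference group (", reference_type, ", day ",
               reference_day, ") empty in batch ", b,
               class = "stats_error")
      if (mean(ref) == 0)
        abort2("reference mean is 0 for marker ", m, " in batch ", b,
               class = "stats_error")
      sel <- in_b & data$marker == m
      data$norm_value[sel] <- data$value[sel] / mean(ref)
    }
  }
  tum <- data[data$tumour_type != "healthy", ]
  comparisons <- do.call(rbind, lapply(unique(tum$marker), function(m) {
    d <- tum[tum$marker == m, ]
    raw <- two_way_anova_tukey(d$value, d$day, d$tumour_type)$comparisons
    nrm <- two_way_anova_tukey(d$norm_value, d$day,
                               d$tumour_type)$comparisons
    data.frame(marker = m, comparison = raw$comparison,
               estimate_raw = raw$estimate, p_raw = raw$p,
               sig_raw = raw$p < alpha,
               estimate_norm = nrm$estimate, p_norm = nrm$p,
               sig_norm = nrm$p < alpha, stringsAsFactors = FALSE)
  }))
  structure(list(normalized = data, comparisons = comparisons,
                 concordance = mean(comparisons$sig_raw ==
                                      comparisons$sig_norm),
                 alpha = alpha,
                 reference = list(tumour_type = reference_type,
                                  day = reference_day)),
            class = "batch_check")
}

#' @export
print.batch_check <- function(x, ...) {
  n <- nrow(x$comparisons)
  flips <- sum(x$comparisons$sig_raw != x$comparisons$sig_norm)
  cat(sprintf(paste0("<batch_check> %d comparisons, %d changed call ",
                     "(concordance %.1f%%)\n"),
              n, flips, 100 * x$concordance))
  invisible(x)
}

# long table of per-marker % of CAF+ from composition profiles
profiles_to_marker_table <- function(profiles) {
  profiles <- usable_profiles(profiles)
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(sample_id = p$sample_id,
               tumour_type = p$meta$tumour_type,
               day = p$meta$day, batch = p$meta$batch,
               marker = caf_markers(),
               value = 100 * unname(p$per_marker_of_caf_pos),
               stringsAsFactors = FALSE)
  }))
}
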