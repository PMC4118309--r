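#' Lag autocorrelation of a marker-level series
#'
#' Pearson autocorrelation of a genome-ordered LRR series at the given lag,
#' mean-centered with the biased (divide-by-n) normalization of the standard
#' sample autocorrelation. High lag-10 autocorrelation of autosomal LRR is
#' the fingerprint of residual genomic waves.
#'
#' @param x numeric series (genome-ordered LRR values); `NA`s dropped.
#' @param lag lag in markers (default 10).
#' @return Scalar autocorrelation; a constant series returns 0 with a
#'   warning.
#' @export
lag_autocorrelation <- function(x, lag = 10) {
  x <- x[!is.na(x)]
  if (length(x) < lag + 2) abort("Series shorter than `lag` + 2.")
  if (sd(x) == 0) {
    warn("Constant series; autocorrelation undefined, returning 0.")
    return(0)
  }
  as.numeric(acf(x, lag.max = lag, plot = FALSE, demean = TRUE)$acf[lag + 1])
}

#' Robust spread of a marker-level series
#'
#' Normal-consistent median absolute deviation,
#' `median(|x - median(x)|) * 1.4826`.
#'
#' @param x numeric series; `NA`s dropped.
#' @return Scalar MAD in the units of `x`.
#' @export
robust_spread <- function(x) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 2)
  mad(x)
}

#' Genotype-cluster signal-to-noise ratio
#'
#' Summarizes array quality as the separation of the canonical genotype
#' clusters of the allelic contrast at diploid SNPs: the ratio of the
#' (weighted) between-cluster variance of cluster centers to the mean
#' within-cluster variance. Reported as a diagnostic only; samples are never
#' excluded on this statistic.
#'
#' @param contrast numeric allelic-contrast values.
#' @param cluster genotype cluster labels aligned to `contrast`.
#' @return Scalar SNR (capped at `1e6`); `NA` if fewer than 2 clusters are
#'   observed.
#' @export
snr_metric <- function(contrast, cluster) {
  ok <- !is.na(contrast) & !is.na(cluster)
  contrast <- contrast[ok]
  cluster <- as.character(cluster[ok])
  levs <- unique(cluster)
  if (length(levs) < 2) return(NA_real_)
  centers <- tapply(contrast, cluster, mean)
  wts <- tapply(contrast, cluster, length) / length(contrast)
  grand <- sum(wts * centers)
  between <- sum(wts * (centers - grand)^2)
  within <- tapply(contrast, cluster, function(v) {
    if (length(v) < 2) 0 else var(v)
  })
  mw <- mean(within)
  if (mw == 0) return(if (between == 0) 0 else 1e6)
  min(between / mw, 1e6)
}

#' Per-sample QC metrics
#'
#' Computes, for every subject, the lag-10 autocorrelation and robust spread
#' (MAD) of the genome-ordered autosomal LRR series (chromosomes
#' concatenated in map order) and the number of CNV calls.
#'
#' @param data an [intensity_data()] object.
#' @param segments CNV segment tibble (post marker filtering) used for the
#'   per-subject CNV count.
#' @return A tibble with columns `subject_id`, `lag10_acf`, `lrr_mad`,
#'   `n_cnv`.
#' @export
qc_metrics <- function(data, segments) {
  stopifnot(inherits(data, "intensity_data"))
  subj <- rownames(data$lrr) %||% as.character(seq_len(nrow(data$lrr)))
  counts <- table(factor(segments$subject_id, levels = subj))
  tibble(
    subject_id = subj,
    lag10_acf = apply(data$lrr, 1, lag_autocorrelation, lag = 10),
    lrr_mad = apply(data$lrr, 1, robust_spread),
    n_cnv = as.integer(counts[subj]))
}

#' Apply sample exclusion rules
#'
#' Excludes a sample if its lag-10 autocorrelation exceeds `acf_max`, its
#' LRR MAD exceeds `mad_max`, or its CNV count exceeds `cnv_max`. All three
#' comparisons are strict: a sample sitting exactly on a threshold is
#' retained.
#'
#' @param metrics tibble from [qc_metrics()] (columns `lag10_acf`,
#'   `lrr_mad`, `n_cnv`; an optional `snr` column is carried through).
#' @param acf_max,mad_max,cnv_max exclusion thresholds.
#' @return The input tibble with logical `excluded` and list-column
#'   `reasons` (character vector per subject, empty when retained).
#' @export
apply_qc <- function(metrics, acf_max = 0.03, mad_max = 0.32, cnv_max = 100) {
  metrics <- as_tibble(metrics)
  reasons <- purrr::pmap(
    list(metrics$lag10_acf, metrics$lrr_mad, metrics$n_cnv),
    function(a, m, k) {
      c(if (a > acf_max) "autocorrelation",
        if (m > mad_max) "mad",
        if (k > cnv_max) "cnv_count")
    })
  mutate(metrics,
         excluded = lengths(reasons) > 0,
         reasons = reasons)
}

#' CNV burden summaries
#'
#' Per-subject counts of deletions and duplications, cumulative kilobases
#' spanned, and counts by size class (`< 25 kb`, `25–200 kb`, `> 200 kb`),
#' with cohort-level medians and interquartile ranges.
#'
#' @param segments filtered CNV segment tibble.
#' @param subject_ids full cohort subject list, so that subjects without any
#'   CNV appear with zeros.
#' @return A list with tibbles `subjects` (one row per subject) and `cohort`
#'   (median and IQR of each burden metric).
#' @export
burden_summary <- function(segments, subject_ids) {
  seg <- as_tibble(segments)
  seg$len_kb <- (seg$end - seg$start + 1) / 1000
  per <- seg |>
    group_by(.data$subject_id) |>
    summarise(n_cnv = n(),
              n_del = sum(.data$cn < 2),
              n_dup = sum(.data$cn > 2),
              cum_kb = sum(.data$len_kb),
              n_small = sum(.data$len_kb < 25),
              n_medium = sum(.data$len_kb >= 25 & .data$len_kb <= 200),
              n_large = sum(.data$len_kb > 200),
              .groups = "drop")
  all <- tibble(subject_id = subject_ids)
  per <- left_join(all, per, by = "subject_id")
  per[is.na(per)] <- 0
  num <- names(per)[-1]
  cohort <- map_dfr(num, function(v) {
    q <- quantile(per[[v]], c(0.25, 0.5, 0.75))
    tibble(metric = v, median = q[[2]], q25 = q[[1]], q75 = q[[3]])
  })
  list(subjects = per, cohort = cohort)
}
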