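#' Missing-call surrogate for homozygous deletion
#'
#' When a SNP lies inside a deletion polymorphism, subjects with zero copies
#' have no allele to hybridize and genotype-calling algorithms tend to
#' return a missing (null) call. The missing-call indicator therefore serves
#' as a surrogate genotype for homozygous deletion on platforms where raw
#' intensities are unavailable.
#'
#' @param calls character genotype calls (`"A"`, `"AB"`, `"B"`, `NA` or
#'   `"missing"`/`"NULL"` for no call).
#' @return Integer 0/1 vector: 1 where the call is missing.
#' @export
surrogate_indicator <- function(calls) {
  as.integer(is.na(calls) | calls %in% c("missing", "NULL", "NN", ""))
}

#' Surrogate accuracy against true copy number
#'
#' Sensitivity is the fraction of true homozygous-deletion (copy number 0)
#' subjects flagged by the surrogate; specificity is the fraction of diploid
#' (copy number 2) subjects not flagged. Hemizygous (copy number 1) subjects
#' are tabulated but enter neither rate, since the surrogate targets the
#' null-genotype cluster specifically.
#'
#' @param indicator 0/1 vector from [surrogate_indicator()].
#' @param true_cn integer copy numbers aligned to `indicator`.
#' @return A list of class `surrogate_eval`: `sensitivity`, `specificity`
#'   (`NA` when the reference class is empty), and `counts`, a tibble of
#'   flagged/unflagged counts by copy number.
#' @export
concordance <- function(indicator, true_cn) {
  stopifnot(length(indicator) == length(true_cn),
            all(indicator %in% 0:1))
  counts <- tibble(cn = rep(sort(unique(true_cn)), each = 2),
                   flagged = rep(c(TRUE, FALSE),
                                 length(unique(true_cn)))) |>
    mutate(n = purrr::map2_int(.data$cn, .data$flagged, function(c_, f) {
      sum(true_cn == c_ & (indicator == 1) == f)
    }))
  n0 <- sum(true_cn == 0)
  n2 <- sum(true_cn == 2)
  structure(list(
    sensitivity = if (n0 == 0) NA_real_ else
      sum(indicator == 1 & true_cn == 0) / n0,
    specificity = if (n2 == 0) NA_real_ else
      sum(indicator == 0 & true_cn == 2) / n2,
    counts = counts
  ), class = "surrogate_eval")
}

#' @export
print.surrogate_eval <- function(x, ...) {
  cat("<surrogate_eval> sensitivity ", signif(x$sensitivity, 4),
      ", specificity ", signif(x$specificity, 4), "\n", sep = "")
  invisible(x)
}

#' Attenuation of surrogate-based effect estimates
#'
#' Quantifies the bias toward zero induced by replacing true copy number
#' with the missing-call surrogate. A cohort with Hardy-Weinberg copy
#' numbers (0/1/2) and a linear per-copy effect on the log trait is
#' simulated; the trait is regressed once on true copy number and once on
#' the surrogate indicator (flagged homozygous deletions versus the rest).
#' Because the unflagged class is contaminated with hemizygous and
#' undetected homozygous deletion subjects, the surrogate contrast is
#' attenuated relative to the true homozygous-deletion (two-copy) contrast.
#'
#' @param n cohort size.
#' @param deletion_freq deletion allele frequency.
#' @param cn_effect per-copy effect on the log trait.
#' @param sensitivity probability that a copy-number-0 subject is flagged
#'   (`(0, 1]`); specificity is 1.
#' @param residual_sd residual sd of the log trait.
#' @param seed integer seed.
#' @return A list of class `attenuation_result`: `estimates`, a tibble with
#'   rows `true_cn` and `surrogate` (columns `beta`, `se`, and
#'   `beta_scaled` — the homozygous-deletion contrast, `-2 * beta` for the
#'   per-copy model and `beta` itself for the surrogate), and
#'   `attenuation_ratio` = surrogate / true on the contrast scale.
#' @export
attenuation_experiment <- function(n = 2000, deletion_freq = 0.24,
                                   cn_effect = -log(1.05),
                                   sensitivity = 0.75,
                                   residual_sd = 0.2, seed = 1) {
  stopifnot(sensitivity > 0, sensitivity <= 1)
  with_seed_local(seed, {
    cn <- rbinom(n, 2, 1 - deletion_freq)
    y <- cn_effect * cn + rnorm(n, 0, residual_sd)
    flagged <- as.integer(cn == 0 & runif(n) < sensitivity)
    f_true <- lm(y ~ cn)
    f_sur <- lm(y ~ flagged)
    b_t <- coef(f_true)[["cn"]]
    b_s <- coef(f_sur)[["flagged"]]
    est <- tibble(
      model = c("true_cn", "surrogate"),
      beta = c(b_t, b_s),
      se = c(sqrt(vcov(f_true)["cn", "cn"]),
             sqrt(vcov(f_sur)["flagged", "flagged"])),
      beta_scaled = c(-2 * b_t, b_s))
    structure(list(estimates = est,
                   attenuation_ratio = b_s / (-2 * b_t)),
              class = "attenuation_result")
  })
}

#' @export
print.attenuation_result <- function(x, ...) {
  cat("<attenuation_result> surrogate/true contrast ratio ",
      signif(x$attenuation_ratio, 4), "\n", sep = "")
  print(x$estimates)
  invisible(x)
}
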