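#' Seasonal adjustment of the trait
#'
#' Serum concentrations of many analytes drift with season. This removes the
#' seasonal trend from the log trait before association testing: within each
#' sex, a locally weighted (tricube-kernel) linear smoother of `log(trait)`
#' on draw date with a total window of `bandwidth_days` is fitted, and the
#' adjusted value is the residual plus the sex-specific grand mean. The
#' smoother is evaluated on a date grid and interpolated, which is
#' numerically identical to pointwise fitting at these sample sizes.
#'
#' @param pheno phenotype tibble with columns `trait`, `draw_date`, `sex`.
#' @param bandwidth_days total smoothing window in days (default 110).
#' @return `pheno` with an added column `adj_log_trait`. Strata with fewer
#'   than 10 subjects are passed through unadjusted (centered log trait plus
#'   grand mean) with a warning.
#' @export
seasonal_adjust <- function(pheno, bandwidth_days = 110) {
  pheno <- as_tibble(pheno)
  stopifnot(all(c("trait", "draw_date", "sex") %in% names(pheno)),
            all(pheno$trait > 0))
  pheno$adj_log_trait <- NA_real_
  for (s in unique(pheno$sex)) {
    rows <- which(pheno$sex == s)
    y <- log(pheno$trait[rows])
    if (length(rows) < 10) {
      warn(paste0("Fewer than 10 subjects of sex ", s,
                  "; seasonal adjustment skipped for this stratum."))
      pheno$adj_log_trait[rows] <- y
      next
    }
    t <- as.numeric(pheno$draw_date[rows])
    sm <- tricube_smooth(t, y, half_width = bandwidth_days / 2)
    pheno$adj_log_trait[rows] <- y - sm + mean(y)
  }
  pheno
}

# local linear regression with tricube weights, grid + interpolation
tricube_smooth <- function(t, y, half_width, n_grid = 201) {
  ut <- sort(unique(t))
  grid <- if (length(ut) <= n_grid) ut else
    seq(min(t), max(t), length.out = n_grid)
  fit <- vapply(grid, function(g) {
    d <- abs(t - g)
    w <- (1 - pmin(d / half_width, 1)^3)^3
    if (sum(w > 0) < 5) {          # sparse window: nearest 5 points
      w <- as.numeric(rank(d, ties.method = "first") <= 5)
    }
    x <- t - g
    sw <- sum(w); sx <- sum(w * x); sxx <- sum(w * x^2)
    sy <- sum(w * y); sxy <- sum(w * x * y)
    det <- sw * sxx - sx^2
    if (det < 1e-10 * max(sw * sxx, 1)) sy / sw else
      (sxx * sy - sx * sxy) / det   # intercept of the local line at g
  }, numeric(1))
  approx(grid, fit, xout = t, rule = 2)$y
}

# right-hand side of the baseline fixed-effects formula
baseline_rhs <- function(pheno) {
  terms <- c("age * sex", "log_bmi * sex")
  if (length(unique(pheno$center)) > 1) terms <- c(terms, "center")
  paste(terms, collapse = " + ")
}

assert_full_rank <- function(formula, data) {
  X <- model.matrix(formula, data)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    abort(paste0("Singular design; collinear columns: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(TRUE)
}

# ML fit of `adj_log_trait ~ rhs (+ (1|plate))`; falls back to OLS when
# fewer than 2 plates are present. Rank checking is for baseline designs;
# extended models tolerate aliased covariates (dropped, LRT contribution 0)
fit_lmm <- function(pheno, rhs, check_rank = TRUE) {
  use_plate <- "plate" %in% names(pheno) && length(unique(pheno$plate)) > 1
  if (check_rank) assert_full_rank(as.formula(paste("~", rhs)), pheno)
  if (use_plate) {
    f <- as.formula(paste("adj_log_trait ~", rhs, "+ (1 | plate)"))
    suppressMessages(lme4::lmer(f, data = pheno, REML = FALSE))
  } else {
    lm(as.formula(paste("adj_log_trait ~", rhs)), data = pheno)
  }
}

#' Fit the baseline trait model
#'
#' The covariate-only mixed model for the seasonally adjusted log trait:
#' fixed effects for study center, age, log BMI, sex and the interactions of
#' age and log BMI with sex, plus a random intercept for chemistry plate.
#' Fitted by maximum likelihood (not REML) so that likelihood-ratio tests
#' against extended models with additional fixed effects are valid.
#'
#' @param pheno phenotype tibble containing `adj_log_trait` (from
#'   [seasonal_adjust()]), `age`, `sex`, `log_bmi`, `center`, `plate`.
#' @return The fitted model (`lmerMod`, or `lm` when fewer than two plates
#'   are present).
#' @export
fit_baseline <- function(pheno) {
  pheno <- as_tibble(pheno)
  if (!"adj_log_trait" %in% names(pheno)) {
    abort("`pheno` lacks `adj_log_trait`; run seasonal_adjust() first.")
  }
  fit_lmm(pheno, baseline_rhs(pheno))
}

wald_row <- function(model, term_names, labels) {
  b <- if (inherits(model, "merMod")) lme4::fixef(model) else coef(model)
  V <- as.matrix(vcov(model))
  out <- map_dfr(seq_along(term_names), function(i) {
    tn <- term_names[i]
    if (!tn %in% names(b) || is.na(b[tn])) {    # aliased covariate, dropped
      return(tibble(term = labels[i], beta = NA_real_, se = NA_real_,
                    p_value = NA_real_))
    }
    beta <- unname(b[tn])
    se <- sqrt(V[tn, tn])
    tibble(term = labels[i], beta = beta, se = se,
           p_value = 2 * pnorm(-abs(beta / se)))
  })
  out
}

#' Test a CNP against the trait
#'
#' Extends the baseline mixed model with copy number as a continuous
#' covariate — either a single slope shared by the sexes, or (with
#' `sex_interaction = TRUE`) separate female and male slopes — and compares
#' against the baseline by a likelihood-ratio test (1 or 2 degrees of
#' freedom). Effect sizes are reported on the percentage-change scale via
#' [pct_change()].
#'
#' @param pheno phenotype tibble with `adj_log_trait` (see
#'   [seasonal_adjust()]).
#' @param cn integer copy-number vector aligned to the rows of `pheno`
#'   (`NA`s dropped pairwise); must take at least two distinct values.
#' @param sex_interaction fit sex-specific slopes and the 2-df test?
#' @param extra_covariates optional data frame of additional fixed-effect
#'   columns (e.g. SNP dosages) included in both the baseline and the
#'   extended model.
#' @return An object of class `cnp_assoc`: `effects` (one row per slope:
#'   `beta` per copy on the log scale, `se`, Wald `p_value`, and the
#'   percentage-change percentiles `pct_2.5`, `pct_50`, `pct_97.5` per copy
#'   increase), `lrt` (statistic, df, p), `n`, and the two fitted models.
#' @export
fit_cnp <- function(pheno, cn, sex_interaction = FALSE,
                    extra_covariates = NULL) {
  pheno <- as_tibble(pheno)
  stopifnot(length(cn) == nrow(pheno))
  if (!"adj_log_trait" %in% names(pheno)) {
    abort("`pheno` lacks `adj_log_trait`; run seasonal_adjust() first.")
  }
  dat <- pheno
  dat$cn <- as.numeric(cn)
  if (!is.null(extra_covariates)) {
    extra_covariates <- as.data.frame(extra_covariates)
    stopifnot(nrow(extra_covariates) == nrow(dat))
    dat <- dplyr::bind_cols(dat, as_tibble(extra_covariates))
  }
  dat <- dat[!is.na(dat$cn), , drop = FALSE]
  if (length(unique(dat$cn)) < 2) abort("Copy number is monomorphic.")
  extra_rhs <- if (!is.null(extra_covariates)) {
    paste("+", paste(sprintf("`%s`", names(extra_covariates)),
                     collapse = " + "))
  } else ""
  rhs0 <- paste0(baseline_rhs(dat), extra_rhs)
  base <- fit_lmm(dat, rhs0)
  if (sex_interaction) {
    dat$cn_female <- dat$cn * (dat$sex == "F")
    dat$cn_male <- dat$cn * (dat$sex == "M")
    ext <- fit_lmm(dat, paste(rhs0, "+ cn_female + cn_male"),
                   check_rank = FALSE)
    eff <- wald_row(ext, c("cn_female", "cn_male"),
                    c("cn_female", "cn_male"))
    df <- 2L
  } else {
    ext <- fit_lmm(dat, paste(rhs0, "+ cn"), check_rank = FALSE)
    eff <- wald_row(ext, "cn", "cn")
    df <- 1L
  }
  stat <- max(0, 2 * (as.numeric(logLik(ext)) - as.numeric(logLik(base))))
  pc <- pct_change(eff$beta, eff$se)
  eff$pct_2.5 <- pc$p2.5
  eff$pct_50 <- pc$p50
  eff$pct_97.5 <- pc$p97.5
  structure(list(
    effects = eff,
    lrt = tibble(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE)),
    n = nrow(dat),
    baseline = base, extended = ext
  ), class = "cnp_assoc")
}

#' @export
print.cnp_assoc <- function(x, ...) {
  cat("<cnp_assoc> n = ", x$n, "; LRT chi^2(", x$lrt$df, ") = ",
      signif(x$lrt$statistic, 4), ", p = ",
      format(x$lrt$p_value, digits = 3), "\n", sep = "")
  print(x$effects)
  invisible(x)
}

#' @rdname fit_cnp
#' @param x a `cnp_assoc`.
#' @param ... unused.
#' @export
tidy.cnp_assoc <- function(x, ...) x$effects

#' @rdname fit_cnp
#' @export
glance.cnp_assoc <- function(x, ...) {
  dplyr::bind_cols(x$lrt, tibble(n = x$n))
}

#' Percentage-change effect scale
#'
#' For a slope `beta` of a log-transformed outcome, the multiplicative
#' effect per unit of the covariate is `exp(beta)`, i.e. a
#' `100 * (exp(beta) - 1)` percent change. The 2.5th and 97.5th percentiles
#' are Wald limits on the log scale transformed to the percentage scale, so
#' the triple `(p2.5, p50, p97.5)` mirrors the percentile notation used for
#' reporting such effects. With `per_deleted = TRUE` the transform is
#' applied to `-beta`, framing the effect per deleted copy.
#'
#' @param beta slope(s) on the log-outcome scale, per copy.
#' @param se standard error(s), `>= 0`.
#' @param per_deleted report the effect per deleted copy (sign-flipped)?
#' @return A tibble with columns `beta`, `se`, `p2.5`, `p50`, `p97.5`
#'   (percent units, `p2.5 <= p50 <= p97.5`).
#' @export
pct_change <- function(beta, se, per_deleted = FALSE) {
  stopifnot(all(is.na(se) | se >= 0))
  b <- if (per_deleted) -beta else beta
  z <- qnorm(0.975)
  tibble(beta = b, se = se,
         p2.5 = 100 * (exp(b - z * se) - 1),
         p50 = 100 * (exp(b) - 1),
         p97.5 = 100 * (exp(b + z * se) - 1))
}

#' Genome-wide CNP scan
#'
#' Runs [fit_cnp()] for every interval of a frequency-filtered copy-number
#' matrix, annotating each with the likelihood-ratio statistic, p-value and
#' a Bonferroni significance flag at family-wise level `alpha` over the
#' number of tested intervals.
#'
#' @param cn_matrix a [build_cn_matrix()] result (rows = intervals, columns
#'   aligned to `pheno$subject_id`).
#' @param pheno phenotype tibble with `adj_log_trait`.
#' @param sex_interaction use the 2-df sex-interaction test per interval?
#' @param alpha family-wise error level for the Bonferroni flag.
#' @return A tibble, one row per tested interval: coordinates, slope(s),
#'   `lrt_stat`, `df`, `p_value`, `neg_log10_p`, `bonferroni_significant`;
#'   monomorphic intervals are skipped. Attribute `"n_tests"` records the
#'   number of tests for the threshold.
#' @export
genome_scan <- function(cn_matrix, pheno, sex_interaction = FALSE,
                        alpha = 0.05) {
  pheno <- as_tibble(pheno)
  intervals <- attr(cn_matrix, "intervals")
  cols <- match(pheno$subject_id, colnames(cn_matrix))
  if (anyNA(cols)) abort("Some `pheno` subjects are missing from the matrix.")
  rows <- map(seq_len(nrow(cn_matrix)), function(i) {
    cn <- as.integer(cn_matrix[i, cols])
    if (length(unique(cn)) < 2) return(NULL)
    fit <- fit_cnp(pheno, cn, sex_interaction = sex_interaction)
    tibble(interval_id = rownames(cn_matrix)[i],
           chrom = intervals$chrom[i], start = intervals$start[i],
           end = intervals$end[i],
           beta = fit$effects$beta[1], se = fit$effects$se[1],
           lrt_stat = fit$lrt$statistic, df = fit$lrt$df,
           p_value = fit$lrt$p_value)
  })
  out <- bind_rows(rows)
  n_tests <- nrow(out)
  out <- mutate(out,
                neg_log10_p = -log10(.data$p_value),
                bonferroni_significant = .data$p_value < alpha / n_tests)
  attr(out, "n_tests") <- n_tests
  attr(out, "alpha") <- alpha
  out
}

#' Manhattan plot of a genome scan
#'
#' @param scan a [genome_scan()] result.
#' @return A ggplot object with the Bonferroni threshold drawn.
#' @export
plot_manhattan <- function(scan) {
  thr <- -log10((attr(scan, "alpha") %||% 0.05) /
                  (attr(scan, "n_tests") %||% nrow(scan)))
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$start,
                                     y = .data$neg_log10_p)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::geom_hline(yintercept = thr, linetype = 2) +
    ggplot2::labs(x = "position (bp)",
                  y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Quantile-quantile plot of scan p-values
#'
#' Expected versus observed `-log10` p-values under the global null.
#'
#' @param scan a [genome_scan()] result.
#' @return A ggplot object.
#' @export
plot_qq <- function(scan) {
  p <- sort(scan$p_value)
  df <- tibble(expected = -log10(stats::ppoints(length(p))),
               observed = -log10(p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected,
                                   y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(expected ~ -log[10](p)),
                  y = expression(observed ~ -log[10](p))) +
    ggplot2::theme_minimal()
}

#' SNP-conditional CNP model
#'
#' Tests whether the CNP association persists after adjusting for SNP allele
#' dosages: the dosages (0/1/2 copies of the B allele, treated as
#' continuous) enter both the baseline and the extended model as fixed
#' effects, and the likelihood-ratio test for copy number (plus its sex
#' interaction) is computed on top.
#'
#' @param pheno phenotype tibble with `adj_log_trait`.
#' @param cn copy-number vector aligned to `pheno`.
#' @param snp_dosages numeric vector, matrix or data frame of dosages in
#'   `{0, 1, 2}`, one column per SNP.
#' @param sex_interaction use the 2-df test (default TRUE)?
#' @return A `cnp_assoc` (see [fit_cnp()]).
#' @export
conditional_fit <- function(pheno, cn, snp_dosages, sex_interaction = TRUE) {
  if (is.null(dim(snp_dosages))) {
    snp_dosages <- data.frame(snp1 = snp_dosages)
  }
  snp_dosages <- as.data.frame(snp_dosages)
  if (is.null(names(snp_dosages)) || any(names(snp_dosages) == "")) {
    names(snp_dosages) <- paste0("snp", seq_len(ncol(snp_dosages)))
  }
  ok <- unlist(snp_dosages)
  stopifnot(all(ok[!is.na(ok)] %in% 0:2))
  fit_cnp(pheno, cn, sex_interaction = sex_interaction,
          extra_covariates = snp_dosages)
}

#' Inverse-variance pooling of two effect estimates
#'
#' Combines two independent slope estimates (e.g. from two cohorts) by
#' weighting with their inverse variances.
#'
#' @param beta,se numeric vectors of length 2.
#' @return A one-row tibble with the pooled `beta`, `se` and Wald `p_value`.
#' @export
inverse_variance_pool <- function(beta, se) {
  stopifnot(length(beta) == 2, length(se) == 2, all(se > 0))
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  tibble(beta = b, se = s, p_value = 2 * pnorm(-abs(b / s)))
}
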