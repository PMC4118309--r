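test_that("pct_change transforms and inverts exactly", {
  z <- pct_change(0, 0)
  expect_equal(c(z$p2.5, z$p50, z$p97.5), c(0, 0, 0))
  expect_equal(pct_change(log(1.0493), 0)$p50, 4.93)
  # per-deleted-copy framing flips the sign
  expect_equal(pct_change(-log(1.0493), 0, per_deleted = TRUE)$p50, 4.93)
  # exact inversion and monotonicity
  betas <- seq(-0.1, 0.1, by = 0.01)
  p <- pct_change(betas, rep(0.01, length(betas)))
  expect_equal(log(1 + p$p50 / 100), betas)
  expect_true(all(diff(p$p50) > 0))
  expect_true(all(p$p2.5 <= p$p50 & p$p50 <= p$p97.5))
})

test_that("seasonal adjustment removes an injected annual cycle per sex", {
  set.seed(44)
  n <- 3000
  dates <- as.Date("1987-01-01") + sample.int(730, n, replace = TRUE)
  sex <- sample(c("F", "M"), n, replace = TRUE)
  doy <- 2 * pi * as.numeric(dates - as.Date("1987-01-01")) / 365.25
  # opposite-phase seasonality by sex
  season <- ifelse(sex == "F", 0.05 * sin(doy), -0.05 * sin(doy))
  log_y <- 1.7 + season + rnorm(n, 0, 0.2)
  ph <- tibble::tibble(subject_id = as.character(seq_len(n)),
                       trait = exp(log_y), draw_date = dates, sex = sex)
  adj <- seasonal_adjust(ph)
  amp <- function(y, keep) {
    f <- lm(y[keep] ~ sin(doy[keep]) + cos(doy[keep]))
    sqrt(sum(coef(f)[2:3]^2))
  }
  for (s in c("F", "M")) {
    keep <- sex == s
    expect_gt(amp(log(ph$trait), keep), 0.03)     # present before
    expect_lt(amp(adj$adj_log_trait, keep), 0.01) # gone after
  }
})

test_that("without seasonal signal the adjustment is nearly the identity", {
  set.seed(45)
  n <- 4000
  ph <- tibble::tibble(
    subject_id = as.character(seq_len(n)),
    trait = exp(rnorm(n, 1.7, 0.2)),
    draw_date = as.Date("1987-01-01") + sample.int(730, n, replace = TRUE),
    sex = sample(c("F", "M"), n, replace = TRUE))
  adj <- seasonal_adjust(ph)
  expect_lt(sqrt(mean((adj$adj_log_trait - log(ph$trait))^2)), 0.02)
})

test_that("tiny sex strata are passed through with a warning", {
  ph <- tibble::tibble(subject_id = as.character(1:12),
                       trait = exp(rnorm(12, 1.7, 0.1)),
                       draw_date = as.Date("1987-06-01") + 1:12,
                       sex = c(rep("F", 11), "M"))
  expect_warning(adj <- seasonal_adjust(ph), "Fewer than 10")
  expect_equal(adj$adj_log_trait[12], log(ph$trait[12]))
})

test_that("baseline model recovers generative covariate and plate effects", {
  cfg <- sim_config(n_subjects = 8500, chrom_lengths = c(chr1 = 2e4),
                    marker_spacing = 2000, n_plates = 100,
                    trait_model = trait_spec(plate_sd = 0.05), seed = 61)
  co <- simulate_cohort(simulate_marker_map(cfg), cfg)
  ph <- seasonal_adjust(co$phenotype)
  fit <- fit_baseline(ph)
  b <- lme4::fixef(fit)
  se_age <- sqrt(diag(as.matrix(vcov(fit))))[["age"]]
  expect_lt(abs(b[["age"]] - cfg$trait_model$age_slope), 3 * se_age)
  vc <- as.data.frame(lme4::VarCorr(fit))
  plate_sd_hat <- vc$sdcor[vc$grp == "plate"]
  expect_lt(abs(plate_sd_hat - 0.05) / 0.05, 0.5)
})

test_that("zero plate variance is estimated near the boundary", {
  cfg <- sim_config(n_subjects = 2000, chrom_lengths = c(chr1 = 2e4),
                    marker_spacing = 2000, n_plates = 20,
                    trait_model = trait_spec(plate_sd = 0), seed = 62)
  co <- simulate_cohort(simulate_marker_map(cfg), cfg)
  ph <- seasonal_adjust(co$phenotype)
  fit <- fit_baseline(ph)
  vc <- as.data.frame(lme4::VarCorr(fit))
  expect_lt(vc$sdcor[vc$grp == "plate"], 0.02)
})

test_that("a singular baseline design names the collinear column", {
  ph <- null_pheno(200, seed = 63)
  ph$center <- ph$sex    # center aliases sex
  expect_error(fit_baseline(ph), "collinear")
})

test_that("permuted copy number shows no effect; monomorphic errors", {
  ph <- null_pheno(600, seed = 64)
  set.seed(1)
  cn <- sample(rbinom(600, 2, 0.7))
  fit <- fit_cnp(ph, cn)
  expect_lt(abs(fit$effects$beta[1]), 3 * fit$effects$se[1])
  expect_error(fit_cnp(ph, rep(2, 600)), "monomorphic")
  # LRT is invariant to affine recoding of the covariate
  fit2 <- fit_cnp(ph, 2 * cn + 1)
  expect_equal(fit2$lrt$statistic, fit$lrt$statistic, tolerance = 1e-6)
})

test_that("with a single plate the mixed model reduces to OLS", {
  ph <- null_pheno(300, n_plates = 1, seed = 65)
  set.seed(2)
  cn <- rbinom(300, 2, 0.7)
  fit <- fit_cnp(ph, cn)
  ols <- lm(adj_log_trait ~ age * sex + log_bmi * sex + center + cn,
            data = dplyr::mutate(ph, cn = cn))
  expect_equal(fit$effects$beta[1], unname(coef(ols)[["cn"]]),
               tolerance = 1e-10)
  expect_equal(fit$effects$se[1],
               unname(sqrt(diag(vcov(ols)))[["cn"]]), tolerance = 1e-10)
})

test_that("tidy and glance expose the association result", {
  ph <- null_pheno(300, seed = 66)
  set.seed(3)
  fit <- fit_cnp(ph, rbinom(300, 2, 0.7), sex_interaction = TRUE)
  td <- tidy(fit)
  expect_equal(td$term, c("cn_female", "cn_male"))
  expect_true(all(c("pct_2.5", "pct_50", "pct_97.5") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$df, 2L)
  expect_gte(gl$statistic, 0)
})

test_that("genome scan flags an injected causal interval and controls FWER", {
  set.seed(71)
  n <- 600
  n_iv <- 60
  ph <- null_pheno(n, n_plates = 1, seed = 72)   # OLS path for speed
  iv <- tibble::tibble(interval_id = sprintf("chr1:%d-%d",
                                             (1:n_iv) * 1000,
                                             (1:n_iv) * 1000 + 999),
                       chrom = "chr1", start = (1:n_iv) * 1000L,
                       end = (1:n_iv) * 1000L + 999L, n_markers = 5L)
  M <- matrix(rbinom(n_iv * n, 2, 0.8), n_iv, n,
              dimnames = list(iv$interval_id, ph$subject_id))
  M <- structure(M, intervals = iv, class = c("cn_matrix", class(M)))
  # null scan: nothing Bonferroni-significant, p-values uniform
  scan0 <- genome_scan(M, ph)
  expect_equal(sum(scan0$bonferroni_significant), 0)
  expect_gt(stats::ks.test(scan0$p_value, "punif")$p.value, 0.01)
  # inject a 5%-per-copy effect at interval 7
  ph1 <- ph
  ph1$adj_log_trait <- ph1$adj_log_trait + log(1.05) * M[7, ]
  scan1 <- genome_scan(M, ph1)
  expect_equal(scan1$interval_id[which.min(scan1$p_value)],
               iv$interval_id[7])
  expect_true(scan1$bonferroni_significant[7])
})

test_that("null p-values from the generator's scan are uniform", {
  cfg <- sim_config(n_subjects = 500, chrom_lengths = c(chr1 = 2e4),
                    marker_spacing = 2000, n_plates = 1,
                    trait_model = trait_spec(seasonal_amplitude = 0),
                    seed = 73)
  co <- simulate_cohort(simulate_marker_map(cfg), cfg)
  ph <- seasonal_adjust(co$phenotype)
  n_iv <- 200
  set.seed(74)
  iv <- tibble::tibble(interval_id = as.character(1:n_iv), chrom = "chr1",
                       start = (1:n_iv) * 10L, end = (1:n_iv) * 10L + 9L,
                       n_markers = 1L)
  M <- matrix(rbinom(n_iv * 500, 2, 0.75), n_iv, 500,
              dimnames = list(iv$interval_id, ph$subject_id))
  M <- structure(M, intervals = iv, class = c("cn_matrix", class(M)))
  scan <- genome_scan(M, ph)
  expect_gt(stats::ks.test(scan$p_value, "punif")$p.value, 0.01)
})

test_that("conditioning on a perfectly tagging SNP absorbs the CNP signal", {
  ph <- null_pheno(500, seed = 75)
  set.seed(5)
  cn <- rbinom(500, 2, 0.7)
  ph$adj_log_trait <- ph$adj_log_trait + 0.05 * cn
  marg <- fit_cnp(ph, cn)
  cond <- conditional_fit(ph, cn, snp_dosages = 2 - cn,
                          sex_interaction = FALSE)
  expect_lt(cond$lrt$statistic, 1e-6)
  # a zero-effect independent SNP leaves the test almost unchanged
  snp0 <- rbinom(500, 2, 0.5)
  cond0 <- conditional_fit(ph, cn, snp0, sex_interaction = FALSE)
  expect_equal(cond0$lrt$statistic, marg$lrt$statistic, tolerance = 0.15)
  # an independent CNP effect survives conditioning on a correlated SNP
  snp_corr <- ifelse(runif(500) < 0.5, 2 - cn, rbinom(500, 2, 0.3))
  cond1 <- conditional_fit(ph, cn, snp_corr, sex_interaction = FALSE)
  expect_lt(cond1$lrt$p_value, marg$lrt$p_value * 100)
  expect_lt(cond1$lrt$p_value, 0.01)
})

test_that("haplotype strata isolate a female-only CNP effect", {
  set.seed(81)
  n <- 1600
  ph <- null_pheno(n, seed = 82)
  # one SNP-haplotype stratum (bb/aa) with CNP variation, one without
  hap1_snp <- sample(c("bb", "aa"), n, TRUE)
  hap2_snp <- "aa"
  hap1_cnp <- ifelse(runif(n) < 0.5, "0", "1")
  hap2_cnp <- "1"
  phased <- tibble::tibble(subject_id = ph$subject_id,
                           hap1_snp, hap2_snp, hap1_cnp, hap2_cnp)
  # +5% per deletion haplotype, women only, within the bb/aa stratum
  del <- hap1_cnp == "0"
  in_str <- hap1_snp == "bb"
  ph$adj_log_trait <- ph$adj_log_trait +
    ifelse(in_str & del & ph$sex == "F", 0.08, 0)
  res <- haplotype_association(ph, phased)
  f_row <- res[res$group == "F" & grepl("bb", res$stratum), ]
  m_row <- res[res$group == "M" & grepl("bb", res$stratum), ]
  expect_lt(f_row$p_value, 1e-3)
  expect_gt(m_row$p_value, 0.01)
  expect_equal(unique(res$df), 1L)   # two categories: 1-df tests
})

test_that("strata without CNP variation are skipped", {
  ph <- null_pheno(100, seed = 83)
  phased <- tibble::tibble(subject_id = ph$subject_id,
                           hap1_snp = "aa", hap2_snp = "aa",
                           hap1_cnp = "1", hap2_cnp = "1")
  res <- haplotype_association(ph, phased)
  expect_equal(nrow(res), 0)
  expect_equal(attr(res, "skipped"), "aa/aa")
})

test_that("gout-style outcomes recover odds ratios and show trait mediation", {
  set.seed(91)
  n <- 8411
  ph <- null_pheno(n, n_plates = 10, seed = 92, residual_sd = 0.15)
  cn <- rbinom(n, 2, 0.7)
  # outcome generated solely through the trait (full mediation)
  ph$adj_log_trait <- ph$adj_log_trait + 0.1 * cn
  lo <- log(0.07 / 0.93) + 5 * (ph$adj_log_trait - mean(ph$adj_log_trait))
  ph$gout <- rbinom(n, 1, 1 / (1 + exp(-lo)))
  marg <- binary_outcome_fit(ph, cn, include_plate = FALSE)
  expect_gt(marg$or, 1)
  adj <- binary_outcome_fit(ph, cn, adjust_trait = TRUE,
                            include_plate = FALSE)
  expect_lt(abs(log(adj$or)), abs(log(marg$or)) / 2)  # attenuated toward 1
  # no CN -> outcome path: OR near 1
  cn0 <- sample(cn)
  null <- binary_outcome_fit(ph, cn0, include_plate = FALSE)
  expect_lt(abs(log(null$or)), 3 * null$se)
  expect_error(binary_outcome_fit(ph, cn, outcome = "missing_col"),
               regexp = "outcome")
})

test_that("inverse-variance pooling weights by precision", {
  p <- inverse_variance_pool(c(0.04, 0.06), c(0.01, 0.02))
  expect_equal(p$beta, (0.04 / 1e-4 + 0.06 / 4e-4) / (1 / 1e-4 + 1 / 4e-4))
  expect_equal(p$se, sqrt(1 / (1 / 1e-4 + 1 / 4e-4)))
})
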