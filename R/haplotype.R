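#' Haplotype-stratified CNP association
#'
#' Tests whether CNP-haplotype variation is associated with the trait within
#' strata of the SNP-allele haplotype pair, establishing independence of the
#' CNP effect from the SNPs. Subjects are stratified by their (unordered)
#' pair of SNP haplotypes; within each stratum showing variation in the
#' (unordered) pair of CNP haplotypes, the adjusted log trait is regressed
#' on the CNP-haplotype-pair category (reference = most common pair) with
#' age and log BMI as covariates, for the sexes combined and separately. A
#' likelihood-ratio test with `#categories - 1` degrees of freedom compares
#' against the covariate-only model.
#'
#' @param pheno phenotype tibble with `adj_log_trait`, `age`, `log_bmi`,
#'   `sex`, `subject_id`.
#' @param phased tibble with one row per subject: `subject_id`, `hap1_snp`,
#'   `hap2_snp` (SNP-allele haplotype strings), `hap1_cnp`, `hap2_cnp`
#'   (CNP copy strings, each locus 0 or 1 copies per haplotype). Phasing
#'   itself is an upstream input.
#' @param min_stratum_n smallest stratum analysed (rarer haplotype pairs are
#'   excluded).
#' @param min_category_n CNP-pair categories rarer than this within a
#'   stratum are dropped before testing.
#' @return A tibble with one row per stratum x group (`all`, `F`, `M`):
#'   `stratum`, `group`, `n`, `n_categories`, `lrt_stat`, `df`, `p_value`.
#'   Strata without CNP variation are skipped; attribute `"skipped"` lists
#'   them.
#' @export
haplotype_association <- function(pheno, phased, min_stratum_n = 30,
                                  min_category_n = 5) {
  pheno <- as_tibble(pheno)
  phased <- as_tibble(phased)
  dat <- left_join(pheno, phased, by = "subject_id")
  dat <- dat[complete.cases(dat[, c("hap1_snp", "hap2_snp",
                                    "hap1_cnp", "hap2_cnp")]), ]
  pair <- function(a, b) {
    ifelse(a <= b, paste(a, b, sep = "/"), paste(b, a, sep = "/"))
  }
  dat$stratum <- pair(dat$hap1_snp, dat$hap2_snp)
  dat$cnp_pair <- pair(dat$hap1_cnp, dat$hap2_cnp)
  skipped <- character(0)
  res <- list()
  for (st in unique(dat$stratum)) {
    sub <- dat[dat$stratum == st, ]
    tab <- sort(table(sub$cnp_pair), decreasing = TRUE)
    keep <- names(tab)[tab >= min_category_n]
    sub <- sub[sub$cnp_pair %in% keep, ]
    if (nrow(sub) < min_stratum_n || length(keep) < 2) {
      skipped <- c(skipped, st)
      next
    }
    sub$cnp_pair <- factor(sub$cnp_pair, levels = keep)  # ref = most common
    groups <- list(all = sub, F = sub[sub$sex == "F", ],
                   M = sub[sub$sex == "M", ])
    for (g in names(groups)) {
      d <- groups[[g]]
      ncat <- length(unique(as.character(d$cnp_pair)))
      if (nrow(d) < min_stratum_n / 2 || ncat < 2) next
      d$cnp_pair <- droplevels(d$cnp_pair)
      rhs_cov <- if (g == "all") "age * sex + log_bmi * sex" else
        "age + log_bmi"
      full <- lm(as.formula(paste("adj_log_trait ~ cnp_pair +", rhs_cov)),
                 data = d)
      null <- lm(as.formula(paste("adj_log_trait ~", rhs_cov)), data = d)
      stat <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))))
      df <- length(levels(d$cnp_pair)) - 1L
      res[[length(res) + 1L]] <- tibble(
        stratum = st, group = g, n = nrow(d),
        n_categories = length(levels(d$cnp_pair)),
        lrt_stat = stat, df = df,
        p_value = pchisq(stat, df, lower.tail = FALSE))
    }
  }
  out <- bind_rows(res)
  attr(out, "skipped") <- skipped
  out
}

#' Logistic model for a binary outcome
#'
#' Logistic regression of a binary outcome (e.g. gout) on copy number with
#' the same clinical and technical covariates as the trait models; chemistry
#' plate enters as a fixed effect. Optionally adjusts for the adjusted log
#' trait to assess whether the copy-number association is mediated through
#' the trait.
#'
#' @param pheno phenotype tibble containing the outcome column and, when
#'   `adjust_trait = TRUE`, `adj_log_trait`.
#' @param cn copy-number vector aligned to `pheno`.
#' @param outcome name of the binary outcome column.
#' @param adjust_trait include `adj_log_trait` as a covariate?
#' @param include_plate include plate fixed effects (disable for small
#'   simulations with many plates)?
#' @return A one-row tibble: `or` (odds ratio per copy), `or_low`,
#'   `or_high` (Wald 95% CI), `beta`, `se`, `p_value`, `n`.
#' @export
binary_outcome_fit <- function(pheno, cn, outcome = "gout",
                               adjust_trait = FALSE, include_plate = TRUE) {
  pheno <- as_tibble(pheno)
  stopifnot(outcome %in% names(pheno), length(cn) == nrow(pheno))
  dat <- pheno
  dat$cn <- as.numeric(cn)
  dat$.y <- dat[[outcome]]
  dat <- dat[!is.na(dat$cn) & !is.na(dat$.y), ]
  if (length(unique(dat$.y)) < 2) abort("Outcome is monomorphic.")
  rhs <- c("cn", "age * sex", "log_bmi * sex")
  if (length(unique(dat$center)) > 1) rhs <- c(rhs, "center")
  if (include_plate && length(unique(dat$plate)) > 1) rhs <- c(rhs, "plate")
  if (adjust_trait) rhs <- c(rhs, "adj_log_trait")
  f <- as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  fit <- glm(f, data = dat, family = binomial())
  beta <- coef(fit)[["cn"]]
  se <- sqrt(vcov(fit)["cn", "cn"])
  z <- qnorm(0.975)
  tibble(or = exp(beta), or_low = exp(beta - z * se),
         or_high = exp(beta + z * se), beta = beta, se = se,
         p_value = 2 * pnorm(-abs(beta / se)), n = nrow(dat))
}
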