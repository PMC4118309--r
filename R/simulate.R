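#' Specify a CNP locus for simulation
#'
#' A CNP locus is a genomic interval at which a deletion allele segregates in
#' the population. Each haplotype carries either one copy (the reference
#' allele) or zero copies (the deletion allele), so subject-level copy number
#' at the locus is 0, 1 or 2 under Hardy-Weinberg equilibrium. A locus may be
#' linked to a previously defined locus with a haplotype-level repulsion
#' parameter `r` in `[-1, 0]`: negative values make deletion alleles at the
#' two loci avoid co-occurring on the same haplotype, which induces a negative
#' correlation of subject copy number across loci. At `r = -1` with compatible
#' allele frequencies no haplotype carries both deletions, so no subject can
#' be homozygously deleted at both loci.
#'
#' @param chrom chromosome name.
#' @param start,end locus bounds in base pairs (1-based, `start < end`).
#' @param deletion_allele_freq frequency of the zero-copy allele in `[0, 1]`.
#' @param linked_to optional integer index (into the configuration's
#'   `cnp_loci` list) of an earlier locus this one is linked to.
#' @param repulsion haplotype correlation parameter in `[-1, 0]` used when
#'   `linked_to` is set.
#' @return A list of class `cnp_spec`.
#' @export
cnp_spec <- function(chrom, start, end, deletion_allele_freq,
                     linked_to = NULL, repulsion = -1) {
  stopifnot(start < end,
            deletion_allele_freq >= 0, deletion_allele_freq <= 1,
            repulsion >= -1, repulsion <= 0)
  structure(list(chrom = chrom, start = start, end = end,
                 deletion_allele_freq = deletion_allele_freq,
                 linked_to = linked_to, repulsion = repulsion),
            class = "cnp_spec")
}

#' Specify the generative trait model
#'
#' Parameters of the log-scale generative model for the quantitative trait
#' (a serum concentration in mg/dL, modeled on its natural-log scale):
#' `log(trait) = intercept + covariate effects + seasonal sinusoid +
#' sex-specific copy-number effects + plate random intercept + residual`.
#' Copy-number effects are per copy on the log scale; a multiplicative effect
#' of `1.05` per deleted copy corresponds to `cn_effect = -log(1.05)` per
#' copy gained.
#'
#' @param intercept log-trait intercept (default `log(5.9)`, a typical serum
#'   urate level).
#' @param sex_effect additive log-trait shift for males.
#' @param age_slope,logbmi_slope slopes for age (years) and log BMI.
#' @param age_sex_interaction,logbmi_sex_interaction additional male slopes.
#' @param center_effects named numeric vector of study-center shifts.
#' @param plate_sd standard deviation of the chemistry-plate random intercept
#'   (log-trait units).
#' @param seasonal_amplitude amplitude of a 365.25-day sinusoid in draw date.
#' @param cn_effect_female,cn_effect_male per-copy log-trait effects; scalars
#'   or vectors with one entry per CNP locus.
#' @param residual_sd residual standard deviation (log-trait units, `> 0`).
#' @param gout_prevalence approximate prevalence of the binary outcome; 0
#'   disables its generation.
#' @param gout_log_trait_coef log-odds of the binary outcome per unit of
#'   log trait (the outcome is generated through the trait, i.e. mediated).
#' @return A list of class `trait_spec`.
#' @export
trait_spec <- function(intercept = log(5.9),
                       sex_effect = 0.17,
                       age_slope = 0.002,
                       logbmi_slope = 0.30,
                       age_sex_interaction = -0.001,
                       logbmi_sex_interaction = -0.05,
                       center_effects = c(A = 0, B = 0.01, C = -0.01, D = 0.02),
                       plate_sd = 0.02,
                       seasonal_amplitude = 0.03,
                       cn_effect_female = 0,
                       cn_effect_male = 0,
                       residual_sd = 0.2,
                       gout_prevalence = 0,
                       gout_log_trait_coef = 3) {
  stopifnot(residual_sd > 0, plate_sd >= 0, seasonal_amplitude >= 0)
  structure(as.list(environment()), class = "trait_spec")
}

#' Configure a synthetic cohort
#'
#' Collects every knob of the synthetic-cohort generator: cohort size, the
#' marker map (chromosome lengths, spacing, SNP fraction), the CNP loci and
#' rare-CNV background, the technical-noise model (genomic waves, plate batch
#' shifts, marker-level noise), and the trait model. Defaults emulate an
#' Affymetrix-6.0-like array (one marker per ~1.7 kb, roughly half SNPs) and
#' cohort-scale noise levels under which common deletions are clearly visible
#' in region-averaged log R ratios.
#'
#' @param n_subjects number of subjects (`>= 2`).
#' @param chrom_lengths named numeric vector, chromosome -> length in bp.
#' @param marker_spacing average spacing between markers in bp.
#' @param snp_fraction fraction of markers that are SNPs (the rest are
#'   nonpolymorphic copy-number probes without BAF).
#' @param cnp_loci list of [cnp_spec()] objects.
#' @param rare_cnv_rate expected number of random rare CNVs per subject.
#' @param wave_amplitude typical per-subject genomic-wave amplitude in LRR
#'   units (per-subject amplitudes are drawn log-normally around this value;
#'   0 disables waves).
#' @param n_qc_violators number of subjects given a deliberately extreme wave
#'   amplitude so that they fail autocorrelation/MAD quality control.
#' @param plate_sd standard deviation of the per-plate LRR shift.
#' @param lrr_sd marker-level LRR noise standard deviation.
#' @param baf_sd spread of BAF genotype clusters (truncated normal on
#'   `[0, 1]`).
#' @param lrr_mu expected LRR per copy number 0..4; the default is compressed
#'   relative to `log2(c/2)`, matching typical array response.
#' @param n_plates number of chemistry plates (default about one per 85
#'   subjects).
#' @param missing_call_rate probability that a homozygous-deletion subject
#'   receives a missing genotype call at a SNP inside a CNP locus (the
#'   surrogate-imputation sensitivity of the calling algorithm).
#' @param trait_model a [trait_spec()].
#' @param seed integer seed; every draw of the generator is a deterministic
#'   function of the configuration including this seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 1000,
                       chrom_lengths = c(chr1 = 1e6),
                       marker_spacing = 1700,
                       snp_fraction = 0.5,
                       cnp_loci = list(),
                       rare_cnv_rate = 0,
                       wave_amplitude = 0,
                       n_qc_violators = 0,
                       plate_sd = 0.01,
                       lrr_sd = 0.2,
                       baf_sd = 0.03,
                       lrr_mu = c(-2.0, -0.55, 0.0, 0.35, 0.65),
                       n_plates = NULL,
                       missing_call_rate = 0.75,
                       trait_model = trait_spec(),
                       seed = 1) {
  stopifnot(n_subjects >= 2, marker_spacing > 0, all(chrom_lengths > 0),
            lrr_sd >= 0, plate_sd >= 0, wave_amplitude >= 0,
            rare_cnv_rate >= 0, length(lrr_mu) == 5,
            missing_call_rate >= 0, missing_call_rate <= 1)
  if (is.null(n_plates)) n_plates <- max(2L, ceiling(n_subjects / 85))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a marker map
#'
#' Generates evenly spaced, jittered marker positions along each chromosome
#' with a smooth (AR(1)) local GC-content series, mimicking the spatial
#' autocorrelation of GC along real genomes that drives genomic waves.
#'
#' @param config a [sim_config()].
#' @return A tibble with columns `marker_id`, `chrom`, `pos` (1-based bp,
#'   strictly increasing within chromosome), `is_snp`, `gc` (fraction in
#'   `[0, 1]`).
#' @export
simulate_marker_map <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(config$marker_spacing > config$chrom_lengths)) {
    abort("`marker_spacing` exceeds a chromosome length; no markers fit.")
  }
  with_seed_local(config$seed, {
    map_dfr(names(config$chrom_lengths), function(ch) {
      len <- config$chrom_lengths[[ch]]
      sp <- config$marker_spacing
      base <- seq(sp / 2, len, by = sp)
      pos <- round(base + runif(length(base), -0.3, 0.3) * sp)
      pos <- pmin(pmax(pos, 1), len)
      pos <- sort(pos)
      # enforce strict monotonicity after rounding
      while (any(d <- diff(pos) <= 0)) pos[which(d) + 1L] <- pos[which(d)] + 1L
      m <- length(pos)
      # smooth AR(1) series mapped to a plausible GC range
      phi <- 0.98
      z <- numeric(m)
      z[1] <- rnorm(1)
      if (m > 1) {
        e <- rnorm(m - 1, sd = sqrt(1 - phi^2))
        for (j in 2:m) z[j] <- phi * z[j - 1] + e[j - 1]
      }
      gc <- pmin(pmax(0.41 + 0.07 * z, 0), 1)
      tibble(marker_id = sprintf("%s_m%05d", ch, seq_len(m)),
             chrom = ch, pos = as.integer(pos),
             is_snp = runif(m) < config$snp_fraction,
             gc = gc)
    })
  })
}

# haplotype deletion indicators for all loci; returns n x 2 x L array
draw_haplotypes <- function(n, loci) {
  L <- length(loci)
  d <- array(0L, dim = c(n, 2L, L))
  done <- rep(FALSE, L)
  for (l in seq_len(L)) {
    if (done[l]) next
    lk <- loci[[l]]$linked_to
    if (!is.null(lk)) {
      stopifnot(lk >= 1, lk < l)
      f1 <- loci[[lk]]$deletion_allele_freq
      f2 <- loci[[l]]$deletion_allele_freq
      r <- loci[[l]]$repulsion
      cv <- r * sqrt(f1 * (1 - f1) * f2 * (1 - f2))
      p11 <- min(max(f1 * f2 + cv, 0), min(f1, f2))
      p10 <- f1 - p11
      p01 <- f2 - p11
      p00 <- 1 - p11 - p10 - p01
      if (p00 < 0) abort("Incompatible allele frequencies for linked loci.")
      h <- matrix(sample.int(4L, 2L * n, replace = TRUE,
                             prob = c(p00, p10, p01, p11)), n, 2)
      d[, , lk] <- (h == 2L | h == 4L) * 1L
      d[, , l] <- (h == 3L | h == 4L) * 1L
      done[c(lk, l)] <- TRUE
    } else {
      f <- loci[[l]]$deletion_allele_freq
      d[, , l] <- matrix(rbinom(2L * n, 1L, f), n, 2)
      done[l] <- TRUE
    }
  }
  d
}

#' Simulate a cohort with known ground truth
#'
#' Generates marker-level intensities (LRR/BAF), a phenotype table, genotype
#' calls at SNPs inside CNP loci, and truth tables for a synthetic cohort.
#' The observation model is
#' `LRR = mu(CN) + subject_amplitude * wave(marker) + plate shift + noise`,
#' with the wave a GC-tracking plus low-frequency sinusoidal pattern; BAF at
#' SNPs is drawn from genotype-conditional truncated-normal clusters at
#' `b / c` for `b` B alleles out of `c` copies (uniform noise at copy number
#' 0). The trait follows the [trait_spec()] model. Haplotypes at linked CNP
#' loci are drawn with repulsion (see [cnp_spec()]).
#'
#' @param map a marker map from [simulate_marker_map()].
#' @param config the same [sim_config()] used for the map.
#' @return A list of class `cnp_cohort` with elements `intensity`
#'   ([intensity_data()]), `phenotype` (tibble), `genotypes` (tibble of calls
#'   at in-CNP SNPs), and `truth` (list: `cn` per subject x locus,
#'   `haplotypes`, `rare_cnvs`, `plate_lrr`, `plate_trait`,
#'   `wave_amplitude`, `qc_flags`).
#' @export
simulate_cohort <- function(map, config) {
  stopifnot(inherits(config, "sim_config"))
  map <- as_tibble(map)
  for (lc in config$cnp_loci) {
    if (!lc$chrom %in% map$chrom ||
        lc$end > config$chrom_lengths[[lc$chrom]]) {
      abort("A CNP locus lies outside the chromosome bounds.")
    }
  }
  n <- config$n_subjects
  m <- nrow(map)
  L <- length(config$cnp_loci)
  ts <- config$trait_model
  with_seed_local(child_seed(config$seed, 1L), {
    subj <- sprintf("S%05d", seq_len(n))

    ## --- latent copy number -------------------------------------------------
    hap <- draw_haplotypes(n, config$cnp_loci)             # deletion indicators
    cn_locus <- if (L > 0) {
      2L - apply(hap, c(1, 3), sum)
    } else {
      matrix(integer(0), n, 0)
    }

    cn <- matrix(2L, n, m)                                  # subject x marker
    locus_idx <- vector("list", L)
    for (l in seq_len(L)) {
      idx <- region_marker_idx(map, config$cnp_loci[[l]])
      locus_idx[[l]] <- idx
      if (length(idx)) cn[, idx] <- cn_locus[, l]
    }

    rare <- tibble(subject_id = character(), chrom = character(),
                   start = integer(), end = integer(), cn = integer(),
                   n_markers = integer())
    if (config$rare_cnv_rate > 0) {
      n_ev <- rpois(n, config$rare_cnv_rate)
      ev <- list()
      for (i in which(n_ev > 0)) {
        for (k in seq_len(n_ev[i])) {
          ch <- sample(unique(map$chrom), 1)
          on_ch <- which(map$chrom == ch)
          width <- sample(5:60, 1)
          if (length(on_ch) <= width) next
          s0 <- sample(seq_len(length(on_ch) - width), 1)
          idx <- on_ch[s0:(s0 + width - 1L)]
          cnv_cn <- sample(c(0L, 1L, 3L, 4L), 1,
                           prob = c(0.05, 0.5, 0.4, 0.05))
          cn[i, idx] <- cnv_cn
          ev[[length(ev) + 1L]] <- tibble(
            subject_id = subj[i], chrom = ch,
            start = map$pos[idx[1]], end = map$pos[idx[length(idx)]],
            cn = cnv_cn, n_markers = width)
        }
      }
      if (length(ev)) rare <- bind_rows(ev)
    }

    ## --- intensities --------------------------------------------------------
    mu <- config$lrr_mu[cn + 1L]
    dim(mu) <- dim(cn)

    wave_base <- numeric(m)
    for (ch in unique(map$chrom)) {
      on_ch <- map$chrom == ch
      wgc <- windowed_mean(map$pos[on_ch], map$gc[on_ch], 5e4)
      sdw <- sd(wgc)
      gpart <- if (is.na(sdw) || sdw == 0) 0 else (wgc - mean(wgc)) / sdw
      wave_base[on_ch] <- 0.8 * gpart + 0.6 * sin(2 * pi * map$pos[on_ch] / 5e5)
    }
    amp <- if (config$wave_amplitude > 0) {
      exp(rnorm(n, log(config$wave_amplitude), 0.5))
    } else rep(0, n)
    violators <- integer(0)
    if (config$n_qc_violators > 0) {
      violators <- seq_len(min(config$n_qc_violators, n))
      amp[violators] <- pmax(config$wave_amplitude, 0.05) * 20
    }

    plate <- sprintf("P%03d", rep_len(seq_len(config$n_plates), n))
    plate_lrr <- rnorm(config$n_plates, 0, config$plate_sd)
    names(plate_lrr) <- sprintf("P%03d", seq_len(config$n_plates))

    lrr <- mu + outer(amp, wave_base) + plate_lrr[plate] +
      matrix(rnorm(n * m, 0, config$lrr_sd), n, m)
    dimnames(lrr) <- list(subj, map$marker_id)

    baf <- matrix(NA_real_, n, m, dimnames = dimnames(lrr))
    snp_cols <- which(map$is_snp)
    pB <- runif(length(snp_cols), 0.05, 0.95)
    bmat <- matrix(NA_integer_, n, length(snp_cols))
    if (length(snp_cols)) {
      cn_snp <- cn[, snp_cols, drop = FALSE]
      pmat <- matrix(pB, n, length(snp_cols), byrow = TRUE)
      bmat <- matrix(rbinom(length(cn_snp), as.vector(cn_snp),
                            as.vector(pmat)),
                     n, length(snp_cols))
      centers <- ifelse(cn_snp > 0, bmat / pmax(cn_snp, 1L), NA_real_)
      vals <- rtruncnorm(length(centers),
                         mean = ifelse(is.na(centers), 0.5, centers),
                         sd = config$baf_sd)
      vals[is.na(centers)] <- runif(sum(is.na(centers)))   # CN0: uniform noise
      baf[, snp_cols] <- vals
    }

    ## --- genotype calls at SNPs inside CNP loci -----------------------------
    geno <- tibble(subject_id = character(), marker_id = character(),
                   call = character())
    for (l in seq_len(L)) {
      in_locus_snps <- intersect(locus_idx[[l]], snp_cols)
      for (j in in_locus_snps) {
        jj <- match(j, snp_cols)
        b <- bmat[, jj]
        c_ <- cn[, j]
        call <- character(n)
        call[c_ == 2L] <- c("A", "AB", "B")[b[c_ == 2L] + 1L]
        call[c_ == 1L] <- c("A", "B")[b[c_ == 1L] + 1L]
        cz <- which(c_ == 0L)
        miss <- runif(length(cz)) < config$missing_call_rate
        call[cz] <- ifelse(miss, NA_character_,
                           sample(c("A", "B"), length(cz), replace = TRUE))
        geno <- bind_rows(geno, tibble(subject_id = subj,
                                       marker_id = map$marker_id[j],
                                       call = call))
      }
    }

    ## --- phenotype ----------------------------------------------------------
    sex <- ifelse(runif(n) < 0.47, "M", "F")
    age <- rnorm(n, 54, 5.7)
    log_bmi <- rnorm(n, log(27), 0.17)
    center <- sample(names(ts$center_effects), n, replace = TRUE)
    draw_date <- as.Date("1987-01-01") + sample.int(730L, n, replace = TRUE) - 1L
    plate_trait <- rnorm(config$n_plates, 0, ts$plate_sd)
    names(plate_trait) <- names(plate_lrr)

    male <- sex == "M"
    eta <- ts$intercept + ts$sex_effect * male +
      ts$age_slope * age + ts$logbmi_slope * log_bmi +
      ts$age_sex_interaction * age * male +
      ts$logbmi_sex_interaction * log_bmi * male +
      ts$center_effects[center] +
      ts$seasonal_amplitude *
        sin(2 * pi * as.numeric(draw_date - as.Date("1987-01-01")) / 365.25) +
      plate_trait[plate]
    if (L > 0) {
      ef <- rep_len(ts$cn_effect_female, L)
      em <- rep_len(ts$cn_effect_male, L)
      for (l in seq_len(L)) {
        eta <- eta + ifelse(male, em[l], ef[l]) * cn_locus[, l]
      }
    }
    log_trait <- eta + rnorm(n, 0, ts$residual_sd)

    pheno <- tibble(subject_id = subj, trait = exp(log_trait),
                    draw_date = draw_date, sex = sex, age = age,
                    log_bmi = log_bmi, center = center, plate = plate)
    if (ts$gout_prevalence > 0) {
      lo <- log(ts$gout_prevalence / (1 - ts$gout_prevalence)) +
        ts$gout_log_trait_coef * (log_trait - mean(log_trait))
      pheno$gout <- rbinom(n, 1L, 1 / (1 + exp(-lo)))
    }

    truth <- list(
      cn = {
        tb <- tibble(subject_id = subj)
        for (l in seq_len(L)) tb[[paste0("locus", l)]] <- cn_locus[, l]
        tb
      },
      haplotypes = if (L > 0) {
        map_dfr(seq_len(L), function(l) {
          tibble(subject_id = subj, locus = l,
                 hap1_copies = 1L - hap[, 1, l],
                 hap2_copies = 1L - hap[, 2, l])
        })
      } else tibble(),
      rare_cnvs = rare,
      plate_lrr = plate_lrr,
      plate_trait = plate_trait,
      wave_amplitude = setNames(amp, subj),
      qc_flags = tibble(subject_id = subj,
                        injected_violator = seq_len(n) %in% violators)
    )

    structure(list(intensity = intensity_data(lrr, baf, map),
                   phenotype = pheno, genotypes = geno, truth = truth),
              class = "cnp_cohort")
  })
}

#' @export
print.cnp_cohort <- function(x, ...) {
  cat("<cnp_cohort> ", nrow(x$phenotype), " subjects, ",
      ncol(x$intensity$lrr), " markers, ",
      max(0, ncol(x$truth$cn) - 1), " CNP locus/loci\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to TSV files
#'
#' Exports the marker map, LRR and BAF matrices (markers in rows, subjects in
#' columns), phenotype table, genotype calls and truth tables as
#' tab-separated files, plus a `manifest.tsv` recording the file names and
#' the generator seed.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param seed the generator seed to record in the manifest.
#' @return Invisibly, the manifest tibble.
#' @export
write_cohort <- function(cohort, dir, seed = NA_integer_) {
  stopifnot(inherits(cohort, "cnp_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(x, f) {
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(cohort$intensity$map, "marker_map.tsv")
  wt(data.frame(marker_id = colnames(cohort$intensity$lrr),
                t(cohort$intensity$lrr), check.names = FALSE), "lrr.tsv")
  wt(data.frame(marker_id = colnames(cohort$intensity$baf),
                t(cohort$intensity$baf), check.names = FALSE), "baf.tsv")
  wt(cohort$phenotype, "phenotype.tsv")
  wt(cohort$genotypes, "genotypes.tsv")
  wt(cohort$truth$cn, "truth_cn.tsv")
  manifest <- tibble(
    file = c("marker_map.tsv", "lrr.tsv", "baf.tsv", "phenotype.tsv",
             "genotypes.tsv", "truth_cn.tsv"),
    seed = seed)
  wt(manifest, "manifest.tsv")
  invisible(manifest)
}
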