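test_that("marker map has the configured density, order and smooth GC", {
  cfg <- sim_config(n_subjects = 10, chrom_lengths = c(chr1 = 1e6),
                    marker_spacing = 1000, seed = 42)
  map <- simulate_marker_map(cfg)
  expect_equal(nrow(map), 1000, tolerance = 0.01)
  expect_true(all(diff(map$pos) > 0))
  expect_false(anyDuplicated(map$marker_id) > 0)
  expect_true(all(map$gc >= 0 & map$gc <= 1))
  # GC is spatially autocorrelated, the precondition for genomic waves
  g <- map$gc
  lag1 <- cor(g[-1], g[-length(g)])
  expect_gt(lag1, 0.5)
})

test_that("map generation is deterministic and rejects impossible spacing", {
  cfg <- sim_config(n_subjects = 10, chrom_lengths = c(chr1 = 1e5),
                    marker_spacing = 500, seed = 7)
  expect_identical(simulate_marker_map(cfg), simulate_marker_map(cfg))
  bad <- sim_config(n_subjects = 10, chrom_lengths = c(chr1 = 100),
                    marker_spacing = 500)
  expect_error(simulate_marker_map(bad), "spacing")
})

test_that("cohort generation is byte-identical under the same seed", {
  cfg <- sim_config(n_subjects = 30, chrom_lengths = c(chr1 = 5e4),
                    marker_spacing = 1000,
                    cnp_loci = list(cnp_spec("chr1", 1e4, 2e4, 0.3)),
                    wave_amplitude = 0.02, seed = 11)
  map <- simulate_marker_map(cfg)
  a <- simulate_cohort(map, cfg)
  b <- simulate_cohort(map, cfg)
  expect_identical(a$intensity$lrr, b$intensity$lrr)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$truth$cn, b$truth$cn)
})

test_that("per-copy-number LRR group means converge to the configured levels", {
  cfg <- sim_config(n_subjects = 5000, chrom_lengths = c(chr1 = 5e4),
                    marker_spacing = 1000,
                    cnp_loci = list(cnp_spec("chr1", 1e4, 3e4, 0.3)),
                    wave_amplitude = 0, plate_sd = 0, lrr_sd = 0.2, seed = 5)
  map <- simulate_marker_map(cfg)
  co <- simulate_cohort(map, cfg)
  idx <- which(map$pos >= 1e4 & map$pos <= 3e4)
  cn <- co$truth$cn$locus1
  for (c_ in 0:2) {
    vals <- co$intensity$lrr[cn == c_, idx]
    se <- 0.2 / sqrt(length(vals))
    expect_lt(abs(mean(vals) - cfg$lrr_mu[c_ + 1]), 3 * se + 1e-12)
  }
})

test_that("copy number equals the sum of the two haplotype copies", {
  cfg <- sim_config(n_subjects = 200, chrom_lengths = c(chr1 = 5e4),
                    marker_spacing = 1000,
                    cnp_loci = list(cnp_spec("chr1", 1e4, 2e4, 0.4),
                                    cnp_spec("chr1", 3e4, 4e4, 0.2,
                                             linked_to = 1, repulsion = -0.5)),
                    seed = 3)
  co <- simulate_cohort(simulate_marker_map(cfg), cfg)
  hap <- co$truth$haplotypes
  for (l in 1:2) {
    h <- hap[hap$locus == l, ]
    expect_identical(h$hap1_copies + h$hap2_copies,
                     as.integer(co$truth$cn[[paste0("locus", l)]]))
    expect_true(all(co$truth$cn[[paste0("locus", l)]] %in% 0:2))
  }
})

test_that("full repulsion forbids double homozygous deletions", {
  cfg <- sim_config(n_subjects = 2000, chrom_lengths = c(chr1 = 5e4),
                    marker_spacing = 1000,
                    cnp_loci = list(cnp_spec("chr1", 1e4, 2e4, 0.5),
                                    cnp_spec("chr1", 3e4, 4e4, 0.5,
                                             linked_to = 1, repulsion = -1)),
                    seed = 9)
  co <- simulate_cohort(simulate_marker_map(cfg), cfg)
  cn1 <- co$truth$cn$locus1
  cn2 <- co$truth$cn$locus2
  expect_equal(sum(cn1 == 0 & cn2 == 0), 0)
  expect_lt(cor(cn1, cn2, method = "spearman"), 0)
})

test_that("BAF respects genotype-conditional clusters", {
  cfg <- sim_config(n_subjects = 400, chrom_lengths = c(chr1 = 5e4),
                    marker_spacing = 1000, snp_fraction = 1,
                    cnp_loci = list(cnp_spec("chr1", 1e4, 3e4, 0.4)),
                    baf_sd = 0.03, seed = 13)
  map <- simulate_marker_map(cfg)
  co <- simulate_cohort(map, cfg)
  idx <- which(map$pos >= 1e4 & map$pos <= 3e4)
  cn <- co$truth$cn$locus1
  # hemizygous subjects have no heterozygous cluster at in-locus SNPs
  baf1 <- co$intensity$baf[cn == 1, idx]
  expect_equal(sum(baf1 > 0.2 & baf1 < 0.8), 0)
})

test_that("a null trait shows no copy-number association", {
  cfg <- sim_config(n_subjects = 800, chrom_lengths = c(chr1 = 3e4),
                    marker_spacing = 1000,
                    cnp_loci = list(cnp_spec("chr1", 1e4, 2e4, 0.3)),
                    trait_model = trait_spec(cn_effect_female = 0,
                                             cn_effect_male = 0),
                    seed = 21)
  co <- simulate_cohort(simulate_marker_map(cfg), cfg)
  ph <- seasonal_adjust(co$phenotype)
  fit <- fit_cnp(ph, co$truth$cn$locus1, sex_interaction = FALSE)
  expect_lt(abs(fit$effects$beta[1]), 3 * fit$effects$se[1])
})

test_that("cohort files round-trip through write_cohort", {
  cfg <- sim_config(n_subjects = 12, chrom_lengths = c(chr1 = 2e4),
                    marker_spacing = 2000,
                    cnp_loci = list(cnp_spec("chr1", 5e3, 1e4, 0.3)),
                    seed = 2)
  co <- simulate_cohort(simulate_marker_map(cfg), cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir, seed = 2)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  lrr <- utils::read.delim(file.path(dir, "lrr.tsv"), check.names = FALSE)
  expect_equal(dim(lrr), c(ncol(co$intensity$lrr), 1 + nrow(co$intensity$lrr)))
  expect_equal(unname(as.matrix(lrr[, -1])), unname(t(co$intensity$lrr)),
               tolerance = 1e-12)
})
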