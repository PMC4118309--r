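# small programmatic fixtures and independent oracles used across tests

# hand-built marker map
tiny_map <- function(pos, chrom = "chr1", gc = NULL, is_snp = TRUE) {
  n <- length(pos)
  tibble::tibble(
    marker_id = sprintf("%s_m%05d", chrom, seq_len(n)),
    chrom = chrom, pos = as.integer(pos),
    is_snp = rep_len(is_snp, n),
    gc = if (is.null(gc)) rep(0.4, n) else gc)
}

# intensity_data from one or more LRR rows (BAF optional)
tiny_intensity <- function(lrr, map, baf = NULL) {
  lrr <- rbind(lrr)
  if (is.null(baf)) baf <- matrix(NA_real_, nrow(lrr), ncol(lrr))
  baf <- rbind(baf)
  rownames(lrr) <- rownames(baf) <- sprintf("S%03d", seq_len(nrow(lrr)))
  colnames(lrr) <- colnames(baf) <- map$marker_id
  intensity_data(lrr, baf, map)
}

# exhaustive Viterbi oracle: argmax over all 6^m state paths
enumerate_best_path <- function(lrr, baf, is_snp, pos, params) {
  m <- length(lrr)
  E <- cnpassoc:::emission_matrix(lrr, baf, is_snp, params)
  lP <- lapply(seq_len(max(m - 1, 0)), function(j) {
    log(transition_matrix(max(pos[j + 1] - pos[j], 1), params))
  })
  paths <- as.matrix(expand.grid(rep(list(1:6), m)))
  scores <- log(params$stationary_probs[paths[, 1]]) + E[cbind(paths[, 1], 1)]
  if (m > 1) {
    for (j in 2:m) {
      scores <- scores + lP[[j - 1]][cbind(paths[, j - 1], paths[, j])] +
        E[cbind(paths[, j], j)]
    }
  }
  list(path = as.integer(paths[which.max(scores), ]), score = max(scores))
}

# per-basepair brute-force oracle for the breakpoint union
bp_scan_intervals <- function(segments, map) {
  out <- list()
  for (ch in sort(unique(segments$chrom))) {
    seg <- segments[segments$chrom == ch, ]
    L <- max(seg$end) + 1L
    sig <- rep("", L)
    for (i in seq_len(nrow(seg))) {
      r <- seg$start[i]:seg$end[i]
      sig[r] <- paste(sig[r], i, sep = ",")
    }
    covered <- sig != ""
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    pos <- map$pos[map$chrom == ch]
    for (k in seq_along(r$values)) {
      if (r$values[k] == "") next
      nm <- sum(pos >= starts[k] & pos <= ends[k])
      if (nm == 0) next
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = ch, start = starts[k], end = ends[k], n_markers = nm)
    }
  }
  dplyr::bind_rows(out)
}

# phenotype table with no genetic or seasonal structure, for model tests
null_pheno <- function(n, n_plates = 10, seed = 1, residual_sd = 0.2) {
  cfg <- sim_config(n_subjects = n, chrom_lengths = c(chr1 = 2e4),
                    marker_spacing = 2000, n_plates = n_plates,
                    trait_model = trait_spec(residual_sd = residual_sd,
                                             seasonal_amplitude = 0),
                    seed = seed)
  co <- simulate_cohort(simulate_marker_map(cfg), cfg)
  seasonal_adjust(co$phenotype)
}
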