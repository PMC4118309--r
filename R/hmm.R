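#' Parameters of the six-state copy-number HMM
#'
#' The hidden chain has six states covering five distinct copy numbers:
#' `CN0`, `CN1`, `CN2`, `CN2-ROH` (copy-neutral run of homozygosity), `CN3`
#' and `CN4`. `CN2` and `CN2-ROH` both report copy number 2; the ROH state
#' exists only to absorb stretches where BAF shows no heterozygotes without
#' forcing a copy-number change. Emissions combine a Gaussian LRR term per
#' state with a BAF mixture at SNPs: permitted BAF cluster centers are
#' `b / c` for `b = 0..c` B alleles out of `c` copies (ROH permits only 0 and
#' 1; CN0 emits uniform BAF noise). Transitions are distance-dependent:
#' `P(stay) = 1 - epsilon * (1 - exp(-d / D))`, with the off-diagonal mass
#' split proportionally to the stationary probabilities of the other states.
#'
#' @param lrr_mean,lrr_sd per-state LRR emission mean and sd (length 6, order
#'   CN0, CN1, CN2, CN2-ROH, CN3, CN4).
#' @param baf_sd sd of the BAF clusters (truncated normal on `[0, 1]`).
#' @param stationary_probs stationary state distribution (simplex, length 6).
#' @param transition_decay distance scale `D` in bp.
#' @param offdiag_total total off-diagonal transition mass `epsilon` at
#'   infinite distance.
#' @return A list of class `hmm_params`.
#' @export
hmm_params <- function(lrr_mean = c(-2.0, -0.55, 0.0, 0.0, 0.35, 0.65),
                       lrr_sd = c(0.35, 0.25, 0.2, 0.2, 0.25, 0.3),
                       baf_sd = 0.05,
                       stationary_probs = c(0.004, 0.045, 0.89,
                                            0.01, 0.045, 0.006),
                       transition_decay = 1e5,
                       offdiag_total = 0.01) {
  stopifnot(length(lrr_mean) == 6, length(lrr_sd) == 6, all(lrr_sd > 0),
            length(stationary_probs) == 6, all(stationary_probs > 0),
            abs(sum(stationary_probs) - 1) < 1e-8,
            transition_decay > 0, offdiag_total >= 0, offdiag_total < 1)
  states <- c("CN0", "CN1", "CN2", "CN2-ROH", "CN3", "CN4")
  baf_centers <- list(NULL,                    # CN0: uniform
                      c(0, 1),                 # CN1
                      c(0, 0.5, 1),            # CN2
                      c(0, 1),                 # CN2-ROH
                      c(0, 1 / 3, 2 / 3, 1),   # CN3
                      c(0, 0.25, 0.5, 0.75, 1))
  structure(list(states = states, cn = c(0L, 1L, 2L, 2L, 3L, 4L),
                 lrr_mean = lrr_mean, lrr_sd = lrr_sd,
                 baf_sd = baf_sd, baf_centers = baf_centers,
                 stationary_probs = stationary_probs,
                 transition_decay = transition_decay,
                 offdiag_total = offdiag_total),
            class = "hmm_params")
}

#' Emission log-likelihood of one marker under one state
#'
#' The LRR contributes a Gaussian log-density; at SNPs with observed BAF the
#' state's BAF mixture (equal weights over permitted truncated-normal
#' clusters; uniform for CN0) contributes additively. Nonpolymorphic markers
#' (or missing BAF) contribute the LRR term only; a missing LRR skips the
#' marker entirely (log-likelihood 0).
#'
#' @param lrr_value,baf_value observed values (`NA` allowed).
#' @param state state index 1..6 or label.
#' @param is_snp whether the marker is a SNP with interpretable BAF.
#' @param params an [hmm_params()].
#' @return Scalar log-density.
#' @export
emission_loglik <- function(lrr_value, baf_value, state, is_snp,
                            params = hmm_params()) {
  if (is.character(state)) state <- match(state, params$states)
  stopifnot(state %in% 1:6)
  if (is.na(lrr_value)) return(0)
  ll <- dnorm(lrr_value, params$lrr_mean[state], params$lrr_sd[state],
              log = TRUE)
  if (isTRUE(is_snp) && !is.na(baf_value)) {
    ll <- ll + log(baf_density(baf_value, state, params))
  }
  ll
}

# BAF mixture density for a state (vectorized over baf)
baf_density <- function(baf, state, params) {
  centers <- params$baf_centers[[state]]
  if (is.null(centers)) return(rep(1, length(baf)))  # CN0: Uniform(0,1)
  dens <- vapply(centers, function(ct) {
    dtruncnorm(baf, mean = ct, sd = params$baf_sd)
  }, numeric(length(baf)))
  if (is.null(dim(dens))) dens <- matrix(dens, nrow = length(baf))
  rowMeans(dens)
}

# 6 x m matrix of emission log-likelihoods for one subject
emission_matrix <- function(lrr, baf, is_snp, params) {
  m <- length(lrr)
  E <- matrix(0, 6, m)
  obs <- !is.na(lrr)
  for (s in 1:6) {
    E[s, obs] <- dnorm(lrr[obs], params$lrr_mean[s], params$lrr_sd[s],
                       log = TRUE)
    use_baf <- obs & is_snp & !is.na(baf)
    if (any(use_baf)) {
      E[s, use_baf] <- E[s, use_baf] +
        log(baf_density(baf[use_baf], s, params))
    }
  }
  E
}

#' Distance-dependent transition matrix
#'
#' `P(stay) = 1 - epsilon * (1 - exp(-d / D))`; the off-diagonal mass is
#' split across the other states proportionally to their stationary
#' probabilities. Rows sum to one; at `d -> 0` (or `epsilon = 0`) the matrix
#' is the identity.
#'
#' @param distance_bp inter-marker distance in bp (`> 0`).
#' @param params an [hmm_params()].
#' @return A 6 x 6 row-stochastic matrix.
#' @export
transition_matrix <- function(distance_bp, params = hmm_params()) {
  stopifnot(distance_bp > 0)
  eps <- params$offdiag_total * (1 - exp(-distance_bp / params$transition_decay))
  P <- matrix(0, 6, 6, dimnames = list(params$states, params$states))
  pi_ <- params$stationary_probs
  for (i in 1:6) {
    w <- pi_
    w[i] <- 0
    P[i, ] <- eps * w / sum(w)
    P[i, i] <- 1 - eps
  }
  P
}

#' Viterbi copy-number segmentation of one subject
#'
#' Decodes the most probable state path per chromosome, initializing at the
#' stationary distribution, and collapses maximal runs of constant state into
#' segments. By default only CNV segments (copy number different from 2) are
#' emitted; `emit_all = TRUE` returns every run including diploid and ROH
#' stretches.
#'
#' @param data an [intensity_data()] object.
#' @param subject subject identifier (row name) or row index.
#' @param params an [hmm_params()].
#' @param emit_all emit diploid/ROH runs as well?
#' @return A tibble with columns `subject_id`, `chrom`, `start`, `end`
#'   (1-based, closed, at marker positions), `state`, `cn`, `n_markers`,
#'   `mean_lrr`.
#' @export
viterbi_segments <- function(data, subject, params = hmm_params(),
                             emit_all = FALSE) {
  stopifnot(inherits(data, "intensity_data"))
  i <- if (is.character(subject)) match(subject, rownames(data$lrr)) else subject
  if (is.na(i)) abort("Unknown subject.")
  sid <- rownames(data$lrr)[i] %||% as.character(i)
  lrr <- data$lrr[i, ]
  baf <- data$baf[i, ]
  if (all(is.na(lrr))) abort("Subject has no observed LRR values.")
  map <- data$map
  out <- list()
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    path <- viterbi_path(lrr[idx], baf[idx], map$is_snp[idx],
                         map$pos[idx], params)
    r <- rle(path)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in seq_along(r$values)) {
      s <- r$values[k]
      seg_idx <- idx[starts[k]:ends[k]]
      out[[length(out) + 1L]] <- tibble(
        subject_id = sid, chrom = ch,
        start = map$pos[seg_idx[1]], end = map$pos[seg_idx[length(seg_idx)]],
        state = params$states[s], cn = params$cn[s],
        n_markers = length(seg_idx),
        mean_lrr = mean(lrr[seg_idx], na.rm = TRUE))
    }
  }
  segs <- bind_rows(out)
  if (!emit_all) segs <- filter(segs, .data$cn != 2L)
  segs
}

# most probable state path for one chromosome (log-space Viterbi)
viterbi_path <- function(lrr, baf, is_snp, pos, params) {
  m <- length(lrr)
  E <- emission_matrix(lrr, baf, is_snp, params)
  delta <- log(params$stationary_probs) + E[, 1]
  if (m == 1) return(which.max(delta))
  psi <- matrix(0L, 6, m)
  for (j in 2:m) {
    lP <- log(transition_matrix(max(pos[j] - pos[j - 1], 1), params))
    cand <- delta + lP            # 6x6: cand[i, s] = delta[i] + log P[i, s]
    best <- max.col(t(cand), ties.method = "first")
    psi[, j] <- best
    delta <- cand[cbind(best, 1:6)] + E[, j]
  }
  path <- integer(m)
  path[m] <- which.max(delta)
  for (j in (m - 1):1) path[j] <- psi[path[j + 1], j + 1]
  path
}

#' Forward-backward posterior state probabilities
#'
#' Marginal posterior probability of each state at each marker for one
#' chromosome of one subject, computed with the scaled forward-backward
#' recursions in log space.
#'
#' @inheritParams viterbi_segments
#' @param chrom chromosome to decode.
#' @return A markers x 6 matrix of posterior probabilities (rows sum to 1);
#'   attribute `"loglik"` carries the observed-data log-likelihood.
#' @export
forward_backward <- function(data, subject, chrom, params = hmm_params()) {
  i <- if (is.character(subject)) match(subject, rownames(data$lrr)) else subject
  idx <- which(data$map$chrom == chrom)
  stopifnot(length(idx) >= 1)
  lrr <- data$lrr[i, idx]
  baf <- data$baf[i, idx]
  E <- emission_matrix(lrr, baf, data$map$is_snp[idx], params)
  pos <- data$map$pos[idx]
  m <- length(idx)
  la <- matrix(-Inf, 6, m)
  lb <- matrix(0, 6, m)
  la[, 1] <- log(params$stationary_probs) + E[, 1]
  lPs <- vector("list", m)
  for (j in 2:max(m, 2)) {
    if (m == 1) break
    lP <- log(transition_matrix(max(pos[j] - pos[j - 1], 1), params))
    lPs[[j]] <- lP
    for (s in 1:6) la[s, j] <- logsumexp(la[, j - 1] + lP[, s]) + E[s, j]
  }
  if (m > 1) {
    for (j in (m - 1):1) {
      for (s in 1:6) {
        lb[s, j] <- logsumexp(lPs[[j + 1]][s, ] + E[, j + 1] + lb[, j + 1])
      }
    }
  }
  ll <- logsumexp(la[, m])
  post <- exp(la + lb - ll)
  post <- t(post) / rowSums(t(post))  # normalize away residual rounding
  structure(post, loglik = ll)
}

logsumexp <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(mx)
  mx + log(sum(exp(x - mx)))
}

# log-likelihood of a given state path (for decoding-optimality checks)
path_loglik <- function(lrr, baf, is_snp, pos, path, params) {
  E <- emission_matrix(lrr, baf, is_snp, params)
  ll <- log(params$stationary_probs[path[1]]) + E[path[1], 1]
  m <- length(path)
  if (m > 1) {
    for (j in 2:m) {
      lP <- log(transition_matrix(max(pos[j] - pos[j - 1], 1), params))
      ll <- ll + lP[path[j - 1], path[j]] + E[path[j], j]
    }
  }
  ll
}

#' Segment every subject of a cohort
#'
#' Runs [viterbi_segments()] independently on each sample, as array HMMs are
#' fit per subject, and binds the CNV calls.
#'
#' @inheritParams viterbi_segments
#' @return A tibble of CNV segments across subjects.
#' @export
segment_cohort <- function(data, params = hmm_params(), emit_all = FALSE) {
  map_dfr(seq_len(nrow(data$lrr)),
          function(i) viterbi_segments(data, i, params, emit_all))
}

#' Drop low-coverage CNV calls
#'
#' Removes CNV segments supported by fewer than `min_markers` markers;
#' short calls are unreliable at array noise levels.
#'
#' @param segments segment tibble from [viterbi_segments()].
#' @param min_markers minimum marker support (default 10; a segment with
#'   exactly `min_markers` markers is retained).
#' @return The filtered tibble.
#' @export
filter_min_markers <- function(segments, min_markers = 10) {
  filter(segments, .data$n_markers >= min_markers)
}
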