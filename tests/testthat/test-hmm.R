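params <- hmm_params()

test_that("emission terms peak at the matching state", {
  # nonpolymorphic marker at the CN1 level: CN1 maximizes the LRR term
  ll <- vapply(1:6, function(s) {
    emission_loglik(params$lrr_mean[2], NA, s, is_snp = FALSE, params)
  }, numeric(1))
  expect_equal(which.max(ll), 2L)
  # a heterozygous BAF favors CN2 over the ROH state
  ll2 <- emission_loglik(0, 0.5, "CN2", TRUE, params)
  llr <- emission_loglik(0, 0.5, "CN2-ROH", TRUE, params)
  expect_gt(ll2, llr)
  # CN0 emits uniform BAF: log-density contribution 0 whatever the BAF
  expect_equal(emission_loglik(-2, 0.17, "CN0", TRUE, params),
               emission_loglik(-2, 0.93, "CN0", TRUE, params))
  # missing LRR skips the marker entirely
  expect_equal(emission_loglik(NA, 0.5, "CN2", TRUE, params), 0)
})

test_that("transition matrix has the distance-dependent closed form", {
  P0 <- transition_matrix(1, params)
  expect_equal(unname(diag(P0)), rep(1, 6), tolerance = 1e-4)
  Pinf <- transition_matrix(1e12, params)
  expect_equal(unname(diag(Pinf)), rep(1 - params$offdiag_total, 6))
  expect_equal(unname(rowSums(Pinf)), rep(1, 6))
  # off-diagonal mass proportional to stationary probabilities
  expect_equal(Pinf[1, 3] / Pinf[1, 2],
               params$stationary_probs[3] / params$stationary_probs[2])
  p0 <- hmm_params(offdiag_total = 0)
  expect_equal(transition_matrix(5e4, p0),
               diag(6), ignore_attr = TRUE)
})

test_that("a diploid genome yields no CNV calls", {
  set.seed(5)
  m <- 2000
  map <- tiny_map(seq(500, by = 1000, length.out = m))
  lrr <- rnorm(m, 0, 0.15)
  baf <- cnpassoc:::rtruncnorm(m, sample(c(0, 0.5, 1), m, TRUE,
                                         prob = c(0.3, 0.4, 0.3)), 0.03)
  data <- tiny_intensity(lrr, map, baf)
  segs <- viterbi_segments(data, 1, params)
  expect_equal(nrow(segs), 0)
  all_runs <- viterbi_segments(data, 1, params, emit_all = TRUE)
  expect_true(all(all_runs$cn == 2))
})

test_that("a clear hemizygous deletion is recovered exactly", {
  set.seed(8)
  m <- 300
  map <- tiny_map(seq(500, by = 1000, length.out = m))
  del <- 101:150
  mu <- rep(0, m); mu[del] <- params$lrr_mean[2]
  lrr <- mu + rnorm(m, 0, 0.12)
  centers <- ifelse(seq_len(m) %in% del,
                    sample(c(0, 1), m, TRUE),
                    sample(c(0, 0.5, 1), m, TRUE))
  baf <- cnpassoc:::rtruncnorm(m, centers, 0.03)
  data <- tiny_intensity(lrr, map, baf)
  segs <- viterbi_segments(data, 1, params)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$cn, 1)
  expect_equal(segs$start, map$pos[del[1]])
  expect_equal(segs$end, map$pos[del[length(del)]])
  expect_equal(segs$n_markers, length(del))
})

test_that("Viterbi equals exhaustive enumeration on short instances", {
  set.seed(77)
  for (rep in 1:50) {
    m <- sample(2:7, 1)
    pos <- sort(sample.int(5e5, m))
    is_snp <- runif(m) < 0.5
    lrr <- rnorm(m, sample(params$lrr_mean, m, TRUE), 0.3)
    baf <- ifelse(is_snp, runif(m), NA_real_)
    path <- cnpassoc:::viterbi_path(lrr, baf, is_snp, pos, params)
    oracle <- enumerate_best_path(lrr, baf, is_snp, pos, params)
    score <- cnpassoc:::path_loglik(lrr, baf, is_snp, pos, path, params)
    expect_equal(score, oracle$score, tolerance = 1e-10)
  }
})

test_that("forward-backward posteriors are proper and consistent", {
  set.seed(12)
  m <- 200
  map <- tiny_map(seq(500, by = 1000, length.out = m))
  mu <- rep(0, m); mu[51:90] <- params$lrr_mean[2]
  lrr <- mu + rnorm(m, 0, 0.15)
  data <- tiny_intensity(lrr, map)
  post <- forward_backward(data, 1, "chr1", params)
  expect_equal(dim(post), c(m, 6))
  expect_lt(max(abs(rowSums(post) - 1)), 1e-10)
  # decoded path log-likelihood is never below the truth path's
  truth <- rep(3L, m); truth[51:90] <- 2L
  path <- cnpassoc:::viterbi_path(lrr, rep(NA_real_, m), rep(FALSE, m),
                                  map$pos, params)
  ll_dec <- cnpassoc:::path_loglik(lrr, rep(NA_real_, m), rep(FALSE, m),
                                   map$pos, path, params)
  ll_tru <- cnpassoc:::path_loglik(lrr, rep(NA_real_, m), rep(FALSE, m),
                                   map$pos, truth, params)
  expect_gte(ll_dec, ll_tru - 1e-10)
})

test_that("segmentation finds long deletions with high recall and precision", {
  set.seed(40)
  m <- 1200
  map <- tiny_map(seq(500, by = 1000, length.out = m), is_snp = FALSE)
  n <- 25
  truth <- list()
  lrr <- matrix(0, n, m)
  for (i in seq_len(n)) {
    start <- sample(50:(m - 90), 1)
    len <- sample(30:60, 1)
    idx <- start:(start + len - 1)
    mu <- rep(0, m); mu[idx] <- params$lrr_mean[2]
    lrr[i, ] <- mu + rnorm(m, 0, 0.25)
    truth[[i]] <- idx
  }
  data <- tiny_intensity(lrr, map)
  segs <- filter_min_markers(segment_cohort(data, params), 10)
  hits <- 0
  for (i in seq_len(n)) {
    s <- segs[segs$subject_id == sprintf("S%03d", i) & segs$cn == 1, ]
    idx <- truth[[i]]
    cov <- 0
    if (nrow(s)) {
      marker_pos <- map$pos[idx]
      cov <- max(vapply(seq_len(nrow(s)), function(k) {
        mean(marker_pos >= s$start[k] & marker_pos <= s$end[k])
      }, numeric(1)))
    }
    if (cov >= 0.9) hits <- hits + 1
  }
  recall <- hits / n
  # precision: every called deletion overlaps its subject's true deletion
  good <- vapply(seq_len(nrow(segs)), function(k) {
    i <- match(segs$subject_id[k], sprintf("S%03d", seq_len(n)))
    idx <- truth[[i]]
    segs$start[k] <= map$pos[idx[length(idx)]] &&
      segs$end[k] >= map$pos[idx[1]]
  }, logical(1))
  precision <- mean(good)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("the minimum-marker filter is a strict boundary at 10", {
  segs <- tibble::tibble(subject_id = "S1", chrom = "chr1",
                         start = c(1, 100), end = c(50, 200),
                         state = "CN1", cn = 1L,
                         n_markers = c(9L, 10L), mean_lrr = -0.5)
  kept <- filter_min_markers(segs, 10)
  expect_equal(kept$n_markers, 10L)
  expect_equal(nrow(filter_min_markers(segs[0, ], 10)), 0)
})

test_that("an all-missing subject is rejected", {
  map <- tiny_map(c(1000, 2000))
  data <- tiny_intensity(matrix(NA_real_, 1, 2), map)
  expect_error(viterbi_segments(data, 1), "no observed")
})
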