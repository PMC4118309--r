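#' Region-averaged log R ratio per subject
#'
#' Arithmetic mean of each subject's LRR over the markers inside a region,
#' skipping missing markers. Averaging over the ~dozens of markers in a CNP
#' locus shrinks marker-level noise so the copy-number classes separate into
#' distinct normal components.
#'
#' @param data an [intensity_data()] object.
#' @param region list or one-row tibble with `chrom`, `start`, `end`.
#' @return A tibble with columns `subject_id`, `mean_lrr` (`NA` if every
#'   marker is missing for a subject).
#' @export
region_mean_lrr <- function(data, region) {
  stopifnot(inherits(data, "intensity_data"))
  idx <- region_marker_idx(data$map, region)
  if (length(idx) == 0) abort("Region contains no markers.")
  vals <- rowMeans(data$lrr[, idx, drop = FALSE], na.rm = TRUE)
  vals[is.nan(vals)] <- NA_real_
  vals <- unname(vals)
  tibble(subject_id = rownames(data$lrr) %||%
           as.character(seq_len(nrow(data$lrr))),
         mean_lrr = vals)
}

#' Gibbs sampler for a three-component normal mixture
#'
#' Approximates the posterior of a k = 3 normal mixture fitted to
#' region-averaged log R ratios, whose components are induced by the latent
#' copy-number classes (homozygous deletion, hemizygous deletion, diploid).
#' Conjugate updates are used throughout: component labels given parameters;
#' means given a normal prior; variances given an inverse-gamma prior;
#' weights given a Dirichlet prior. Identifiability under label switching is
#' enforced by relabeling components in ascending order of their means at
#' every sweep. Per-subject membership probabilities are Rao-Blackwellized
#' averages of the conditional responsibilities over post-burn-in sweeps.
#'
#' @param values numeric vector of region-averaged LRRs (`NA`s dropped for
#'   fitting; posterior membership is `NA` for those subjects).
#' @param k number of components (fixed at 3).
#' @param prior list with elements `mean` (length-k prior means; default the
#'   empirical 1/6, 3/6, 5/6 quantiles), `mean_sd` (prior sd of the means,
#'   default 1), `var_shape`, `var_rate` (inverse-gamma, default 2 and
#'   0.05), `weights` (Dirichlet concentration, default `c(1, 1, 1)`).
#' @param n_iter,burn_in total and discarded sweeps.
#' @param seed integer seed; identical seeds give identical chains.
#' @return An object of class `cnp_mixture`: component `means`, `vars`,
#'   `weights` (posterior means, ascending by mean), `posterior` (n x k
#'   membership matrix), `map_cn` (integer copy number 0..k-1 per subject),
#'   and `diagnostics` (iterations, burn-in, seed, fraction of sweeps with
#'   an empty component, degeneracy flag).
#' @export
gibbs_mixture <- function(values, k = 3, prior = NULL,
                          n_iter = 4000, burn_in = 1000, seed = 1) {
  stopifnot(k == 3, n_iter > burn_in)
  obs <- !is.na(values)
  y <- values[obs]
  if (length(y) < 3 * k) abort("Need at least 3k observations.")
  if (!all(is.finite(y))) abort("Values must be finite.")
  n <- length(y)
  pr <- list(mean = quantile(y, probs = (2 * seq_len(k) - 1) / (2 * k),
                             names = FALSE),
             mean_sd = 1, var_shape = 2, var_rate = 0.05,
             weights = rep(1, k))
  if (!is.null(prior)) pr[names(prior)] <- prior

  with_seed_local(seed, {
    # initialize the chain at k-means centers: the rare homozygous-deletion
    # component sits far from the bulk, where quantile starts would miss it
    km <- if (length(unique(y)) >= k) {
      tryCatch(stats::kmeans(y, centers = k, nstart = 10),
               error = function(e) NULL)
    } else NULL
    if (!is.null(km)) {
      o <- order(km$centers)
      mu <- as.numeric(km$centers[o])
      s2 <- vapply(o, function(j) {
        v <- var(y[km$cluster == j])
        max(if (is.na(v)) 0 else v, 1e-6)
      }, numeric(1))
      w <- km$size[o] / n
    } else {
      mu <- sort(pr$mean)
      s2 <- rep(max(var(y) / k^2, 1e-6), k)
      w <- rep(1 / k, k)
    }
    resp_sum <- matrix(0, n, k)
    mu_sum <- s2_sum <- w_sum <- numeric(k)
    n_kept <- 0L
    empty_sweeps <- 0L
    tau2 <- pr$mean_sd^2

    resp <- function(mu, s2, w) {
      logd <- vapply(seq_len(k), function(j) {
        log(w[j]) + dnorm(y, mu[j], sqrt(s2[j]), log = TRUE)
      }, numeric(n))
      mx <- pmax(logd[, 1], logd[, 2], logd[, 3])
      p <- exp(logd - mx)
      p / (p[, 1] + p[, 2] + p[, 3])
    }

    for (it in seq_len(n_iter)) {
      # responsibilities and label draw
      p <- resp(mu, s2, w)
      u <- runif(n)
      z <- 1L + (u > p[, 1]) + (u > p[, 1] + p[, 2])

      nk <- tabulate(z, nbins = k)
      if (any(nk == 0)) empty_sweeps <- empty_sweeps + 1L

      # means | z  (normal prior)
      for (j in seq_len(k)) {
        yj <- y[z == j]
        prec <- nk[j] / s2[j] + 1 / tau2
        mean_post <- (sum(yj) / s2[j] + pr$mean[j] / tau2) / prec
        mu[j] <- rnorm(1, mean_post, sqrt(1 / prec))
      }
      # variances | z, mu  (inverse gamma)
      for (j in seq_len(k)) {
        yj <- y[z == j]
        shape <- pr$var_shape + nk[j] / 2
        rate <- pr$var_rate + sum((yj - mu[j])^2) / 2
        s2[j] <- 1 / rgamma(1, shape, rate)
      }
      # weights | z  (Dirichlet via gammas)
      g <- rgamma(k, pr$weights + nk, 1)
      w <- g / sum(g)

      # relabel ascending by mean
      o <- order(mu)
      mu <- mu[o]; s2 <- s2[o]; w <- w[o]

      if (it > burn_in) {
        resp_sum <- resp_sum + resp(mu, s2, w)
        mu_sum <- mu_sum + mu
        s2_sum <- s2_sum + s2
        w_sum <- w_sum + w
        n_kept <- n_kept + 1L
      }
    }

    post_obs <- resp_sum / n_kept
    posterior <- matrix(NA_real_, length(values), k)
    posterior[obs, ] <- post_obs
    # ties broken toward the lower component (lower copy number)
    map_obs <- apply(post_obs, 1, function(pp) which(pp >= max(pp))[1]) - 1L
    map_cn <- rep(NA_integer_, length(values))
    map_cn[obs] <- as.integer(map_obs)

    degenerate <- empty_sweeps / n_iter > 0.5
    if (degenerate) {
      warn("Mixture sampler degenerate: a component was empty in >50% of sweeps.")
    }
    structure(list(
      means = mu_sum / n_kept,
      vars = s2_sum / n_kept,
      weights = w_sum / n_kept,
      posterior = posterior,
      map_cn = map_cn,
      values = values,
      diagnostics = list(n_iter = n_iter, burn_in = burn_in, seed = seed,
                         empty_fraction = empty_sweeps / n_iter,
                         degenerate = degenerate)
    ), class = "cnp_mixture")
  })
}

#' @export
print.cnp_mixture <- function(x, ...) {
  cat("<cnp_mixture> 3-component normal mixture\n")
  cat("  means  ", paste(signif(x$means, 3), collapse = "  "), "\n")
  cat("  weights", paste(signif(x$weights, 3), collapse = "  "), "\n")
  if (x$diagnostics$degenerate) cat("  [degenerate fit]\n")
  invisible(x)
}

#' Tidy a mixture fit
#'
#' One row per mixture component with posterior-mean parameters.
#'
#' @param x a `cnp_mixture`.
#' @param ... unused.
#' @return A tibble with `component`, `cn`, `mean`, `sd`, `weight`.
#' @export
tidy.cnp_mixture <- function(x, ...) {
  tibble(component = seq_along(x$means),
         cn = seq_along(x$means) - 1L,
         mean = x$means, sd = sqrt(x$vars), weight = x$weights)
}

#' Glance at a mixture fit
#'
#' @param x a `cnp_mixture`.
#' @param ... unused.
#' @return A one-row tibble with sample size, sampler settings and the
#'   degeneracy diagnostic.
#' @export
glance.cnp_mixture <- function(x, ...) {
  tibble(n = sum(!is.na(x$values)),
         n_iter = x$diagnostics$n_iter,
         burn_in = x$diagnostics$burn_in,
         empty_fraction = x$diagnostics$empty_fraction,
         degenerate = x$diagnostics$degenerate)
}

#' Plot a mixture fit
#'
#' Histogram of the region-averaged LRRs with the posterior-mean mixture
#' density overlaid, in the style of the classic CNP genotyping figure.
#'
#' @param object a `cnp_mixture`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cnp_mixture <- function(object, ...) {
  y <- object$values[!is.na(object$values)]
  grid <- seq(min(y) - 0.2, max(y) + 0.2, length.out = 400)
  dens <- map_dfr(seq_along(object$means), function(j) {
    tibble(x = grid, component = factor(j - 1L),
           density = object$weights[j] *
             dnorm(grid, object$means[j], sqrt(object$vars[j])))
  })
  total <- dens |> group_by(.data$x) |>
    summarise(density = sum(.data$density), .groups = "drop")
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = tibble(y = y),
      ggplot2::aes(x = .data$y, y = ggplot2::after_stat(density)),
      bins = 60, fill = "grey80", colour = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(x = .data$x, y = .data$density,
                                    colour = .data$component)) +
    ggplot2::geom_line(data = total,
                       ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::labs(x = "average log R ratio", y = "density",
                  colour = "copy number") +
    ggplot2::theme_minimal()
}

#' Maximum a posteriori copy-number assignment
#'
#' Maps each subject to the component of maximal posterior membership, with
#' component order ascending in mean so that index 1 is copy number 0. Ties
#' are broken toward the lower copy number.
#'
#' @param fit a [gibbs_mixture()] result.
#' @return Integer vector of copy numbers 0, 1, 2 (NA where the input value
#'   was missing).
#' @export
map_assign <- function(fit) {
  stopifnot(inherits(fit, "cnp_mixture"))
  fit$map_cn
}

#' Cross-tabulate mixture copy number against SNP genotype calls
#'
#' Corroborates mixture-based copy-number estimates with the genotype
#' clusters of a SNP inside the region: copy-number-1 subjects can only
#' populate hemizygous-compatible (homozygous-looking) clusters, and
#' copy-number-0 subjects should concentrate in the missing/null cluster.
#'
#' @param map_cn integer copy numbers from [map_assign()].
#' @param calls character genotype calls (`"A"`, `"AB"`, `"B"`, `NA`)
#'   aligned to `map_cn`.
#' @return A tibble cross-table with counts for every `cn` x `call`
#'   combination (missing calls labeled `"missing"`).
#' @export
genotype_concordance <- function(map_cn, calls) {
  stopifnot(length(map_cn) == length(calls))
  calls <- ifelse(is.na(calls), "missing", calls)
  tb <- table(cn = map_cn, call = factor(calls,
                                         levels = c("A", "AB", "B", "missing")))
  as_tibble(tb) |>
    mutate(cn = as.integer(.data$cn), n = as.integer(.data$n))
}
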