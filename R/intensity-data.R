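#' Marker-level intensity container
#'
#' Bundles the two marker-level summaries produced by SNP-array preprocessing
#' — the log R ratio (LRR, log-scale total intensity relative to a diploid
#' reference) and the B allele frequency (BAF, relative intensity of the B
#' allele) — together with the marker map. Rows of both matrices are subjects,
#' columns are markers in map order. BAF is missing at nonpolymorphic
#' (copy-number-only) markers.
#'
#' @param lrr numeric matrix, subjects x markers, of log R ratios. Row names
#'   are subject identifiers, column names marker identifiers.
#' @param baf numeric matrix of the same shape with B allele frequencies in
#'   `[0, 1]`; `NA` where the marker is nonpolymorphic.
#' @param map tibble with columns `marker_id`, `chrom`, `pos`, `is_snp`, `gc`
#'   (see [simulate_marker_map()]), one row per column of `lrr`.
#'
#' @return An object of class `intensity_data`: a list with elements `lrr`,
#'   `baf` and `map`.
#' @export
intensity_data <- function(lrr, baf, map) {
  stopifnot(is.matrix(lrr), is.matrix(baf))
  map <- as_tibble(map)
  if (ncol(lrr) != nrow(map) || ncol(baf) != nrow(map)) {
    abort("`lrr` and `baf` must have one column per row of `map`.")
  }
  if (!identical(dim(lrr), dim(baf))) {
    abort("`lrr` and `baf` must have identical dimensions.")
  }
  req <- c("marker_id", "chrom", "pos", "is_snp", "gc")
  if (!all(req %in% names(map))) {
    abort(paste0("`map` is missing columns: ",
                 paste(setdiff(req, names(map)), collapse = ", ")))
  }
  bad <- baf[!is.na(baf)]
  if (length(bad) && (min(bad) < 0 || max(bad) > 1)) {
    abort("Non-missing BAF values must lie in [0, 1].")
  }
  if (anyDuplicated(map$marker_id)) abort("Marker ids must be unique.")
  structure(list(lrr = lrr, baf = baf, map = map), class = "intensity_data")
}

#' @export
print.intensity_data <- function(x, ...) {
  cat("<intensity_data> ", nrow(x$lrr), " subjects x ", ncol(x$lrr),
      " markers (", sum(x$map$is_snp), " SNPs, ",
      length(unique(x$map$chrom)), " chromosome(s))\n", sep = "")
  invisible(x)
}

#' @export
dim.intensity_data <- function(x) dim(x$lrr)

subject_ids <- function(data) rownames(data$lrr)

# indices of map rows falling inside a chrom/start/end region
region_marker_idx <- function(map, region) {
  which(map$chrom == region$chrom &
          map$pos >= region$start & map$pos <= region$end)
}
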