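#' Disjoint intervals from CNV breakpoint union
#'
#' Cuts the genomic territory covered by any CNV call at every segment start
#' and end coordinate, producing maximal disjoint intervals such that every
#' input segment is an exact union of intervals. Within each interval the
#' set of overlapping CNVs — and hence every subject's copy number — is
#' constant ("unambiguous"). Intervals containing no marker are dropped.
#'
#' @param segments CNV segment tibble (QC-passed, marker-filtered), columns
#'   `chrom`, `start`, `end` (1-based closed).
#' @param map marker map tibble (for the marker-count requirement).
#' @return A tibble with columns `interval_id`, `chrom`, `start`, `end`,
#'   `n_markers`, sorted by chromosome and position.
#' @export
breakpoint_union <- function(segments, map) {
  segments <- as_tibble(segments)
  map <- as_tibble(map)
  if (nrow(segments) == 0) {
    return(tibble(interval_id = character(), chrom = character(),
                  start = integer(), end = integer(), n_markers = integer()))
  }
  out <- map_dfr(unique(segments$chrom), function(ch) {
    seg <- filter(segments, .data$chrom == ch)
    ir <- IRanges::IRanges(start = seg$start, end = seg$end)
    dj <- IRanges::disjoin(ir)
    pos <- map$pos[map$chrom == ch]
    nm <- IRanges::countOverlaps(
      dj, IRanges::IRanges(start = pos, width = 1L))
    tibble(chrom = ch,
           start = IRanges::start(dj), end = IRanges::end(dj),
           n_markers = as.integer(nm))
  })
  out <- out |>
    filter(.data$n_markers >= 1L) |>
    arrange(.data$chrom, .data$start) |>
    mutate(interval_id = sprintf("%s:%d-%d", .data$chrom, .data$start,
                                 .data$end)) |>
    select("interval_id", "chrom", "start", "end", "n_markers")
  out
}

#' Assemble the cohort copy-number matrix
#'
#' Entry `[i, j]` is subject `j`'s integer copy number at disjoint interval
#' `i`: the copy number of the unique CNV covering the interval, or 2 where
#' no CNV overlaps. Because intervals come from the breakpoint union, a CNV
#' either covers an interval entirely or not at all; a partial overlap, or
#' two same-subject CNVs of different copy number over one interval,
#' violates the construction and raises an error.
#'
#' @param intervals tibble from [breakpoint_union()].
#' @param segments the CNV segment tibble the intervals were built from.
#' @param subject_ids full cohort subject list (matrix columns).
#' @return An integer matrix of class `cn_matrix` (intervals x subjects) with
#'   the interval tibble attached as attribute `"intervals"`.
#' @export
build_cn_matrix <- function(intervals, segments, subject_ids) {
  intervals <- as_tibble(intervals)
  segments <- as_tibble(segments)
  M <- matrix(2L, nrow(intervals), length(subject_ids),
              dimnames = list(intervals$interval_id, subject_ids))
  for (ch in unique(segments$chrom)) {
    iv <- which(intervals$chrom == ch)
    if (!length(iv)) next
    seg <- filter(segments, .data$chrom == ch)
    ir_iv <- IRanges::IRanges(intervals$start[iv], intervals$end[iv])
    ir_seg <- IRanges::IRanges(seg$start, seg$end)
    ov <- IRanges::findOverlaps(ir_iv, ir_seg)
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    partial <- IRanges::start(ir_iv)[qi] < IRanges::start(ir_seg)[si] |
      IRanges::end(ir_iv)[qi] > IRanges::end(ir_seg)[si]
    if (any(partial)) {
      abort("A CNV partially overlaps a disjoint interval; intervals must come from breakpoint_union() on these segments.")
    }
    rows <- iv[qi]
    cols <- match(seg$subject_id[si], subject_ids)
    if (anyNA(cols)) abort("Segment subject not in `subject_ids`.")
    key <- paste(rows, cols)
    dup <- duplicated(key)
    if (any(dup)) {
      same <- tapply(seg$cn[si], key, function(v) length(unique(v)) == 1)
      if (!all(same)) {
        abort("Two same-subject CNVs with different copy number overlap one interval.")
      }
    }
    M[cbind(rows, cols)] <- as.integer(seg$cn[si])
  }
  structure(M, intervals = intervals, class = c("cn_matrix", class(M)))
}

#' Carrier-frequency filter for CNP intervals
#'
#' A subject carries a CNV at an interval when its copy number differs from
#' 2 (deletion or duplication). Intervals where the carrier fraction is at
#' least `min_freq` are CNPs; the rest are excluded.
#'
#' @param cn_matrix a [build_cn_matrix()] result.
#' @param min_freq minimum carrier fraction (default 0.01, i.e. at least one
#'   percent of subjects).
#' @return The interval tibble augmented with `carrier_count`,
#'   `carrier_freq` and logical `kept`.
#' @export
frequency_filter <- function(cn_matrix, min_freq = 0.01) {
  intervals <- attr(cn_matrix, "intervals")
  carriers <- rowSums(cn_matrix != 2L)
  n <- ncol(cn_matrix)
  mutate(intervals,
         carrier_count = as.integer(carriers),
         carrier_freq = carriers / n,
         kept = .data$carrier_freq >= min_freq)
}

#' Group retained intervals into CNP loci
#'
#' Merges genomically adjacent retained intervals into loci: two retained
#' intervals on the same chromosome belong to one locus when no marker lies
#' strictly between them (adjacency is marker-relative, not base-pair
#' relative). Locus coordinates are the minimum start and maximum end of the
#' merged intervals.
#'
#' @param intervals tibble from [frequency_filter()] (uses the `kept` flag;
#'   if absent, all intervals are treated as retained).
#' @param map marker map tibble.
#' @return A tibble with `locus_id`, `chrom`, `start`, `end`, `n_intervals`,
#'   `n_markers`.
#' @export
group_loci <- function(intervals, map) {
  intervals <- as_tibble(intervals)
  map <- as_tibble(map)
  if (!"kept" %in% names(intervals)) intervals$kept <- TRUE
  kept <- intervals |> filter(.data$kept) |>
    arrange(.data$chrom, .data$start)
  if (nrow(kept) == 0) {
    return(tibble(locus_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  n_intervals = integer(), n_markers = integer()))
  }
  kept <- kept |>
    group_by(.data$chrom) |>
    mutate(gap_markers = {
      pos <- map$pos[map$chrom == .data$chrom[1]]
      prev_end <- dplyr::lag(.data$end)
      vapply(seq_along(.data$start), function(k) {
        if (k == 1) return(NA_integer_)
        sum(pos > prev_end[k] & pos < .data$start[k])
      }, integer(1))
    }) |>
    mutate(new_locus = is.na(.data$gap_markers) | .data$gap_markers > 0,
           locus_num = cumsum(.data$new_locus)) |>
    ungroup()
  kept |>
    group_by(.data$chrom, .data$locus_num) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_intervals = n(), n_markers = sum(.data$n_markers),
              .groups = "drop") |>
    arrange(.data$chrom, .data$start) |>
    mutate(locus_id = sprintf("%s:%d-%d", .data$chrom, .data$start,
                              .data$end)) |>
    select("locus_id", "chrom", "start", "end", "n_intervals", "n_markers")
}
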