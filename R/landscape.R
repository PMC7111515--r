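# Landscape statistics over chromatin-state segmentations: per-state
# genome coverage, the fraction of the genome quiescent in every cell
# type, pairwise state-transition matrices, and aggregated signal
# meta-profiles around interval classes.

segmentation_genome <- function(segmentation) {
  segmentation %>%
    group_by(.data$chrom) %>%
    summarise(length = max(.data$end), .groups = "drop")
}

#' Per-state genome coverage fractions
#'
#' Fraction of segmented bases assigned to each state; the vector sums
#' to 1.
#'
#' @param segmentation A segmentation tibble (`chrom`, `start`, `end`,
#'   `state`).
#' @param n_states Number of states (default: inferred from the maximum
#'   observed state id).
#' @return A tibble with `state` and `fraction`, one row per state
#'   (including states with zero coverage).
#' @export
state_coverage_fractions <- function(segmentation, n_states = NULL) {
  if (nrow(segmentation) == 0) abort("empty segmentation")
  if (is.null(n_states)) n_states <- max(segmentation$state) + 1L
  bases <- rep(0, n_states)
  agg <- rowsum(
    as.numeric(segmentation$end - segmentation$start),
    group = segmentation$state
  )
  bases[as.integer(rownames(agg)) + 1L] <- agg[, 1]
  tibble(
    state = seq_len(n_states) - 1L,
    fraction = bases / sum(bases)
  )
}

#' Fraction of the genome quiescent in every cell type
#'
#' Base-level intersection of the quiescent-state intervals across all
#' segmentations, divided by the shared genome size. Always at most the
#' minimum per-cell-type quiescent coverage.
#'
#' @param segmentations Named list of segmentation tibbles sharing one
#'   genome.
#' @param quiescent Quiescent state id (default 0).
#' @return A single numeric fraction.
#' @export
quiescent_everywhere_fraction <- function(segmentations, quiescent = 0L) {
  if (length(segmentations) == 0) abort("no segmentations supplied")
  genomes <- lapply(segmentations, segmentation_genome)
  g0 <- genomes[[1]]
  for (g in genomes[-1]) {
    if (!identical(
      g[order(g$chrom), ], g0[order(g0$chrom), ]
    )) {
      abort("segmentations do not share a genome")
    }
  }
  q <- lapply(segmentations, function(seg) {
    seg[seg$state == quiescent, c("chrom", "start", "end")]
  })
  inter <- Reduce(intersect_intervals, q)
  interval_bases(inter) / sum(g0$length)
}

#' State-transition matrix between two cell types
#'
#' Counts units jointly by their state in segmentation A and in
#' segmentation B. Units are genome bins of `bin_size` bases when
#' `regions` is NULL, otherwise the supplied regions, each reduced to one
#' state per cell type by the majority-base rule (ties to the lowest state
#' id).
#'
#' @param seg_a,seg_b Segmentation tibbles over the same genome.
#' @param regions Optional interval tibble (`chrom`, `start`, `end`).
#' @param n_states Number of states (default: inferred).
#' @param bin_size Bin width in bases used as the counting unit when
#'   `regions` is NULL.
#' @return An object of class `transition_matrix`: the counts matrix with
#'   attributes `unit` ("bins" or "regions") and `bin_size`.
#' @export
transition_matrix <- function(seg_a, seg_b, regions = NULL,
                              n_states = NULL, bin_size = 200) {
  if (is.null(n_states)) {
    n_states <- max(seg_a$state, seg_b$state) + 1L
  }
  counts <- matrix(0, n_states, n_states, dimnames = list(
    from = paste0("s", seq_len(n_states) - 1L),
    to = paste0("s", seq_len(n_states) - 1L)
  ))
  if (is.null(regions)) {
    ga <- as_granges(seg_a)
    gb <- as_granges(seg_b)
    ov <- GenomicRanges::findOverlaps(ga, gb)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(ga)[qh], GenomicRanges::ranges(gb)[sh]
    ))
    key <- seg_a$state[qh] * n_states + seg_b$state[sh] + 1
    acc <- rowsum(as.numeric(w), group = key)
    idx <- as.integer(rownames(acc))
    counts[cbind((idx - 1) %/% n_states + 1, (idx - 1) %% n_states + 1)] <-
      acc[, 1] / bin_size
    unit <- "bins"
  } else {
    genome <- segmentation_genome(seg_a)
    out_of <- !(regions$chrom %in% genome$chrom) |
      regions$end > genome$length[match(regions$chrom, genome$chrom)] |
      regions$start < 0
    if (any(out_of, na.rm = TRUE)) abort("region outside the segmented genome")
    sa <- majority_state(interval_state_proportions(regions, seg_a, n_states))
    sb <- majority_state(interval_state_proportions(regions, seg_b, n_states))
    for (i in seq_along(sa)) {
      counts[sa[i] + 1, sb[i] + 1] <- counts[sa[i] + 1, sb[i] + 1] + 1
    }
    unit <- "regions"
  }
  structure(counts,
    class = c("transition_matrix", "matrix"),
    unit = unit, bin_size = if (is.null(regions)) bin_size else NA
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> unit:", attr(x, "unit"), "\n")
  print(unclass(x)[seq_len(min(nrow(x), 10)), seq_len(min(ncol(x), 10))])
  invisible(x)
}

#' Tidy a transition matrix into long format
#' @param x A `transition_matrix`.
#' @param ... Unused.
#' @export
tidy.transition_matrix <- function(x, ...) {
  m <- unclass(x)
  tibble(
    from_state = rep(seq_len(nrow(m)) - 1L, ncol(m)),
    to_state = rep(seq_len(ncol(m)) - 1L, each = nrow(m)),
    count = as.numeric(m)
  )
}

#' Aggregated signal meta-profile around interval classes
#'
#' Centers a window of +/- `window` bases on each interval midpoint,
#' averages the signal into `n_position_bins` equal position bins
#' (coverage-weighted; bases missing from the track count as 0 signal,
#' with a warning), and aggregates per class as the column means.
#'
#' @param signal A binned signal tibble (`chrom`, `start`, `end`,
#'   `value`).
#' @param intervals Interval tibble (`chrom`, `start`, `end`), optionally
#'   with a `class` column of labels.
#' @param window Half-width of the profile window in bases.
#' @param n_position_bins Number of columns in the profile.
#' @return An object of class `meta_profile`: list with `matrix`
#'   (interval x position), `classes`, `aggregate` (tibble class x
#'   position x mean), `window`, `n_position_bins`.
#' @export
meta_profile <- function(signal, intervals, window = 2000,
                         n_position_bins = 20) {
  if (n_position_bins < 1) abort("n_position_bins must be >= 1")
  n_int <- nrow(intervals)
  classes <- if ("class" %in% names(intervals)) {
    as.character(intervals$class)
  } else {
    rep("all", n_int)
  }
  mid <- floor((intervals$start + intervals$end) / 2)
  pb_w <- 2 * window / n_position_bins
  pos_df <- tibble(
    chrom = rep(intervals$chrom, each = n_position_bins),
    row = rep(seq_len(n_int), each = n_position_bins),
    col = rep(seq_len(n_position_bins), times = n_int)
  )
  pos_df$start <- rep(mid - window, each = n_position_bins) +
    (pos_df$col - 1) * pb_w
  pos_df$end <- pos_df$start + pb_w
  pos_df$start <- pmax(pos_df$start, 0)
  keep <- pos_df$end > pos_df$start
  mat <- matrix(0, n_int, n_position_bins)
  if (any(keep) && nrow(signal) > 0) {
    gq <- as_granges(pos_df[keep, ])
    gs <- as_granges(signal)
    ov <- GenomicRanges::findOverlaps(gq, gs)
    if (length(ov) > 0) {
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      w <- GenomicRanges::width(IRanges::pintersect(
        GenomicRanges::ranges(gq)[qh], GenomicRanges::ranges(gs)[sh]
      ))
      sums <- rowsum(as.numeric(w) * signal$value[sh], group = qh)
      covered <- rowsum(as.numeric(w), group = qh)
      ki <- which(keep)
      rows_hit <- as.integer(rownames(sums))
      if (any(covered < pb_w - 1e-9)) {
        warn("some profile bins are not fully covered by the signal track; missing bases treated as 0")
      }
      vals <- sums[, 1] / pb_w
      mat[cbind(pos_df$row[ki][rows_hit], pos_df$col[ki][rows_hit])] <- vals
    } else {
      warn("no signal overlaps the profile windows; profiles are 0")
    }
  }
  agg <- tibble(
    class = rep(sort(unique(classes)), each = n_position_bins),
    position_bin = rep(seq_len(n_position_bins), length(unique(classes)))
  )
  agg$mean_signal <- unlist(lapply(sort(unique(classes)), function(cl) {
    colMeans(mat[classes == cl, , drop = FALSE])
  }))
  structure(
    list(
      matrix = mat, classes = classes, aggregate = agg,
      window = window, n_position_bins = n_position_bins
    ),
    class = "meta_profile"
  )
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(
    "<meta_profile>", nrow(x$matrix), "intervals x", x$n_position_bins,
    "position bins; classes:", paste(unique(x$classes), collapse = ", "), "\n"
  )
  invisible(x)
}

#' @export
tidy.meta_profile <- function(x, ...) {
  x$aggregate
}
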