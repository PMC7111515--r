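# Interval plumbing shared across modules. All user-facing coordinates are
# BED-style: 0-based, half-open. IRanges is 1-based, closed; the two helpers
# below are the only place the conversion happens.

#' Convert a BED-style interval tibble to a GRanges
#'
#' @param df Data frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open).
#' @return A [GenomicRanges::GRanges] object.
#' @keywords internal
#' @noRd
as_granges <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) {
    return(GenomicRanges::GRanges())
  }
  if (any(df$start < 0)) {
    abort("negative coordinates are not allowed")
  }
  if (any(df$start >= df$end)) {
    abort("interval with start >= end")
  }
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

#' Convert a GRanges back to a BED-style tibble
#' @keywords internal
#' @noRd
as_bed_tibble <- function(gr) {
  if (length(gr) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr))
  ) %>%
    arrange(.data$chrom, .data$start)
}

# Merge intervals overlapping by >= 1 base. Bookended (touching) intervals
# are NOT merged: the half-open convention makes touching unambiguous.
merge_intervals <- function(df) {
  as_bed_tibble(GenomicRanges::reduce(as_granges(df), min.gapwidth = 0L))
}

# Base-level intersection of two interval sets, reported as maximal
# intervals of the intersected base set (adjacent bases coalesce).
intersect_intervals <- function(a, b) {
  ga <- as_granges(a)
  gb <- as_granges(b)
  seqs <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- seqs
  GenomeInfoDb::seqlevels(gb) <- seqs
  as_bed_tibble(GenomicRanges::intersect(ga, gb))
}

# Total bases covered by a (disjoint) interval set.
interval_bases <- function(df) {
  if (nrow(df) == 0) return(0)
  sum(df$end - df$start)
}

#' Per-interval chromatin-state proportions under one segmentation
#'
#' For each query interval, the fraction of its bases assigned to each state
#' by `segmentation`. Bases falling outside the segmented genome contribute
#' to no state; rows are normalised by the covered width, so fully covered
#' intervals have rows summing to 1.
#'
#' @param intervals Data frame with `chrom`, `start`, `end`.
#' @param segmentation A state segmentation (`chrom`, `start`, `end`,
#'   `state`).
#' @param n_states Number of states; states are `0:(n_states - 1)`.
#' @return Numeric matrix of dimension `nrow(intervals)` x `n_states`.
#' @export
interval_state_proportions <- function(intervals, segmentation, n_states) {
  m <- matrix(0, nrow = nrow(intervals), ncol = n_states)
  colnames(m) <- paste0("s", seq_len(n_states) - 1)
  if (nrow(intervals) == 0) {
    return(m)
  }
  gq <- as_granges(intervals)
  gs <- as_granges(segmentation)
  ov <- GenomicRanges::findOverlaps(gq, gs)
  if (length(ov) > 0) {
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(gq)[qh], GenomicRanges::ranges(gs)[sh]
    ))
    st <- segmentation$state[sh]
    key <- (qh - 1) * n_states + st + 1
    acc <- rowsum(as.numeric(w), group = key)
    idx <- as.integer(rownames(acc))
    m[cbind((idx - 1) %/% n_states + 1, (idx - 1) %% n_states + 1)] <- acc[, 1]
    covered <- rowSums(m)
    nz <- covered > 0
    m[nz, ] <- m[nz, , drop = FALSE] / covered[nz]
  }
  m
}

# Majority state per interval: the state covering the most bases, ties
# broken by the lowest state id.
majority_state <- function(prop_matrix) {
  max.col(prop_matrix, ties.method = "first") - 1L
}

# Checksums for manifest files. Uses sha256sum when the binary is on PATH,
# otherwise falls back to tools::md5sum.
file_checksums <- function(paths) {
  algo <- "sha256"
  sums <- rep(NA_character_, length(paths))
  has_sha <- nzchar(Sys.which("sha256sum"))
  if (has_sha && length(paths) > 0) {
    out <- system2("sha256sum", shQuote(paths), stdout = TRUE)
    sums <- sub(" .*$", "", out)
  } else if (length(paths) > 0) {
    algo <- "md5"
    sums <- unname(tools::md5sum(paths))
  }
  tibble(file = paths, checksum = sums, algorithm = algo)
}

# Moore-Penrose pseudoinverse via SVD; used only for rank-deficient fits.
pseudoinverse <- function(x, tol = 1e-10) {
  s <- svd(x)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) {
    return(matrix(0, ncol(x), nrow(x)))
  }
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}
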