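# Brute-force, base-level oracles and tiny-instance generators. Every
# oracle works on explicit per-base vectors over toy genomes (<= 1 Mb), so
# interval arithmetic in the package can be checked exactly.

# A small generator config for fast tests.
toy_config <- function(seed = 1, ...) {
  defaults <- list(
    n_cell_types = 3, n_states = 6,
    chrom_lengths = c(chrA = 2e5, chrB = 1e5),
    bin_size = 100, accessible_states = c(2L, 4L),
    n_genes = 25, links_per_gene = 2, n_replicates = 2,
    expression_noise_sd = 0, peak_dropout = 0, peak_jitter_bins = 0,
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Per-base state vector of one chromosome under a segmentation.
base_states <- function(seg, chrom, len) {
  v <- rep(NA_integer_, len)
  s <- seg[seg$chrom == chrom, ]
  for (i in seq_len(nrow(s))) {
    v[(s$start[i] + 1):s$end[i]] <- s$state[i]
  }
  v
}

# Per-base membership vector of an interval set on one chromosome.
base_set <- function(intervals, chrom, len) {
  v <- rep(FALSE, len)
  s <- intervals[intervals$chrom == chrom, ]
  for (i in seq_len(nrow(s))) {
    if (s$end[i] > s$start[i]) v[(s$start[i] + 1):s$end[i]] <- TRUE
  }
  v
}

# Maximal intervals from a per-base membership vector.
set_to_intervals <- function(v, chrom) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  tibble::tibble(chrom = chrom, start = starts[keep], end = ends[keep])
}

# Random interval set on a toy genome.
random_intervals <- function(n, chrom_lens, max_width = 5000) {
  chroms <- names(chrom_lens)
  ci <- sample(seq_along(chroms), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  start <- floor(runif(n) * pmax(chrom_lens[ci] - w, 1))
  tibble::tibble(
    chrom = chroms[ci], start = start,
    end = pmin(start + w, chrom_lens[ci])
  )
}

# Random segmentation tiling a toy genome (bin-aligned runs).
random_segmentation <- function(chrom_lens, n_states, bin = 100) {
  dplyr::bind_rows(lapply(names(chrom_lens), function(chrom) {
    n <- chrom_lens[[chrom]] / bin
    states <- sample.int(n_states, n, replace = TRUE) - 1L
    r <- rle(states)
    ends <- cumsum(r$lengths) * bin
    tibble::tibble(
      chrom = chrom, start = ends - r$lengths * bin, end = ends,
      state = r$values
    )
  }))
}

# Oracle: majority state of an interval under a segmentation (per-base).
oracle_majority <- function(interval, seg, n_states, len_by_chrom) {
  v <- base_states(seg, interval$chrom, len_by_chrom[[interval$chrom]])
  b <- v[(interval$start + 1):interval$end]
  counts <- tabulate(b + 1L, nbins = n_states)
  which.max(counts) - 1L
}

# Oracle: exhaustive agglomerative clustering (average/complete/single
# linkage) returning merge heights, for comparison with hclust.
oracle_agglomerate <- function(d, linkage = "average") {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        dd <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        val <- switch(linkage,
          average = mean(dd), complete = max(dd), single = min(dd)
        )
        if (val < best_d) {
          best_d <- val
          best <- c(j, i)
        }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Simulated two-branch lineage signal matrix with chosen within/between
# correlations (shared + branch + private Gaussian factors).
two_branch_matrix <- function(n_units = 400, per_branch = 4,
                              r_within = 0.9, r_between = 0.3) {
  shared <- rnorm(n_units)
  branches <- list(rnorm(n_units), rnorm(n_units))
  out <- sapply(seq_len(2 * per_branch), function(i) {
    branch <- branches[[if (i <= per_branch) 1 else 2]]
    sqrt(r_between) * shared + sqrt(r_within - r_between) * branch +
      sqrt(1 - r_within) * rnorm(n_units)
  })
  colnames(out) <- c(
    paste0("a", seq_len(per_branch)), paste0("b", seq_len(per_branch))
  )
  out
}
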