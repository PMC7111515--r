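# Readers and writers for the plain-text formats the package exchanges:
# 4-column state BED, 3-column peak BED, bedGraph signal, TSV tables.

#' Read / write a chromatin-state segmentation BED
#'
#' 4-column BED: chrom, start, end, integer state; 0-based half-open.
#' Adjacent same-state segments are merged on read, so `read_state_bed()`
#' after `write_state_bed()` is the identity on canonical segmentations.
#'
#' @param path File path.
#' @return A segmentation tibble (`chrom`, `start`, `end`, `state`).
#' @export
read_state_bed <- function(path) {
  df <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "state"),
    col_types = "cddi", progress = FALSE
  )
  validate_segmentation(df)
}

#' @rdname read_state_bed
#' @param segmentation A segmentation tibble.
#' @export
write_state_bed <- function(segmentation, path) {
  readr::write_tsv(segmentation[, c("chrom", "start", "end", "state")],
    path,
    col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Validate (and canonicalise) a state segmentation
#'
#' Checks coordinates and non-overlap, sorts, and merges adjacent segments
#' that share a state.
#'
#' @param segmentation A tibble with `chrom`, `start`, `end`, `state`.
#' @return The canonical segmentation tibble.
#' @export
validate_segmentation <- function(segmentation) {
  df <- as_tibble(segmentation)
  if (nrow(df) == 0) {
    return(df)
  }
  if (any(df$start < 0)) abort("negative coordinates in segmentation")
  if (any(df$start >= df$end)) abort("segment with start >= end")
  if (any(df$state < 0)) abort("negative state id")
  df <- arrange(df, .data$chrom, .data$start)
  prev_end <- c(-Inf, head(df$end, -1))
  same_chrom <- c(FALSE, head(df$chrom, -1) == tail(df$chrom, -1))
  if (any(same_chrom & df$start < prev_end)) {
    abort("overlapping segments in segmentation")
  }
  # merge adjacent same-state segments
  new_run <- !(same_chrom & df$start == prev_end &
    c(NA, head(df$state, -1)) == df$state)
  df$.run <- cumsum(ifelse(is.na(new_run), TRUE, new_run))
  df %>%
    group_by(.data$.run) %>%
    summarise(
      chrom = .data$chrom[1], start = min(.data$start),
      end = max(.data$end), state = .data$state[1], .groups = "drop"
    ) %>%
    select("chrom", "start", "end", "state") %>%
    arrange(.data$chrom, .data$start)
}

#' Read / write 3-column peak BED files
#' @param path File path.
#' @return A peak tibble (`chrom`, `start`, `end`).
#' @export
read_peak_bed <- function(path) {
  df <- readr::read_tsv(path,
    col_names = c("chrom", "start", "end"),
    col_types = "cdd", progress = FALSE
  )
  if (nrow(df) > 0 && (any(df$start < 0) || any(df$start >= df$end))) {
    abort("invalid peak coordinates")
  }
  arrange(df, .data$chrom, .data$start)
}

#' @rdname read_peak_bed
#' @param peaks A peak tibble.
#' @export
write_peak_bed <- function(peaks, path) {
  readr::write_tsv(peaks[, c("chrom", "start", "end")], path,
    col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Read / write a bedGraph signal track
#' @param path File path.
#' @return A tibble (`chrom`, `start`, `end`, `value`).
#' @export
read_bedgraph <- function(path) {
  readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "value"),
    col_types = "cddd", progress = FALSE
  )
}

#' @rdname read_bedgraph
#' @param track A signal tibble.
#' @export
write_bedgraph <- function(track, path) {
  readr::write_tsv(track[, c("chrom", "start", "end", "value")], path,
    col_names = FALSE, progress = FALSE
  )
  invisible(path)
}

#' Read / write an expression matrix TSV
#'
#' First column `gene_id`, remaining columns one per cell type (TPM).
#' @param path File path.
#' @export
read_expression_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
}

#' @rdname read_expression_tsv
#' @param expression Expression tibble.
#' @export
write_expression_tsv <- function(expression, path) {
  readr::write_tsv(expression, path, progress = FALSE)
  invisible(path)
}

#' Write the full synthetic fixture bundle to disk
#'
#' Writes state maps (4-column BED), per-replicate peak calls (3-column
#' BED), expression and gene annotation (TSV), ground-truth tables (TSV),
#' optionally signal tracks (bedGraph), the generator config (YAML), and a
#' manifest with one checksum line per file. Rerunning with the same
#' config (seed included) reproduces byte-identical files.
#'
#' @param truth A `sim_truth` from [simulate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @param config The generator config (defaults to `truth$config`).
#' @param signals Whether to write signal tracks if present in `truth`.
#' @return Invisibly, the manifest tibble (`file`, `checksum`,
#'   `algorithm`).
#' @export
write_fixture_bundle <- function(truth, out_dir, config = truth$config,
                                 signals = TRUE) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(paste("cannot create directory", out_dir))
  for (d in c("states", "peaks", "expression", "truth")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  rel <- character(0)
  put <- function(p) rel <<- c(rel, p)

  write_sim_config(config, file.path(out_dir, "config.yaml"))
  put("config.yaml")

  for (ct in names(truth$state_maps)) {
    p <- file.path("states", paste0(ct, ".states.bed"))
    write_state_bed(truth$state_maps[[ct]], file.path(out_dir, p))
    put(p)
  }
  if (!is.null(truth$peaks)) {
    for (ct in names(truth$peaks)) {
      for (r in names(truth$peaks[[ct]])) {
        p <- file.path("peaks", paste0(ct, ".", r, ".peaks.bed"))
        write_peak_bed(truth$peaks[[ct]][[r]], file.path(out_dir, p))
        put(p)
      }
    }
  }
  if (!is.null(truth$expression)) {
    p <- file.path("expression", "expression_tpm.tsv")
    write_expression_tsv(truth$expression, file.path(out_dir, p))
    put(p)
    p <- file.path("expression", "genes.tsv")
    readr::write_tsv(
      truth$genes[, c("gene_id", "chrom", "tss", "strand")],
      file.path(out_dir, p), progress = FALSE
    )
    put(p)
    p <- file.path("truth", "true_links.tsv")
    readr::write_tsv(truth$true_links, file.path(out_dir, p),
      progress = FALSE
    )
    put(p)
    p <- file.path("truth", "beta_truth.tsv")
    readr::write_tsv(
      tibble(
        state = seq_len(config$n_states) - 1L,
        beta_promoter = config$beta_promoter_truth,
        beta_ccre = config$beta_ccre_truth
      ),
      file.path(out_dir, p), progress = FALSE
    )
    put(p)
    p <- file.path("truth", "noiseless_expression.tsv")
    readr::write_tsv(
      bind_cols(
        tibble(gene_id = truth$genes$gene_id),
        as_tibble(truth$noiseless_expression)
      ),
      file.path(out_dir, p), progress = FALSE
    )
    put(p)
  }
  if (signals && !is.null(truth$signals)) {
    dir.create(file.path(out_dir, "signals"), showWarnings = FALSE)
    for (ct in names(truth$signals)) {
      for (f in names(truth$signals[[ct]])) {
        p <- file.path("signals", paste0(ct, ".", f, ".bedgraph"))
        write_bedgraph(truth$signals[[ct]][[f]], file.path(out_dir, p))
        put(p)
      }
    }
  }
  manifest <- write_manifest(out_dir, rel, seed = config$seed)
  invisible(manifest)
}

write_manifest <- function(out_dir, rel_paths, seed = NA) {
  sums <- file_checksums(file.path(out_dir, rel_paths))
  sums$file <- rel_paths
  lines <- c(
    paste0("# seed: ", seed),
    paste0("# checksum_algorithm: ", sums$algorithm[1] %||% "sha256"),
    paste0(sums$checksum, "\t", sums$file)
  )
  writeLines(lines, file.path(out_dir, "manifest.txt"))
  sums
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Write / read a generator config as YAML
#' @param config A [sim_config()].
#' @param path File path.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$emission_means <- apply(config$emission_means, 1, as.numeric,
    simplify = FALSE
  )
  x$chrom_lengths <- as.list(config$chrom_lengths)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  em <- do.call(rbind, lapply(x$emission_means, as.numeric))
  rownames(em) <- paste0("s", seq_len(nrow(em)) - 1)
  colnames(em) <- x$emission_features
  sim_config(
    n_cell_types = x$n_cell_types,
    lineage_tree = vapply(
      x$lineage_tree, function(v) if (is.null(v)) NA_integer_ else as.integer(v),
      integer(1)
    ),
    cell_types = x$cell_types,
    n_states = x$n_states,
    bin_size = x$bin_size,
    chrom_lengths = unlist(x$chrom_lengths),
    quiescent_target = x$quiescent_target,
    inherit_prob = x$inherit_prob,
    markov_persistence = x$markov_persistence,
    accessible_states = unlist(x$accessible_states),
    peak_dropout = x$peak_dropout,
    peak_jitter_bins = x$peak_jitter_bins,
    n_replicates = x$n_replicates,
    emission_features = x$emission_features,
    emission_means = em,
    signal_noise_sd = x$signal_noise_sd,
    n_genes = x$n_genes,
    links_per_gene = x$links_per_gene,
    coactive_links = x$coactive_links,
    tss_at_elements = x$tss_at_elements,
    max_link_distance = x$max_link_distance,
    promoter_window = x$promoter_window,
    expression_intercept = x$expression_intercept,
    beta_promoter_truth = unlist(x$beta_promoter_truth),
    beta_ccre_truth = unlist(x$beta_ccre_truth),
    expression_noise_sd = x$expression_noise_sd,
    seed = x$seed
  )
}
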