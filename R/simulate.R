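# Synthetic-data generator: lineage-correlated state maps, replicate
# accessibility peaks, per-feature signal tracks, and expression from a
# known linear model over state proportions. Every layer records its
# ground truth so downstream recovery can be tested.

topo_order <- function(parent) {
  n <- length(parent)
  done <- logical(n)
  ord <- integer(0)
  while (length(ord) < n) {
    ready <- which(!done &
      (is.na(parent) | done[ifelse(is.na(parent), 1L, parent)]))
    if (length(ready) == 0) abort("lineage_tree is not a tree")
    ord <- c(ord, ready)
    done[ready] <- TRUE
  }
  ord
}

# A state sequence with run-length persistence: each bin repeats the
# previous bin's state with probability `persistence`, otherwise draws
# fresh from the stationary distribution `pi`.
persistent_chain <- function(n, pi, persistence) {
  if (n == 0) {
    return(integer(0))
  }
  s <- length(pi)
  if (s == 1) {
    return(rep(0L, n))
  }
  change <- c(TRUE, runif(n - 1) > persistence)
  draws <- sample.int(s, sum(change), replace = TRUE, prob = pi) - 1L
  draws[cumsum(change)]
}

bins_to_segments <- function(states, chrom, bin_size) {
  if (length(states) == 0) {
    return(tibble(
      chrom = character(), start = numeric(), end = numeric(),
      state = integer()
    ))
  }
  r <- rle(as.integer(states))
  end_bin <- cumsum(r$lengths)
  tibble(
    chrom = chrom,
    start = (end_bin - r$lengths) * bin_size,
    end = end_bin * bin_size,
    state = r$values
  )
}

#' Simulate lineage-correlated chromatin-state maps
#'
#' Tiles every chromosome in `bin_size` bins for every cell type. The root
#' cell type draws states from a stationary distribution putting
#' `quiescent_target` mass on state 0 and the rest uniformly on the other
#' states, with run-length persistence `markov_persistence` along the
#' chromosome. Each child cell type copies its parent's state per bin with
#' probability `inherit_prob` and otherwise resamples from its own
#' persistent chain, which produces the local cross-cell-type similarity of
#' real differentiation series.
#'
#' @param config A [sim_config()].
#' @return A `sim_truth` object holding the per-cell-type segmentations
#'   (`$state_maps`, BED-style tibbles), the underlying bin-level state
#'   matrices (`$bin_states`), and the config.
#' @export
simulate_state_maps <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  s <- config$n_states
  pi <- if (s == 1) 1 else c(
    config$quiescent_target,
    rep((1 - config$quiescent_target) / (s - 1), s - 1)
  )
  ord <- topo_order(config$lineage_tree)
  chroms <- names(config$chrom_lengths)
  n_bins <- as.integer(config$chrom_lengths / config$bin_size)
  bin_states <- lapply(seq_along(chroms), function(ci) {
    matrix(NA_integer_, nrow = n_bins[ci], ncol = config$n_cell_types,
      dimnames = list(NULL, config$cell_types)
    )
  })
  names(bin_states) <- chroms
  for (ct in ord) {
    parent <- config$lineage_tree[ct]
    for (ci in seq_along(chroms)) {
      n <- n_bins[ci]
      innov <- persistent_chain(n, pi, config$markov_persistence)
      if (is.na(parent)) {
        bin_states[[ci]][, ct] <- innov
      } else {
        keep <- runif(n) < config$inherit_prob
        bin_states[[ci]][, ct] <- ifelse(keep, bin_states[[ci]][, parent], innov)
      }
    }
  }
  state_maps <- lapply(seq_len(config$n_cell_types), function(ct) {
    bind_rows(lapply(seq_along(chroms), function(ci) {
      bins_to_segments(bin_states[[ci]][, ct], chroms[ci], config$bin_size)
    }))
  })
  names(state_maps) <- config$cell_types
  structure(
    list(
      config = config,
      bin_states = bin_states,
      state_maps = state_maps
    ),
    class = "sim_truth"
  )
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(
    "<sim_truth>", x$config$n_cell_types, "cell types over",
    format(sum(x$config$chrom_lengths), big.mark = ","), "bases;",
    "layers:", paste(intersect(
      c("state_maps", "peaks", "expression", "signals"), names(x)
    ), collapse = ", "), "\n"
  )
  invisible(x)
}

accessible_runs <- function(truth, cell_type) {
  cfg <- truth$config
  bind_rows(lapply(names(truth$bin_states), function(chrom) {
    acc <- truth$bin_states[[chrom]][, cell_type] %in% cfg$accessible_states
    seg <- bins_to_segments(as.integer(acc), chrom, cfg$bin_size)
    seg[seg$state == 1L, c("chrom", "start", "end")]
  }))
}

#' Simulate replicate accessibility peak calls
#'
#' The true accessible intervals of a cell type are the maximal runs of
#' bins in accessible states. Each replicate retains each true interval
#' with probability `1 - peak_dropout` and jitters both endpoints
#' independently by up to `peak_jitter_bins` bins (uniform in bases);
#' overlapping jittered peaks are merged.
#'
#' @param truth A `sim_truth` from [simulate_state_maps()].
#' @param config The same [sim_config()].
#' @return `truth` with `$true_accessibility` (per cell type tibbles) and
#'   `$peaks` (per cell type, per replicate tibbles) added.
#' @export
simulate_peaks <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  if (config$n_replicates < 1) abort("n_replicates must be >= 1")
  set.seed(config$seed + 1L)
  jit <- config$peak_jitter_bins * config$bin_size
  chrom_len <- config$chrom_lengths
  true_acc <- lapply(config$cell_types, function(ct) accessible_runs(truth, ct))
  names(true_acc) <- config$cell_types
  peaks <- lapply(config$cell_types, function(ct) {
    tr <- true_acc[[ct]]
    reps <- lapply(seq_len(config$n_replicates), function(r) {
      keep <- runif(nrow(tr)) >= config$peak_dropout
      p <- tr[keep, , drop = FALSE]
      if (jit > 0 && nrow(p) > 0) {
        ds <- sample.int(2 * jit + 1, nrow(p), replace = TRUE) - jit - 1
        de <- sample.int(2 * jit + 1, nrow(p), replace = TRUE) - jit - 1
        ns <- pmax(p$start + ds, 0)
        ne <- pmin(p$end + de, chrom_len[p$chrom])
        bad <- ns >= ne
        ns[bad] <- p$start[bad]
        ne[bad] <- p$end[bad]
        p$start <- ns
        p$end <- ne
        p <- merge_intervals(p)
      }
      p
    })
    names(reps) <- paste0("rep", seq_len(config$n_replicates))
    reps
  })
  names(peaks) <- config$cell_types
  truth$true_accessibility <- true_acc
  truth$peaks <- peaks
  truth
}

# State proportions of arbitrary windows, computed straight from the
# bin-level state vector of one chromosome (partial edge bins weighted by
# covered bases). This is the generator's own route, independent of the
# segment-overlap route used by the analysis modules.
window_props_from_bins <- function(states, bin_size, starts, ends, n_states) {
  m <- matrix(0, length(starts), n_states)
  if (length(starts) == 0) {
    return(m)
  }
  first <- floor(starts / bin_size)
  last <- floor((ends - 1) / bin_size)
  nb <- last - first + 1
  win <- rep(seq_along(starts), nb)
  bin <- sequence(nb, from = first + 1)
  bs <- (bin - 1) * bin_size
  w <- pmin(ends[win], bs + bin_size) - pmax(starts[win], bs)
  st <- states[bin]
  key <- (win - 1) * n_states + st + 1
  acc <- rowsum(as.numeric(w), group = key)
  idx <- as.integer(rownames(acc))
  m[cbind((idx - 1) %/% n_states + 1, (idx - 1) %% n_states + 1)] <- acc[, 1]
  m / pmax(rowSums(m), .Machine$double.eps)
}

props_by_cell_type <- function(truth, intervals) {
  cfg <- truth$config
  out <- lapply(cfg$cell_types, function(ct) {
    m <- matrix(0, nrow(intervals), cfg$n_states)
    for (chrom in names(truth$bin_states)) {
      on <- which(intervals$chrom == chrom)
      if (length(on) == 0) next
      m[on, ] <- window_props_from_bins(
        truth$bin_states[[chrom]][, ct], cfg$bin_size,
        intervals$start[on], intervals$end[on], cfg$n_states
      )
    }
    m
  })
  names(out) <- cfg$cell_types
  out
}

#' Simulate expression from state proportions with known coefficients
#'
#' Genes get TSSs placed uniformly per chromosome and `links_per_gene` true
#' regulatory links to accessible elements within `max_link_distance` of
#' the TSS (a co-active hub of elements with similar state trajectories
#' when `coactive_links` is set; see [sim_config()]). Noiseless log2
#' expression is
#' `intercept + sum_s beta_promoter[s] P_prom(g,t,s) +
#'  sum_s beta_ccre[s] P_pool(g,t,s)`,
#' where `P_prom` is the state-proportion vector of the promoter window and
#' `P_pool` the unweighted mean over the gene's linked elements of their
#' state-proportion vectors. Gaussian noise is added on the log2 scale and
#' values are exported as TPM via `2^x - 1` floored at 0 (so
#' `log2(TPM + 1)` round-trips for nonnegative x).
#'
#' @inheritParams simulate_peaks
#' @return `truth` with `$genes`, `$true_links`, `$elements`,
#'   `$promoter_props`, `$pooled_props`, `$noiseless_expression`, and
#'   `$expression` (tibble, gene_id + one TPM column per cell type) added.
#' @export
simulate_expression <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(config$seed + 2L)
  cfg <- config
  w <- cfg$promoter_window
  chroms <- names(cfg$chrom_lengths)

  # union of accessible runs across cell types = the true element universe
  elements <- merge_intervals(bind_rows(lapply(
    cfg$cell_types, function(ct) accessible_runs(truth, ct)
  )))
  elements$element_id <- sprintf("e%06d", seq_len(nrow(elements)))
  elements$mid <- floor((elements$start + elements$end) / 2)

  n_g <- cfg$n_genes
  if (n_g > 0 && length(chroms) > 0) {
    all_runs <- bind_rows(lapply(
      cfg$cell_types, function(ct) accessible_runs(truth, ct)
    ))
    if (cfg$tss_at_elements && nrow(all_runs) > 0) {
      # real promoters are nuclease accessible: anchor each TSS at the
      # midpoint of one cell type's accessible run, so the promoter
      # window is accessible exactly where that run is
      ri <- sample.int(nrow(all_runs), n_g, replace = TRUE)
      chrom_g <- all_runs$chrom[ri]
      mid_r <- floor((all_runs$start[ri] + all_runs$end[ri]) / 2)
      tss <- pmin(pmax(mid_r, w), cfg$chrom_lengths[chrom_g] - w)
    } else {
      ci <- sample.int(length(chroms), n_g, replace = TRUE,
        prob = cfg$chrom_lengths
      )
      avail <- pmax(cfg$chrom_lengths[ci] - 2 * w, 1)
      tss <- w + floor(runif(n_g) * avail)
      tss <- pmin(tss, cfg$chrom_lengths[ci] - 1)
      chrom_g <- chroms[ci]
    }
    genes <- tibble(
      gene_id = sprintf("g%05d", seq_len(n_g)),
      chrom = chrom_g,
      tss = as.numeric(tss),
      strand = sample(c("+", "-"), n_g, replace = TRUE)
    )
  } else {
    genes <- tibble(
      gene_id = character(), chrom = character(), tss = numeric(),
      strand = character()
    )
  }

  # element state annotation used for hub sampling and pooled predictors
  element_props <- props_by_cell_type(truth, elements)
  maj_traj <- NULL
  dynamic <- NULL
  if (cfg$coactive_links && nrow(elements) > 0) {
    maj_traj <- vapply(
      cfg$cell_types, function(ct) majority_state(element_props[[ct]]),
      integer(nrow(elements))
    )
    maj_traj <- matrix(maj_traj, nrow = nrow(elements))
    n_active <- rowSums(maj_traj != 0)
    dynamic <- n_active >= 2 & n_active <= cfg$n_cell_types - 2
  }

  # true links: links_per_gene elements within max_link_distance of the
  # TSS. With coactive_links, links form a hub: a random dynamic seed
  # element plus its most similar neighbours by majority-state trajectory
  # (several seeds are tried and the tightest hub kept).
  mids_by_chrom <- split(
    seq_len(nrow(elements)), factor(elements$chrom, levels = chroms)
  )
  link_list <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    idx <- mids_by_chrom[[genes$chrom[g]]]
    if (length(idx) == 0) next
    d <- abs(elements$mid[idx] - genes$tss[g])
    # distal only: elements overlapping the promoter window are not links
    distal <- elements$end[idx] <= genes$tss[g] - w |
      elements$start[idx] >= genes$tss[g] + w
    cand <- idx[d <= cfg$max_link_distance & distal]
    if (length(cand) == 0) next
    if (length(cand) <= cfg$links_per_gene) {
      sel <- cand
    } else if (!cfg$coactive_links) {
      sel <- sort(sample(cand, cfg$links_per_gene))
    } else {
      pool <- cand[dynamic[cand]]
      if (length(pool) < cfg$links_per_gene) pool <- cand
      if (length(pool) <= cfg$links_per_gene) {
        sel <- pool
      } else {
        best <- NULL
        best_sim <- -Inf
        for (try in seq_len(5)) {
          s0 <- pool[sample.int(length(pool), 1)]
          sims <- colMeans(t(maj_traj[pool, , drop = FALSE]) == maj_traj[s0, ])
          sims[pool == s0] <- Inf
          sel_try <- pool[order(-sims)[seq_len(cfg$links_per_gene)]]
          ms <- mean(colMeans(
            t(maj_traj[setdiff(sel_try, s0), , drop = FALSE]) == maj_traj[s0, ]
          ))
          if (ms > best_sim) {
            best_sim <- ms
            best <- sel_try
          }
          if (ms >= 0.8) break
        }
        sel <- sort(best)
      }
    }
    link_list[[g]] <- tibble(gene_id = genes$gene_id[g], element_idx = sel)
  }
  true_links <- bind_rows(link_list)
  if (nrow(true_links) == 0) {
    true_links <- tibble(gene_id = character(), element_idx = integer())
  }
  genes$n_links <- as.integer(table(factor(
    true_links$gene_id, levels = genes$gene_id
  )))
  genes$zero_links <- genes$n_links == 0

  # predictors from the generator's own bin matrices
  prom_windows <- genes
  prom_windows$start <- pmax(genes$tss - w, 0)
  prom_windows$end <- pmin(genes$tss + w, cfg$chrom_lengths[genes$chrom])
  promoter_props <- props_by_cell_type(truth, prom_windows)

  pooled_props <- lapply(cfg$cell_types, function(ct) {
    m <- matrix(0, nrow(genes), cfg$n_states)
    if (nrow(true_links) > 0) {
      gi <- match(true_links$gene_id, genes$gene_id)
      acc <- rowsum(
        element_props[[ct]][true_links$element_idx, , drop = FALSE],
        group = gi
      )
      rows <- as.integer(rownames(acc))
      m[rows, ] <- acc / genes$n_links[rows]
    }
    m
  })
  names(pooled_props) <- cfg$cell_types

  noiseless <- matrix(0, nrow(genes), cfg$n_cell_types,
    dimnames = list(genes$gene_id, cfg$cell_types)
  )
  for (ct in cfg$cell_types) {
    noiseless[, ct] <- cfg$expression_intercept +
      promoter_props[[ct]] %*% cfg$beta_promoter_truth +
      pooled_props[[ct]] %*% cfg$beta_ccre_truth
  }
  observed <- noiseless
  if (cfg$expression_noise_sd > 0 && length(noiseless) > 0) {
    observed <- noiseless + matrix(
      rnorm(length(noiseless), sd = cfg$expression_noise_sd),
      nrow(noiseless), ncol(noiseless)
    )
  }
  tpm <- pmax(2^observed - 1, 0)
  expression <- bind_cols(
    tibble(gene_id = genes$gene_id),
    as_tibble(tpm)
  )

  link_export <- tibble(
    gene_id = true_links$gene_id,
    element_id = elements$element_id[true_links$element_idx],
    chrom = elements$chrom[true_links$element_idx],
    start = elements$start[true_links$element_idx],
    end = elements$end[true_links$element_idx]
  )

  truth$genes <- genes
  truth$elements <- elements
  truth$true_links <- link_export
  truth$promoter_props <- promoter_props
  truth$pooled_props <- pooled_props
  truth$noiseless_expression <- noiseless
  truth$expression <- expression
  truth
}

#' Simulate binned signal tracks from state emission means
#'
#' Each bin's signal for a feature is the emission mean of its state plus
#' Gaussian noise, truncated at 0. Each (cell type, feature) track gets its
#' own derived seed, so a track is reproducible regardless of which subset
#' is requested.
#'
#' @inheritParams simulate_peaks
#' @param cell_types,features Subsets to generate (default: all).
#' @return Named list: cell type -> feature -> bedGraph-style tibble
#'   (`chrom`, `start`, `end`, `value`).
#' @export
simulate_signal_tracks <- function(truth, config = truth$config,
                                   cell_types = config$cell_types,
                                   features = config$emission_features) {
  stopifnot(inherits(truth, "sim_truth"))
  missing_f <- setdiff(features, config$emission_features)
  if (length(missing_f) > 0) {
    abort(paste("no emission means for feature:", paste(missing_f, collapse = ", ")))
  }
  cfg <- config
  out <- lapply(cell_types, function(ct) {
    cti <- match(ct, cfg$cell_types)
    tracks <- lapply(features, function(f) {
      fi <- match(f, cfg$emission_features)
      set.seed((cfg$seed + 7919L * cti + 104729L * fi) %% .Machine$integer.max)
      bind_rows(lapply(names(truth$bin_states), function(chrom) {
        st <- truth$bin_states[[chrom]][, cti]
        v <- unname(cfg$emission_means[st + 1, fi])
        if (cfg$signal_noise_sd > 0) {
          v <- v + rnorm(length(v), sd = cfg$signal_noise_sd)
        }
        n <- length(st)
        tibble(
          chrom = chrom,
          start = (seq_len(n) - 1) * cfg$bin_size,
          end = seq_len(n) * cfg$bin_size,
          value = pmax(v, 0)
        )
      }))
    })
    names(tracks) <- features
    tracks
  })
  names(out) <- cell_types
  out
}

#' Run every simulation layer
#'
#' @param config A [sim_config()].
#' @param signals Whether to also simulate signal tracks (stored under
#'   `$signals`; off by default because tracks are large).
#' @param signal_features Features to simulate when `signals = TRUE`.
#' @return A complete `sim_truth`.
#' @export
simulate_dataset <- function(config, signals = FALSE,
                             signal_features = config$emission_features[1]) {
  truth <- simulate_state_maps(config)
  truth <- simulate_peaks(truth, config)
  truth <- simulate_expression(truth, config)
  if (signals) {
    truth$signals <- simulate_signal_tracks(
      truth, config,
      features = signal_features
    )
  }
  truth
}

#' Map true links to registry cCRE ids
#'
#' Matches each true (gene, element) link from the generator to the
#' registry cCREs overlapping that element, giving the ground-truth pair
#' set against which screened/subselected pairs can be scored.
#'
#' @param truth A `sim_truth` with `$true_links`.
#' @param registry A `ccre_registry` built from the same simulation.
#' @return Tibble with `gene_id` and `ccre_id` (one row per true pair;
#'   elements split across several cCREs yield several rows).
#' @export
true_link_pairs <- function(truth, registry) {
  tl <- truth$true_links
  if (is.null(tl) || nrow(tl) == 0 || nrow(registry$ccres) == 0) {
    return(tibble(gene_id = character(), ccre_id = character()))
  }
  ov <- GenomicRanges::findOverlaps(
    as_granges(tl), as_granges(registry$ccres)
  )
  distinct(tibble(
    gene_id = tl$gene_id[S4Vectors::queryHits(ov)],
    ccre_id = registry$ccres$ccre_id[S4Vectors::subjectHits(ov)]
  ))
}
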