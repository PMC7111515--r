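#' Configuration for the synthetic hematopoiesis-like data generator
#'
#' Builds and validates the configuration controlling every layer of the
#' synthetic data: lineage-correlated chromatin-state maps over a set of
#' cell types, accessibility peaks with replicate noise, per-feature signal
#' tracks drawn from state emission means, and gene expression generated
#' from a linear model over promoter and pooled-cCRE state proportions with
#' known coefficients and known cCRE-gene links.
#'
#' The defaults emulate the study conditions the package targets: 20 cell
#' types on a branching lineage, 27 chromatin states with a dominant
#' quiescent state (state 0) covering ~86% of the genome, 200-bp bins,
#' reproducible peaks from 2 replicates, and 2,000 genes whose expression
#' is a linear function of state proportions at the promoter (TSS +/- 1
#' kb) and at 5 linked distal elements within 1 Mb. By default a gene's
#' true links form a co-active "enhancer hub" of elements with similar
#' state trajectories across cell types, the premise under which
#' correlation-based enhancer-gene assignment is informative.
#'
#' @param n_cell_types Number of cell types.
#' @param lineage_tree Integer vector of parent indices (NA for the root).
#'   Defaults to a balanced binary tree rooted at cell type 1.
#' @param cell_types Character names for the cell types.
#' @param n_states Number of chromatin states; state 0 is quiescent.
#' @param bin_size Segmentation bin width in bases.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bases.
#'   Lengths are truncated to whole bins.
#' @param quiescent_target Stationary fraction of the genome in state 0.
#' @param inherit_prob Probability that a child cell type keeps its parent's
#'   state in a bin; otherwise the bin is resampled from the child's own
#'   persistent chain.
#' @param markov_persistence Probability a bin repeats the previous bin's
#'   state along a chromosome.
#' @param accessible_states Integer set of states that produce nuclease
#'   accessibility; must not contain the quiescent state.
#' @param peak_dropout Per-replicate probability of missing a true
#'   accessible interval.
#' @param peak_jitter_bins Peak endpoint jitter, in bins (0 disables).
#' @param n_replicates Accessibility replicates per cell type.
#' @param emission_features Feature (assay) names for signal tracks.
#' @param emission_means States x features matrix of mean signals.
#' @param signal_noise_sd Gaussian noise sd added to signal bins.
#' @param n_genes Number of genes.
#' @param links_per_gene True regulatory links per gene.
#' @param coactive_links Sample each gene's links as a co-active hub
#'   (seed element plus its most similar dynamic neighbours by
#'   majority-state trajectory) instead of uniformly.
#' @param tss_at_elements Anchor gene TSSs at accessible elements
#'   (jittered by up to one promoter width), so promoters are nuclease
#'   accessible as real promoters are; otherwise TSSs are uniform.
#' @param max_link_distance Maximum |cCRE midpoint - TSS| for a true link,
#'   in bases.
#' @param promoter_window Promoter half-width around the TSS, in bases.
#' @param expression_intercept Intercept of the expression model
#'   (log2 scale).
#' @param beta_promoter_truth,beta_ccre_truth Per-state true coefficients;
#'   entry 1 (state 0) must be 0.
#' @param expression_noise_sd Gaussian noise sd on the log2 expression
#'   scale.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(
#'   n_cell_types = 3, n_states = 5,
#'   chrom_lengths = c(chr1 = 2e5), n_genes = 10
#' )
#' cfg$quiescent_target
#' @export
sim_config <- function(n_cell_types = 20,
                       lineage_tree = NULL,
                       cell_types = sprintf("ct%02d", seq_len(n_cell_types)),
                       n_states = 27,
                       bin_size = 200,
                       chrom_lengths = c(chr1 = 16e6, chr2 = 16e6, chr3 = 16e6),
                       quiescent_target = 0.86,
                       inherit_prob = 0.85,
                       markov_persistence = 0.9,
                       accessible_states = default_accessible_states(n_states),
                       peak_dropout = 0.1,
                       peak_jitter_bins = 1,
                       n_replicates = 2,
                       emission_features = c(
                         "atac", "h3k4me1", "h3k4me3", "h3k27ac",
                         "h3k36me3", "h3k27me3", "h3k9me3", "ctcf"
                       ),
                       emission_means = default_emission_means(
                         n_states, emission_features, accessible_states
                       ),
                       signal_noise_sd = 0.5,
                       n_genes = 2000,
                       links_per_gene = 5,
                       coactive_links = TRUE,
                       tss_at_elements = TRUE,
                       max_link_distance = 1e6,
                       promoter_window = 1000,
                       expression_intercept = 4,
                       beta_promoter_truth = default_beta_truth(
                         n_states, "promoter", accessible_states
                       ),
                       beta_ccre_truth = default_beta_truth(
                         n_states, "ccre", accessible_states
                       ),
                       expression_noise_sd = 0.5,
                       seed = 1L) {
  if (is.null(lineage_tree)) {
    lineage_tree <- NA_integer_
    if (n_cell_types >= 2) {
      lineage_tree <- c(NA_integer_, (2:n_cell_types) %/% 2)
    }
  }
  cfg <- structure(
    list(
      n_cell_types = as.integer(n_cell_types),
      lineage_tree = as.integer(lineage_tree),
      cell_types = as.character(cell_types),
      n_states = as.integer(n_states),
      bin_size = as.integer(bin_size),
      chrom_lengths = chrom_lengths,
      quiescent_target = quiescent_target,
      inherit_prob = inherit_prob,
      markov_persistence = markov_persistence,
      accessible_states = as.integer(accessible_states),
      peak_dropout = peak_dropout,
      peak_jitter_bins = as.integer(peak_jitter_bins),
      n_replicates = as.integer(n_replicates),
      emission_features = emission_features,
      emission_means = emission_means,
      signal_noise_sd = signal_noise_sd,
      n_genes = as.integer(n_genes),
      links_per_gene = as.integer(links_per_gene),
      coactive_links = isTRUE(coactive_links),
      tss_at_elements = isTRUE(tss_at_elements),
      max_link_distance = max_link_distance,
      promoter_window = promoter_window,
      expression_intercept = expression_intercept,
      beta_promoter_truth = beta_promoter_truth,
      beta_ccre_truth = beta_ccre_truth,
      expression_noise_sd = expression_noise_sd,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(
    "<sim_config>", x$n_cell_types, "cell types,", x$n_states, "states,",
    length(x$chrom_lengths), "chromosomes (",
    format(sum(x$chrom_lengths), big.mark = ","), "bases ),",
    x$n_genes, "genes, seed", x$seed, "\n"
  )
  invisible(x)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_cell_types < 1) abort("n_cell_types must be >= 1")
  if (length(cfg$lineage_tree) != cfg$n_cell_types) {
    abort("lineage_tree must have one entry per cell type")
  }
  roots <- which(is.na(cfg$lineage_tree))
  if (length(roots) != 1) {
    abort("lineage_tree must have exactly one root (one NA parent)")
  }
  # acyclicity: walking up from every node must reach the root
  for (i in seq_len(cfg$n_cell_types)) {
    seen <- logical(cfg$n_cell_types)
    j <- i
    while (!is.na(cfg$lineage_tree[j])) {
      if (seen[j]) abort("lineage_tree contains a cycle")
      seen[j] <- TRUE
      j <- cfg$lineage_tree[j]
      if (j < 1 || j > cfg$n_cell_types) abort("lineage_tree parent out of range")
    }
  }
  if (cfg$quiescent_target < 0 || cfg$quiescent_target > 1) {
    abort("quiescent_target must lie in [0, 1]")
  }
  if (cfg$n_states < 1) abort("n_states must be >= 1")
  if (0L %in% cfg$accessible_states) {
    abort("the quiescent state (0) cannot be accessible")
  }
  if (any(cfg$accessible_states < 0 | cfg$accessible_states >= cfg$n_states)) {
    abort("accessible_states out of range")
  }
  if (cfg$n_replicates < 1) abort("n_replicates must be >= 1")
  if (cfg$signal_noise_sd < 0 || cfg$expression_noise_sd < 0) {
    abort("noise standard deviations must be nonnegative")
  }
  if (any(cfg$chrom_lengths < cfg$bin_size)) {
    abort("every chromosome must hold at least one bin")
  }
  if (is.null(names(cfg$chrom_lengths))) {
    abort("chrom_lengths must be named")
  }
  for (nm in c("beta_promoter_truth", "beta_ccre_truth")) {
    b <- cfg[[nm]]
    if (length(b) != cfg$n_states) {
      abort(paste(nm, "must have one entry per state"))
    }
    if (b[1] != 0) abort(paste(nm, "entry for state 0 must be 0"))
  }
  if (!is.matrix(cfg$emission_means) ||
    nrow(cfg$emission_means) != cfg$n_states ||
    ncol(cfg$emission_means) != length(cfg$emission_features)) {
    abort("emission_means must be an n_states x n_features matrix")
  }
  # truncate chromosome lengths to whole bins
  cfg$chrom_lengths <- floor(cfg$chrom_lengths / cfg$bin_size) * cfg$bin_size
  cfg
}

#' Default accessible-state set
#'
#' A fixed subset of non-quiescent states standing in for enhancer-,
#' promoter- and CTCF-like accessible states. About 30% of the
#' non-quiescent states are accessible.
#'
#' @param n_states Number of states.
#' @return Integer vector of state ids.
#' @export
default_accessible_states <- function(n_states) {
  if (n_states <= 1) {
    return(integer(0))
  }
  k <- max(1, round((n_states - 1) * 0.3))
  ids <- unique(round(seq(2, n_states - 1, length.out = k)))
  as.integer(ids[ids >= 1 & ids <= n_states - 1])
}

#' Default true regression coefficients
#'
#' State 0 (quiescent) is the reference and fixed at 0. Accessible
#' (enhancer-like) states carry strong positive effects (1.5 to 3 on the
#' log2 expression scale), as active enhancer states do; the remaining
#' non-quiescent states receive an evenly spaced ladder from -2
#' (repressive, polycomb/heterochromatin-like) to +1. The promoter-context
#' ladders are reversed within each group so the two contexts carry
#' distinct signal.
#'
#' @param n_states Number of states.
#' @param context `"promoter"` or `"ccre"`.
#' @param accessible_states Accessible state ids (given strong positive
#'   coefficients).
#' @return Numeric vector of length `n_states`.
#' @export
default_beta_truth <- function(n_states, context = c("ccre", "promoter"),
                               accessible_states = default_accessible_states(n_states)) {
  context <- match.arg(context)
  b <- rep(0, n_states)
  if (n_states == 1) {
    return(b)
  }
  acc <- intersect(accessible_states + 1, seq(2, n_states))
  non_acc <- setdiff(seq(2, n_states), acc)
  if (length(acc) > 0) {
    b[acc] <- seq(1.5, 3, length.out = length(acc))
  }
  if (length(non_acc) > 0) {
    b[non_acc] <- seq(-2, 1, length.out = length(non_acc))
  }
  if (context == "promoter") {
    # reverse within each group: accessible states stay strongly
    # activating in both contexts, but the two ladders differ per state
    b[acc] <- rev(b[acc])
    b[non_acc] <- rev(b[non_acc])
  }
  b
}

#' Default state emission means
#'
#' A deterministic, synthetic states x features matrix: the quiescent state
#' is near-silent in every feature, accessible states have high
#' accessibility signal, and the remaining states receive a fixed staggered
#' pattern so that every state has a distinct signature.
#'
#' @param n_states Number of states.
#' @param features Character feature names.
#' @param accessible_states Accessible state ids.
#' @return Numeric matrix (`n_states` x `length(features)`).
#' @export
default_emission_means <- function(n_states, features,
                                   accessible_states = integer(0)) {
  m <- matrix(0.1, nrow = n_states, ncol = length(features),
    dimnames = list(paste0("s", seq_len(n_states) - 1), features)
  )
  if (n_states > 1) {
    for (s in seq(2, n_states)) {
      for (f in seq_along(features)) {
        m[s, f] <- 0.2 + ((s * 7 + f * 3) %% 11) / 2
      }
    }
  }
  if (length(accessible_states) > 0 && length(features) > 0) {
    m[accessible_states + 1, 1] <- m[accessible_states + 1, 1] + 4
  }
  m
}
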