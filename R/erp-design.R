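# Predictor construction for the eRP regression: gene categories,
# candidate cCRE-gene pairs, promoter-window state proportions, pooled
# cCRE proportions, and the design matrix.

#' log2(TPM + 1) expression matrix
#'
#' @param expression Expression tibble (`gene_id` + TPM columns).
#' @return Numeric matrix, genes x cell types, rownames = gene ids.
#' @export
expression_log2 <- function(expression) {
  m <- as_signal_matrix(expression)
  log2(m + 1)
}

#' Categorize genes by expression breadth and variability
#'
#' A gene is expressed in a cell type when TPM strictly exceeds
#' `low_threshold`. Categories: `consistently_low` (expressed nowhere),
#' `consistently_high` (expressed everywhere, log2(TPM+1) spread below
#' `variability_threshold`), `differentially_high` (expressed everywhere,
#' spread at or above the threshold), `differentially_low` (the
#' remainder: expressed in some but not all cell types).
#'
#' @param expression Expression tibble (TPM).
#' @param low_threshold TPM threshold for "expressed" (default 1).
#' @param variability_threshold log2 spread separating consistent from
#'   differential among always-expressed genes (default 1).
#' @return Tibble with `gene_id`, `category`, `n_expressed`,
#'   `log2_spread`.
#' @export
categorize_genes <- function(expression, low_threshold = 1,
                             variability_threshold = 1) {
  m <- as_signal_matrix(expression)
  if (length(m) == 0) abort("empty expression matrix")
  expressed <- m > low_threshold
  n_exp <- rowSums(expressed)
  lg <- log2(m + 1)
  spread <- apply(lg, 1, max) - apply(lg, 1, min)
  category <- case_when(
    n_exp == 0 ~ "consistently_low",
    n_exp == ncol(m) & spread < variability_threshold ~ "consistently_high",
    n_exp == ncol(m) ~ "differentially_high",
    TRUE ~ "differentially_low"
  )
  tibble(
    gene_id = rownames(m) %||% as.character(seq_len(nrow(m))),
    category = category,
    n_expressed = as.integer(n_exp),
    log2_spread = spread
  )
}

#' Candidate cCRE-gene pairs within a distance window
#'
#' One pair per (gene, cCRE) on the same chromosome with the cCRE midpoint
#' within `max_distance` of the TSS (inclusive). cCREs overlapping the
#' promoter window are excluded from the distal candidate set by default,
#' so promoter and distal predictors stay separate.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `tss`).
#' @param registry A `ccre_registry`.
#' @param max_distance Maximum |cCRE midpoint - TSS| in bases (default
#'   1 Mb).
#' @param promoter_window Promoter half-width used for the exclusion.
#' @param exclude_promoter_overlap Drop cCREs overlapping the promoter
#'   window.
#' @return Pair tibble: `gene_id`, `ccre_id`, `distance`, `selected`
#'   (all TRUE initially), `screen_correlation` (NA until screened).
#' @export
assign_candidates <- function(genes, registry, max_distance = 1e6,
                              promoter_window = 1000,
                              exclude_promoter_overlap = TRUE) {
  cc <- registry$ccres
  mid <- floor((cc$start + cc$end) / 2)
  out <- vector("list", length(unique(genes$chrom)))
  names(out) <- unique(genes$chrom)
  for (chrom in unique(genes$chrom)) {
    gi <- which(genes$chrom == chrom)
    ci <- which(cc$chrom == chrom)
    if (length(ci) == 0) next
    ord <- ci[order(mid[ci])]
    mids <- mid[ord]
    # midpoints are integers; the +/- 0.5 shift makes both bounds inclusive
    lo <- findInterval(genes$tss[gi] - max_distance - 0.5, mids) + 1
    hi <- findInterval(genes$tss[gi] + max_distance + 0.5, mids)
    n_per <- pmax(hi - lo + 1, 0)
    g_rep <- rep(gi, n_per)
    c_rep <- ord[sequence(n_per[n_per > 0], from = lo[n_per > 0])]
    out[[chrom]] <- tibble(
      gene_id = genes$gene_id[g_rep],
      ccre_id = cc$ccre_id[c_rep],
      distance = abs(mid[c_rep] - genes$tss[g_rep]),
      tss = genes$tss[g_rep],
      ccre_start = cc$start[c_rep],
      ccre_end = cc$end[c_rep]
    )
  }
  pairs <- bind_rows(out)
  if (nrow(pairs) == 0) {
    return(tibble(
      gene_id = character(), ccre_id = character(), distance = numeric(),
      selected = logical(), screen_correlation = numeric()
    ))
  }
  if (exclude_promoter_overlap) {
    overlaps_prom <- pairs$ccre_end > pairs$tss - promoter_window &
      pairs$ccre_start < pairs$tss + promoter_window
    pairs <- pairs[!overlaps_prom, , drop = FALSE]
  }
  pairs %>%
    select("gene_id", "ccre_id", "distance") %>%
    mutate(selected = TRUE, screen_correlation = NA_real_) %>%
    arrange(.data$gene_id, .data$distance)
}

#' Promoter-window state proportions per cell type
#'
#' State proportions of the TSS +/- `window` interval under each cell
#' type's segmentation.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `tss`).
#' @param segmentations Named list of segmentation tibbles.
#' @param n_states Number of states.
#' @param window Promoter half-width in bases (default 1000).
#' @return Named list: cell type -> genes x states matrix (rownames =
#'   gene ids).
#' @export
promoter_state_proportions <- function(genes, segmentations, n_states,
                                       window = 1000) {
  wins <- tibble(
    chrom = genes$chrom,
    start = pmax(genes$tss - window, 0),
    end = genes$tss + window
  )
  out <- lapply(segmentations, function(seg) {
    m <- interval_state_proportions(wins, seg, n_states)
    rownames(m) <- genes$gene_id
    m
  })
  out
}

# Pooled (unweighted mean) state proportions over each gene's selected
# cCREs, per cell type. `prop_list` defaults to the registry's full
# proportion matrices; passing one-hot matrices gives the single-state
# representation used during subselection.
pooled_gene_props <- function(pairs, registry, gene_ids,
                              prop_list = registry$proportions,
                              cell_types = registry$cell_types) {
  sel <- pairs[pairs$selected, , drop = FALSE]
  gi <- match(sel$gene_id, gene_ids)
  ci <- match(sel$ccre_id, registry$ccres$ccre_id)
  if (anyNA(ci)) abort("pair references a cCRE absent from the registry")
  n_per <- tabulate(gi, nbins = length(gene_ids))
  out <- lapply(cell_types, function(ct) {
    m <- matrix(0, length(gene_ids), registry$n_states)
    rownames(m) <- gene_ids
    if (nrow(sel) > 0) {
      acc <- rowsum(prop_list[[ct]][ci, , drop = FALSE], group = gi)
      rows <- as.integer(rownames(acc))
      m[rows, ] <- acc / n_per[rows]
    }
    m
  })
  names(out) <- cell_types
  out
}

# One-hot (majority-state) proportion matrices per cell type.
onehot_proportions <- function(registry) {
  lapply(setNames(registry$cell_types, registry$cell_types), function(ct) {
    maj <- majority_state(registry$proportions[[ct]])
    m <- matrix(0, nrow(registry$ccres), registry$n_states)
    rownames(m) <- registry$ccres$ccre_id
    if (nrow(registry$ccres) > 0) {
      m[cbind(seq_len(nrow(m)), maj + 1)] <- 1
    }
    m
  })
}

#' Build the eRP design matrix
#'
#' Observations are (gene, cell type) pairs; the response is
#' log2(TPM + 1). The promoter block is the promoter-window
#' state-proportion vector; the cCRE block is the unweighted mean of the
#' gene's selected cCREs' proportion vectors. The reference
#' (quiescent) state column is dropped from each block for
#' identifiability; `mode` selects promoter, cCRE, or both blocks.
#'
#' @param pairs Candidate pair tibble (rows with `selected = FALSE` are
#'   ignored).
#' @param registry A `ccre_registry`.
#' @param expression Expression tibble (TPM).
#' @param genes Gene tibble; a `category` column, if present, is carried
#'   into the observations.
#' @param promoter_props Output of [promoter_state_proportions()]
#'   (required for promoter/both modes).
#' @param mode `"both"`, `"promoter"`, or `"ccre"`.
#' @param reference Reference state id (default: the registry's quiescent
#'   state).
#' @param cell_types Cell types to include as observations.
#' @param ccre_prop_list Optional override of the per-cCRE proportion
#'   matrices (used internally for the single-state representation).
#' @return An object of class `erp_design`: list with `X`, `obs` (tibble
#'   `gene_id`, `cell_type`, `y`, `category`, `n_pairs`), `mode`,
#'   `n_states`, `reference`.
#' @export
build_design <- function(pairs, registry, expression, genes,
                         promoter_props = NULL,
                         mode = c("both", "promoter", "ccre"),
                         reference = registry$quiescent,
                         cell_types = registry$cell_types,
                         ccre_prop_list = registry$proportions) {
  mode <- match.arg(mode)
  lg <- expression_log2(expression)
  gene_ids <- genes$gene_id
  lg <- lg[gene_ids, cell_types, drop = FALSE]
  if (mode %in% c("promoter", "both") && is.null(promoter_props)) {
    abort("promoter_props required in promoter/both mode")
  }
  n_states <- registry$n_states
  ref_col <- reference + 1
  state_cols <- setdiff(seq_len(n_states), ref_col)

  pooled <- NULL
  n_per <- NULL
  if (mode %in% c("ccre", "both")) {
    pooled <- pooled_gene_props(pairs, registry, gene_ids,
      prop_list = ccre_prop_list, cell_types = cell_types
    )
    sel <- pairs[pairs$selected, , drop = FALSE]
    n_per <- tabulate(match(sel$gene_id, gene_ids), nbins = length(gene_ids))
    if (any(n_per == 0)) {
      inform(paste(
        sum(n_per == 0),
        "gene(s) have no selected cCREs; their pooled predictor is all-zero"
      ))
    }
  }

  blocks <- lapply(cell_types, function(ct) {
    xs <- NULL
    if (mode %in% c("promoter", "both")) {
      pm <- promoter_props[[ct]][gene_ids, state_cols, drop = FALSE]
      colnames(pm) <- paste0("prom_s", state_cols - 1)
      xs <- pm
    }
    if (mode %in% c("ccre", "both")) {
      cm <- pooled[[ct]][, state_cols, drop = FALSE]
      colnames(cm) <- paste0("ccre_s", state_cols - 1)
      xs <- if (is.null(xs)) cm else cbind(xs, cm)
    }
    xs
  })
  X <- do.call(rbind, blocks)
  obs <- tibble(
    gene_id = rep(gene_ids, times = length(cell_types)),
    cell_type = rep(cell_types, each = length(gene_ids)),
    y = as.numeric(lg),
    category = if ("category" %in% names(genes)) {
      rep(genes$category, times = length(cell_types))
    } else {
      rep("all", length(gene_ids) * length(cell_types))
    },
    n_pairs = if (is.null(n_per)) {
      NA_integer_
    } else {
      rep(as.integer(n_per), times = length(cell_types))
    }
  )
  structure(
    list(
      X = X, obs = obs, mode = mode, n_states = n_states,
      reference = reference
    ),
    class = "erp_design"
  )
}

#' @export
print.erp_design <- function(x, ...) {
  cat(
    "<erp_design>", nrow(x$X), "observations x", ncol(x$X),
    "predictors; mode:", x$mode, "; reference state:", x$reference, "\n"
  )
  invisible(x)
}
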