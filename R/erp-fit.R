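# Fitting and evaluating the eRP regression: OLS with a reference-state
# constraint, eRP scores, the mean-of-eRP prediction rule, the candidate
# correlation screen, iterative subselection, leave-one-out evaluation,
# and pair export.

row_cor <- function(a, b) {
  a <- a - rowMeans(a)
  b <- b - rowMeans(b)
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a^2) * rowSums(b^2))
  ifelse(den > 0, num / den, NA_real_)
}

#' Fit the eRP linear model
#'
#' Ordinary least squares of log2(TPM + 1) on the design's state-
#' proportion blocks, with an intercept. The reference state's
#' coefficient is 0 by column omission. Rank-deficient designs are fitted
#' by pseudoinverse with a warning listing the aliased columns (fitted
#' values are unaffected).
#'
#' @param design An `erp_design` from [build_design()].
#' @param category Gene category to restrict the observations to, or
#'   `"all"`.
#' @return An object of class `erp_model` with per-state coefficient
#'   vectors `beta_promoter` and `beta_ccre` (length `n_states`, reference
#'   entry 0), `intercept`, and fit diagnostics.
#' @export
fit_erp <- function(design, category = "all") {
  rows <- if (identical(category, "all")) {
    rep(TRUE, nrow(design$X))
  } else {
    design$obs$category == category
  }
  x <- design$X[rows, , drop = FALSE]
  y <- design$obs$y[rows]
  if (length(y) == 0) abort("no observations for this category")
  xi <- cbind("(Intercept)" = 1, x)
  qx <- qr(xi)
  aliased <- character(0)
  if (qx$rank < ncol(xi)) {
    aliased <- colnames(xi)[qx$pivot[seq(qx$rank + 1, ncol(xi))]]
    warn(paste(
      "rank-deficient design; aliased columns fitted by pseudoinverse:",
      paste(aliased, collapse = ", ")
    ))
    coef <- drop(pseudoinverse(xi) %*% y)
    names(coef) <- colnames(xi)
  } else {
    coef <- qr.coef(qx, y)
  }
  fitted <- drop(xi %*% coef)
  resid <- y - fitted
  n_states <- design$n_states
  beta_promoter <- rep(0, n_states)
  beta_ccre <- rep(0, n_states)
  # accumulate so duplicated (aliased) columns sum to one effective
  # coefficient and fitted values are preserved
  for (k in seq_along(coef)[-1]) {
    nm <- names(coef)[k]
    s <- as.integer(sub("^(prom|ccre)_s", "", nm)) + 1
    if (startsWith(nm, "prom_s")) beta_promoter[s] <- beta_promoter[s] + coef[k]
    if (startsWith(nm, "ccre_s")) beta_ccre[s] <- beta_ccre[s] + coef[k]
  }
  ss_tot <- sum((y - mean(y))^2)
  structure(
    list(
      intercept = unname(coef[1]),
      beta_promoter = beta_promoter,
      beta_ccre = beta_ccre,
      mode = design$mode,
      category = category,
      reference = design$reference,
      n = length(y),
      p = ncol(x),
      mse = mean(resid^2),
      r_squared = if (ss_tot > 0) 1 - sum(resid^2) / ss_tot else NA_real_,
      aliased = aliased
    ),
    class = "erp_model"
  )
}

#' @export
print.erp_model <- function(x, ...) {
  cat(
    "<erp_model> mode:", x$mode, "; category:", x$category,
    "; n =", x$n, ", p =", x$p, "\n",
    "intercept:", signif(x$intercept, 4),
    "; training MSE:", signif(x$mse, 4),
    "; r^2:", signif(x$r_squared, 4), "\n"
  )
  invisible(x)
}

#' Tidy an eRP model into per-state coefficients
#' @param x An `erp_model`.
#' @param ... Unused.
#' @return Tibble with `state`, `context` ("promoter"/"ccre"),
#'   `estimate`, and `reference` flag.
#' @export
tidy.erp_model <- function(x, ...) {
  n_states <- length(x$beta_ccre)
  out <- tibble(
    state = rep(seq_len(n_states) - 1L, 2),
    context = rep(c("promoter", "ccre"), each = n_states),
    estimate = c(x$beta_promoter, x$beta_ccre),
    reference = rep(seq_len(n_states) - 1L, 2) == x$reference
  )
  if (x$mode == "promoter") out <- filter(out, .data$context == "promoter")
  if (x$mode == "ccre") out <- filter(out, .data$context == "ccre")
  out
}

#' @export
glance.erp_model <- function(x, ...) {
  tibble(
    mode = x$mode, category = x$category, n = x$n, p = x$p,
    mse = x$mse, r.squared = x$r_squared,
    n_aliased = length(x$aliased)
  )
}

#' Epigenetic regulatory potential (eRP) scores
#'
#' The eRP of a cCRE in a cell type is the sum of the fitted cCRE-context
#' state coefficients weighted by the cCRE's state proportions; the
#' reference state contributes 0.
#'
#' @param registry A `ccre_registry`.
#' @param model An `erp_model`.
#' @param cell_types Cell types to score (default: all in the registry).
#' @return Tibble `ccre_id` + one eRP column per cell type.
#' @export
erp_scores <- function(registry, model, cell_types = registry$cell_types) {
  m <- vapply(
    cell_types,
    function(ct) drop(registry$proportions[[ct]] %*% model$beta_ccre),
    numeric(nrow(registry$ccres))
  )
  m <- matrix(m,
    nrow = nrow(registry$ccres),
    dimnames = list(NULL, cell_types)
  )
  bind_cols(tibble(ccre_id = registry$ccres$ccre_id), as_tibble(m))
}

# Pair-level eRP matrix (pairs x cell types) under a given proportion
# representation.
pair_erp_matrix <- function(pairs, registry, model,
                            prop_list = registry$proportions,
                            cell_types = registry$cell_types) {
  ci <- match(pairs$ccre_id, registry$ccres$ccre_id)
  m <- vapply(
    cell_types,
    function(ct) drop(prop_list[[ct]][ci, , drop = FALSE] %*% model$beta_ccre),
    numeric(nrow(pairs))
  )
  matrix(m, nrow = nrow(pairs), dimnames = list(NULL, cell_types))
}

#' Predict expression from a fitted eRP model
#'
#' In cCRE mode the prediction is the intercept plus the mean of the eRP
#' scores over the gene's selected cCREs (the mean-of-eRP rule), which is
#' algebraically identical to the pooled-design prediction because pooling
#' is an unweighted mean of proportion vectors. Promoter mode adds the
#' promoter term instead; both mode adds both. Genes with no selected
#' cCREs are predicted from the intercept (plus the promoter term in both
#' mode) and flagged.
#'
#' @param pairs Pair tibble (`selected` column respected).
#' @param model An `erp_model`.
#' @param registry A `ccre_registry`.
#' @param genes Gene tibble.
#' @param promoter_props Promoter proportions (promoter/both modes).
#' @param mode Prediction mode; defaults to the model's mode.
#' @param cell_types Cell types to predict for.
#' @return Tibble `gene_id`, `cell_type`, `predicted`, `n_pairs`.
#' @export
predict_expression <- function(pairs, model, registry, genes,
                               promoter_props = NULL,
                               mode = model$mode,
                               cell_types = registry$cell_types) {
  gene_ids <- genes$gene_id
  pred <- matrix(model$intercept, length(gene_ids), length(cell_types),
    dimnames = list(gene_ids, cell_types)
  )
  n_per <- rep(NA_integer_, length(gene_ids))
  if (mode %in% c("promoter", "both")) {
    if (is.null(promoter_props)) abort("promoter_props required")
    for (ct in cell_types) {
      pred[, ct] <- pred[, ct] +
        drop(promoter_props[[ct]][gene_ids, , drop = FALSE] %*% model$beta_promoter)
    }
  }
  if (mode %in% c("ccre", "both")) {
    sel <- pairs[pairs$selected, , drop = FALSE]
    gi <- match(sel$gene_id, gene_ids)
    n_per <- tabulate(gi, nbins = length(gene_ids))
    if (nrow(sel) > 0) {
      e <- pair_erp_matrix(sel, registry, model, cell_types = cell_types)
      acc <- rowsum(e, group = gi)
      rows <- as.integer(rownames(acc))
      pred[rows, ] <- pred[rows, , drop = FALSE] + acc / n_per[rows]
    }
  }
  tibble(
    gene_id = rep(gene_ids, times = length(cell_types)),
    cell_type = rep(cell_types, each = length(gene_ids)),
    predicted = as.numeric(pred),
    n_pairs = rep(as.integer(n_per), times = length(cell_types))
  )
}

#' Correlation screen for candidate pairs
#'
#' Sets each pair's `screen_correlation` to the Pearson correlation,
#' across cell types, between a per-cell-type activity proxy for the cCRE
#' and the gene's log2(TPM + 1). The proxy is the cCRE's eRP under
#' `model` when one is supplied (an initial fit on all pairs), otherwise
#' the cCRE's non-quiescent proportion. Pairs pass the screen when
#' |r| >= `min_abs_r`; pairs with undefined correlation (constant proxy
#' or constant expression) are deselected.
#'
#' @param pairs Pair tibble.
#' @param expression Expression tibble (TPM).
#' @param registry A `ccre_registry`.
#' @param model Optional `erp_model` providing the eRP proxy.
#' @param min_abs_r Minimum |r| to keep a pair (default 0.1; the screen is
#'   a coarse sensitivity-preserving filter, the subselection does the
#'   pruning).
#' @param cell_types Cell types used for the correlation (>= 3).
#' @return The pair tibble with `screen_correlation` and `selected`
#'   updated.
#' @export
correlation_filter <- function(pairs, expression, registry, model = NULL,
                               min_abs_r = 0.1,
                               cell_types = registry$cell_types) {
  if (length(cell_types) < 3) abort("need >= 3 cell types to screen")
  lg <- expression_log2(expression)
  ci <- match(pairs$ccre_id, registry$ccres$ccre_id)
  if (is.null(model)) {
    proxy <- vapply(
      cell_types,
      function(ct) 1 - registry$proportions[[ct]][ci, registry$quiescent + 1],
      numeric(nrow(pairs))
    )
    proxy <- matrix(proxy, nrow = nrow(pairs))
  } else {
    proxy <- pair_erp_matrix(pairs, registry, model, cell_types = cell_types)
  }
  ym <- lg[pairs$gene_id, cell_types, drop = FALSE]
  r <- row_cor(proxy, ym)
  n_undef <- sum(is.na(r))
  if (n_undef > 0) {
    inform(paste(n_undef, "pair(s) with undefined screen correlation deselected"))
  }
  pairs$screen_correlation <- r
  pairs$selected <- !is.na(r) & abs(r) >= min_abs_r
  pairs
}

#' Iterative subselection of contributing pairs
#'
#' Refines the screened pair set by iterating: (a) represent each cCRE in
#' each cell type by its majority state only (one-hot proportions); (b)
#' fit the model; (c) score each pair by the absolute correlation, across
#' cell types, between its eRP trajectory and the gene's partial residual
#' with respect to the cCRE block (the residual plus the pooled eRP term
#' added back, so each pair is judged against the expression signal the
#' cCRE pool is responsible for); (d) per gene, deselect pairs scoring
#' below `min_contribution`, lowest first, at most a `drop_fraction` of
#' the gene's current pairs per iteration. Stops when no pair is dropped
#' or after `max_iter` iterations, then refits on the survivors with full
#' proportion vectors. Deterministic given its inputs; pairs are never
#' re-added.
#'
#' @param pairs Screened pair tibble (only `selected` pairs participate).
#' @param expression Expression tibble (TPM).
#' @param registry A `ccre_registry`.
#' @param genes Gene tibble.
#' @param promoter_props Promoter proportions (for `mode = "both"`).
#' @param mode `"ccre"` or `"both"`.
#' @param max_iter,drop_fraction,min_contribution Subselection schedule
#'   (defaults 20, 0.15, 0.55).
#' @param cell_types Cell types used for fitting and scoring.
#' @return List with `pairs` (tibble, `selected` and `contribution`
#'   updated), `model` (final fit on full proportions), and `n_iter`.
#' @export
subselect <- function(pairs, expression, registry, genes,
                      promoter_props = NULL, mode = c("ccre", "both"),
                      max_iter = 20, drop_fraction = 0.15,
                      min_contribution = 0.55,
                      cell_types = registry$cell_types) {
  mode <- match.arg(mode)
  onehot <- onehot_proportions(registry)
  pairs$contribution <- NA_real_
  n_iter <- 0
  lg <- expression_log2(expression)[genes$gene_id, cell_types, drop = FALSE]
  repeat {
    n_iter <- n_iter + 1
    design <- build_design(pairs, registry, expression, genes,
      promoter_props = promoter_props, mode = mode,
      cell_types = cell_types, ccre_prop_list = onehot
    )
    model <- fit_erp(design)
    sel_idx <- which(pairs$selected)
    if (length(sel_idx) == 0) break
    sel <- pairs[sel_idx, , drop = FALSE]
    e <- pair_erp_matrix(sel, registry, model,
      prop_list = onehot, cell_types = cell_types
    )
    pred <- predict_expression_from_design(design, model, genes, cell_types)
    resid <- lg - pred
    gi <- match(sel$gene_id, genes$gene_id)
    n_per <- tabulate(gi, nbins = nrow(genes))
    pool_sum <- rowsum(e, group = gi)
    pool_mean <- pool_sum[match(gi, sort(unique(gi))), , drop = FALSE] /
      n_per[gi]
    score <- abs(row_cor(e, resid[gi, , drop = FALSE] + pool_mean))
    score[is.na(score)] <- 0
    pairs$contribution[sel_idx] <- score
    # per-gene drop set: below threshold, lowest first, bounded per iter
    drop_idx <- integer(0)
    low <- which(score < min_contribution)
    if (length(low) > 0) {
      by_gene <- split(low, gi[low])
      for (g in names(by_gene)) {
        cand <- by_gene[[g]]
        cand <- cand[order(score[cand])]
        k <- min(length(cand), ceiling(drop_fraction * n_per[as.integer(g)]))
        drop_idx <- c(drop_idx, cand[seq_len(k)])
      }
    }
    if (length(drop_idx) == 0 || n_iter >= max_iter) break
    pairs$selected[sel_idx[drop_idx]] <- FALSE
  }
  final_design <- build_design(pairs, registry, expression, genes,
    promoter_props = promoter_props, mode = mode, cell_types = cell_types
  )
  list(pairs = pairs, model = fit_erp(final_design), n_iter = n_iter)
}

# Prediction matrix (genes x cell types) straight from a design and model;
# used internally where the design is already built.
predict_expression_from_design <- function(design, model, genes, cell_types) {
  xi <- cbind(1, design$X)
  coef <- c(model$intercept, vapply(colnames(design$X), function(nm) {
    s <- as.integer(sub("^(prom|ccre)_s", "", nm)) + 1
    if (startsWith(nm, "prom_s")) model$beta_promoter[s] else model$beta_ccre[s]
  }, numeric(1)))
  matrix(drop(xi %*% coef),
    nrow = nrow(genes),
    dimnames = list(genes$gene_id, cell_types)
  )
}

adjusted_r2 <- function(observed, predicted, p) {
  n <- length(observed)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0 || n <= p + 1) {
    return(tibble(n = n, r_squared = NA_real_, adj_r_squared = NA_real_))
  }
  r2 <- 1 - sum((observed - predicted)^2) / ss_tot
  tibble(
    n = n, r_squared = r2,
    adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - p - 1)
  )
}

#' Leave-one-out cross-cell-type evaluation
#'
#' For each cell type: fit on the remaining cell types (optionally after
#' the correlation screen and subselection, re-run within the training
#' set), predict expression in the left-out cell type, and report
#' adjusted r-squared with n = genes evaluated and p = fitted coefficients
#' excluding the intercept. With `by_category = TRUE`, fitting and
#' evaluation are additionally restricted to each gene category.
#'
#' @param expression Expression tibble (TPM).
#' @param registry A `ccre_registry`.
#' @param genes Gene tibble (with `category` column if `by_category`).
#' @param pairs Candidate pair tibble.
#' @param promoter_props Promoter proportions.
#' @param mode `"both"`, `"promoter"`, or `"ccre"`.
#' @param by_category Also evaluate per gene category.
#' @param screen Re-run the correlation screen inside each training fold.
#' @param run_subselect Re-run subselection inside each training fold.
#' @param min_abs_r Screen threshold.
#' @param subselect_control List of subselection knobs
#'   (`max_iter`, `drop_fraction`, `min_contribution`).
#' @param cell_types Cell types to evaluate over (>= 3).
#' @return Tibble: `left_out`, `mode`, `category`, `n`, `p`,
#'   `r_squared`, `adj_r_squared`.
#' @export
loo_evaluate <- function(expression, registry, genes, pairs,
                         promoter_props = NULL,
                         mode = c("both", "promoter", "ccre"),
                         by_category = FALSE, screen = FALSE,
                         run_subselect = FALSE, min_abs_r = 0.2,
                         subselect_control = list(),
                         cell_types = registry$cell_types) {
  mode <- match.arg(mode)
  if (length(cell_types) < 3) abort("need >= 3 cell types")
  lg <- expression_log2(expression)
  categories <- "all"
  if (by_category) {
    if (!"category" %in% names(genes)) {
      abort("by_category requires a category column in genes")
    }
    categories <- c("all", sort(unique(genes$category)))
  }
  out <- list()
  for (t in cell_types) {
    train <- setdiff(cell_types, t)
    pr <- pairs
    if (screen && mode != "promoter") {
      model0 <- fit_erp(build_design(pr, registry, expression, genes,
        promoter_props = promoter_props, mode = mode, cell_types = train
      ))
      pr <- correlation_filter(pr, expression, registry,
        model = model0, min_abs_r = min_abs_r, cell_types = train
      )
    }
    model_final <- NULL
    if (run_subselect && mode != "promoter") {
      args <- c(
        list(
          pairs = pr, expression = expression, registry = registry,
          genes = genes, promoter_props = promoter_props, mode = mode,
          cell_types = train
        ),
        subselect_control
      )
      ss <- do.call(subselect, args)
      pr <- ss$pairs
    }
    for (cat in categories) {
      g_idx <- if (cat == "all") {
        rep(TRUE, nrow(genes))
      } else {
        genes$category == cat
      }
      g_sub <- genes[g_idx, , drop = FALSE]
      if (nrow(g_sub) == 0) next
      design <- build_design(
        pr[pr$gene_id %in% g_sub$gene_id, , drop = FALSE],
        registry, expression, g_sub,
        promoter_props = promoter_props, mode = mode, cell_types = train
      )
      model <- fit_erp(design)
      pred <- predict_expression(
        pr[pr$gene_id %in% g_sub$gene_id, , drop = FALSE],
        model, registry, g_sub,
        promoter_props = promoter_props, mode = mode, cell_types = t
      )
      obs <- lg[g_sub$gene_id, t]
      stats_row <- adjusted_r2(obs, pred$predicted, model$p)
      out[[length(out) + 1]] <- bind_cols(
        tibble(left_out = t, mode = mode, category = cat, p = model$p),
        stats_row
      )
    }
  }
  bind_rows(out) %>%
    select("left_out", "mode", "category", "n", "p", "r_squared", "adj_r_squared")
}

#' Export thresholded cCRE-gene pairs
#'
#' Keeps selected pairs whose |eRP| reaches `erp_threshold` in at least
#' one cell type, with per-cell-type eRP columns. When TAD intervals are
#' supplied, `same_tad` marks pairs whose cCRE midpoint and gene TSS fall
#' in one common TAD interval; `within_tad_only = TRUE` filters to those.
#'
#' @param pairs Pair tibble.
#' @param registry A `ccre_registry`.
#' @param model An `erp_model`.
#' @param genes Gene tibble.
#' @param erp_threshold Minimum |eRP| (default 0: all scored pairs).
#' @param tads Optional TAD interval tibble (`chrom`, `start`, `end`).
#' @param within_tad_only Keep only same-TAD pairs.
#' @param cell_types Cell types to score.
#' @return Tibble: pair columns, `same_tad` (if TADs given), and one
#'   `erp_<cell type>` column per cell type.
#' @export
export_pairs <- function(pairs, registry, model, genes, erp_threshold = 0,
                         tads = NULL, within_tad_only = FALSE,
                         cell_types = registry$cell_types) {
  sel <- pairs[pairs$selected, , drop = FALSE]
  e <- pair_erp_matrix(sel, registry, model, cell_types = cell_types)
  keep <- if (nrow(sel) > 0) {
    apply(abs(e), 1, max) >= erp_threshold
  } else {
    logical(0)
  }
  sel <- sel[keep, , drop = FALSE]
  e <- e[keep, , drop = FALSE]
  colnames(e) <- paste0("erp_", cell_types)
  out <- bind_cols(sel, as_tibble(e))
  if (!is.null(tads)) {
    if (!all(c("chrom", "start", "end") %in% names(tads)) ||
      (nrow(tads) > 0 && any(tads$start >= tads$end))) {
      abort("malformed TAD intervals")
    }
    ci <- match(out$ccre_id, registry$ccres$ccre_id)
    mid <- floor((registry$ccres$start[ci] + registry$ccres$end[ci]) / 2)
    gi <- match(out$gene_id, genes$gene_id)
    out$same_tad <- points_share_interval(
      registry$ccres$chrom[ci], mid,
      genes$chrom[gi], genes$tss[gi], tads
    )
    if (within_tad_only) out <- filter(out, .data$same_tad)
  }
  out
}

# TRUE where point A and point B fall inside one common interval.
points_share_interval <- function(chrom_a, pos_a, chrom_b, pos_b, intervals) {
  n <- length(pos_a)
  res <- logical(n)
  if (nrow(intervals) == 0 || n == 0) {
    return(res)
  }
  gt <- as_granges(intervals)
  pa <- GenomicRanges::GRanges(chrom_a, IRanges::IRanges(pos_a + 1, pos_a + 1))
  pb <- GenomicRanges::GRanges(chrom_b, IRanges::IRanges(pos_b + 1, pos_b + 1))
  ova <- GenomicRanges::findOverlaps(pa, gt)
  ovb <- GenomicRanges::findOverlaps(pb, gt)
  key_a <- paste(S4Vectors::queryHits(ova), S4Vectors::subjectHits(ova))
  key_b <- paste(S4Vectors::queryHits(ovb), S4Vectors::subjectHits(ovb))
  shared <- intersect(key_a, key_b)
  idx <- as.integer(sub(" .*", "", shared))
  res[idx] <- TRUE
  res
}
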