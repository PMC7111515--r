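# Cross-cell-type comparative analytics: correlation matrices,
# hierarchical clustering on correlation distance, PCA with variance
# explained, quantile normalization, expressed-gene counts, and the
# expressed-genes vs dynamic-cCREs association.

# Accept either a numeric matrix or a data frame whose first column is a
# character id; returns a numeric matrix with column (sample) names.
as_signal_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else {
    df <- as.data.frame(x)
    id_col <- !vapply(df, is.numeric, logical(1))
    m <- as.matrix(df[, !id_col, drop = FALSE])
    if (any(id_col)) rownames(m) <- as.character(df[[which(id_col)[1]]])
  }
  if (anyNA(m)) {
    warn("missing values in signal matrix set to 0")
    m[is.na(m)] <- 0
  }
  if (anyDuplicated(colnames(m))) abort("sample (column) labels must be unique")
  m
}

#' Sample-by-sample correlation matrix
#'
#' @param x Numeric matrix (rows = genomic units, columns = samples) or a
#'   data frame with an id column first.
#' @param method `"pearson"` or `"spearman"` (ranks with average ties).
#' @return Symmetric samples x samples correlation matrix with unit
#'   diagonal; correlations involving constant columns are `NA` (logged).
#' @export
correlation_matrix <- function(x, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- as_signal_matrix(x)
  if (nrow(m) < 2) abort("need >= 2 rows to correlate")
  const <- apply(m, 2, function(v) sd(v) == 0)
  r <- suppressWarnings(cor(m, method = method))
  if (any(const)) {
    warn(paste(
      "constant columns have undefined correlations:",
      paste(colnames(m)[const], collapse = ", ")
    ))
    r[const, ] <- NA
    r[, const] <- NA
  }
  diag(r)[!const] <- 1
  r
}

#' Hierarchical clustering on correlation distance
#'
#' Agglomerative clustering with `1 - r` as the distance, as used for
#' cell-type similarity heatmaps.
#'
#' @param corr A correlation matrix (e.g. from [correlation_matrix()]).
#' @param linkage `"average"` (UPGMA, default), `"complete"`, or
#'   `"single"`.
#' @return An object of class `corr_clustering`: list with the `hclust`
#'   object (`$hclust`), `method`, `leaf_order`, and cophenetic distances.
#' @export
hierarchical_cluster <- function(corr, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (anyNA(corr)) {
    bad <- colnames(corr)[apply(corr, 2, anyNA)]
    abort(paste(
      "undefined correlation distances for:", paste(bad, collapse = ", ")
    ))
  }
  d <- stats::as.dist(1 - corr)
  hc <- stats::hclust(d, method = linkage)
  structure(
    list(
      hclust = hc,
      linkage = linkage,
      leaf_order = hc$labels[hc$order],
      cophenetic = stats::cophenetic(hc)
    ),
    class = "corr_clustering"
  )
}

#' @export
print.corr_clustering <- function(x, ...) {
  cat(
    "<corr_clustering>", length(x$leaf_order), "samples,",
    x$linkage, "linkage on 1 - r\n"
  )
  invisible(x)
}

#' Cut a correlation clustering into k groups
#' @param clustering A `corr_clustering`.
#' @param k Number of groups.
#' @return Named integer vector of group labels.
#' @export
cut_clusters <- function(clustering, k = 2) {
  stats::cutree(clustering$hclust, k = k)
}

#' PCA of a signal matrix with variance explained
#'
#' Samples (columns of `x`) are the observations; each genomic unit is
#' centered across samples before the decomposition (no scaling by
#' default).
#'
#' @param x Matrix or data frame as in [correlation_matrix()].
#' @param scale Scale units to unit variance as well (default FALSE).
#' @return List with `scores` (tibble: sample, PC coordinates),
#'   `variance_fraction` (numeric, sums to 1), and the `prcomp` object.
#' @export
pca_variance <- function(x, scale = FALSE) {
  m <- as_signal_matrix(x)
  if (ncol(m) < 2) abort("need >= 2 samples for PCA")
  keep <- apply(m, 1, function(v) sd(v) > 0) | !scale
  p <- prcomp(t(m[keep, , drop = FALSE]), center = TRUE, scale. = scale)
  vf <- p$sdev^2 / sum(p$sdev^2)
  scores <- bind_cols(
    tibble(sample = colnames(m)),
    as_tibble(p$x)
  )
  list(scores = scores, variance_fraction = vf, prcomp = p)
}

#' Quantile normalization
#'
#' Makes every column share one distribution: each column's sorted values
#' are replaced by the cross-column mean of sorted values; ties receive
#' the mean of their target quantiles. Idempotent.
#'
#' @param x Matrix or data frame as in [correlation_matrix()].
#' @return Same shape as the input (data frames keep their id column).
#' @export
quantile_normalize <- function(x) {
  m <- as_signal_matrix(x)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  if (!is.matrix(x)) {
    df <- as.data.frame(x)
    id_col <- which(!vapply(df, is.numeric, logical(1)))[1]
    res <- as_tibble(out)
    if (!is.na(id_col)) {
      res <- bind_cols(df[, id_col, drop = FALSE], res)
    }
    return(as_tibble(res))
  }
  out
}

#' Expressed-gene counts at TPM thresholds
#'
#' Counts genes with TPM strictly above each threshold, per cell type.
#'
#' @param expression Expression tibble (`gene_id` + one TPM column per
#'   cell type).
#' @param thresholds Numeric thresholds (default 1, 5, 10).
#' @return Tibble with `cell_type`, `threshold`, `n_expressed`.
#' @export
expressed_gene_counts <- function(expression, thresholds = c(1, 5, 10)) {
  m <- as_signal_matrix(expression)
  if (any(m < 0)) abort("negative TPM values")
  out <- lapply(thresholds, function(tau) {
    tibble(
      cell_type = colnames(m),
      threshold = tau,
      n_expressed = as.integer(colSums(m > tau))
    )
  })
  bind_rows(out)
}

#' Association between expressed-gene and dynamic-cCRE counts
#'
#' Pearson correlation and least-squares line between the per-cell-type
#' number of expressed genes and the number of dynamic cCREs, with an
#' optional exclusion list applied before fitting (as done for outlying
#' immortalized cell lines).
#'
#' @param expressed Tibble with `cell_type` and `n_expressed` (one
#'   threshold).
#' @param dynamic Tibble with `cell_type` and `n` (from
#'   [dynamic_ccre_counts()]).
#' @param exclude Character cell types to drop before fitting.
#' @return Tibble with `r`, `slope`, `intercept`, `n`, `excluded`.
#' @export
expression_ccre_association <- function(expressed, dynamic, exclude = NULL) {
  df <- left_join(
    rename(expressed, n_genes = "n_expressed"),
    rename(dynamic, n_ccres = "n"),
    by = "cell_type"
  )
  if (!is.null(exclude)) {
    missing_ex <- setdiff(exclude, df$cell_type)
    if (length(missing_ex) > 0) {
      warn(paste(
        "excluded cell types not present:", paste(missing_ex, collapse = ", ")
      ))
    }
    df <- filter(df, !(.data$cell_type %in% exclude))
  }
  df <- filter(df, !is.na(.data$n_genes) & !is.na(.data$n_ccres))
  if (nrow(df) < 3) abort("need >= 3 paired cell types")
  fit <- stats::lm(n_genes ~ n_ccres, data = df)
  tibble(
    r = cor(df$n_ccres, df$n_genes),
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    n = nrow(df),
    excluded = paste(exclude %||% character(0), collapse = ",")
  )
}
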