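# One mid-sized noiseless fixture shared across the eRP tests (built once;
# everything downstream is deterministic).
erp_fixture <- local({
  cfg <- sim_config(
    n_cell_types = 6, n_states = 8, chrom_lengths = c(chr1 = 2e6, chr2 = 1e6),
    accessible_states = c(2L, 4L, 6L), n_genes = 120,
    expression_noise_sd = 0, peak_dropout = 0, peak_jitter_bins = 0,
    seed = 19
  )
  truth <- simulate_dataset(cfg)
  repro <- lapply(truth$peaks, reproducible_peaks)
  registry <- build_registry(repro, truth$state_maps, 0L, cfg$n_states)
  genes <- truth$genes
  pp <- promoter_state_proportions(
    genes, truth$state_maps, cfg$n_states,
    window = cfg$promoter_window
  )
  pairs <- true_link_pairs(truth, registry) |>
    dplyr::mutate(distance = NA_real_, selected = TRUE, screen_correlation = NA_real_)
  list(
    cfg = cfg, truth = truth, registry = registry, genes = genes,
    promoter_props = pp, pairs = pairs
  )
})

test_that("gene categories follow the expression-breadth rules", {
  expr <- tibble::tibble(
    gene_id = c("zero", "high", "diffhigh", "some"),
    c1 = c(0, 100, 2, 0), c2 = c(0, 110, 100, 5), c3 = c(0.5, 90, 50, 8)
  )
  cats <- categorize_genes(expr)
  expect_equal(cats$category[cats$gene_id == "zero"], "consistently_low")
  expect_equal(cats$category[cats$gene_id == "high"], "consistently_high")
  expect_equal(cats$category[cats$gene_id == "diffhigh"], "differentially_high")
  expect_equal(cats$category[cats$gene_id == "some"], "differentially_low")

  # random matrix vs direct rule application
  set.seed(81)
  m <- matrix(rexp(90, 1 / 3), 30, 3)
  expr2 <- tibble::as_tibble(m) |>
    rlang::set_names(c("c1", "c2", "c3")) |>
    dplyr::mutate(gene_id = paste0("g", 1:30), .before = 1)
  got <- categorize_genes(expr2, low_threshold = 1, variability_threshold = 1)
  lg <- log2(m + 1)
  for (i in 1:30) {
    nexp <- sum(m[i, ] > 1)
    spread <- max(lg[i, ]) - min(lg[i, ])
    oracle <- if (nexp == 0) {
      "consistently_low"
    } else if (nexp == 3 && spread < 1) {
      "consistently_high"
    } else if (nexp == 3) {
      "differentially_high"
    } else {
      "differentially_low"
    }
    expect_equal(got$category[i], oracle)
  }
})

test_that("candidate assignment respects the 1 Mb inclusive boundary", {
  seg <- tibble::tibble(chrom = "c", start = 0, end = 4e6, state = 1L)
  mk_reg <- function(starts) {
    peaks <- list(ct1 = tibble::tibble(
      chrom = "c", start = starts, end = starts + 200
    ))
    build_registry(peaks, list(ct1 = seg), 0L, 2)
  }
  # cCRE midpoint exactly 1,000,000 bases away -> included
  reg <- mk_reg(c(2e6 + 1e6 - 100, 2e6 + 1e6 + 100, 2e6 - 5e5))
  genes <- tibble::tibble(gene_id = "g1", chrom = "c", tss = 2e6)
  pairs <- assign_candidates(genes, reg, max_distance = 1e6)
  mids <- floor((reg$ccres$start + reg$ccres$end) / 2)
  expect_setequal(
    pairs$ccre_id,
    reg$ccres$ccre_id[abs(mids - 2e6) <= 1e6]
  )
  expect_true(any(pairs$distance == 1e6))

  # different chromosome -> excluded
  genes2 <- tibble::tibble(gene_id = "g2", chrom = "other", tss = 2e6)
  expect_equal(nrow(assign_candidates(genes2, reg)), 0)

  # promoter-overlapping cCREs are excluded from the distal set
  reg2 <- mk_reg(c(2e6 - 100, 2e6 + 5e4))
  pairs2 <- assign_candidates(genes, reg2, promoter_window = 1000)
  expect_equal(nrow(pairs2), 1)
  expect_equal(pairs2$distance, 5e4 + 100 - 2e6 + 2e6) # mid - tss
})

test_that("candidate assignment equals an all-pairs distance scan", {
  fx <- erp_fixture
  pairs <- assign_candidates(fx$genes, fx$registry,
    max_distance = 3e5, promoter_window = fx$cfg$promoter_window
  )
  cc <- fx$registry$ccres
  mids <- floor((cc$start + cc$end) / 2)
  w <- fx$cfg$promoter_window
  oracle <- list()
  for (g in seq_len(nrow(fx$genes))) {
    for (k in seq_len(nrow(cc))) {
      same <- cc$chrom[k] == fx$genes$chrom[g]
      near <- abs(mids[k] - fx$genes$tss[g]) <= 3e5
      distal <- !(cc$end[k] > fx$genes$tss[g] - w &
        cc$start[k] < fx$genes$tss[g] + w)
      if (same && near && distal) {
        oracle[[length(oracle) + 1]] <- paste(
          fx$genes$gene_id[g], cc$ccre_id[k]
        )
      }
    }
  }
  expect_setequal(paste(pairs$gene_id, pairs$ccre_id), unlist(oracle))
})

test_that("pooled predictors average the per-cCRE proportion vectors", {
  fx <- erp_fixture
  reg <- fx$registry
  g <- fx$genes$gene_id[which(!fx$genes$zero_links)[1]]
  pr <- fx$pairs[fx$pairs$gene_id == g, ]
  pooled <- ccreg:::pooled_gene_props(pr, reg, g)
  ci <- match(pr$ccre_id, reg$ccres$ccre_id)
  for (ct in fx$cfg$cell_types) {
    manual <- colMeans(reg$proportions[[ct]][ci, , drop = FALSE])
    expect_lt(max(abs(pooled[[ct]][1, ] - manual)), 1e-12)
  }
})

test_that("noiseless synthetic data recovers the true coefficients", {
  fx <- erp_fixture
  design <- build_design(fx$pairs, fx$registry, fx$truth$expression,
    fx$genes,
    promoter_props = fx$promoter_props, mode = "both"
  )
  fit <- fit_erp(design)
  expect_lt(max(abs(fit$beta_promoter - fx$cfg$beta_promoter_truth)), 1e-6)
  expect_lt(max(abs(fit$beta_ccre - fx$cfg$beta_ccre_truth)), 1e-6)
  expect_lt(abs(fit$intercept - fx$cfg$expression_intercept), 1e-6)
  expect_equal(fit$beta_promoter[1], 0) # reference state constraint
  expect_equal(fit$beta_ccre[1], 0)

  td <- tidy(fit)
  expect_equal(nrow(td), 2 * fx$cfg$n_states)
  expect_true(all(td$estimate[td$reference] == 0))
})

test_that("constant responses give an intercept-only fit", {
  fx <- erp_fixture
  expr <- fx$truth$expression
  expr[, -1] <- 7 # constant TPM -> constant log2
  design <- build_design(fx$pairs, fx$registry, expr, fx$genes,
    promoter_props = fx$promoter_props, mode = "both"
  )
  fit <- fit_erp(design)
  expect_equal(fit$intercept, 3, tolerance = 1e-9)
  expect_lt(max(abs(c(fit$beta_promoter, fit$beta_ccre))), 1e-9)
})

test_that("duplicated predictors warn but leave fitted values unchanged", {
  fx <- erp_fixture
  design <- build_design(fx$pairs, fx$registry, fx$truth$expression,
    fx$genes,
    promoter_props = fx$promoter_props, mode = "ccre"
  )
  fit0 <- fit_erp(design)
  design2 <- design
  dup_col <- colnames(design$X)[2]
  design2$X <- cbind(design$X, design$X[, 2])
  colnames(design2$X)[ncol(design2$X)] <- dup_col
  expect_warning(fit2 <- fit_erp(design2), "aliased")
  # the two half-coefficients of the duplicated column are accumulated,
  # so predictions from the coefficient vectors agree
  p0 <- ccreg:::predict_expression_from_design(
    design, fit0, fx$genes, fx$cfg$cell_types
  )
  p2 <- ccreg:::predict_expression_from_design(
    design, fit2, fx$genes, fx$cfg$cell_types
  )
  expect_lt(max(abs(p0 - p2)), 1e-6)
})

test_that("eRP scores are proportion-weighted coefficient sums", {
  fx <- erp_fixture
  design <- build_design(fx$pairs, fx$registry, fx$truth$expression,
    fx$genes,
    promoter_props = fx$promoter_props, mode = "both"
  )
  fit <- fit_erp(design)
  scores <- erp_scores(fx$registry, fit)
  for (ct in fx$cfg$cell_types[1:2]) {
    manual <- drop(fx$registry$proportions[[ct]] %*% fit$beta_ccre)
    expect_lt(max(abs(scores[[ct]] - manual)), 1e-12)
  }
  # a cCRE fully in one state scores exactly that state's coefficient;
  # fully-reference cCREs score 0
  p1 <- fx$registry$proportions[[fx$cfg$cell_types[1]]]
  pure <- which(apply(p1, 1, max) == 1)
  for (k in head(pure, 5)) {
    s <- which(p1[k, ] == 1)
    expect_equal(unname(scores[[fx$cfg$cell_types[1]]][k]), fit$beta_ccre[s])
  }
})

test_that("mean-of-eRP prediction equals the pooled-design prediction", {
  fx <- erp_fixture
  design <- build_design(fx$pairs, fx$registry, fx$truth$expression,
    fx$genes,
    promoter_props = fx$promoter_props, mode = "ccre"
  )
  fit <- fit_erp(design)
  via_mean <- predict_expression(fx$pairs, fit, fx$registry, fx$genes,
    mode = "ccre"
  )
  via_design <- ccreg:::predict_expression_from_design(
    design, fit, fx$genes, fx$cfg$cell_types
  )
  m <- matrix(via_mean$predicted,
    nrow = nrow(fx$genes),
    dimnames = list(fx$genes$gene_id, fx$cfg$cell_types)
  )
  expect_lt(max(abs(m - via_design)), 1e-12)

  # all-zero coefficients predict the intercept everywhere
  fit0 <- fit
  fit0$beta_ccre[] <- 0
  pred0 <- predict_expression(fx$pairs, fit0, fx$registry, fx$genes,
    mode = "ccre"
  )
  expect_true(all(abs(
    pred0$predicted[pred0$n_pairs > 0] - fit$intercept
  ) < 1e-12))
})

test_that("fitted values are invariant to the reference-state choice", {
  fx <- erp_fixture
  d0 <- build_design(fx$pairs, fx$registry, fx$truth$expression, fx$genes,
    promoter_props = fx$promoter_props, mode = "both", reference = 0L
  )
  d3 <- build_design(fx$pairs, fx$registry, fx$truth$expression, fx$genes,
    promoter_props = fx$promoter_props, mode = "both", reference = 3L
  )
  f0 <- fit_erp(d0)
  f3 <- fit_erp(d3)
  p0 <- ccreg:::predict_expression_from_design(d0, f0, fx$genes, fx$cfg$cell_types)
  p3 <- ccreg:::predict_expression_from_design(d3, f3, fx$genes, fx$cfg$cell_types)
  expect_lt(max(abs(p0 - p3)), 1e-9)
})

test_that("the correlation screen sets and applies screen correlations", {
  fx <- erp_fixture
  scr <- suppressMessages(correlation_filter(
    fx$pairs, fx$truth$expression, fx$registry
  ))
  expect_true(all(!is.na(scr$screen_correlation) | !scr$selected))
  # formula oracle on a sample of pairs (proxy = non-quiescent proportion)
  lg <- expression_log2(fx$truth$expression)
  set.seed(82)
  for (k in sample(nrow(scr), 10)) {
    ci <- match(scr$ccre_id[k], fx$registry$ccres$ccre_id)
    proxy <- vapply(
      fx$cfg$cell_types,
      function(ct) 1 - fx$registry$proportions[[ct]][ci, 1], numeric(1)
    )
    y <- lg[scr$gene_id[k], ]
    oracle <- suppressWarnings(cor(proxy, y))
    if (is.na(oracle)) {
      expect_false(scr$selected[k])
    } else {
      expect_lt(abs(scr$screen_correlation[k] - oracle), 1e-12)
    }
  }
  # a proxy identical to expression screens at r = 1 (eRP-proxy route)
  expect_error(correlation_filter(
    fx$pairs, fx$truth$expression, fx$registry,
    cell_types = fx$cfg$cell_types[1:2]
  ), ">= 3")
})

test_that("subselection drops reference-state pairs and keeps true links", {
  fx <- erp_fixture
  # a pair whose cCRE is quiescent-majority in every cell type cannot
  # exist in the registry (the removal rule), so emulate the
  # zero-contribution case with a constant-trajectory pair: pick a cCRE
  # with identical majority state everywhere.
  onehot <- ccreg:::onehot_proportions(fx$registry)
  maj <- sapply(
    fx$cfg$cell_types,
    function(ct) ccreg:::majority_state(fx$registry$proportions[[ct]])
  )
  const_idx <- which(apply(maj, 1, function(r) length(unique(r)) == 1))[1]
  const_pair <- tibble::tibble(
    gene_id = fx$genes$gene_id[!fx$genes$zero_links][1],
    ccre_id = fx$registry$ccres$ccre_id[const_idx],
    distance = NA_real_, selected = TRUE, screen_correlation = NA_real_
  )
  pr <- dplyr::bind_rows(fx$pairs, const_pair)
  ss <- suppressMessages(subselect(
    pr, fx$truth$expression, fx$registry, fx$genes,
    promoter_props = fx$promoter_props, mode = "both"
  ))
  got <- ss$pairs
  expect_false(got$selected[
    got$ccre_id == const_pair$ccre_id & got$gene_id == const_pair$gene_id
  ][1])
  # noiseless true links are overwhelmingly retained
  true_keys <- paste(fx$pairs$gene_id, fx$pairs$ccre_id)
  kept <- got$selected[paste(got$gene_id, got$ccre_id) %in% true_keys]
  expect_gt(mean(kept), 0.95)
  # monotone shrinkage: subselection output is deterministic
  ss2 <- suppressMessages(subselect(
    pr, fx$truth$expression, fx$registry, fx$genes,
    promoter_props = fx$promoter_props, mode = "both"
  ))
  expect_identical(ss$pairs, ss2$pairs)
})

test_that("LOO evaluation is exact for perfect and degenerate predictors", {
  fx <- erp_fixture
  loo <- loo_evaluate(fx$truth$expression, fx$registry, fx$genes, fx$pairs,
    promoter_props = fx$promoter_props, mode = "both"
  )
  expect_equal(nrow(loo), fx$cfg$n_cell_types)
  # model class contains the truth; folds whose training cell types
  # under-represent a state fall back to the pseudoinverse and lose a
  # little exactness
  expect_true(all(loo$adj_r_squared > 0.99))
  expect_true(all(loo$p == 2 * (fx$cfg$n_states - 1)))

  # predictions equal to the mean of observed give r^2 = 0, adjusted <= 0
  set.seed(83)
  y <- rnorm(50)
  stats_row <- ccreg:::adjusted_r2(y, rep(mean(y), 50), p = 5)
  expect_equal(stats_row$r_squared, 0)
  expect_lte(stats_row$adj_r_squared, 0)

  expect_error(
    loo_evaluate(fx$truth$expression, fx$registry, fx$genes, fx$pairs,
      promoter_props = fx$promoter_props, mode = "both",
      cell_types = fx$cfg$cell_types[1:2]
    ),
    ">= 3"
  )
})

test_that("per-category LOO restricts fitting and evaluation", {
  fx <- erp_fixture
  genes <- dplyr::left_join(
    fx$genes, categorize_genes(fx$truth$expression),
    by = "gene_id"
  )
  loo <- loo_evaluate(fx$truth$expression, fx$registry, genes, fx$pairs,
    promoter_props = fx$promoter_props, mode = "both", by_category = TRUE,
    cell_types = fx$cfg$cell_types[1:3]
  )
  expect_true("all" %in% loo$category)
  expect_gt(length(unique(loo$category)), 1)
  per_cat_n <- loo$n[loo$category != "all" & loo$left_out == fx$cfg$cell_types[1]]
  expect_equal(sum(per_cat_n), nrow(genes))
})

test_that("pair export applies eRP thresholds and TAD containment", {
  fx <- erp_fixture
  design <- build_design(fx$pairs, fx$registry, fx$truth$expression,
    fx$genes,
    promoter_props = fx$promoter_props, mode = "ccre"
  )
  fit <- fit_erp(design)
  all_pairs <- export_pairs(fx$pairs, fx$registry, fit, fx$genes,
    erp_threshold = 0
  )
  expect_equal(nrow(all_pairs), sum(fx$pairs$selected))

  thr <- 1.5
  some <- export_pairs(fx$pairs, fx$registry, fit, fx$genes,
    erp_threshold = thr
  )
  emat <- as.matrix(some[, paste0("erp_", fx$cfg$cell_types)])
  expect_true(all(apply(abs(emat), 1, max) >= thr))
  # oracle: recompute the kept set directly
  e_all <- ccreg:::pair_erp_matrix(fx$pairs, fx$registry, fit)
  expect_equal(nrow(some), sum(apply(abs(e_all), 1, max) >= thr))

  # TSS and cCRE in disjoint TADs are excluded under the TAD filter
  tads <- tibble::tibble(
    chrom = "chr1", start = c(0, 1e6), end = c(1e6, 2e6)
  )
  tt <- export_pairs(fx$pairs, fx$registry, fit, fx$genes,
    erp_threshold = 0, tads = tads
  )
  ci <- match(tt$ccre_id, fx$registry$ccres$ccre_id)
  gi <- match(tt$gene_id, fx$genes$gene_id)
  mid <- floor((fx$registry$ccres$start[ci] + fx$registry$ccres$end[ci]) / 2)
  same_side <- fx$registry$ccres$chrom[ci] == "chr1" &
    fx$genes$chrom[gi] == "chr1" &
    (mid < 1e6) == (fx$genes$tss[gi] < 1e6) &
    mid < 2e6 & fx$genes$tss[gi] < 2e6
  expect_equal(tt$same_tad, unname(same_side))
  only <- export_pairs(fx$pairs, fx$registry, fit, fx$genes,
    erp_threshold = 0, tads = tads, within_tad_only = TRUE
  )
  expect_equal(nrow(only), sum(same_side))

  expect_error(
    export_pairs(fx$pairs, fx$registry, fit, fx$genes,
      tads = tibble::tibble(chrom = "c", start = 10, end = 5)
    ),
    "malformed"
  )
})
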