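test_that("reproducible peaks follow the stated replicate rules", {
  one <- tibble::tibble(chrom = "c", start = 100, end = 300)
  expect_equal(as.data.frame(reproducible_peaks(list(one))), as.data.frame(one))

  two <- tibble::tibble(chrom = "c", start = 200, end = 400)
  got <- reproducible_peaks(list(one, two))
  expect_equal(got$start, 200)
  expect_equal(got$end, 300)

  expect_error(reproducible_peaks(list()), "replicate")

  disjoint <- tibble::tibble(chrom = "c", start = 500, end = 600)
  expect_equal(nrow(reproducible_peaks(list(one, disjoint))), 0)
})

test_that("reproducible peaks equal the per-base boolean-AND oracle", {
  set.seed(31)
  lens <- c(chrA = 5e4, chrB = 3e4)
  for (i in 1:20) {
    reps <- lapply(1:3, function(j) random_intervals(15, lens, 3000))
    got <- reproducible_peaks(reps)
    oracle <- dplyr::bind_rows(lapply(names(lens), function(chrom) {
      v <- Reduce(`&`, lapply(reps, base_set, chrom = chrom, len = lens[[chrom]]))
      set_to_intervals(v, chrom)
    }))
    expect_equal(as.data.frame(got), as.data.frame(oracle))
  }
})

test_that("registry construction applies the quiescence-removal rule", {
  seg_q <- tibble::tibble(chrom = "c", start = 0, end = 1e4, state = 0L)
  peaks <- list(ct1 = tibble::tibble(chrom = "c", start = 1000, end = 2000))
  reg <- build_registry(peaks, list(ct1 = seg_q), quiescent = 0L, n_states = 13)
  expect_equal(nrow(reg$ccres), 0) # quiescent everywhere -> removed

  seg_12 <- tibble::tibble(
    chrom = "c", start = c(0, 1000, 2000), end = c(1000, 2000, 1e4),
    state = c(0L, 12L, 0L)
  )
  reg2 <- build_registry(peaks, list(ct1 = seg_12), quiescent = 0L, n_states = 13)
  expect_equal(nrow(reg2$ccres), 1)
  expect_equal(unname(reg2$proportions[["ct1"]][1, 13]), 1)
  expect_true(all(reg2$annotation$active))
  expect_equal(reg2$annotation$majority_state, 12L)

  out_of_genome <- list(ct1 = tibble::tibble(chrom = "c", start = 9000, end = 11000))
  expect_error(
    build_registry(out_of_genome, list(ct1 = seg_q), 0L, 13),
    "outside"
  )
})

test_that("registry equals a base-level brute-force oracle on random toys", {
  set.seed(33)
  lens <- c(chrA = 6e4, chrB = 4e4)
  for (i in 1:8) {
    segs <- lapply(1:3, function(j) random_segmentation(lens, 4, bin = 100))
    names(segs) <- paste0("ct", 1:3)
    peaks <- lapply(1:3, function(j) random_intervals(12, lens, 2500))
    names(peaks) <- names(segs)
    reg <- build_registry(peaks, segs, quiescent = 0L, n_states = 4)

    # oracle: merge per-base, then majority state per cell type per element
    for (chrom in names(lens)) {
      v <- Reduce(`|`, lapply(peaks, base_set, chrom = chrom, len = lens[[chrom]]))
      merged <- set_to_intervals(v, chrom)
      if (nrow(merged) == 0) next
      maj <- sapply(segs, function(s) {
        vapply(seq_len(nrow(merged)), function(k) {
          oracle_majority(merged[k, ], s, 4, as.list(lens))
        }, integer(1))
      })
      maj <- matrix(maj, nrow = nrow(merged),
        dimnames = list(NULL, names(segs))
      )
      keep <- rowSums(maj != 0) > 0
      oracle_ccres <- merged[keep, , drop = FALSE]
      got <- reg$ccres[reg$ccres$chrom == chrom, c("chrom", "start", "end")]
      expect_equal(as.data.frame(got), as.data.frame(oracle_ccres),
        ignore_attr = TRUE
      )
      # majority states agree too
      if (nrow(oracle_ccres) > 0) {
        ann <- tidy(reg)
        for (ct in names(segs)) {
          got_maj <- ann$majority_state[ann$chrom == chrom & ann$cell_type == ct]
          expect_equal(got_maj, unname(maj[keep, ct]))
        }
      }
    }
    # proportion vectors all sum to 1; activity flag consistent
    for (ct in names(segs)) {
      expect_true(all(abs(rowSums(reg$proportions[[ct]]) - 1) < 1e-9))
    }
    ann <- reg$annotation
    expect_equal(ann$active, ann$majority_state != 0L)
  }
})

test_that("registry construction is idempotent", {
  cfg <- toy_config(seed = 6)
  truth <- simulate_dataset(cfg)
  repro <- lapply(truth$peaks, reproducible_peaks)
  reg <- build_registry(repro, truth$state_maps, 0L, cfg$n_states)
  bed <- registry_bed(reg)
  reg2 <- build_registry(
    list(all = bed[, c("chrom", "start", "end")]),
    truth$state_maps, 0L, cfg$n_states
  )
  expect_equal(as.data.frame(reg2$ccres), as.data.frame(reg$ccres))
  expect_equal(reg2$proportions, reg$proportions)
})

test_that("active and dynamic cCRE counts match direct tallies", {
  cfg <- toy_config(seed = 13)
  truth <- simulate_dataset(cfg)
  repro <- lapply(truth$peaks, reproducible_peaks)
  reg <- build_registry(repro, truth$state_maps, 0L, cfg$n_states)

  counts <- active_ccre_counts(reg)
  ann <- reg$annotation
  for (ct in cfg$cell_types) {
    tot <- counts$n[counts$cell_type == ct & is.na(counts$state)]
    expect_equal(tot, sum(ann$active[ann$cell_type == ct]))
    per <- counts[counts$cell_type == ct & !is.na(counts$state), ]
    for (k in seq_len(nrow(per))) {
      expect_equal(per$n[k], sum(
        ann$majority_state[ann$cell_type == ct] == per$state[k]
      ))
    }
  }

  dyn <- dynamic_ccre_counts(reg)
  gc <- reg$ccres
  for (ct in cfg$cell_types) {
    hits <- vapply(seq_len(nrow(gc)), function(i) {
      p <- repro[[ct]]
      any(p$chrom == gc$chrom[i] & p$start < gc$end[i] & p$end > gc$start[i])
    }, logical(1))
    expect_equal(dyn$n[dyn$cell_type == ct], sum(hits))
  }
})

test_that("a cell type with states but no peaks contributes zero dynamic cCREs", {
  cfg <- toy_config(seed = 14)
  truth <- simulate_dataset(cfg)
  repro <- lapply(truth$peaks, reproducible_peaks)
  repro[[2]] <- repro[[2]][0, ] # MK/CLP-like: no accessibility data
  reg <- build_registry(repro, truth$state_maps, 0L, cfg$n_states)
  dyn <- dynamic_ccre_counts(reg)
  expect_equal(dyn$n[dyn$cell_type == cfg$cell_types[2]], 0L)
  # but the cell type is still annotated on every cCRE
  expect_equal(
    sum(reg$annotation$cell_type == cfg$cell_types[2]), nrow(reg$ccres)
  )
})

test_that("catalog overlap partitions match the per-base oracle", {
  a <- tibble::tibble(chrom = "c", start = c(0, 1000), end = c(500, 1500))
  ident <- catalog_overlap(list(x = a, y = a))
  expect_equal(ident$counts$pattern, "x+y")
  expect_equal(ident$counts$n, 2)

  b <- tibble::tibble(chrom = "c", start = 5000, end = 5500)
  disj <- catalog_overlap(list(x = a, y = b))
  expect_equal(sort(disj$counts$pattern), c("x", "y"))
  expect_equal(disj$n_elements, 3)

  set.seed(51)
  lens <- c(chrA = 4e4)
  for (i in 1:10) {
    cats <- lapply(1:3, function(j) random_intervals(10, lens, 2000))
    names(cats) <- c("u", "v", "w")
    got <- catalog_overlap(cats)
    v <- Reduce(`|`, lapply(cats, base_set, chrom = "chrA", len = 4e4))
    merged <- set_to_intervals(v, "chrA")
    oracle_patterns <- vapply(seq_len(nrow(merged)), function(k) {
      member <- vapply(cats, function(cc) {
        any(cc$start < merged$end[k] & cc$end > merged$start[k])
      }, logical(1))
      paste(names(cats)[member], collapse = "+")
    }, character(1))
    oracle_counts <- sort(table(oracle_patterns))
    got_counts <- sort(setNames(got$counts$n, got$counts$pattern))
    expect_equal(as.integer(got_counts), as.integer(oracle_counts))
    expect_equal(names(got_counts), names(oracle_counts))
    expect_equal(sum(got$counts$n), got$n_elements)
  }
})

test_that("capture curves count overlapped known elements", {
  known <- tibble::tibble(chrom = "c", start = c(100, 900), end = c(200, 1000))
  catalog <- tibble::tibble(chrom = "c", start = 0, end = 2000)
  expect_equal(capture_curve(catalog, known)$n_known_captured, 2L)

  far <- tibble::tibble(chrom = "c", start = 5000, end = 6000)
  expect_equal(capture_curve(far, known)$n_known_captured, 0L)

  # monotonicity: adding catalog intervals never decreases capture
  set.seed(61)
  lens <- c(chrA = 3e4)
  known <- random_intervals(20, lens, 1000)
  cat1 <- random_intervals(5, lens, 1500)
  prev <- capture_curve(cat1, known)$n_known_captured
  for (i in 1:5) {
    cat1 <- dplyr::bind_rows(cat1, random_intervals(3, lens, 1500))
    cur <- capture_curve(cat1, known)$n_known_captured
    expect_gte(cur, prev)
    prev <- cur
  }
})
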