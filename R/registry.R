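# cCRE registry construction: reproducible peaks per cell type, a merged
# cross-cell-type registry with state annotation, the quiescence removal
# rule, activity and dynamic counts, catalog overlap partitions and
# capture curves.

#' Reproducible peaks across replicates
#'
#' With a single replicate the peaks are returned as-is (unreplicated data
#' are accepted at face value). With two or more replicates, the result is
#' the base-level intersection across all replicates, reported as maximal
#' intervals.
#'
#' @param replicates List of peak tibbles (`chrom`, `start`, `end`), one
#'   per replicate. ATAC and DNase peak sets for the same cell type should
#'   be unioned per replicate before calling.
#' @return A peak tibble.
#' @export
reproducible_peaks <- function(replicates) {
  if (is.data.frame(replicates)) replicates <- list(replicates)
  if (length(replicates) == 0) abort("at least one replicate is required")
  if (length(replicates) == 1) {
    return(merge_intervals(replicates[[1]]))
  }
  Reduce(intersect_intervals, replicates)
}

#' Build the cCRE registry
#'
#' Merges reproducible peaks across cell types into maximal intervals
#' (overlap by >= 1 base; bookended intervals stay separate), annotates
#' every merged interval with its per-cell-type state proportions and
#' majority state (ties to the lowest state id) in every supplied
#' segmentation - including cell types with no peaks of their own - and
#' removes intervals whose majority state is quiescent in all cell types.
#' Surviving intervals get stable ids in genomic order.
#'
#' @param peaks_by_cell_type Named list of reproducible-peak tibbles; cell
#'   types absent from the list (but present in `segmentations`) are
#'   allowed.
#' @param segmentations Named list of segmentation tibbles, one per cell
#'   type.
#' @param quiescent Quiescent state id (default 0).
#' @param n_states Number of states (default: inferred from the
#'   segmentations).
#' @return An object of class `ccre_registry`.
#' @export
build_registry <- function(peaks_by_cell_type, segmentations,
                           quiescent = 0L, n_states = NULL) {
  cell_types <- names(segmentations)
  if (is.null(cell_types)) abort("segmentations must be a named list")
  if (is.null(n_states)) {
    n_states <- max(vapply(segmentations, function(s) max(s$state), numeric(1))) + 1L
  }
  all_peaks <- bind_rows(peaks_by_cell_type)
  if (nrow(all_peaks) > 0) {
    genome <- segmentation_genome(segmentations[[1]])
    bad <- !(all_peaks$chrom %in% genome$chrom) |
      all_peaks$end > genome$length[match(all_peaks$chrom, genome$chrom)] |
      all_peaks$start < 0
    if (any(bad, na.rm = TRUE)) abort("peak outside the segmented genome")
  }
  merged <- merge_intervals(all_peaks)
  props <- lapply(cell_types, function(ct) {
    interval_state_proportions(merged, segmentations[[ct]], n_states)
  })
  names(props) <- cell_types
  maj <- vapply(props, majority_state, integer(max(nrow(merged), 0)))
  maj <- matrix(maj, nrow = nrow(merged), dimnames = list(NULL, cell_types))
  keep <- if (nrow(merged) > 0) {
    rowSums(maj != quiescent) > 0
  } else {
    logical(0)
  }
  ccres <- merged[keep, , drop = FALSE]
  maj <- maj[keep, , drop = FALSE]
  props <- lapply(props, function(m) m[keep, , drop = FALSE])
  ids <- sprintf("ccre_%06d", seq_len(nrow(ccres)))
  ccres <- bind_cols(tibble(ccre_id = ids), ccres)
  for (ct in cell_types) rownames(props[[ct]]) <- ids

  annotation <- tibble(
    ccre_id = rep(ids, times = length(cell_types)),
    cell_type = rep(cell_types, each = length(ids)),
    majority_state = as.integer(maj),
    active = as.integer(maj) != quiescent
  )

  support <- NULL
  if (nrow(ccres) > 0 && length(peaks_by_cell_type) > 0) {
    gc <- as_granges(ccres)
    support <- bind_rows(lapply(names(peaks_by_cell_type), function(ct) {
      pk <- peaks_by_cell_type[[ct]]
      if (nrow(pk) == 0) {
        return(NULL)
      }
      hit <- unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(gc, as_granges(pk))
      ))
      tibble(ccre_id = ids[hit], cell_type = ct)
    }))
  }
  if (is.null(support)) {
    support <- tibble(ccre_id = character(), cell_type = character())
  }

  structure(
    list(
      ccres = ccres,
      cell_types = cell_types,
      n_states = n_states,
      quiescent = as.integer(quiescent),
      proportions = props,
      annotation = annotation,
      peak_support = support
    ),
    class = "ccre_registry"
  )
}

#' @export
print.ccre_registry <- function(x, ...) {
  cat(
    "<ccre_registry>", nrow(x$ccres), "cCREs,", length(x$cell_types),
    "cell types,", x$n_states, "states (quiescent =", x$quiescent, ")\n"
  )
  invisible(x)
}

#' Tidy a registry into one row per (cCRE, cell type)
#'
#' @param x A `ccre_registry`.
#' @param proportions Include per-state proportion columns (`prop_s0`,
#'   ...).
#' @param ... Unused.
#' @export
tidy.ccre_registry <- function(x, proportions = FALSE, ...) {
  out <- left_join(x$annotation, x$ccres, by = "ccre_id") %>%
    select("ccre_id", "chrom", "start", "end", "cell_type",
      "majority_state", "active"
    )
  out$peak_support <- paste0(out$ccre_id, ":", out$cell_type) %in%
    paste0(x$peak_support$ccre_id, ":", x$peak_support$cell_type)
  if (proportions) {
    pm <- do.call(rbind, x$proportions[unique(out$cell_type)])
    # annotation is ordered cell-type-major, matching rbind order
    colnames(pm) <- paste0("prop_s", seq_len(x$n_states) - 1)
    out <- bind_cols(out, as_tibble(pm))
  }
  out
}

#' @export
glance.ccre_registry <- function(x, ...) {
  tibble(
    n_ccres = nrow(x$ccres),
    n_cell_types = length(x$cell_types),
    n_states = x$n_states,
    mean_width = mean(x$ccres$end - x$ccres$start),
    total_bases = sum(x$ccres$end - x$ccres$start)
  )
}

#' Active-cCRE counts per cell type and per state
#'
#' A cCRE is active in a cell type when its majority state there is not
#' quiescent. Totals exclude the quiescent state by construction.
#'
#' @param registry A `ccre_registry`.
#' @return A tibble with `cell_type`, `state`, `n`, plus per-cell-type
#'   totals in attribute-free form: rows with `state = NA` carry the
#'   total.
#' @export
active_ccre_counts <- function(registry) {
  per_state <- registry$annotation %>%
    filter(.data$majority_state != registry$quiescent) %>%
    count(.data$cell_type, state = .data$majority_state, name = "n")
  totals <- per_state %>%
    group_by(.data$cell_type) %>%
    summarise(n = sum(.data$n), .groups = "drop") %>%
    mutate(state = NA_integer_)
  missing_ct <- setdiff(registry$cell_types, totals$cell_type)
  if (length(missing_ct) > 0) {
    totals <- bind_rows(
      totals,
      tibble(cell_type = missing_ct, n = 0L, state = NA_integer_)
    )
  }
  bind_rows(per_state, totals) %>%
    arrange(.data$cell_type, .data$state)
}

#' Dynamic-cCRE counts per cell type
#'
#' A cCRE is dynamic in a cell type when a reproducible accessibility peak
#' of that cell type overlaps it.
#'
#' @param registry A `ccre_registry`.
#' @return A tibble with `cell_type` and `n` (zero for peak-less cell
#'   types).
#' @export
dynamic_ccre_counts <- function(registry) {
  counts <- count(registry$peak_support, .data$cell_type, name = "n")
  missing_ct <- setdiff(registry$cell_types, counts$cell_type)
  bind_rows(
    counts,
    tibble(cell_type = missing_ct, n = rep(0L, length(missing_ct)))
  ) %>%
    arrange(.data$cell_type)
}

#' Overlap partition of interval catalogs
#'
#' Merges the union of all catalogs into maximal elements and labels each
#' element with the set of catalogs it intersects, as in an UpSet plot.
#'
#' @param catalogs Named list (>= 2) of interval tibbles.
#' @return An object of class `overlap_partition`: list with `counts`
#'   (tibble: `pattern`, `n`), `set_totals` (tibble: `set`,
#'   `n_merged_elements`), and `n_elements`.
#' @export
catalog_overlap <- function(catalogs) {
  if (length(catalogs) < 2 || is.null(names(catalogs))) {
    abort("catalog_overlap needs >= 2 named catalogs")
  }
  merged <- merge_intervals(bind_rows(catalogs))
  member <- matrix(FALSE, nrow(merged), length(catalogs),
    dimnames = list(NULL, names(catalogs))
  )
  if (nrow(merged) > 0) {
    gm <- as_granges(merged)
    for (nm in names(catalogs)) {
      if (nrow(catalogs[[nm]]) == 0) next
      hit <- unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(gm, as_granges(catalogs[[nm]]))
      ))
      member[hit, nm] <- TRUE
    }
  }
  pattern <- apply(member, 1, function(r) {
    paste(names(catalogs)[r], collapse = "+")
  })
  counts <- tibble(pattern = pattern) %>%
    count(.data$pattern, name = "n") %>%
    arrange(dplyr::desc(.data$n))
  set_totals <- tibble(
    set = names(catalogs),
    n_merged_elements = colSums(member)
  )
  structure(
    list(
      counts = counts, set_totals = set_totals,
      n_elements = nrow(merged), membership = member, elements = merged
    ),
    class = "overlap_partition"
  )
}

#' @export
print.overlap_partition <- function(x, ...) {
  cat("<overlap_partition>", x$n_elements, "merged elements\n")
  print(x$counts)
  invisible(x)
}

#' @export
tidy.overlap_partition <- function(x, ...) {
  x$counts
}

#' Capture of known elements by a catalog
#'
#' @param catalog Interval tibble (the cCRE collection).
#' @param known_elements Interval tibble of known regulatory elements.
#' @return A tibble with `n_catalog` (catalog intervals) and
#'   `n_known_captured` (known elements overlapping the catalog by >= 1
#'   base).
#' @export
capture_curve <- function(catalog, known_elements) {
  captured <- 0L
  if (nrow(known_elements) > 0 && nrow(catalog) > 0) {
    captured <- length(unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(
        as_granges(known_elements), as_granges(catalog)
      )
    )))
  }
  tibble(n_catalog = nrow(catalog), n_known_captured = captured)
}

#' Export the registry as a BED tibble (id in column 4)
#' @param registry A `ccre_registry`.
#' @export
registry_bed <- function(registry) {
  registry$ccres[, c("chrom", "start", "end", "ccre_id")]
}
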