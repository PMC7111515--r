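# Convenience wrappers that run the full synthetic study (generator ->
# registry -> predictors) and the link-recovery benchmark against
# generator truth. Used by the validation suite and the acceptance
# script.

#' Simulate a complete study and build its registry and predictors
#'
#' Runs the generator, computes reproducible peaks, builds the annotated
#' cCRE registry, the promoter state proportions, and the ground-truth
#' pair set.
#'
#' @param config A [sim_config()].
#' @return List with `config`, `truth`, `registry`, `genes`,
#'   `promoter_props`, and `true_pairs` (a pair tibble over the true
#'   links, all selected).
#' @export
simulate_study <- function(config) {
  truth <- simulate_dataset(config)
  repro <- lapply(truth$peaks, reproducible_peaks)
  registry <- build_registry(repro, truth$state_maps,
    quiescent = 0L, n_states = config$n_states
  )
  genes <- truth$genes
  promoter_props <- promoter_state_proportions(
    genes, truth$state_maps, config$n_states,
    window = config$promoter_window
  )
  true_pairs <- true_link_pairs(truth, registry) %>%
    mutate(
      distance = NA_real_, selected = TRUE,
      screen_correlation = NA_real_
    )
  list(
    config = config, truth = truth, registry = registry, genes = genes,
    promoter_props = promoter_props, true_pairs = true_pairs
  )
}

#' Candidate set with a fixed number of distractors per gene
#'
#' Labels every candidate pair by whether it is a true link and keeps all
#' true pairs plus at most `n_distractors` randomly chosen unlinked
#' candidates per gene - the benchmark layout for link-recovery scoring.
#'
#' @param study Output of [simulate_study()].
#' @param n_distractors Unlinked candidates kept per gene.
#' @param seed Seed for the distractor draw.
#' @return Pair tibble with an `is_true` column.
#' @export
benchmark_pairs <- function(study, n_distractors = 20,
                            seed = study$config$seed + 99L) {
  cand <- assign_candidates(study$genes, study$registry,
    promoter_window = study$config$promoter_window
  )
  keys <- paste(study$true_pairs$gene_id, study$true_pairs$ccre_id)
  cand$is_true <- paste(cand$gene_id, cand$ccre_id) %in% keys
  set.seed(seed)
  bind_rows(lapply(split(cand, cand$gene_id), function(d) {
    tp <- d[d$is_true, , drop = FALSE]
    fp <- d[!d$is_true, , drop = FALSE]
    if (nrow(fp) > n_distractors) {
      fp <- fp[sample.int(nrow(fp), n_distractors), , drop = FALSE]
    }
    bind_rows(tp, fp)
  }))
}

#' Link-recovery benchmark against generator truth
#'
#' Screens and subselects the benchmark candidate set (true links plus
#' distractors) and scores the surviving pairs against the generator's
#' true links.
#'
#' @param config A [sim_config()] describing the study conditions.
#' @param n_distractors Distractors per gene (default 20).
#' @param mode Model context used during selection.
#' @param ... Passed to [subselect()].
#' @return One-row tibble: `recall`, `precision`, `n_true`, `n_selected`,
#'   `screen_recall`.
#' @export
benchmark_link_recovery <- function(config, n_distractors = 20,
                                    mode = "both", ...) {
  study <- simulate_study(config)
  sub <- benchmark_pairs(study, n_distractors)
  model0 <- fit_erp(build_design(sub, study$registry,
    study$truth$expression, study$genes,
    promoter_props = study$promoter_props, mode = mode
  ))
  scr <- correlation_filter(sub, study$truth$expression, study$registry,
    model = model0
  )
  ss <- subselect(scr, study$truth$expression, study$registry, study$genes,
    promoter_props = study$promoter_props, mode = mode, ...
  )
  fin <- ss$pairs
  tibble(
    recall = sum(fin$selected & fin$is_true) / sum(fin$is_true),
    precision = sum(fin$selected & fin$is_true) / max(sum(fin$selected), 1),
    n_true = sum(fin$is_true),
    n_selected = sum(fin$selected),
    screen_recall = sum(scr$selected & scr$is_true) / sum(scr$is_true)
  )
}

#' Leave-one-out summary over modes on the true-link pair set
#'
#' @param study Output of [simulate_study()].
#' @param modes Modes to evaluate.
#' @return The bound [loo_evaluate()] tables.
#' @export
loo_summary <- function(study, modes = c("promoter", "ccre", "both")) {
  bind_rows(lapply(modes, function(m) {
    loo_evaluate(study$truth$expression, study$registry, study$genes,
      study$true_pairs,
      promoter_props = study$promoter_props, mode = m
    )
  }))
}
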