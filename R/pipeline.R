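#' Run the full single-gene versus multi-gene comparison
#'
#' For every drug shared by the two releases: build the time-stamped split,
#' binarise responses at the training-median threshold, select the best
#' single-gene marker from training-data association tests (corrected across
#' the whole drug-by-feature family), train the random-forest multi-gene
#' classifier with cross-validated mtry selection, and evaluate both models on
#' the identical training and test cell lines. Drugs that cannot be compared
#' (empty test set, markerless, single-class training labels) are excluded
#' with a recorded reason, never silently dropped.
#'
#' @param r1,r2 \code{\link{dataset_release}} objects (first and later
#'   release).
#' @param fdr false discovery rate for BH correction of association p-values.
#' @param p_mode \code{"bh"} or \code{"fixed"} (see
#'   \code{\link{adjust_pvalues}}).
#' @param min_mutants minimum mutant count for a testable association.
#' @param min_test minimum test-set size for a drug to be compared.
#' @param forest a \code{\link{forest_config}}; its seed field is replaced by
#'   a per-drug seed derived from \code{seed} and the drug id.
#' @param direction_aware single-gene prediction mode (see
#'   \code{\link{predict_single_gene}}).
#' @param seed cohort-level seed.
#' @return list of class \code{marker_comparison_run} with components
#'   \code{comparisons} (list of \code{drug_comparison}), \code{summary}
#'   (\code{cohort_summary}), \code{associations} (data.frame),
#'   \code{markers} (list of \code{marker_classifier}), \code{excluded}
#'   (data.frame drug_id/reason), \code{panel}.
#' @export
run_comparison <- function(r1, r2, fdr = 0.2, p_mode = c("bh", "fixed"),
                           min_mutants = 3L, min_test = 1L,
                           forest = forest_config(),
                           direction_aware = FALSE, seed = 1L) {
  p_mode <- match.arg(p_mode)
  panel <- common_panel(r1, r2)
  excluded <- data.frame(drug_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  exclude <- function(drug, reason) {
    message("excluding drug ", drug, ": ", reason)
    rbind(excluded, data.frame(drug_id = drug, reason = reason,
                               stringsAsFactors = FALSE))
  }

  splits <- list(); thresholds <- list(); train_labels <- list()
  for (d in panel$drugs) {
    sp <- build_time_stamped_split(r1, r2, d)
    if (!length(sp$training_cell_lines)) {
      excluded <- exclude(d, "empty training set"); next
    }
    if (length(sp$test_cell_lines) < min_test) {
      excluded <- exclude(d, "test set below minimum size"); next
    }
    resp <- drug_responses(r1, d, sp$training_cell_lines)
    thr <- compute_threshold(resp)
    lab <- assign_labels(resp, thr)
    if (length(unique(lab)) < 2L) {
      excluded <- exclude(d, "single-class training labels"); next
    }
    splits[[d]] <- sp; thresholds[[d]] <- thr
    train_labels[[d]] <- stats::setNames(lab, sp$training_cell_lines)
  }

  # association tests for every (kept drug) x (common feature), corrected
  # jointly across the whole family
  assoc <- list()
  for (d in names(splits)) {
    cells <- splits[[d]]$training_cell_lines
    resp <- drug_responses(r1, d, cells)
    for (g in panel$features)
      assoc[[paste(d, g)]] <- test_association(
        resp, r1$features[cells, g], drug_id = d, feature_name = g,
        min_mutants = min_mutants)
  }
  assoc_tab <- adjust_pvalues(associations_table(assoc), fdr = fdr,
                              mode = p_mode)

  markers <- list()
  comparisons <- list()
  for (d in names(splits)) {
    mk <- select_best_marker(assoc_tab[assoc_tab$drug_id == d, ])
    if (is.null(mk)) {
      excluded <- exclude(d, "markerless (no testable association)"); next
    }
    markers[[d]] <- mk
    sp <- splits[[d]]
    tr_cells <- sp$training_cell_lines
    te_cells <- sp$test_cell_lines
    tr_truth <- unname(train_labels[[d]])
    te_truth <- assign_labels(drug_responses(r2, d, te_cells), thresholds[[d]])

    # training features come from the release-1 snapshot; test cells only
    # exist in release 2
    sg_tr <- predict_single_gene(mk, r1$features, tr_cells, direction_aware)
    sg_te <- predict_single_gene(mk, r2$features, te_cells, direction_aware)
    no_pred <- sum(r2$features[te_cells, mk$feature_name]) == 0L
    single <- list(
      train = metric_set(tr_truth, unname(sg_tr)),
      test = metric_set(te_truth, unname(sg_te), no_prediction = no_pred))

    fc <- forest
    fc$seed <- drug_seed(seed, d)
    xtr <- r1$features[tr_cells, panel$features, drop = FALSE]
    cv <- cross_validate_mtry(xtr, tr_truth, fc)
    rf <- train_forest(xtr, tr_truth, cv$chosen_mtry, fc, cv = cv)
    rf_tr <- predict_multi_gene(rf, r1$features[, panel$features], tr_cells)
    rf_te <- predict_multi_gene(rf, r2$features[, panel$features], te_cells)
    multi <- list(
      train = metric_set(tr_truth, unname(rf_tr$labels)),
      cv = metric_set(tr_truth, unname(cv$cv_predictions)),
      test = metric_set(te_truth, unname(rf_te$labels)))

    cls <- "unknown"
    if (!is.null(r1$drug_metadata)) {
      i <- match(d, r1$drug_metadata$drug_id)
      if (!is.na(i)) cls <- r1$drug_metadata$class[i]
    }
    comparisons[[d]] <- compare_drug(
      single, multi,
      meta = list(drug_id = d, class = cls, marker_feature = mk$feature_name,
                  marker_p = mk$p_value,
                  marker_direction = mk$effect_direction,
                  chosen_mtry = rf$chosen_mtry,
                  cv_score_per_mtry = rf$cv_score_per_mtry,
                  threshold = thresholds[[d]]),
      test_truth = te_truth)
  }

  structure(list(panel = panel,
                 comparisons = comparisons,
                 summary = if (length(comparisons) >= 2)
                   summarize_cohort(comparisons) else NULL,
                 associations = assoc_tab,
                 markers = markers,
                 excluded = excluded,
                 seed = seed),
            class = "marker_comparison_run")
}

#' @export
print.marker_comparison_run <- function(x, ...) {
  cat(sprintf("<marker_comparison_run: %d drugs compared, %d excluded>\n",
              length(x$comparisons), nrow(x$excluded)))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Export the split manifest of a run's drugs
#'
#' One row per (drug, cell line) with its role, response and class label;
#' the per-drug analogue of a reproducible train/test registry.
#'
#' @param r1,r2 the releases the run was built from.
#' @param run a \code{marker_comparison_run}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_split_manifest <- function(r1, r2, run, path) {
  rows <- lapply(run$comparisons, function(cp) {
    d <- cp$drug_id
    sp <- build_time_stamped_split(r1, r2, d)
    thr <- cp$meta$threshold
    tr <- drug_responses(r1, d, sp$training_cell_lines)
    te <- drug_responses(r2, d, sp$test_cell_lines)
    rbind(
      data.frame(drug_id = d, cell_line_id = sp$training_cell_lines,
                 role = "train", log_ic50 = tr,
                 label = assign_labels(tr, thr), stringsAsFactors = FALSE),
      data.frame(drug_id = d, cell_line_id = sp$test_cell_lines,
                 role = "test", log_ic50 = te,
                 label = assign_labels(te, thr), stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  out$log_ic50 <- sprintf("%.17g", out$log_ic50)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
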