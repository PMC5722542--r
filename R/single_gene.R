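#' Univariate drug-gene association test on training data
#'
#' Compares training-set logIC50 between mutant and wild-type cell lines for
#' one binary feature with a pooled-variance two-group test (equivalent to a
#' two-group one-way ANOVA). Features with fewer than \code{min_mutants}
#' mutant lines are untestable and reported with p = 1. The effect direction
#' is sensitising when mutants have the lower mean logIC50, otherwise
#' resistance-associated.
#'
#' @param responses numeric training logIC50 values (log10 uM).
#' @param feature integer 0/1 mutation flags aligned with \code{responses}.
#' @param drug_id,feature_name identifiers carried into the result.
#' @param min_mutants minimum mutant count for a testable association.
#' @return list of class \code{association_result}: p_value, effect_size
#'   (mutant mean - WT mean), effect_direction, n_mutant, n_wildtype,
#'   testable.
#' @export
test_association <- function(responses, feature, drug_id = NA_character_,
                             feature_name = NA_character_, min_mutants = 3L) {
  stopifnot(length(responses) == length(feature), all(feature %in% 0:1))
  mut <- responses[feature == 1L]
  wt <- responses[feature == 0L]
  res <- list(drug_id = drug_id, feature_name = feature_name,
              n_mutant = length(mut), n_wildtype = length(wt),
              testable = TRUE, adjusted_significant = NA)
  if (length(mut) < min_mutants || length(wt) < 2L) {
    res$testable <- FALSE
    res$p_value <- 1
    res$effect_size <- if (length(mut) && length(wt)) mean(mut) - mean(wt) else 0
  } else if (stats::var(mut) == 0 && stats::var(wt) == 0) {
    # degenerate pooled variance: identical constants carry no evidence,
    # distinct constants separate the groups perfectly
    res$effect_size <- mean(mut) - mean(wt)
    res$p_value <- if (res$effect_size == 0) 1 else 0
  } else {
    tt <- stats::t.test(mut, wt, var.equal = TRUE)
    res$p_value <- tt$p.value
    res$effect_size <- mean(mut) - mean(wt)
  }
  res$effect_direction <- if (res$effect_size < 0) "sensitising" else
    "resistance-associated"
  structure(res, class = "association_result")
}

#' Flag significant associations after multiple-testing correction
#'
#' Two modes: \code{"bh"} applies Benjamini-Hochberg across the whole
#' drug-by-feature family at the given FDR; \code{"fixed"} compares raw
#' p-values against a fixed cutoff (default the GDSC-published adjusted
#' threshold 0.00840749, retained as a compatibility mode).
#'
#' @param results data.frame of association results (one row each, as built
#'   by \code{\link{associations_table}}) or a list of
#'   \code{association_result}s.
#' @param fdr false discovery rate for BH mode.
#' @param mode \code{"bh"} or \code{"fixed"}.
#' @param fixed_cutoff raw p-value cutoff for fixed mode.
#' @return the table with an \code{adjusted_significant} logical column.
#' @export
adjust_pvalues <- function(results, fdr = 0.2, mode = c("bh", "fixed"),
                           fixed_cutoff = 0.00840749) {
  mode <- match.arg(mode)
  if (!is.data.frame(results)) results <- associations_table(results)
  if (!nrow(results)) stop("no association results")
  if (mode == "bh") {
    if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
    results$adjusted_significant <-
      stats::p.adjust(results$p_value, method = "BH") <= fdr
  } else {
    results$adjusted_significant <- results$p_value <= fixed_cutoff
  }
  results
}

#' Flatten association results into a data.frame
#'
#' @param results list of \code{association_result}s.
#' @return data.frame with one row per association.
#' @export
associations_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(drug_id = r$drug_id, feature_name = r$feature_name,
               p_value = r$p_value, effect_size = r$effect_size,
               effect_direction = r$effect_direction,
               n_mutant = r$n_mutant, n_wildtype = r$n_wildtype,
               testable = r$testable,
               adjusted_significant = r$adjusted_significant,
               stringsAsFactors = FALSE)))
}

#' Select the best single-gene marker for one drug
#'
#' The marker is the testable association with the lowest p-value, whether or
#' not it survives multiple-testing correction (a non-significant best marker
#' is still the best-case single-gene model). Ties are broken by larger
#' absolute effect size, then lexicographic feature name. A drug with no
#' testable association is markerless (returns NULL).
#'
#' @param results data.frame of this drug's association results.
#' @return list of class \code{marker_classifier} (drug_id, feature_name,
#'   p_value, effect_direction, effect_size, adjusted_significant), or NULL.
#' @export
select_best_marker <- function(results) {
  if (!is.data.frame(results)) results <- associations_table(results)
  results <- results[results$testable, , drop = FALSE]
  if (!nrow(results)) return(NULL)
  ord <- order(results$p_value, -abs(results$effect_size),
               results$feature_name)
  best <- results[ord[1L], ]
  structure(list(drug_id = best$drug_id, feature_name = best$feature_name,
                 p_value = best$p_value,
                 effect_direction = best$effect_direction,
                 effect_size = best$effect_size,
                 adjusted_significant = best$adjusted_significant),
            class = "marker_classifier")
}

#' Predict classes with a single-gene marker
#'
#' By default a cell line harbouring the marker alteration is predicted
#' sensitive and wild-type lines resistant, regardless of the association's
#' direction (this matches how univariate markers are deployed: the
#' actionable mutation selects the treated population). The optional
#' direction-aware mode inverts predictions for resistance-associated
#' markers.
#'
#' @param marker a \code{marker_classifier}.
#' @param features binary feature matrix (cell lines x features).
#' @param cell_ids cell lines to predict.
#' @param direction_aware invert predictions for resistance markers.
#' @return named character vector of predicted labels.
#' @export
predict_single_gene <- function(marker, features, cell_ids,
                                direction_aware = FALSE) {
  stopifnot(inherits(marker, "marker_classifier"))
  if (!marker$feature_name %in% colnames(features))
    stop("marker feature '", marker$feature_name, "' absent from matrix")
  flag <- features[cell_ids, marker$feature_name]
  pred <- ifelse(flag == 1L, "sensitive", "resistant")
  if (direction_aware && marker$effect_direction == "resistance-associated")
    pred <- ifelse(flag == 1L, "resistant", "sensitive")
  stats::setNames(pred, cell_ids)
}
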