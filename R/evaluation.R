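#' Confusion matrix of a binary sensitivity prediction
#'
#' Sensitive is the positive class: tp counts cell lines sensitive in truth
#' and prediction, fp predicted sensitive but resistant, fn predicted
#' resistant but sensitive, tn resistant in both.
#'
#' @param truth,predicted aligned character vectors of
#'   "sensitive"/"resistant" labels.
#' @return list of class \code{confusion_matrix} with tp, tn, fp, fn.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("label vectors differ in length")
  stopifnot(all(truth %in% c("sensitive", "resistant")),
            all(predicted %in% c("sensitive", "resistant")))
  structure(list(
    tp = sum(truth == "sensitive" & predicted == "sensitive"),
    tn = sum(truth == "resistant" & predicted == "resistant"),
    fp = sum(truth == "resistant" & predicted == "sensitive"),
    fn = sum(truth == "sensitive" & predicted == "resistant")),
    class = "confusion_matrix")
}

#' Matthews correlation coefficient
#'
#' MCC = (tp tn - fp fn) / sqrt((tp+fn)(fn+tn)(tn+fp)(fp+tp)). Whenever any
#' factor of the denominator is zero the coefficient is 0: MCC = 0 is the
#' random baseline, and the same value is assigned when no informative
#' prediction is possible (e.g. the marker is absent from the evaluated set).
#'
#' @param cm a \code{\link{confusion}} matrix.
#' @return value in [-1, 1].
#' @export
mcc <- function(cm) {
  tp <- as.numeric(cm$tp); tn <- as.numeric(cm$tn)
  fp <- as.numeric(cm$fp); fn <- as.numeric(cm$fn)
  den <- (tp + fn) * (fn + tn) * (tn + fp) * (fp + tp)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Precision and recall
#'
#' Precision is tp/(tp+fp) — among cell lines called sensitive, the fraction
#' truly sensitive; recall is tp/(tp+fn) — among truly sensitive lines, the
#' fraction recovered. Either ratio is 0 when its denominator is 0 (no
#' positive calls, or no sensitive lines).
#'
#' @param cm a \code{\link{confusion}} matrix.
#' @return named numeric vector c(precision, recall).
#' @export
precision_recall <- function(cm) {
  pr <- if (cm$tp + cm$fp == 0) 0 else cm$tp / (cm$tp + cm$fp)
  rc <- if (cm$tp + cm$fn == 0) 0 else cm$tp / (cm$tp + cm$fn)
  c(precision = pr, recall = rc)
}

#' F-score
#'
#' Equally-weighted harmonic mean of precision and recall, 0 by convention
#' when both are 0.
#'
#' @param precision,recall values in [0, 1].
#' @return value in [0, 1].
#' @export
f_score <- function(precision, recall) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' All confusion-derived metrics for one evaluation
#'
#' @param truth,predicted aligned label vectors.
#' @param no_prediction flag a degenerate evaluation in which the model could
#'   make no informative prediction (e.g. single-gene marker absent from the
#'   test set); MCC and precision are assigned 0 in that case (recall and F1
#'   are already 0 since there are no true positives).
#' @return list of class \code{metric_set}: mcc, precision, recall, f1, the
#'   four counts, n, no_prediction.
#' @export
metric_set <- function(truth, predicted, no_prediction = FALSE) {
  cm <- confusion(truth, predicted)
  pr <- precision_recall(cm)
  m <- list(mcc = mcc(cm), precision = pr[["precision"]],
            recall = pr[["recall"]],
            f1 = f_score(pr[["precision"]], pr[["recall"]]),
            tp = cm$tp, tn = cm$tn, fp = cm$fp, fn = cm$fn,
            n = length(truth), no_prediction = no_prediction)
  if (no_prediction) {
    m$mcc <- 0
    m$precision <- 0
  }
  structure(m, class = "metric_set")
}

empty_metric_set <- function() {
  structure(list(mcc = NA_real_, precision = NA_real_, recall = NA_real_,
                 f1 = NA_real_, tp = NA_integer_, tn = NA_integer_,
                 fp = NA_integer_, fn = NA_integer_, n = 0L,
                 no_prediction = FALSE),
            class = "metric_set")
}

#' Assemble the per-drug comparison record
#'
#' Pairs the single-gene and multi-gene metric sets computed on identical
#' train/cv/test partitions of one drug, together with the drug's metadata
#' and test-set composition (imbalance is n_sensitive - n_resistant among
#' test-set truth labels).
#'
#' @param single named list of \code{metric_set}s (train, test; cv optional).
#' @param multi named list of \code{metric_set}s (train, cv, test).
#' @param meta list with drug_id and optionally class, marker_feature,
#'   marker_p, marker_direction, chosen_mtry, threshold.
#' @param test_truth character vector of test-set truth labels.
#' @return list of class \code{drug_comparison}.
#' @export
compare_drug <- function(single, multi, meta, test_truth) {
  stopifnot(!is.null(single$test), !is.null(multi$test))
  if (single$test$n != multi$test$n)
    stop("models evaluated on different test sets for drug ", meta$drug_id)
  structure(list(
    drug_id = meta$drug_id,
    class = if (is.null(meta$class)) "unknown" else meta$class,
    meta = meta,
    single = single,
    multi = multi,
    test_size = length(test_truth),
    test_imbalance = sum(test_truth == "sensitive") -
      sum(test_truth == "resistant")),
    class = "drug_comparison")
}

metrics_row <- function(drug_id, class, model, dataset, m) {
  data.frame(drug_id = drug_id, class = class, model = model,
             dataset = dataset, mcc = m$mcc, precision = m$precision,
             recall = m$recall, f1 = m$f1, tp = m$tp, tn = m$tn, fp = m$fp,
             fn = m$fn, n = m$n, no_prediction = m$no_prediction,
             stringsAsFactors = FALSE)
}

#' Tidy per-drug metric table
#'
#' @param comparisons list of \code{drug_comparison}s.
#' @return data.frame with one row per drug x model x dataset.
#' @export
comparison_table <- function(comparisons) {
  do.call(rbind, lapply(comparisons, function(cp) {
    rows <- list()
    for (model in c("single_gene", "multi_gene")) {
      ms <- if (model == "single_gene") cp$single else cp$multi
      for (ds in names(ms))
        if (!is.null(ms[[ds]]) && ms[[ds]]$n > 0)
          rows[[paste(model, ds)]] <-
            metrics_row(cp$drug_id, cp$class, model, ds, ms[[ds]])
    }
    do.call(rbind, rows)
  }))
}

spearman_or_flag <- function(x, y) {
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(rho = NA_real_, p = NA_real_, computable = FALSE))
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", alternative = "two.sided"))
  list(rho = unname(ct$estimate), p = ct$p.value, computable = TRUE)
}

#' Cohort-level summary of the paired comparisons
#'
#' Computes, over all compared drugs: per-metric counts of drugs where the
#' multi-gene model strictly beats the single-gene marker on the test set
#' (ties counted separately); the 2x2 sign table of test MCC (positive vs
#' non-positive, with exact zeros also reported as ties); mean and median of
#' every metric per model and dataset; the overfitting gap (mean training MCC
#' minus mean test MCC per model); two-tailed Spearman correlations of
#' multi-gene test MCC against test-set class imbalance and test-set size;
#' and the same win counts stratified by drug class.
#'
#' @param comparisons list of \code{drug_comparison}s (at least 2).
#' @return list of class \code{cohort_summary}.
#' @export
summarize_cohort <- function(comparisons) {
  if (length(comparisons) < 2L) stop("need at least two drug comparisons")
  tab <- comparison_table(comparisons)
  test <- tab[tab$dataset == "test", ]
  s <- test[test$model == "single_gene", ]
  m <- test[test$model == "multi_gene", ]
  s <- s[match(m$drug_id, s$drug_id), ]

  wins <- function(metric) {
    d <- m[[metric]] - s[[metric]]
    c(multi = sum(d > 0), single = sum(d < 0), tie = sum(d == 0))
  }
  win_counts <- sapply(c("mcc", "precision", "recall", "f1"), wins)

  sign_table <- matrix(
    c(sum(m$mcc > 0 & s$mcc > 0), sum(m$mcc > 0 & s$mcc <= 0),
      sum(m$mcc <= 0 & s$mcc > 0), sum(m$mcc <= 0 & s$mcc <= 0)),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("RF>0", "RF<=0"), c("single>0", "single<=0")))

  agg <- function(fun) stats::aggregate(
    tab[, c("mcc", "precision", "recall", "f1")],
    by = tab[, c("model", "dataset")], FUN = fun)
  means <- agg(mean)
  medians <- agg(stats::median)

  gap <- function(model) {
    tr <- tab[tab$model == model & tab$dataset == "train", "mcc"]
    te <- tab[tab$model == model & tab$dataset == "test", "mcc"]
    mean(tr) - mean(te)
  }

  imb <- vapply(comparisons, function(cp) cp$test_imbalance, 0)
  sz <- vapply(comparisons, function(cp) cp$test_size, 0)
  ord <- match(m$drug_id, vapply(comparisons, function(cp) cp$drug_id, ""))

  by_class <- lapply(split(seq_len(nrow(m)), m$class), function(i)
    sapply(c("mcc", "precision", "recall", "f1"), function(metric) {
      d <- m[[metric]][i] - s[[metric]][i]
      c(multi = sum(d > 0), single = sum(d < 0), tie = sum(d == 0))
    }))

  structure(list(
    n_drugs = nrow(m),
    win_counts = win_counts,
    mcc_ties_at_zero = sum(m$mcc == 0 | s$mcc == 0),
    sign_table = sign_table,
    means = means, medians = medians,
    overfitting_gap = c(single_gene = gap("single_gene"),
                        multi_gene = gap("multi_gene")),
    spearman_imbalance = spearman_or_flag(m$mcc, imb[ord]),
    spearman_test_size = spearman_or_flag(m$mcc, sz[ord]),
    win_counts_by_class = by_class),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary over %d drugs>\n", x$n_drugs))
  cat("test-set wins (multi/single/tie):\n")
  print(x$win_counts)
  cat("test MCC sign table:\n")
  print(x$sign_table)
  cat(sprintf("overfitting gap (train-test mean MCC): single %.3f, multi %.3f\n",
              x$overfitting_gap[["single_gene"]],
              x$overfitting_gap[["multi_gene"]]))
  invisible(x)
}

#' Write the cohort reports to disk
#'
#' Emits \code{per_drug_metrics.csv} (every metric per drug, model and
#' dataset), \code{sign_breakdown.csv} (the 2x2 test-MCC sign table plus a
#' per-drug winner list), and \code{cohort_summary.txt}.
#'
#' @param summary a \code{cohort_summary}.
#' @param comparisons the list of \code{drug_comparison}s it was built from.
#' @param out_dir output directory (created if needed).
#' @return invisible character vector of written paths.
#' @export
export_reports <- function(summary, comparisons, out_dir) {
  if (!length(comparisons)) stop("no comparisons to export")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- comparison_table(comparisons)
  num <- vapply(tab, is.numeric, TRUE) & !vapply(tab, is.integer, TRUE)
  tab[num] <- lapply(tab[num], function(v) sprintf("%.17g", v))
  p1 <- file.path(out_dir, "per_drug_metrics.csv")
  utils::write.csv(tab, p1, row.names = FALSE)

  test <- comparison_table(comparisons)
  test <- test[test$dataset == "test", ]
  s <- test[test$model == "single_gene", ]
  m <- test[test$model == "multi_gene", ]
  s <- s[match(m$drug_id, s$drug_id), ]
  sign_df <- data.frame(
    drug_id = m$drug_id,
    single_mcc = s$mcc, multi_mcc = m$mcc,
    single_positive = s$mcc > 0, multi_positive = m$mcc > 0,
    winner = ifelse(m$mcc > s$mcc, "multi_gene",
                    ifelse(m$mcc < s$mcc, "single_gene", "tie")),
    stringsAsFactors = FALSE)
  p2 <- file.path(out_dir, "sign_breakdown.csv")
  utils::write.csv(sign_df, p2, row.names = FALSE)

  p3 <- file.path(out_dir, "cohort_summary.txt")
  con <- file(p3, "w")
  sink(con); print(summary); sink()
  close(con)
  invisible(c(p1, p2, p3))
}
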