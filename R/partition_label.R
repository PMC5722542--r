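#' Drugs and features shared by two releases
#'
#' All downstream comparison is restricted to the drug ids and feature names
#' present in both releases, so every model sees the same feature panel.
#'
#' @param r1,r2 \code{\link{dataset_release}} objects.
#' @return list with character vectors \code{drugs} and \code{features}.
#' @export
common_panel <- function(r1, r2) {
  stopifnot(inherits(r1, "dataset_release"), inherits(r2, "dataset_release"))
  drugs <- intersect(unique(r1$responses$drug_id), unique(r2$responses$drug_id))
  features <- intersect(colnames(r1$features), colnames(r2$features))
  if (!length(drugs)) stop("releases share no drugs")
  if (!length(features)) stop("releases share no features")
  list(drugs = sort(drugs), features = features)
}

#' Build the time-stamped train/test split for one drug
#'
#' Training cell lines are those with a measured response in the first
#' release; test cell lines are those measured in the second release and not
#' in the training set. The two sets are disjoint by construction, so the test
#' set mimics prospectively acquired data.
#'
#' @param r1,r2 \code{\link{dataset_release}} objects.
#' @param drug_id drug to split.
#' @return list of class \code{time_stamped_split} with \code{drug_id},
#'   \code{training_cell_lines}, \code{test_cell_lines}.
#' @export
build_time_stamped_split <- function(r1, r2, drug_id) {
  train <- unique(r1$responses$cell_line_id[r1$responses$drug_id == drug_id])
  in_r2 <- unique(r2$responses$cell_line_id[r2$responses$drug_id == drug_id])
  test <- setdiff(in_r2, train)
  structure(list(drug_id = drug_id,
                 training_cell_lines = train,
                 test_cell_lines = test),
            class = "time_stamped_split")
}

#' Sensitivity threshold from training responses
#'
#' The per-drug threshold is the median training logIC50 (mean of the two
#' central order statistics for an even count); it is fixed at training time
#' and reused unchanged on the test set.
#'
#' @param training_responses numeric vector of training-set log10 uM values.
#' @return the threshold (log10 micromolar).
#' @export
compute_threshold <- function(training_responses) {
  if (!length(training_responses)) stop("no training responses")
  stats::median(training_responses)
}

#' Assign sensitive/resistant class labels
#'
#' A cell line is sensitive iff its logIC50 is strictly below the threshold;
#' values equal to the threshold are resistant (sensitivity is defined by
#' strictly lower concentration).
#'
#' @param responses numeric vector of log10 uM values.
#' @param threshold the per-drug threshold.
#' @return character vector in \code{c("sensitive", "resistant")}.
#' @export
assign_labels <- function(responses, threshold) {
  stopifnot(is.finite(threshold))
  ifelse(responses < threshold, "sensitive", "resistant")
}

# responses of one drug for a set of cell lines, in that order
drug_responses <- function(release, drug_id, cell_ids) {
  rec <- release$responses[release$responses$drug_id == drug_id, ]
  rec$log_ic50[match(cell_ids, rec$cell_line_id)]
}
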