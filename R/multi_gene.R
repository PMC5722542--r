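#' Random-forest configuration
#'
#' @param n_trees trees per forest (1000 by default, matching the evaluation
#'   protocol; smaller values trade variance for speed).
#' @param mtry_grid candidate values of mtry (features tried per split); NULL
#'   means the full grid 1..n_features, resolved at fit time.
#' @param cv_folds folds for cross-validated mtry selection.
#' @param selection_metric \code{"cv_mcc"} (maximised) or \code{"cv_rmse"}
#'   (root-mean-square error of the sensitive-vote fraction against the 0/1
#'   label, minimised).
#' @param vote_threshold sensitive-vote fraction strictly above which a cell
#'   line is predicted sensitive; exactly at the threshold is resistant.
#' @param seed integer seed for fold assignment and forest growth.
#' @return an object of class \code{forest_config}.
#' @export
forest_config <- function(n_trees = 1000L, mtry_grid = NULL, cv_folds = 10L,
                          selection_metric = c("cv_mcc", "cv_rmse"),
                          vote_threshold = 0.5, seed = 1L) {
  selection_metric <- match.arg(selection_metric)
  stopifnot(n_trees >= 1, cv_folds >= 2,
            vote_threshold > 0, vote_threshold < 1)
  structure(list(n_trees = as.integer(n_trees), mtry_grid = mtry_grid,
                 cv_folds = as.integer(cv_folds),
                 selection_metric = selection_metric,
                 vote_threshold = vote_threshold, seed = as.integer(seed)),
            class = "forest_config")
}

label_factor <- function(labels)
  factor(labels, levels = c("resistant", "sensitive"))

# stratified fold assignment; refolds (bounded) if a fold misses a class
stratified_folds <- function(labels, k, seed, max_retry = 20L) {
  y <- label_factor(labels)
  for (attempt in seq_len(max_retry)) {
    set.seed(seed + attempt - 1L)
    folds <- integer(length(y))
    for (lv in levels(y)) {
      idx <- which(y == lv)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(y[folds != f])) == 2L, TRUE))
    if (ok) {
      if (attempt > 1L) message("refolded ", attempt - 1L, " time(s)")
      return(folds)
    }
  }
  stop("could not build folds containing both classes")
}

#' Select mtry by stratified cross-validation
#'
#' For each candidate mtry, a forest is trained on each of \code{cv_folds}
#' training folds and scored out-of-fold; the same folds are reused across the
#' whole grid so candidates face identical partitions. The chosen mtry
#' maximises mean out-of-fold MCC (or minimises RMSE), ties going to the
#' smallest mtry.
#'
#' @param features binary feature matrix (training cell lines x features).
#' @param labels training class labels ("sensitive"/"resistant").
#' @param config a \code{\link{forest_config}}.
#' @return list: \code{chosen_mtry}, \code{cv_score_per_mtry} (named numeric),
#'   \code{cv_predictions} (out-of-fold predicted labels at the chosen mtry),
#'   \code{cv_votes} (out-of-fold sensitive-vote fractions), \code{folds}.
#' @export
cross_validate_mtry <- function(features, labels, config = forest_config()) {
  stopifnot(inherits(config, "forest_config"),
            nrow(features) == length(labels))
  y <- label_factor(labels)
  if (nlevels(droplevels(y)) < 2L)
    stop("training labels contain a single class")
  grid <- config$mtry_grid
  if (is.null(grid)) grid <- seq_len(ncol(features))
  grid <- sort(unique(as.integer(grid)))
  stopifnot(all(grid >= 1), all(grid <= ncol(features)))
  folds <- stratified_folds(labels, config$cv_folds, config$seed)

  votes <- matrix(NA_real_, nrow = length(y), ncol = length(grid),
                  dimnames = list(rownames(features), as.character(grid)))
  for (f in seq_len(config$cv_folds)) {
    tr <- folds != f
    for (j in seq_along(grid)) {
      set.seed(config$seed + 1000L * f + j)
      rf <- randomForest::randomForest(
        x = features[tr, , drop = FALSE], y = y[tr],
        ntree = config$n_trees, mtry = grid[j])
      votes[!tr, j] <- stats::predict(rf, features[!tr, , drop = FALSE],
                                      type = "prob")[, "sensitive"]
    }
  }
  pred_lab <- function(v) ifelse(v > config$vote_threshold,
                                 "sensitive", "resistant")
  scores <- vapply(seq_along(grid), function(j) {
    if (config$selection_metric == "cv_rmse")
      -sqrt(mean((votes[, j] - as.numeric(y == "sensitive"))^2))
    else
      mean(vapply(seq_len(config$cv_folds), function(f) {
        i <- folds == f
        mcc(confusion(as.character(y[i]), pred_lab(votes[i, j])))
      }, 0))
  }, 0)
  names(scores) <- as.character(grid)
  if (config$selection_metric == "cv_rmse") scores <- -scores
  best <- if (config$selection_metric == "cv_rmse")
    grid[which.min(scores)] else grid[which.max(scores)]
  j <- match(as.character(best), colnames(votes))
  list(chosen_mtry = best, cv_score_per_mtry = scores,
       cv_predictions = stats::setNames(pred_lab(votes[, j]), rownames(features)),
       cv_votes = votes[, j], folds = folds)
}

#' Train the final forest at a chosen mtry
#'
#' Fits the full-size ensemble on the entire training set and records the
#' training-set MCC (typically near 1; the gap to test MCC quantifies
#' overfitting).
#'
#' @param features binary training feature matrix.
#' @param labels training class labels.
#' @param mtry features tried per split.
#' @param config a \code{\link{forest_config}}.
#' @param cv result of \code{\link{cross_validate_mtry}}, attached if given.
#' @return list of class \code{selected_forest}: \code{model},
#'   \code{chosen_mtry}, \code{cv_score_per_mtry}, \code{training_mcc},
#'   \code{feature_names}, \code{config}.
#' @export
train_forest <- function(features, labels, mtry, config = forest_config(),
                         cv = NULL) {
  y <- label_factor(labels)
  if (nlevels(droplevels(y)) < 2L)
    stop("training labels contain a single class")
  stopifnot(mtry >= 1, mtry <= ncol(features))
  set.seed(config$seed)
  rf <- randomForest::randomForest(x = features, y = y,
                                   ntree = config$n_trees, mtry = mtry)
  obj <- structure(list(model = rf, chosen_mtry = as.integer(mtry),
                        cv_score_per_mtry = cv$cv_score_per_mtry,
                        feature_names = colnames(features),
                        config = config),
                   class = "selected_forest")
  train_pred <- predict_multi_gene(obj, features, rownames(features))
  obj$training_mcc <- mcc(confusion(as.character(y), train_pred$labels))
  obj
}

#' Predict classes with a trained forest
#'
#' Columns are aligned to the training feature order by name, so feature
#' matrices may arrive in any column order. A cell line is predicted
#' sensitive iff its sensitive-vote fraction strictly exceeds the vote
#' threshold (an exact tie is resistant).
#'
#' @param model a \code{selected_forest}.
#' @param features binary feature matrix containing all training features.
#' @param cell_ids cell lines to predict.
#' @return list: \code{labels} (named character), \code{vote_fraction}
#'   (named numeric).
#' @export
predict_multi_gene <- function(model, features, cell_ids) {
  stopifnot(inherits(model, "selected_forest"))
  missing <- setdiff(model$feature_names, colnames(features))
  if (length(missing))
    stop("feature matrix lacks training feature(s): ",
         paste(missing, collapse = ", "))
  x <- features[cell_ids, model$feature_names, drop = FALSE]
  votes <- stats::predict(model$model, x, type = "prob")[, "sensitive"]
  labels <- ifelse(votes > model$config$vote_threshold,
                   "sensitive", "resistant")
  list(labels = stats::setNames(labels, cell_ids),
       vote_fraction = stats::setNames(as.numeric(votes), cell_ids))
}

# deterministic per-drug seed derived from a cohort seed and the drug id,
# independent of drug processing order; kept below 2^31
drug_seed <- function(seed, drug_id) {
  h <- sum(utf8ToInt(drug_id) * seq_along(utf8ToInt(drug_id)) * 131L)
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
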