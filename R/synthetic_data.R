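#' Configuration for the synthetic two-release cohort generator
#'
#' Defaults mirror the scale of the public GDSC releases used for time-stamped
#' evaluation: 638 cell lines in the first release and 70 further lines in the
#' second, 71 binary features (67 genes, 3 fusions, msi), 127 drugs, and
#' drug-cell coverage of 57.6\% / 80.68\% per release.
#'
#' @param n_cell_lines_release1 cell lines present in release 1.
#' @param n_new_cell_lines_release2 additional cell lines in release 2.
#' @param n_features number of binary features (the last is msi, the three
#'   before it gene fusions).
#' @param n_drugs number of drugs.
#' @param prevalence_range (low, high) bounds for per-feature mutation
#'   frequencies, drawn log-uniformly.
#' @param drug_mix fractions of (single-driver, multi-driver, null) drugs;
#'   must sum to 1. Counts are allocated by largest-remainder rounding.
#' @param drivers_per_multi_drug planted drivers per multi-driver drug.
#' @param effect_size log10 micromolar shift per planted driver (negative =
#'   sensitising).
#' @param noise_sd measurement noise s.d. in log10 micromolar.
#' @param coverage length-2 fraction of drug-cell pairs measured per release.
#' @param cytotoxic_fraction fraction of drugs labelled cytotoxic (labels are
#'   deterministic and only feed stratified reporting).
#' @param seed integer seed driving every random draw.
#' @return an object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_cell_lines_release1 = 638,
                          n_new_cell_lines_release2 = 70,
                          n_features = 71,
                          n_drugs = 127,
                          prevalence_range = c(0.02, 0.3),
                          drug_mix = c(single_driver = 0.4,
                                       multi_driver = 0.4,
                                       null = 0.2),
                          drivers_per_multi_drug = 3,
                          effect_size = -1.0,
                          noise_sd = 0.5,
                          coverage = c(0.576, 0.8068),
                          cytotoxic_fraction = 14 / 127,
                          seed = 1L) {
  stopifnot(n_cell_lines_release1 >= 2, n_new_cell_lines_release2 >= 1,
            n_features >= 5, n_drugs >= 1,
            length(prevalence_range) == 2,
            prevalence_range[1] > 0, prevalence_range[2] < 1,
            prevalence_range[1] <= prevalence_range[2],
            length(drug_mix) == 3, all(drug_mix >= 0),
            abs(sum(drug_mix) - 1) < 1e-9,
            drivers_per_multi_drug >= 1, noise_sd >= 0,
            length(coverage) == 2, all(coverage > 0), all(coverage <= 1),
            cytotoxic_fraction >= 0, cytotoxic_fraction <= 1)
  if (drivers_per_multi_drug > n_features - 4)
    stop("drivers_per_multi_drug exceeds the available gene features")
  names(drug_mix) <- c("single_driver", "multi_driver", "null")
  structure(as.list(environment()), class = "cohort_config")
}

#' Read a cohort configuration from a YAML file
#'
#' @param path YAML file whose keys are \code{\link{cohort_config}} arguments.
#' @return a \code{cohort_config}.
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(cohort_config, vals)
}

# largest-remainder apportionment of n into integer counts ~ fractions
allocate_counts <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  left <- n - sum(counts)
  if (left > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(left)]] <- counts[order_rem[seq_len(left)]] + 1L
  }
  as.integer(counts)
}

#' Generate a two-release synthetic pharmacogenomic cohort
#'
#' Mutations are independent Bernoulli draws with per-feature prevalences
#' drawn log-uniformly from \code{prevalence_range}. Each drug's logIC50 for a
#' cell line is a drug baseline (N(0,1) log10 uM) plus the sum of planted
#' driver effects over the line's mutations plus Gaussian noise; a pair
#' measured in release 1 keeps the identical value in release 2. Release 2
#' contains every release-1 cell line plus new lines drawn from the same law,
#' and every release-1 measured pair plus newly sampled pairs up to the
#' release-2 coverage. Draws consume the seeded generator in a fixed order
#' (prevalences, mutations, baselines, driver assignment, noise, coverage), so
#' identical configs give bit-identical cohorts.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return list with components \code{release1}, \code{release2}
#'   (\code{\link{dataset_release}}) and \code{ground_truth} (see
#'   \code{\link{summarize_ground_truth}}).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  n1 <- config$n_cell_lines_release1
  n_all <- n1 + config$n_new_cell_lines_release2
  p <- config$n_features
  nd <- config$n_drugs
  cells <- sprintf("CL%04d", seq_len(n_all))
  n_genes <- p - 4L
  feats <- c(sprintf("GENE%02d", seq_len(n_genes)),
             "BCR_ABL", "MLL_AFF1", "EWS_FLI1", "msi")
  drugs <- sprintf("D%03d", seq_len(nd))

  # 1. prevalences (log-uniform), 2. mutation matrix over all release-2 lines
  prev <- exp(stats::runif(p, log(config$prevalence_range[1]),
                           log(config$prevalence_range[2])))
  X <- vapply(seq_len(p),
              function(j) stats::rbinom(n_all, 1L, prev[j]),
              integer(n_all))
  dimnames(X) <- list(cells, feats)

  # 3. per-drug baselines
  baseline <- stats::rnorm(nd)

  # 4. drug categories (deterministic) and driver assignment (sampled)
  counts <- allocate_counts(config$drug_mix, nd)
  category <- rep(c("single_driver", "multi_driver", "null"), counts)
  driver_pool <- setdiff(feats, "msi")
  drivers <- lapply(seq_len(nd), function(i) {
    k <- switch(category[i], single_driver = 1L,
                multi_driver = config$drivers_per_multi_drug, null = 0L)
    if (k == 0L) return(stats::setNames(numeric(0), character(0)))
    g <- sample(driver_pool, k)
    stats::setNames(rep(config$effect_size, k), g)
  })

  # 5. noise, one draw per drug-cell pair (shared across releases)
  noise <- matrix(stats::rnorm(nd * n_all, sd = config$noise_sd), nrow = nd)

  resp_mat <- matrix(baseline, nrow = nd, ncol = n_all) + noise
  for (i in seq_len(nd)) {
    eff <- drivers[[i]]
    if (length(eff))
      resp_mat[i, ] <- resp_mat[i, ] +
        as.numeric(X[, names(eff), drop = FALSE] %*% eff)
  }

  # 6. coverage masks; release-1 pairs are all retained in release 2
  m1 <- round(config$coverage[1] * nd * n1)
  pairs1 <- sample.int(nd * n1, m1)           # index into drugs x r1 cells
  idx1 <- cbind(drug = ((pairs1 - 1L) %% nd) + 1L,
                cell = ((pairs1 - 1L) %/% nd) + 1L)
  all1 <- (idx1[, "cell"] - 1L) * nd + idx1[, "drug"]  # in drugs x all cells
  m2 <- round(config$coverage[2] * nd * n_all)
  extra <- max(0L, m2 - length(all1))
  candidates <- setdiff(seq_len(nd * n_all), all1)
  all2 <- c(all1, sample(candidates, extra))
  idx2 <- cbind(drug = ((all2 - 1L) %% nd) + 1L,
                cell = ((all2 - 1L) %/% nd) + 1L)

  mk_resp <- function(idx) data.frame(
    drug_id = drugs[idx[, "drug"]],
    cell_line_id = cells[idx[, "cell"]],
    log_ic50 = resp_mat[idx],
    stringsAsFactors = FALSE)

  k_cyto <- round(config$cytotoxic_fraction * nd)
  cls <- rep("targeted", nd)
  if (k_cyto > 0)
    cls[unique(round(seq(1, nd, length.out = k_cyto)))] <- "cytotoxic"
  meta <- data.frame(drug_id = drugs, name = paste0("compound_", drugs),
                     class = cls, stringsAsFactors = FALSE)

  gt <- data.frame(drug_id = drugs, category = category, class = cls,
                   stringsAsFactors = FALSE)
  gt$drivers <- drivers

  list(release1 = dataset_release("release1", X[seq_len(n1), , drop = FALSE],
                                  mk_resp(idx1), meta),
       release2 = dataset_release("release2", X, mk_resp(idx2), meta),
       ground_truth = structure(gt, class = c("ground_truth", "data.frame")))
}

#' Tabulate the planted drivers of a synthetic cohort
#'
#' @param gt the \code{ground_truth} component of \code{\link{generate_cohort}}.
#' @return data.frame with one row per drug: category, class, number of
#'   drivers, and semicolon-separated driver names and effects.
#' @export
summarize_ground_truth <- function(gt) {
  stopifnot(inherits(gt, "ground_truth"))
  data.frame(
    drug_id = gt$drug_id,
    category = gt$category,
    class = gt$class,
    n_drivers = vapply(gt$drivers, length, 0L),
    drivers = vapply(gt$drivers, function(d) paste(names(d), collapse = ";"), ""),
    effects = vapply(gt$drivers, function(d) paste(d, collapse = ";"), ""),
    stringsAsFactors = FALSE)
}
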