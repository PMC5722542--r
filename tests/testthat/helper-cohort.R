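# Shared synthetic cohorts, built once per test run.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cohort_cache[[key]])) .cohort_cache[[key]] <- builder()
  .cohort_cache[[key]]
}

# small general-purpose cohort for io/partition/pipeline tests
small_cohort <- function() cached("small", function() {
  generate_cohort(cohort_config(
    n_cell_lines_release1 = 60, n_new_cell_lines_release2 = 30,
    n_features = 12, n_drugs = 6, prevalence_range = c(0.1, 0.3),
    coverage = c(0.9, 0.95), noise_sd = 0.5, seed = 2024L))
})

# fast forest settings for unit tests
tiny_forest <- function(seed = 1L)
  forest_config(n_trees = 60L, mtry_grid = c(2L, 6L), cv_folds = 5L,
                seed = seed)

# hand-built two-release pair: one drug, marker gene mutated only in
# release-1 cells, so the marker is absent from every test cell line
degenerate_marker_releases <- function() cached("degenerate", function() {
  set.seed(7)
  n1 <- 40; n2 <- 20
  cells <- sprintf("C%02d", seq_len(n1 + n2))
  feats <- c("GENE_A", "GENE_B", "GENE_C", "GENE_D")
  X <- matrix(rbinom((n1 + n2) * 4, 1, 0.25), ncol = 4,
              dimnames = list(cells, feats))
  X[, "GENE_A"] <- 0L
  X[seq_len(12), "GENE_A"] <- 1L          # mutants only among release-1 lines
  X[(n1 + 1):(n1 + n2), "GENE_A"] <- 0L
  resp_all <- -2 * X[, "GENE_A"] + rnorm(n1 + n2, sd = 0.3)
  r1 <- dataset_release("w1", X[seq_len(n1), ],
                        data.frame(drug_id = "DRUG1",
                                   cell_line_id = cells[seq_len(n1)],
                                   log_ic50 = resp_all[seq_len(n1)]))
  r2 <- dataset_release("w2", X,
                        data.frame(drug_id = "DRUG1", cell_line_id = cells,
                                   log_ic50 = resp_all))
  list(r1 = r1, r2 = r2)
})
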