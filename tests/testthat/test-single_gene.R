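test_that("association p-values match the two-group ANOVA oracle", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(20:80, 1)
    flag <- rbinom(n, 1, 0.3)
    if (sum(flag) < 3 || sum(1 - flag) < 3) next
    resp <- rnorm(n) - 0.8 * flag * (i %% 2)
    r <- test_association(resp, flag, min_mutants = 3)
    oracle <- summary(stats::aov(resp ~ factor(flag)))[[1]][["Pr(>F)"]][1]
    expect_equal(r$p_value, oracle, tolerance = 1e-12)
    expect_equal(r$effect_size, mean(resp[flag == 1]) - mean(resp[flag == 0]))
  }
})

test_that("a strongly sensitising mutation is detected with direction", {
  r <- test_association(c(-3, -3.1, -2.9, 0, 0.1, -0.1),
                        c(1, 1, 1, 0, 0, 0))
  expect_lt(r$p_value, 0.01)
  expect_identical(r$effect_direction, "sensitising")
})

test_that("sparse and degenerate features follow the stated conventions", {
  r <- test_association(rnorm(10), c(1, rep(0, 9)), min_mutants = 3)
  expect_false(r$testable)
  expect_identical(r$p_value, 1)
  # zero variance in both groups, equal means
  r2 <- test_association(rep(2, 6), c(1, 1, 1, 0, 0, 0))
  expect_identical(r2$p_value, 1)
  # zero variance, separated means: perfect separation
  r3 <- test_association(c(0, 0, 0, 5, 5, 5), c(1, 1, 1, 0, 0, 0))
  expect_identical(r3$p_value, 0)
  expect_identical(r3$effect_direction, "sensitising")
})

test_that("null associations produce uniform p-values", {
  set.seed(53)
  pvals <- replicate(300, {
    flag <- rbinom(60, 1, 0.3)
    while (sum(flag) < 3) flag <- rbinom(60, 1, 0.3)
    test_association(rnorm(60), flag)$p_value
  })
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("BH flagging matches a brute-force step-up oracle", {
  bh_oracle <- function(p, q) {
    m <- length(p)
    ord <- order(p)
    k <- max(c(0, which(p[ord] <= q * seq_len(m) / m)))
    sig <- logical(m)
    if (k > 0) sig[ord[seq_len(k)]] <- TRUE
    sig
  }
  set.seed(61)
  for (i in 1:20) {
    p <- c(runif(30), runif(10)^4)
    tab <- data.frame(drug_id = "d", feature_name = paste0("f", seq_along(p)),
                      p_value = p, effect_size = 0,
                      effect_direction = "sensitising", n_mutant = 5,
                      n_wildtype = 5, testable = TRUE,
                      adjusted_significant = NA)
    out <- adjust_pvalues(tab, fdr = 0.2)
    expect_identical(out$adjusted_significant, bh_oracle(p, 0.2))
  }
  tab3 <- data.frame(drug_id = "d", feature_name = c("a", "b", "c"),
                     p_value = c(0.001, 0.02, 0.9), effect_size = 0,
                     effect_direction = "sensitising", n_mutant = 5,
                     n_wildtype = 5, testable = TRUE,
                     adjusted_significant = NA)
  expect_identical(adjust_pvalues(tab3, fdr = 0.2)$adjusted_significant,
                   c(TRUE, TRUE, FALSE))
  tab3$p_value <- rep(1, 3)
  expect_false(any(adjust_pvalues(tab3, fdr = 0.2)$adjusted_significant))
  tab3$p_value <- c(0.008, 0.0085, 0.5)
  out <- adjust_pvalues(tab3, mode = "fixed")
  expect_identical(out$adjusted_significant, c(TRUE, FALSE, FALSE))
  expect_error(adjust_pvalues(tab3, fdr = 1.5), "fdr")
})

test_that("best-marker selection takes the lowest p-value with tie rules", {
  tab <- data.frame(drug_id = "d", feature_name = c("TP53", "MYCN"),
                    p_value = c(0.03, 0.002), effect_size = c(-1, -0.5),
                    effect_direction = "sensitising", n_mutant = 10,
                    n_wildtype = 50, testable = TRUE,
                    adjusted_significant = c(FALSE, TRUE))
  expect_identical(select_best_marker(tab)$feature_name, "MYCN")
  tie <- tab
  tie$p_value <- c(0.01, 0.01)
  expect_identical(select_best_marker(tie)$feature_name, "TP53")  # |effect|
  tie$effect_size <- c(-1, -1)
  expect_identical(select_best_marker(tie)$feature_name, "MYCN")  # name
  none <- tab
  none$testable <- FALSE
  expect_null(select_best_marker(none))
})

test_that("single-gene predictions depend only on the marker column", {
  co <- small_cohort()
  X <- co$release1$features
  mk <- structure(list(drug_id = "d", feature_name = colnames(X)[3],
                       p_value = 0.001, effect_direction = "sensitising",
                       effect_size = -1, adjusted_significant = TRUE),
                  class = "marker_classifier")
  cells <- rownames(X)
  pred <- predict_single_gene(mk, X, cells)
  expect_identical(unname(pred),
                   unname(ifelse(X[, 3] == 1, "sensitive", "resistant")))
  # permuting every other column leaves predictions unchanged
  Xp <- X
  set.seed(9)
  for (j in setdiff(seq_len(ncol(X)), 3)) Xp[, j] <- sample(Xp[, j])
  expect_identical(predict_single_gene(mk, Xp, cells), pred)
  # direction-aware mode inverts resistance-associated markers
  mk$effect_direction <- "resistance-associated"
  pred_dir <- predict_single_gene(mk, X, cells, direction_aware = TRUE)
  expect_identical(unname(pred_dir),
                   unname(ifelse(X[, 3] == 1, "resistant", "sensitive")))
  expect_error(predict_single_gene(mk, X[, -3], cells), "absent")
})

test_that("all-null cohorts yield few BH-significant drugs", {
  co <- generate_cohort(cohort_config(
    n_cell_lines_release1 = 150, n_new_cell_lines_release2 = 30,
    n_features = 20, n_drugs = 25, drug_mix = c(0, 0, 1),
    coverage = c(1, 1), seed = 17L))
  res <- list()
  for (d in unique(co$release1$responses$drug_id)) {
    rec <- co$release1$responses[co$release1$responses$drug_id == d, ]
    for (g in colnames(co$release1$features))
      res[[paste(d, g)]] <- test_association(
        rec$log_ic50, co$release1$features[rec$cell_line_id, g],
        drug_id = d, feature_name = g)
  }
  tab <- adjust_pvalues(associations_table(res), fdr = 0.2)
  hit <- tapply(tab$adjusted_significant, tab$drug_id, any)
  expect_lte(mean(hit), 0.25)
})
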