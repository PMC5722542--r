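# independent routes: MCC as the Pearson correlation of the 0/1 label
# vectors (NA for a constant vector maps to the zero convention), precision
# and recall as conditional proportions over the vectors themselves
oracle_metrics <- function(truth, pred) {
  t01 <- as.numeric(truth == "sensitive")
  p01 <- as.numeric(pred == "sensitive")
  m <- suppressWarnings(stats::cor(t01, p01))
  if (is.na(m)) m <- 0
  pr <- if (sum(p01) == 0) 0 else mean(t01[p01 == 1])
  rc <- if (sum(t01) == 0) 0 else mean(p01[t01 == 1])
  f1 <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  c(mcc = m, precision = pr, recall = rc, f1 = f1)
}

random_labels <- function(n) sample(c("sensitive", "resistant"), n,
                                    replace = TRUE)

test_that("confusion counts match a brute-force tally", {
  expect_identical(unclass(confusion(c("sensitive", "sensitive", "resistant",
                                       "resistant"),
                                     c("sensitive", "resistant", "sensitive",
                                       "resistant")))[c("tp", "fn", "fp", "tn")],
                   list(tp = 1L, fn = 1L, fp = 1L, tn = 1L))
  set.seed(101)
  truth <- random_labels(1000)
  pred <- random_labels(1000)
  cm <- confusion(truth, pred)
  tally <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (i in seq_along(truth)) {
    k <- if (truth[i] == "sensitive" && pred[i] == "sensitive") "tp"
         else if (truth[i] == "resistant" && pred[i] == "resistant") "tn"
         else if (pred[i] == "sensitive") "fp" else "fn"
    tally[k] <- tally[k] + 1
  }
  expect_equal(unlist(cm[c("tp", "tn", "fp", "fn")]), tally)
  cm2 <- confusion(truth, truth)
  expect_identical(cm2$fp + cm2$fn, 0L)
  expect_error(confusion(truth, pred[-1]), "length")
})

test_that("metric formulas agree with the correlation oracle", {
  expect_equal(mcc(confusion(rep(c("sensitive", "resistant"), each = 2),
                             rep(c("sensitive", "resistant"), each = 2))), 1)
  expect_equal(mcc(confusion(rep(c("sensitive", "resistant"), each = 2),
                             rep(c("resistant", "sensitive"), each = 2))), -1)
  set.seed(103)
  for (i in 1:500) {
    n <- sample(2:40, 1)
    truth <- random_labels(n)
    pred <- random_labels(n)
    m <- metric_set(truth, pred)
    o <- oracle_metrics(truth, pred)
    expect_equal(m$mcc, o[["mcc"]], tolerance = 1e-12)
    expect_equal(m$precision, o[["precision"]], tolerance = 1e-12)
    expect_equal(m$recall, o[["recall"]], tolerance = 1e-12)
    expect_equal(m$f1, o[["f1"]], tolerance = 1e-12)
  }
})

test_that("precision and recall reproduce the marker worked example", {
  # 3 true positives, 1 false positive, 57 missed sensitive lines
  truth <- c(rep("sensitive", 60), rep("resistant", 40))
  pred <- c(rep("sensitive", 3), rep("resistant", 57),
            "sensitive", rep("resistant", 39))
  cm <- confusion(truth, pred)
  pr <- precision_recall(cm)
  expect_equal(pr[["precision"]], 0.75)
  expect_equal(pr[["recall"]], 0.05)
  expect_equal(f_score(pr[["precision"]], pr[["recall"]]), 0.09375)
})

test_that("degenerate conventions hold", {
  all_res <- metric_set(c("sensitive", "resistant"),
                        c("resistant", "resistant"))
  expect_identical(all_res$precision, 0)
  expect_identical(all_res$mcc, 0)
  expect_identical(f_score(0, 0), 0)
  expect_identical(f_score(1, 1), 1)
  np <- metric_set(rep("sensitive", 3), rep("resistant", 3),
                   no_prediction = TRUE)
  expect_true(np$no_prediction)
  expect_identical(np$mcc, 0)
  expect_identical(np$precision, 0)
})

test_that("F1 lies between precision and recall when both are positive", {
  set.seed(107)
  for (i in 1:200) {
    pr <- runif(1); rc <- runif(1)
    f <- f_score(pr, rc)
    expect_lte(f, 1)
    expect_gte(f, min(pr, rc) - 1e-12)
    expect_lte(f, max(pr, rc) + 1e-12)
  }
  expect_equal(f_score(1, 1), 1)
})

make_cmp <- function(drug, s_test, m_test, class = "targeted",
                     truth = rep(c("sensitive", "resistant"), 5)) {
  compare_drug(single = list(train = s_test, test = s_test),
               multi = list(train = m_test, cv = m_test, test = m_test),
               meta = list(drug_id = drug, class = class),
               test_truth = truth)
}

test_that("drug comparison assembles paired records with imbalance", {
  set.seed(109)
  truth <- random_labels(10)
  pred <- random_labels(10)
  m <- metric_set(truth, pred)
  cp <- make_cmp("d1", m, m, truth = truth)
  expect_equal(cp$test_imbalance,
               sum(truth == "sensitive") - sum(truth == "resistant"))
  expect_equal(cp$test_size, 10)
  tab <- comparison_table(list(cp))
  expect_equal(tab$mcc[tab$model == "multi_gene" & tab$dataset == "test"],
               tab$mcc[tab$model == "single_gene" & tab$dataset == "test"])
  bal <- make_cmp("d2", m, m, truth = rep(c("sensitive", "resistant"), 5))
  expect_identical(bal$test_imbalance, 0L)
})

test_that("cohort summary counts wins and swaps them under model exchange", {
  set.seed(113)
  cmps <- lapply(1:6, function(i) {
    truth <- random_labels(20)
    s <- metric_set(truth, random_labels(20))
    m <- metric_set(truth, truth)  # multi model perfect
    make_cmp(paste0("d", i), s, m, truth = truth)
  })
  sm <- summarize_cohort(cmps)
  expect_equal(unname(sm$win_counts["multi", "recall"] +
                      sm$win_counts["single", "recall"] +
                      sm$win_counts["tie", "recall"]), 6)
  swapped <- lapply(cmps, function(cp) {
    tmp <- cp$single; cp$single <- cp$multi
    cp$multi <- list(train = tmp$train, cv = tmp$train, test = tmp$test)
    cp
  })
  sw <- summarize_cohort(swapped)
  for (metric in c("mcc", "precision", "recall", "f1")) {
    expect_equal(unname(sm$win_counts["multi", metric]),
                 unname(sw$win_counts["single", metric]))
    expect_equal(unname(sm$win_counts["tie", metric]),
                 unname(sw$win_counts["tie", metric]))
  }
  expect_equal(sum(sm$sign_table), 6)
})

test_that("constant MCCs flag the rank correlation as not computable", {
  truth <- rep(c("sensitive", "resistant"), 5)
  m <- metric_set(truth, truth)
  cmps <- lapply(1:3, function(i) make_cmp(paste0("d", i), m, m, truth = truth))
  sm <- summarize_cohort(cmps)
  expect_false(sm$spearman_imbalance$computable)
})

test_that("a planted monotone trend gives a significant positive rho", {
  # drugs constructed so multi-gene test MCC increases with test size
  set.seed(127)
  cmps <- lapply(1:12, function(i) {
    n <- 10 + 4 * i
    truth <- rep(c("sensitive", "resistant"), length.out = n)
    pred <- truth
    flip <- seq_len(max(0, round((12 - i) * n / 30)))
    pred[flip] <- ifelse(truth[flip] == "sensitive", "resistant", "sensitive")
    make_cmp(paste0("d", i), metric_set(truth, random_labels(n)),
             metric_set(truth, pred), truth = truth)
  })
  sm <- summarize_cohort(cmps)
  expect_true(sm$spearman_test_size$computable)
  expect_gt(sm$spearman_test_size$rho, 0.5)
  expect_lt(sm$spearman_test_size$p, 0.05)
  # cross-check against the direct rank-correlation oracle
  mccs <- vapply(cmps, function(cp) cp$multi$test$mcc, 0)
  sizes <- vapply(cmps, function(cp) cp$test_size, 0)
  ct <- stats::cor.test(mccs, sizes, method = "spearman")
  expect_equal(sm$spearman_test_size$rho, unname(ct$estimate))
  expect_equal(sm$spearman_test_size$p, ct$p.value)
})

test_that("report export round-trips metric values at full precision", {
  set.seed(131)
  cmps <- lapply(1:4, function(i) {
    truth <- random_labels(15)
    make_cmp(paste0("d", i), metric_set(truth, random_labels(15)),
             metric_set(truth, random_labels(15)), truth = truth)
  })
  sm <- summarize_cohort(cmps)
  out <- withr::local_tempdir()
  paths <- export_reports(sm, cmps, out)
  per_drug <- utils::read.csv(file.path(out, "per_drug_metrics.csv"))
  orig <- comparison_table(cmps)
  expect_equal(nrow(per_drug), nrow(orig))
  expect_identical(per_drug$mcc, orig$mcc)
  expect_identical(per_drug$f1, orig$f1)
  sign_df <- utils::read.csv(file.path(out, "sign_breakdown.csv"))
  expect_equal(nrow(sign_df), 4)
  expect_error(export_reports(sm, list(), out), "no comparisons")
})
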