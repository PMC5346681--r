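# A ranking object over n genes with the given positives placed at the
# stated ranks.
make_ranking <- function(n, positive_ranks) {
  genes <- sprintf("g%03d", seq_len(n))
  structure(list(metric = "degree", order = genes,
                 scores = stats::setNames(rev(seq_len(n)), genes),
                 tie_rule = "lexicographic", seed = NULL),
            class = "gene_ranking")
}

test_that("confusion counts follow the top-fraction rule", {
  rk <- make_ranking(100)
  # 5 of the 10 positives sit in the top 10
  pos <- gene_set(c(sprintf("g%03d", c(1, 3, 5, 7, 9)),
                    sprintf("g%03d", 51:55)))
  cc <- confusion_at_fraction(rk, pos, 0.10)
  expect_equal(cc[c("TP", "FP", "FN", "TN")],
               list(TP = 5L, FP = 5L, FN = 5L, TN = 85L))
  # fraction 0: nothing predicted
  cc0 <- confusion_at_fraction(rk, pos, 0)
  expect_equal(cc0[c("TP", "FP", "FN", "TN")],
               list(TP = 0L, FP = 0L, FN = 10L, TN = 90L))
  # fraction 1: everything predicted
  cc1 <- confusion_at_fraction(rk, pos, 1)
  expect_equal(cc1[c("TP", "FP", "FN", "TN")],
               list(TP = 10L, FP = 90L, FN = 0L, TN = 0L))
  # positives outside the ranking are a contract error
  expect_error(confusion_at_fraction(rk, gene_set("absent"), 0.1),
               "restrict_to_network")
})

test_that("metric formulas give the hand-computed values", {
  cc <- structure(list(TP = 5L, FP = 5L, TN = 85L, FN = 5L,
                       threshold_fraction = 0.1),
                  class = "confusion_counts")
  m <- classification_metrics(cc)
  expect_equal(unname(m["recall"]), 0.5)
  expect_equal(unname(m["accuracy"]), 0.9)
  expect_equal(unname(m["specificity"]), 85 / 90)
  # recall 1 when nothing is missed; specificity 1 when nothing is predicted
  full <- structure(list(TP = 10L, FP = 0L, TN = 90L, FN = 0L,
                         threshold_fraction = 1),
                    class = "confusion_counts")
  expect_equal(unname(classification_metrics(full)["recall"]), 1)
  none <- structure(list(TP = 0L, FP = 0L, TN = 90L, FN = 10L,
                         threshold_fraction = 0),
                    class = "confusion_counts")
  m0 <- classification_metrics(none)
  expect_equal(unname(m0["recall"]), 0)
  expect_equal(unname(m0["specificity"]), 1)
  expect_equal(unname(m0["accuracy"]), 0.9)
})

test_that("zero denominators yield NA with a note, never silent zeros", {
  cc <- structure(list(TP = 0L, FP = 5L, TN = 0L, FN = 0L,
                       threshold_fraction = 1),
                  class = "confusion_counts")
  expect_message(m <- classification_metrics(cc), "denominator")
  expect_true(is.na(m[["recall"]]))
})

test_that("an optional common denominator changes only recall", {
  rk <- make_ranking(100)
  pos <- gene_set(sprintf("g%03d", 1:10))
  cc <- confusion_at_fraction(rk, pos, 0.10)
  m_net <- classification_metrics(cc)
  m_all <- classification_metrics(cc, positives_total = 40)
  expect_equal(unname(m_net["recall"]), 1)
  expect_equal(unname(m_all["recall"]), 0.25)
  expect_equal(m_net[c("accuracy", "specificity")],
               m_all[c("accuracy", "specificity")])
})

test_that("curves match independent set-membership recounting", {
  set.seed(42)
  n <- 200
  genes <- sprintf("g%03d", sample.int(n))
  rk <- structure(list(metric = "degree", order = genes,
                       scores = stats::setNames(rev(seq_len(n)), genes),
                       tie_rule = "lexicographic", seed = NULL),
                  class = "gene_ranking")
  pos <- gene_set(sample(genes, 25))
  fr <- seq(0, 1, by = 0.05)
  cv <- evaluation_curve(rk, pos, fr)
  # oracle: recount membership directly at every fraction
  for (i in seq_along(fr)) {
    k <- floor(fr[i] * n + 1e-9)
    tp <- length(intersect(genes[seq_len(k)], pos$ids))
    expect_equal(cv$TP[i], tp)
    expect_equal(cv$TP[i] + cv$FP[i], k)          # conservation
    expect_equal(cv$TP[i] + cv$FN[i], 25)          # conservation
    expect_equal(cv$recall[i], tp / 25)
  }
  # monotonicity of recall and 1 - specificity; endpoint contract
  expect_true(all(diff(cv$recall) >= 0))
  expect_true(all(diff(1 - cv$specificity) >= 0))
  expect_equal(cv$recall[1], 0)
  expect_equal(cv$recall[length(fr)], 1)
  expect_equal(cv$specificity[length(fr)], 0)
})

test_that("a front-loaded ranking dominates every other ranking in recall", {
  n <- 100
  genes <- sprintf("g%03d", seq_len(n))
  pos <- gene_set(genes[1:10])
  front <- make_ranking(n)
  set.seed(5)
  other_order <- sample(genes)
  other <- structure(list(metric = "degree", order = other_order,
                          scores = stats::setNames(rev(seq_len(n)), other_order),
                          tie_rule = "lexicographic", seed = NULL),
                     class = "gene_ranking")
  fr <- seq(0, 1, by = 0.1)
  cv_front <- evaluation_curve(front, pos, fr)
  cv_other <- evaluation_curve(other, pos, fr)
  expect_true(all(cv_front$recall >= cv_other$recall))
  # front-loaded ranking reaches full recall exactly at |P|/N
  expect_equal(cv_front$recall[fr == 0.1], 1)
  expect_error(evaluation_curve(front, pos, c(0.5, 0.1)), "ascending")
})

test_that("curves serialize with all declared columns", {
  rk <- make_ranking(50)
  pos <- gene_set(sprintf("g%03d", 1:5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_curve(evaluation_curve(rk, pos, c(0, 0.5, 1)), f)
  df <- utils::read.delim(f)
  expect_equal(names(df), c("fraction", "TP", "FP", "TN", "FN",
                            "recall", "accuracy", "specificity"))
  expect_equal(nrow(df), 3L)
})
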