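# Exact one-sided Mann-Whitney p by enumerating all rank assignments:
# P(W >= observed) over all C(m+n, m) ways the combined ranks could fall.
enumerate_ranksum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2   # Mann-Whitney U for x
  combos <- utils::combn(m + n, m)
  ws <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mean(ws >= w_obs)
}

write_toy_maf <- function(path, rows) {
  writeLines(c("#version 2.4",
               "Hugo_Symbol\tEntrez_Gene_Id\tTumor_Sample_Barcode\tVariant_Classification",
               rows), path)
}

test_that("MAF parsing keeps one record per row and enforces columns", {
  f <- withr::local_tempfile(fileext = ".maf")
  write_toy_maf(f, c("TP53\t7157\tS1\tMissense_Mutation",
                     "TP53\t7157\tS2\tNonsense_Mutation",
                     "KRAS\t3845\tS1\tSilent"))
  rec <- read_maf(f, cancer_type = "LUAD")
  expect_equal(nrow(rec), 3L)
  expect_equal(length(unique(rec$sample)), 2L)
  expect_true(all(rec$cancer_type == "LUAD"))
  # silent filtering is opt-in and logged
  expect_message(rec2 <- read_maf(f, "LUAD", exclude_silent = TRUE), "Silent")
  expect_equal(nrow(rec2), 2L)
  # header-only file
  g <- withr::local_tempfile(fileext = ".maf")
  write_toy_maf(g, character(0))
  expect_equal(nrow(read_maf(g, "LUAD")), 0L)
  # missing required column is named in the error
  h <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode", "TP53\tS1"), h)
  expect_error(read_maf(h, "LUAD"), "Variant_Classification")
})

test_that("mutation frequency deduplicates per sample and divides by totals", {
  rec <- data.frame(
    gene = c("A", "A", "A", "A", "A", "B", "B", "B"),
    sample = c("S1", "S1", "S1", "S2", "S3", "S1", "S1", "S1"),
    cancer_type = "LUAD",
    variant_class = "Missense_Mutation")
  tab <- mutation_frequency(rec, total_samples = c(LUAD = 20))
  # A mutated in 3 of 20 samples, B (5 records, one sample) in 1 of 20
  expect_equal(frequency_of(tab, c("A", "B", "absent"), "LUAD"),
               c(3 / 20, 1 / 20, 0))
  # duplication of records never changes frequencies
  tab2 <- mutation_frequency(rbind(rec, rec), total_samples = c(LUAD = 20))
  expect_equal(tab2$freq, tab$freq)
  # inferred totals are the distinct observed samples (3 here)
  tab3 <- mutation_frequency(rec)
  expect_equal(frequency_of(tab3, "A", "LUAD"), 1)
  # declared totals below the observed count violate the contract
  expect_error(mutation_frequency(rec, total_samples = c(LUAD = 2)),
               "below the observed")
})

test_that("planted-rate frequencies land inside the binomial interval", {
  genes <- sprintf("m%03d", 1:40)
  rec <- generate_mutations(genes, genes[1:10], n_samples = 500,
                            baseline_rate = 0.02, planted_rate = 0.20,
                            seed = 17)
  tab <- mutation_frequency(rec)
  f_pos <- frequency_of(tab, genes[1:10], "SYNTH")
  ci <- stats::qbinom(c(0.005, 0.995), 500, 0.20) / 500
  expect_true(all(f_pos >= ci[1] & f_pos <= ci[2]))
})

test_that("one-sided rank-sum p matches exact enumeration", {
  rec <- data.frame(gene = sprintf("G%d", 1:6), sample = "S1",
                    cancer_type = "X", variant_class = "M")
  tab0 <- mutation_frequency(rec, total_samples = c(X = 10))
  # inject known frequencies by constructing counts: G1..G3 mutated in
  # 4,5,6 samples; G4..G6 in 1,2,3 samples (of 10)
  counts <- c(4, 5, 6, 1, 2, 3)
  rec2 <- do.call(rbind, lapply(1:6, function(i) {
    data.frame(gene = sprintf("G%d", i),
               sample = sprintf("S%d", seq_len(counts[i])),
               cancer_type = "X", variant_class = "M")
  }))
  tab <- mutation_frequency(rec2, total_samples = c(X = 10))
  top <- sprintf("G%d", 1:3); bottom <- sprintf("G%d", 4:6)
  res <- compare_rank_groups(tab, top, bottom, "X")
  # full enumeration of all C(6,3) = 20 rank assignments gives p = 1/20
  expect_equal(res$p_value, 0.05)
  expect_equal(res$p_value,
               enumerate_ranksum_p(c(0.4, 0.5, 0.6), c(0.1, 0.2, 0.3)))
  expect_equal(res$statistic, 9)   # Mann-Whitney U: all 3x3 pairs won
  # label swap moves the mass to the opposite tail
  swapped <- compare_rank_groups(tab, bottom, top, "X")
  expect_equal(swapped$p_value, 1)
  expect_equal(swapped$p_value,
               enumerate_ranksum_p(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6)))
  # identical groups cannot look enriched one-sidedly
  same <- compare_rank_groups(tab, top, top, "X")
  expect_gte(same$p_value, 0.5)
})

test_that("rank-sum test agrees with enumeration on random small samples", {
  set.seed(31)
  for (rep in 1:10) {
    x <- round(stats::runif(4), 3)   # distinct with prob ~1 after rounding
    y <- round(stats::runif(5), 3)
    if (anyDuplicated(c(x, y))) next
    rec <- do.call(rbind, lapply(seq_along(c(x, y)), function(i) {
      data.frame(gene = sprintf("R%d", i),
                 sample = sprintf("S%d", seq_len(round(1000 * c(x, y)[i]))),
                 cancer_type = "Z", variant_class = "M")
    }))
    tab <- mutation_frequency(rec, total_samples = c(Z = 1000))
    res <- compare_rank_groups(tab, sprintf("R%d", 1:4), sprintf("R%d", 5:9), "Z")
    expect_equal(res$p_value, enumerate_ranksum_p(x, y), tolerance = 1e-10)
  }
})

test_that("degenerate all-identical frequencies report p = 1 with a note", {
  rec <- data.frame(gene = c("A", "B"), sample = "S1", cancer_type = "X",
                    variant_class = "M")
  tab <- mutation_frequency(rec, total_samples = c(X = 10))
  expect_message(res <- compare_rank_groups(tab, "A", "B", "X"), "degenerate")
  expect_equal(res$p_value, 1)
  expect_true(res$degenerate)
  expect_error(compare_rank_groups(tab, character(0), "B", "X"), "nonempty")
})

test_that("type-I error sits at the nominal level on equal-rate tables", {
  genes <- sprintf("m%03d", 1:100)
  rej <- vapply(1:400, function(r) {
    rec <- generate_mutations(genes, character(0), n_samples = 50,
                              baseline_rate = 0.1, planted_rate = 0.1,
                              seed = 5000 + r)
    tab <- mutation_frequency(rec)
    compare_rank_groups(tab, genes[1:50], genes[51:100], "SYNTH")$p_value < 0.05
  }, logical(1))
  # 3 SE of 0.05 at 400 reps is ~0.033
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})

test_that("power grows with the planted effect size", {
  genes <- sprintf("m%03d", 1:60)
  power_at <- function(rate) {
    mean(vapply(1:60, function(r) {
      rec <- generate_mutations(genes, genes[1:30], n_samples = 50,
                                baseline_rate = 0.05, planted_rate = rate,
                                seed = 9000 + r * 7)
      tab <- mutation_frequency(rec)
      compare_rank_groups(tab, genes[1:30], genes[31:60], "SYNTH")$p_value < 0.05
    }, logical(1)))
  }
  pw <- c(power_at(0.05), power_at(0.10), power_at(0.25))
  expect_true(all(diff(pw) >= 0))
  expect_gt(pw[3], 0.9)
})

test_that("frequency matrices write genes by cancer types", {
  genes <- c("A", "B")
  rec <- rbind(
    generate_mutations(genes, "A", n_samples = 30, baseline_rate = 0.2,
                       planted_rate = 0.8, cancer_types = "C1", seed = 1),
    generate_mutations(genes, "A", n_samples = 30, baseline_rate = 0.2,
                       planted_rate = 0.8, cancer_types = "C2", seed = 2))
  attr(rec, "total_samples") <- c(C1 = 30L, C2 = 30L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_frequency_matrix(mutation_frequency(rec), f)
  df <- utils::read.delim(f)
  expect_setequal(names(df), c("gene", "C1", "C2"))
})
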