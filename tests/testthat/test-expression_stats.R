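test_that("FPKM follows its definition and scales linearly", {
  expect_equal(compute_fpkm(10, 1000, 1e6), 10)
  expect_equal(compute_fpkm(0, 1000, 1e6), 0)
  expect_equal(compute_fpkm(5, 500, 2e6), 5)
  expect_equal(compute_fpkm(20, 1000, 1e6), 2 * compute_fpkm(10, 1000, 1e6))
  expect_equal(compute_fpkm(10, 1000, 2e6), compute_fpkm(10, 1000, 1e6) / 2)
  expect_error(compute_fpkm(10, 1000, 0), "positive")
  expect_error(compute_fpkm(10, 0, 1e6), "positive")
})

test_that("protein per transcript is a guarded ratio", {
  expect_equal(protein_per_transcript(100, 10), 10)
  expect_equal(protein_per_transcript(0, 5), 0)
  expect_true(is.na(protein_per_transcript(10, 0)))   # flagged, not Inf
  expect_true(is.na(protein_per_transcript(10, NA)))
  expect_error(protein_per_transcript(-1, 5), ">= 0")
})

test_that("replicate FPKMs average within project before the ratio", {
  proteins <- data.frame(gene_id = "g1", abundance = 10)
  fpkm <- data.frame(gene_id = "g1", project = "P1", fpkm = c(4, 6))
  classes <- data.frame(gene_id = "g1", label = "SD-facilitated")
  rec <- build_expression_records(proteins, fpkm, classes)
  expect_equal(rec$mean_fpkm.P1, 5)
  expect_equal(rec$ppt.P1, 2)
  # zero-protein genes are excluded by default
  proteins0 <- data.frame(gene_id = c("g1", "g2"), abundance = c(10, 0))
  classes2 <- data.frame(gene_id = c("g1", "g2"),
                         label = c("SD-facilitated", "SD-independent"))
  expect_equal(nrow(build_expression_records(proteins0, fpkm, classes2)), 1)
})

test_that("the exact Wilcoxon branch reproduces enumeration results", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)  # most extreme split: 2 of 20 assignments
  expect_equal(r$statistic, 0)
  expect_equal(r$method, "exact enumeration")
  # identical multisets
  expect_equal(wilcoxon_rank_sum(c(1, 2, 5), c(1, 2, 5))$p_value, 1)
  # all values identical
  expect_equal(wilcoxon_rank_sum(rep(2, 4), rep(2, 3))$p_value, 1)
  # tied data against the brute-force permutation oracle
  a <- c(1, 1, 2); b <- c(2, 3, 3)
  expect_equal(wilcoxon_rank_sum(a, b)$p_value, brute_wilcoxon_p(a, b))
})

test_that("exact p matches the enumeration oracle on random small fixtures", {
  set.seed(14)
  for (i in 1:20) {
    na <- sample(2:8, 1); nb <- sample(2:8, 1)
    a <- sample(1:6, na, replace = TRUE)  # heavy ties
    b <- sample(1:6, nb, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(a, b)$p_value, brute_wilcoxon_p(a, b))
  }
})

test_that("the approximation branch equals wilcox.test and tracks the exact p", {
  set.seed(15)
  for (i in 1:10) {
    a <- round(rnorm(12, 0, 2), 1)
    b <- round(rnorm(15, 0.5, 2), 1)
    got <- wilcoxon_rank_sum(a, b)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
  }
  # normal approximation is close to enumeration already at n = 8..10
  for (i in 1:10) {
    a <- rnorm(sample(8:10, 1)); b <- rnorm(sample(8:10, 1))
    pe <- wilcoxon_rank_sum(a, b, exact = TRUE)$p_value
    pa <- wilcoxon_rank_sum(a, b, exact = FALSE)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("Kendall tau-b handles perfect order, reversal and ties", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(kendall_tau_b(x, x), 1)
  expect_equal(kendall_tau_b(x, -x), -1)
  expect_equal(kendall_tau_b(c(1, 2, 3, 4), c(1, 3, 2, 4)), 4 / 6,
               tolerance = 1e-12)
  expect_warning(res <- kendall_tau_b(rep(1, 5), 1:5), "tied")
  expect_true(is.na(res))
})

test_that("tau-b equals the pair-enumeration oracle, with and without ties", {
  set.seed(16)
  for (i in 1:20) {
    n <- sample(5:15, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:6, n, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    expect_equal(kendall_tau_b(x, y), brute_tau_b(x, y), tolerance = 1e-12)
  }
  # no ties: equals the classical tau
  x <- sample(1:12); y <- sample(1:12)
  expect_equal(kendall_tau_b(x, y), brute_tau_b(x, y), tolerance = 1e-12)
})

test_that("group contrasts report sizes, medians and a two-sided p", {
  set.seed(17)
  rec <- data.frame(
    label = rep(c("SD-facilitated", "SD-independent"), c(30, 25)),
    protein_abundance = c(rlnorm(30, log(100)), rlnorm(25, log(50))))
  ct <- contrast_groups(rec, "protein_abundance")
  expect_equal(ct$n_facilitated, 30)
  expect_equal(ct$n_independent, 25)
  expect_true(ct$p_value >= 0 && ct$p_value <= 1)
  expect_gt(ct$medians[["facilitated"]], ct$medians[["independent"]])
  # a single-gene class still computes through the exact branch
  rec1 <- data.frame(label = c("SD-facilitated", rep("SD-independent", 5)),
                     mfe = c(-2, -8, -7.5, -9, -6, -10))
  ct1 <- contrast_groups(rec1, "mfe")
  expect_equal(ct1$n_facilitated, 1)
  expect_equal(ct1$method, "exact enumeration")
  # an empty class names the filter
  rec2 <- data.frame(label = rep("SD-independent", 3), mfe = c(-1, -2, NA))
  expect_error(contrast_groups(rec2, "mfe"), "SD-facilitated.*mfe")
})

test_that("CDS read counting assigns multiplicity to the best gene only", {
  g <- simulate_genome(n_genes = 6, seed = 44)$genome
  genes <- g$genes
  reads <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    gene <- genes[i, ]
    rep <- g$replicons[[gene$replicon_id]]
    cds <- if (gene$strand == "+") {
      substr(rep$seq, gene$start_codon_ref, gene$start_codon_ref + gene$length_nt - 1)
    } else {
      rev_comp(substr(rep$seq, gene$start_codon_ref - gene$length_nt + 1,
                      gene$start_codon_ref))
    }
    data.frame(id = sprintf("%s_%d", gene$gene_id, i + 1),
               seq = substr(cds, 4, 43), mult = i + 1,
               stringsAsFactors = FALSE)
  }))
  cnt <- count_cds_reads(g, reads)
  expect_equal(cnt$count[match(genes$gene_id, cnt$gene_id)],
               as.numeric(2:7))
  expect_equal(attr(cnt, "total_mapped"), sum(2:7))
  fpkm <- compute_fpkm(cnt$count, cnt$length_nt, attr(cnt, "total_mapped"))
  expect_true(all(fpkm >= 0))
})
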