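TAIL <- "GAUCACCUCCUUU"

test_that("a canonical AGGAGG window yields the expected single duplex", {
  w <- paste0(strrep("C", 19), "AGGAGG", strrep("C", 5))
  m <- find_sd_matches(w, TAIL)
  expect_equal(nrow(m), 1)
  expect_equal(m$match_seq, "AGGAGG")
  expect_equal(c(m$p, m$q), c(-11, -6))
  expect_equal(c(m$t_lo, m$t_hi), c(6, 11))   # pairs CCUCCU
  expect_equal(m$d_to_start, 13)
})

test_that("windows without 4-nt complementarity yield no matches", {
  expect_equal(nrow(find_sd_matches(strrep("A", 30), TAIL)), 0)
  # poly-A pairs only the terminal UUU run (length 3 < 4)
  expect_equal(nrow(find_sd_matches(strrep("A", 30), TAIL, min_len = 3)), 28)
  # degenerate window shorter than min_len
  expect_equal(nrow(find_sd_matches("AGG", TAIL)), 0)
})

test_that("a full reverse-complement window gives exactly one maximal full-length duplex", {
  L <- nchar(TAIL)
  w <- paste0(strrep("G", 30 - L), sdscan:::rev_comp_rna(TAIL))
  m <- find_sd_matches(w, TAIL)
  full <- m[m$match_len == L, ]
  expect_equal(nrow(full), 1)
  expect_equal(c(full$p, full$q), c(-L, -1))
  expect_equal(c(full$t_lo, full$t_hi), c(1, L))
  expect_equal(full$d_to_start, L)
})

test_that("D_toStart follows the antiparallel duplex geometry", {
  expect_equal(compute_d_to_start(-11, 11, 13), 13)
  expect_equal(compute_d_to_start(-4, 13, 13), 4)    # no 3' overhang
  expect_equal(compute_d_to_start(-30, 4, 13), 39)   # documented maximum
})

test_that("the scanner equals the brute-force oracle on random window/tail pairs", {
  set.seed(101)
  for (i in 1:300) {
    w <- random_rna(sample(4:30, 1), runif(1, 0.25, 0.7))
    tl <- random_rna(sample(5:20, 1), runif(1, 0.3, 0.8))
    got <- find_sd_matches(w, tl)
    got <- got[order(got$p, got$t_hi), c("p", "q", "t_lo", "t_hi", "match_len")]
    rownames(got) <- NULL
    oracle <- brute_sd_scan(w, tl)
    oracle[] <- lapply(oracle, as.integer)
    expect_identical(got, oracle)
  }
})

test_that("reported D_toStart values stay inside their theoretical bounds", {
  set.seed(7)
  for (i in 1:100) {
    tl <- random_rna(sample(5:20, 1), 0.5)
    m <- find_sd_matches(random_rna(30, 0.5), tl)
    if (!nrow(m)) next
    expect_true(all(m$d_to_start >= 1))
    expect_true(all(m$d_to_start <= 30 + nchar(tl) - 4))
  }
})

test_that("shifting a planted SD one base toward the start codon drops D_toStart by one", {
  sd6 <- rna_to_dna(sdscan:::rev_comp_rna(substr(TAIL, 6, 11)))  # pairs CCUCCU
  d_at <- function(gap3p) {
    w <- paste0(strrep("C", 30 - 6 - gap3p), sd6, strrep("C", gap3p))
    m <- find_sd_matches(w, TAIL)
    expect_equal(nrow(m), 1)
    m$d_to_start
  }
  ds <- vapply(0:10, d_at, numeric(1))
  expect_equal(diff(ds), rep(1, 10))  # larger gap = further from start codon
  expect_equal(ds[1], compute_d_to_start(-6, 11, 13))
})

test_that("G:U wobble pairs are off by default and honoured when enabled", {
  # GGGGG can pair UCCUU (tail 8..12) only through G:U wobble
  w <- paste0(strrep("C", 20), "GGGGG", strrep("C", 5))
  expect_equal(nrow(find_sd_matches(w, TAIL)), 0)
  m_wob <- find_sd_matches(w, TAIL, wobble = TRUE)
  expect_gte(max(m_wob$match_len), 5)
})

test_that("classification follows the optimal D_toStart range", {
  w15 <- paste0(strrep("C", 13), "AGGAGG", strrep("C", 11))  # d = 15 + ...
  m <- find_sd_matches(w15, TAIL)
  cl <- classify_genes(cbind(gene_id = "g1", m), "g1", c(11, 21))
  expect_equal(cl$label, "SD-facilitated")
  expect_equal(cl$best_d, m$d_to_start[which.max(m$match_len)])
  # no matches at all
  cl0 <- classify_genes(find_sd_matches(strrep("A", 30), TAIL)[0, ],
                        "g2", c(11, 21))
  expect_equal(cl0$label, "SD-independent")
  expect_true(is.na(cl0$best_len))
})

test_that("an out-of-range match leaves the gene SD-independent but keeps its best match", {
  m <- data.frame(gene_id = "g1", p = -30, q = -27, t_lo = 10, t_hi = 13,
                  match_len = 4, match_seq = "AGGA", d_to_start = 30,
                  stringsAsFactors = FALSE)
  cl <- classify_genes(m, "g1", c(11, 21))
  expect_equal(cl$label, "SD-independent")
  expect_equal(cl$best_d, 30)
  # boundary: d exactly at the range edges is facilitated
  for (d in c(11, 21)) {
    m$d_to_start <- d
    expect_equal(classify_genes(m, "g1", c(11, 21))$label, "SD-facilitated")
  }
  m$d_to_start <- 25
  expect_equal(classify_genes(m, "g1", c(11, 21))$label, "SD-independent")
})

test_that("the best in-range match maximises length then minimises D_toStart", {
  m <- data.frame(gene_id = "g1",
                  p = c(-15, -16, -20), q = c(-12, -12, -16),
                  t_lo = c(9, 8, 9), t_hi = c(12, 12, 12),
                  match_len = c(4, 5, 5),
                  match_seq = c("AAGG", "AAGGA", "AAGGA"),
                  d_to_start = c(16, 17, 21), stringsAsFactors = FALSE)
  cl <- classify_genes(m, "g1", c(11, 21))
  expect_equal(cl$best_len, 5)
  expect_equal(cl$best_d, 17)
})

test_that("propose_optimal_range matches the exhaustive-interval oracle", {
  expect_equal(propose_optimal_range(rep(13, 10)), c(13, 13))
  set.seed(55)
  v_unif <- sample(1:100, 300, replace = TRUE)
  expect_equal(propose_optimal_range(v_unif, 0.6), brute_optimal_range(v_unif, 0.6))
  v_bim <- c(sample(12:18, 160, replace = TRUE), rep(30, 40))
  r <- propose_optimal_range(v_bim, 0.6)
  expect_equal(r, brute_optimal_range(v_bim, 0.6))
  expect_true(r[1] >= 12 && r[2] <= 18)
  # uniform support: shortest interval covers 60% of the span, leftmost on ties
  r2 <- propose_optimal_range(rep(1:100, each = 2), 0.6)
  expect_equal(r2, c(1, 60))
  expect_error(propose_optimal_range(integer(0)), "empty")
})

test_that("motif usage proportions count matched SD strings and sum to one", {
  m <- data.frame(gene_id = c("a", "b", "c"),
                  match_seq = c("AGGA", "GGAG", "AGGA"),
                  d_to_start = c(12, 13, 30), stringsAsFactors = FALSE)
  tab <- motif_usage_table(m)
  expect_equal(tab$proportion[tab$motif == "AGGA"], 2 / 3)
  expect_equal(tab$proportion[tab$motif == "GGAG"], 1 / 3)
  expect_equal(sum(tab$proportion), 1, tolerance = 1e-12)
  topt <- motif_usage_table(m, "optimal", c(11, 21))
  expect_equal(sum(topt$count), 2)
  expect_equal(nrow(motif_usage_table(m[0, ])), 0)
})

test_that("per-gene representatives keep one longest match per gene", {
  g <- simulate_genome(n_genes = 40, seed = 77)
  mm <- scan_genes(upstream_windows(g$genome), g$tail)
  rep <- sdscan:::representative_matches(mm)
  expect_false(anyDuplicated(rep$gene_id) > 0)
  for (gid in head(unique(mm$gene_id), 10)) {
    sub <- mm[mm$gene_id == gid, ]
    r <- rep[rep$gene_id == gid, ]
    expect_equal(r$match_len, max(sub$match_len))
    expect_equal(r$d_to_start,
                 min(sub$d_to_start[sub$match_len == max(sub$match_len)]))
  }
})
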