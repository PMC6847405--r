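make_query_fixture <- function(seed = 7) {
  rdna <- make_synthetic_rdna(seed = seed)
  list(rdna = rdna, query = build_query(rdna$seq))
}

pileup_from_counts <- function(counts, query) {
  structure(list(counts = counts, total_mapped = sum(counts),
                 total_reads = sum(counts), query = query),
            class = "tail_pileup")
}

test_that("query construction centres the core with 100-nt flanks", {
  set.seed(4)
  bg <- rna_to_dna(random_rna(1600, 0.5))
  while (grepl("CCTCC", bg, fixed = TRUE)) bg <- sub("CCTCC", "AATCC", bg)
  rdna <- paste0(substr(bg, 1, 1399), "CCTCC", substr(bg, 1405, 1600))
  # guard: the planted core must be unique for this fixture
  stopifnot(length(gregexpr("CCTCC", rdna, fixed = TRUE)[[1]]) == 1)
  q <- build_query(rdna)
  expect_equal(nchar(q$seq), 205)
  expect_equal(q$core_offset, 101)
  expect_equal(substr(q$seq, q$core_offset, q$core_offset + 4), "CCTCC")
})

test_that("query truncates with a flag when the core is near an end", {
  rdna <- paste0(strrep("A", 29), "CCTCC", strrep("G", 200))
  expect_warning(q <- build_query(rdna), "truncated")
  expect_true(q$truncated_5p)
  expect_equal(q$core_offset, 30)
  expect_equal(nchar(q$seq), 29 + 5 + 100)
})

test_that("multiple core occurrences require an explicit occurrence index", {
  rdna <- paste0(strrep("A", 120), "CCTCC", strrep("G", 120), "CCTCC",
                 strrep("A", 120))
  expect_error(build_query(rdna), "occurs 2 times")
  q <- build_query(rdna, occurrence = 2)
  expect_equal(substr(q$seq, q$core_offset, q$core_offset + 4), "CCTCC")
  expect_error(build_query(strrep("A", 300)), "not found")
})

test_that("an exact substring read contributes its multiplicity at its 3' end", {
  f <- make_query_fixture()
  read <- substr(f$query$seq, 91, 120)
  p <- map_read_ends(stats::setNames(read, "r1_7"), f$query)
  expect_equal(p$counts[120], 7)
  expect_equal(sum(p$counts), 7)
  expect_equal(p$total_mapped, 7)
  # below min_match: a 24-nt exact substring does not map
  p24 <- map_read_ends(stats::setNames(substr(f$query$seq, 97, 120), "r1_3"),
                       f$query)
  expect_equal(sum(p24$counts), 0)
  expect_equal(p24$total_mapped, 0)
})

test_that("reverse-complemented reads pile up at the brute-force 3' end", {
  f <- make_query_fixture()
  set.seed(11)
  for (k in 1:8) {
    s <- sample(30:150, 1)
    read <- rev_comp(substr(f$query$seq, s, s + 39))
    got <- map_reads_cpp(read, f$query$seq, 25L, 0.95)
    oracle <- brute_map_end(read, f$query$seq)
    expect_true(got[1, 1] == 1)
    expect_true(got[1, 2] %in% oracle$ends)
    expect_equal(got[1, 3], oracle$matchcols)
  }
})

test_that("the pileup is invariant to reverse-complementing every read", {
  f <- make_query_fixture()
  sim <- simulate_16s_reads(f$rdna$seq, f$rdna$terminus, depth = 300, seed = 5)
  p1 <- map_read_ends(sim$reads, f$query)
  rc <- sim$reads
  rc$seq <- rev_comp(rc$seq)
  p2 <- map_read_ends(rc, f$query)
  expect_identical(p1$counts, p2$counts)
})

test_that("pileup counts conserve multiplicity of reads whose 3' end is on the query", {
  f <- make_query_fixture()
  sim <- simulate_16s_reads(f$rdna$seq, f$rdna$terminus, depth = 200, seed = 9)
  p <- map_read_ends(sim$reads, f$query)
  expected <- 0
  for (i in seq_len(nrow(sim$reads))) {
    o <- brute_map_end(sim$reads$seq[i], f$query$seq)
    if (o$matchcols > 0 && any(o$ends > 0)) expected <- expected + sim$reads$mult[i]
  }
  expect_equal(sum(p$counts), expected)
  expect_lte(sum(p$counts), p$total_mapped)
})

test_that("strict multiplicity mode errors on malformed headers naming the read", {
  f <- make_query_fixture()
  reads <- stats::setNames(substr(f$query$seq, 91, 120), "readX")
  expect_error(map_read_ends(reads, f$query, multiplicity = "header"), "readX")
  expect_error(map_read_ends(character(0), f$query), "empty read set|unsupported")
})

test_that("FASTA+ and SAM ingestion give the same pileup as in-memory reads", {
  f <- make_query_fixture()
  sim <- simulate_16s_reads(f$rdna$seq, f$rdna$terminus, depth = 150, seed = 13)
  p0 <- map_read_ends(sim$reads, f$query)
  fa <- tempfile(fileext = ".fasta")
  write_fasta_plus(sim$reads, fa)
  expect_identical(map_read_ends(fa, f$query)$counts, p0$counts)
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:q\tLN:%d", nchar(f$query$seq)),
               sprintf("%s\t0\tq\t1\t60\t%dM\t*\t0\t0\t%s\t*",
                       sim$reads$id, nchar(sim$reads$seq), sim$reads$seq)),
             sam)
  expect_identical(map_read_ends(sam, f$query)$counts, p0$counts)
})

test_that("the caller picks the highest qualifying peak (brute-force check)", {
  f <- make_query_fixture()
  q <- f$query
  qrna <- dna_to_rna(q$seq)
  motif_start <- as.integer(regexpr("GAUCACCUCCUU[UA]", qrna))
  tstar <- motif_start + 12  # last base of the conserved 13-mer
  counts <- integer(nchar(q$seq))
  counts[tstar] <- 50
  counts[(tstar + 1):(tstar + 5)] <- c(2, 1, 1, 1, 1)
  counts[40] <- 400  # huge peak far outside the conserved motif: ineligible
  p <- pileup_from_counts(counts, q)
  tc <- call_prominent_tail(p)
  expect_equal(tc$terminus, tstar)
  expect_equal(tc$tail_seq, substr(qrna, motif_start, tstar))
  expect_true(grepl("CCUCC", tc$tail_seq, fixed = TRUE))
  expect_equal(tc$peak_count, 50)
  expect_equal(tc$downstream_sum, 6)
  # brute force: no candidate satisfying both criteria outscores the call
  cand <- sdscan:::tail_candidates(p, "GAUCACCUCCUUW", 4)
  for (t in cand$termini) {
    if (sdscan:::passes_downstream(counts, t, 5)) {
      expect_lte(counts[t], counts[tc$terminus])
    }
  }
})

test_that("sites whose tail lacks the CCUCC core are rejected as termini", {
  f <- make_query_fixture()
  q <- f$query
  qrna <- dna_to_rna(q$seq)
  motif_start <- as.integer(regexpr("GAUCACCUCCUU[UA]", qrna))
  core_end <- q$core_offset + q$core_len - 1
  counts <- integer(nchar(q$seq))
  counts[motif_start + 1] <- 90   # inside the motif span but 5' of the core end
  counts[core_end + 1] <- 40      # tail contains CCUCC: eligible
  p <- pileup_from_counts(counts, q)
  tc <- call_prominent_tail(p)
  expect_equal(tc$terminus, core_end + 1)
})

test_that("ties break toward the most upstream terminus and zero pileups fail", {
  f <- make_query_fixture()
  q <- f$query
  qrna <- dna_to_rna(q$seq)
  motif_start <- as.integer(regexpr("GAUCACCUCCUU[UA]", qrna))
  counts <- integer(nchar(q$seq))
  counts[motif_start + 9] <- 50    # two equal peaks > 5 sites apart so that
  counts[motif_start + 15] <- 50   # neither falls in the other's decay window
  tc <- call_prominent_tail(pileup_from_counts(counts, q))
  expect_equal(tc$terminus, motif_start + 9)
  expect_error(call_prominent_tail(pileup_from_counts(integer(nchar(q$seq)), q)),
               "no-call")
  # no qualifying candidate: error reports the best-failing one
  counts2 <- integer(nchar(q$seq))
  counts2[motif_start + 12] <- 5
  counts2[motif_start + 17] <- 200  # read-through just past the candidate span
  expect_error(call_prominent_tail(pileup_from_counts(counts2, q)), "best-failing")
})

test_that("secondary tails require both criteria and the count threshold", {
  f <- make_query_fixture()
  q <- f$query
  qrna <- dna_to_rna(q$seq)
  motif_start <- as.integer(regexpr("GAUCACCUCCUU[UA]", qrna))
  counts <- integer(nchar(q$seq))
  counts[motif_start + 12] <- 100
  counts[motif_start + 10] <- 30   # 30% of primary: reported
  p <- pileup_from_counts(counts, q)
  prim <- call_prominent_tail(p)
  sec <- detect_secondary_tails(p, prim)
  expect_length(sec, 1)
  expect_equal(sec[[1]]$terminus, motif_start + 10)
  expect_equal(sec[[1]]$tail_seq, substr(qrna, motif_start, motif_start + 10))
  # a 10%-of-primary peak is below the default threshold
  counts[motif_start + 10] <- 10
  p2 <- pileup_from_counts(counts, q)
  expect_length(detect_secondary_tails(p2, call_prominent_tail(p2)), 0)
})

test_that("the trimmer drops low-quality reads, cuts adapters and enforces length", {
  reads <- data.frame(id = c("a_1", "b_1", "c_1"),
                      seq = c(paste0(strrep("ACGT", 10), "AGATCGGAAGAG"),
                              strrep("ACGT", 10),
                              strrep("AC", 14)),
                      mult = 1,
                      qual = c(strrep("I", 52), strrep("#", 40), strrep("I", 28)),
                      stringsAsFactors = FALSE)
  out <- trim_reads(reads, adapters = "AGATCGGAAGAG")
  expect_equal(out$id, c("a_1", "c_1"))   # b dropped on quality
  expect_equal(out$seq[1], strrep("ACGT", 10))  # adapter removed
  out2 <- trim_reads(reads[3, ], min_len = 30)
  expect_equal(nrow(out2), 0)
})
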