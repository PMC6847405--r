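# Independent brute-force oracles used to check the package implementations.
# These deliberately use different algorithms from the package code paths.

wc_pair_chr <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "G" & b == "C") | (a == "C" & b == "G")
}

# All maximal antiparallel Watson-Crick duplexes by run-start detection over
# every (window position, tail position) anchor pair.
brute_sd_scan <- function(window, tail, min_len = 4) {
  w <- strsplit(dna_to_rna(window), "", fixed = TRUE)[[1]]
  t <- strsplit(dna_to_rna(tail), "", fixed = TRUE)[[1]]
  W <- length(w); L <- length(t)
  rows <- list()
  for (a in seq_len(W)) {
    for (b in seq_len(L)) {
      if (!wc_pair_chr(w[a], t[b])) next
      # only anchor at the start of a run (not extendable 5' on the window)
      if (a > 1 && b < L && wc_pair_chr(w[a - 1], t[b + 1])) next
      len <- 1
      while (a + len <= W && b - len >= 1 && wc_pair_chr(w[a + len], t[b - len])) {
        len <- len + 1
      }
      if (len >= min_len) {
        rows[[length(rows) + 1]] <- data.frame(
          p = a - W - 1L, q = a + len - 1L - W - 1L,
          t_lo = b - len + 1L, t_hi = b,
          match_len = len, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(p = integer(0), q = integer(0), t_lo = integer(0),
                      t_hi = integer(0), match_len = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$t_hi), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Transcript-orientation 3'-end query position of a read under the ungapped
# contract, by exhaustive enumeration of orientation x diagonal x segment.
# Per diagonal the best-scoring (+1 match / -19 mismatch) segment is selected
# and must meet the length/identity thresholds; returns the maximal matching
# columns and the set of optimal 3' ends (0 = extrapolated end off query).
brute_map_end <- function(read, query, min_match = 25, min_identity = 0.95) {
  q <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  ql <- length(q)
  best_mc <- -1
  ends <- integer(0)
  for (orient in c("fwd", "rc")) {
    r <- if (orient == "fwd") toupper(read) else rev_comp(read)
    rc <- strsplit(r, "", fixed = TRUE)[[1]]
    rl <- length(rc)
    for (d in seq(-(rl - 1), ql - 1)) {
      i <- seq_len(rl)
      ok <- i + d >= 1 & i + d <= ql
      if (sum(ok) < min_match) next
      idx <- i[ok]
      match <- rc[idx] == q[idx + d] & rc[idx] != "N"
      sc <- ifelse(match, 1, -19)
      n <- length(idx)
      cs <- c(0, cumsum(sc))
      cm <- c(0, cumsum(match))
      # enumerate all (s, e) segment scores at once
      score_m <- outer(cs[-1], cs[-(n + 1)], `-`)     # score(e, s) = cs[e+1]-cs[s]
      score_m[!lower.tri(score_m, diag = TRUE)] <- -Inf  # require e >= s
      best <- which(score_m == max(score_m), arr.ind = TRUE)[1, ]
      e <- best[["row"]]; s <- best[["col"]]
      if (score_m[e, s] <= 0) next
      len <- e - s + 1
      mc <- cm[e + 1] - cm[s]
      if (len < min_match || mc / len < min_identity) next
      end <- rl + d
      end <- if (end >= 1 && end <= ql) end else 0L
      if (mc > best_mc) {
        best_mc <- mc
        ends <- end
      } else if (mc == best_mc) {
        ends <- union(ends, end)
      }
    }
  }
  list(matchcols = best_mc, ends = ends)
}

# Exact two-sided Wilcoxon p by enumeration over raw-value group assignments.
brute_wilcoxon_p <- function(a, b) {
  pool <- c(a, b)
  N <- length(pool); na <- length(a)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- combn(N, na)
  us <- apply(combs, 2, function(ix) sum(r[ix]) - na * (na + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Kendall tau-b by direct pair enumeration.
brute_tau_b <- function(x, y) {
  n <- length(x)
  C <- D <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (C - D) / sqrt((n0 - n1) * (n0 - n2))
}

# Shortest integer interval holding >= mass of the values, exhaustively.
brute_optimal_range <- function(v, mass = 0.6) {
  v <- as.integer(v)
  lo_all <- min(v):max(v)
  best <- NULL
  for (lo in lo_all) {
    for (hi in lo:max(v)) {
      if (mean(v >= lo & v <= hi) >= mass) {
        w <- hi - lo
        if (is.null(best) || w < best$w || (w == best$w && lo < best$lo)) {
          best <- list(lo = lo, hi = hi, w = w)
        }
        break  # larger hi only widens
      }
    }
  }
  c(best$lo, best$hi)
}

# All permutations of a vector (small n only).
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

random_rna <- function(n, gc = 0.5) {
  paste(sample(c("A", "U", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# A tiny three-gene genome used across the I/O tests: two plus-strand genes
# (one pseudo) and one minus-strand gene on a linear replicon.
toy_genome <- function(circular = FALSE) {
  up1 <- "TTAGGAGGTTTTT"                       # abuts gene A's ATG
  cdsA <- "ATGAAACCCGGGTAA"
  up2 <- "ACGTACGTAC"
  cdsB <- "ATGTTTAAATAA"                        # pseudo
  cdsC <- "ATGGGGTTTTAA"                        # minus strand
  lead <- strrep("C", 20)
  mid <- "GACTGACTGA"
  tailseq <- strrep("G", 25)
  seq <- paste0(lead, up1, cdsA, up2, cdsB, mid, rev_comp(cdsC), tailseq)
  startA <- nchar(lead) + nchar(up1) + 1
  startB <- nchar(lead) + nchar(up1) + nchar(cdsA) + nchar(up2) + 1
  startC_ref <- nchar(lead) + nchar(up1) + nchar(cdsA) + nchar(up2) +
    nchar(cdsB) + nchar(mid) + nchar(cdsC)     # last base of revcomp block
  genes <- data.frame(
    gene_id = c("geneA", "geneB", "geneC"),
    replicon_id = "toy1",
    strand = c("+", "+", "-"),
    start_codon_ref = c(startA, startB, startC_ref),
    length_nt = c(nchar(cdsA), nchar(cdsB), nchar(cdsC)),
    is_pseudo = c(FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  sd_genome(list(toy1 = list(seq = seq, circular = circular)), genes)
}
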