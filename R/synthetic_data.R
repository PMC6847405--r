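# Synthetic fixtures with recorded ground truth: 16S read sets with a
# planted mature 3' terminus, annotated genomes with SDs planted at known
# D_toStart, and expression tables with a planted class effect. One global
# seed expands to per-stage seeds through a fixed splitting rule so stages
# are independently reproducible.

random_dna <- function(n, gc = 0.5, composition = NULL) {
  prob <- if (!is.null(composition)) {
    composition[c("A", "T", "G", "C")] / sum(composition)
  } else {
    c(A = (1 - gc) / 2, T = (1 - gc) / 2, G = gc / 2, C = gc / 2)
  }
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE, prob = prob),
        collapse = "")
}

#' Synthetic 16S rDNA reference with a planted mature terminus
#'
#' Generates a random rDNA sequence containing exactly one CCTCC core,
#' carried by the conserved `GATCACCTCCTTT` block whose last base is the
#' planted mature 3' terminus; downstream sequence emulates the unprocessed
#' precursor.
#'
#' @param length total sequence length (default 1600 nt, 16S-like).
#' @param terminus position of the planted mature 3'-terminal base (default
#'   `length - 120`, leaving a full downstream query flank).
#' @param motif planted conserved block (DNA; default `GATCACCTCCTTT`).
#' @param gc background GC content (default 0.5).
#' @param seed RNG seed.
#' @return list with `seq` (DNA), `terminus`, `motif`.
#' @export
make_synthetic_rdna <- function(length = 1600, terminus = length - 120,
                                motif = "GATCACCTCCTTT", gc = 0.5,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mlen <- nchar(motif)
  stopifnot(terminus > mlen, terminus <= length)
  repeat {
    bg <- random_dna(length, gc)
    seq <- paste0(substr(bg, 1, terminus - mlen), motif,
                  substr(bg, terminus + 1, length))
    # exactly one CCTCC core (the planted one)
    if (length(gregexpr("CCTCC", seq, fixed = TRUE)[[1]]) == 1) break
  }
  list(seq = seq, terminus = terminus, motif = motif)
}

#' Simulate 16S RNA-Seq reads with a planted 3' terminus
#'
#' A configured fraction of reads ends exactly at the planted terminus;
#' downstream noise reads end at geometrically decaying distances past it
#' (precursor leakage) and upstream noise reads end uniformly within the
#' mature body. Reads are exact substrings of the rDNA ending at their
#' assigned 3' position. Deterministic given `seed`.
#'
#' @param rdna rDNA sequence (DNA string).
#' @param terminus planted 3'-terminal position within `rdna`.
#' @param depth total read count (default 1000).
#' @param noise list with `upstream_frac` (default 0.25), `downstream_frac`
#'   (default 0.15) and `downstream_geom_p` (default 0.5); the remaining
#'   fraction ends exactly at the terminus. Set both fractions to 0 for a
#'   noise-free pileup.
#' @param read_len read length (default 50); `terminus` must be at least
#'   `read_len` into the sequence.
#' @param upstream_span how far upstream noise 3' ends may fall (default 100).
#' @param seed RNG seed.
#' @return list with `reads` (data.frame `id`, `seq`, `mult`, multiplicity
#'   headers in the `SeqID_count` convention) and `truth` (`terminus`,
#'   `depth`, `noise`, `seed`).
#' @export
simulate_16s_reads <- function(rdna, terminus, depth = 1000,
                               noise = list(upstream_frac = 0.25,
                                            downstream_frac = 0.15,
                                            downstream_geom_p = 0.5),
                               read_len = 50, upstream_span = 100,
                               seed = NULL) {
  rdna <- toupper(rdna)
  n <- nchar(rdna)
  stopifnot(terminus <= n, depth > 0)
  if (terminus < read_len) {
    stop("terminus is closer than read_len to the sequence start", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  up <- noise$upstream_frac %||% 0.25
  dn <- noise$downstream_frac %||% 0.15
  gp <- noise$downstream_geom_p %||% 0.5
  stopifnot(up + dn < 1)
  cnt <- as.vector(stats::rmultinom(1, depth, c(1 - up - dn, up, dn)))
  ends <- c(rep(terminus, cnt[1]),
            if (cnt[2] > 0) sample(seq.int(max(read_len, terminus - upstream_span),
                                           terminus - 1), cnt[2], replace = TRUE),
            if (cnt[3] > 0) pmin(n, terminus + 1 + stats::rgeom(cnt[3], gp)))
  seqs <- substring(rdna, ends - read_len + 1, ends)
  tab <- table(seqs)
  reads <- data.frame(
    id = sprintf("S%04d_%d", seq_along(tab), as.integer(tab)),
    seq = names(tab), mult = as.integer(tab),
    stringsAsFactors = FALSE)
  list(reads = reads,
       truth = list(terminus = terminus, depth = depth, noise = noise,
                    read_len = read_len, seed = seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write reads as multiplicity-header FASTA
#'
#' @param reads data.frame with `id`, `seq` (ids already in `SeqID_count`
#'   form, as produced by [simulate_16s_reads()]).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_fasta_plus <- function(reads, path) {
  writeLines(as.vector(rbind(paste0(">", reads$id), reads$seq)), path)
  invisible(path)
}

# ---- synthetic genomes ------------------------------------------------------

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_cds <- function(n_codons) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, STOP_CODONS)
  paste0("ATG", paste(sample(sense, n_codons, replace = TRUE), collapse = ""), "TAA")
}

# Plant a window-side SD (reverse complement of tail[t_lo..t_hi]) into a
# random 30-nt window so that D_toStart equals d; reject windows where the
# planted duplex is not the unique longest maximal match.
plant_sd_window <- function(tail_rna, m, d, gc, min_len = 4, max_tries = 200,
                            composition = NULL) {
  L <- nchar(tail_rna)
  W <- 30L
  lo <- max(m, m + L - d)
  hi <- min(L, W + L - d)
  if (lo > hi) return(NULL)
  t_hi_ok <- seq.int(lo, hi)
  for (try in seq_len(max_tries)) {
    t_hi <- if (length(t_hi_ok) == 1) t_hi_ok else sample(t_hi_ok, 1)
    t_lo <- t_hi - m + 1
    sd_rna <- rev_comp_rna(substr(tail_rna, t_lo, t_hi))
    p <- -(d - (L - t_hi))
    i0 <- p + W + 1
    w <- strsplit(random_dna(W, gc, composition), "", fixed = TRUE)[[1]]
    w[i0:(i0 + m - 1)] <- strsplit(rna_to_dna(sd_rna), "", fixed = TRUE)[[1]]
    w <- paste(w, collapse = "")
    mm <- find_sd_matches(w, tail_rna, min_len)
    if (!nrow(mm)) next
    top <- max(mm$match_len)
    if (top != m || sum(mm$match_len == m) != 1) next
    rep <- mm[order(-mm$match_len, mm$d_to_start), ][1, ]
    if (rep$d_to_start == d && rep$match_len == m) {
      return(list(window = w, motif = sd_rna, t_lo = t_lo, t_hi = t_hi))
    }
  }
  NULL
}

rev_comp_rna <- function(x) dna_to_rna(rev_comp(rna_to_dna(x)))

#' Simulate an annotated genome with planted SD sequences
#'
#' Builds a circular replicon of `n_genes` protein-coding genes (random
#' strands), each preceded by a 30-nt upstream window drawn from an i.i.d.
#' composition model. With probability `sd_fraction` a gene receives a
#' planted SD: the reverse complement of a random tail substring of length
#' `>= 4`, positioned so its D_toStart equals a draw from `d_sampler`.
#' Planting rejects windows in which a spurious equal-or-longer duplex
#' arises, so the planted match is the unique longest and the scanner's
#' per-gene representative recovers the planted D_toStart exactly.
#'
#' @param n_genes number of genes (default 500).
#' @param sd_fraction fraction of genes with a planted SD (default 0.6).
#' @param d_sampler function(n) drawing planted D_toStart values (default
#'   uniform on 11..21, the preferred range scale).
#' @param tail anti-SD tail (RNA, default `GAUCACCUCCUUU`).
#' @param gc background GC content of windows/CDS bodies (default 0.45).
#' @param composition optional named base probabilities (`A`,`C`,`G`,`T`)
#'   for window/spacer backgrounds, overriding `gc`; lets nulls be biased
#'   for or against tail complementarity.
#' @param len_sampler function(n) drawing CDS codon counts (default uniform
#'   30..80 codons).
#' @param match_len_sampler function(n) drawing planted duplex lengths
#'   (default 4..6 with decaying weights).
#' @param seed RNG seed.
#' @return list with `genome` (an [sd_genome]), `truth` (data.frame
#'   `gene_id`, `planted`, `motif`, `match_len`, `d_planted`, `strand`) and
#'   `tail`.
#' @export
simulate_genome <- function(n_genes = 500, sd_fraction = 0.6,
                            d_sampler = function(n) sample(11:21, n, replace = TRUE),
                            tail = "GAUCACCUCCUUU", gc = 0.45,
                            composition = NULL,
                            len_sampler = function(n) sample(30:80, n, replace = TRUE),
                            match_len_sampler = function(n)
                              sample(4:6, n, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
                            seed = NULL) {
  stopifnot(sd_fraction >= 0, sd_fraction <= 1)
  tail <- assert_rna(dna_to_rna(tail), "tail")
  if (!is.null(seed)) set.seed(seed)
  planted <- stats::runif(n_genes) < sd_fraction
  ds <- d_sampler(n_genes)
  ms <- match_len_sampler(n_genes)
  codons <- len_sampler(n_genes)
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  pieces <- character(0)
  pos <- 1L
  gene_rows <- truth_rows <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    spacer <- random_dna(sample(20:50, 1), gc, composition)
    pieces <- c(pieces, spacer)
    pos <- pos + nchar(spacer)
    gid <- sprintf("SYN%04d", i)
    win <- NULL
    if (planted[i]) {
      for (k in 1:25) {  # bounded retries over fresh (m, d) draws
        win <- plant_sd_window(tail, ms[i], ds[i], gc, composition = composition)
        if (!is.null(win)) break
        ms[i] <- match_len_sampler(1)
        ds[i] <- d_sampler(1)
      }
      if (is.null(win)) stop("could not plant SD for gene ", gid, call. = FALSE)
      wseq <- win$window
    } else {
      wseq <- random_dna(30, gc, composition)
    }
    cds <- random_cds(codons[i])
    cl <- nchar(cds)
    block <- paste0(wseq, cds)
    if (strands[i] == "+") {
      start_ref <- pos + 30L
      pieces <- c(pieces, block)
    } else {
      start_ref <- pos + cl - 1L
      pieces <- c(pieces, rev_comp(block))
    }
    pos <- pos + nchar(block)
    gene_rows[[i]] <- data.frame(
      gene_id = gid, replicon_id = "synrep1", strand = strands[i],
      start_codon_ref = start_ref, length_nt = cl, is_pseudo = FALSE,
      stringsAsFactors = FALSE)
    truth_rows[[i]] <- data.frame(
      gene_id = gid, planted = planted[i],
      motif = if (planted[i]) win$motif else NA_character_,
      match_len = if (planted[i]) ms[i] else NA_integer_,
      d_planted = if (planted[i]) ds[i] else NA_integer_,
      strand = strands[i], stringsAsFactors = FALSE)
  }
  pieces <- c(pieces, random_dna(60, gc))
  genome <- sd_genome(
    replicons = list(synrep1 = list(seq = paste(pieces, collapse = ""),
                                    circular = TRUE)),
    genes = do.call(rbind, gene_rows))
  list(genome = genome, truth = do.call(rbind, truth_rows), tail = tail)
}

# ---- expression tables ------------------------------------------------------

#' Simulate protein and read-count tables with a planted class effect
#'
#' Protein abundances are log-normal with the SD-facilitated mean multiplied
#' by `effect`; read counts are negative-binomial and independent of class
#' (the null mode for transcript abundance). Deterministic given `seed`.
#'
#' @param classes data.frame with `gene_id` and `label` (both labels
#'   present).
#' @param effect multiplicative protein shift for SD-facilitated genes
#'   (default 2; 1 gives the null).
#' @param protein_meanlog baseline log-mean protein abundance (default
#'   `log(50)` ppm).
#' @param protein_sigma log-normal sigma (default 1).
#' @param count_mu,count_size negative-binomial mean and size for per-replicate
#'   counts (defaults 100 and 2).
#' @param n_projects,n_replicates BioProjects and replicates per project
#'   (defaults 2 and 3).
#' @param gene_len nominal gene length used for FPKM (default 1000 nt).
#' @param seed RNG seed.
#' @return list with `proteins` (gene_id, abundance, unit), `counts`
#'   (gene_id, project, replicate, count, gene_len), `truth`.
#' @export
simulate_expression <- function(classes, effect = 2,
                                protein_meanlog = log(50), protein_sigma = 1,
                                count_mu = 100, count_size = 2,
                                n_projects = 2, n_replicates = 3,
                                gene_len = 1000, seed = NULL) {
  stopifnot(all(c("gene_id", "label") %in% names(classes)),
            length(unique(classes$label)) == 2, effect >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(classes)
  fac <- classes$label == "SD-facilitated"
  proteins <- data.frame(
    gene_id = classes$gene_id,
    abundance = stats::rlnorm(n, protein_meanlog + log(effect) * fac,
                              protein_sigma),
    unit = "ppm", stringsAsFactors = FALSE)
  counts <- do.call(rbind, lapply(seq_len(n_projects), function(pr) {
    do.call(rbind, lapply(seq_len(n_replicates), function(rp) {
      data.frame(gene_id = classes$gene_id,
                 project = sprintf("PRJ%02d", pr),
                 replicate = rp,
                 count = stats::rnbinom(n, mu = count_mu, size = count_size),
                 gene_len = gene_len, stringsAsFactors = FALSE)
    }))
  }))
  list(proteins = proteins, counts = counts,
       truth = list(effect = effect, seed = seed,
                    facilitated = classes$gene_id[fac]))
}

# ---- writers (round-trip formats) ------------------------------------------

#' Write a genome as a GenBank flat file
#'
#' Emits LOCUS (with topology), CDS features (complement() on the minus
#' strand, `/locus_tag`, `/pseudo`) and the ORIGIN sequence, in a form
#' [read_genbank()] parses back to an identical gene set.
#'
#' @param genome an [sd_genome].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rn in names(genome$replicons)) {
    rep <- genome$replicons[[rn]]
    topo <- if (isTRUE(rep$circular)) "circular" else "linear"
    writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   BCT 01-JAN-2026",
                       rn, rep$length, topo), con)
    writeLines(sprintf("DEFINITION  synthetic genome %s.", rn), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    genes <- genome$genes[genome$genes$replicon_id == rn, , drop = FALSE]
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      if (g$strand == "+") {
        s <- g$start_codon_ref; e <- s + g$length_nt - 1
        loc <- sprintf("%d..%d", s, e)
      } else {
        e <- g$start_codon_ref; s <- e - g$length_nt + 1
        loc <- sprintf("complement(%d..%d)", s, e)
      }
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"", g$gene_id), con)
      if (g$is_pseudo) writeLines("                     /pseudo", con)
    }
    writeLines("ORIGIN", con)
    seq <- tolower(rep$seq)
    starts <- seq.int(1, nchar(seq), by = 60)
    for (s in starts) {
      chunk <- substr(seq, s, min(s + 59, nchar(seq)))
      grp <- regmatches(chunk, gregexpr(".{1,10}", chunk))[[1]]
      writeLines(sprintf("%9d %s", s, paste(grp, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Write a genome as a FASTA + GFF3 pair
#'
#' @param genome an [sd_genome].
#' @param fasta,gff output paths.
#' @return invisibly, `c(fasta, gff)`.
#' @export
write_fasta_gff <- function(genome, fasta, gff) {
  fa <- character(0)
  for (rn in names(genome$replicons)) {
    fa <- c(fa, paste0(">", rn), genome$replicons[[rn]]$seq)
  }
  writeLines(fa, fasta)
  lines <- "##gff-version 3"
  g <- genome$genes
  for (i in seq_len(nrow(g))) {
    if (g$strand[i] == "+") {
      s <- g$start_codon_ref[i]; e <- s + g$length_nt[i] - 1
    } else {
      e <- g$start_codon_ref[i]; s <- e - g$length_nt[i] + 1
    }
    attrs <- sprintf("ID=%s;locus_tag=%s", g$gene_id[i], g$gene_id[i])
    if (g$is_pseudo[i]) attrs <- paste0(attrs, ";pseudo=true")
    lines <- c(lines, paste(g$replicon_id[i], "sdscan", "CDS", s, e, ".",
                            g$strand[i], "0", attrs, sep = "\t"))
  }
  writeLines(lines, gff)
  invisible(c(fasta, gff))
}

#' Write a TSV table
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
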