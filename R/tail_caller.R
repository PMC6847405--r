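# Mature 16S rRNA 3'-terminus (anti-SD tail) calling from RNA-Seq read-end
# pileups along a 205-nt query built around the CCTCC core anti-SD motif.

#' Build the 16S rDNA tail query
#'
#' Extracts the core anti-SD motif plus `flank` bases on each side from a 16S
#' rDNA sequence (205 nt total at the defaults). If the core sits nearer than
#' `flank` to a sequence end the query is truncated and flagged.
#'
#' @param rdna_16s 16S rDNA sequence (DNA string).
#' @param core core anti-SD motif in DNA alphabet (default `"CCTCC"`).
#' @param flank flank length on each side (default 100).
#' @param occurrence which core occurrence to use when the motif occurs more
#'   than once (1-based); an ambiguity error is raised otherwise.
#' @return list of class `tail_query`: `seq` (DNA), `core_offset` (1-based
#'   start of the core within the query), `core_len`, `truncated_5p`,
#'   `truncated_3p`, `offset_in_rdna` (query start within the input).
#' @export
build_query <- function(rdna_16s, core = "CCTCC", flank = 100, occurrence = NULL) {
  rdna <- toupper(rdna_16s)
  core <- toupper(core)
  hits <- gregexpr(core, rdna, fixed = TRUE)[[1]]
  if (hits[1] == -1) stop("core motif ", core, " not found in 16S rDNA", call. = FALSE)
  if (length(hits) > 1 && is.null(occurrence)) {
    stop("core motif ", core, " occurs ", length(hits),
         " times; supply `occurrence` to disambiguate", call. = FALSE)
  }
  occ <- if (is.null(occurrence)) 1L else as.integer(occurrence)
  if (occ < 1 || occ > length(hits)) stop("occurrence out of range", call. = FALSE)
  cs <- hits[occ]
  ce <- cs + nchar(core) - 1
  qstart <- cs - flank
  qend <- ce + flank
  trunc5 <- qstart < 1
  trunc3 <- qend > nchar(rdna)
  qstart <- max(1, qstart)
  qend <- min(nchar(rdna), qend)
  if (trunc5 || trunc3) {
    warning("query truncated at the ", paste(c("5'", "3'")[c(trunc5, trunc3)],
            collapse = " and "), " end (core within ", flank,
            " nt of a sequence end)", call. = FALSE)
  }
  structure(list(seq = substr(rdna, qstart, qend),
                 core_offset = cs - qstart + 1,
                 core_len = nchar(core),
                 truncated_5p = trunc5, truncated_3p = trunc3,
                 offset_in_rdna = qstart),
            class = "tail_query")
}

#' @export
print.tail_query <- function(x, ...) {
  cat("<tail_query> ", nchar(x$seq), " nt, core at ", x$core_offset, "..",
      x$core_offset + x$core_len - 1,
      if (x$truncated_5p || x$truncated_3p) " (truncated)", "\n", sep = "")
  invisible(x)
}

# ---- read input -------------------------------------------------------------

# Multiplicity-aware read container: data.frame(id, seq, mult).
normalise_reads <- function(reads, multiplicity = c("auto", "header", "none")) {
  multiplicity <- match.arg(multiplicity)
  if (is.data.frame(reads)) {
    stopifnot(all(c("seq", "mult") %in% names(reads)))
    if (is.null(reads$id)) reads$id <- sprintf("R%06d", seq_len(nrow(reads)))
    return(data.frame(id = reads$id, seq = toupper(reads$seq),
                      mult = as.numeric(reads$mult), stringsAsFactors = FALSE))
  }
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    return(read_reads(reads, multiplicity = multiplicity))
  }
  if (is.character(reads)) {
    ids <- names(reads)
    if (is.null(ids)) ids <- sprintf("R%06d", seq_along(reads))
    return(parse_multiplicity(ids, toupper(reads), multiplicity))
  }
  stop("unsupported reads input; give a file path, a character vector, or a ",
       "data.frame with columns seq and mult", call. = FALSE)
}

parse_multiplicity <- function(ids, seqs, multiplicity) {
  has <- grepl("_\\d+$", ids)
  mult <- rep(1, length(ids))
  mult[has] <- as.numeric(sub("^.*_(\\d+)$", "\\1", ids[has]))
  if (multiplicity == "header" && any(!has)) {
    stop("malformed multiplicity header (expected SeqID_count) for read: ",
         ids[which(!has)[1]], call. = FALSE)
  }
  if (multiplicity == "none") mult <- rep(1, length(ids))
  data.frame(id = ids, seq = seqs, mult = mult, stringsAsFactors = FALSE)
}

#' Read sequencing reads from FASTA/FASTQ/SAM
#'
#' FASTA headers of the form `SeqID_count` carry read multiplicity (the
#' collapsed-identical-reads convention); plain FASTQ reads count once.
#' SAM input keeps mapped records' SEQ fields (alignments are re-checked
#' against the package's ungapped contract by [map_read_ends()]).
#'
#' @param path input file; format inferred from extension/content.
#' @param multiplicity `"auto"` (use `_count` suffix when present),
#'   `"header"` (require it; malformed headers are an error naming the read),
#'   or `"none"`.
#' @return data.frame with `id`, `seq`, `mult`.
#' @export
read_reads <- function(path, multiplicity = "auto") {
  first <- readLines(path, n = 1, warn = FALSE)
  if (grepl("\\.(sam)$", path, ignore.case = TRUE) || grepl("^@(HD|SQ|RG|PG)\t", first)) {
    return(read_reads_sam(path, multiplicity))
  }
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  ids <- sub("\\s.*$", "", names(ss))
  parse_multiplicity(ids, as.character(ss), multiplicity)
}

read_reads_sam <- function(path, multiplicity = "auto") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) stop("SAM file has no alignment records: ", path, call. = FALSE)
  f <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(f, `[[`, "", 1)
  flag <- as.integer(vapply(f, `[[`, "", 2))
  seqs <- toupper(vapply(f, `[[`, "", 10))
  keep <- bitwAnd(flag, 4L) == 0L & seqs != "*"
  # SAM stores reverse-strand SEQ reference-forward; the mapper tries both
  # orientations, so SEQ can be passed through unchanged.
  parse_multiplicity(ids[keep], seqs[keep], multiplicity)
}

#' Minimal read trimmer
#'
#' Convenience pre-filter mirroring common practice: drops reads with mean
#' Phred quality below `min_mean_phred` (when qualities are available), trims
#' a 3' adapter at its first exact occurrence, and keeps reads of at least
#' `min_len` nt. Full read QC is out of scope; inputs are normally
#' pre-trimmed.
#'
#' @param reads data.frame with `id`, `seq`, `mult` and optionally `qual`
#'   (Phred+33 strings).
#' @param min_mean_phred minimum mean Phred score (default 20).
#' @param adapters character vector of adapter sequences to trim (DNA).
#' @param min_len minimum retained read length (default 25).
#' @return filtered/trimmed reads data.frame.
#' @export
trim_reads <- function(reads, min_mean_phred = 20, adapters = character(0),
                       min_len = 25) {
  if (!is.null(reads$qual)) {
    mq <- vapply(reads$qual, function(q) mean(utf8ToInt(q) - 33), numeric(1))
    reads <- reads[mq >= min_mean_phred, , drop = FALSE]
  }
  for (ad in toupper(adapters)) {
    pos <- regexpr(ad, reads$seq, fixed = TRUE)
    hit <- pos > 0
    reads$seq[hit] <- substr(reads$seq[hit], 1, pos[hit] - 1)
  }
  reads[nchar(reads$seq) >= min_len, , drop = FALSE]
}

# ---- pileup -----------------------------------------------------------------

#' Pile up read 3' ends along the tail query
#'
#' Each read admitting an ungapped local alignment to the query (either
#' orientation, best hit only) with at least `min_match` aligned columns at
#' `min_identity` identity contributes its transcript-orientation 3'-end
#' position, weighted by multiplicity. Reads whose extrapolated 3' end falls
#' off the query are counted in `total_mapped` but not in the pileup.
#'
#' @param reads reads input accepted by [read_reads()]/`normalise_reads`:
#'   a path, a (optionally named) character vector, or a data.frame with
#'   `seq` and `mult`.
#' @param query a [build_query()] result (or a plain DNA string).
#' @param min_match minimum aligned columns (default 25).
#' @param min_identity minimum identity within the aligned segment
#'   (default 0.95).
#' @param multiplicity header-multiplicity mode, see [read_reads()].
#' @return object of class `tail_pileup`: `counts` (integer per query
#'   position), `total_mapped`, `total_reads`, `query`.
#' @export
map_read_ends <- function(reads, query, min_match = 25, min_identity = 0.95,
                          multiplicity = "auto") {
  rd <- normalise_reads(reads, multiplicity)
  if (!nrow(rd)) stop("empty read set", call. = FALSE)
  qseq <- if (inherits(query, "tail_query")) query$seq else toupper(query)
  hits <- map_reads_cpp(rd$seq, qseq, as.integer(min_match), min_identity)
  mapped <- hits[, 1] == 1L
  counts <- integer(nchar(qseq))
  on_query <- mapped & hits[, 2] > 0
  if (any(on_query)) {
    agg <- tapply(rd$mult[on_query], hits[on_query, 2], sum)
    counts[as.integer(names(agg))] <- as.integer(round(agg))
  }
  structure(list(counts = counts,
                 total_mapped = sum(rd$mult[mapped]),
                 total_reads = sum(rd$mult),
                 query = if (inherits(query, "tail_query")) query
                         else structure(list(seq = qseq, core_offset = NA_integer_,
                                             core_len = NA_integer_),
                                        class = "tail_query")),
            class = "tail_pileup")
}

#' @export
print.tail_pileup <- function(x, ...) {
  cat("<tail_pileup> ", length(x$counts), " sites; ", sum(x$counts),
      " read 3' ends on query (", x$total_mapped, " mapped of ",
      x$total_reads, " reads)\n", sep = "")
  nz <- which(x$counts > 0)
  if (length(nz)) {
    top <- nz[order(x$counts[nz], decreasing = TRUE)][seq_len(min(5, length(nz)))]
    cat("  top sites:", paste(sprintf("%d:%d", top, x$counts[top]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.tail_pileup <- function(x, ...) {
  graphics::barplot(x$counts, names.arg = seq_along(x$counts), border = NA,
                    xlab = "query position", ylab = "read 3'-end count", ...)
  invisible(x)
}

#' Export a pileup as a TSV table
#' @param pileup a `tail_pileup`.
#' @param path output TSV path (position, base, count); NULL returns the
#'   data.frame only.
#' @return the pileup data.frame, invisibly when written.
#' @export
pileup_table <- function(pileup, path = NULL) {
  df <- data.frame(position = seq_along(pileup$counts),
                   base = strsplit(dna_to_rna(pileup$query$seq), "", fixed = TRUE)[[1]],
                   count = pileup$counts)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

# ---- tail calling -----------------------------------------------------------

# Candidate termini: tail (motif start .. t) contains the CCUCC core and the
# terminus lies within the conserved-motif span or <= proximity_nt downstream.
tail_candidates <- function(pileup, conserved_motif, proximity_nt) {
  q <- pileup$query
  qrna <- dna_to_rna(q$seq)
  rx <- iupac_to_regex(conserved_motif)
  hits <- gregexpr(rx, qrna)[[1]]
  if (hits[1] == -1) {
    stop("conserved motif ", conserved_motif, " not found in query; ",
         "supply the species' genomic motif via `conserved_motif`", call. = FALSE)
  }
  lens <- attr(hits, "match.length")
  core_end <- if (!is.na(q$core_offset)) q$core_offset + q$core_len - 1 else NA_integer_
  # prefer the occurrence containing the core
  pick <- 1L
  if (!is.na(core_end)) {
    inside <- which(hits <= q$core_offset & hits + lens - 1 >= core_end)
    if (length(inside)) pick <- inside[1]
  }
  ms <- hits[pick]
  me <- ms + lens[pick] - 1
  lo <- if (!is.na(core_end)) max(ms, core_end) else ms
  t <- seq.int(lo, min(me + proximity_nt, nchar(qrna)))
  list(termini = t, motif_start = ms, motif_end = me, qrna = qrna)
}

# exclude: sites ignored in the downstream sum (used when re-applying the
# peak criterion to secondary candidates, whose downstream window may contain
# the already-called primary terminus — a mature end, not precursor noise)
passes_downstream <- function(counts, t, k, exclude = integer(0)) {
  idx <- seq.int(t + 1, min(t + k, length(counts)))
  idx <- setdiff(idx, exclude)
  counts[t] > sum(counts[idx])
}

#' Call the most prominent mature 3' tail
#'
#' Applies the two identification criteria to a read-end pileup: the implied
#' tail (conserved-motif start through the terminus) must contain the CCUCC
#' core and end within, or at most `proximity_nt` downstream of, the
#' conserved motif; and the terminus count must exceed the combined counts of
#' the next `k_downstream` sites. Among qualifying candidates the one with
#' the highest count is called, ties broken toward the most upstream
#' terminus.
#'
#' @param pileup a `tail_pileup` from [map_read_ends()].
#' @param conserved_motif conserved genomic motif around the mature terminus,
#'   IUPAC RNA (default `GAUCACCUCCUUW`, i.e. `GAUCACCUCCUU(U|A)`).
#' @param k_downstream number of downstream sites whose combined count the
#'   peak must exceed (default 5).
#' @param proximity_nt how far downstream of the conserved motif a terminus
#'   may lie and still be deemed "close" (default 4).
#' @return object of class `mature_tail_call`: `terminus` (query position),
#'   `tail_seq` (RNA, 5'->3'), `peak_count`, `downstream_sum`, `motif_span`,
#'   and `secondary` (empty; see [detect_secondary_tails()]).
#' @export
call_prominent_tail <- function(pileup, conserved_motif = "GAUCACCUCCUUW",
                                k_downstream = 5, proximity_nt = 4) {
  stopifnot(inherits(pileup, "tail_pileup"))
  if (all(pileup$counts == 0)) stop("no-call: pileup has no nonzero counts", call. = FALSE)
  cand <- tail_candidates(pileup, conserved_motif, proximity_nt)
  counts <- pileup$counts
  ok <- vapply(cand$termini, function(t) passes_downstream(counts, t, k_downstream),
               logical(1))
  if (!any(ok)) {
    best <- cand$termini[which.max(counts[cand$termini])]
    stop("no-call: no candidate terminus satisfies both criteria; best-failing ",
         "candidate at query position ", best, " (count ", counts[best],
         ", downstream sum ",
         sum(counts[seq.int(best + 1, min(best + k_downstream, length(counts)))]),
         ")", call. = FALSE)
  }
  tq <- cand$termini[ok]
  t <- tq[order(-counts[tq], tq)][1]
  structure(list(terminus = t,
                 tail_seq = substr(cand$qrna, cand$motif_start, t),
                 peak_count = counts[t],
                 downstream_sum = sum(counts[seq.int(t + 1, min(t + k_downstream, length(counts)))]),
                 motif_span = c(cand$motif_start, cand$motif_end),
                 k_downstream = k_downstream,
                 secondary = list()),
            class = "mature_tail_call")
}

#' @export
print.mature_tail_call <- function(x, ...) {
  cat("<mature_tail_call> 5'-", x$tail_seq, "-3' at query position ",
      x$terminus, "\n  peak count ", x$peak_count, " > ", x$downstream_sum,
      " (sum of next ", x$k_downstream, " sites)\n", sep = "")
  if (length(x$secondary)) {
    for (s in x$secondary) {
      cat("  secondary: 5'-", s$tail_seq, "-3' at ", s$terminus,
          " (count ", s$peak_count, ")\n", sep = "")
    }
  }
  invisible(x)
}

#' Detect secondary 3'-tail peaks
#'
#' Returns every non-primary terminus meeting both calling criteria with a
#' count of at least `min_frac_of_primary` of the primary peak, sorted by
#' count (an empty list is allowed). When re-applying the downstream-decay
#' criterion the primary terminus is excluded from the downstream sum: it is
#' an already-called mature end, not the precursor read-through the
#' criterion guards against, and tail heterogeneity places secondary ends a
#' few nt up- or downstream of the primary.
#'
#' @inheritParams call_prominent_tail
#' @param primary the primary `mature_tail_call`.
#' @param min_frac_of_primary minimum fraction of the primary peak count
#'   (default 0.25).
#' @return list of secondary calls (`terminus`, `tail_seq`, `peak_count`).
#' @export
detect_secondary_tails <- function(pileup, primary,
                                   conserved_motif = "GAUCACCUCCUUW",
                                   k_downstream = 5, proximity_nt = 4,
                                   min_frac_of_primary = 0.25) {
  stopifnot(inherits(primary, "mature_tail_call"))
  cand <- tail_candidates(pileup, conserved_motif, proximity_nt)
  counts <- pileup$counts
  keep <- vapply(cand$termini, function(t) {
    t != primary$terminus &&
      counts[t] >= min_frac_of_primary * primary$peak_count &&
      passes_downstream(counts, t, k_downstream, exclude = primary$terminus)
  }, logical(1))
  tq <- cand$termini[keep]
  tq <- tq[order(-counts[tq])]
  lapply(tq, function(t) {
    list(terminus = t, tail_seq = substr(cand$qrna, cand$motif_start, t),
         peak_count = counts[t])
  })
}
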