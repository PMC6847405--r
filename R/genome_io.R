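# Genome input: GenBank flat files or FASTA+GFF3 pairs, a common in-memory
# genome representation, and strand-aware upstream-window extraction.
#
# Internal coordinates are 1-based inclusive on the reference (plus) strand;
# the GeneRecord field `cds_start` follows the convention that positions are
# counted along the gene's own strand (for minus-strand genes, position 1 is
# the last reference base).

#' Construct a genome object
#'
#' @param replicons named list; each element a list with `seq` (DNA string)
#'   and `circular` (logical).
#' @param genes data.frame with columns `gene_id`, `replicon_id`, `strand`
#'   (`+`/`-`), `start_codon_ref` (1-based reference position of the first
#'   base of the start codon), `length_nt`, `is_pseudo`.
#' @return an object of class `sd_genome`.
#' @export
sd_genome <- function(replicons, genes) {
  stopifnot(is.list(replicons), length(replicons) >= 1, !is.null(names(replicons)))
  need <- c("gene_id", "replicon_id", "strand", "start_codon_ref",
            "length_nt", "is_pseudo")
  if (!all(need %in% names(genes))) {
    stop("genes table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("gene_id values must be unique within a genome", call. = FALSE)
  }
  if (any(genes$length_nt < 3)) stop("gene length_nt must be >= 3", call. = FALSE)
  genes$gene_id <- as.character(genes$gene_id)
  genes$replicon_id <- as.character(genes$replicon_id)
  genes$strand <- as.character(genes$strand)
  genes$start_codon_ref <- as.integer(genes$start_codon_ref)
  genes$length_nt <- as.integer(genes$length_nt)
  genes$is_pseudo <- as.logical(genes$is_pseudo)
  for (r in names(replicons)) {
    replicons[[r]]$seq <- toupper(replicons[[r]]$seq)
    replicons[[r]]$length <- nchar(replicons[[r]]$seq)
    if (is.null(replicons[[r]]$circular)) replicons[[r]]$circular <- TRUE
  }
  rl <- vapply(replicons, function(r) r$length, numeric(1))
  genes$cds_start <- ifelse(genes$strand == "+",
                            genes$start_codon_ref,
                            rl[genes$replicon_id] - genes$start_codon_ref + 1)
  rownames(genes) <- NULL
  structure(list(replicons = replicons, genes = genes), class = "sd_genome")
}

#' @export
print.sd_genome <- function(x, ...) {
  cat("<sd_genome> ", length(x$replicons), " replicon(s), ",
      nrow(x$genes), " CDS (", sum(x$genes$is_pseudo), " pseudo)\n", sep = "")
  for (r in names(x$replicons)) {
    cat("  ", r, ": ", x$replicons[[r]]$length, " nt, ",
        if (isTRUE(x$replicons[[r]]$circular)) "circular" else "linear",
        "\n", sep = "")
  }
  invisible(x)
}

#' Load an annotated genome
#'
#' Reads either a GenBank flat file or a FASTA+GFF3 pair and returns a
#' genome whose CDS features become gene records; features flagged pseudo are
#' retained but marked `is_pseudo` and excluded from downstream analyses.
#'
#' @param path GenBank flat file, or the genome FASTA when `gff` is given.
#' @param gff optional GFF3 annotation accompanying a FASTA `path`.
#' @param circular default circularity for replicons whose file does not
#'   state it (GenBank LOCUS topology wins when present).
#' @return an [sd_genome] object.
#' @export
load_genome <- function(path, gff = NULL, circular = TRUE) {
  if (is.null(gff)) read_genbank(path, circular = circular)
  else read_fasta_gff(path, gff, circular = circular)
}

# ---- GenBank flat file ------------------------------------------------------

# Parse a (possibly joined/complemented) GenBank location string. Returns
# strand, per-segment starts/ends, and the reference position of the first
# base of the start codon (first segment start on +, last segment end on -).
parse_gb_location <- function(loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  segs <- strsplit(loc, ",", fixed = TRUE)[[1]]
  m <- regmatches(segs, regexec("^(\\d+)\\.\\.(\\d+)$|^(\\d+)$", segs))
  starts <- ends <- integer(length(segs))
  for (i in seq_along(segs)) {
    g <- m[[i]]
    if (length(g) == 0 || g[1] == "") stop("unparseable location: ", loc, call. = FALSE)
    if (g[2] != "") { starts[i] <- as.integer(g[2]); ends[i] <- as.integer(g[3]) }
    else { starts[i] <- ends[i] <- as.integer(g[4]) }
  }
  list(strand = strand, starts = starts, ends = ends,
       start_codon_ref = if (strand == "+") starts[1] else ends[length(ends)],
       length_nt = sum(ends - starts + 1))
}

#' Read a GenBank flat file
#'
#' Minimal parser for LOCUS topology, CDS features (including
#' `complement()`/`join()` locations and the `/pseudo` qualifier) and the
#' ORIGIN sequence. Multi-record files yield multiple replicons.
#'
#' @inheritParams load_genome
#' @return an [sd_genome] object.
#' @export
read_genbank <- function(path, circular = TRUE) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1])) {
    stop("not a GenBank flat file (no LOCUS line): ", path, call. = FALSE)
  }
  rec_start <- grep("^LOCUS", lines)
  rec_end <- c(rec_start[-1] - 1, length(lines))
  replicons <- list()
  gene_rows <- list()
  for (k in seq_along(rec_start)) {
    rec <- lines[rec_start[k]:rec_end[k]]
    locus_tok <- strsplit(trimws(rec[1]), "\\s+")[[1]]
    rep_id <- locus_tok[2]
    circ <- if (any(grepl("circular", rec[1], ignore.case = TRUE))) TRUE
            else if (any(grepl("linear", rec[1], ignore.case = TRUE))) FALSE
            else circular
    oi <- grep("^ORIGIN", rec)
    if (!length(oi)) stop("GenBank record lacks ORIGIN sequence: ", rep_id, call. = FALSE)
    seq_lines <- rec[(oi[1] + 1):length(rec)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    fi <- grep("^FEATURES", rec)
    feats <- if (length(fi)) rec[(fi[1] + 1):(oi[1] - 1)] else character(0)
    # feature keys start at column 6; continuation/qualifier lines at column 22
    is_key <- grepl("^ {5}\\S", feats)
    key_idx <- which(is_key)
    n_cds <- 0
    for (j in seq_along(key_idx)) {
      block <- feats[key_idx[j]:(if (j < length(key_idx)) key_idx[j + 1] - 1 else length(feats))]
      key <- strsplit(trimws(block[1]), "\\s+")[[1]][1]
      if (!identical(key, "CDS")) next
      n_cds <- n_cds + 1
      qual_start <- grep("^\\s+/", block)
      loc_end <- if (length(qual_start)) qual_start[1] - 1 else length(block)
      loc <- sub("^CDS", "",
                 paste(gsub("\\s", "", block[1:loc_end]), collapse = ""))
      pl <- parse_gb_location(loc)
      quals <- paste(block, collapse = "\n")
      get_q <- function(q) {
        m <- regmatches(quals, regexec(paste0("/", q, "=\"([^\"]*)\""), quals))[[1]]
        if (length(m) >= 2) m[2] else NA_character_
      }
      gid <- get_q("locus_tag")
      if (is.na(gid)) gid <- get_q("gene")
      if (is.na(gid)) gid <- sprintf("%s_CDS%03d", rep_id, n_cds)
      gene_rows[[length(gene_rows) + 1]] <- data.frame(
        gene_id = gid, replicon_id = rep_id, strand = pl$strand,
        start_codon_ref = pl$start_codon_ref, length_nt = pl$length_nt,
        is_pseudo = grepl("/pseudo(\\s|$|=)", quals),
        stringsAsFactors = FALSE)
    }
    replicons[[rep_id]] <- list(seq = seq, circular = circ)
  }
  if (!length(gene_rows)) {
    stop("no CDS features found in ", path, " (empty annotation)", call. = FALSE)
  }
  sd_genome(replicons, do.call(rbind, gene_rows))
}

# ---- FASTA + GFF3 -----------------------------------------------------------

#' Read a genome from a FASTA and GFF3 pair
#'
#' CDS features are taken from the GFF3 (via rtracklayer); a feature is
#' pseudo when it carries a `pseudo` attribute or `gene_biotype=pseudogene`.
#'
#' @param fasta genome FASTA path.
#' @param gff GFF3 annotation path.
#' @param circular logical scalar or named logical vector per replicon.
#' @return an [sd_genome] object.
#' @export
read_fasta_gff <- function(fasta, gff, circular = TRUE) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff)
  df <- as.data.frame(gr)
  df <- df[df$type == "CDS", , drop = FALSE]
  if (!nrow(df)) stop("no CDS features found in ", gff, " (empty annotation)", call. = FALSE)
  pseudo <- rep(FALSE, nrow(df))
  if ("pseudo" %in% names(df)) pseudo <- pseudo | !is.na(df$pseudo) & df$pseudo %in% c(TRUE, "true", "TRUE")
  if ("gene_biotype" %in% names(df)) pseudo <- pseudo | (!is.na(df$gene_biotype) & df$gene_biotype == "pseudogene")
  gid <- if ("locus_tag" %in% names(df) && !all(is.na(df$locus_tag))) df$locus_tag else NULL
  if (is.null(gid) && "ID" %in% names(df)) gid <- df$ID
  if (is.null(gid)) gid <- sprintf("CDS%04d", seq_len(nrow(df)))
  genes <- data.frame(
    gene_id = as.character(gid),
    replicon_id = as.character(df$seqnames),
    strand = as.character(df$strand),
    start_codon_ref = ifelse(df$strand == "+", df$start, df$end),
    length_nt = df$width,
    is_pseudo = pseudo,
    stringsAsFactors = FALSE)
  # joined CDS (one ID, several segments): keep the segment carrying the
  # start codon and the summed length
  if (anyDuplicated(genes$gene_id)) {
    parts <- split(seq_len(nrow(genes)), genes$gene_id)
    genes <- do.call(rbind, lapply(parts, function(ii) {
      g <- genes[ii, , drop = FALSE]
      tot <- sum(g$length_nt)
      row <- if (g$strand[1] == "+") g[which.min(g$start_codon_ref), ] else g[which.max(g$start_codon_ref), ]
      row$length_nt <- tot
      row
    }))
    rownames(genes) <- NULL
  }
  reps <- list()
  for (nm in names(seqs)) {
    circ <- if (length(circular) > 1) isTRUE(circular[[nm]]) else isTRUE(circular)
    reps[[nm]] <- list(seq = as.character(seqs[[nm]]), circular = circ)
  }
  sd_genome(reps, genes)
}

# ---- upstream windows -------------------------------------------------------

#' Extract the upstream window of one gene
#'
#' Returns the `window_len` bases immediately 5' of the annotated start codon
#' on the coding strand, transcribed to the RNA alphabet. Minus-strand genes
#' use the reverse complement of the reference segment 3' of the CDS end.
#' Circular replicons wrap across the origin; linear replicons with fewer
#' than `window_len` upstream bases return a truncated window with
#' `truncated = TRUE` (and a warning), never silent padding.
#'
#' @param genome an [sd_genome].
#' @param gene_id gene identifier present in the genome.
#' @param window_len window length in nt (default 30).
#' @return list with `gene_id`, `seq` (RNA), `positions` (labels -L..-1 where
#'   -1 abuts the start codon) and `truncated`; class `upstream_window`.
#' @export
extract_upstream_window <- function(genome, gene_id, window_len = 30) {
  stopifnot(inherits(genome, "sd_genome"))
  g <- genome$genes[genome$genes$gene_id == gene_id, , drop = FALSE]
  if (!nrow(g)) stop("gene not found in genome: ", gene_id, call. = FALSE)
  rep <- genome$replicons[[g$replicon_id]]
  n <- rep$length
  truncated <- FALSE
  if (g$strand == "+") {
    from <- g$start_codon_ref - window_len
    to <- g$start_codon_ref - 1
    if (from < 1 && !rep$circular) {
      truncated <- TRUE
      from <- max(1, from)
    }
    seq <- if (from < 1) circ_substr(rep$seq, from, to)
           else if (to < 1) "" else substr(rep$seq, from, to)
  } else {
    from <- g$start_codon_ref + 1
    to <- g$start_codon_ref + window_len
    if (to > n && !rep$circular) {
      truncated <- TRUE
      to <- min(n, to)
    }
    seg <- if (to > n) circ_substr(rep$seq, from, to)
           else if (from > n) "" else substr(rep$seq, from, to)
    seq <- rev_comp(seg)
  }
  if (truncated) {
    warning("upstream window truncated to ", nchar(seq), " nt for gene ",
            gene_id, " (linear replicon boundary)", call. = FALSE)
  }
  seq <- dna_to_rna(seq)
  structure(list(gene_id = gene_id, seq = seq,
                 positions = if (nchar(seq)) seq.int(-nchar(seq), -1) else integer(0),
                 truncated = truncated),
            class = "upstream_window")
}

#' @export
print.upstream_window <- function(x, ...) {
  cat("<upstream_window> ", x$gene_id, ": 5'-", x$seq, "-3' (",
      length(x$positions), " nt", if (x$truncated) ", truncated", ")\n", sep = "")
  invisible(x)
}

#' Extract upstream windows for all genes
#'
#' @inheritParams extract_upstream_window
#' @param include_pseudo keep pseudo genes (default FALSE; they are excluded
#'   from all analyses).
#' @return data.frame with `gene_id`, `strand`, `window_seq` (RNA),
#'   `truncated`.
#' @export
upstream_windows <- function(genome, window_len = 30, include_pseudo = FALSE) {
  genes <- genome$genes
  if (!include_pseudo) genes <- genes[!genes$is_pseudo, , drop = FALSE]
  rows <- lapply(genes$gene_id, function(id) {
    w <- withCallingHandlers(
      extract_upstream_window(genome, id, window_len),
      warning = function(c) invokeRestart("muffleWarning"))
    data.frame(gene_id = id,
               strand = genes$strand[genes$gene_id == id],
               window_seq = w$seq, truncated = w$truncated,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write upstream windows to TSV and/or FASTA
#'
#' @param windows data.frame from [upstream_windows()].
#' @param tsv,fasta output paths (either may be NULL).
#' @return invisibly, the windows table.
#' @export
write_windows <- function(windows, tsv = NULL, fasta = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(windows, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fasta)) {
    writeLines(as.vector(rbind(paste0(">", windows$gene_id), windows$window_seq)),
               fasta)
  }
  invisible(windows)
}
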