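# Expression statistics: FPKM, protein-per-transcript, and the group
# contrasts between SD-facilitated and SD-independent genes (Wilcoxon rank
# sum with continuity correction; Kendall tau-b with tie adjustment).

#' Fragments per kilobase of transcript per million mapped reads
#'
#' `FPKM = count * 1e9 / (gene_len_nt * total_mapped)`; vectorised over
#' `count` and `gene_len_nt`.
#'
#' @param count fragment count(s) assigned to the gene.
#' @param gene_len_nt gene length(s) in nt (> 0).
#' @param total_mapped total mapped fragments in the library (> 0).
#' @return numeric FPKM.
#' @examples
#' compute_fpkm(10, 1000, 1e6) # 10
#' @export
compute_fpkm <- function(count, gene_len_nt, total_mapped) {
  if (any(gene_len_nt <= 0)) stop("gene_len_nt must be positive", call. = FALSE)
  if (length(total_mapped) != 1 || total_mapped <= 0) {
    stop("total_mapped must be a single positive count", call. = FALSE)
  }
  count * 1e9 / (gene_len_nt * total_mapped)
}

#' Count reads per gene (CDS assignment)
#'
#' Assigns each read (multiplicity-weighted) to the single best-scoring gene
#' whose CDS it aligns to under the same ungapped contract as the tail
#' mapper; ambiguous multi-gene hits go to the best-scoring gene only.
#'
#' @param genome an [sd_genome].
#' @param reads reads input (path, character vector, or data.frame; see
#'   [map_read_ends()]).
#' @param min_match,min_identity mapper thresholds (defaults 25, 0.95).
#' @param include_pseudo count pseudo genes too (default FALSE).
#' @return data.frame with `gene_id`, `length_nt`, `count`, plus attribute
#'   `total_mapped`.
#' @export
count_cds_reads <- function(genome, reads, min_match = 25, min_identity = 0.95,
                            include_pseudo = FALSE) {
  rd <- normalise_reads(reads, "auto")
  genes <- genome$genes
  if (!include_pseudo) genes <- genes[!genes$is_pseudo, , drop = FALSE]
  cds <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    rep <- genome$replicons[[g$replicon_id]]
    if (g$strand == "+") {
      s <- g$start_codon_ref; e <- s + g$length_nt - 1
      if (e > rep$length && rep$circular) circ_substr(rep$seq, s, e)
      else substr(rep$seq, s, min(e, rep$length))
    } else {
      e <- g$start_codon_ref; s <- e - g$length_nt + 1
      seg <- if (s < 1 && rep$circular) circ_substr(rep$seq, s, e)
             else substr(rep$seq, max(1, s), e)
      rev_comp(seg)
    }
  }, character(1))
  score <- matrix(0L, nrow(rd), nrow(genes))
  for (j in seq_len(nrow(genes))) {
    h <- map_reads_cpp(rd$seq, cds[j], as.integer(min_match), min_identity)
    score[, j] <- ifelse(h[, 1] == 1L, h[, 3], 0L)
  }
  best <- max.col(score, ties.method = "first")
  hit <- score[cbind(seq_len(nrow(rd)), best)] > 0
  counts <- numeric(nrow(genes))
  if (any(hit)) {
    agg <- tapply(rd$mult[hit], best[hit], sum)
    counts[as.integer(names(agg))] <- agg
  }
  out <- data.frame(gene_id = genes$gene_id, length_nt = genes$length_nt,
                    count = counts, stringsAsFactors = FALSE)
  attr(out, "total_mapped") <- sum(counts)
  out
}

#' Protein per transcript
#'
#' `protein_abundance / mean FPKM`, the translation-efficiency proxy; genes
#' with zero (or undefined) mean FPKM get NA and are excluded from
#' contrasts, never an infinity.
#'
#' @param protein non-negative protein abundance (ppm, spectral counts or
#'   unique peptides).
#' @param mean_fpkm replicate-averaged FPKM within one BioProject.
#' @return numeric ratio, NA where `mean_fpkm <= 0` (vectorised).
#' @export
protein_per_transcript <- function(protein, mean_fpkm) {
  if (any(protein < 0, na.rm = TRUE)) stop("protein abundance must be >= 0", call. = FALSE)
  ifelse(is.na(mean_fpkm) | mean_fpkm <= 0, NA_real_, protein / mean_fpkm)
}

# ---- rank statistics --------------------------------------------------------

# Mann-Whitney U of sample a (counting pairs where a precedes b), from
# midranks.
mw_u <- function(ra, na) sum(ra) - na * (na + 1) / 2

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon test with midranks for ties. When both
#' groups have at most `exact_max` observations the null distribution is
#' enumerated exhaustively over all group assignments of the (mid)ranks
#' (valid under ties, where the classical exact tables are not); otherwise
#' the normal approximation with tie-corrected variance and a 0.5 continuity
#' correction is used via [stats::wilcox.test()]. Identical pooled values
#' give p = 1 by convention.
#'
#' @param a,b numeric samples (non-empty).
#' @param continuity apply the 0.5 continuity correction in the normal
#'   approximation (default TRUE).
#' @param exact force (TRUE) or forbid (FALSE) enumeration; default NULL
#'   enumerates when both sizes are <= `exact_max`.
#' @param exact_max size bound for the enumeration branch (default 10).
#' @return list with `statistic` (Mann-Whitney U of `a`), `p_value`,
#'   `method`.
#' @export
wilcoxon_rank_sum <- function(a, b, continuity = TRUE, exact = NULL,
                              exact_max = 10) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty", call. = FALSE)
  na <- length(a); nb <- length(b); N <- na + nb
  r <- rank(c(a, b))
  u <- mw_u(r[seq_len(na)], na)
  if (length(unique(c(a, b))) == 1) {
    return(list(statistic = u, p_value = 1, method = "degenerate"))
  }
  do_exact <- if (is.null(exact)) (na <= exact_max && nb <= exact_max) else isTRUE(exact)
  if (do_exact && choose(N, na) <= 2e5) {
    combs <- utils::combn(N, na)
    ws <- colSums(matrix(r[combs], nrow = na))
    us <- ws - na * (na + 1) / 2
    p <- 2 * min(mean(us <= u), mean(us >= u))
    return(list(statistic = u, p_value = min(1, p), method = "exact enumeration"))
  }
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = continuity)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = "normal approximation")
}

#' Kendall's tau-b
#'
#' Rank correlation with the tie adjustment
#' `tau_b = (C - D) / sqrt((n0 - n1)(n0 - n2))`; undefined (NA, with a
#' warning) when either vector is entirely tied.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return tau-b in `[-1, 1]`, or NA when undefined.
#' @examples
#' kendall_tau_b(c(1, 2, 3, 4), c(1, 3, 2, 4)) # 2/3
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warning("tau-b undefined: a vector is entirely tied", call. = FALSE)
    return(NA_real_)
  }
  unname(stats::cor(x, y, method = "kendall"))
}

#' Normal-approximation p-value for Kendall's tau
#'
#' Two-sided p from the variance of the tau statistic under independence
#' (ties ignored in the variance, as in the large-sample z-test).
#'
#' @param tau tau-b estimate.
#' @param n number of pairs.
#' @return two-sided p-value.
#' @export
kendall_tau_p <- function(tau, n) {
  z <- 3 * tau * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
  2 * stats::pnorm(-abs(z))
}

# ---- contrasts --------------------------------------------------------------

#' Contrast a metric between SD-facilitated and SD-independent genes
#'
#' Applies the Wilcoxon rank-sum test (continuity-corrected normal
#' approximation, or exact enumeration for very small groups) to a per-gene
#' metric split by SD class. Records with missing metric are dropped; an
#' empty class after filtering is an error naming the filter.
#'
#' @param records data.frame with columns `label` (`SD-facilitated` /
#'   `SD-independent`) and the metric column.
#' @param metric metric column name, e.g. `"protein_abundance"`,
#'   `"protein_per_transcript"` or `"mfe"`.
#' @return object of class `group_contrast`: `metric`, `n_facilitated`,
#'   `n_independent`, `medians` (named pair), `statistic`, `p_value`.
#' @export
contrast_groups <- function(records, metric) {
  stopifnot(metric %in% names(records), "label" %in% names(records))
  v <- records[[metric]]
  keep <- !is.na(v)
  records <- records[keep, , drop = FALSE]
  v <- v[keep]
  a <- v[records$label == "SD-facilitated"]
  b <- v[records$label == "SD-independent"]
  if (!length(a) || !length(b)) {
    stop("class ", if (!length(a)) "SD-facilitated" else "SD-independent",
         " is empty after filtering to non-missing `", metric, "`", call. = FALSE)
  }
  wt <- wilcoxon_rank_sum(a, b)
  structure(list(metric = metric,
                 n_facilitated = length(a), n_independent = length(b),
                 medians = c(facilitated = stats::median(a),
                             independent = stats::median(b)),
                 statistic = wt$statistic, p_value = wt$p_value,
                 method = wt$method),
            class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat("<group_contrast> ", x$metric, "\n",
      "  SD-facilitated: n = ", x$n_facilitated, ", median = ",
      signif(x$medians[["facilitated"]], 4), "\n",
      "  SD-independent: n = ", x$n_independent, ", median = ",
      signif(x$medians[["independent"]], 4), "\n",
      "  Wilcoxon W = ", signif(x$statistic, 6), ", p = ",
      signif(x$p_value, 4), " (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Assemble per-gene expression records
#'
#' Merges a protein-abundance table, per-project mean FPKM values and the SD
#' classification into one table with protein-per-transcript columns (one per
#' BioProject). Genes with zero protein abundance are excluded from
#' contrasts downstream (set `keep_zero_protein = TRUE` to retain them).
#'
#' @param proteins data.frame with `gene_id`, `abundance` (and optionally
#'   `unit`).
#' @param fpkm data.frame with `gene_id`, `project`, `fpkm` (replicate
#'   FPKMs; averaged within project).
#' @param classes data.frame from [classify_genes()].
#' @param keep_zero_protein keep genes with `abundance == 0` (default FALSE,
#'   matching "protein abundance > 0").
#' @return data.frame with `gene_id`, `label`, `protein_abundance`,
#'   `mean_fpkm.<project>` and `ppt.<project>` columns.
#' @export
build_expression_records <- function(proteins, fpkm, classes,
                                     keep_zero_protein = FALSE) {
  stopifnot(all(c("gene_id", "abundance") %in% names(proteins)),
            all(c("gene_id", "project", "fpkm") %in% names(fpkm)))
  out <- merge(classes[, c("gene_id", "label")],
               data.frame(gene_id = proteins$gene_id,
                          protein_abundance = proteins$abundance,
                          stringsAsFactors = FALSE),
               by = "gene_id")
  if (!keep_zero_protein) out <- out[out$protein_abundance > 0, , drop = FALSE]
  for (proj in unique(fpkm$project)) {
    sub <- fpkm[fpkm$project == proj, , drop = FALSE]
    mf <- tapply(sub$fpkm, sub$gene_id, mean)
    mfv <- as.numeric(mf)[match(out$gene_id, names(mf))]
    out[[paste0("mean_fpkm.", proj)]] <- mfv
    out[[paste0("ppt.", proj)]] <- protein_per_transcript(out$protein_abundance, mfv)
  }
  rownames(out) <- NULL
  out
}
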