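# SD/anti-SD complementarity scanning: maximal contiguous antiparallel
# Watson-Crick duplexes (>= 4 nt) between 30-nt upstream windows and the 16S
# rRNA 3' tail, the D_toStart spacing statistic, and gene classification.

#' Enumerate SD/anti-SD duplexes in an upstream window
#'
#' Finds every maximal contiguous antiparallel Watson-Crick duplex of length
#' at least `min_len` between an upstream window and the anti-SD tail, over
#' all window and tail offsets. Maximal means not extendable on either side.
#' Window position `p` (most 5' paired base, labelled -L..-1 with -1 abutting
#' the start codon) pairs tail position `t_hi` (most 3' paired tail base).
#'
#' @param window upstream window, RNA (or DNA; transcribed) string of length
#'   at most 30. An `upstream_window` object is also accepted.
#' @param tail anti-SD tail, RNA string (5'->3'), length 5..20.
#' @param min_len minimum duplex length (default 4).
#' @param wobble also allow G:U pairs (default FALSE; Watson-Crick only).
#' @return data.frame with one row per maximal duplex: `p`, `q` (window
#'   positions, negative), `t_lo`, `t_hi` (tail positions, 1-based),
#'   `match_len`, `match_seq` (the window-side SD sequence, 5'->3') and
#'   `d_to_start`. Windows shorter than `min_len` yield zero rows.
#' @examples
#' find_sd_matches("AAAAAAAAAAAAAAAAAAAAGGAGGAAAAA", "GAUCACCUCCUUU")
#' @export
find_sd_matches <- function(window, tail, min_len = 4, wobble = FALSE) {
  if (inherits(window, "upstream_window")) window <- window$seq
  w <- assert_rna(dna_to_rna(window), "window")
  tail <- assert_rna(dna_to_rna(tail), "tail")
  L <- nchar(tail)
  W <- nchar(w)
  empty <- data.frame(p = integer(0), q = integer(0), t_lo = integer(0),
                      t_hi = integer(0), match_len = integer(0),
                      match_seq = character(0), d_to_start = integer(0),
                      stringsAsFactors = FALSE)
  if (W < min_len) return(empty)
  m <- scan_pair_cpp(w, tail, as.integer(min_len), isTRUE(wobble))
  if (!nrow(m)) return(empty)
  p <- m[, 1] - W - 1L
  q <- m[, 2] - W - 1L
  data.frame(p = p, q = q, t_lo = m[, 3], t_hi = m[, 4],
             match_len = m[, 2] - m[, 1] + 1L,
             match_seq = substring(w, m[, 1], m[, 2]),
             d_to_start = compute_d_to_start(p, m[, 4], L),
             stringsAsFactors = FALSE)
}

#' D_toStart spacing statistic
#'
#' Number of mRNA nucleotides from the projected position of the tail's
#' 3'-terminal base (given the antiparallel SD/anti-SD duplex) through the
#' base immediately upstream of the start codon, inclusive:
#' `|p| + (tail_len - t_hi)`.
#'
#' @param p window position of the duplex's 5'-most paired base (negative,
#'   -1 abuts the start codon).
#' @param t_hi tail position (1-based) paired with `p`.
#' @param tail_len tail length L.
#' @return positive integer (vectorised).
#' @examples
#' compute_d_to_start(-11, 11, 13) # 13
#' @export
compute_d_to_start <- function(p, t_hi, tail_len) {
  abs(p) + (tail_len - t_hi)
}

#' Scan all genes' upstream windows against a tail
#'
#' @param windows data.frame from [upstream_windows()] (columns `gene_id`,
#'   `window_seq`).
#' @param tail anti-SD tail (RNA).
#' @param min_len minimum duplex length (default 4).
#' @param wobble allow G:U pairs (default FALSE).
#' @return data.frame of all maximal matches with a `gene_id` column.
#' @export
scan_genes <- function(windows, tail, min_len = 4, wobble = FALSE) {
  res <- lapply(seq_len(nrow(windows)), function(i) {
    m <- find_sd_matches(windows$window_seq[i], tail, min_len, wobble)
    if (nrow(m)) cbind(gene_id = windows$gene_id[i], m, stringsAsFactors = FALSE)
    else NULL
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(data.frame(gene_id = character(0), p = integer(0), q = integer(0),
                      t_lo = integer(0), t_hi = integer(0),
                      match_len = integer(0), match_seq = character(0),
                      d_to_start = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Per-gene representative match: longest, ties -> smallest D_toStart.
representative_matches <- function(matches) {
  if (!nrow(matches)) return(matches)
  ord <- order(matches$gene_id, -matches$match_len, matches$d_to_start)
  m <- matches[ord, , drop = FALSE]
  m <- m[!duplicated(m$gene_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Classify genes as SD-facilitated or SD-independent
#'
#' A gene is SD-facilitated iff at least one of its duplexes has D_toStart
#' inside the configured optimal range; its best match is then the in-range
#' match of greatest length (ties toward smaller D_toStart). SD-independent
#' genes carry their longest overall match, or none.
#'
#' @param matches match table from [scan_genes()].
#' @param gene_ids all gene identifiers to classify (genes without matches
#'   are SD-independent).
#' @param optimal_range inclusive integer interval `c(lo, hi)`; use the
#'   species' preferred D_toStart range (see [optimal_dtostart_ranges()]).
#' @return data.frame with `gene_id`, `label` (`SD-facilitated` /
#'   `SD-independent`), `best_len`, `best_d`, `best_seq` (NA when no match);
#'   attribute `optimal_range`.
#' @export
classify_genes <- function(matches, gene_ids, optimal_range) {
  stopifnot(length(optimal_range) == 2, optimal_range[1] <= optimal_range[2])
  out <- data.frame(gene_id = gene_ids, label = "SD-independent",
                    best_len = NA_integer_, best_d = NA_integer_,
                    best_seq = NA_character_, stringsAsFactors = FALSE)
  if (nrow(matches)) {
    inr <- matches[matches$d_to_start >= optimal_range[1] &
                   matches$d_to_start <= optimal_range[2], , drop = FALSE]
    rep_in <- representative_matches(inr)
    rep_all <- representative_matches(matches)
    fac <- out$gene_id %in% rep_in$gene_id
    out$label[fac] <- "SD-facilitated"
    pick <- function(ids, rep) {
      i <- match(ids, rep$gene_id)
      list(len = rep$match_len[i], d = rep$d_to_start[i], seq = rep$match_seq[i])
    }
    pin <- pick(out$gene_id[fac], rep_in)
    out$best_len[fac] <- pin$len; out$best_d[fac] <- pin$d; out$best_seq[fac] <- pin$seq
    ind <- !fac & out$gene_id %in% rep_all$gene_id
    pall <- pick(out$gene_id[ind], rep_all)
    out$best_len[ind] <- pall$len; out$best_d[ind] <- pall$d; out$best_seq[ind] <- pall$seq
  }
  attr(out, "optimal_range") <- as.integer(optimal_range)
  out
}

#' Propose an optimal D_toStart range
#'
#' Helper that returns the shortest contiguous integer interval containing at
#' least `mass` of the supplied D_toStart values (ties toward the smaller
#' left end). Classification always uses an explicitly configured range; the
#' bundled per-species defaults are in [optimal_dtostart_ranges()].
#'
#' @param d_values integer D_toStart values (non-empty).
#' @param mass fraction of values the interval must cover (default 0.6).
#' @return integer `c(lo, hi)`.
#' @export
propose_optimal_range <- function(d_values, mass = 0.6) {
  if (!length(d_values)) stop("d_values is empty", call. = FALSE)
  v <- sort(as.integer(d_values))
  n <- length(v)
  k <- ceiling(mass * n)
  i <- seq_len(n - k + 1)
  width <- v[i + k - 1] - v[i]
  best <- i[order(width, v[i])][1]
  c(v[best], v[best + k - 1])
}

#' SD motif usage table
#'
#' Tabulates the relative frequency of each distinct matched SD string (the
#' window-side sequence of the duplex) over the selected matches; proportions
#' sum to 1.
#'
#' @param matches match table (e.g. from [scan_genes()] or
#'   [representative_matches()]).
#' @param which `"all"` matches or `"optimal"` (D_toStart within
#'   `optimal_range` only).
#' @param optimal_range required when `which = "optimal"`.
#' @return data.frame with `motif`, `count`, `proportion`, sorted by
#'   decreasing proportion; zero rows when there are no matches.
#' @export
motif_usage_table <- function(matches, which = c("all", "optimal"),
                              optimal_range = NULL) {
  which <- match.arg(which)
  if (which == "optimal") {
    stopifnot(!is.null(optimal_range))
    matches <- matches[matches$d_to_start >= optimal_range[1] &
                       matches$d_to_start <= optimal_range[2], , drop = FALSE]
  }
  if (!nrow(matches)) {
    return(data.frame(motif = character(0), count = integer(0),
                      proportion = numeric(0), stringsAsFactors = FALSE))
  }
  tab <- sort(table(matches$match_seq), decreasing = TRUE)
  data.frame(motif = names(tab), count = as.integer(tab),
             proportion = as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Plot a D_toStart histogram
#'
#' @param matches match table with a `d_to_start` column (all maximal
#'   matches by default, per-gene representatives if pre-filtered).
#' @param ... passed to [graphics::hist()].
#' @return invisibly, the histogram object.
#' @export
plot_d_to_start <- function(matches, ...) {
  invisible(graphics::hist(matches$d_to_start,
                           breaks = seq(0.5, max(matches$d_to_start) + 0.5),
                           xlab = "D_toStart (nt)", main = "", ...))
}
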