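# Observed-vs-expected site-specific anti-SD usage across the 3' tail and
# the upper-tailed CLT Z-test for preferred anti-SD sites.

#' Observed site-specific anti-SD usage
#'
#' Each duplex increments every tail site it pairs, so `O[i]` counts how many
#' matches involve tail site `i`; the total `sum(O)` equals the summed match
#' lengths.
#'
#' @param matches match table from [scan_genes()] (single tail).
#' @param tail_len tail length L.
#' @return integer vector of length `tail_len`.
#' @export
tabulate_observed_usage <- function(matches, tail_len) {
  O <- integer(tail_len)
  if (nrow(matches)) {
    sites <- unlist(mapply(seq.int, matches$t_lo, matches$t_hi, SIMPLIFY = FALSE))
    tab <- tabulate(sites, nbins = tail_len)
    O <- as.integer(tab)
  }
  O
}

#' Observed site usage directly from windows
#'
#' Equivalent to [scan_genes()] followed by [tabulate_observed_usage()], but
#' runs the whole window set in compiled code; convenient for large
#' simulation studies.
#'
#' @param windows data.frame with `window_seq`, or a character vector (RNA).
#' @param tail anti-SD tail (RNA).
#' @param min_len minimum duplex length (default 4).
#' @param wobble allow G:U pairs (default FALSE).
#' @return integer vector `O` of length `nchar(tail)`.
#' @export
observed_site_usage <- function(windows, tail, min_len = 4, wobble = FALSE) {
  ws <- if (is.data.frame(windows)) windows$window_seq else windows
  ws <- assert_rna(dna_to_rna(ws), "windows")
  tail <- assert_rna(dna_to_rna(tail), "tail")
  as.integer(site_counts_cpp(ws, tail, as.integer(min_len), isTRUE(wobble)))
}

#' Expected site usage under composition-preserving shuffling
#'
#' For each replicate every window's bases are permuted uniformly at random
#' (mononucleotide composition preserved), the duplex scan is rerun, and
#' per-site counts accumulated; the expectation is the per-site mean across
#' replicates, optionally rescaled so that the expected total matches the
#' observed total `n` (the normalisation behind the expected proportions).
#' Reproducible given `seed`.
#'
#' @param windows data.frame with `window_seq` (same gene set as the
#'   observed tabulation) or a character vector of windows (RNA).
#' @param tail anti-SD tail (RNA).
#' @param min_len minimum duplex length (default 4).
#' @param n_shuffles shuffle replicates (default 1000).
#' @param seed optional RNG seed.
#' @param rescale_to observed total `n` to rescale the expectation to
#'   (`sum(E) == n` exactly); NULL leaves raw per-shuffle means.
#' @param wobble allow G:U pairs (default FALSE).
#' @return numeric vector `E` of length `nchar(tail)`.
#' @export
estimate_expected_usage <- function(windows, tail, min_len = 4,
                                    n_shuffles = 1000, seed = NULL,
                                    rescale_to = NULL, wobble = FALSE) {
  ws <- if (is.data.frame(windows)) windows$window_seq else windows
  ws <- assert_rna(dna_to_rna(ws), "windows")
  tail <- assert_rna(dna_to_rna(tail), "tail")
  if (!is.null(seed)) set.seed(seed)
  E <- shuffle_counts_cpp(ws, tail, as.integer(min_len), isTRUE(wobble),
                          as.integer(n_shuffles))
  if (!is.null(rescale_to)) {
    if (rescale_to <= 0) stop("rescale_to (observed n) must be positive", call. = FALSE)
    if (sum(E) == 0) {
      stop("expected usage is zero at every site under shuffling; ",
           "the expectation is undefined for this window set", call. = FALSE)
    }
    E <- E * (rescale_to / sum(E))
  }
  E
}

#' Upper-tailed Z-test for preferred anti-SD sites
#'
#' With `n = sum(O)`, observed proportions `p_i = O_i/n` and expected
#' proportions `phat_i = E_i/n` (E rescaled to total `n`), computes
#' `Z_i = (p_i - phat_i) / sqrt(phat_i (1 - phat_i) / n)` and flags site `i`
#' significant when `Z_i >= z_crit` (one-sided 5% at the 1.645 default; no
#' multiple-testing correction). Sites with `E_i = 0` are untestable and are
#' excluded from the preferred motif, which is the longest contiguous run of
#' significant sites (ties toward the most 3' run).
#'
#' @param O observed site counts.
#' @param E expected site counts (rescaled internally so `sum(E) == sum(O)`).
#' @param z_crit significance threshold (default 1.645).
#' @param tail optional tail sequence (RNA) used to label sites.
#' @return object of class `anti_sd_usage`: `table` (site, base, O, E,
#'   oe_ratio, p, phat, z, significant, untestable), `n`, `z_crit`,
#'   `preferred_motif` (possibly "").
#' @export
z_test_sites <- function(O, E, z_crit = 1.645, tail = NULL) {
  stopifnot(length(O) == length(E))
  n <- sum(O)
  if (n <= 0) stop("sum(O) must be positive", call. = FALSE)
  if (sum(E) <= 0) stop("sum(E) must be positive", call. = FALSE)
  E <- E * (n / sum(E))
  p <- O / n
  phat <- E / n
  untestable <- E == 0
  z <- rep(NA_real_, length(O))
  idx <- !untestable
  z[idx] <- (p[idx] - phat[idx]) / sqrt(phat[idx] * (1 - phat[idx]) / n)
  significant <- !untestable & z >= z_crit
  bases <- if (!is.null(tail)) strsplit(assert_rna(dna_to_rna(tail)), "", fixed = TRUE)[[1]]
           else rep(NA_character_, length(O))
  tab <- data.frame(site = seq_along(O), base = bases, O = O, E = E,
                    oe_ratio = ifelse(E > 0, O / E, NA_real_),
                    p = p, phat = phat, z = z,
                    significant = significant, untestable = untestable,
                    stringsAsFactors = FALSE)
  motif <- ""
  if (any(significant)) {
    r <- rle(significant)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    best <- runs[order(-r$lengths[runs], -starts[runs])][1]
    if (!is.null(tail)) {
      motif <- paste(bases[starts[best]:ends[best]], collapse = "")
    } else {
      motif <- paste0("sites ", starts[best], "..", ends[best])
    }
  }
  structure(list(table = tab, n = n, z_crit = z_crit, preferred_motif = motif),
            class = "anti_sd_usage")
}

#' @export
print.anti_sd_usage <- function(x, digits = 3, ...) {
  cat("<anti_sd_usage> n = ", x$n, ", z_crit = ", x$z_crit, "\n", sep = "")
  tab <- x$table
  tab$O <- round(tab$O, 1); tab$E <- round(tab$E, 1)
  tab$oe_ratio <- round(tab$oe_ratio, digits)
  tab$z <- round(tab$z, digits)
  print(tab[, c("site", "base", "O", "E", "oe_ratio", "z", "significant")],
        row.names = FALSE)
  cat("preferred anti-SD motif: ",
      if (nzchar(x$preferred_motif)) paste0("5'-", x$preferred_motif, "-3'")
      else "(none)", "\n", sep = "")
  invisible(x)
}

#' Full anti-SD site-preference analysis
#'
#' Convenience wrapper: observed usage from the real windows, expected usage
#' from composition-preserving shuffles of the same windows, then the
#' upper-tailed Z-test.
#'
#' @inheritParams estimate_expected_usage
#' @inheritParams z_test_sites
#' @return an `anti_sd_usage` object (see [z_test_sites()]).
#' @export
anti_sd_preference <- function(windows, tail, min_len = 4, n_shuffles = 1000,
                               seed = NULL, z_crit = 1.645, wobble = FALSE) {
  tail <- assert_rna(dna_to_rna(tail), "tail")
  ws <- if (is.data.frame(windows)) windows else data.frame(
    gene_id = sprintf("g%04d", seq_along(windows)), window_seq = windows,
    stringsAsFactors = FALSE)
  matches <- scan_genes(ws, tail, min_len, wobble)
  O <- tabulate_observed_usage(matches, nchar(tail))
  if (sum(O) == 0) {
    stop("no duplexes found in the observed windows; site usage undefined",
         call. = FALSE)
  }
  E <- estimate_expected_usage(ws, tail, min_len, n_shuffles, seed,
                               rescale_to = sum(O), wobble = wobble)
  z_test_sites(O, E, z_crit = z_crit, tail = tail)
}
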