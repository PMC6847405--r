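# Minimum free energy of the 40-nt translation-initiation region, delegated
# to the ViennaRNA folding engine (RNAfold) at 37 C with lonely pairs
# disallowed. Energy-model internals are not reimplemented.

rnafold_path <- function() {
  p <- Sys.which("RNAfold")
  if (!nzchar(p)) {
    stop("RNAfold (ViennaRNA) not found on the PATH; minimum-free-energy ",
         "computation requires it", call. = FALSE)
  }
  p
}

#' Folding engine version string
#' @return e.g. `"RNAfold 2.7.2"`.
#' @export
rnafold_version <- function() {
  out <- suppressWarnings(system2(rnafold_path(), "--version", stdout = TRUE))
  trimws(out[1])
}

#' Minimum free energy of RNA sequences
#'
#' Folds each sequence with a standard nearest-neighbour model at 37 C,
#' lonely (isolated) pairs disallowed by default, and returns the MFE in
#' kcal/mol (<= 0; a sequence admitting no pair folds to exactly 0). The
#' engine name/version is recorded in the `engine` attribute.
#'
#' @param seqs character vector of RNA sequences (DNA accepted and
#'   transcribed).
#' @param no_lonely_pairs disallow isolated base pairs (default TRUE).
#' @param temperature folding temperature in Celsius (default 37).
#' @return named numeric vector of MFEs with attribute `engine`.
#' @export
compute_mfe <- function(seqs, no_lonely_pairs = TRUE, temperature = 37) {
  if (!length(seqs)) stop("no sequences supplied", call. = FALSE)
  seqs <- assert_rna(dna_to_rna(seqs), "sequence")
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("seq%05d", seq_along(seqs))
  args <- c("--noPS", if (no_lonely_pairs) "--noLP",
            if (temperature != 37) c("--temp", format(temperature)))
  inp <- as.vector(rbind(paste0(">", ids), unname(seqs)))
  out <- system2(rnafold_path(), args, stdout = TRUE, input = inp)
  en_lines <- grep("\\(\\s*-?\\d+\\.\\d+\\)\\s*$", out, value = TRUE)
  if (length(en_lines) != length(seqs)) {
    stop("RNAfold returned ", length(en_lines), " energies for ",
         length(seqs), " sequences", call. = FALSE)
  }
  mfe <- as.numeric(sub(".*\\(\\s*(-?\\d+\\.\\d+)\\)\\s*$", "\\1", en_lines))
  names(mfe) <- ids
  attr(mfe, "engine") <- rnafold_version()
  mfe
}

#' MFE of the translation-initiation region for all genes
#'
#' Extracts the `window_len` nt immediately upstream of each start codon
#' (wrapping on circular replicons; truncated with a flag on linear ones)
#' and folds them.
#'
#' @param genome an [sd_genome].
#' @param window_len initiation-region length in nt (default 40).
#' @param include_pseudo include pseudo genes (default FALSE).
#' @inheritParams compute_mfe
#' @return data.frame with `gene_id`, `window_seq`, `truncated`,
#'   `mfe_kcal_mol`; attribute `engine` records the folding engine.
#' @export
mfe_initiation_regions <- function(genome, window_len = 40,
                                   include_pseudo = FALSE,
                                   no_lonely_pairs = TRUE, temperature = 37) {
  w <- upstream_windows(genome, window_len, include_pseudo)
  mfe <- compute_mfe(stats::setNames(w$window_seq, w$gene_id),
                     no_lonely_pairs, temperature)
  out <- data.frame(gene_id = w$gene_id, window_seq = w$window_seq,
                    truncated = w$truncated, mfe_kcal_mol = unname(mfe),
                    stringsAsFactors = FALSE)
  attr(out, "engine") <- attr(mfe, "engine")
  out
}
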