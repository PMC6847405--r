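# Small sequence helpers shared across modules. Sequences are plain upper-case
# character scalars internally; Biostrings is used at file boundaries.

DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return character vector of reverse complements (upper case).
#' @examples
#' rev_comp("ATGC")
#' @export
rev_comp <- function(x) {
  x <- toupper(x)
  vapply(x, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    comp <- DNA_COMP[chars]
    if (anyNA(comp)) stop("invalid DNA character in sequence", call. = FALSE)
    paste(rev(comp), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Transcribe DNA to RNA alphabet
#'
#' Upper-cases and replaces T with U; RNA input passes through unchanged.
#'
#' @param x character vector.
#' @return character vector in the RNA alphabet.
#' @examples
#' dna_to_rna("ttaggaggt")
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' Back-transcribe RNA to DNA alphabet
#' @param x character vector.
#' @return character vector in the DNA alphabet.
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

# Validate an RNA string (strict alphabet).
assert_rna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", toupper(x))
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,U}: %s",
                 what, paste(utils::head(x[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  toupper(x)
}

# IUPAC-aware motif -> regular expression (RNA alphabet).
iupac_to_regex <- function(motif) {
  map <- c(A = "A", C = "C", G = "G", U = "U", T = "U",
           R = "[AG]", Y = "[CU]", S = "[GC]", W = "[AU]",
           K = "[GU]", M = "[AC]", B = "[CGU]", D = "[AGU]",
           H = "[ACU]", V = "[ACG]", N = "[ACGU]")
  chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  out <- map[chars]
  if (anyNA(out)) stop("invalid IUPAC code in motif: ", motif, call. = FALSE)
  paste(out, collapse = "")
}

# Deterministic per-stage seed derived from one global seed (kept < 2^31).
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  (abs(seed) * 7919 + 104729 * stage) %% 2147483629
}

# substring on a circular sequence; from..to may run off either end.
circ_substr <- function(seq, from, to) {
  n <- nchar(seq)
  idx <- ((seq.int(from, to) - 1) %% n) + 1
  paste(strsplit(seq, "", fixed = TRUE)[[1]][idx], collapse = "")
}
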