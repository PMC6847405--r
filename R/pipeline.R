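# Pipeline orchestration: one configuration object, staged execution
# (tail call -> SD scan -> classification -> site preference -> expression
# -> MFE -> contrasts), and a manifest that reproduces every number.

#' Bundled per-species preferred D_toStart ranges
#'
#' Inclusive optimal spacing ranges (nt) within which a >=4-nt SD/anti-SD
#' duplex marks a gene as SD-facilitated; overridable per run.
#'
#' @return data.frame with `species`, `lo`, `hi`.
#' @export
optimal_dtostart_ranges <- function() {
  data.frame(
    species = c("Synechocystis sp.", "Microcystis aeruginosa",
                "S-SSM6a", "S-SSM6b",
                "Nicotiana tabacum chloroplast",
                "Arabidopsis thaliana chloroplast"),
    lo = c(11, 11, 8, 10, 8, 10),
    hi = c(21, 20, 16, 21, 16, 21),
    stringsAsFactors = FALSE)
}

#' Build a pipeline run configuration
#'
#' Thresholds default to the study's standard values: 30-nt windows, duplex
#' length at least 4 nt, 25-column ungapped mapping at 0.95 identity, and a
#' site-test threshold of Z = 1.645.
#'
#' @param species species label; when it matches a row of
#'   [optimal_dtostart_ranges()] the bundled range is used unless
#'   `optimal_range` is given.
#' @param genome an [sd_genome] (or a path readable by [load_genome()]).
#' @param gff optional GFF3 path when `genome` is a FASTA path.
#' @param reads optional reads input for tail calling (path/vector/df).
#' @param rdna_16s optional 16S rDNA sequence for tail calling.
#' @param tail optional anti-SD tail override (RNA); skips tail calling.
#' @param optimal_range optional `c(lo, hi)` D_toStart range.
#' @param proteins optional protein table (`gene_id`, `abundance`).
#' @param fpkm optional FPKM table (`gene_id`, `project`, `fpkm`).
#' @param window_len upstream-window length for SD scanning (default 30).
#' @param mfe_window initiation-region length for folding (default 40).
#' @param min_match,min_identity mapper thresholds (25, 0.95).
#' @param min_len minimum duplex length (default 4).
#' @param z_crit site-test threshold (default 1.645).
#' @param n_shuffles shuffle replicates for the expected usage (default 1000).
#' @param run_mfe fold initiation regions (default TRUE when RNAfold is
#'   available and `genome` is present).
#' @param seed global seed, split deterministically across stages.
#' @return list of class `sd_run_config`.
#' @export
sd_run_config <- function(species = "unspecified", genome = NULL, gff = NULL,
                          reads = NULL, rdna_16s = NULL, tail = NULL,
                          optimal_range = NULL, proteins = NULL, fpkm = NULL,
                          window_len = 30, mfe_window = 40,
                          min_match = 25, min_identity = 0.95, min_len = 4,
                          z_crit = 1.645, n_shuffles = 1000,
                          run_mfe = NULL, seed = 1) {
  if (is.null(optimal_range)) {
    tab <- optimal_dtostart_ranges()
    i <- match(species, tab$species)
    optimal_range <- if (!is.na(i)) c(tab$lo[i], tab$hi[i]) else c(11, 21)
  }
  if (is.null(tail) && (is.null(reads) || is.null(rdna_16s))) {
    stop("config invalid: supply either `tail` or both `reads` and `rdna_16s`",
         call. = FALSE)
  }
  structure(list(species = species, genome = genome, gff = gff, reads = reads,
                 rdna_16s = rdna_16s, tail = tail,
                 optimal_range = optimal_range, proteins = proteins,
                 fpkm = fpkm, window_len = window_len, mfe_window = mfe_window,
                 min_match = min_match, min_identity = min_identity,
                 min_len = min_len, z_crit = z_crit, n_shuffles = n_shuffles,
                 run_mfe = run_mfe, seed = seed),
            class = "sd_run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full SD-usage pipeline
#'
#' Executes tail calling (or uses the configured tail override), upstream
#' window extraction, duplex scanning, gene classification, the anti-SD
#' site-preference test, and, when inputs are available, expression and MFE
#' contrasts. The returned report carries a manifest (package and engine
#' versions, seeds, thresholds) sufficient to reproduce every number.
#'
#' @param config an [sd_run_config()].
#' @return list of class `sd_report` with elements `tail_call`, `tail`,
#'   `windows`, `matches`, `classes`, `usage`, `expression`, `contrasts`,
#'   `mfe`, `manifest`.
#' @export
run_sd_pipeline <- function(config) {
  stopifnot(inherits(config, "sd_run_config"))
  genome <- config$genome
  if (is.character(genome)) {
    genome <- run_stage("load_genome", load_genome(genome, gff = config$gff))
  }
  tail_call <- NULL
  tail <- config$tail
  if (is.null(tail)) {
    tail_call <- run_stage("tail_call", {
      q <- build_query(config$rdna_16s)
      p <- map_read_ends(config$reads, q, config$min_match, config$min_identity)
      tc <- call_prominent_tail(p)
      tc$secondary <- detect_secondary_tails(p, tc)
      tc
    })
    tail <- tail_call$tail_seq
  }
  windows <- matches <- classes <- usage <- NULL
  if (!is.null(genome)) {
    windows <- run_stage("windows", upstream_windows(genome, config$window_len))
    matches <- run_stage("sd_scan", scan_genes(windows, tail, config$min_len))
    classes <- run_stage("classify",
                         classify_genes(matches, windows$gene_id,
                                        config$optimal_range))
    usage <- run_stage("anti_sd", {
      O <- tabulate_observed_usage(matches, nchar(tail))
      if (sum(O) > 0) {
        E <- estimate_expected_usage(windows, tail, config$min_len,
                                     config$n_shuffles,
                                     seed = stage_seed(config$seed, 3),
                                     rescale_to = sum(O))
        z_test_sites(O, E, config$z_crit, tail = tail)
      } else NULL
    })
  }
  expression <- contrasts <- NULL
  if (!is.null(config$proteins) && !is.null(classes)) {
    expression <- run_stage("expression", {
      if (!is.null(config$fpkm)) {
        build_expression_records(config$proteins, config$fpkm, classes)
      } else {
        recs <- merge(classes[, c("gene_id", "label")],
                      data.frame(gene_id = config$proteins$gene_id,
                                 protein_abundance = config$proteins$abundance,
                                 stringsAsFactors = FALSE), by = "gene_id")
        recs[recs$protein_abundance > 0, , drop = FALSE]
      }
    })
    contrasts <- run_stage("contrasts", {
      out <- list(protein_abundance = contrast_groups(expression, "protein_abundance"))
      for (cn in grep("^ppt\\.", names(expression), value = TRUE)) {
        out[[cn]] <- contrast_groups(expression, cn)
      }
      out
    })
  }
  mfe <- NULL
  do_mfe <- config$run_mfe %||% (!is.null(genome) && nzchar(Sys.which("RNAfold")))
  if (isTRUE(do_mfe) && !is.null(genome)) {
    mfe <- run_stage("mfe", mfe_initiation_regions(genome, config$mfe_window))
    if (!is.null(classes)) {
      m <- merge(classes[, c("gene_id", "label")],
                 mfe[, c("gene_id", "mfe_kcal_mol")], by = "gene_id")
      names(m)[names(m) == "mfe_kcal_mol"] <- "mfe"
      contrasts$mfe <- run_stage("mfe_contrast", contrast_groups(m, "mfe"))
    }
  }
  manifest <- list(
    package = as.character(utils::packageVersion("sdscan")),
    r_version = R.version.string,
    folding_engine = if (!is.null(mfe)) attr(mfe, "engine") else NA_character_,
    species = config$species, seed = config$seed,
    tail = tail, tail_called = is.null(config$tail),
    optimal_range = config$optimal_range,
    thresholds = config[c("window_len", "mfe_window", "min_match",
                          "min_identity", "min_len", "z_crit", "n_shuffles")])
  structure(list(tail_call = tail_call, tail = tail, windows = windows,
                 matches = matches, classes = classes, usage = usage,
                 expression = expression, contrasts = contrasts, mfe = mfe,
                 manifest = manifest),
            class = "sd_report")
}

#' @export
print.sd_report <- function(x, ...) {
  cat("<sd_report> ", x$manifest$species, "\n", sep = "")
  cat("  anti-SD tail: 5'-", x$tail, "-3'",
      if (x$manifest$tail_called) " (called from reads)" else " (override)",
      "\n", sep = "")
  if (!is.null(x$classes)) {
    tab <- table(x$classes$label)
    n_fac <- if ("SD-facilitated" %in% names(tab)) tab[["SD-facilitated"]] else 0
    cat("  genes: ", nrow(x$classes), " (",
        n_fac, " SD-facilitated within D_toStart ",
        x$manifest$optimal_range[1], "..", x$manifest$optimal_range[2],
        ")\n", sep = "")
  }
  if (!is.null(x$usage)) {
    cat("  preferred anti-SD motif: ",
        if (nzchar(x$usage$preferred_motif)) paste0("5'-", x$usage$preferred_motif, "-3'")
        else "(none)", "\n", sep = "")
  }
  for (nm in names(x$contrasts)) {
    ct <- x$contrasts[[nm]]
    cat("  contrast ", nm, ": p = ", signif(ct$p_value, 4), "\n", sep = "")
  }
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Emits TSV tables (pileup/windows/matches/classes/site usage/MFE) and a
#' JSON summary with the manifest and contrast statistics.
#'
#' @param report an `sd_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_sd_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$windows)) write_tsv(report$windows, file.path(dir, "windows.tsv"))
  if (!is.null(report$matches)) write_tsv(report$matches, file.path(dir, "sd_matches.tsv"))
  if (!is.null(report$classes)) write_tsv(report$classes, file.path(dir, "gene_classes.tsv"))
  if (!is.null(report$usage)) write_tsv(report$usage$table, file.path(dir, "anti_sd_usage.tsv"))
  if (!is.null(report$mfe)) write_tsv(report$mfe, file.path(dir, "mfe.tsv"))
  if (!is.null(report$expression)) write_tsv(report$expression, file.path(dir, "expression.tsv"))
  summary <- list(
    manifest = report$manifest,
    tail = report$tail,
    tail_call = if (!is.null(report$tail_call)) {
      list(terminus = report$tail_call$terminus,
           peak_count = report$tail_call$peak_count,
           downstream_sum = report$tail_call$downstream_sum,
           secondary = lapply(report$tail_call$secondary, function(s)
             list(tail_seq = s$tail_seq, peak_count = s$peak_count)))
    },
    preferred_motif = if (!is.null(report$usage)) report$usage$preferred_motif,
    contrasts = lapply(report$contrasts, function(ct)
      list(metric = ct$metric, n_facilitated = ct$n_facilitated,
           n_independent = ct$n_independent,
           medians = as.list(ct$medians),
           statistic = ct$statistic, p_value = ct$p_value)))
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
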