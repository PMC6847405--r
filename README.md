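# sdscan

Shine–Dalgarno (SD) usage analysis for bacteria, cyanophages and
chloroplasts, from three standard inputs: an annotated genome
(GenBank or FASTA+GFF3), RNA-Seq reads (FASTA/FASTQ/SAM) and a
protein-abundance table (TSV).

Translation initiation in prokaryotes is often rate-limiting, and an SD
sequence in the 5' UTR recruits the ribosome by pairing with the anti-SD —
the 3'-terminal single-stranded segment ("tail") of mature 16S rRNA.
Because the mature 16S 3' end is frequently mis-annotated, `sdscan` first
calls it empirically from RNA-Seq, then quantifies SD usage against the
called tail. The pipeline:

1. **Tail calling** — read 3' ends are piled up along a 205-nt query
   (`CCTCC` core anti-SD motif ± 100 nt of rDNA). A terminus is called
   when its implied tail contains `CCUCC` and ends within (or ≤ 4 nt
   downstream of) the conserved block `5'-GAUCACCUCCUU(U/A)-3'`, and its
   count exceeds the summed counts of the next five sites. Secondary peaks
   ≥ 25% of the primary are reported (tail heterogeneity).
2. **SD scanning** — every maximal contiguous antiparallel Watson–Crick
   duplex ≥ 4 nt between each gene's 30-nt upstream window and the tail,
   with the spacing statistic

   `D_toStart = |p| + (L_tail − t_hi)`

   — the distance (nt) from the projected 16S 3' terminus to the base
   immediately upstream of the start codon, which is comparable across SD
   variants because initiation geometry is set by the tail end, not the
   motif.
3. **Anti-SD site preference** — per-site observed counts `O_i` vs
   expected `E_i` from composition-preserving window shuffles;
   `Z_i = (p_i − p̂_i)/sqrt(p̂_i(1−p̂_i)/n)`, preferred when `Z_i ≥ 1.645`
   (upper-tailed 5%).
4. **Classification and contrasts** — genes with an in-range duplex
   (e.g. `D_toStart` 11–21 for *Synechocystis* sp.) are *SD-facilitated*;
   contrasts of protein abundance, protein-per-transcript
   (abundance / mean FPKM) and 40-nt 5'-UTR minimum free energy
   (ViennaRNA `RNAfold`, no lonely pairs) between classes use the Wilcoxon
   rank-sum test; motif-usage concordance uses Kendall's tau-b.

A synthetic-data module generates all three inputs with recorded ground
truth (planted terminus, planted per-gene `D_toStart`, planted expression
effect), so the whole chain is verifiable without downloads.

## Worked example (synthetic data)

```r
library(sdscan)
gsim  <- simulate_genome(n_genes = 300, seed = 42)     # planted SDs, D in 11..21
rdna  <- make_synthetic_rdna(seed = 42)                # planted mature terminus
reads <- simulate_16s_reads(rdna$seq, rdna$terminus, depth = 1000, seed = 43)

wdf <- upstream_windows(gsim$genome)
cl  <- classify_genes(scan_genes(wdf, gsim$tail), wdf$gene_id, c(11, 21))
ex  <- simulate_expression(cl, effect = 2, seed = 44)  # 2x protein effect

cfg <- sd_run_config(species = "synthetic", genome = gsim$genome,
                     reads = reads$reads, rdna_16s = rdna$seq,
                     optimal_range = c(11, 21), proteins = ex$proteins,
                     n_shuffles = 500, seed = 42)
report <- run_sd_pipeline(cfg)
report
#> <sd_report> synthetic
#>   anti-SD tail: 5'-GAUCACCUCCUUU-3' (called from reads)
#>   genes: 300 (205 SD-facilitated within D_toStart 11..21)
#>   preferred anti-SD motif: (none)
#>   contrast protein_abundance: p = 2.343e-09
#>   contrast mfe: p = 0.0646
```

Reading the output: the caller recovered the planted 13-nt tail
`GAUCACCUCCUUU` from the read pileup; 205 of 300 genes carry a ≥ 4-nt SD
duplex at an in-range spacing (the 60% planted fraction plus chance
matches); the planted 2× protein effect is detected
(Wilcoxon p ≈ 2×10⁻⁹), while no anti-SD site preference is declared —
correct, since this generator plants SDs at uniform positions along the
tail. Per-site detail sits in `report$usage` (O, E, O:E, Z per tail site),
per-gene classes in `report$classes`, folded windows in `report$mfe`, and
`write_sd_report(report, dir)` emits the TSV/JSON bundle. A thin
command-line wrapper over the same functions ships at
`inst/cli/sdscan-pipeline.R`.

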