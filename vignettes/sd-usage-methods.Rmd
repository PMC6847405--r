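---
title: "Methods: Shine-Dalgarno usage, anti-SD site preference and initiation-region structure"
author: "sdscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Shine-Dalgarno usage, anti-SD site preference and initiation-region structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdscan)
```

## The biological question and the model

In bacteria, translation initiation is frequently rate-limiting, and a
Shine-Dalgarno (SD) sequence in the 5' UTR recruits the 30S subunit by
base-pairing with the single-stranded 3' terminus of mature 16S rRNA (the
anti-SD "tail"). Two gene features therefore shape initiation efficiency:
the position and strength of the SD/anti-SD duplex, and the secondary
structure of the region around the start codon. `sdscan` implements a
pipeline to quantify both from standard inputs (annotated genome, RNA-Seq
reads, protein-abundance table):

1. **Tail calling.** The mature 16S 3' terminus is frequently mis-annotated,
   so it is determined empirically from RNA-Seq: read 3' ends are piled up
   along a query built from the `CCTCC` core anti-SD motif plus 100 nt of
   flanking rDNA (205 nt in total), and the terminus is called by two
   criteria (below).
2. **SD scanning.** Every maximal contiguous antiparallel Watson-Crick
   duplex of length >= 4 nt between each gene's 30-nt upstream window and
   the tail is enumerated, and its spacing from the start codon is measured
   with `D_toStart`.
3. **Site preference.** Observed involvement of each tail site across all
   duplexes is compared with its expectation under composition-preserving
   shuffling of the same windows, with an upper-tailed Z-test per site.
4. **Classification and contrasts.** Genes with a duplex whose `D_toStart`
   falls in the species' preferred range are *SD-facilitated*; the rest are
   *SD-independent*. The two classes are contrasted in protein abundance,
   protein-per-transcript (abundance / mean FPKM), and the minimum free
   energy (MFE) of the 40-nt window upstream of the start codon.

## The spacing statistic

For a duplex whose 5'-most paired window base sits at position `p`
(positions are labelled `-L..-1`, with `-1` immediately 5' of the start
codon) and pairs tail position `t_hi` (1-based, 5'->3' along the tail of
length `L_tail`), the spacing is

```
D_toStart = |p| + (L_tail - t_hi)
```

i.e. the number of mRNA nucleotides from the projected position of the
tail's 3'-terminal base to the base immediately upstream of the start
codon, inclusive. Measuring to the *projected tail end* rather than to the
SD motif itself makes genes with different SD forms comparable: what
matters for positioning the start codon at the ribosomal A site is where
the 16S 3' end sits, not where the SD motif starts. With 30-nt windows,
`D_toStart` ranges over `[1, 30 + L_tail - 4]`.

Antiparallel geometry is enforced directly in the scanner: a duplex lies on
an anti-diagonal of the pairing matrix (window index + tail index
constant), and maximality means the run of Watson-Crick pairs cannot be
extended on either side. G:U wobble pairs are excluded by default
(`wobble = FALSE`): "complementary" is taken in the strict Watson-Crick
sense, and the canonical SD examples pair without wobble; the switch exists
for sensitivity analyses.

## Tail calling: the two criteria

A candidate terminus `t` (a query position) is accepted when:

1. the implied tail — the query segment from the start of the conserved
   block `5'-GAUCACCUCCUU(U/A)-3'` through `t` — contains the `CCUCC` core,
   and `t` lies within the conserved block or at most `proximity_nt = 4` nt
   downstream of it ("close to" is not quantified in the source analyses;
   4 nt spans the observed end heterogeneity);
2. the count at `t` exceeds the combined counts of the next
   `k_downstream = 5` sites — intermediates between the mature and
   precursor 16S are cleaved rapidly, so read ends should be depleted
   immediately downstream of a genuine mature terminus.

Among qualifying candidates the highest peak wins; ties break toward the
most upstream terminus (conservative: precursor accumulates downstream).
Secondary peaks with at least 25% of the primary count are reported
separately; when re-applying criterion 2 to secondary candidates the
primary terminus is excluded from the downstream sum, since it is itself a
mature end rather than precursor read-through (without this exclusion a
secondary end 1-2 nt upstream of the primary — the commonly observed form
of heterogeneity — could never qualify).

Read mapping uses an ungapped local alignment contract: at least
`min_match = 25` aligned columns at `min_identity = 0.95`, both
orientations tried, best hit only, read 3' ends extrapolated along the
(ungapped) diagonal. This replaces a BLAST E-value cutoff: E-values depend
on database size, whereas the essential constraint is the 25-column
ungapped match. SAM input is accepted and re-checked under the same
contract so that pileups are consistent across input routes. An optional
minimal trimmer (mean Phred >= 20, adapter clipping, length >= 25) is
provided, but inputs are normally pre-trimmed upstream.

## The site-preference test

Let `O_i` be the number of duplexes (over all non-pseudo genes) involving
tail site `i`, and `n = sum(O_i)`. Expected counts `E_i` come from
`n_shuffles = 1000` per-window mononucleotide shuffles — each replicate
permutes every window (preserving its base composition, the main
confounder), rescans, and accumulates — then are rescaled so
`sum(E) = n`. With `p_i = O_i/n` and `phat_i = E_i/n`,

```
Z_i = (p_i - phat_i) / sqrt(phat_i (1 - phat_i) / n)
```

and site `i` is *preferred* when `Z_i >= 1.645` (upper-tailed 5%, no
multiple-testing correction — a deliberately simple, fixed rule). The
preferred anti-SD motif is the longest contiguous run of significant
sites (ties toward the 3' end, where genuine preference concentrates).

Two design notes:

* An analytic closed-form expectation is not offered. The quantity being
  counted — coverage by *maximal* runs of complementarity — has no
  tractable closed form under a composition model; the shuffle null is the
  definition, and it is exact in the limit of replicates. The enumeration
  oracle in the test suite verifies the shuffle estimator against exhaustive
  permutation on small windows.
* **Calibration caveat.** The Z-test treats the `n` site-involvements as
  independent draws; in reality one duplex of length `m` contributes `m`
  involvements of *adjacent, distinct* sites, so each site receives at most
  one count per duplex. `O_i` is therefore under-dispersed relative to the
  binomial the test assumes, and the test is conservative: in a simulation
  with windows drawn i.i.d. from their composition (1,000 datasets of 150
  windows, 300 shuffles each) the empirical per-site type-I rate at
  `Z >= 1.645` is about 0.02, not 0.05. We keep the test exactly as
  specified — its conservatism means reported preferred sites are, if
  anything, understated — and the acceptance suite records the measured
  rate rather than adjusting the statistic toward nominal.

## Expression and structure contrasts

`FPKM = count * 1e9 / (gene_len * total_mapped)`; replicate FPKMs are
averaged within a BioProject, and each project yields its own
protein-per-transcript value (`abundance / mean FPKM`). Genes with zero
protein abundance are excluded from contrasts; genes with zero mean FPKM
get an undefined (excluded) ratio, never an infinity. Fragments are
assigned to the single best-scoring CDS under the same ungapped mapper
contract.

Class contrasts use the two-sided Wilcoxon rank-sum test. The
normal-approximation branch (midranks, tie-corrected variance, 0.5
continuity correction) delegates to `stats::wilcox.test`; for very small
groups (both `n <= 10`) the null is enumerated exhaustively over group
assignments of the midranks, which remains valid under ties where the
classical exact distribution does not apply. Motif-usage concordance
between species uses Kendall's tau-b (tie-adjusted, via `stats::cor`), with
a large-sample normal p-value.

Secondary structure is summarised as the MFE of the 40-nt window
immediately upstream of the start codon — a window that contains every
qualifying SD — folded with the ViennaRNA engine (`RNAfold`) at 37 °C with
lonely pairs disallowed. Folding thermodynamics are deliberately delegated,
not reimplemented; the engine version is recorded in every output. Engine
upgrades can shift MFEs by a few tenths of a kcal/mol, so frozen regression
values carry a ±0.5 kcal/mol tolerance.

## Coordinates, defaults and degenerate inputs

* Internal coordinates are 1-based inclusive on the reference strand;
  minus-strand `cds_start` is reported on the gene's own strand. Window
  positions are labelled `-L..-1` with `-1` abutting the start codon.
* Start codons are taken from the annotation (not restricted to `AUG`);
  pseudo-flagged genes are excluded everywhere; upstream windows come from
  genomic sequence regardless of operon context (no TSS inference).
* Replicons are treated as circular unless the file says linear; circular
  windows wrap the origin, linear ones truncate with a warning flag and
  never pad. Windows shorter than `min_len` simply yield no duplexes, so
  such genes classify as SD-independent.
* Bundled preferred `D_toStart` ranges (nt): *Synechocystis* sp. 11-21,
  *M. aeruginosa* 11-20, cyanophage S-SSM6a 8-16, S-SSM6b 10-21,
  *N. tabacum* chloroplast 8-16, *A. thaliana* chloroplast 10-21 — always
  overridable. `propose_optimal_range()` (shortest interval holding 60% of
  the `D_toStart` mass, ties leftmost) is a helper for new species;
  classification always uses an explicitly configured range.
* One putative SD per gene — the longest match, ties toward the smallest
  `D_toStart` — is the per-gene representative used for gene counting and
  motif-usage tables; *all* maximal matches feed the site-preference
  tabulation and `D_toStart` histograms.

## What the synthetic data emulate — and what they do not

The generator produces the three study inputs with recorded ground truth:

* `simulate_16s_reads()`: a configurable fraction of reads ends exactly at
  the planted terminus; downstream noise ends decay geometrically
  (precursor leakage), upstream noise is uniform (degradation). Defaults —
  60% signal, 25% upstream, 15% downstream with geometric p = 0.5 at depth
  1,000 — give pileups with the peak-over-downstream shape seen in real
  read-end profiles.
* `simulate_genome()`: 500 genes by default, random strands on a circular
  replicon; with probability 0.6 a gene receives a planted SD (reverse
  complement of a random tail substring, length 4-6 with decaying weights,
  the range that dominates real SD length distributions) at a `D_toStart`
  drawn from 11-21; planting rejects windows where a spurious equal-or-
  longer duplex arises, so the planted duplex is provably the scanner's
  representative. Background composition is i.i.d. at GC 0.45
  (cyanobacteria-like), overridable with full base composition.
* `simulate_expression()`: log-normal protein abundance (sigma = 1) with a
  multiplicative class effect; negative-binomial counts (mu = 100,
  size = 2) independent of class (a null transcriptome, so protein effects
  are not confounded with mRNA effects).

Not emulated: sequencing errors, rRNA-depletion artifacts, operon
structure, multiple 16S copies, codon-usage realism. Passing the recovery
and power checks therefore demonstrates correctness of the computational
chain under the stated statistical structure, not robustness to every
artefact of real libraries.

A single global seed expands into per-stage seeds through a fixed affine
splitting rule, so each stage is independently reproducible and the
pipeline manifest (package version, engine version, seeds, thresholds)
suffices to regenerate every number bit-for-bit.

## Verification sizes

The packaged checks run at desk scale: 50 seeded read sets (depth 1,000)
for tail recovery; 1,000 random window/tail pairs against the brute-force
duplex oracle; 20 genomes of 500 genes for planted-`D_toStart` recovery;
1,000 null datasets (150 windows, 300 shuffles) for the Z-test level; 60
small fixtures against exhaustive rank-test enumeration; 200 simulations
for the 2x-effect power check. These sizes keep every Monte-Carlo standard
error well below the margins being asserted.

## Known limitations

* The site Z-test is conservative (see above); preferred-motif calls are
  correspondingly cautious.
* The ungapped mapper evaluates the best-scoring segment per diagonal; a
  diagonal whose best segment is a short perfect match can mask a longer,
  slightly imperfect qualifying segment elsewhere on the same diagonal.
  This corner case is vanishingly rare in practice and absent from exact-
  substring reads.
* Multi-copy 16S operons are not disambiguated: the user supplies one rDNA
  query (conventionally the first annotated copy).
* Plastid intron-containing genes use the annotated CDS start; no
  transcript reconstruction is attempted.
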