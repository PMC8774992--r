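---
title: "Motif-level McDonald-Kreitman tests: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-level McDonald-Kreitman tests: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifmk)
```

## The statistical model

The classic McDonald–Kreitman test contrasts two site classes — one
putatively selected, one a neutral reference — in a 2×2 table of fixed
interspecies differences (D) against within-species polymorphisms (P).
Under neutrality the D:P ratio is the same in both classes; an excess of
fixed differences in the selected class indicates adaptive substitution.

`motifmk` applies this logic at the resolution of a short DNA motif.
Every exact occurrence of the core motif (and of its reverse complement)
is located genome-wide, extended `flank_bp = 7` base pairs on each side
into a 21-bp segment, and the motif core plays the selected class while
the 14 flanking sites are the neutral reference. The adaptive fraction
is the standard MK estimator

$$\alpha \;=\; 1 - \frac{D_\text{flank}\,P_\text{core}}
                       {D_\text{core}\,P_\text{flank}},$$

the proportion of core-site fixed differences attributable to positive
selection. Using immediate flanks as the reference is deliberately
conservative: flanking bases may themselves be constrained (bound by
other factors, or coding), which depresses the reference's polymorphism
and inflates the denominator of the selected class's excess.
`synonymous_reference_alpha()` substitutes externally supplied
synonymous-site counts for the flank counts when a less constrained
reference is available.

Inference has three prongs:

* **Segment bootstrap.** Sites within 21 bp are tightly linked, so the
  resampling unit is the segment, never the site: `bootstrap_alpha()`
  resamples segments with replacement, recomputes the aggregate table
  per resample, and forms a percentile interval (99% by default).
  Resamples with an undefined $\alpha$ ($D_\text{core}=0$ or
  $P_\text{flank}=0$) are excluded and their fraction reported.
* **Table tests.** `mk_tests()` applies the G (likelihood-ratio, 1 df,
  no continuity correction) and two-sided Fisher exact tests to the
  table.
* **Shuffled-motif battery.** Every two-position transposition of the
  motif (17 distinct strings for `ACTGCTT` after removing the identity
  swaps, duplicates, and the motif's own reverse complement, which
  matches the same genomic sites) is pushed through the identical
  scan → segment → lift → classify → $\alpha$ pipeline. Selection
  specific to the focal motif should leave every control's $\alpha$
  below the focal value; Bonferroni-adjusted bootstrap p-values are
  reported across the battery.

$\alpha$ is aggregated from one genome-wide table by default rather than
averaged over per-segment estimates: per-segment tables are dominated by
zero cells at realistic rates, and the aggregate is the form whose
expectation relates simply to the underlying rates (see below). The
per-segment route remains available through `segment_count_matrix()`
consumers such as `stratified_alpha_contrast()`, which permutes segment
labels between strata (X vs autosome, exonic vs intergenic) and compares
aggregate $\alpha$ values per stratum.

## Cross-genome mapping

Motif instances are located in a source genome and must be compared with
their orthologous positions in a destination genome. Real analyses use
liftOver chains; `motifmk` uses an equivalent but bit-reproducible
ungapped **block map**: equal-length aligned intervals with an identity
fraction, and a `min_match = 0.95` threshold mirroring liftOver's
default. A segment lifts only when it lies entirely inside one block of
sufficient identity; segments touching two blocks (`split`), inside a
low-identity block (`below_min_match`), or outside all blocks
(`unmapped`) are logged and excluded, as are segments on
unassembled/heterochromatic contigs (`filter_segments()`), where
alignment is unreliable. The five statuses partition the input exactly.

Orthologous sequences are compared in both orientations and the
orientation minimizing the Hamming distance is kept (ties go forward);
this mirrors the practice of accepting whichever strand the aligner
reported. Per-site records then mark each position core/flank, fixed
difference (under the chosen orientation), and polymorphic — a site that
is simultaneously polymorphic and divergent counts only as polymorphic,
the standard way to avoid double counting in MK tables.

Polymorphism enters as biallelic SNPs filtered at minor allele frequency
strictly greater than 0.05 (indels dropped by default). The filter
removes weakly deleterious rare variation that would otherwise inflate
the polymorphism cells asymmetrically.

## The synthetic-data generators

Every input the pipeline consumes can be generated with the statistical
structure the analysis assumes, so the whole method is testable without
external data:

* `simulate_genome()` draws i.i.d. background sequence at a configured
  GC content (0.42 by default, a fly-like value) and plants
  `n_motifs` non-overlapping motif copies, forward or reverse
  complement with equal probability, optionally biased toward 1 kb of
  simulated exons. Chance background matches arise at the expected
  $2L/4^7$ rate and are deliberately *not* in the truth set — they are
  real occurrences that downstream scanning should and does find.
* `simulate_divergence()` mutates every site independently —
  `mu_core` at planted cores, `mu_flank` elsewhere — and emits the
  identity block map plus a substitution log. `block_shuffle` fragments
  the map and randomizes identities to exercise mapping failures.
* `simulate_polymorphism()` places SNPs at `theta_core` / `theta_flank`
  with minor allele frequencies drawn from a folded neutral (1/i)
  spectrum for a 205-chromosome panel, the size of a typical inbred
  reference panel.
* `simulate_annotation()`, `simulate_chip()` and `simulate_bm_traits()`
  provide gene models with strand-aware TSSs, replicate ChIP read/peak
  sets with fold enrichment at bound TSSs, and Brownian-motion tip
  traits with an optional group shift.

One master seed fans out to fixed per-generator substreams
(`substream_seed()`), so adding one generator never perturbs another and
identical configs give byte-identical FASTA/VCF/BED/GFF3 output.

The default rates encode the adaptive regime
(`mu_core = 0.10`, `mu_flank = 0.05`, `theta_core = 0.04`,
`theta_flank = 0.08`). Substituting expectations into the $\alpha$
formula, the per-site counts cancel and

$$\alpha^\* = 1 - \frac{\mu_\text{flank}\,\theta_\text{core}}
                      {\mu_\text{core}\,\theta_\text{flank}} = 0.75 .$$

Setting core rates equal to flank rates gives the neutral regime with
$\alpha^\* = 0$. Two small, documented biases separate simulation from
this analytic value: background chance matches of the motif evolve
neutrally and dilute $\alpha$ toward 0 (negligible when planted copies
dominate, substantial when they do not), and the polymorphic-wins rule
deflates the D cells by factors $(1-\theta_\text{eff})$ that do not
perfectly cancel. At the problem sizes used for calibration (below) the
combined bias is about $-0.01$.

A flank divergence of 5% corresponds roughly to a melanogaster–yakuba
scale comparison; 4–8% per-site polymorphism (before the MAF filter,
which passes about half the folded-neutral mass) is deliberately
generous so that desk-scale genomes yield informative tables.

What the generators do **not** model: linkage and coalescent ancestry,
sequencing error, gapped alignment, context-dependent mutation, real
chain-file pathologies. Passing tests therefore demonstrate the
statistical machinery is correct and calibrated under its own
assumptions, not that those assumptions hold in any particular real
genome.

## ChIP signal module

Per-gene signal is the count of read positions in the closed window
±350 bp around the TSS (the 700-bp total extension used throughout;
100/500/1000 bp are supported as sensitivity settings), scaled per
sample to unit mean to remove depth differences. Reads are represented
as single positions: at these window sizes the difference from counting
36-bp read overlaps is confined to the window boundary and is immaterial
at desk scale. Replicate structure is checked by mean-centred PCA over
samples with a silhouette score of the factor labels in PC1–PC2;
between-factor divergence uses Euclidean distance between factor-mean
profiles with replicate-reassignment permutation. Chromosome-level
enrichment uses the ratio of median normalized X signal to median
autosomal signal, with gene-label permutation; medians make the
statistic robust to the handful of strongly bound genes. Conservative
peaks are the interval intersection of two replicates' peaks, and bound
genes are genes whose span overlaps a conservative peak. All permutation
p-values carry the +1 correction, so they lie in (0, 1].

## Phylogenetic ANOVA

Whether per-species motif frequency differs between clades that do and
do not carry the duplicate factor cannot be tested by ordinary ANOVA:
species are phylogenetically dependent. `phyl_anova()` computes the
observed one-way F at the tips, estimates the single Brownian-motion
rate from phylogenetically independent contrasts
(`bm_rate_estimate()`, the unbiased REML-type mean squared contrast),
simulates `n_sim` Brownian datasets on the tree, and takes the upper
tail of the simulated F distribution with the same group labels. Because
F is scale-invariant, the plug-in rate does not affect calibration and
the test is exact in the Monte-Carlo sense. A star tree collapses it to
ordinary ANOVA, which the tests confirm numerically, and an independent
implementation (phytools) is used as a cross-check. The packaged
`fixture_tree()` mirrors a nine-species design with three tips in the
duplicate-bearing clade.

## Numerical and design choices

* Intervals are 1-based closed inside R (the GRanges convention); all
  BED-format files are written/read 0-based half-open via rtracklayer,
  and the block-map TSV is 0-based half-open on disk.
* Exon proximity uses a closed threshold: a gap of exactly 1000 bp
  still counts as "within 1 kb". Annotation-size matching for the
  between-species exon-bias comparison downsamples the larger exon set
  until the first exon whose inclusion reaches the smaller set's total
  length, and conservatively reports the maximum Fisher p over 10
  iterations.
* Segments that would overrun a chromosome end are dropped, not
  trimmed, keeping every segment the same length so per-class site
  totals stay proportional to segment counts.
* Promoter windows are the 500 bp strictly upstream of the TSS,
  strand-aware, truncated at chromosome edges; an instance counts only
  if fully inside the window.
* Orientation ties in `count_differences()` go to forward; a
  palindromic motif would be reported once per strand by the scanner
  (the default motif is not palindromic).
* Undefined $\alpha$ (zero `D_core` or `P_flank`) is always signalled,
  never silently 0; batteries and strata report such cases as no-data
  rows.

## Problem sizes used in the packaged checks

Calibration and recovery checks run the full pipeline on single-
chromosome genomes of 300 kb with 2000 planted motifs (about 98% of
scanned instances are then planted, so the analytic $\alpha^\*$
applies): 100 neutral replicates for 99%-CI coverage of 0, 100 adaptive
replicates for recovery of $\alpha^\* = 0.75$, and 1000 table-level
replicates for G-test type-I error. The shuffled-motif battery instead
needs chance occurrences of every control motif, so it runs once on a
4-Mb genome where each control accumulates roughly 500 occurrences and
its $\alpha$ is estimated with standard error ~0.13. The phylogenetic
calibration uses 500 nine-tip replicates with 199 simulations each
(rejection at 5% is then exactly 10/200 under the null). These sizes are
the package's chosen desk-scale study conditions; the acceptance script
reports the same quantities at 30 pipeline replicates.

## Known limitations

* The MK framework here is deliberately minimal: no demographic
  correction, no asymptotic-MK extrapolation, no outgroup polarization.
  Flank-referenced $\alpha$ is a lower bound when flanks are
  constrained.
* The block map cannot represent gapped within-segment alignment;
  segments whose true orthologs contain indels will be dropped as
  `split`/`unmapped` rather than realigned.
* Silhouette on PC1–PC2 is a coarse clustering check; with very few
  replicates per factor it is noisy.
* The generators draw sites independently; linked selection and
  demography, which distort real MK tables, are out of scope by design.
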