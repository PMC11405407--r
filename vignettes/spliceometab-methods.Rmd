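---
title: "Methods: splicing-metabolism integration with spliceometab"
author: "spliceometab authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: splicing-metabolism integration with spliceometab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceometab)
```

# Scope and model overview

`spliceometab` implements the quantitative core of a splicing-metabolism
integration analysis for two-condition transcriptomic studies, such as a
spliceosome-gene knockdown in a glycolytic cancer model. Five analysis
stages share one synthetic-data generator:

1. **Intron retention quantification and testing** -- PSI from counts or
   qPCR cycle thresholds, differential retention between conditions.
2. **Retained-intron sequence characterization** -- donor/acceptor
   splice-site strength, motif matrices, trimmed GC ratios, premature
   termination codon (PTC) consequences.
3. **Metabolite pathway scoring** -- per-metabolite rank tests aggregated
   into a pathway differential-abundance (DA) score.
4. **Single-cell spliceosome activity** -- rank-AUC gene-set scoring with
   automatic bimodal thresholding and SG+/SG- labeling.
5. **Cohort distribution distances** -- per-pair r.m.s.d. of spliceosome
   gene expression between tumor strata and matched normals.

# Intron retention

## PSI estimators

For an intron-retention event with `ir` intron-supporting reads and `sj`
junction-spanning reads, the count-based estimator is

$$\mathrm{PSI} = \frac{ir}{ir + sj}.$$

No length normalization is applied: the bundled simulator generates
intron and junction evidence on the same per-event scale, so the raw
proportion is the maximum-likelihood retention estimate under the
binomial read model. Events with zero total reads are undefined and
return `NA` rather than 0, since absence of coverage is not evidence of
splicing. Length normalization for externally derived counts is left to
the caller (scale the inputs before testing); the proportion test below
is invariant to common scaling of both groups.

The qPCR estimator inverts exponential amplification. With one assay
spanning the adjacent exons (all transcripts, $CT_{all}$) and one inside
the retained intron (retaining transcripts only, $CT_{in}$),

$$\mathrm{PSI} = 2^{\,CT_{all} - CT_{in}},$$

because each extra cycle corresponds to a twofold template deficit.
Measurement noise can produce estimates above 1; these are returned as
computed and flagged (`out_of_range` attribute) so replicate averaging is
not biased by truncation.

## Differential retention

`diff_ir()` pools counts within each condition and applies a two-sided
Fisher exact test to the per-event 2x2 table
$[(ir_A, sj_A), (ir_B, sj_B)]$, followed by Benjamini-Hochberg adjustment
across all tested events. An event is called significant when
`fdr < 0.05` **and** `|delta_psi| > 0.02` (both defaults configurable).
The delta-PSI gate is applied two-sided: retention gains and losses are
both reportable, matching how up- and down-regulated events are read off
a differential-splicing screen.

Choices worth noting:

* *Pooled-count exact test rather than a replicate-aware model.* At desk
  scale the pooled table admits an exact test whose p-value can be
  verified against direct hypergeometric enumeration (the test suite does
  exactly that, for totals up to 200). Pooling discards between-replicate
  variability; a replicate-aware test is a plug-in point, not the
  default, and the simulator's binomial read model contains no
  extra-binomial dispersion that pooling would hide.
* *Skipping untestable events.* An event with zero total counts in one
  group has no defined proportion; such events are excluded and recorded
  in the `skipped` attribute rather than silently assigned a p-value.

## Coding consequences

`detect_ptc()` splices the transcript with one intron retained and
translates from the coding start. The synthetic convention places the
coding start at transcript nucleotide 1; simulated exons are generated
stop-free in that frame so premature stops can only arise from retained
intron sequence, which is the biological signature of interest. The
frameshift flag is determined solely by intron length modulo 3; the first
in-frame stop at or after the intron is reported as a codon offset, and
the truncation flag compares its position against the normal transcript's
stop mapped into retained coordinates.

# Splice-site strength

The scorer is a position-weight matrix (PWM) log2-odds model over the
standard windows of splice-site strength analysis: 9 positions for the
donor (3 exonic + 6 intronic) and 23 for the acceptor (20 intronic + 3
exonic). Per-position frequencies are estimated from aligned window
sequences with an additive pseudocount (default 0.5) and converted to
log2-odds against a background distribution (default uniform 0.25). A
site's strength is the sum of its per-position weights, in bits.

This is deliberately a PWM rather than a trained maximum-entropy model:
the comparative analyses downstream (retained vs non-retained introns,
weak vs consensus donors) consume any monotone strength score, and the
scorer interface is pluggable so an externally trained model can be
substituted. The PWM's properties are easy to verify exhaustively -- the
test suite enumerates all sequences of a toy window to confirm that the
consensus is the score maximum and that no sequence exceeds the sum of
per-position maxima.

Windows are extracted strand-aware: minus-strand sites are
reverse-complemented before scoring, and a round-trip test confirms that
a gene's windows are identical regardless of which strand it was placed
on.

## GC ratio

Splice-signal nucleotides are removed before comparing composition: 20 nt
from either end of the intron and 3 nt from either end of each flanking
exon. The reported quantity is

$$\mathrm{GC\ ratio} = \frac{GC(\text{trimmed intron})}
{\tfrac{1}{2}\left[GC(\text{trimmed exon}_{up}) + GC(\text{trimmed exon}_{down})\right]}.$$

Cores that vanish after trimming yield `NA` with a recorded reason; this
is why the simulator enforces a 70-nt minimum intron length (a 70-nt
intron retains a 30-nt scorable core).

## RI vs NRI comparison

`compare_ri_nri()` is a two-sided Wilcoxon rank-sum test. The
non-retained comparison set is defined as all introns of genes harboring
at least one retained intron, minus the retained introns themselves, so
gene-level covariates (expression, GC isochore) are matched by
construction. The exact null distribution is used when both groups have
at most 10 observations without ties; otherwise the tie-corrected normal
approximation applies.

# Metabolite pathway DA score

Per-metabolite testing is a two-sided Mann-Whitney U test between the
two sample groups with Benjamini-Hochberg adjustment across **all
metabolites in the table** -- one family, not per pathway. A per-pathway
family would make a metabolite's q-value depend on which pathway is being
scored (and on pathway order, for shared metabolites); the single family
is conservative and order-invariant. The change direction is the sign of
the median log2 difference, which is rank-coherent with the test.

The pathway score is

$$\mathrm{DA} = \frac{n_{increased} - n_{decreased}}{n_{measured}} \in [-1, 1],$$

where the counts are over significantly changed member metabolites and
all measured members respectively. DA = 1 means every measured member
increased; DA = -1 means every member decreased. These endpoint
equivalences are exact rational arithmetic and are property-tested over
random admissible count triples. Pathways with fewer than `min_size = 2`
measured members are dropped with a recorded reason; a metabolite in
several pathways contributes to each.

# Single-cell spliceosome activity

## Rank-AUC

For each cell, genes are ranked by decreasing expression with a
deterministic tie-break (descending expression, then lexicographic gene
id -- no random jitter, so results need no seed). The recovery curve
counts set genes among the top $x$ ranks for $x = 1..k$ with
$k = \lceil \text{top\_fraction} \cdot n_{genes} \rceil$, and

$$\mathrm{AUC} = \frac{\sum_{x=1}^{k} y(x)}{\sum_{x=1}^{k} \min(x, m)},
\qquad m = \min(|\text{set}|, k),$$

i.e. the step-curve area normalized by the best achievable recovery.
The default `top_fraction = 0.05` follows the rank-AUC scoring
convention established for single-cell gene-set activity. Because only
within-cell ranks enter, the score is invariant to monotone per-cell
normalization -- raw counts and normalized expression give identical
results, which the test suite asserts.

## Threshold detection

The AUC distribution of a mixed tumor population is expected to be
bimodal: a low-activity bulk and a high-activity (SG+) population. The
threshold finder fits a Gaussian kernel density with the Sheather-Jones
plug-in bandwidth and places the threshold at the density minimum between
the two highest modes. Two refinements keep this honest:

* Kernel densities of single-population data ripple; a secondary local
  maximum only counts as a genuine mode if it reaches at least 5% of the
  dominant mode's density **and** the valley between them drops below
  80% of the smaller mode. Otherwise the distribution is treated as
  unimodal.
* The unimodal fallback is `mean + 3 sd` (clamped into the data range)
  and the result is explicitly flagged, so downstream consumers can tell
  which branch fired.

Labeling follows a strict `auc > threshold` rule: a cell exactly at the
threshold is SG-. The proportion of SG+ cells between two groups (e.g.
responders vs non-responders) is compared with a Pearson chi-square test
without continuity correction (configurable), verified in the tests
against the hand-computed $\sum (O - E)^2 / E$ statistic.

# Cohort distribution distances

The distance between two samples over a gene subset is the
root-mean-square difference of log expression,

$$\mathrm{r.m.s.d.} = \sqrt{\tfrac{1}{|G|} \sum_{g \in G} (a_g - b_g)^2}.$$

`group_distances()` evaluates it per matched tumor/normal pair within
each subtype stratum, and under an all-cross-pairs policy for strata
without pairing (the normal-vs-normal baseline). Matched-pairs strata
silently dropping unpaired samples would hide data problems, so excluded
samples are recorded. Distance distributions are compared pairwise with
two-sided Wilcoxon rank-sum tests and across three or more strata with a
Kruskal-Wallis test.

`ss_enrichment()` is the bundled per-sample pathway score for the
correlation stage: gene-wise z-scoring across samples followed by a
within-sample mean over pathway genes. It has cohort mean zero per
pathway by construction (asserted to 1e-10 in the tests). The
correlation stage itself (`correlate_scores()`, Spearman with
tie-average ranks, exact permutation p for n <= 9 without ties) accepts
any per-sample score, so a more elaborate enrichment method can be
substituted without touching the rest of the pipeline.

# The synthetic-data generator

The generator defines the study conditions under which every stage is
validated. It emulates:

* **Gene models** -- three exons and two introns per gene, each gene on
  its own contig, alternating strands. Every junction carries the
  consensus donor (`CAGGTAAGT`) and acceptor (polypyrimidine tract +
  `CAG`) except the first-intron donor of a `weak_fraction` subset of
  genes, which carries a fixed 9-mer with three consensus positions
  mutated. Exon interiors are stop-free in the coding frame; introns are
  unconstrained. Default intron lengths vary deterministically around
  90 nt (>= 70 nt enforced).
* **Read counts** -- per-sample event totals are Poisson around `depth`,
  split binomially by the true PSI. Control-condition PSI is uniform on
  [0.05, 0.15]; weak-donor genes gain `ir_effect` (default 0.3) in the
  knockdown condition. True PSI is clipped to [0, 1] with clipped events
  recorded, and clipping more than 10% of events warns.
* **qPCR readings** -- `ct_in = ct_all - log2(PSI)` plus Gaussian cycle
  noise per replicate; zero retention is rejected since it has no finite
  cycle threshold.
* **Metabolite tables** -- log-normal abundances with per-metabolite
  baseline ~ N(10, 1) log2 units, per-sample noise `noise_sd`, and the
  specified signed log2 shift in group B.
* **Cell matrices** -- negative-binomial counts (size 2); gene-set genes
  have mean 20 in the SG+ fraction of cells and 1 elsewhere, background
  genes mean 2. These means give cleanly separated AUC modes at the
  default 5% rank cutoff.
* **Expression cohorts** -- 42-gene log-expression profiles for three
  tumor subtypes with matched normals; subtype upshifts of 0.4/1.6/0.9
  log2 units (lipogenic/glycolytic/mixed) reproduce the expected ordering
  of distances from normal tissue, with the glycolytic stratum farthest.

Where the simulated magnitudes were not dictated by the analysis design,
they were chosen once as values a transcriptomics practitioner would call
realistic at desk scale (coverage of tens to hundreds of reads per event,
2-fold metabolite shifts, 10x expression separation for active gene
sets) and not revisited.

Determinism: one global seed fans out to fixed per-generator child seeds,
so adding a generator never perturbs the streams of existing ones, and
identical configurations reproduce byte-identical output files (GTF,
FASTA, TSV, MatrixMarket). The pipeline manifest records a hash of the
canonical configuration plus md5 checksums of every output, making rerun
verification a string comparison.

What the simulator does **not** model -- and hence what passing tests do
not establish about real data: overdispersed read counts, length- and
position-dependent read sampling, mappability, correlated metabolites
within pathways, doublets/ambient RNA in cell matrices, and batch
structure in cohorts. The simulator exists to verify that each method
recovers what was planted under its own assumptions, not to certify
performance on patient data.

# Numerical and design choices

* **Coordinates** are 1-based closed genome-forward internally, the
  IRanges/GenomicRanges/rtracklayer convention, so GTF I/O needs no
  shifting. All sequence extraction is strand-aware.
* **Exactness boundaries**: Fisher p-values are exact always; Wilcoxon
  exact for groups <= 10 without ties; Spearman permutation-exact for
  n <= 9 without ties. Beyond these, standard tie-corrected
  approximations apply.
* **Tie-breaks** in cell-gene ranking are deterministic (expression,
  then gene id), so no seed is needed for reproducible labels.
* **Degenerate inputs** error early with the offending item named:
  zero-read events (NA, skipped), constant metabolites (p = 1, null
  direction), constant AUC vectors (error), zero-variance enrichment
  genes (dropped with warning), empty trimmed cores (NA with reason),
  sub-70-nt introns (configuration error naming the gene).
* **Problem sizes** in the test-suite simulations (60-gene recovery
  runs, 500-replicate null calibrations, 1000-cell mixtures, the
  30-gene demo pipeline) were chosen as the smallest sizes at which the
  statistical claims under test have comfortable margins.

# Known limitations

* The pooled Fisher test treats replicates as exchangeable sequencing
  lanes; strong biological replicate variability would make it
  anti-conservative. The module interface accepts any per-event p-value
  column, so a replicate-aware test can be plugged in.
* The PWM scorer ignores inter-position dependence within splice sites;
  a maximum-entropy or neural scorer can be substituted through the same
  interface.
* The packaged 42-gene spliceosome list is a curated stand-in covering
  U1/U2/U4/U6/U5 snRNP components; users reproducing a specific study
  should supply that study's gene list via `spliceosome_genes(file)`.
* `ss_enrichment()` is a z-score mean, not a full distribution-based
  enrichment method; it is the bundled default for the correlation
  stage, not a claim of equivalence to more elaborate scores.

# Session

```{r}
sessionInfo()
```
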