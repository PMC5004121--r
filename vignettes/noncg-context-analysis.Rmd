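---
title: "Decomposing non-CpG methylation contexts with middcontext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing non-CpG methylation contexts with middcontext}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(middcontext)
```

## The problem

Mammalian genomes carry cytosine methylation outside the canonical CpG
dinucleotide (mCH, H = A, C or T), most prominently in pluripotent cells,
oocytes, primordial germ cells and neurons. mCH is sparse (per-site levels
of a few percent), strongly sequence-dependent, and its sub-contexts need
not behave as one class: CW (W = A or T) and CC methylation can differ in
level, motif and genomic distribution. `middcontext` implements a complete
toolchain for asking, from per-cytosine bisulfite calls alone:

* which sub-contexts of mCH behave as statistically independent classes
  (minimum dependence decomposition, MiDD);
* what the sequence preference of each class looks like once genomic
  6-mer abundance is corrected for (normalized motif matrices);
* whether samples group by cell type or by species when compared on
  context preference ranks;
* where recurrently methylated CW sites concentrate in the genome
  (gene subregions, repeat families), per autosome, with significance;
* whether CW methylation is strand-asymmetric inside genes and
  transposable elements.

Every stage can be exercised end-to-end on synthetic methylomes with
planted ground truth, which is how the package validates itself.

## Input model

The unit record is a per-cytosine call: chromosome, 1-based position,
strand, methylated and total read counts, and the 6-mer sequence context
`NN-C-H-NN` — two bases upstream and three downstream of the cytosine,
read 5'→3' on the cytosine's own strand. Calls arrive in the 8-column
BS-Seeker2 CGmap dialect (`read_cgmap()`), contexts are filled from a
genome FASTA (`annotate_contexts()`), and three filters mirror standard
practice:

* cytosines within 1 bp of a known SNV are discarded (`filter_near_snv()`;
  the window is symmetric and includes the SNV base itself — the
  conservative reading);
* positional masks (genes, repeats, CpG islands) can exclude or restrict
  calls (`mask_regions()`; interval strand is deliberately ignored, the
  exclusion is positional);
* 6-mers containing the `CCGG` substring can be dropped so that RRBS
  (MspI-digested, CCGG-anchored) and WGBS samples are comparable
  (`sixmer_table(exclude_ccgg = TRUE)`). Note that a CW-class 6-mer can
  never contain `CCGG`; the exclusion matters for tables that include CC
  and CG keys, and for cross-library-type comparability of site sets.

The per-sample summary is the context table: for each fully resolved
6-mer `w`, the aggregate level `M_w`. The default aggregation is
read-weighted (`sum(n_meth)/sum(n_total)`), the standard bulk convention;
an unweighted per-site mean is available
(`level_aggregation = "sites"`) because the two differ under uneven
coverage and only one can be the default.

## Minimum dependence decomposition

MiDD asks, for a degenerate pattern such as `NNCHNN`: at which position,
and into which two nucleotide subsets, should the pattern be split so that
the two halves have the most significantly different methylation? All
bipartitions of every position are enumerated — a position with *k*
allowed letters contributes 2^(k−1) − 1 splits, so the root `NNCHNN`
admits 31. Each candidate is scored by a Pearson chi-squared test (1 df,
no continuity correction) on a 2×2 subgroup-by-state table in which every
6-mer contributes `round(1000 × M_w)` methylated and the complement
unmethylated pseudo-counts ("occurrences in 1000 cases"). Per sample the
minimum-p split wins (ties break deterministically: larger chi-squared,
then enumeration order); across samples the modal top split is adopted
when at least half of all samples report it, with support recorded as
`n/m` (n samples with this top split / m with any significant split). The
procedure recurses into both halves until no consensus split remains,
producing a motif tree whose leaves partition the 6-mer space exactly.

Two constructions of the chi-squared table are defensible readings and
both are implemented (`chi2_mode`): `"pooled"` (default) sums pseudo-counts
over the 6-mers of each subgroup, weighting each 6-mer equally at 1000
cases; `"stratified"` uses each subgroup's mean count so that subgroups of
unequal size carry equal weight. No multiple-testing correction is applied
across the 31 candidate splits — the raw p < 0.05 rule is the method as
defined; a Bonferroni-minded user can lower `alpha`.

Two behaviours of this greedy statistic are worth knowing:

* **Extreme-letter preference.** When the three H-letter classes are
  spaced like CA ≫ CT ≫ CC (e.g. planted true levels 0.35 / 0.10 / 0.01),
  any between-group chi-squared ranks the split {A}|{C,T} above
  {A,T}|{C}: with equal key counts the statistic reduces to the squared
  difference of group means, and 0.35 − mean(0.10, 0.01) exceeds
  mean(0.35, 0.10) − 0.01 whenever the middle class is closer to the
  bottom than to the top. The tree then isolates CA first and separates
  CT from CC one level down — the same three leaf contexts, in a
  different merge order than a CW-first decomposition. The CW-first root
  split is recovered when CA and CT are comparable (e.g. both 0.30
  against CC 0.01). The package's acceptance suite asserts both
  configurations and the second documents exactly this behaviour.
* **Depth under large counts.** The pseudo-count scale of 1000 treats
  every `M_w` as if estimated from 1000 cases; with many 6-mers per
  subgroup the pooled table accumulates large counts and small true
  differences become significant, so trees grown to exhaustion are deep.
  `build_midd_tree(max_depth = )` bounds the recursion when only the top
  of the hierarchy is of interest.

## Normalized motif matrices

Genomic 6-mer abundance is unbalanced, so raw letter counts at each
position of a methylated-context list would reflect the genome more than
the methylation. The package therefore weights each nucleotide *n* at
each position *p* by the **mean** of `M_w` over the stored 6-mers with
`w_p = n`, and closes the four weights to frequencies at each position.
The mean (rather than a sum) is the module's central assumption: a sum
re-introduces abundance imbalance whenever the key set is uneven across
letters — which the CCGG exclusion guarantees for CC tables. Frequencies
are invariant to any uniform rescaling of `M_w`. A position whose every
matching `M_w` is zero has no information and falls back to uniform over
the letters present, with a warning. `consensus_string()` renders a PFM
as a degenerate IUPAC string using a 0.4 dominance threshold; matrices
export in JASPAR-style and minimal MEME formats for logo rendering
elsewhere.

## Rank-based sample clustering

Sample-to-sample similarity of context preference uses Spearman's rank
correlation ρ over the shared 6-mer keys of two CW tables, with distance
1 − ρ². Ranks make samples with different absolute mCW levels comparable;
the squared correlation means perfectly anticorrelated preferences also
count as similar, which is the printed definition and is preserved here.
Ties get average ranks; fewer than `min_shared` (default 100) shared keys
is an error rather than a silent small-sample estimate; a zero-variance
vector gives distance 1 with a warning. Agglomeration is complete-linkage
(`stats::hclust`), deterministic for a given input order, exported as
Newick via **ape**. For the cell-type comparison recipe the tables should
be built after masking genes, repeats and CpG islands, so that
transcription- and library-coupled composition differences do not drive
the ranks; the pipeline applies this mask by default and records it in
the stage provenance.

## Recurrent CW sites and region enrichment

For cohorts of at least four non-RRBS samples: the background is every CW
site covered by ≥ 4 reads in ≥ 4 samples; per sample the covered
background sites are ranked by level and the top 10% flagged (ties at the
cutoff break by genomic position, so the flag set is deterministic); the
foreground is the sites flagged in ≥ 75% of the samples *in which they
are covered*. Using covered samples as the recurrence denominator (rather
than all samples) was the genuinely open choice; the alternative is one
comparison away in the code and the toy fixture in `inst/extdata`
documents the exact arithmetic. For small cohorts (oocytes), samples are
merged site-wise into a meta-methylome; the top-80%-coverage sites form
the background ("top 80% coverage" read as the 80% highest-coverage
sites, implemented as at-or-above the 20th coverage percentile so that
uniform coverage keeps everything) and the top 10% by merged level the
foreground.

Enrichment of the foreground in a region class is scored per autosome as
the log2 odds ratio `log2((fg_in/fg_out)/(bg_in/bg_out))`; an
observed/expected variant (`score_mode = "obs_exp"`) is provided since
both formulations appear in practice — they agree in sign and nearly in
value when in-region fractions are small. Autosomes with an empty cell
get a 0.5 (Haldane) pseudo-count in all four cells and are flagged. The
summary across autosomes is mean, SD and a two-tailed one-sample t-test
against zero; sex chromosomes are the caller's responsibility to exclude.
Under a null in which the foreground is a uniform draw from the
background, the per-autosome scores are centred on zero and the t-test
p-values are approximately uniform — one of the package's acceptance
properties.

## Profiles and strand skew

Chromosome-scale profiles average levels (read-weighted) in fixed 20 kb
bins per context class, with a centered rolling mean over 5 bins for
display (both raw and smoothed are returned; the smoothing method is a
display choice, not part of any statistic). Pearson correlations between
context profiles over shared covered bins, with distance 1 − r², cluster
the contexts themselves — concordance of CA and CT profiles is the
expected structure.

Metaregion profiles average over a set of stranded elements: 500 bp
flanks in fixed 50 bp bins, the body linearly rescaled into 20 bins with
sites assigned by fractional overlap (so elements shorter than the bin
count are kept, not dropped), minus-strand elements reversed so bin 1 is
always the 5' end. Sense and antisense (call strand relative to element
strand) are reported separately on request. The construction is exactly
invariant under mirroring the genome and flipping strands, and under
element order permutation — both are tested.

The strand skew statistic, per region class and sample: for every element
with at least 3 covered CW sites on each strand, compute the unweighted
per-strand mean level; across elements run a paired two-tailed t-test of
sense versus antisense; report `S = sign(mean difference) × (−log2 p)`.
Positive S means higher sense-strand methylation; S is exactly
antisymmetric under strand exchange, and fewer than 3 qualifying elements
yields an explicit NA result rather than a number. The per-element paired
construction (rather than pooling sites) is the package's choice where
the procedure was underdetermined; it matches the heatmap semantics of
larger |S| = more significant.

## Gene subregions

From gene models (BED12): promoter = 500 bp upstream to 100 bp
downstream of the TSS; 1stExon; postExon and postIntron = exons/introns 2
and later in transcription order; post5SS / post3SS = first / last 200 bp
of each posterior intron with postMI the central remainder (dropped for
introns under 500 bp; the 200/500 sizes are config keys, chosen as
round defaults where no sizes were fixed); geneBody = TSS to transcription
end; intergenic = a 1 kb window 10 kb upstream of the TSS. All windows
are computed in transcription direction. Minus-strand windows use the
half-open reflection `[TSS0 − e, TSS0 − s)` of the relative window
`[s, e)` in 0-based coordinates — the convention standard BED arithmetic
produces; a pure base-centre mirror would differ by one base. Windows
clip at position 1 and never go negative. Intervals are 1-based GRanges
in memory; all text interchange (BED) is 0-based half-open, converted at
the boundary only.

## The synthetic cohort generator

`simulation_config()` fixes the study conditions: 4 chromosomes × 500 kb
of i.i.d. sequence at GC 0.42; two cell types × two species × three
replicates; negative-binomial coverage (mean 10, dispersion 0.3, i.e.
`size = 1/0.3`); binomial methylated reads; per-site Gaussian level
jitter (sd 0.01). True levels compose multiplicatively from the base rate
of the context class (CG 0.8, CW 0.03, CC 0.01 — optionally separate CA
and CT rates), a cell-type consensus motif factor (e.g. `TNCACC` × 8), a
graded cell-type 6-mer preference (a fixed 4 × 6 log-factor matrix with
spread `preference_sd = 0.3`, drawn once per cell type deterministically
from the master seed, so replicates of a cell type share a rich
preference ranking while cell types differ), a species level scale (1.0 /
1.3 — rank-preserving by design, so species form a background rather than
a competing preference), repeat-family CW factors including a
young-to-ancient LINE-like gradient (0.3 / 0.7 / 1.0), and an
antisense/sense ratio for CW sites inside introns (1.5 for the ESC-like
type). Everything clips to [0, 1]. RRBS samples report only sites within
40 bp of a CCGG occurrence, which exercises the comparability machinery.
A cohort writes FASTA, BED/BED12 annotations, per-sample CGmaps and a
`truth.json` recording every planted effect, and a fixed master seed
reproduces all of it byte-for-byte.

What the generator does *not* emulate: real repeat sequence (repeats are
labelled intervals over i.i.d. sequence, so no sequence-driven
mappability or composition structure), correlated neighbouring sites,
bisulfite conversion failure, copy-number or allelic effects. Passing
recovery tests therefore demonstrates that the statistics detect the
structures they are defined on, not that real data meet those
assumptions.

## Validation at a glance

The test suite builds every fixture in code (or ships it as small
hand-written text files) and checks, among others: CGmap round trips;
strand symmetry of context annotation; enumeration counts against
brute-force subset enumeration; the chi-squared against
`stats::chisq.test` on random tables and the worked 2×2 with statistic
exactly 240; planted-split, planted-motif, planted-clustering,
planted-enrichment and planted-skew recovery over 20 seeds each; null
calibration (uniform p-values) for enrichment and skew; and the exact
deterministic site sets of the packaged toy cohort. The problem sizes —
2 × 100 kb genomes with 6 samples for decomposition runs, 2 × 50 kb for
single-sample motif runs, 4 × 4000 background sites for enrichment, 500
null replicates — were chosen so the whole suite runs comfortably on a
laptop; all recovery margins are large at these sizes (sampling error an
order of magnitude below the planted effects). `scripts/acceptance.R`
recomputes the same quantities from scratch under a caller-supplied seed
and writes them as JSON.

## Known limitations

* The MiDD chi-squared inherits the pseudo-count scale: significance is
  relative to "1000 cases" per 6-mer regardless of the real read depth
  behind `M_w`; comparisons across cohorts with very different depths
  should fix `scale` thoughtfully.
* The greedy split order is not a model of the joint dependence
  structure; as described above, geometric level spacing isolates the
  extreme letter first.
* Rank clustering needs a shared key space; cross-library-type
  comparisons rely on the upstream CCGG exclusion and intersection of
  keys (union-with-imputation is deliberately not offered).
* The enrichment t-test treats autosomes as exchangeable replicates;
  with few autosomes (the synthetic default is 4) its p-values are
  coarse, though calibrated under the null.
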