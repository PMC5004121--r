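# middcontext

Decomposition and comparative analysis of non-CpG DNA methylation (mCH)
from per-cytosine bisulfite-sequencing calls.

Mammalian cytosine methylation outside CpG — mCH, with H ∈ {A, C, T} —
is abundant in pluripotent cells, germ cells and neurons, sparse
(per-site levels of a few percent), and strongly sequence-dependent.
`middcontext` is for researchers who have per-cytosine call files
(BS-Seeker2 CGmap dialect) and want to know which sub-contexts of mCH
behave as independent classes, what their sequence motifs are, whether
samples group by cell type or species, and where and how asymmetrically
recurrent CW-methylation concentrates in the genome.

## What it computes

**Minimum dependence decomposition (MiDD).** For a degenerate 6-mer
context pattern `NN·C·H·NN`, enumerate every bipartition of every
position (the root admits 31), score each by a Pearson chi-squared test
(1 df) on a 2×2 subgroup × (methylated, unmethylated) table in which each
6-mer *w* contributes `round(1000 · M_w)` methylated pseudo-counts, where

    M_w = Σ n_meth / Σ n_total   over genomic sites with context w,

select per sample the most significant bipartition (p < 0.05), adopt the
split reported as top by at least half the samples (support `n/m`), and
recurse — yielding a hierarchical motif tree whose top split separates
the CW (W = {A, T}) and CC classes of mCH.

**Normalized motif matrices.** Per position p and nucleotide n, weight
`w(p, n) = mean{ M_w : w_p = n }`, closed to frequencies per position —
a position frequency matrix corrected for unbalanced genomic 6-mer
abundance, exportable as JASPAR or MEME text.

**Preference clustering.** Pairwise sample distance `1 − ρ²` with ρ the
Spearman correlation of shared-key `M_w` vectors; complete-linkage
dendrogram (Newick export).

**Recurrent-mCW enrichment.** Background = CW sites covered ≥ 4 reads in
≥ 4 samples; foreground = sites in a sample's top 10% by level in ≥ 75%
of the samples covering them (a merged meta-methylome variant serves
small cohorts). Per autosome, `score = log2((fg_in/fg_out)/(bg_in/bg_out))`,
summarised by mean, SD and a two-tailed one-sample t-test.

**Profiles and strand skew.** 20-kb binned chromosome profiles per
context with context–context correlation (distance `1 − r²`); metaregion
profiles over stranded elements (500 bp flanks, 20 rescaled body bins,
sense/antisense separated); and the skew statistic
`S = sign(mean sense − mean antisense) × (−log2 p)` from a paired t-test
across elements.

**Synthetic cohorts.** A fully seeded generator plants genomes, gene
models, repeat families, cell-type motif and graded 6-mer preferences,
region-localised CW enrichment, subfamily gradients and intron strand
skew, with a machine-readable `truth.json` — every analysis above is
validated by recovering what was planted.

## Worked example

```r
library(middcontext)

# a seeded 6-sample cohort with CW methylation planted at 0.30 and CC at 0.01
cfg <- simulation_config(
  seed = 11, n_chrom = 2, chrom_len = 100000,
  samples = data.frame(sample_id = paste0("s", 1:6), cell_type = "ct",
                       species = "sp", library_type = "WGBS"),
  cell_type_profiles = list(ct = list(base_cw = 0.30, base_cc = 0.01,
                                      base_cg = 0.8, motif_effects = NULL)),
  species_effects = list(sp = list(scale = 1)),
  region_effects = NULL, subfamily_gradient = NULL,
  intron_strand_skew = c(ct = 1), genes_per_chrom = 2, repeats_per_chrom = 6)
cohort <- simulate_cohort(cfg)

tables <- lapply(cohort$methylomes, sixmer_table, class_filter = "CH")
tree <- build_midd_tree(tables, max_depth = 2)
tree
#> <midd_tree> 6 sample(s), alpha = 0.05
#> NNCHNN split pos 4: {A,T}|{C} [n/m = 6/6]
#>   NNCWNN (leaf)
#>   NNCCNN (leaf)
```

The root split isolates `{A,T}` from `{C}` at the H position with
support 6/6: all six samples report the CW/CC bipartition as their most
significant, recovering the planted decomposition. The leaf patterns are
printed as IUPAC strings (`NNCWNN`, `NNCCNN`).

```r
pfm <- normalized_pfm(sixmer_table(cohort$methylomes$s1, "CW",
                                   exclude_ccgg = TRUE))
round(pfm[, 4], 2)
#>   A   C   G   T
#> 0.5 0.0 0.0 0.5
```

At the constrained H position the normalized frequencies put all mass on
A and T, as they must for a CW table; unconstrained positions stay near
0.25 because this cohort plants no motif.

## Pipeline

`run_pipeline()` (or `inst/scripts/midd-pipeline.R` from a shell) drives
the whole analysis from a YAML configuration: CGmap manifest, genome
FASTA, BED12 genes, repeat and CpG-island BEDs, optional SNV list, and
per-stage parameter blocks whose defaults are the printed ones (20 kb
bins, coverage ≥ 4 in ≥ 4 samples, top 10%, 75% recurrence, α = 0.05,
promoter −500/+100, intergenic 10 kb/1 kb, 500 bp flanks). Stage outputs
carry a provenance hash so interrupted runs resume.
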