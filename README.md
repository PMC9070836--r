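# dodderlign

Computational toolkit for studying **lignin-based resistance of tomato to
field dodder** (*Cuscuta campestris*), a parasitic plant that drains its
hosts through haustoria. Certain Heinz hybrid cultivars (H9492, H9553)
resist dodder by lignifying the stem **cortex** at the attachment site,
walling the haustorium out; susceptible cultivars (H1706, H9775) do not.
The package implements the quantitative pipeline such a study needs, end
to end, together with synthetic-data generators that plant known ground
truth into every input — so each stage can be validated before it ever
touches real data.

It is aimed at plant biologists and bioinformaticians who quantify
histochemical staining, select differentially expressed genes across a
genotype × treatment design, cluster expression profiles, build gene
co-expression networks, and follow up candidate regulatory variants.

## What the pipeline computes

**Stained-section imaging.** Phloroglucinol–HCl (Wiesner) staining turns
lignin red. Images are Gaussian-blurred (σ = 2 px), converted to CIELAB,
and thresholded adaptively from each image's own histograms: a pixel is
called lignin when

    L8 ≤ peak(L8)   and   a8 ≥ peak(a8)

i.e. darker than the lightness histogram peak and redder than the
green–red histogram peak (the blue–yellow channel is unrestricted). The
cortex lignin area is the masked area minus the xylem ROI, reported as a
percentage of the cortex ROI.

**Differential expression.** Counts are CPM-normalised and modelled per
gene on log2(CPM + 0.5) under the interaction design
`~ condition + genotype + condition:genotype`; the tested contrast is the
difference-of-differences between a resistant and a susceptible
cultivar's infestation response, selected at BH-adjusted *p* < 0.1 and
|log2FC| > 1. A two-factor ANOVA omnibus variant (FDR < 0.1) produces the
broader DEG list, and helpers compute Venn-style DEG-set overlaps and
Euclidean/complete-linkage heat-map orderings.

**Expression clustering.** DEG profiles are row z-scored, embedded in 2-D
with t-SNE (perplexity 20, early-exaggeration "lying" phase 250
iterations, seed 2) and grouped density-wise with an explicit noise
group; any candidate group smaller than the cutoff (20 genes) dissolves
into noise.

**Co-expression networks.** Per (cultivar, treatment) stratum, Pearson
correlations over a selected gene list are Fisher z-transformed,
standardised, and thresholded at the standard-normal quantile for
q = 0.997 (≈ 2.75 σ). Communities are detected by greedy modularity
maximisation, hubs ranked by degree, and genes with no co-expression
connection reported separately.

**Variants and motifs.** Resistance-specific SNPs are calls shared by the
two resistant cultivars but different from the susceptible comparator.
They are intersected with strand-aware 5-kb promoter windows and with
W-box cis-elements (IUPAC `TTGACY`, both strands), noting whether the
alternate allele breaks the motif.

**Lignin chemistry.** %ABSL from acetyl-bromide digests via Beer–Lambert
(`%ABSL = A / (ε·l) · V/m · 100`, ε = 17.2, 1-cm path) and pyro-GC-MS
peak areas normalised into H/G/S monolignol class fractions.

## Worked example

```r
library(dodderlign)

## a synthetic stained cross-section with 45% of the cortex lignified
img <- render_section(section_spec(cortex_stain_fraction = 0.45, seed = 7))
quantify_section(img)
#> <lignin_quant> total 72016 px | xylem 32650 px | cortex 39366 px
#>   (45.91% of 85744 cortex px)
```

The estimate (45.91%) sits within half a percentage point of the planted
truth (45%): the adaptive mask found the stained wedge, and subtracting
the xylem ROI isolated the cortex response.

```r
## counts with one 50-gene cluster upregulated 4 log2 units only in
## infested H9553 — the signature of a resistant-specific response
sim <- simulate_counts(expr_sim_spec(
  n_genes = 1000, strata = default_strata(3L),
  cluster_plan = list(list(size = 50, shift = c(0, 0, 0, 0, 0, 0, 0, 4))),
  seed = 7))
res <- interaction_dge(sim, genotype_test = "H9553", genotype_ref = "H9775")
head(res[res$passes, ], 3)
#>        gene   log2fc            p          fdr passes
#> 1 gene00001 3.481108 5.086577e-05 1.017315e-03   TRUE
#> 2 gene00002 3.645461 1.169570e-05 2.923925e-04   TRUE
#> 3 gene00003 3.570652 3.171067e-07 1.668983e-05   TRUE
```

All 50 planted genes pass at the default thresholds; their fitted log2
fold changes (~3.5) are the planted 4 minus the compositional shift that
per-million scaling imposes when a large planted signal inflates a
library.

The whole synthetic study — imaging, DGE, embedding/clustering, per-
cultivar networks, SNP/W-box analysis, chemistry — runs with:

```r
run_pipeline(pipeline_config(), out_dir = "dodderlign-run")
```

which writes per-stage TSV/VCF/GFF3/FASTA/PNG outputs, a hash manifest
(`manifest.json`) and a summary `report.txt`. A command-line wrapper
lives at `inst/cli/dodderlign.R` (`run`, `quantify-lignin`,
`resistance-snps`, `absl` subcommands).

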