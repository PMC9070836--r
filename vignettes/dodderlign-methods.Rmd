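---
title: "Methods: quantifying lignin-based dodder resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying lignin-based dodder resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dodderlign implements the computational pipeline of a lignin-based
resistance study: resistant tomato cultivars respond to dodder
(*Cuscuta campestris*) attachment by lignifying the stem cortex, and the
evidence for that mechanism rests on stained-section image
quantification, differential expression under a cultivar × infestation
design, expression clustering, per-cultivar co-expression networks,
resistance-specific variant analysis, and lignin chemistry. This
vignette records the models behind each stage, the parameters that
matter, and the design decisions taken where the procedure left room for
interpretation. Everything quantitative asserted here is computed by the
test suite or by `scripts/acceptance.R`; nothing is quoted from external
runs.

## Imaging: adaptive histogram-peak thresholding in CIELAB

The procedure mirrors interactive colour thresholding in common image
software: blur, convert to L\*a\*b\*, then keep pixels that are *darker
than the lightness mode* and *redder than the green–red mode*:

$$\text{lignin}(x,y) \iff L8(x,y) \le \mathrm{peak}(L8)
  \;\wedge\; a8(x,y) \ge \mathrm{peak}(a8)$$

with 8-bit rescaled channels (L\*: 0–100 → 0–255; a\*, b\*: −128–127 →
0–255, neutral at 128) and peaks taken over 256 integer bins with ties
broken toward the lowest bin. Key choices:

* **Blur before thresholding** (`sigma = 2.0` px, kernel truncated at
  3σ, reflective borders, rounded back to 8 bits). The blur suppresses
  sensor noise so each tissue population occupies few histogram bins.
* **Peaks are recomputed per image** on the smoothed image's own
  histograms. The alternative — freezing thresholds from a reference
  image — was rejected because section illumination varies; adaptivity
  is the point of the histogram-peak rule.
* **Percentage denominator.** "Cortex lignin area percentage" is
  cortex-lignin pixels over *cortex ROI* pixels. Among the candidate
  denominators (image, section, cortex), only the cortex ROI stays
  comparable across sections of different size, and it makes 100% mean
  "the whole cortex is lignified".
* **ROIs are supplied, not segmented.** Xylem selection was a manual
  step in the original workflow; the package takes masks (from the
  generator, or PNG masks via the CLI) and only does the arithmetic
  `cortex = total − xylem`.
* **Degenerate input:** on a constant image every pixel ties both peaks
  and the mask covers the frame. This is documented rather than made an
  error — the procedure presupposes that pale unstained tissue dominates
  the histograms, and a constant image has no such structure.

The rule is *adaptive and relative*: whichever population forms the
modal bin of a channel is included at its own mode (both inequalities
are inclusive). The procedure therefore only isolates stain when the
image histogram has the right structure — pale tissue dominating the
lightness mode, a near-neutral background dominating the green–red
mode. The synthetic generator (below) reproduces exactly that
structure, and the test suite checks the vectorised mask against a
naive per-pixel evaluation of the rule, pixel for pixel.

## What the section generator emulates — and what it does not

`render_section()` draws concentric annuli (pith, xylem ring, cortex,
epidermis) on a pale background: the simplest geometry with the
cortex-outside-xylem topology the quantification relies on. The stained
cortex is a contiguous angular wedge, so the stained fraction grows
monotonically and stained patches survive the σ = 2 blur. Three
realistic nuisance features are included deliberately, because the
adaptive rule's behaviour depends on histogram shape:

* a **radial vignette** (default 5.5% at the corners), as under a
  stereo microscope — it spreads background lightness over many bins so
  the uniform background cannot capture the lightness mode;
* a low-frequency **colour mottle** on tissue along the green–red axis
  (amplitude 3, roughly constant lightness), standing in for biological
  colour texture;
* a **stain-depth jitter** (10% relative), standing in for variable
  staining intensity.

The default stain tone (RGB 120/100/103) is chosen
*threshold-symmetric*: the colour midway between stain and tissue sits
at the neutral a8 = 128 threshold, so the blurred transition band at a
stain boundary crosses the threshold at the geometric edge and boundary
misclassifications cancel instead of accumulating. With a strongly
saturated stain the same rule systematically annexes a ~2-px halo
around every stained region (the halo is redder than neutral long
before it is half stain); that bias is a property of the published
procedure itself, not of this implementation.

The generator is **not** photorealistic histology: no cell outlines, no
uneven section thickness, no out-of-focus regions, no white-balance
drift. Passing tests therefore show the procedure is implemented
correctly and recovers truth under controlled histogram structure —
they do not show robustness to arbitrary real-world images.

## Differential expression

DESeq2-style negative-binomial fitting is replaced by a per-gene linear
model on `log2(CPM + 0.5)` (pseudocount ½ guards log 0). What the
pipeline actually consumes is the *selection logic* — an interaction
contrast, BH adjustment, fold-change cutoffs — and a log-linear model
implements that logic transparently and is calibratable by simulation
(the suite checks a ~5% raw-p rate under a null simulation and ≥90%
power on planted 4-log2 interaction shifts at the default thresholds,
FDR < 0.1 and |log2FC| > 1).

The interaction contrast for genotype *g* against reference *r* is the
difference of differences of stratum means,
$(\bar y_{g,\mathrm{inf}} - \bar y_{g,\mathrm{un}}) -
 (\bar y_{r,\mathrm{inf}} - \bar y_{r,\mathrm{un}})$,
which in the treatment-coded full-factorial fit is exactly the
`condition:genotype` coefficient. "FDR" always means Benjamini–Hochberg.
The two-factor ANOVA variant uses the omnibus F of
`~ condition * genotype` against the intercept, selecting at FDR < 0.1
with no fold-change rule.

One consequence of per-million normalisation worth knowing: a large
planted (or real) expression shift moves library mass, so every other
gene's CPM shifts oppositely in the affected samples. The generator
therefore places planted cluster and module genes at moderate
abundance, keeping that compositional artefact small; it cannot be
removed entirely without a robust normaliser, which is out of scope.

## Expression clustering with a noise group

Profiles are row-standardised (sample sd; constant rows become zeros
and are flagged), embedded with t-SNE, and grouped density-wise:

* **t-SNE** is implemented in the package with the standard schedule:
  per-point Gaussian bandwidths calibrated to perplexity 20, early
  exaggeration ×12 for the first 250 iterations (the "lying" phase —
  the parameter conventionally called *lying* in Barnes–Hut t-SNE
  implementations), momentum 0.5→0.8 at iteration 250, learning rate
  200, adaptive gains, 1000 iterations, seed 2. Gradients are computed
  exactly; the Barnes–Hut `theta` argument is accepted for interface
  parity and documented as exact evaluation, which is fast at the
  hundreds-to-low-thousands of genes this stage handles.
  Coordinates are bitwise reproducible for a fixed seed within one
  environment, but *not* across t-SNE implementations — only
  structure-recovery properties are contractual.
* **Clustering** is DBSCAN-style on the embedding: the neighbourhood
  radius comes from the knee of the k-nearest-neighbour distance curve
  (k = cutoff; knee = point of maximum deviation from the chord), core
  points need `cutoff` neighbours, and any candidate group smaller than
  `cutoff` (default 20) dissolves into the reserved noise label 0.
  The upstream tool's clustering internals are not described beyond a
  size "cutoff" and a noise group; a density method with a size filter
  is the minimal mechanism producing both, and "cutoff" is read as a
  *size* (a distance reading would leave the noise group undefined).
  Clusters are renumbered by decreasing size.

## Co-expression networks

Within each (cultivar, treatment) stratum, Pearson correlations over
the selected gene list (Pearson being the default of the cited network
methodology; constant genes are flagged and excluded) are thresholded
by the **normal-quantile rule**: Fisher z-transform the off-diagonal
correlations, standardise by their own mean and sd, and keep pairs
exceeding `qnorm(0.997)` ≈ 2.75. The phrase "normal quantile cutoff"
implies a Gaussian reference, and Fisher z is the standard normalising
transform for correlations; an `empirical` mode (99.7th percentile of
|r|, which lets strong negative correlations through) is provided as a
switch, while the default upper-tail rule matches the reading of an
edge as a *co-expression connection*. Communities come from greedy
modularity maximisation (igraph's fast-greedy), hubs from plain degree
with stable tie-breaking, and degree-zero genes are reported as the
"no connections" list.

Because the threshold is *relative*, ~0.3% of pairs exceed it even in
pure noise. Two simulation-design consequences (used by the tests and
the acceptance script):

* planted-module recovery is checked by **edge precision** (edges
  landing within planted modules), which the relative rule supports
  directly;
* the stratum-specific hub check pairs the hub's module (active in one
  stratum) with **absorber modules** of comparable strength in each
  stratum, so the top quantile is occupied by planted structure rather
  than manufactured from noise — without an absorber, a null stratum
  would still emit ~0.3% of pairs as edges and no gene could be
  expected to stay isolated. Module genes are simulated at low-mid
  abundance so the shared factor moves a negligible share of the
  library (see the compositional note above), with dispersion 0.01 and
  biological sd 0.1 in that simulation so the planted covariance
  dominates counting noise.

## Variants and the W-box

The resistance-specific filter keeps biallelic SNPs whose calls in the
two resistant cultivars are identical (heterozygous calls compared as
unordered allele sets) and differ from the susceptible cultivar;
records with missing calls, indels and multiallelic sites are skipped
and counted. Promoter windows are strand-aware 5-kb intervals upstream
of the gene feature's 5′ end (no UTR refinement — the source material
says only "upstream"), clipped at chromosome ends, in 1-based inclusive
coordinates throughout (VCF/GFF3 convention; BED's 0-based half-open
appears only at export). The W-box scan matches IUPAC `TTGACY`
(Y = C/T) on both strands via Biostrings with subject bases literal, so
`N` never matches; reverse-strand hits are reported in forward
coordinates with the matched word in pattern orientation. The overlap
step reports, for each resistance-specific SNP inside a promoter, every
motif hit whose 6-bp span contains it, and whether the alternate allele
(complemented for minus-strand hits) violates the IUPAC code at that
motif position — the "SNP interrupts WRKY binding" readout.

## Lignin chemistry

%ABSL uses the standard acetyl-bromide Beer–Lambert form
$\%ABSL = \frac{A}{\varepsilon l}\cdot\frac{V}{m}\cdot 100$ with
ε = 17.2 absorbance·mL·mg⁻¹·cm⁻¹ (the tobacco-family stem coefficient
adopted for tomato) and a 1-cm path; the formula itself is not printed
in the source material, and this is the only reading consistent with
"percent absorbance of soluble lignin". The measurement wavelength does
not enter the computation given absorbance as input. Pyrogram
normalisation divides each compound's peak area by the per-sample total
and sums fractions by monolignol class (H/G/S, p-coumarate, other);
compound→class assignment is taken from the input table, not inferred
from spectra.

## Orchestration and reproducibility

`run_pipeline()` runs the stages in dependency order from one
declarative configuration whose defaults are the study's printed
parameters (σ 2.0; FDR 0.1; log2FC 1; perplexity 20; lying 250; cutoff
20; seed 2; q 0.997; 5-kb window; `TTGACY`; ε 17.2). Every output file
is recorded with an MD5 hash in `manifest.json`, and a rerun with the
same configuration and seeds reproduces the hashes — including the
embedding, since the in-package t-SNE is seed-deterministic. Per-stage
seeds derive from the master seed. The default synthetic study uses
2000 genes, four cultivars × two conditions × five replicates, three
planted DEG clusters, two planted modules (one resistant-infested-only
with a hub), a 50-kb chromosome with 1000 SNP sites (10%
resistance-specific, two planted inside promoter W-boxes), and caps the
embedding at the 400 most significant DEGs — sizes chosen so a complete
run finishes in well under a minute on a laptop while every downstream
stage still has recoverable structure.

## Known limitations

* The imaging rule assumes unstained tissue dominates the histograms;
  images violating that (e.g. mostly-stained frames) degrade gracefully
  but are not flagged.
* The log-linear DGE model has no dispersion shrinkage, independent
  filtering or outlier handling; with few replicates its power profile
  differs from negative-binomial tooling even though the selection
  logic is identical.
* CPM is not a compositional normaliser (see above).
* t-SNE coordinates, and hence the exact cluster count on real data,
  are implementation- and seed-sensitive by nature; headline partition
  sizes from any particular run of the original tooling are not
  reproduction targets.
* The variant stage takes calls as given; no caller thresholds are
  re-implemented.
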