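---
title: "Quantifying biofilm-related phenotypes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biofilm-related phenotypes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biofilmq)
```

Natural isolates of *Saccharomyces cerevisiae* vary enormously in
biofilm-related traits: complex colony morphology, mat formation on soft
agar, flocculation (settling of cell flocs out of liquid culture), invasion
into solid agar, and adhesion to polystyrene. Two of these traits are graded
visually on an ordinal 0–5 scale; the other three can be quantified from
photographs and plate-reader tables. This vignette documents how biofilmq
computes each quantitative statistic, the statistical layer built on top of
them, the synthetic data generator that makes the whole pipeline testable by
parameter recovery, and the design decisions taken where the procedure was
genuinely open.

## Settling (flocculation) ratio

A tube of settled culture is photographed, converted to grayscale, and a
line is drawn from the meniscus to the bottom of the tube. The plot profile
of gray intensity along that line rises where the dense, settled cell
material begins. The per-line statistic is

$$\text{ratio} = \frac{x_{1/2}}{L},$$

where $L$ is the line length and $x_{1/2}$ is the distance from the meniscus
end to the **first sampled position whose intensity reaches half of the
line's maximum gray**. Three lines are measured per image and averaged
(`settling_score()`); the result is the fraction of the tube cleared.

Numerical choices:

* Profiles are sampled by bilinear interpolation at 1-px spacing
  (`extract_profile()`); positions run from 0 to $L$, so a crossing at the
  first sample gives ratio 0 and one at the last sample gives ratio 1.
* The half-max threshold uses the per-line maximum, not a per-image maximum,
  so uniform rescaling of intensities leaves the ratio unchanged.
* Dense settled material is assumed to image *bright* and cleared
  supernatant dark. For photographs with the opposite polarity,
  `settling_ratio(..., invert = TRUE)` reflects the profile before
  thresholding.
* An all-zero profile carries no signal; the ratio is reported as 0 with a
  warning rather than an error, since an empty tube is a legitimate assay
  outcome for a non-flocculent strain.

## Background-corrected invasion intensity

After washing surface growth off the agar, the invaded spot is photographed
and the mean gray intensity of the spot is corrected for the plate
background. With $A_t, I_t$ the area and mean intensity of the whole image
and $A_s, I_s$ those of the spot ROI, the background is

$$B = \frac{A_t I_t - A_s I_s}{A_t - A_s},$$

which is algebraically the mean intensity of the pixels *outside* the ROI —
an identity the test suite checks against brute-force pixel averaging. The
corrected intensity is $\max(0, I_s - B)$: spots fainter than their
surroundings score zero rather than negative. The clamp is applied **per
spot image**, before the three technical replicates are averaged by
`invasion_score()`; the alternative reading (clamping the per-strain
average) differs only for strains whose replicates straddle zero, and the
per-spot reading keeps each measurement interpretable on its own.

ROIs are circles (pixel membership: center-of-pixel distance ≤ radius) or
arbitrary logical masks. The synthetic spot renderer uses the same
membership rule, so an ROI with the rendered center and radius covers the
spot exactly and noise-free recovery is exact to well under one gray unit.

## Crystal-violet adhesion

Adhered cells are stained with crystal violet, the dye is solubilized, and
absorbance is read at 570 nm. `adhesion_score()` averages the two to three
technical replicate wells; blank subtraction is optional and off by default,
since the assay protocol defines no blank wells. Negative readings (possible
after subtracting a blank) are clamped to zero with a warning.

## Panel transforms

* `linear_normalize()` maps per-strain values of one phenotype onto the
  visual scoring scale: $x \mapsto 5(x - \min)/(\max - \min)$. A constant
  vector maps to all zeros. Normalization is applied per phenotype within
  one ploidy set (the clustering input is haploid-only).
* `bin_quantitative()` assigns 5 equal-width bins over the observed range,
  the dialect used to put quantitative assays on the same 5-level color
  scale as ordinal scores. Equal-width (not equal-frequency) binning was
  chosen because it preserves the visual meaning of "twice as strong"; it is
  affine-invariant, so binning before or after normalization is identical.
  The range is per panel (per ploidy set), not pooled across ploidies.
* `aggregate_replicates()` collapses technical (or biological) replicates by
  the arithmetic mean, ignoring missing values; ordinal scores aggregate by
  rounded mean.
* Missing-data policy: missing replicates are dropped from means; strains
  missing an entire phenotype are excluded pairwise from correlations and
  excluded (with a named warning, never imputed) from clustering.

## Statistical layer

**Kendall tau-b** (`kendall_tau()`) correlates ordinal score vectors.
Ordinal 0–5 grades guarantee heavy ties, so tau-b's tie correction matters
and p-values use the tie-corrected normal approximation (exact enumeration
is available for small untied samples). The implementation is
`stats::cor.test`; an exhaustive concordant/discordant pair-count oracle in
the test suite verifies the tie-corrected statistic on thousands of random
ordinal vectors.

**Welch's two-sample t-test** (`welch_test()`) compares haploid against
diploid technical replicates. The assay protocol's description — a *paired*
test *assuming unequal variance* — is internally contradictory: a paired
test operates on differences and has no two-sample variance assumption,
while unequal variances imply Welch's unpaired test. Technical replicates of
separately grown haploid and diploid cultures have no natural pairing, so
the unpaired Welch test is the default; a paired-on-means variant (pairing
per-strain haploid and diploid *means* across strains, one test per
phenotype) is available via `classify_ploidy_changes(paired_on_means =
TRUE)` for the other reading.

**FDR** (`fdr_adjust()`) uses Benjamini–Hochberg adjusted p-values as
q-values, significant at $q \le 0.05$. Storey's $\pi_0$ estimation is not
implemented: BH is deterministic, explicitly named in the protocol, and
conservative relative to Storey, so a BH discovery would also be a Storey
discovery at the same nominal rate. The FDR family is **per phenotype,
pooled across strains** — each phenotype column of the change table is its
own multiple-testing family.

**Classification** (`classify_ploidy_changes()`) calls each strain ×
phenotype `decrease` or `increase` by the sign of (diploid mean − haploid
mean) when significant, else `no_change`, and `ploidy_change_summary()`
tabulates the per-phenotype triple of counts. Strains lacking two replicates
in either ploidy are excluded and named in a warning, which is why the
per-phenotype strain denominators can differ.

A calibration note: with only three technical replicates per side, Welch's
test is mildly conservative (measured type-I rate ≈ 0.035 at nominal 0.05 in
a 10,000-replicate Monte Carlo). This is a property of the
Welch–Satterthwaite approximation at very small n, not of the
implementation — at ten replicates per group the measured rate is 0.046–0.048.
Conservatism at n = 3 only makes the FDR classification more cautious.

## Hierarchical clustering and TreeView export

Strains are clustered on their complete normalized phenotype vectors with
Euclidean distance. The linkage is configurable (average, complete, single)
with **average linkage as default**: the original analysis used the Cluster
3.0 program without naming a linkage, and average linkage is that program's
common choice for phenotype matrices; the dendrogram topology is therefore a
dialect, not an exact reproduction surface. Strain rows are sorted
lexicographically before clustering so that tie-breaking — and hence the
tree — is invariant to input order.

`write_treeview()` emits the Cluster/TreeView file pair: a CDT
(tab-delimited, GID/ORF/NAME/GWEIGHT header, rows in dendrogram leaf order)
and a GTR whose node heights are mapped to the similarity scale
$1 - d/d_{\max}$ that TreeView expects (its GTR field historically stores
correlations, so the root merge maps to 0 and a zero-distance merge to 1).
A Newick file (branch lengths on the original distance scale, ultrametric
with leaf depth $h_{\max}/2$) and a plain leaf-order listing are written
alongside.

## The synthetic data generator

Every pipeline stage is tested by parameter recovery against synthetic data
with known ground truth; no external images or tables are required.

**Tube images** (`render_settling_image()`): a vertical-axis tube with a
dark cleared band over a bright dense band. The meniscus-to-bottom line
spans rows $0$ to $h-1$, and the transition midpoint sits at fraction $f$
along that line (row $f(h-1)$), so the settling pipeline recovers $f$
exactly up to one pixel for any $f \in [0, 1]$, including the fully settled
and fully cleared extremes. Boundary softness is a linear ramp; noise is
additive Gaussian, clipped to $[0, 255]$, seeded from the spec.

**Spot images** (`render_invasion_image()`): a uniform disk on a uniform
background with ground truth $\max(0, \text{spot} - \text{background})$.

**Phenotype panels** (`simulate_panel()`): per-strain latent propensities
are multivariate Gaussian with a specified inter-phenotype correlation,
mapped to the nonnegative quantitative scale by the softplus function
$\log(1 + e^z)$ — a smooth monotone map that keeps rank structure, hence
approximately preserves the correlation targets, while producing the
left-anchored, nonnegative value distributions the assays yield. Diploid
latent values are the haploid latent times a per-phenotype factor (with
per-strain exception overrides), applied *before* technical replicate noise,
so ground truth is explicit. Ordinal scores threshold the noise-free latent
and are therefore monotone in it by construction.

Defaults were fixed once to emulate the study conditions: 30 strains, six
phenotypes, three technical replicates, replicate noise SD 0.1 on values of
order 1 (a 10–20% technical CV, typical of these assays), and diploid
factors (flocculation 0.2, adhesion 0.5, colony 0.7, mat 0.8, invasion 0.9,
filamentous 1.0) reproducing the observed qualitative pattern across ploidy:
flocculation strongly attenuated in diploids, adhesion intermediate,
invasion nearly unchanged with occasional increases (representable via
`exception_strains`). The default latent correlation encodes the observed
trait relationships (colony–mat strong; flocculation–adhesion moderate;
invasion–adhesion and colony–invasion moderate; flocculation–invasion near
zero). Photograph noise magnitudes were never reported for the original
assays, so image noise SDs are free parameters of the generator, not
calibrated values.

What the generator deliberately does **not** emulate: colony/mat morphology
itself (scores are consumed as ordinal inputs, never derived from images),
lighting gradients, tube curvature and meniscus reflections, spot shape
irregularity, or plate-position effects. Passing recovery tests therefore
demonstrates correctness of the measurement arithmetic and statistical
machinery under the stated noise model — not robustness to the optical
artifacts of real photographs, which the manual line/ROI annotation step is
expected to absorb.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on synthetic data at
desk scale: 200 random image/ROI pairs for the background-formula identity,
a 9-point cleared-fraction grid at noise SD 2, 1,000 random length-8 ordinal
vectors against the pair-count oracle, a 10,000-replicate Monte Carlo for
the Welch type-I rate, 50-strain panels for null and attenuated-recovery
classification, and 40 seeds × 30 strains for two-group clustering
recovery. All randomness is seeded; every command of the `biofilm_cli()`
layer is deterministic given (inputs, config, seed), and fixed-seed
simulation output is byte-identical across runs.

## Known limitations

* Settling and invasion require manual line/ROI annotations; there is no
  automatic meniscus detection or spot segmentation.
* JPEG photographs must be converted to PNG or TIFF first; only those two
  formats are read.
* The grayscale conversion uses fixed Rec. 709 luminance weights, which need
  not match the consumer image-processing software used historically for
  black-and-white conversion; for step-like settling profiles the half-max
  ratio is insensitive to this choice.
* Kendall p-values for tied data rely on the normal approximation, which is
  coarse below n ≈ 10.
* No phylogenetic correction is applied to trait correlations; strains are
  treated as independent.
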