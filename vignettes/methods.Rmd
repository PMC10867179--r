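---
title: "Methods: segmenting and phenotyping the tumor lymphovasculature and immune infiltrate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmenting and phenotyping the tumor lymphovasculature and immune infiltrate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the choices
behind them. Sequential chromogenic multiplexed IHC images one marker per
round with AEC over a hematoxylin counterstain; after registration the
analysis sees a stack of co-registered grayscale channels for one region
of interest (ROI). The package turns such a stack into object tables —
vessels with lymphovascular subtypes and morphology, single leukocytes
with mutually exclusive classes, TLS-like aggregates — and into
region-stratified summaries (intratumoral IT vs peritumoral PT).

## Chromogen separation

Each round's RGB image follows the Beer–Lambert law: transmitted intensity
$I_c = W_c\,\exp(-(d_H v_{H,c} + d_A v_{A,c}))$ per channel $c$, where
$d_H, d_A$ are hematoxylin and AEC optical densities and $v_H, v_A$ unit
OD color vectors (Ruifrok–Johnston convention; defaults
$v_H = (0.650, 0.704, 0.286)$, $v_A = (0.2743, 0.6796, 0.6803)$,
normalized). `deconvolve_h_aec()` inverts this by log-transforming against
the white reference and least-squares projection onto the two-stain basis,
clipping negative projections. On densities inside the span of the basis
the inversion is exact to numerical precision, which is what the
round-trip tests assert. Saturated-black pixels have unbounded OD; they
are capped at the image's maximum finite density and flagged.

`clean_background()` zeroes values at or below a background threshold
(default: mean + 2 SD of a user-designated blank region). A 3×3 median
denoise is available but off by default: thresholding alone is exactly
idempotent and preserves genuine signal pixelwise, whereas a median
erodes the corners of sharp structures and is not idempotent. The exact
cleaning steps of the original macro are not published; this explicit
pair is the package's stand-in.

## Registration and ROI handling

Rounds are aligned by integer translation only: `estimate_offset()`
maximizes the cross-correlation of mean-subtracted images (FFT with zero
padding) and reports the normalized correlation at the chosen offset as a
quality score in [0, 1]. The convention is
`moving[i - dy, j - dx] == fixed[i, j]`. Rotation and deformation are
out of scope. QC (`qc_registration()`) fails an ROI when any round's
quality drops below 0.5 — the original workflow judged registration
visually, so the numeric threshold is a configurable operationalization.
Square ROIs are cropped identically across channels; the 6.25 mm²
whole-slide preset corresponds to a 2.5 mm square (5000 px at 0.5 µm/px,
the assumed scan resolution — the scanner's pixel size is configurable
because it is not fixed by the source workflow).

## Region masks

Tissue is hematoxylin above the triangle threshold (geometric Zack rule:
the bin farthest from the peak–tail chord, axes normalized, ties to the
lower bin), hole-filled, speck-filtered. Tumor (IT) is S100 passed through
an alternating sequential filter (closing∘opening at disc radii 1, 2, 3 px)
then triangle-thresholded; connected components below `min_nest_area_um2`
(default 500 µm², roughly more than three melanocyte cross-sections) are
removed so single S100⁺ cells — Langerhans cells, dendritic cells,
macrophages, neural cells — do not count as tumor. Components exactly at
the minimum are kept. PT is defined as `tissue & !IT`, so
|IT| + |PT| = |tissue| holds pixel-exactly by construction; this is
enforced in the constructor rather than assumed.

Both histogram rules are implemented as exhaustive searches and are tested
for exact agreement with independent brute-force implementations. On
continuous images the threshold returned is the *upper edge* of the
selected histogram bin, not its center — with a bin-center convention,
background values in the upper half of the cut bin leak above threshold,
which measurably corrupted cell gating before the convention was fixed.

## Vessel segmentation and gating

AQP1, CD34 and PDPN are each median-denoised (3×3 sorting-network median;
exact, no intensity quantization) and locally flattened by a white top-hat
(disc radius 25 px, larger than a vessel wall's half-width), then
binarized by Otsu's rule. Otsu degrades when foreground is a tiny fraction
of the field (a single positive vessel), so binarization falls back to the
triangle rule when the Otsu split fails a separation guard
(foreground–background mean difference ≥ 4 background SDs); if neither
split passes, the channel is declared signal-free rather than slicing
noise. Candidates are the union of the three binaries, labeled with
8-connectivity, size-filtered to [100 µm², 10⁶ µm²] (excludes single cells
and scan artifacts; bounds configurable).

Per object and marker, positivity = coverage ≥ 0.10 of object pixels
inside the marker's own binary AND mean intensity ≥ 0.5× the channel
threshold — explicit defaults where the original thresholds were set
manually per sample. PDPN⁺ objects with panCK coverage above 0.5 are
removed as basal epithelium. The hierarchical gate (AQP1 branch before
PDPN on double positives, logged) yields five named subtypes, the
AQP1⁺CD34⁻αSMA⁻ single-cell rejection, and an anomaly bin; MECA79 flags
HEV-like vessels across the blood subtypes instead of forming a class of
its own. Morphology (area, filled/lumen area from hole filling, perimeter
as exposed pixel edges, moment eccentricity, convex-hull solidity, form
factor) is computed per object; the edge-count perimeter overestimates
smooth contours (taxicab metric), which biases form factors low but is
deterministic and monotone — comparisons across vessels remain valid.
Region assignment is a strict-majority rule (IT iff > 50% of pixels;
ties go to PT).

## Cells

Nuclei: Gaussian smoothing (σ = 1 px), white top-hat (radius 12 px) so
diffuse parenchymal hematoxylin does not set the threshold, Otsu, then a
distance-transform watershed to split touching nuclei. Intensities are
measured on each marker over the nucleus dilated by 2 px (the chromogenic
markers are membranous/cytoplasmic); dilated footprints stay disjoint via
geodesic label propagation. Nuclei outside a [10, 200] µm² sanity band are
flagged, not dropped — the original workflow's manual morphology check is
out of scope.

Gating priority encodes the myeloid caveat: CD68 above threshold is a
macrophage *without* requiring CD45 (myeloid cells stain weakly for CD45);
then CD45⁺CD8⁺ → T cell, CD45⁺CD20⁺ → B cell, CD45⁺ → other leukocyte,
else non-leukocyte. Cells eligible for several lineages go to the
strongest z-scored marker and are logged. Thresholds default to per-marker
Otsu over the cell means with the same separation guard, so a marker
absent from an ROI yields no positives instead of noise calls.

## Spatial metrics

Densities are counts over region area (mm²); empty regions yield missing
values, never 0/0. Subtype proportions are normalized within the blood
(AQP1⁺) and lymphatic (PDPN⁺) families and sum to 1 whenever the family is
non-empty. The infiltration call is the CD8 IT:PT density ratio with
cutoff 1.0 (the ratio is always reported alongside the call; the source
defines the ratio but no cutoff): ratio ≥ 1 INFILTRATED, < 1 EXCLUDED,
PT = 0 with IT > 0 INFILTRATED, both zero or missing UNDEFINED. TLS are
single-linkage clusters (link radius 50 µm) over CD8 T and CD20 B cells
requiring ≥ 10 of each — co-aggregation is mandatory, a pure T-cell
cluster is not a TLS. Vessels are associated with a TLS when their
centroid is within 100 µm of the aggregate's convex hull (vessels sit at
aggregate margins). All three TLS parameters are unspecified in the source
and exposed in the API.

## Statistics

`compare_groups()` operationalizes "tested for normality, tests applied as
appropriate": Shapiro–Wilk at α = 0.05 per group; both normal → Student's
t (paired on request), otherwise Mann–Whitney (Wilcoxon signed-rank when
paired). `correlate()` chooses Pearson vs Spearman the same way.
`anova_oneway()` is the classical one-way ANOVA, delegating two groups to
the pairwise test. No multiple-testing correction is applied (none is
stated in the source); raw p values are emitted with test names.
ROI values aggregate to samples as plain means of non-missing values.
`inflammatory_subtypes()` z-scores each sample's leukocyte-density profile
(constant profiles scale to zero and are flagged), clusters samples by
Ward/Euclidean, cuts at k = 3, and renumbers labels by descending mean CD8
density for reproducibility; whether the original grouping was algorithmic
is unknown, so Ward with a configurable k is the package's explicit
choice.

## The synthetic benchmark

The generator emulates what the pipeline assumes, not tissue realism: a
tissue disk occupying ~45% of the frame on a darker background (the
background must dominate the hematoxylin histogram for triangle
thresholding, exactly as glass dominates a scanned slide), two S100⁺
nests, vessels as filled annuli whose walls carry the marker set of their
subtype with the lumen at background (giving analytic truth for lumen
area and openness), leukocytes as disks painting their marker set over a
slightly dilated nucleus, macrophage CD45 at 0.3× contrast to exercise
the relaxed myeloid gate, and Beer–Lambert RGB rounds. Intensities are
background (0.2) + contrast (1.0) with Gaussian noise (SD 0.1, clipped at
zero; the background sits two SDs above zero so clipping does not create
a spike at 0), i.e. SNR ≈ 10 — the high-SNR regime of chromogenic
staining. The default desk-scale ROI is 1000×1000 px at 1 µm/px (1 mm²);
the 6.25 mm² geometry is a preset. The standard study layout
(`random_roi_spec()`) plants 20 vessels cycling the five subtypes (six
blood vessels intratumoral, lymphatics peritumoral), 300 cells across the
five classes (40% intratumoral), and one peritumoral TLS (15 CD8 + 20
CD20) with an adjacent MECA79⁺ vessel drawn from the vessel budget.

Two generator choices need justification. First, scattered peritumoral
T/B cells are placed with > 52 µm mutual dispersion: at the layout's
lymphocyte densities, a 50 µm link radius percolates
($\lambda \pi r^2 > 1$), so unconstrained background cells would form
chance chains satisfying the 10+10 co-aggregation rule and the generator's
own TLS count would be wrong — the constraint makes the ground truth
well-defined; the detector is untouched. Second, nuclei are drawn only
for planted cells (synthetic tissue is nuclei-sparse), so cell
segmentation is tested on detection and splitting, not on the cellularity
of real parenchyma.

What passing tests show — and what they do not: recovery of planted
objects at SNR 10 with hard edges demonstrates the correctness of the
thresholding, labeling, gating and accounting logic, and the exactness of
the geometry (areas, regions, densities). It does not demonstrate
robustness to out-of-focus blur, stain variation across batches, melanin,
tissue folds, or densely packed irregular nuclei; on real slides the
manual threshold review that the original workflow used remains
advisable.

## Numerical choices and degenerate inputs

Ties: Otsu and triangle both break toward the lower bin; region
assignment at exactly 50% goes to PT; `which.max` everywhere takes the
first maximum. Connected components are 8-connected (diagonal merge over
the 4-connected labeling). Constant images are rejected by the threshold
rules ("degenerate histogram"), produce empty masks with warnings in
segmentation, and fail registration with "degenerate input". Empty
families, regions, or tables propagate as missing values or empty tibbles
with stable schemas. All randomness flows from explicit seeds; two runs
of the same spec or config are bit-identical, which the suite asserts.

Problem sizes in the test-suite and acceptance script — five 1 mm² ROIs
with 20 vessels and 300 cells each, 100 random histograms per threshold
rule, 20 registration pairs, 1000 null replicates for the type-I error —
were chosen so the full suite completes in a few minutes on one CPU while
keeping binomial error bands tight enough for the asserted tolerances.

## Known limitations

Translation-only registration; fixed stain vectors (no per-slide
estimation, no melanin model); the perimeter metric's taxicab bias; Otsu
on extremely unbalanced channels relies on the triangle fallback and
separation guard rather than a principled mixture fit; TLS detection is
purely geometric with no germinal-center criteria; and the statistics
module intentionally reports uncorrected p values.
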