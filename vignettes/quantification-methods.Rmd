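---
title: "Quantification methods: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauscope)
```

tauscope packages the image and electrophysiology quantifications used to
study how astrocytes take up, store and spread pathological tau: particle
(inclusion) analysis with integrated-density reporting, DAPI-based
live/condensed nucleus scoring, skeleton-based branching morphometry, a
FRET-biosensor seeding readout, and template-fit detection of excitatory
postsynaptic currents (EPSCs) with an asymptotic test for equality of
coefficients of variation. Because no raw micrographs or recordings are
publicly deposited for this kind of study, the package ships a synthetic-data
generator that emits images and current traces together with an exact
ground-truth ledger, so every stage can be validated quantitatively. This
vignette explains the models behind each stage, the parameters that matter,
the numerical choices, and what the validation on synthetic data does and
does not establish.

## The inclusion (particle) quantification chain

Fluorescent tau deposits inside cells are quantified by a fixed chain of
raster operations on the deposit channel:

1. maximum-intensity projection across z (identity for single planes);
2. rolling-ball background subtraction;
3. a fixed intensity threshold, identical for every image of a batch;
4. clearing everything outside a region of interest (ROI) derived from a
   cellular marker channel, so only intracellular signal is measured;
5. connected-component ("particle") analysis with an area floor.

For each particle the pipeline reports the pixel area, the physical area,
the mean intensity, and the integrated density
$\mathrm{IntDen} = \text{area} \times \text{mean intensity}$, which equals
the sum of pixel intensities over the particle. Per-field totals are
normalised to the number of living cells, identified as live-classified DAPI
nuclei. Particles are partitioned into size classes by pixel area: small
(5–200 px), medium (201–2000 px) and large (2001 px and up); particles below
5 px fall under the detection floor and are discarded (but counted). The
classes partition the retained particles by construction, and classification
depends only on pixel areas, never on the physical pixel size.

Key parameter choices:

* **Threshold** (`deposit_threshold`, `yfp_threshold`). Mandatory
  configuration with no default: a fixed threshold shared across all time
  points is part of the measurement definition, so the package refuses to
  guess one per image. `calibrate_threshold()` (Otsu on a designated
  reference plane) freezes one for a batch.
* **Rolling-ball radius** (`ball_radius_px`, default 50). The background
  estimate is the grayscale morphological opening of the plane with a disc
  of this radius; structures narrower than about twice the radius are
  treated as signal. The default comfortably exceeds the diameter of the
  largest deposits (a 3000 px deposit at 2:1 elongation spans about 88 px).
  The opening is computed through EBImage's grayscale morphology behind an
  affine rescaling shim (EBImage assumes intensities in [0, 1]; min/max
  filters commute with increasing affine maps, so this is exact).
* **Background pre-smoothing** (`bg_presmooth_sigma_px`, default 1). A
  morphological minimum over a noisy surface is biased low, which would
  inflate IntDen by roughly the bias times the particle area. Estimating
  the background on a lightly blurred copy (the estimate is still
  subtracted from the *original* plane) suppresses that bias; at a noise
  standard deviation of 10% of deposit intensity the summed-IntDen error
  drops from about 2.6% to about 1.5% with a 1 px sigma.
* **Thresholding convention**: strictly greater-than. Dialects of the
  common tools differ on boundary pixels; the choice is recorded in each
  mask's provenance so batch runs are auditable. A consequence used in the
  tests: a pixel exactly at the threshold is background.
* **Connectivity** (default 8-connected, configurable to 4).

The pixel-to-µm² conversion is always explicit configuration (default
0.3 µm/px). The printed pixel/area correspondences in this line of work are
not mutually consistent across sources, so pixel-unit results are treated as
authoritative and physical areas are derived from the configured scale only.

## Nucleus scoring and condensed-nuclei accumulation

Nuclei are segmented from the DAPI channel by threshold, closing cycles and
component labelling with nucleus-scale area gates (20–400 px at the default
scale); optionally a distance-transform watershed splits touching nuclei.
A nucleus is classified *condensed* (pyknotic, marking a dead cell) when it
is simultaneously small (`area_px <= area_max_condensed_px`) and bright
(`mean_intensity >= intensity_min_condensed`), both boundaries inclusive.
No published criterion exists for this call, so the thresholds are a design
decision of this package: the defaults in `nucleus_defaults()` sit between
the generator's two rendered populations (condensed nuclei drawn at 40% of
the live area and 2.5 times the live intensity), which makes generator and
classifier self-consistent. **On real images the two thresholds must be
calibrated explicitly**; the defaults only make sense relative to the
synthetic rendering.

Accumulation scoring assigns each condensed nucleus to the astrocyte whose
mask contains its centroid — a proxy for the visual engulfment judgement a
human scorer makes; condensed nuclei outside every mask stay in the field
total but join no per-cell bin. Per-astrocyte corpse loads are binned
as 0, 1–2, 3–4 and 5+, and bin fractions over astrocytes always sum to one.
The ratio reported per field is total condensed nuclei over live
astrocytes.

## Branching morphometry

Astrocyte process complexity is measured on the cytoskeletal (GFAP) channel
by the chain: convert to 8-bit (linear min–max rescale), fixed threshold,
Sobel edge magnitude, Gaussian blur (sigma 2 px), binarisation of the
blurred edge image, refinement by dilation–erosion (closing) cycles,
skeletonization, and branch-point counting. Running edge detection on the
thresholded image follows the macro's literal step order even though
edge-then-threshold is the more common arrangement; a config flag
(`edge_then_threshold`) provides the variant.

Numerical choices that the chain's stated steps leave open:

* **Mask binarisation** (`branch_mask_frac`, default 0.25): the blurred
  edge image is binarised at this fraction of its maximum. The value keeps
  the edge band narrow enough that junctions ~16 px apart remain distinct.
* **Skeletonization** is Zhang–Suen thinning (own compiled implementation;
  no thinning operator exists in the installed imaging stack). Thinning is
  homotopic — the skeleton preserves the component count — and idempotent
  on 1-px-wide input.
* **Branch points**: a skeleton pixel qualifies when its 8-neighbourhood
  holds three or more skeleton pixels. Two corrections are needed to turn
  the pixel rule into a junction count. First, a thick junction yields
  several adjacent qualifying pixels; adjacent qualifying pixels are merged
  and each cluster counts once (an X crossing is one junction, not four
  pixels). Second, thinning leaves *staircase elbows* — pixel pairs that
  touch three neighbours without any branching — so a merged cluster is
  kept only when at least three distinct skeleton branches leave it
  (`min_arms = 3`): a Y junction has three departing arms, a crossing four,
  an elbow only two.
* **Spur pruning** (`spur_prune_px`, default 6): skeletons of blurred
  outlines grow 3–5 px terminal forks at stroke tips; terminal branches
  shorter than the limit that end at a junction are removed before
  counting. Real processes in the synthetic fields are at least ~15 px, so
  the default cannot eat a true branch; for real data the limit should stay
  below the shortest biologically meaningful process length.

The cell count divides the junction total: since confluent astrocytes merge
into one mask component, cells are counted as live nuclei whose centroid
lies inside the refined GFAP mask, not as mask components. Mean cell area is
the mask area over the cell count. The per-cell breakdown assigns each
junction to its skeleton component and each component to the nearest
contained nucleus.

With the default parameters, per-cell branch counts on noise-free rendered
trees are exact across stroke widths 1–5 px and 0–6 branch points per cell
(validated on 100 held-out random cells after the defaults were frozen).

## FRET-biosensor seeding readout

The biosensor stage quantifies aggregated-reporter YFP signal: max-project
the z-stack, run the inclusion chain (background subtraction, fixed
threshold, particle analysis) on the projection, sum the particle integrated
densities, and divide by the cell-covered area in µm². The normaliser is a
cell-area mask — typically hand-drawn on phase contrast and ingested as a
mask file — because DAPI-based cell counting would interfere with CFP/YFP
emission; `build_roi()` on a marker channel is a fallback. No FRET ratioing
is performed: the readout is the scalar YFP emission under 405 nm
excitation. The identity `normalized_int_den * cell_area_um2 = yfp_int_den`
holds exactly, the readout is invariant to appending empty z-slices, and for
single-plane stacks it coincides with the inclusion pipeline run directly.

## EPSC detection and group statistics

Synaptic events are inward (negative) current deflections modelled as a
difference of exponentials
$w(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$, normalised to unit peak
magnitude; amplitudes are reported as positive magnitudes. A template is
either constructed from kinetics (`epsc_template()`) or built from 10–20
representative events (`build_template()`): snippets are baseline-subtracted
(baseline = median of the 5 ms before onset), peak-aligned, averaged,
normalised, and the two time constants are fitted to the average. Fewer than
10 or more than 20 candidates are refused, matching the stated construction.

Detection slides the template along the trace and fits scale and offset by
least squares at every position; the detection criterion is the fitted
scale over its standard error (a t-statistic), with threshold 3 by default.
Because the criterion stays elevated along an event's own decay tail, one
event is accepted per contiguous above-threshold segment (the criterion
must fall below threshold before a new event can begin), and candidates
within one template time-to-peak merge, keeping the higher criterion.
Events with fitted amplitude in (0, 10] pA are discarded — the 10 pA gate —
and analysis is restricted to a 1-minute window (configurable offset).
Detection is invariant to a constant holding current, and a sampling-rate
mismatch between template and trace is resolved by resampling (logged).
Per-event kinetics are the 10–90% rise time (interpolated crossings) and a
single-exponential decay constant fitted log-linearly over the contiguous
100%→20% stretch of the decay.

Timing precision: the kernel starts at zero amplitude, so the onset sample
itself carries almost no information and the profile-likelihood alignment
has a heavy-tailed error of up to ±2 samples (±0.2 ms at the 10 kHz default)
for a fraction of a percent of events at signal-to-noise ratios near 5–8.
Event identity in recovery checks is therefore matched within ±1 ms, the
usual window in detection benchmarking; on low-noise traces the alignment
is exact to ±1 sample.

Group-level comparison of relative variability uses the asymptotic
(Feltz–Miller) test for equality of coefficients of variation: with
per-group CVs $c_i$, weights $m_i = n_i - 1$ and pooled
$\bar c = \sum m_i c_i / \sum m_i$,

$$D = \frac{\sum_i m_i (c_i - \bar c)^2}{\bar c^2 (0.5 + \bar c^2)}
\;\sim\; \chi^2_{k-1}$$

under the null of equal CVs. $D$ is zero when all CVs coincide, invariant
to rescaling all observations, and its type-I error at $\alpha = 0.05$ is
within Monte-Carlo error of 0.05 on simulated equal-CV normal groups
(1000 simulations in the recovery suite). The statistic is implemented from
the published formula and cross-checked in the tests against a direct,
independent evaluation on fixed vectors.

## The synthetic-data generator

The generator emulates the statistical structure the analyses assume, with
an exact ledger recorded *before* background and noise are added:

* **Inclusion fields** (`generate_inclusion_field()`): three channels
  (nuclei, cellular marker, deposit). Deposits are filled, rotated ellipses
  of uniform interior intensity (optionally a 1-px half-intensity rim),
  drawn so each true pixel area falls inside its requested size class, and
  placed by rejection sampling with a minimum separation inside the marker
  ROI; a bounded number of failed attempts raises a "field too crowded"
  error. Intensities are drawn from 300–900 over a background of 10, so the
  default fixed threshold in the validation suites (150) sits far from both.
  With z-stacks, each deposit occupies one slice while nuclei and marker
  appear on all slices, so a max projection recovers the composite exactly.
  Live nuclei are discs (radius 6 px, intensity 120); condensed nuclei are
  rendered at 40% of the live area and 2.5× the live intensity.
* **Branch fields** (`generate_branch_field()`): cells are stroke trees — a
  trunk with k side branches sprouting from interior points spaced 16 px
  apart at ±55°±8° — so the true topological branch count is k by
  construction. One live nucleus sits on each trunk; cells occupy a
  non-overlapping grid.
* **Traces** (`generate_trace()`): baseline + linear superposition of
  difference-of-exponential events (defaults: rise 0.8 ms, decay 6 ms,
  10 kHz) + Gaussian noise. Event placement is explicit or Poisson; the
  ledger holds true onsets, amplitudes and kinetics. The rendered
  baseline-to-peak magnitude of an isolated noise-free event matches its
  ledger amplitude within 1%.
* **Scenarios** (`generate_scenario()`): labelled groups of fields with
  per-group spec overrides, 12 fields per group by default (the typical
  number of randomly captured images per experiment). The standard
  contrast configured in the validation suite is a 67% reduction in live
  nuclei (30 → 10 per field), mirroring the late toxic loss of
  tau-burdened astrocytes.

Every generator draw flows through R's RNG seeded from the spec, so
identical spec + seed give bit-identical rasters, traces and ledgers.

**What passing on synthetic data shows — and what it does not.** The
generator produces geometrically simple, well-separated objects with flat
backgrounds and white Gaussian noise. Exact ledger recovery under these
conditions establishes that the chain's bookkeeping (areas, sums,
classes, counts, normalisations) is correct and that the operators compose
as specified. It does not establish robustness to the hard parts of real
micrographs — uneven illumination, overlapping and textured deposits,
out-of-focus light, clumped nuclei, autofluorescence — nor does it
validate the condensed-nucleus thresholds or a fixed deposit threshold for
any particular microscope. Those require calibration on real reference
images.

## Degenerate inputs and flags

Fields with no live nucleus report raw metrics and flag the per-cell
normalisations as undefined (`normalization_defined = FALSE`); empty ROIs
and empty cell-area masks warn and flag likewise; zero detected events give
frequency 0 with undefined kinetic means; a group mean of zero is an error
in the CV test (its CV is undefined). Batch runs isolate per-field
failures: a corrupt field is logged in the run manifest and skipped, never
silently aborting the batch. All emitted coordinates are 0-based
(row, col) with the origin at the top-left pixel.

## Problem sizes in the validation suite

The recovery suite runs 50 noise-free plus 12 noisy inclusion fields
(256×256 px), 100 tree cells across stroke widths 1–5, 200 random 64×64
masks against a flood-fill oracle, 100 random accumulation assignments,
five 5-slice FRET fields, 50 one-minute traces with 30 planted events each,
and 1000 null simulations of the CV test — sizes chosen to give exact
combinatorial coverage (boundaries, both connectivities, all widths) and
tight Monte-Carlo error on the calibration checks while staying
desk-scale.
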