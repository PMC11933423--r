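---
title: "Coordinate network mapping: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinate network mapping: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coordnet)
```

## The scientific problem

Group-level neuroimaging studies of a disease often report abnormality
*coordinates* — peaks of gray-matter atrophy or functional hyperactivity in a
standard space — that scatter widely across studies. Coordinate network
mapping asks whether these heterogeneous locations nonetheless belong to one
*brain network*: it seeds a normative functional connectome (resting-state
fMRI from many healthy subjects) at each study's coordinates, computes which
voxels are significantly connected to those seeds, and then overlaps the
per-study networks. Voxels connected to most studies' seeds — positively or
negatively — define the disease network. The same machinery applies to
stimulation sites: seeding the connectome at each patient's volume of
activated tissue (VAT) and weighting by clinical outcome yields a
treatment-derived network that can be compared with the abnormality-derived
one.

`coordnet` implements this pipeline end to end, together with the
surrounding statistics used to characterize such a network: an activation
likelihood estimation (ALE) meta-analysis of the raw coordinates,
specificity testing against random-coordinate control networks, ROI-overlap
statistics with parcel-based nulls, spatial correlations, ROI-to-ROI
connectivity profiles, and outcome-weighted stimulation-site networks.
Because the real normative connectomes (hundreds of subjects on a 2 mm MNI
grid) are large external datasets, the package ships a synthetic connectome
generator with planted ground truth so that every stage runs — and is
tested — on a desk-scale problem.

## The mapping model

For one study with foci $x_1, \dots, x_m$ (mm):

1. **Seed construction.** A sphere of diameter $d$ (default 6 mm; 3 and 9 mm
   are the standard sensitivity variants) is rasterized at each focus: a
   voxel belongs to the sphere iff its center lies within $d/2$ of the
   focus (closed ball). The spheres are merged by set union into one
   study-level seed, because foci reported by one study are not independent
   observations. A per-coordinate mode treats each focus as its own seed.
2. **Seed-to-voxel connectivity.** For each connectome subject, the seed
   time series is the unweighted mean of in-seed voxel series, and the map
   value at voxel $v$ is the Pearson correlation $r(v)$ between the seed
   series and $v$'s series, Fisher-transformed $z = \operatorname{atanh}(r)$
   (with $|r|$ clipped at $1 - 10^{-7}$). The Fisher transform before the
   group test is the standard construction in seed-based connectivity; it
   can be disabled.
3. **Group inference.** A voxelwise one-sample t-test of the subject-level
   $z$ values against zero, $t = \bar z / (s_z / \sqrt n)$.
4. **Signed ternarization.** The t-map is thresholded at $\pm t_{thr}$
   (default 5.1, the voxelwise-FWE-equivalent constant used with
   full-size normative connectomes; 4.7, 5.6, 7 and 9 form the published
   sensitivity set): $+1$ where $t > t_{thr}$, $-1$ where $t < -t_{thr}$,
   else 0. Inequalities are strict, so a value exactly at the threshold maps
   to 0 — a declared tie rule that makes the operation exactly testable.
5. **Overlap.** The study ternaries are summed and divided by the number of
   studies. The resulting map in $[-1, 1]$ is the signed proportion of
   studies connected to each voxel and is kept *unthresholded*; it is the
   disease-network estimate. Multiplied by the study count it is an exact
   integer field, which the tests assert.

Because $t_{thr} = 5.1$ is a constant inherited from full-size connectomes
rather than recomputed for each grid, `fwe_t_threshold()` reports the
Bonferroni-equivalent threshold for any grid and cohort size for
transparency.

## The synthetic connectome and what it does (not) emulate

`planted_network_model()` defines $K$ spatial components on a desk-scale
grid (default $24 \times 28 \times 24$ voxels at 3 mm with an ellipsoidal
brain mask — small enough for fast permutation loops while preserving
genuine 3-D geometry). Component 1 is the planted "disease network": a
signed topography with positive lobes (a compact subcortical blob standing
in for a thalamic hub, plus superior sensorimotor-like blobs) and negative
lobes (frontal-pole and posterior blobs), emulating the anticorrelated
organisation that seed-based disease networks show. The remaining
components are smooth random background networks.

Subject data are generated as
$X(v, t) = \sum_k L_k(v)\, c_k(t) + \varepsilon(v, t)$
with i.i.d. Gaussian component time courses $c_k$ and i.i.d. Gaussian
voxel noise. Time courses are white: the mapping statistics depend only on
the spatial covariance structure, so temporal autocorrelation,
hemodynamics, motion and physiological confounds are deliberately not
modelled. Passing tests on this generator therefore demonstrates that the
*statistical machinery* recovers a planted spatial covariance structure;
it does not certify preprocessing choices on real fMRI.

Study coordinates are sampled from voxels whose planted disease loading
exceeds a quantile cutoff (default 0.85), with Gaussian mm jitter (default
sd 2 mm) plus a fraction of uniformly placed off-network foci (default
0.2, mirroring the observation that only a minority of published foci
share any one structure). Sampling defaults to the *positive* lobe: foci
in the anticorrelated lobe would seed sign-flipped networks that cancel in
the overlap map, and the abnormality literature this emulates reports
foci predominantly in positively connected territory. `mode = "absolute"`
draws from both lobes for experiments on that very cancellation.

The literature-emulation preset `synth_ige_coordinates()` fixes the
bookkeeping of the emulated corpus: 21 studies, 131 foci, 540 patients and
778 controls across studies, subtype counts (8 GTCS / 7 JME / 2 AE / 4
mixed), modality counts (13 atrophy / 8 hyperactivity), and exactly 22
foci (17%) inside the model's thalamic mask.

Stimulated patients get spherical VATs (default radius 2 mm — a plumbing
stand-in; biophysical VAT modelling is out of scope) scattered around the
subcortical peak (sd 4 mm), and outcomes
`gain x (mean disease loading in VAT) + noise`, truncated at 100%. The
default gain 95 and noise sd 10 place the cohort in the high-response
regime reported for thalamic stimulation of generalized seizures.

The shipped 21-patient outcome table
(`synthetic_dbs_outcomes()`) is a *synthetic* cohort: its individual
values were solved once to be consistent with the published cohort summary
(median 90%, IQR 66.5–96.5%, mean 66.7%, SE 14.3, 19/21 responders), which
are the only anchored quantities. Given those constraints — 19 values
strictly above 50 and capped at 100 — the variance forces at least one
strongly negative (worsened) outcome; the solved table contains
outcomes of −7.2% and −198.1%.

## ALE meta-analysis

The modeled-activation (MA) map of a study places an isotropic Gaussian at
each focus — the Gaussian *density* of FWHM `fwhm_mm` scaled by the voxel
volume, so a voxel's value approximates the probability mass it captures
(truncated at 3.5 sd). Within a study, overlapping foci combine by
*maximum*, so repeated or adjacent peaks do not inflate the study's
evidence. Across studies the ALE statistic is the probabilistic union
$1 - \prod_i (1 - MA_i)$.

The full-size method chooses the kernel width from each study's sample
size; since those widths are implementation constants of external
software, `coordnet` declares the kernel as an explicit parameter: a
scalar FWHM (default 10 mm) or any monotone function of `n_patients`.

Inference redistributes each study's foci uniformly over the brain mask.
The voxel-level null pools permuted ALE values over voxels and
permutations (valid under the exchangeability of uniformly placed foci)
and sets the cluster-forming threshold (default $p < 0.001$); the null of
maximum 26-connected cluster sizes sets the cluster-level FWE size cut
(default $p_{FWE} < 0.01$). 26-neighbour connectivity is the declared
cluster rule throughout the package, including TFCE.

## Specificity and validation statistics

Control networks come from `random_coordinate_sets()`: each study's foci
are redistributed uniformly over in-mask voxel centers, preserving
per-study focus counts; four repeats of a 21-study table give the 84
random study-level seed sets of the published construction.

`two_sample_permutation_test()` compares two groups of (unthresholded)
study t-maps voxel by voxel with an unequal-variance Welch t — the
unthresholded maps are used because thresholding discards effect-size
information and the choice is configurable. The null permutes group
labels; two-sided p-values use the add-one estimator
$(1 + \#\{|t_\pi| \ge |t_{obs}|\})/(1 + B)$, so the smallest attainable p
is $1/(B+1)$. Benjamini–Hochberg correction runs across in-mask voxels
(significance at $q < 0.05$). TFCE ($H = 2$, $E = 0.5$, the field
defaults, as the method was named without parameters) can be applied to
the t-maps before ranking but is off by default so the core path is
exactly reproducible; an exhaustive-enumeration mode exists for small
groups, where p-values are exactly invariant under swapping the groups.

ROI overlap is the mask mean of the network map times 100, sign
preserved — an ROI on anticorrelated territory scores negative. Parcel
nulls draw parcels uniformly *with replacement* (10,000 draws from a
~68-parcel atlas necessarily resample) and report the one-sided
add-one p-value. Group comparisons of overlap scores use the Welch
t-test; network profiles use a one-way equal-variance ANOVA with subjects
as observations. Lesion-style overlap uses the *signed* network values
rather than separate positive/negative maps — the simplest rule consistent
with the sign convention above. The 10–20 electrode montage is placed by
casting rays from the mask centroid at the montage's canonical angles and
taking the outermost in-mask point, so the same labelled layout scales to
any head geometry, including the synthetic ellipsoid; electrode ROIs are
25 mm-diameter spheres.

## Stimulation-site networks

Each patient's VAT network uses exactly the coordinate-network machinery
(seed = VAT). The cohort network is the outcome-weighted average
$\sum_i w_i M_i / \sum_i w_i$ with raw percentage weights; individually
negative weights (worsened patients) are allowed but the total must be
positive — published descriptions of outcome weighting are silent on
worsened patients, so this is the declared rule. Patient maps enter as unthresholded t-maps
(configurable), consistent with the networks being computed on the same
normative connectome. The convergent network z-scores the two input maps
within the mask and averages them; by construction it correlates equally
with both inputs when compared on the same mask, which the tests assert
to $10^{-10}$.

## Numerical choices and degenerate inputs

- mm coordinates are RAS; voxel indices are 0-based in the public
  interface; mm↔voxel conversion rounds to the nearest lattice point and
  flags (rather than throws on) out-of-bounds results.
- Sphere inclusion is voxel-center-within-radius with a closed ball; the
  published method does not state its rule, and its own sensitivity
  analyses show threshold-level robustness, so the simplest exactly
  testable rule is declared.
- A focus whose sphere misses the brain mask is an error naming the
  coordinate; `snap_to_mask = TRUE` moves the center to the nearest
  in-mask voxel instead.
- Voxels with zero time-series variance get $r = 0$ and are counted; a
  zero-variance *seed* is an error. Zero across-subject variance in the
  group t-test yields a signed infinite sentinel (0 if the mean is also
  0) and a flag; map-comparison operations exclude non-finite voxels.
- Quartiles use linear interpolation between order statistics
  (`quantile type 7`, configurable) — printed interquartile ranges depend
  on this convention. Responders are strictly `> 50%`.
- Peak localization breaks ties to the lowest linear voxel index.
- All stochastic stages take explicit seeds; pipeline re-runs are
  reproducible bit for bit.

## Problem sizes

The default synthetic preset uses 40 subjects × 200 timepoints with 12
studies on the 3 mm grid (~6,600 in-mask voxels) — chosen so that the
planted-network recovery analysis completes in well under a minute while
leaving enough statistical resolution for the t-threshold machinery.
Calibration experiments (false-discovery control under the null; ALE
cluster-FWE rates over 50 replicate runs at 200 permutations) run on a
coarser 6 mm grid (~500 voxels), where a full replicate set takes about a
minute. The published analyses use 10,000 permutations; the package
defaults scale these to 1,000 (ALE) and 200 (voxelwise test), and all
counts are configurable.

## Known limitations

- No surface (GIFTI/CIFTI) support, no registration, no DICOM; volumes
  are NIfTI-1 only.
- The ALE implementation is not bit-compatible with external ALE
  software; its kernel is a declared parameter rather than a sample-size
  table, and exact reproduction of published ALE peak tables would
  require the original foci and kernels.
- Printed validation statistics that depend on the real 652-subject
  connectome and external ROI datasets (ENIGMA maps, lesion atlases,
  SCAN coordinates) are represented structurally — any ROI set or map can
  play those roles — but their published values are not reproducible at
  desk scale, and the package does not attempt to encode them.
- The synthetic generator's white time courses and Gaussian blobs are a
  deliberate simplification; effect sizes on real data will differ.
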