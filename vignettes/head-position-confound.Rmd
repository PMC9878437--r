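---
title: "Head position, coil sensitivity, and within-session connectome fingerprinting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Head position, coil sensitivity, and within-session connectome fingerprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coilprint)
```

## The problem

Multi-channel phased-array receive coils deliver high signal-to-noise near
their elements and markedly less at the coil center — a factor of 2–3
between shell and center is typical. An infant's head occupies only part of
the coil volume and rests at a position that varies substantially between
scanning sessions (brainmask centroids spread over roughly −5…+29 mm
posterior–anterior and −14…+7 mm left–right) but barely moves within a
session. Regional temporal SNR (tSNR) therefore carries a *pose signature*:
nearly constant across the two halves of one session, substantially
different between sessions.

Connectome fingerprinting identifies a participant by matching the Spearman
similarity of connectome edge vectors across two segments. If the segments
come from the same session, the shared pose signature alone can drive the
match — identification then partly decodes head position rather than
individual brain connectivity. `coilprint` implements the full analysis
chain needed to demonstrate and quantify this confound, together with a
synthetic-cohort generator so every stage is testable without access to
real infant data.

## The generative model

### Coil sensitivity field

`makeCoilField()` sums compressed-exponential radial kernels
$\exp\{-(d/\lambda)^{p}\}$ centered on 32 elements arranged on a 60 mm
Fibonacci shell. Two anchor facts constrain the shape: the shell/center
ratio must lie in $[2,3]$, and a 20 mm displacement should cost about 50%
of the SNR. A pure exponential kernel ($p=1$) cannot satisfy both — fixing
the 20 mm attenuation forces shell/center ratios of 5–9 — so the kernel
shape is $p=2.5$, and $\lambda$ is calibrated once by bisection so that the
*steepest* 20 mm window along the posterior ray attenuates by exactly 50%.
That window sits ~11 mm from the center, where the edge of a posteriorly
resting head actually sits. With the calibrated $\lambda \approx 36.6$ mm
the default field has shell/center ratio 2.74 and a center-to-20 mm ratio
of 0.578:

```{r field}
field <- makeCoilField()
v <- sampleField(field, rbind(c(0, 0, 0), c(0, -20, 0), c(0, -60, 0)))
c(shell_center = v[3] / v[1], atten_20mm = v[1] / v[2])
```

### Sessions

`simulateSession()` draws latent ROI signals as a stationary multivariate
Gaussian whose correlation matrix blends three components, each a valid
correlation matrix so every convex combination is too:

* a cohort-shared **group** connectome (`structuredCorrelationMatrix()`:
  one latent network per ROI plus a weak global factor, giving
  within-network correlations of ~0.3–0.8 — the magnitude structure of real
  resting-state connectomes; Wishart draws are far too weak);
* an **individual** component (weight `individualWeight`, default 0.3) —
  the trait a fingerprint could legitimately detect;
* a **session-state** component (weight `stateNoise`, default 0.5) —
  day-to-day network reconfiguration, shared by the two halves of a session
  but not across sessions.

White observation noise is added per ROI with variance chosen so that
measured tSNR is proportional to the coil-field value at the ROI's posed
position (`tsnrCenter = 40` at the coil center). Because the mean BOLD
level is fixed, this choice *forces* the attenuation of observed
correlations to scale with the product of the two ROIs' field values:
$c^{obs}_{ij} \approx a_i a_j \rho_{ij}$ with $a_i \propto f_i$. That is
the mechanism of interest — SNR and functional connectivity are coupled
through head position — and it emerges from the noise model rather than
being painted on. The proportionality reference is the highest field value
any posed ROI attains in the cohort (that ROI keeps 99% of its variance as
signal); for a homogeneous field the attenuation is therefore uniform and
~1, and the sampled connectome converges to the trait matrix.

### Poses and motion

Between-session base poses draw translations uniformly from the observed
centroid ranges (PA −5…+29 mm, LR −14…+7 mm; the superior–inferior span,
±5 mm, and rotations, ±5°, are not reported quantities and are documented
defaults). A fraction `poseConsistency` (default 0.3) of each subject's
position is a stable resting preference, the rest is redrawn per session.

Within a session the head follows a slow AR(1) postural drift with marginal
SD 1 mm / 0.5° and correlation time `8 * nVolumes`: sleeping infants change
posture on the tens-of-minutes scale, not volume-to-volume. Independent
1 mm jumps every 0.392 s would imply mean framewise displacements of
~2 mm/volume — two orders of magnitude above what preprocessed infant data
show — and would erase the within-session pose similarity the analysis is
about. With the drift model the two split-segment reference poses of one
session differ by ~0.4 mm while two sessions differ by ~10 mm. Poisson
motion spikes (rate 0.0015/volume, ~3 per session) add brief displacements
and a transient global intensity artifact, so high-motion sessions have
genuinely less stable connectomes.

### Head geometry

ROI centers form a shared ellipsoidal cortical shell (axes 0.85/1.05/0.80
of 90% of the head radius, with per-ROI radial scatter), scaled by each
subject's head radius (mean 28 mm, SD 1.5 mm — a scaled-down neonatal
geometry chosen so heads stay inside the 60 mm element shell under the full
repositioning range). Head circumference in the covariate table is tied to
this radius. Because the template is shared, SNR profiles differ between
subjects only through pose and scale — by design, so that SNR-only
identification measures pose, not anatomy.

## The analysis chain

The pipeline follows the order quality control → segmentation → filtering →
connectomes → similarity → identification → regression:

* `qcRoiFilter()` removes ROIs whose mean intensity falls 3 SD below the
  across-ROI mean in strictly more than 10% of sessions (raw series — QC
  precedes filtering).
* `splitSession()` removes 60 s (rounded to volumes; the replication preset
  pins 154) from the middle, centered, odd remainder to the first segment.
  `bandpass()` applies a zero-phase order-2 Butterworth 0.01–0.1 Hz filter
  per ROI (an FFT-mask alternative exists for cross-checks).
* `computeConnectome()` computes Pearson edges; `computeRsm()` Spearman
  across-segment similarity (ranks are robust to the non-normality of
  correlation values); `identifyParticipants()` matches each target to its
  most similar database entry, with ties never credited to self.
* `snrProfileFromCenters()` / `predictSnrGroup()` sample the coil field at
  the atlas posed by the segment's reference volume
  (`poseAtReferenceVolume()`, the floor-midpoint volume of the segment).
* `edgewiseSnrFcRegression()` fits, per edge, standardized connectivity on
  the standardized SNR product $s_i s_j$ across participants; the primary
  inference is a permutation test (B = 1000 by default) that shuffles the
  participant-to-profile assignment and recomputes the mean slope.
  `predictorComparison()` enters segment-1 SNR product and segment-1
  connectivity as standardized regressors for segment-2 connectivity.
* `stabilityRegression()` regresses within-participant Spearman stability
  on z-scored explanatory variables (five for full sessions: mean SNR,
  mean FWD, inter-session interval, age, head circumference; two for
  split-sessions: mean SNR, mean FWD). Coefficients are standardized in the
  explanatory variables only, so planted effect sizes are recovered on
  their own scale.

## Numerical conventions and edge cases

* Coordinates: 0-based voxel indices, half-open volume ranges, RAS+ mm.
* Poses: FSL `.par` column order (3 rotations in radians about x, y, z
  applied in that order about the volume center, then 3 translations in
  mm); round-trip parameter↔affine tested to 1e-8.
* Reference volumes: the floor-midpoint convention reproduces index 1763
  for the second split of a 2300-volume session and 1149 for the full
  session; for the first split it gives 536. The two printed indices of the
  protocol this mirrors (537 and 1763) are mutually inconsistent with any
  single midpoint rule (537 − 0 ≠ 1763 − 1227); the implementation keeps
  the self-consistent rule.
* Interpolation: trilinear for field/SNR values, nearest-neighbour for
  atlas labels (labels must never be averaged). Points outside a map's
  defined region are NA, never 0 — 0 is a legal SNR.
* "Soft mean": per voxel, the mean over only those maps defined (and
  finite) there, with the contributing fraction stored as coverage.
* Zero residual SD in tSNR (e.g. a pure ramp) flags the value infinite and
  warns rather than silently dropping it; zero-variance regressors skip
  their edges and are counted; exact similarity ties are reported and never
  credited to self.
* The 60 s gap at TR 0.392 s rounds to 153 volumes; the replication preset
  pins the printed 154 instead. Both are honoured via `gapVolumes`.

## What the generator does and does not emulate

The synthetic cohort reproduces the statistical skeleton the analysis
relies on: coil-profile tSNR geometry, pose-coupled attenuation of
measured connectivity, network-structured connectomes with group /
individual / session-state layers, slow within-session drift with spikes,
and the covariate table. It does **not** emulate spatial autocorrelation
within ROIs, hemodynamic temporal autocorrelation (latent signals are
white, so bandpassing costs degrees of freedom but leaves attenuation
ratios untouched), cardiorespiratory or multiband artifacts, anatomical
variability beyond a scale factor, or registration error. Passing tests
therefore validate the *pipeline logic and the confound mechanism*, not
claims about any particular real dataset.

Problem sizes in the test-suite experiments are the package's own choices:
the demonstration cohort runs at the full 44 × 2 × 2300-volume design with
a 100-ROI parcellation (a scaled-down stand-in for a 400-region cortical
atlas; edge counts scale as R², not the phenomenon), the edge-wise
regression cohort at 400 × 1 × 512 volumes with 40 ROIs, and regime
separation at 44 subjects with 40 ROIs.

## A worked demonstration

```{r demo, eval = FALSE}
demo <- demoConfound(seed = 1, nSubjects = 44)
round(demo$rates, 3)
#> connAcross connWithin  snrAcross  snrWithin
#>      0.159      0.955      0.000      0.989
```

Connectome identification succeeds within sessions (96%) but largely fails
across sessions (16%), and head-pose SNR profiles alone — no functional
data — identify 99% of participants within a session. The within-session
fingerprint is, to a large extent, a head-position fingerprint.

## Known limitations

* Spearman similarity saturates for colinear head displacements (profiles
  become near-monotone transforms); discrimination in the cohort comes from
  direction and rotation diversity, as it would in real data.
* The attenuation model ties connectivity attenuation linearly to tSNR; in
  real data ROI averaging over spatially correlated voxels softens this
  link. The qualitative coupling (higher SNR → stronger measured
  connectivity) is what matters for the analyses.
* The permutation summary treats edges jointly through the mean slope;
  per-edge p-values assume independent Gaussian errors and are reported for
  completeness only.
* Confidence intervals over edges in the predictor comparison are
  descriptive (edges are strongly dependent).
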