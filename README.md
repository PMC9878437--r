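# coilprint

Head-position SNR artifacts in infant connectome fingerprinting.

## The problem

Phased-array MRI head coils are inhomogeneous: signal near the receive
elements is 2–3× higher than at the coil center, falling off smoothly in
between. An infant's head sits at a position that varies substantially
between scanning sessions (brainmask centroids spread over roughly
−5…+29 mm posterior–anterior and −14…+7 mm left–right) but is nearly fixed
within a session. Regional temporal signal-to-noise (tSNR) therefore
carries a *pose signature* — and because observation noise attenuates
measured Pearson connectivity, that signature leaks into the functional
connectome itself: `c_ij ≈ a_i a_j ρ_ij` with attenuation `a_i`
proportional to the local coil sensitivity.

Connectome **fingerprinting** identifies a participant by Spearman-matching
connectome edge vectors across two segments. When the two segments come
from the *same* session (split-half designs), the shared pose signature
alone can drive the match: identification partly decodes where the head
was, not whose brain it is. `coilprint` implements the analysis chain that
demonstrates and quantifies this confound:

* **Synthetic cohort generator** — smooth coil-sensitivity field (sum of
  compressed-exponential element kernels, calibrated by bisection to the
  shell/center ratio ∈ [2, 3] and ~50% SNR loss per 20 mm anchors),
  rigid-body head poses with realistic between-session repositioning and
  slow within-session drift, and SNR-coupled multivariate Gaussian ROI
  timeseries with network-structured connectomes, with a ground-truth
  ledger for parameter recovery.
* **SNR mapping** — tSNR (mean / detrended SD), mask erosion, reslicing to
  scanner space, soft-mean group averaging ("SNR-coil"), and per-ROI SNR
  prediction from head pose alone ("SNR-group").
* **Connectomics** — split-session segmentation (60 s central gap),
  0.01–0.1 Hz zero-phase Butterworth bandpass, Pearson connectomes, and an
  ROI quality-control filter (mean − 3 SD outliers in >10% of sessions).
* **Fingerprinting** — Spearman representational similarity matrices,
  identification with conservative tie handling, within/between-participant
  summaries.
* **Regression models** — edge-wise OLS of standardized connectivity on
  the standardized SNR product `s_i s_j` with a permutation test;
  a two-predictor comparison (does segment-1 SNR or segment-1 connectivity
  better predict segment-2 connectivity?); connectome-stability models on
  SNR, framewise displacement, interval, age and head size; framewise
  displacement itself.

## Worked example

```r
library(coilprint)

# the coil field and its two anchor properties
field <- makeCoilField()
v <- sampleField(field, rbind(c(0, 0, 0), c(0, -20, 0), c(0, -60, 0)))
v[3] / v[1]   # shell/center ratio     -> 2.74
v[1] / v[2]   # value 20 mm posterior  -> 0.578 (~50% loss)

# the full demonstration: 44 subjects x 2 sessions x 2300 volumes
demo <- demoConfound(seed = 1, nSubjects = 44)
print(demo)
#> head-position confound demonstration
#>   connectome ID: within 96%, across 16%
#>   SNR-only ID:   within 99%, across 0%
#>   predictor comparison (split): beta_SNR 0.079, beta_FC 0.135
```

Reading those numbers: matching split-halves of the same session identifies
96% of participants, while matching across sessions identifies only 16% —
and head-pose SNR profiles *alone*, computed without any functional data,
identify 99% within a session. Within-session fingerprinting is largely a
head-position readout. In the predictor comparison, the segment-1 SNR
product still explains a substantial share of segment-2 connectivity
(standardized coefficient 0.079) next to segment-1 connectivity itself
(0.135).

Individual stages are available directly, e.g.:

```r
cohort <- makeCohort(10, 2, cohortConfig(nRoi = 60, nVolumes = 1150), seed = 7)
an <- analyzeCohort(cohort)          # QC, connectomes, RSMs, identification
an$identification$acrossConn$rate
splits <- splitSession(cohort$sessions[[1]])
computeTsnr(roiTimeseries(cohort$sessions[[1]]))[1:5]
```

## Package layout

```
R/                  S4 classes (CoilField, HeadPose, SessionRecord,
                    Segment, Connectome, RSM, ...) and the analysis chain
tests/testthat/     unit, property and end-to-end tests with independent
                    brute-force oracles
scripts/acceptance.R  end-to-end reproduction script
vignettes/          methods vignette: model, assumptions, conventions
```
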