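---
title: "Methods: quantitative SPECT dosimetry for Ac-225 targeted alpha therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative SPECT dosimetry for Ac-225 targeted alpha therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acdosim)
```

## The problem

[225Ac]Ac-PSMA radioligand therapy delivers its dose through a chain of four
alpha decays: Ac-225 (half-life 9.92 d) decays through Fr-221 (4.8 min),
At-217 (32 ms) and Bi-213 (45.6 min) to stable-ish Pb-209, emitting alphas of
5.8, 6.3, 7.1 and — after Bi-213 — either 8.4 MeV (97.8%, via Po-213) or
5.9 MeV (2.2%, via the Bi-213 alpha branch). Ac-225 itself is essentially
invisible in vivo, but Fr-221 (218 keV) and Bi-213 (440 keV) have usable
gamma lines, so quantitative SPECT of those photopeaks is the only
image-based access to the chain's pharmacokinetics.

The complication is alpha recoil: each decay imparts ~100–200 keV to the
daughter nucleus, enough to break any chemical bond. Fr-221 and At-217 are
too short-lived to migrate before decaying, so their spatial distribution
tracks the PSMA-bound Ac-225. Bi-213, with 45.6 min, can relocate — free
Bi-213 is known to accumulate in the kidneys and to be excreted in urine. The
package therefore treats the chain as two segments: the *Fr segment*
(Ac-225, Fr-221, At-217; 19.2 MeV of alpha energy per decay, surrogate:
218-keV imaging) and the *Bi segment* (Bi-213 and daughters;
0.978·8.4 + 0.022·5.9 = 8.345 MeV, surrogate: 440-keV imaging).

## Activity quantification and SUV

Reconstructed SPECT volumes arrive in cps/voxel. A uniform cylinder phantom
with known concentration provides one calibration factor per energy window
(mean cps/voxel in a large central VOI divided by the known Bq/ml). Patient
images are divided by this factor, post-filtered with an isotropic Gaussian
(default FWHM 30 mm, a compromise between noise suppression and recovery at
the count levels of ~8 MBq therapies), and analyzed per VOI:

* kidneys are consumed as supplied (CT-based) masks;
* lesions are segmented on the *filtered* 24-h image with an inclusive 80%
  isocontour of the regional maximum, keeping the 6-connected component that
  contains the maximum; the 24-h mask is reused at 48 h, with an optional
  integer-voxel manual shift; segmentation is done separately per window;
* SUV_mean is the mean concentration divided by injected activity per body
  mass, with tissue density 1 g/ml. No recovery or partial-volume correction
  is applied anywhere — reported concentrations and SUVs are "as imaged".

Whether SUV statistics should be read from the filtered or the raw
calibrated image is genuinely open; the package defaults to the filtered
image (consistent with segmenting on it) and exposes
`statistics_on_filtered = FALSE` for the alternative.

## Kinetics

With two imaging time points (24/48 h — the realistic in-patient window),
the mono-exponential model
\[ A(t) = A(t_0)\, e^{-\ln(2)\, t / T_{1/2}} \]
is an exact interpolation: the fit is closed-form, the residual is zero and
no uncertainty is fabricated. With more points an unweighted (optionally
1/σ²-weighted) Levenberg–Marquardt fit is used; the two paths agree to
1e-8 on two-point data. Non-decaying two-point TACs are rejected with a
classed error and listed in the pipeline's `rejected_tacs` table rather than
clamped. The effective half-life decomposes as
1/T_eff = 1/T_phys + 1/T_bio.

The time-integrated activity is `A(t0)·T_eff/ln 2`, integrating from t = 0
with the fit extrapolated back to injection — standard MIRD practice when no
early imaging exists; the uptake phase before the first scan is thereby
approximated as instantaneous, a documented limitation. A deferred lower
bound (`integrate_from_h`) is available and recorded in the run log.

## Dosimetry

Self-irradiation only:
\[ D = \tilde A \cdot S, \qquad
   S = \frac{E_\alpha \cdot 1.602\times 10^{-13}\,\mathrm{J/MeV}}{m} \]
under the default `alpha_local` energy model (alphas absorbed locally,
photons/electrons neglected; VOI mass = segmented volume × 1 g/ml). A
user-supplied per-nuclide S-value table (e.g. an OpenDose export, which is
not redistributable here) replaces the local-alpha S values and reproduces
the full photon/electron pathway; with a table whose entries equal the
local-alpha values both models agree to 1e-12. RBE weighting (default 5)
multiplies the alpha component; under `alpha_local` all counted energy is
alpha, so `Sv_RBE = 5 × Gy`.

Three chain-partitioning methods mirror the imaging choices:

1. whole chain on the Bi-213 (440 keV) TAC;
2. whole chain on the Fr-221 (218 keV) TAC;
3. Fr segment on the Fr-221 TAC plus Bi segment on the Bi-213 TAC.

Daughters within a segment share their surrogate's time-integrated activity
(the implicit transient-equilibrium assumption). Identical TACs make the
three methods coincide exactly. Method comparisons report the symmetric
percent difference 100|a−b|/mean(a,b) *and* the relative-to-second
convention, because which denominator a given report uses is often
ambiguous. The 78-keV X-ray window participates in SUV and half-life tables
but never in dosimetry.

## Urine analysis

A 1-ml urine aliquot counted in a gamma counter for ≥ 6 h (until secular
equilibrium, reached to ~0.3% residual transient after ~6.4 h) shows the
Bi-213 activity
\[ A_{Bi}(t) = A_{Ac}(0)\,\frac{\lambda_{Bi}}{\lambda_{Bi}-\lambda_{Ac}}
   \left(e^{-\lambda_{Ac}t} - e^{-\lambda_{Bi}t}\right)
   + A_{Bi}(0)\, e^{-\lambda_{Bi}t}, \]
with Fr-221/At-217 treated as instantaneous. A bound-constrained (≥ 0)
nonlinear least squares recovers both amplitudes at collection. Count data
are fitted with the *bin-averaged* forward model (the closed-form integral
over each counting bin) and Poisson weights; pre-calibrated activities are
fitted unweighted with the instantaneous model. When the counting efficiency
is unknown, the amplitudes are reported on an arbitrary scale and flagged;
the Bi/Ac ratio is scale-invariant and remains trustworthy. Dead-time and
decay-of-standard corrections are assumed upstream.

Cohort summaries use the population (divide-by-n) standard deviation, and
the "mean increase" between collection epochs is the mean of per-patient
ratio differences in percentage points; the mean relative change is emitted
alongside, since the two conventions differ for small cohorts.

## Statistics

Small cohorts need exact inference: the Wilcoxon signed-rank p-value is
computed from the exact permutation null — the distribution of the
positive-rank sum over all 2^n sign assignments, evaluated by a
dynamic-programming convolution over (doubled, mid-tied) ranks, identical to
full enumeration but feasible to n = 25 — with the two-sided convention
2·min(P(W≤w), P(W≥w)) capped at 1. Eight one-signed pairs give exactly
2/256 ≈ 0.0078. Zero differences are dropped and counted. Above n = 25 a
normal approximation with continuity and tie correction takes over.
Pearson's r is tested via the t transform on n−2 degrees of freedom. Where
kidney and lesion doses must be compared without a natural pairing, every
kidney is paired with every lesion within a patient, in listed VOI order.

## The synthetic cohort

The generators produce every input the pipeline consumes, as a pure function
of (scenario, seed) with per-component seed streams. The default scenario
fixes the study conditions: five patients injected with 7.9/8.0/7.8/7.6/7.4
MBq (weights 107/85/70/93/98 kg), two scans at 24/48 h, three windows
(440 keV/20%, 218 keV/20%, 78 keV/50%), eight kidneys plus nine lesions
(0/2/3/2/2 per patient), kidney effective half-lives around 27/24/23 h for
the three windows (the Fr-221 value strictly below Bi-213 for every kidney,
via a shared patient-level factor), lesion half-lives around 38–39 h with
small per-window jitter, kidney volumes ~247 ml, lesion volumes ~23 ml,
SUVs at 24 h around 3.4/3.2/4.3 (kidneys) and 5.3/4.8/5.8 (lesions),
between-subject CVs of 20–25%, and urine Bi/Ac ratios drawn around 0.98
(~24 h) and 1.08 (~48 h) on the measured per-patient Ac concentrations.
Images default to 128³ voxels of 4.7952 mm with a 15-mm system blur, a
per-window calibration factor and Poisson counting noise scaled by an
effective counting time; the calibration phantom is a uniform 524 Bq/ml,
25.5-cm/8.7-l cylinder (4.56 MBq). Urine series default to 0.25-h bins over
8 h with efficiency 0.25 counts/decay; expected counts use the exact bin
integral of the forward model.

What the generator does *not* emulate: projection-domain physics (collimator
response, attenuation, scatter and down-scatter between windows,
reconstruction artifacts), organ shape realism, intra-organ heterogeneity,
patient motion, and background structures near lesions. Passing tests
therefore demonstrate the correctness of the quantification–kinetics–
dosimetry chain given faithfully reconstructed images, not the accuracy of
any particular reconstruction.

```{r, eval = FALSE}
sc  <- cohort_scenario(seed = 1)
res <- run_pipeline(study_config(sc, out_dir = "report"))
res$urine_summary
```

## Numerical choices and problem sizes

* Internal time unit: hours; all half-lives converted on ingestion. The
  Ac-225 half-life (9.92 d) and all chain constants live in an editable
  packaged CSV with a reference column, so nuclear-data updates need no code
  change.
* Gaussian filtering is an FFT (circular) convolution with a grid-sampled
  kernel normalized to DC gain 1; total counts are conserved exactly, and
  wrap-around is negligible for interior-supported images.
* Isocontour threshold is inclusive (≥); ties for the maximum are broken by
  array scan order with a warning.
* S-value tables interpolate log-log in mass (self-absorbed S scales ~1/m).
* The test suite runs the imaging pipeline on 48³ grids with two patients —
  the package's own choice of test scale; the full 128³ five-patient default
  behaves identically and is exercised by the same code paths. Monte-Carlo
  properties use 500 seeded replicates (coverage, bias), 2000 for the
  Wilcoxon type-I check.
* Time-to-equilibrium has no canonical "reached" threshold; the residual
  transient fraction is an explicit parameter (0.003 reproduces the ~6.3 h
  figure often quoted for this chain).

## Known limitations

No recovery/partial-volume correction (deliberate); self-dose only (no
photon/beta crossfire between organs); mono-exponential kinetics with
integration from t = 0; NIfTI-only I/O; integer-voxel mask shifts in place
of true registration; RBE treated as a constant multiplier without dose
dependence.
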