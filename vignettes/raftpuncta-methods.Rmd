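---
title: "Methods: models, estimators and design choices in raftpuncta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in raftpuncta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

`raftpuncta` implements the quantitative assays used to test whether a
membrane protein's lipid-raft targeting depends on a GPI anchor. The question
is answered with several independent lines of evidence — punctum statistics on
surface-labelling images, model predictions of what anchor cleavage should do
to those puncta, whole-cell current fitting, a motif scan of candidate
C-termini, and raft-fraction quantification of sucrose gradients — and the
package provides each line as a tested computation over a synthetic-data
generator with known ground truth. The `analysis/` scripts present the
pipeline as a narrative workflow; everything they do is a call into the
package.

## Punctum statistics

Particles are connected components (default 8-connectivity, exposed as a
flag) of a thresholded image, with area equal to pixel count. Two summaries
drive the biology:

* **Size distribution**: counts `Np_i` of particles per area bin, expressed
  as a percentage of the total count `N_t`, so cells with different absolute
  punctum numbers overlay.
* **Fractional coverage**: `f_i = Np_i * Ap_i / C_t`, the share of total
  particulate area `C_t = sum(Ap)` contributed by each size class. This
  separates "many small puncta" from "few large puncta" even when count
  distributions look similar.

Default bins are unit-width (1 px²) up to the largest particle. Under
binning, the representative area `Ap_i` is the *mean area of the bin's
members* rather than the arithmetic midpoint: the two coincide for unit bins,
and the mean-area choice keeps `sum(f_i) = 1` at machine precision for any
binning, which we treat as the defining invariant of the quantity. Empty
bins fall back to the midpoint (their `f_i` is zero regardless).

Thresholding is either a fixed global level or an adaptive local mean
(square window, odd width, default 15 px) minus an offset; the adaptive
kernel is deliberately simple and is cross-checked against a brute-force
local mean in the tests. Signal-to-background uses arithmetic means of raw
(non-background-subtracted) intensities over on-cell and off-cell ROIs
(a median variant exists but is not the default); `(S/B) - 1` is the
background-referenced intensity compared across treatment groups, and
`percent_of_control` reports `100 * mean(treated)/mean(control)`, rounded to
integer percent only at the reporting layer.

Group comparisons use Student's pooled-variance t-test for two groups and
one-way ANOVA with a Student–Newman–Keuls (SNK) step-down on studentized
ranges (via `ptukey`) for more, at alpha = 0.05; ties in group means are
broken by group label order, which only affects the step-down ordering.

## Synthetic punctate images

The generator emulates the structure of the real data — many small,
high-intensity surface puncta over low interstitial signal — not any specific
acquisition. Particles get integer pixel² areas (lognormal by default,
mean 20 px², sdlog 0.4), uniform positions with a hard-core minimum
separation (rejection sampling, budget 100·n attempts, error beyond it), and
are rasterised as the `area` pixels nearest their centroid at their peak
intensity. Rendering then applies a normalised Gaussian PSF (so integrated
intensity is preserved), a constant background, and optionally Poisson shot
noise plus Gaussian read noise — the standard fluorescence camera model. The
acquisition noise of the original experiments is unknown, so noise levels are
free parameters; defaults (background 100, peak 800, read noise 5) give
SNR ≈ 20.

**Detection calibration.** The PSF attenuates the central amplitude of a
small rasterised disc by `1 - exp(-r²/2σ²)`; at the default area range and
σ = 1 px, the half-maximum contour of a blurred punctum sits near 0.4 of the
nominal peak rather than 0.5. The round-trip analyses therefore threshold at
`background + 0.4 × peak`, a calibration recorded in the image metadata. With
separation > 4σ and SNR > 10 this recovers the exact particle count and total
area within a few percent; the tests assert count exactness and a 10% area
bound. Passing these tests shows the estimator chain is self-consistent on
well-separated Gaussian-blob puncta; it does not certify performance on
confluent or strongly aberrated real imagery.

## Redistribution models

Anchor cleavage could in principle "strip" puncta (shrink every particle),
"disassemble" them (fragment at conserved total area), or both. The package
models these as distribution transforms:

* **Binomial family curves**: expected counts proportional to `p⁴`,
  `6p²q²` or `q⁴` with `q = 1 - p`, evaluated along the area axis. The
  mapping between area and `p` is not dictated by the source material, so we
  fix the simplest choice, `p = Ap / Ap'` (linear onto (0, 1]); this is the
  module's single largest interpretive choice and is recorded in the output
  attributes. The count scale is then solved so `sum(Np_i · Ap_i)` equals a
  target `C_t` (default 1×10⁵ px²) — the normalisation constraint that makes
  the three curves comparable. Curves are expected counts by default; a
  seeded Poisson-sampling mode supports stochastic tests.
* **Stripping** multiplies every area by a factor (default 0.5) with `N_t`
  held constant; **disassembly** splits each particle into `m` fragments
  whose areas sum *exactly* to the parent (the last fragment takes the
  floating-point remainder), placed tangentially around the parent centroid
  (geometric bookkeeping only — spatial statistics are out of scope).
* **Comparison**: observed-after is compared against observed-before and a
  predicted-after on a common grid by L1 distance on normalised counts and on
  coverage (mean of the two; L1 is exact on binned data, a KS statistic is
  available secondarily). The verdict is "no effect" when the observation is
  closer to before than to the prediction. On 500-particle populations this
  call is essentially always correct under the null, which the tests verify
  over 100 seeded replicates.

## Current-voltage and kinetic fitting

Per-cell current density–voltage families follow
`I(V) = g (V − V_rev) / (1 + exp((V_50 − V)/k))` — a Boltzmann activation
gate (slope `k > 0`, activation grows with depolarisation) times the linear
driving force. Inward currents are negative; `Imax` is reported as the signed
extremum of the fitted curve over the protocol range (−30 to +65 mV in 5 mV
steps by default), with magnitudes used for fold changes. Fitting is
Levenberg–Marquardt least squares with a deterministic, protocol-aware
initialisation: `V_rev` from the interpolated zero-crossing beyond the peak,
`V_50` at half-extremal current, `k = 5` mV, and `g` from the driving-force
slope at the measured peak (robust where the last two protocol points are
noise-dominated). Zero-noise generator data are inverted to 1×10⁻⁶ relative;
at 5% noise with 10 cells the V50 bias stays below 0.5 mV and the g bias
below 2% over 200 replicates (asserted in tests).

The preset group pair encodes the canonical auxiliary-subunit contrast — a
4.0-fold `|Imax|` enhancement and a −13 mV `V_50` shift — by solving the
conductances so the configured ratio is exact; recovery of that contrast from
noisy simulated groups is the module's end-to-end check.

Current traces follow
`I(t) = A (1 − exp(−t/τ_act)) · exp(−t/τ_inact)`, whose noiseless peak is at
`t = τ_act · ln(1 + τ_inact/τ_act)`. Each phase is fitted with a single
exponential: the decay (peak to end) directly, and the activation phase after
dividing the fitted decay out of the trace — without this compensation the
product form biases `τ_act` upward by roughly the peak-time/τ_inact ratio.
The first 1 ms (capacitive transient, configurable) is excluded. Fit windows
are returned with every fit.

## GPI-motif rule engine

The scanner implements the four canonical motif elements as explicit rules:
(a) a small ω residue (G, C, D, A, N, S); (b) small residues (G, A, S) at
ω+1..2; (c) a hydrophilic spacer — strictly more than 6 residues with
Kyte–Doolittle hydropathy < 0 within some 7–12 residue window starting at
ω+3; (d) a C-terminal hydrophobic stretch — a terminal run of ≥ 8 residues
with mean hydropathy ≥ +1.5, evaluated only within the region downstream of
ω+2 so a candidate cannot borrow upstream hydrophobicity. No hydropathy
scale or cutoffs are canonical for this rule set; Kyte–Doolittle with these
values is exposed as configuration and logged. The composite score is the
mean of the four component scores (each capped at 1), but classification
additionally gates on *all* components passing, so partial matches cannot
inflate a call. Candidates are searched within 40 residues of the C-terminus
by default (cryptic internal motifs are rare; internal scanning is available
by widening the window). Residue numbering is 1-based on the full-length
polypeptide. Where several candidates pass, all are scored and the best is
reported rather than adjudicating between near-adjacent ω assignments.

The truncation scan removes one C-terminal residue at a time and re-runs the
full search on each truncated sequence — by construction each step equals an
independent rescan, which the tests assert — so anchoring potential collapses
within a few steps of the hydrophobic tail being clipped. This engine is a
transparent surrogate for dedicated predictors (profile-, NN- or HMM-based);
it reproduces qualitative anchored/not-anchored contrasts of designed
constructs, and its specificity on random 100-mers is below 5%, but it does
not reproduce any published predictor's numeric scores.

## Gradient quantification

Profiles are 15 fractions, top (buoyant) to bottom. The raft fraction is the
share of total signal in the designated raft fractions (default 3–6, the
buoyant 5–30% sucrose interface; configurable since gradient geometry
varies), making it invariant to loading differences. A treatment "shift" is
called when the raft fraction drops by ≥ 50% relative (default).

The generator mixes two discretised Gaussians over the fraction index,
normalised to unit mass over 1..15 and weighted `raft_weight : 1 −
raft_weight`. The peak width default (0.7 fraction units) keeps > 99% of each
peak's mass inside its 4-fraction window, matching sharply peaked blot
profiles and making the noiseless round trip exact to within 1% of
discretisation leakage. Noise is Gaussian with a signal-dependent scale
(`sd_i = sd_peak · sqrt(s_i / s_peak)`), the shot-noise-like behaviour of
densitometry: additive homoscedastic noise clamped at zero would rectify the
empty fractions upward and bias the raft fraction down by several percent at
high raft weights, which is an artefact of the noise model rather than of the
estimator.

## Reproducibility and problem sizes

Every generator takes an integer seed and is bit-reproducible under it;
multi-stage fixtures derive sub-seeds as documented offsets from one
top-level seed. The test suite and `scripts/acceptance.R` use deliberately
modest problem sizes — 200-particle images on 768² frames, 10 cells per
group with 200 replicate simulations for bias estimates, 100 replicates for
verdict rates, 1,000 random sequences for specificity — chosen so the whole
suite runs in well under a minute while keeping Monte-Carlo error far from
the asserted bounds.

## Limitations

The synthetic generator emulates statistical structure, not optics: no 3-D
stacks, aberrations, deconvolution artefacts, or confluent labelling (where
particle analysis is inapplicable and contour/box-scan displays are the
fallback, as implemented). The redistribution model's area↔p mapping is an
interpretive choice; conclusions that depend on the exact shape of the
binomial curves (rather than the `C_t` normalisation and the coverage
contrast between terms) should not be drawn. The motif engine is qualitative.
Real gradient and blot data carry background and loading artefacts that the
per-lane normalisation here only partially addresses.
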