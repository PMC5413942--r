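---
title: "Models and methods behind the tonbpull pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the tonbpull pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonbpull)
```

## The experiment this package analyses

TonB-dependent transporters (TBDTs) are 22-strand outer-membrane
beta-barrels whose lumen is blocked by an N-terminal plug domain. Transport
requires the periplasmic protein TonB, which binds the plug's Ton box and —
under the prevailing mechanical models — pulls on it, unfolding part of the
plug to open a substrate channel. The decisive observable is single-molecule
force spectroscopy: an AFM tip carrying TonB is pressed onto a surface
presenting the transporter (or a Ton-box peptide), retracted at constant
velocity, and the resulting force-extension trace records the stretching of
the PEG tethers and protein followed by one or more abrupt force drops —
unfolding of a plug subdomain and, finally, dissociation of the TonB-Ton box
complex. The amount of polypeptide released between ruptures, read from
worm-like-chain fits, converts directly into a count of unfolded residues at
0.4 nm per stretched amino acid.

`tonbpull` implements that analysis chain as composable, tested functions:
preprocessing, event detection, WLC fitting, acceptance filtering,
contour-length-increment statistics, dynamic force spectra, and the
companion microscale-thermophoresis (MST) affinity fit. Because no raw
instrument traces are distributed, a seeded Monte-Carlo generator stands in
for the instrument and provides ground truth for every stage.

## Polymer model

Rising edges are described by the Marko-Siggia interpolation of the
worm-like chain,

$$F(x) = \frac{k_B T}{p}\left[\frac{1}{4}\left(1-\frac{x}{L_c}\right)^{-2}
  - \frac{1}{4} + \frac{x}{L_c}\right],$$

with persistence length $p$ held fixed at 0.4 nm (the conventional value
for polypeptide/PEG tethers at these forces) and contour length $L_c$ the
single free mechanical parameter per edge. `wlc_stiffness()` is its exact
derivative; the loading rate of an event is that slope at rupture times the
retraction velocity. The inverse map `wlc_extension()` is solved by
safeguarded bisection on the bracket $[0, L_c(1-10^{-12})]$ to a relative
tolerance of $10^{-9}$; forward/inverse round trips are tested over
0.1-500 pN. $k_B$ is fixed at 0.0138065 pN nm K$^{-1}$ and the default
temperature is 298 K (the experiments ran at 25 °C), giving
$k_BT = 4.114$ pN nm.

Contour-length bookkeeping is additive: the PEG24 linker pair contributes
19 nm, the folded TonB-Ton box complex 5.5 nm, and unstructured polypeptide
0.4 nm per residue. `length_to_residues()` rounds half away from zero;
reported residue counts in the literature are not always consistent with a
single convention, so the rounding rule is an explicit argument.

## From instrument frame to events

`convert_to_force_separation()` zeroes each retraction in two steps: the
force baseline is the mean over the trailing 20% of samples (the probe is
far from the surface at the end of a retraction), and zero separation is
the zero-force intercept of a line fitted through the steepest 25% of the
repulsive contact wall. Separation is piezo travel minus cantilever
bending. No smoothing is applied to the stored channels; the published
analysis does not state any, and detection does its own smoothing
internally. Curves without a detectable wall (empty traces, pre-zeroed
input) keep a zero contact offset and are flagged, which also makes the
conversion idempotent.

Detection looks for sharp negative transitions in the Savitzky-Golay
smoothed force (window 11 samples, order 2): any fall exceeding the
threshold within 6 samples marks a candidate, and the rupture sample is
refined to the largest single-step drop of the raw channel near the
smoothed cliff. The threshold is the larger of 20 pN and 3 robust noise
sigmas (MAD of the residual around the smooth). The 20 pN floor is not a
published number; it is chosen so that a flat trace at the generator's
5 pN noise never triggers, and it implies that genuinely weak ruptures
(force drops under ~20 pN) are invisible — exactly as they are to the
thresholded analysis of real data.

Each candidate's rising edge — from the previous event or the last
baseline crossing, ties broken toward the longer window — is fitted by
least squares with $p$ fixed, using one-dimensional minimisation over
$L_c$ (the profile is unimodal, so `optimize()` on the bracket
$(x_{max}, \max(500, 3x_{max}))$ nm is sufficient and cannot diverge).
The rupture force is read from the raw force at the last pre-rupture
sample rather than from the fitted curve, matching standard per-trace
practice. Edges shorter than 8 samples are flagged unfittable.

Filters mirror the experimental binning rules, each with a recorded
reason: ruptures below 10 nm separation are non-specific tip-sample
adhesion; fitted $L_c \le 19$ nm cannot contain the complex beyond the
PEG pair; edges whose WLC fit does not beat a straight line by at least
0.01 in $R^2$, or sampled only below 20% fractional extension, are
"linear" profiles; RMS residuals above 15 pN are poor fits. Filtering is
total — accepted plus rejected equals detected — and that conservation is
asserted in the tests.

## Ensemble statistics

Modal values are estimated the way the field reports them: histogram at a
stated bin width (10 pN for force, 2 nm for contour lengths and their
increments; only the scatterplot bins 5 nm x 10 pN are published values),
then a single-Gaussian least-squares fit to the bin counts, mode = fitted
mean. The histogram is padded with one empty bin on each flank so that
very tight distributions (fewer occupied bins than Gaussian parameters)
still pose a well-conditioned three-parameter fit. The estimator is
checked to be unbiased within half a bin on symmetric samples at
$n = 10^4$.

$\Delta L_c$ is computed **per curve** — differences of successive fitted
contour lengths within one trace — and the distribution of those per-curve
differences is then fitted. It is *not* the difference of ensemble modal
$L_c$ values; the two disagree in general, and only per-curve differencing
measures how much one molecule unfolded. Records with fewer than two
accepted events or non-increasing contour lengths are skipped with a
message. Replicate experiments aggregate as mean of modes plus/minus half
the range, not a standard error.

The specificity diagnostic bins $(L_c, F_U)$ pairs on the 5 nm x 10 pN
grid and reports hotspots: 8-connected clusters of bins whose count
exceeds 5x the median occupied-bin density. The factor 5 is configurable;
at that default a uniform cloud of a few thousand points produces no
hotspots while a reproducible interaction of ~100 events concentrates
tens of counts in one or two bins.

Dynamic force spectra regress the per-velocity modal rupture force on the
mean natural log of per-event loading rates (the published analysis does
not state its averaging; the mean of logs is used). Under the Bell-Evans
model the modal force is
$F^* = (k_BT/x_\beta)\,\ln\!\left(x_\beta r / (k_0 k_B T)\right)$, so the
regression slope gives $x_\beta = k_BT/\mathrm{slope}$ and the intercept
gives $k_0$. The published analysis stops at the linear regression; the
kinetic-parameter extraction is a standard extension, and both raw
coefficients and derived parameters are reported. A non-positive slope
aborts the fit: it signals non-Bell behaviour rather than a parameter set.

## MST binding model

The titration fit uses the exact 1:1 law of mass action with depletion of
the labelled species,

$$F_B = \frac{A + L + K_D - \sqrt{(A+L+K_D)^2 - 4AL}}{2A},$$

evaluated in its conjugate form for numerical stability at small $A$, and
a linear two-state signal $F_{norm} = F_u + F_B (F_b - F_u)$. The physical
components of the thermophoresis signal (temperature-jump sensitivity,
$\Delta T$, Soret coefficient) are not separately identifiable from a
titration, so the fit estimates composite bound/unbound amplitudes — the
same parametrisation instrument software effectively uses. $K_D$ is
optimised on the log10 scale with the half-amplitude concentration as the
start; least squares is unweighted (the vendor loss function is unknown);
the confidence interval is a seeded 200-resample residual bootstrap. A
series whose amplitude is within 4 robust noise sigmas of flat is rejected
outright, and a titration spanning less than a decade either side of the
fitted $K_D$ warns.

A note on attainable precision: for the reference design (16 two-fold
dilutions, 7 nM-244 uM, label 250 nM, noise 2% of amplitude) the
Cramer-Rao bound puts the relative standard deviation of any unbiased
$K_D$ estimator near 7%. Single-series fits at this noise are therefore
expected to scatter by several percent around truth; the noiseless
parameter-recovery sweep (0.1-100 uM) verifies the estimator itself to
optimizer tolerance.

## What the generator emulates — and what it does not

`simulate_pull()` advances the piezo at constant velocity and solves the
series force balance $z = F/k_c + x_{wlc}(F; L_c)$ in closed form: the
balance is parametrised by extension, $z(x) = x + F(x)/k_c$, sampled on a
dense grid and inverted by monotone interpolation, rebuilt whenever the
contour length changes. Geometry closure (piezo = bending + extension) is
asserted in the tests to 0.1 nm. Rupturable elements carry Bell hazards
$k_0 e^{F x_\beta / k_BT}$; rupture times come from inverse sampling of
the cumulative hazard along the force trajectory, which is exact for the
discretised trajectory and independent of any per-step probability
approximation. Unfolding adds the released residues to the contour length
(the force relaxes accordingly); unbinding zeroes the force. Gaussian
noise (default sigma 5 pN — the instrument noise is not published, so
this is an explicit assumption), a configurable force baseline offset, a
piezo contact offset and a repulsive contact wall complete the raw trace,
so preprocessing is exercised end to end.

Scenario presets encode the constructs studied: wild-type (weak plug
subdomain releasing 50 residues before unbinding), XL_barrel (unfolding
disabled by a plug-to-barrel crosslink), XL_loop (a covalent 15-residue
loop shortens the release to 35 residues), 3A (a destabilised strong
subdomain adds a second, 64-residue unfolding), and an adhesion-only
binding-deficient control. The base contour length at the first rupture is
set to 58 nm (linker pair 19 + complex 5.5 + a 33.5 nm force-resistant,
partially extended linker conformation), so simulated double ruptures sit
near 58 and 78 nm — the bookkeeping is additive in exactly the published
terms. Default kinetics (unbinding $k_0 = 0.1$ s$^{-1}$,
$x_\beta = 0.35$ nm; weak-subdomain unfolding $k_0 = 1$ s$^{-1}$,
$x_\beta = 0.5$ nm; destabilised subdomain $k_0 = 0.5$ s$^{-1}$,
$x_\beta = 0.4$ nm) were chosen once so that the modal unfolding force
stays below the modal unbinding force at the experimental ~10^4 pN/s —
the observed mechanical hierarchy — and are generator conveniences, not
measured quantities.

The generator deliberately omits several features of real data: PEG's
helix-to-coil two-state elasticity (linkers are lumped into a single
effective WLC), refolding between ruptures, instrument drift and 1/f
noise, attachment-geometry heterogeneity (which broadens real $L_c$
distributions well beyond fit noise), and multiple simultaneous tethers.
Passing recovery tests therefore demonstrates correctness of the analysis
chain under the stated stochastic model — not that the pipeline conquers
every artefact of a live instrument. The published modal forces and
contour lengths for membrane-reconstituted transporters are reproduced
only in the sense of these recovery properties, since no raw curves are
deposited.

PEG linkers are modelled at 25 kHz sampling; at 1000 nm/s that is one
sample per 0.04 nm, and the hazard per sample stays well below unity at
modal forces, so rupture-time quantisation is negligible against the 2 nm
analysis bins.

## Problem sizes and reproducibility

The default study sizes — 200 wild-type curves for the delta-Lc round
trip, 150 per crosslink scenario, 600 cycles for the hit-rate check at the
7.5% specific fraction, 500 ruptures per velocity at four loading rates
for the Bell-Evans recovery, and single 16-point titrations — were chosen
as the package's own balance between Monte-Carlo error and runtime on a
laptop; all are parameters, not constants. Every stochastic path takes an
explicit integer seed, and both the map generator and the bootstrap are
bit-reproducible under it (asserted in the tests). All tunables surface in
`run_config()`, whose defaults equal the published values where one exists
(0.4 nm persistence length, 19 nm linker pair, 10 nm adhesion cutoff,
5 nm x 10 pN scatter bins); every run writes its resolved configuration
and a provenance block beside its outputs.

## Known limitations

* Single-Gaussian modal fits by design: bimodal pools (e.g. pooled
  unfolding + unbinding forces) should be split upstream, as the
  per-event-type grouping does, rather than fitted with mixtures.
* The detector cannot see force drops below its threshold; curves whose
  unfolding occurred at very low force are classified single-event and
  excluded from delta-Lc, a selection shared with the thresholded manual
  analysis of real traces.
* Vendor binary formats are out of scope; the TSV dialect plus a
  converter hook is the supported ingestion path.
* The Bell-Evans extraction assumes a single barrier and constant
  effective loading rate per event; no Dudko-Hummer-Szabo style
  reconstruction is attempted.
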