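# tonbpull

Single-molecule force spectroscopy analysis of TonB-dependent transporter
(TBDT) gating, plus the companion microscale-thermophoresis (MST) affinity
fit and a seeded Monte-Carlo instrument simulator.

## The scientific problem

TonB-dependent transporters are 22-strand outer-membrane β-barrels whose
lumen is occluded by an N-terminal plug domain. TonB binds the plug's Ton
box and is thought to mechanically remodel the plug to open a substrate
channel. AFM force spectroscopy probes this directly: a TonB-derivatized
tip is retracted at constant velocity from a surface carrying the
transporter, and each tether stretch/rupture cycle leaves a saw-tooth
force–extension trace. Fitting every rising edge with a worm-like chain
(WLC) gives the contour length *L*<sub>c</sub> of the stretched structure
at each rupture; the per-curve increment Δ*L*<sub>c</sub> between
successive ruptures converts into the number of residues unfolded before
the complex dissociates (0.4 nm per stretched amino acid).

This package is for force-spectroscopy practitioners who want that whole
chain — preprocessing, event detection, WLC fitting, acceptance filtering,
modal statistics, dynamic force spectra, binding fits — as reproducible,
composable, tested R functions rather than interactive vendor tooling.

## The models at the core

* **WLC (Marko–Siggia) elasticity**
  *F*(x) = (*k*<sub>B</sub>*T*/*p*) [¼(1 − *x*/*L*<sub>c</sub>)<sup>−2</sup> − ¼ + *x*/*L*<sub>c</sub>],
  with *p* fixed at 0.4 nm and *L*<sub>c</sub> the only free mechanical
  parameter per rupture edge; the loading rate is the WLC slope at rupture
  times the retraction velocity.
* **Bell–Evans kinetics** *k*(F) = *k*<sub>0</sub> exp(*F x*<sub>β</sub>/*k*<sub>B</sub>*T*):
  modal rupture force is linear in ln(loading rate), with slope
  *k*<sub>B</sub>*T*/*x*<sub>β</sub>; the simulator draws rupture times from
  these hazards, and `fit_bell_evans()` inverts the regression into
  (*x*<sub>β</sub>, *k*<sub>0</sub>).
* **1:1 law of mass action with depletion** for MST titrations:
  F<sub>B</sub> = (A + L + K<sub>D</sub> − √((A+L+K<sub>D</sub>)² − 4AL))/(2A),
  fitted to normalized fluorescence against log₁₀ titrant concentration.

## Worked example

Simulate a wild-type pulling experiment (double-rupture curves whose weak
plug subdomain releases 50 residues), run the full analysis, and read off
how much of the plug unfolded:

```r
library(tonbpull)

ds  <- simulate_map(pulling_config(), "wild-type", n_curves = 200,
                    fractions = c(specific = 1, adhesion = 0), seed = 42)
rep <- run_analyze(ds)
#> analyze: 200 curves -> 351 detected events -> 349 accepted (hit rate 99.0%)
#> analyze: rejections - linear_profile: 2
#> compute_delta_lc: skipped 47 curve(s) with < 2 usable events or non-increasing Lc.

rep$modes$dLc1
#> <gaussian_mode_fit> mode = 20, sigma = 0.502 (n = 151, bin = 2)
length_to_residues(rep$modes$dLc1$mode)
#> [1] 50
```

The modal contour-length increment of 20 nm is the Gaussian-fitted mode of
151 per-curve Δ*L*<sub>c</sub> records; at 0.4 nm per residue it means 50
amino acids of the plug unfolded before the TonB–Ton box complex
dissociated. Curves skipped in `compute_delta_lc()` had only one
detectable rupture (an unfolding too weak to clear the 20 pN detection
threshold), as in thresholded analysis of real traces.

The MST side, with the reference 16-point serial dilution (7 nM–244 µM,
labelled species 250 nM) and 2%-of-amplitude noise:

```r
ts  <- simulate_mst(9.4e-6, seed = 1)
fit <- fit_kd(ts)
fit
#> <binding_fit> KD = 8.96e-06 M (95% CI 8.13e-06-1.02e-05), amplitude 800 -> 850, rms 0.934
glance(fit)
#> # A tibble: 1 x 4
#>         KD_M KD_uM residual_rms     n
#> 1 0.00000896  8.96        0.934    16
```

The fitted K<sub>D</sub> of 9.0 µM recovers the generating 9.4 µM within
the precision a single 16-point series supports (see the methods
vignette). Replicate modes aggregate the way experiments are reported,
mean ± half-range: `aggregate_replicates(c(19.2, 20.0, 20.4))` gives
19.9 ± 0.6 nm.

`autoplot()` methods exist for processed curves, modal fits, density
scatters (with hotspot markers), dynamic force spectra and binding fits;
`tidy()`/`glance()` methods cover the fitted objects. A thin command-line
wrapper over the same functions lives at `inst/cli/tonbpull.R`
(subcommands `simulate`, `analyze`, `mstfit`, `dfs`).

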