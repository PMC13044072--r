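---
title: "Geometric band schemes: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric band schemes: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geobands)
```

## The model

A band scheme is generated by two parameters. Centers follow the exponential
law $f_n = f_{\mathrm{ref}} \cdot R^n$ with integer band index $n$, and the
boundary between adjacent bands is the geometric mean
$f_{\mathrm{sep}} = \sqrt{f_n f_{n+1}}$, i.e. the arithmetic midpoint of the
centers on a log-frequency axis. Because both rules are multiplicative, the
whole construction is scale-equivariant: rescaling $f_{\mathrm{ref}}$ by $s$
rescales every center and boundary by $s$ (this is a tested invariant). The
inverse map $n = \log_R(f/f_{\mathrm{ref}})$ places any frequency on the
continuous index axis; integers land on centers, half-integers on
boundaries.

The model asserts nothing about the biology at the boundaries — it is a
segmentation rule. Its appeal is that a single ratio generates a complete,
non-overlapping tessellation, in contrast to committee-defined cutoffs that
vary across guidelines.

## Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| `f_ref` | 10.5 | Hz | population mean of the adult dominant alpha rhythm; also near the log-center of the 0.5–100 Hz analysis span scaled by the golden ratio (`golden_ratio_reference(0.5, 100)` ≈ 11.4 Hz) |
| `R` | 1.7275 | — | Blagg's constant exponential spacing ratio, replacing the coarse doubling of the classical Titius–Bode progression |
| `n_min`, `n_max` | −2, +3 | — | spans delta through gamma2; widen `n_max` to 4 for a gamma3 extrapolation into the high-frequency-oscillation range |
| `subdivide_alpha` | `TRUE` | — | splits the $n=0$ band at `f_ref` into alpha1 (idling-associated lower alpha) and alpha2 (processing-associated upper alpha) |

With these defaults the full-precision centers are 3.5185, 6.0781, 10.5,
18.1388, 31.3347 and 54.1307 Hz and the boundaries 4.6245, 7.9888, 10.5,
13.8006, 23.8406 and 41.1846 Hz.

## Two precision modes

The engine always computes at full floating precision. A second mode,
`tbb_scheme("tabulated")`, builds the scheme on the conventional two-decimal
center tabulation (3.52, 6.07, 10.50, 18.14, 31.35, 54.21 Hz), stored as the
constant `tbb_tabulated_centers`. The two modes exist because the familiar
two-decimal boundary values (4.62, 7.98, 13.81, 23.85, 41.22 Hz) are only
reproducible from that tabulation, and the tabulation itself cannot be
derived by rounding the full-precision centers: three of its entries (6.07,
31.35, 54.21) differ from exact rounding (6.08, 31.33, 54.13). The
discrepancy matters for the headline alignment figure below, so both modes
are first-class rather than display options.

## Interval convention and open ends

Bands are lower-closed/upper-open, $[\mathrm{lower}, \mathrm{upper})$: a
frequency equal to a shared boundary belongs to the upper band, so 10.5 Hz
classifies as alpha2. This is the standard half-open tessellation; any
convention would do, but this one is deterministic and makes the
tessellation property ("every positive frequency in exactly one band")
exact. The lowest band is open below and the highest open above; the open
limits are represented by the sentinels 0 and `Inf` and serialized as `null`
in JSON. Band-power integration truncates open bands at the PSD grid limits.

## Alignment metrics

`schumann_alignment()` reports, for each environmental reference mode, the
nearest scheme feature (any center or closed boundary) and the percent
deviation $100\,|f_{\mathrm{feature}} - f_{\mathrm{mode}}|/f_{\mathrm{mode}}$.
The denominator is the mode frequency, matching the usual "x% below the
fundamental" phrasing; the metric is descriptive, and the package makes no
claim of coupling or entrainment. The default mode list is 7.83 Hz plus
harmonics at 14.1, 20.3, 26.0 and 33.0 Hz; the harmonics are quoted in the
literature both as rounded integers (~14, ~20) and with decimals (14.1,
20.3), so the list is an argument, not a constant.

The theta–alpha boundary versus the first mode is reported as a named
headline. At full precision the deviation is 2.028%; on the tabulated
centers it is 1.959% (boundary $\sqrt{6.07 \times 10.5} = 7.983$ Hz). The
often-quoted "below 2%" figure therefore holds for the tabulated scheme, not
for the full-precision one — one reason both modes are exposed. The
classical comparator (`classical_tb_centers`, multipliers $0.4 + 0.3
\cdot 2^m$ with alpha anchored at $m = 1$ so that theta takes multiplier 0.7
and delta the limiting 0.4) gives a theta *center* of 7.35 Hz, 6.1% below
the fundamental. The multiplier-to-band assignment is the unique natural one
reproducing that value; the classical progression has no geometric boundary
rule, so it participates in center comparisons only.

## IAF estimation and re-anchoring

`estimate_iaf()` removes the aperiodic component by a straight-line
least-squares fit of log-power on log-frequency over the full PSD support —
the simplest 1/f model, deliberately without a knee term; it is adequate for
fixture-scale spectra and documented as replaceable. The most prominent
residual local maximum within the search window (default 7–14 Hz, bracketing
both the classical alpha range and the scheme's alpha1/alpha2 span) is the
IAF. Prominence is the standard topographic definition. Equally prominent
peaks (within 1e−9 log-units, absorbing floating-point asymmetries) resolve
to the lower frequency, for determinism. If no residual maximum rises above
the fitted baseline inside the window, a classed `geobands_no_peak` error is
raised — never a silent default.

Peak frequencies are refined to sub-bin precision by quadratic interpolation
through the three samples around each maximum in log-frequency coordinates
(a Gaussian peak is locally parabolic there); the vertex is clamped to the
neighbor interval so refinement can never move a peak by more than one bin.

Two distinct responses to an individual anchor are exposed, since either is
defensible: `reanchor()` moves `f_ref` only, keeping the ratio $R$ fixed (the
scheme as a rigid template sliding along the log axis), while
`estimate_geometric_ratio()` refits both $R$ and $f_{\mathrm{ref}}$ from
observed peaks (the scheme as a family). Neither is asserted to be the
canonical interpretation.

## The ratio-conformity fit

Given $k \ge 2$ distinct peak frequencies, each trial anchor from a grid of
64 log-spaced candidates between $\min(f)/R_{\mathrm{init}}$ and $\max(f)$
assigns every peak the integer index nearest $\log_{R_\mathrm{init}}(f /
f_{\mathrm{cand}})$. For each distinct assignment, $\log f = \log
f_{\mathrm{ref}} + n \log R$ is fit by ordinary least squares; the
assignment minimizing the RMS log-residual wins, and $\hat R$ is the
exponential of the slope. The candidate count 64 is a fixed, documented
constant — the search is bounded and deterministic. The index origin is not
identifiable (shifting all indices by 1 rescales $\hat f_{\mathrm{ref}}$ by
$R$), which is irrelevant for $\hat R$ and the residual. The RMS
log-residual is the conformity measure: ~0 for an exact geometric
progression, visibly larger for, e.g., an arithmetic one. This is one
concrete realization of "conformity to the geometric template", not a
canonical definition.

## Synthetic fixtures

`synth_spec()`/`synth_psd()` emulate the gross structure of a resting EEG
power spectrum: an aperiodic power-law background
$A f^{-\beta}$, Gaussian oscillatory peaks, and multiplicative log-normal
observation noise (multiplicative so the PSD stays positive). Defaults were
chosen once as realistic resting-state values: a 1–45 Hz grid at 0.5 Hz
resolution (what a 2-s-segment Welch estimate delivers), $\beta = 1$, peak
sd 1 Hz, noise sd 0.05 log-units. `synth_timeseries()` produces the matching
time series — sinusoids carrying each peak's power integral plus 1/f noise
synthesized by spectral shaping of white noise, which hits the target slope
exactly in expectation. All generation is seed-deterministic
(`withr::with_seed`), a tested contract.

What the fixtures do *not* emulate: multichannel structure, artifacts
(blinks, EMG), non-stationarity, spectral knees, or asymmetric peak shapes.
Passing tests therefore demonstrate correctness of the estimators under the
stated generative model, not performance on recorded EEG.

`welch_psd()` is a standard Hann-windowed averaged periodogram with
one-sided density scaling; its tests check spectral identities (tone
location, white-noise flatness, variance consistency within 10%) rather than
any band-scheme property.

## Numerical choices

- Boundary bins in `band_power()` are split by linear interpolation of the
  PSD at the boundary frequency — exact for trapezoid-consistent (piecewise
  linear) spectra, so band powers conserve the trapezoidal total to 1e−9
  relative, a tested invariant.
- Degenerate inputs fail loudly: empty PSD/scheme overlap, all-equal peak
  sets, windows covered by fewer than 5 samples, Nyquist violations.
- Test problem sizes: tessellation and classification properties use 10^4
  frequencies; parameter-recovery batteries use 100 seeded replicates
  (ratio jitter ±2%, IAF fixtures with SNR 3–8 and $\beta \in [0.5, 2]$);
  time-series fixtures are 8–60 s at 128–256 Hz. The full suite runs in a
  few seconds.

## Limitations

The anchor 10.5 Hz is a population-level idealization; dominant alpha varies
with age and state, which is why IAF re-anchoring is built in. The aperiodic
model has no knee, so very wide-band spectra with a bend will bias the
detrend. The conformity fit assumes peaks sit near integer indices of a
single progression; spectra whose peaks follow no geometric spacing yield a
large residual rather than an error. Nothing in the package tests, or could
test, whether any environmental correspondence is more than numerical
coincidence.
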