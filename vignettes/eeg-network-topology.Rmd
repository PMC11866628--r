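---
title: "From multichannel EEG to global network topology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From multichannel EEG to global network topology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

eegraph analyzes multichannel resting-state EEG as a functional brain
network and tests whether an intervention changed that network's global
topology. This vignette is the package's account of the method: the model at
each stage, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the design choices made where more than one
reasonable option existed.

## The analysis chain

A study consists of 19-channel scalp recordings (10–20 montage, 500 Hz in
the emulated protocol), one `pre` and one `post` resting segment per subject
per condition, where condition crosses `active`/`sham` with stimulation
`side` (`left`/`right`). The chain is:

1. **Cleaning** (`preprocess_recording()`): zero-phase Butterworth bandpass
   1–55 Hz; detection and repair of transient spikes and flat runs; bad-channel
   interpolation from montage neighbors; common-average re-reference;
   ICA-based removal of stereotyped artifact components. The order is fixed —
   re-referencing before component removal, filtering before everything — and
   the orchestrator does not allow reordering.
2. **Connectivity** (`band_connectivity()`): the cleaned series is cut into
   non-overlapping 10-s epochs; cross-spectral densities are estimated per
   epoch with discrete prolate spheroidal (Slepian) tapers and averaged over
   tapers and epochs; the **imaginary part of coherency**
   $\left|\mathrm{Im}\,\frac{S_{xy}}{\sqrt{S_{xx}S_{yy}}}\right|$
   is computed per channel pair and frequency bin, and averaged over bins into
   five band-specific 19×19 adjacency matrices (delta 1–4, theta 4–8, alpha
   8–13, beta 13–30, gamma 30–55 Hz).
3. **Graph topology** (`band_metric_curves()`): each weighted adjacency is
   thresholded at sparsity levels 5%–95% (step 5%), keeping the top-ranked
   edges and binarizing; at every level the global metrics are computed:
   clustering coefficient $C_p$, characteristic path length $L_p$, global and
   local efficiency $E_g$, $E_{loc}$, and the null-normalized indices
   $\gamma = C_p/C_p^{rand}$, $\lambda = L_p/L_p^{rand}$,
   $\sigma = \gamma/\lambda$, with the null ensemble built by
   degree-preserving double-edge-swap rewiring.
4. **Statistics** (`compare_conditions()`): per subject and arm, metrics are
   normalized to their own pre-intervention values,
   $M_{nor} = (M_{post} - M_{pre})/M_{pre}$, and active vs sham normalized
   changes are compared with two-sided paired t-tests per
   (metric, band, sparsity) cell at $p < 0.05$, side-matched (left active vs
   left sham, right active vs right sham). No multiple-comparison correction
   is applied; the map carries raw p-values so any correction can be applied
   downstream, and this is deliberately prominent as a caveat: with
   7 metrics × 5 bands × 19 levels per side, isolated flags are expected by
   chance and only contiguous sparsity ranges should be interpreted.

## Why the imaginary part of coherency

Scalp channels record instantaneous linear mixtures of underlying sources
(volume conduction). Any zero-lag mixture inflates the magnitude and the real
part of coherency, but contributes nothing to its imaginary part: a purely
instantaneous real mixing cannot create a phase lag. Using
$|\mathrm{Im}|$ therefore trades away sensitivity to genuinely zero-lag
physiological coupling for robustness against the dominant scalp-level
confound. Two implementation details:

* Cross-spectral phases equal to 0 (equivalently $2\pi$) within a tolerance
  of 0.01 rad are set to zero explicitly. The tolerance is not given by the
  underlying method description; 0.01 rad is small enough that genuine lagged
  coupling at any realistic lag is untouched.
* The absolute value of the imaginary part is used as the edge weight, since
  rank-based sparsity thresholding needs non-negative weights. A signed
  variant is available (`imaginary_coherence(signed = TRUE)`), and it is the
  signed version whose mean is statistically zero under pure mixing — the
  magnitude has a positive noise floor that shrinks as epochs accumulate
  (roughly like $1/\sqrt{\text{epochs} \times \text{tapers}}$).

## Multitaper parameters

The cross-spectra use a half-bandwidth of $W = 0.5$ Hz by default, i.e. a
time-bandwidth product $NW = 5$ and $2NW - 1 = 9$ tapers for 10-s epochs.
This follows common practice for resting EEG: ±0.5 Hz smoothing is narrow
enough to keep delta separate from theta, and 9 tapers × 42 epochs gives a
stable estimate. The tapers are computed from the classical symmetric
tridiagonal eigenproblem; for epochs longer than 1024 samples they are
computed at 1024 points and spline-interpolated, then re-orthonormalized.
The interpolation error for the smooth low-order tapers is orders of
magnitude below the estimator's own sampling noise.

Band edges are half-open $[low, high)$ at 4, 8, 13 and 30 Hz so no bin is
counted in two bands. Imaginary coherence is computed per bin and then
averaged over the band's bins (not computed from band-averaged
cross-spectra): bin-wise averaging is the reading most consistent with
"frequency-dependent values grouped into bands", and it commutes with the
magnitude operation we need for non-negative weights.

## Thresholding and metric conventions

* Edge count at sparsity $s$ is $\mathrm{round}(s \cdot n(n-1)/2)$
  (round half up); weight ties are broken by a fixed lexicographic pair
  order, so thresholding is fully deterministic.
* Binary graphs are used after thresholding. Binary metrics are the common
  default of the graph-theory toolboxes used in this literature and make
  $\gamma$, $\lambda$, $\sigma$ well defined.
* Disconnected graphs are unavoidable at the sparse end of the grid. $L_p$
  averages over reachable pairs only and reports the unreachable count;
  $E_g$ counts unreachable pairs as zero contribution. These are the
  conventions that keep both metrics defined across the whole 5–95% grid;
  levels where a metric is genuinely undefined (no connected pair at all,
  or a null ensemble with zero clustering) are recorded as `NA`, never
  imputed.
* Nodes with degree < 2 contribute 0 to $C_p$ and $E_{loc}$.
* The null ensemble is 100 rewired graphs (10 attempted swaps per edge) by
  default; the ensemble size is a precision/cost trade-off, and the
  per-level seeds derive deterministically from the master seed.
* A note on monotonicity: $E_g$ is provably non-decreasing in sparsity
  (adding edges never lengthens a shortest path) and the test suite asserts
  it. $C_p$ is *not* monotone in general — adding an edge can grow
  $\binom{k}{2}$ faster than a node's triangle count — so no such property
  is asserted for it; only $C_p = 1$ at $s = 1$ is exact.

## The synthetic-data generator

No public recordings accompany the protocol this package emulates, so the
generator is a first-class module with known ground truth rather than a test
fixture. A recording is

$$x_i(t) = \text{noise}_i(t) + \sum_k a_k \,\mathrm{Re}\!\left[z_k(t)\,
e^{\,i\,\phi_{k,i}}\right],$$

where each $z_k$ is a narrowband analytic Gaussian source (frequency-domain
construction), $\phi_{k,i}$ steps by the oscillator's phase lag across its
channel set, and the background is $1/f$ Gaussian noise (10 µV RMS at
`noise_level = 1`, matching the resting-EEG spectral shape). Oscillator
amplitude is `strength × 10 µV`, so `strength` is a coupling knob in
$[0, 1]$: imaginary coherence at the coupled frequency rises monotonically
with it, and is zero when it is zero. Instantaneous volume conduction is
emulated by an optional full-rank real mixing matrix; because the mixing is
real and instantaneous, it inflates real-part coherence while the signed
imaginary part stays centered on zero — the property the estimator is built
to exploit, and the property the test suite checks.

A simulated study gives every subject a fixed set of band-specific pair
oscillators: all pairs of a canonical six-channel subset per band (frontal
for delta, frontal-midline for theta, posterior for alpha, centro-parietal
for beta, temporal for gamma), with subject-specific lags drawn once in
$(0.35\pi, 0.65\pi)$ and strengths jittered around `baseline_strength`
(default 0.25). Pre and post segments are independent realizations of the
same subject-level process, so sham arms are exchangeable with their
baselines by construction.

**Effect injection.** The post-intervention effect adds a coupling-strength
increment (default 0.5) to every target-band pair within a configurable pair
set. The default pair set is the montage's *neighbor pairs* — a scalp-wide
local lattice — rather than one dense clique. This choice is forced by how
rank thresholding works: strengthening edges that are already top-ranked
changes nothing in the binary graph, and recruiting a single clique raises
the degree-preserving nulls' clustering as fast as the real clustering,
pushing $\sigma$ *down*. Local lattice-like recruitment is the minimal
mechanism that raises clustering faster than its null and therefore moves
both $C_p$ and $\sigma$ up — the direction of the effect the pipeline is
designed to detect. Supplying `effect$channels` explicitly gives the literal
clique-subset behavior instead.

**What the generator does not emulate:** realistic head-model lead fields,
dipolar source geometry, non-stationarity, drowsiness drift, eye-blink or
muscle waveform shapes (artifact tests inject simple surrogates), and any
biophysical claim about what an intervention does. Effect sizes are chosen
for testability: passing recovery tests shows the pipeline detects coupling
reorganization of the injected kind and size, not that any real intervention
produces such effects.

## Cleaning defaults

The underlying protocol description names the cleaning steps but almost no
thresholds; the package's defaults are therefore explicit and configurable:

| parameter | default | rationale |
|---|---|---|
| Butterworth order | 4, forward–backward | common EEG default; zero phase protects coherence phases |
| spike threshold | robust z (median/MAD) > 8 | flags rare high-amplitude excursions only |
| flat detection | running variance < 1e-3 µV² over ≥ 0.1 s | dead-channel/clipping signature |
| bad channel | neighbor-mean correlation < 0.4 | volume-conducted EEG correlates strongly with neighbors |
| neighbor map | 10–20 schematic coordinates, distance < 0.35 head diameters, equal weights | immediate spatial neighbors only |
| ICA rejection | component kurtosis z > 5, or low-frequency power fraction > 0.6 with frontal-pole loading > 0.4 | spiky/muscle and ocular signatures |

Two robustness details. Transient repair replaces each flagged run with the
50/50 average of the equal-length flanking windows, using the single
available side at a recording boundary (noted in the report). The automatic
bad-channel criterion assumes volume-conducted data; when more than half the
channels fall below the correlation floor the criterion is treated as
inapplicable (none interpolated, with a warning) — this is what happens on
unmixed synthetic data, whose channels are deliberately far less correlated
than real scalp EEG.

The ICA stage is a symmetric fixed-point decomposition (logcosh contrast)
with a seeded random initial rotation, run on whitened data with
near-degenerate directions dropped (after average referencing the data are
rank 18, and reconstruction is exact on that subspace). Decomposition
failure to converge raises an error carrying the iteration count rather than
returning a half-converged rotation. The stage is skipped by default in
`pipeline_config()` (`ica = FALSE`) because simulated recordings carry no
ocular or muscle components and the stage dominates runtime; it is the first
thing to switch on for real data.

The cleaning chain is approximately idempotent: on oscillation-dominated
data with little energy in the filter's transition bands, re-running the
chain changes the signal by well under 1% RMS; the residual is entirely
re-attenuation of transition-band energy (just above 1 Hz and around 55 Hz).

## Problem sizes used by the test suite

The replicate-based suites run the full pipeline at reduced sizes, chosen
once as this package's simulation design. Type-I calibration: 100 replicate
null studies (effect increment 0), 8 subjects, one side, 120 Hz, 25-s
recordings, 5-s epochs, sparsity {0.3, 0.4, 0.5}, small-world indices
skipped (t-test calibration does not depend on which metric a cell holds).
Effect recovery: 5 replicate studies at the full 26 subjects, one side,
160 Hz, 50-s recordings, 5-s epochs, 1-Hz half-bandwidth, sparsity 0.2–0.6
step 0.1, 6 nulls per level. Shorter recordings raise the connectivity noise
floor relative to the 7-min protocol, which makes these settings
*conservative* for detection while keeping the suite fast; the paired design
and the scalp-wide injected effect keep power high regardless.

## Known limitations

* Sensor-space analysis only; no source reconstruction, and nothing here
  mitigates the spatial blurring of sensor-level graphs beyond the choice of
  the imaginary part of coherency.
* Global metrics only; nodal/regional topography is out of scope.
* The paired t-test map is uncorrected by design (matching the analysis it
  reimplements); users wanting family-wise control should correct
  `tidy(result)$p` themselves.
* The EDF writer covers the subset of the format the package produces
  (common sampling rate, 1-s records, 16-bit); it is not a general EDF+
  implementation.
* Statistical behavior at very sparse thresholds (≤ 0.15) is dominated by
  disconnected-graph instability; flags isolated to the sparse end deserve
  skepticism.
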