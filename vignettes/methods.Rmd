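---
title: "Methods: simulating and classifying transient decorrelation events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying transient decorrelation events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`speckleclass` is an end-to-end in-silico pipeline for a diffuse
correlation spectroscopy (DCS) classification instrument: a source fiber
injects coherent light into a dynamic turbid medium, a ring of multimode
detection fibers collects the diffusely reflected speckle onto blocks of
single-photon (SPAD) pixels, and transient perturbations underneath the
medium — shapes flickering on a micromirror panel, or fluid flowing in
embedded tubes — are classified *without labels* from the temporal
intensity autocorrelation of the photon counts.

This vignette documents the physical model, every default parameter with
its rationale, the numerical methods, and the known limitations.

## 1. Physical model

### Speckle statistics and photon detection

The field at each SPAD pixel is modelled as a stationary, zero-mean
circular complex Gaussian process $E_p(t)$ with prescribed field
autocorrelation $g_1(\tau)$. For fully developed speckle the Siegert
relation links field and intensity correlations,

$$ g_2(\tau) = 1 + \beta\,|g_1(\tau)|^2, $$

with coherence factor $\beta \le 1$. Photon counts in a bin of width
$\Delta t$ are conditionally Poisson given the instantaneous normalized
intensity $X(t) = |E(t)|^2$:

$$ n_p(t) \sim \mathrm{Poisson}\!\big(r\,[(1-\sqrt\beta) + \sqrt\beta X(t)] + d\big), $$

where $r$ is the mean detected rate per bin and $d$ the dark rate. The
linear mixing with weight $\sqrt\beta$ is the standard
partial-coherence construction that yields exactly
$g_2 = 1 + \beta |g_1|^2$ for the intensity process while keeping the
mean rate at $r$.

For the default exponential model
$g_1(\tau) = e^{-\tau/\tau_c}$ the sampled field is an **exact complex
AR(1)** process, $E_t = \rho E_{t-1} + \sqrt{1-\rho^2}\,\xi_t$ with
$\rho = e^{-\Delta t/\tau_c}$, generated in compiled code
(`src/speckle.cpp`) with a self-contained xoshiro256++ RNG so event
simulation is reproducible and independent of R's global RNG. Two other
field models are available through `field_g1()` and a circulant-embedding
sampler (`simulate_field_trace()`): a stretched exponential, and the
semi-infinite solution of the correlation diffusion equation (CDE), the
standard analytic DCS model.

### Medium, perturbations and probe

Two optical presets bracket tissue-like phantoms (`tissue_preset()`):

| preset    | $\mu_s'$ (mm$^{-1}$) | $\mu_a$ (mm$^{-1}$) | $\tau_c$ baseline |
|-----------|-----|------|--------|
| `tissue1` | 0.7 | 0.01 | 1.0 ms |
| `tissue2` | 1.2 | 0.02 | 0.583 ms |

The preset names follow the optical parameter values: `tissue1` is always
the less scattering, less absorbing preset. Three consequences of higher
turbidity are carried through the generator, each with a physical
argument rather than a fitted constant:

1. **Faster baseline decorrelation**: $\tau_c \propto 1/\mu_s'$
   (anchored at 1 ms for $\mu_s' = 0.7$), as in diffusing-wave
   spectroscopy where phase decorrelation accumulates with the number of
   scattering events per path.
2. **Weaker perturbation coupling**: the perturbation-to-surface
   sensitivity scales as $\mu_{s,\mathrm{ref}}'/\mu_s'$ (reference
   0.7 mm$^{-1}$).
3. **Photon starvation**: the detected rate is scaled by the ratio of
   semi-infinite continuous-wave diffuse reflectances at the 9 mm
   source-detector separation (`cw_reflectance()`), ≈ 0.40 for
   `tissue2` relative to `tissue1`.

The probe (`make_probe()`) defaults to 12 detection fibers at 9 mm
separation, 250 µm cores, 8 SPAD pixels per fiber. Perturbations live on
a 10.6 × 13.9 mm panel (`panel_grid()`); each fiber sees the panel
through a normalized Gaussian sensitivity kernel with
$\sigma = \rho_{sd}/2$ (`sensitivity_kernel()`) — a parametric stand-in
for a transport-level sensitivity map that preserves the property that a
perturbation mostly affects the fibers above it. A pattern shortens each
fiber's decorrelation time additively in rate
(`pattern_to_fiber_tau()`):

$$ \frac{1}{\tau_p} = \frac{1}{\tau_c} + \frac{\mu_{s,\mathrm{ref}}'}{\mu_s'}\, R \sum_{xy} k_p(xy)\, m(xy), $$

with $R$ the pattern's rate scale and $m$ its mask.

### Pattern families and their transfer constants

* **Letters** (`letter_pattern()`): binary 16 × 16 glyph rasters of
  "D", "U", "K", "E" with per-event affine jitter (±0.5 mm shift,
  ±0.15 rad rotation, ±10 % scale). A mirror panel flipping at $f$ kHz
  contributes $R = 4000\,f$ s$^{-1}$ — the flip-to-decorrelation
  transfer is modelled as linear, so 10 kHz induces exactly twice the
  rate of 5 kHz.
* **Circles** (`circles_pattern()`): four spatio-temporal classes
  crossing circle size (1.4 / 2.8 mm radius) with flip rate
  (5 / 10 kHz).
* **Flow tubes** (`tubes_pattern()`): two 3 mm tubes at $x = \pm 3$ mm;
  the mask stores speed relative to 2 mm/s, the transfer is
  3000 s$^{-1}$ per mm/s, and depth attenuates coupling as
  $e^{-(z-5)/1.5\,\mathrm{mm}}$. Pump speeds carry 3 % log-normal
  jitter per event.

The transfer constants (4000 s$^{-1}$/kHz, 3000 s$^{-1}$/(mm/s)) were
fixed once, during initial design, so that perturbed decorrelation times
fall 1–2 orders of magnitude below baseline — the regime in which an
instrument of this type operates — and were not revisited afterwards.

### Sensor and photon budget

`sim_config()` defaults: bin width 10 µs (`reduced` scale; the `full`
scale uses the 1.5 µs hardware bin on a 32 × 32 array), $\beta = 0.9$,
mean rate 0.03 photons/bin (3 kcps — a deliberately photon-starved,
deep-tissue-like budget; it is what makes integration time and turbidity
matter), dark rate $5\times10^{-4}$/bin (50 cps). The reduced scale
(12 fibers × 8 pixels on a 10 × 12 grid with a dark 2-column margin) is
this package's own choice to keep a full benchmark tractable on one CPU;
all estimators also run at the full scale.

## 2. Correlation analysis

`pixel_autocorrelation()` estimates, per pixel and integration window
$T_{int}$,

$$ g_2(\tau) = \frac{\langle n(t)\,n(t+\tau)\rangle}{\langle n\rangle^2} $$

on a log-spaced lag grid (`lag_grid()`, 24 lags up to
$\min(5\tau_c, T_{int}/10)$). The default "symmetric" normalization
divides by the means of the two overlapped segments, removing most
finite-window bias; "whole_window" gives the literal time-average form.
Windows without photons yield `NA` rather than an error and are skipped
downstream. Pixels are grouped to fibers either from the simulator's
ground truth (`lookup_from_layout()`) or from a flat-field image by
nearest-spot-centroid assignment with a brightness threshold
(`build_lookup_table()`), and `fiber_average()` pools the $Q_p$ pixel
curves of a fiber — the ensemble average that cuts estimator variance
like $1/Q_p$. `assemble_features()` flattens the fiber-major curves into
one row per event and normalizes by each event's mean first-lag excess,
removing the overall coherence/intensity scale while keeping decay
shape and spatial structure.

## 3. Unsupervised classification

The deep clustering network (`dcn_fit()`) is a fully connected stacked
autoencoder (default 288→256→64→8, tanh hidden layers, linear latent and
output) trained on the joint objective

$$ \sum_i \lVert g(f(x_i)) - x_i\rVert^2 + \frac{\lambda}{2}\,\lVert f(x_i) - M s_i\rVert^2, $$

with one-hot assignments $s_i$ and centroids $M$. Training alternates
(a) minibatch Adam steps on the network with $(M, S)$ fixed, (b) the
nearest-centroid assignment step, and (c) the centroid mean update —
both discrete steps provably never increase the clustering cost for the
fixed embedding, and the implementation asserts this at every epoch.
Pretraining (100 epochs) precedes k-means++ initialization and 40 joint
epochs; the full minibatch schedule is drawn up front from its own seed
stream, so setting $\lambda = 0$ reproduces plain autoencoder training
bit for bit. Backpropagation, Adam and k-means++ are implemented in
plain R matrix algebra — the fit is a few seconds at benchmark sizes.

Comparators (`baseline_embed()`): an exact $O(N^2)$ t-SNE implemented
in-package ("tsne_like": perplexity-calibrated Gaussian affinities,
Student-t kernel, early exaggeration and momentum) and PCA, each
followed by k-means. Evaluation uses permutation-matched accuracy
(`matched_accuracy()`): the optimal one-to-one mapping of cluster labels
onto classes, solved exactly by dynamic programming over class subsets,
against a chance level of $1/K$ (`chance_baseline()`).

## 4. Benchmarks

`experiment_spec()` names four studies: `letters_DUKE` (4 × 200 events,
`tissue1`), `circles` (4 × 200, `tissue1`), `tubes_9combo` (two tubes ×
three flow states 0/0.7/1.4 mm/s = 9 classes × 100, `tissue2`) and
`tubes_depth` (3 shared-flow classes × 100 at configurable depth,
`tissue2`). `run_experiment()` chains simulation, correlation,
clustering and evaluation; `stream_features()` keeps memory at one
photon record by reducing each event to its correlation features
immediately (bit-identical to retaining the dataset, which a unit test
enforces).

## 5. Numerical choices

* Exact AR(1) recursion for exponential $g_1$ — no spectral truncation
  error; circulant embedding with clipped negative spectral mass for the
  other models (clipped mass is negligible for these kernels and the
  empirical correlation is tested).
* Correlation sums accumulate in 64-bit integers in C++; the estimator
  is tested to $10^{-9}$ against a direct-sum oracle.
* One root seed drives everything through `derive_seed()` (an exact
  integer hash in doubles), giving decoupled reproducible streams for
  simulation, initialization, batches and k-means++.
* Windowing truncates to whole bins with a $10^{-9}$ epsilon guard
  against floating-point division artifacts.

## 6. What the generator does and does not emulate

Emulated: Siegert-consistent speckle with partial coherence, shot noise
and dark counts, photon starvation and contrast loss with turbidity,
fiber-level ensemble statistics, per-event nuisance jitter (pattern
placement, pump speed), depth attenuation for tubes.

Not emulated: photon-transport-accurate sensitivity maps (the Gaussian
kernel is parametric), afterpulsing/crosstalk/dead time of SPADs,
speckle correlations between neighboring pixels, source power drift,
non-ergodic (static scattering) components, and the motion of the tubes'
fluid as a directed-flow $g_1$ shape (flow enters as an effective
decorrelation rate; the CDE model with a Brownian index is available as
an alternative field shape).

## 7. Limitations

Accuracies depend on the frozen photon budget; at much higher count
rates all benchmarks saturate and the integration-time and turbidity
orderings flatten. The reduced sensor scale trades statistical power for
runtime. The t-SNE comparator is exact but $O(N^2)$ and intended for
benchmark-sized inputs.
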