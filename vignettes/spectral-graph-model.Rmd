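---
title: "A spectral graph model of brain oscillations: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spectral graph model of brain oscillations: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`spectralgm` implements a hierarchical *linear* model of resting-state
brain activity in which the entire regional power spectrum is available in
closed form — no time-domain integration, no regionally varying
parameters. The same canonical rate equation is applied at two scales:

**Local (mesoscopic) scale.** Within a region, excitatory and inhibitory
populations are lumped into gamma-shaped neural impulse responses
`f(t) = (t/tau) exp(-t/tau)`, whose frequency-domain form is taken as

    F(omega) = (1/tau^2) / (j*omega + 1/tau)^2,

normalized so that `F(0) = 1`. (The exact Fourier transform of the
gamma-shaped `f(t)` above carries an extra factor of `tau`; the unit-DC
convention is the one used consistently by every downstream equation in
this package, so it is the authoritative form here. `gamma_spectrum()`
implements it verbatim.) Each population has transfer function
`H(omega) = 1/(j*omega + (g/tau) F(omega))`; the excitatory gain is fixed
at `g_ee = 1` without loss of generality. Signals alternating through the
E-I loop contribute `H_ei = He*Hi/(1 + g_ei*He*Hi)`, and the total
cortical transfer function is `H_local = He + Hi + H_ei`. Every region
shares `H_local`: all regional differentiation in this model comes from
the network, not from local tissue differences.

**Macroscopic (network) scale.** Long-range influences travel along
white-matter fibers with conduction delay `tau_jk = d_jk / v`. In the
frequency domain delays are phases, giving a *complex connectivity
matrix* `C*(omega) = { c_jk exp(-j omega d_jk / v) }` and, after
normalization by the (real) degree `deg_k = sum_j c_jk`, the complex
Laplacian

    L(omega) = I - alpha * diag(1/deg) * C*(omega).

Each eigenmode `u_i(omega)` of `L` responds with
`h_i(omega) = 1/(j*omega + (lambda_i/tau_G) F_G(omega))`, and under unit
white-noise drive at every region the steady-state response is

    X(omega) = sum_i u_i u_i^H h_i(omega) H_local(omega) 1.

`regional_spectrum()` returns `|X|` per region per frequency.

## Parameters

Seven global parameters are exposed to fitting (`tunable_parameters()`),
with defaults and box bounds from `sgm_params()` / `sgm_bounds()`:

| parameter | meaning                    | unit | default | bounds        |
|-----------|----------------------------|------|---------|---------------|
| `tau_e`   | excitatory time constant   | s    | 0.012   | [0.005, 0.02] |
| `tau_i`   | inhibitory time constant   | s    | 0.003   | [0.001, 0.02] |
| `tau_G`   | graph time constant        | s    | 0.006   | [0.005, 0.02] |
| `g_ii`    | inhibitory gain            | –    | 1       | [0.5, 5]      |
| `g_ei`    | E-I loop gain              | –    | 4       | [0.5, 5]      |
| `v`       | conduction speed           | m/s  | 5       | [5, 20]       |
| `alpha`   | long-range coupling        | –    | 1       | [0.1, 1]      |

The canonical inhibitory default (3 ms) lies below the conventional 5 ms
optimization floor for the time constants; we therefore relax the
inhibitory lower bound to 1 ms so the default is inside its own box.
Distances are millimetres, speeds metres/second, time constants seconds;
the mm-to-m conversion happens at exactly one place
(`complex_connectivity()`) and is pinned by a hand-computed phase test
(50 mm at 5 m/s and 10 Hz gives phase `-0.2*pi`).

## Numerical choices

* **Eigenmode bookkeeping.** Eigenvalues are sorted by ascending
  magnitude with ties broken by real then imaginary part; eigenvectors
  are unit-norm with phase fixed so the largest-magnitude entry is
  real-positive. This makes decompositions reproducible across runs and
  platforms. "The first two-thirds of eigenmodes" (the default
  `num_modes`) means the lowest-|lambda| two-thirds. Decompositions are
  computed independently per frequency; no eigenvector continuation is
  attempted across the grid.
* **Rank-one expansion vs direct solve.** The eigenmode sum with
  `u_i u_i^H` is exact only when the eigenvectors are orthonormal, which
  holds for the symmetric normalization at zero delay. For the default
  row normalization the expansion is the model's stated form, and
  `direct_inverse_spectrum()` — a dense linear solve per frequency — is
  kept as the always-available exact reference. The test suite pins the
  two together to relative error 1e-6 in the Hermitian configuration.
* **Degenerate responses.** An exactly singular eigenmode response
  (possible only at `omega = 0` with `lambda = 0`) is capped at magnitude
  1e12 with a warning rather than returning infinity.
* **Zero-distance fast path.** When all fiber distances are zero the
  Laplacian is frequency-independent, so one eigendecomposition serves
  the whole grid. The Laplacian itself (not the normalized connectivity)
  is decomposed so that degenerate cases such as `alpha = 0` keep an
  orthonormal eigenbasis and reproduce the region-identical limit
  exactly.
* **Eigenvalue range.** With row normalization, `|lambda - 1| <= alpha`
  (Gershgorin), so magnitudes live in `[0, 1 + alpha]`. On the synthetic
  delay connectomes below, magnitudes above 1 do occur at the default
  `alpha = 1`; the nominal unit-interval range should be read as a
  property of real measured connectomes near low frequencies. The hard
  invariants tested are the Gershgorin bound and the observation that
  low-|lambda| modes shift far more with frequency than high-|lambda|
  modes.

## Fitting

`fit_parameters()` maximizes the *spectral correlation*: per region, the
Pearson correlation between model and empirical spectra across
frequencies — computed on the dB scale (`20*log10`), since raw
magnitudes let the lowest frequencies dominate the statistic — averaged
over (masked) regions. A linear-scale switch is provided.

The optimizer is bounded simulated annealing in normalized `[0,1]^7`
coordinates: Gaussian proposals scaled by the current temperature and
reflected at the bounds; geometric cooling `T_k = 0.95^k` from `T0 = 1`;
logistic acceptance `1/(1 + exp(delta/T))` for worse moves (improving
moves are always accepted); and a reanneal — temperature reset and
restart from the incumbent best — every 100 acceptances. Each proposal
perturbs a single randomly chosen parameter. This choice matters: the
cost surface has long curved ridges along which the two gains (and the
three time constants) trade off, and simultaneous perturbation of all
seven coordinates steps off such a ridge almost surely, stalling
convergence around the basin it first finds; axis-aligned moves walk
ridges efficiently and reliably push the self-consistency fits past
spectral correlation 0.99. The iteration cap defaults to 3000 per
tunable parameter (21000). All schedule constants are arguments
(including a `reanneal_decay` for a progressively cooler multistart,
off by default — it proved prone to premature lock-in). A fit is a pure
function of its seed: the proposal stream is seeded locally and the
caller's RNG state restored.

Identifiability caveat: the model's spectrum depends on parameter
*combinations* (notably the three time constants trade off against the
gains), so spectrum-level recovery is the primary self-consistency
criterion; parameter-level recovery is checked at the median across
annealing seeds. On noiseless self-generated spectra (N = 68, 80%
sparsity), five 8000-iteration runs each reach spectral correlation
above 0.99, and five 2000-iteration runs recover the generating
excitatory time constant to about one percent at the median.

## Synthetic data

Because the model is meant for source-localized resting-state spectra,
the package ships generators for both sides of the fit:

* **Connectomes** (`generate_connectome()`): `"uniform"` (all-ones,
  diagonal included — chosen so the normalized Laplacian has the exact
  closed-form spectrum `{1 - alpha, 1 x (N-1)}` at zero delay, a test
  anchor), `"random"` (symmetric uniform(0,1] weights at a requested
  sparsity, zero diagonal), and `"distance"` (regions on a seeded
  ellipsoidal shell with semi-axes 65 x 85 x 55 mm — the scale of a
  human brain — and weights `exp(-d/sigma)` with `sigma` the median
  pairwise distance). Uniform and random connectomes default to zero
  distances (no delays); supplying coordinates attaches a Euclidean
  distance matrix.
* **Pseudo-empirical spectra** (`generate_pseudo_spectra()`): the
  forward model plus independent Gaussian noise in the dB domain
  (multiplicative in linear magnitude), default 1 dB — the natural noise
  model for averaged log-scale spectral estimates.

What these do *not* emulate: beamformer leakage, sensor noise
covariance, volume conduction, regional heterogeneity of local
parameters, or the edge-weight statistics of tractography. Passing tests
on synthetic data therefore demonstrate internal consistency of model,
optimizer and selection machinery — not fidelity to any particular
measured dataset.

## Eigenmode selection

`sorted_cumulative_selection()` asks which small set of eigenmodes best
explains an empirical band-power map (alpha 8-12 Hz; beta 13-25 Hz by
default, with the broader 15-30 Hz convention available): modes are
ranked by the spatial correlation of their band-integrated single-mode
patterns with the empirical map (ties by ascending index), then their
*complex* responses are accumulated in that order — magnitude of the
sum, never sum of magnitudes — re-scoring the correlation after each
addition. Selection uses band-integrated patterns because the target is
band power; the raw single-frequency eigenvector view remains available
through `laplacian_eigs()`. On fixtures whose target map is built from a
few modes plus noise, the curve rises, peaks at a small interior subset,
and declines as the remaining modes are added.

## Problem sizes used by the shipped tests

The test suite and acceptance script run entirely on generated data:
68-region connectomes for the closed-form and recovery checks (matching
a standard cortical parcellation count), 2000-iteration annealing runs
for recovery medians, 8000-iteration runs for the noiseless
self-consistency bound (4000 under 1 dB noise), and 8-30-region
fixtures elsewhere. These sizes
were chosen as the smallest that exercise each property cleanly.

## Known limitations

* The rank-one eigenmode expansion is approximate off the Hermitian
  configuration (see above); the direct solve is exact and cheap at
  N ~ 100, so use it when absolute magnitudes matter.
* Peak *positions* of the modeled spectrum are strongly parameter
  dependent; the acceptance script prints the values the shipped
  parameter sets actually produce.
* Simulated annealing with the default schedule explores aggressively at
  high temperature; for refining an already-good starting point, shrink
  `t0`.
* The model is linear by construction: no amplitude-dependent dynamics,
  no cross-frequency coupling, and the gamma band is outside its
  intended range.
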