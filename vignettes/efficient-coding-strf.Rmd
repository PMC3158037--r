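---
title: "Efficient coding of auditory spectrograms: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Efficient coding of auditory spectrograms: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecstrf)
```

## The model

The package treats an auditory receptive field as the solution of an
information–cost tradeoff. The input is a vector `x` of spectrogram
fluctuations (mean-subtracted power across tonotopic channels, or across
time steps, or both), assumed zero-mean Gaussian with correlation matrix
`R`. The input arrives corrupted by iid Gaussian *input noise* of variance
`N` per channel; the encoding `O = K (x + n) + n_e` adds iid *encoding
noise* of variance `N_e` per output. The optimal linear transform `K`
minimizes

```
E = cost − λ · I,
cost = Σ_k ⟨O_k²⟩,
I = mutual information between O and x (Gaussian channels),
```

where `λ` (`tradeoff`) prices information in units of output power.

Because all variables are Gaussian, the optimum decomposes into
decorrelation, per-channel gain control, and an information-neutral
orthonormal multiplexing. For a decorrelated channel with signal power `S`,

```
I(g) = ½ log2[(g²(S+N) + N_e) / (g²N + N_e)]  bits,
e(g) = g²(S+N) + N_e − λ · I_nats(g),
g*² = max{0, N_e/(2N(S+N)) · [√(S² + 2λNS/N_e) − (S + 2N)]}.
```

Internally the objective uses information in **nats** (the stationarity
algebra then carries a clean `λ/2` factor); every reported information
value is in **bits**, and `objective = cost − λ · total_information ·
log(2)`. The closed form is exercised against an independent numeric
minimizer of `e(g)` in the test suite and the acceptance script.

Two consequences drive everything else:

* **Intensity (SNR) adaptation.** At high SNR the active band is wide and
  the gain approaches the whitening profile `g ∝ S^{-1/2}`
  (`whitening_flatness()` measures the flatness of `g²S`); the channels
  just above threshold are boosted hardest, so the gain profile is
  band-pass. As intensity falls, the threshold `λ > 2N_e(1 + N/S)` silences
  high-frequency channels first and the profile becomes low-pass.
* **Correlation adaptation.** Longer-range input correlations concentrate
  `S_k` at low modulation frequencies; with total power held fixed, the
  passband shrinks and the filters widen.

## Synthetic ensembles

`make_spectral_ensemble()` draws spectra `x = intensity_scale · A W z`,
`z ~ N(0, I)`: `W` is a Gaussian smoothing matrix of width
`smoothing_length` (channel units) whose rows are normalized to unit L2
norm, so each pre-scale channel has unit variance and `intensity_scale`
and the intensity profile `A(f) = exp(−decay_rate·(f−1)/n)` are the sole
controllers of power. The spectral generator truncates `W` at the edges
(edge channels genuinely differ, as on a real tonotopic axis);
`make_temporal_ensemble()` wraps it circularly, making the correlation
exactly translation invariant, circulant, and diagonalized by the DFT —
`fourier_decorrelate()` then replaces the eigendecomposition.
`analytic_correlation()` returns the exact `R = s²·A W W' A` so tests can
separate sampling error from model error.

`modulation_power_2d()` supplies the 2-D analogue directly in the
decorrelated (moving-ripple) domain:
`S(ω_f, ω_t) ∝ exp(−corr_f·|ω_f| − corr_t·|ω_t|)`, normalized so the total
power over the grid is `scale × (grid size)` regardless of the correlation
parameters — ensembles differing only in correlation range carry equal
power, which is the construction the correlation-adaptation comparisons
require. The decay constants `corr_f` (octaves) and `corr_t` (seconds) are
the correlation ranges: doubling them halves the modulation bandwidth.

What the generators deliberately do **not** emulate: non-Gaussian
amplitude statistics of natural sounds, nonstationarity, co-modulation
across distant frequencies, and any cochlear mechanics (phase locking,
compression beyond an optional log transform in the spectrogram
front-end). Passing tests therefore show that the *solver and
constructions* behave as the theory predicts under the stated Gaussian
conditions — not that real auditory input has these statistics.

## Default study conditions

All defaults are set once, here, and frozen in `config_defaults()`:

| parameter | default | unit | why |
|---|---|---|---|
| `n_channels`, `n_samples` | 250, 250 | – | reference spectral simulation size |
| `smoothing_length` | 5 | channels | mid-range correlation; `srf-corr` contrasts 3 vs 10 |
| `decay_rate` | `log(10)/2` | – | top-channel power ≈ 10% of the bottom channel |
| `intensity_scale` | 10 | – | reference "high SNR": band-pass gain, interior peak |
| `N`, `N_e` | 1, 1 | power | noise units; everything else is relative to them |
| `tradeoff` λ | 6 | power/nat | see below |
| 2-D grid | 32 × 64 | – | 0.125 oct and 3 ms steps: Nyquist 4 cyc/oct, ~167 Hz |
| `corr_f`, `corr_t` | 3 oct, 0.1 s | – | passband (threshold crossing) inside the grid at the ladder top |
| intensity ladder | ×0.03 … ×10 | – | spans low-pass through band-pass regimes |

**Choosing λ = 6.** Two constraints pin the default. The gain must be
band-pass with an interior peak at the reference intensity, which any
λ well above the activation threshold satisfies. But the high-SNR
whitening approximation carries a relative error of
`λ²N / (2 N_e S (λ − 2N_e))` at signal-to-noise ratio `S/N`; requiring at
most 5% deviation down to `S/N = 100` (the package's high-SNR threshold)
bounds `λ ≲ 6.5` for `N = N_e = 1`. λ = 6 satisfies both with margin;
λ = 10 — used in some unit tests as a convenient worked example for the
closed form — would violate the 5% bound at the passband edge.

**Low-SNR regime for the correlation contrast (scale 0.4).** The claim
"longer correlations ⇒ strictly smaller cutoff" holds only while the gain
threshold sits below the crossing point of the two equal-power eigenvalue
spectra (the long-range ensemble has *more* power at low `k`, less at high
`k`; the spectra cross near `k ≈ 8` at value ≈ 4 per unit scale²). At the
default λ the threshold power is 0.5, so the comparison is meaningful for
scales above ≈ 0.35. Scale 0.4 (= 0.04 × reference) is the lowest regime
that respects this and renders both gain profiles low-pass.

## Filter construction

* **SRF**: `K = U' G U` with `U` the eigenvector rows. The transpose choice
  localizes each row around its own channel; `K` is symmetric.
* **TRF**: gains over temporal modulation frequency → zero-phase inverse
  DFT (an even, acausal kernel whose DFT magnitude equals the gains
  exactly) → minimum-phase causalization.
* **STRF**: per spectral modulation frequency `ω_f`, the temporal slice
  `g(ω_f, ·)` is causalized as for the TRF, then an inverse DFT across
  `ω_f` assembles `STRF(f − f0, t)`. Since causalization preserves each
  slice's temporal magnitude response, the 2-D DFT magnitude of the kernel
  reproduces the full gain profile; the kernel has no taps at negative
  latency by construction.

**Minimum phase by root reflection.** Taps below `1e-12` of the maximum are
trimmed, the polynomial roots (in `z^{-1}`) are computed as eigenvalues of
the companion matrix, roots with modulus below `1 − 1e-8` (zeros of the
transfer function outside the unit circle) are reflected to their conjugate
reciprocals, and the coefficients are rebuilt from real linear factors and
conjugate-pair quadratics — sequential complex products drift measurably
non-real at the grid sizes used, real factor pairs do not. The result is
rescaled by the product of the reflected moduli (exact magnitude
preservation), a median-ratio FFT correction absorbs residual drift, and
the sign is fixed so the largest tap is positive. Roots within `1e-8` of
the unit circle are left in place. The construction is validated by
brute-force enumeration of every conjugate-closed root-reflection
alternative for short filters: the minimum-phase assignment dominates the
cumulative energy sum at every lag.

## Measurement conventions

* **MTF**: DFT magnitude on the kernel's own grid; symmetric under
  frequency negation for real kernels; peaks and cutoffs are reported on
  the nonnegative-frequency quadrant only.
* **Per-axis peak (best modulation frequency) of a 2-D gain.** The joint
  argmax of a 2-D gain surface is degenerate: the gain is constant along
  the level set `S(ω) = S*` where it is maximal, so a raw argmax lands
  wherever grid jitter puts it. The per-axis peak is therefore taken along
  the axis slice through the origin (the other modulation frequency held
  at zero) — a proper 1-D profile with a unique interior maximum that
  moves strictly outward with intensity.
* **Cutoff**: largest nonnegative frequency at which the magnitude
  (maximized over the other axis in 2-D) reaches 5% of the peak. For
  analytic gain vectors the exact-zero cutoff `k_c = max{k : g_k > 0}` is
  used instead, since the closed form reaches zero exactly.
* **Band-pass vs low-pass**: band-pass iff the maximum over nonzero
  frequencies exceeds the zero-frequency bin by 10% (`margin`).
* **Lobes**: maximal same-sign runs with peak at least 5% of the global
  maximum (`noise_floor`) and at least 2 taps (`min_run`); the main-lobe
  width is measured at half the lobe peak; inhibitory strength is
  `Σ|negative| / Σ|positive|` over qualifying lobes.
* **Ties** at an MTF argmax resolve toward the lowest frequency —
  conservative with respect to band-pass claims.

## Numerical choices and degenerate inputs

Eigenvalues are clipped at zero (sampling noise produces `O(−1e−14)`
negatives; anything below `−1e-8·max` warns). Eigenvector signs are fixed
by making the first non-negligible component positive; numerically
degenerate eigenvalue blocks (circulant correlations produce exact pairs)
are ordered by ascending zero-crossing count, preserving the monotone
index-to-modulation-frequency relation. All-zero gain profiles warn (gain
solver) or error (filter construction); all-zero filters cannot be
causalized and error. `encode()` accepts zero noise variances so noiseless
limits are testable. One RNG stream per generator call, seeded explicitly;
the caller's RNG state is restored afterwards.

## Problem sizes

The reference spectral pipeline runs at 250 channels; ladders reuse its
analytic eigenvalues. Temporal filters use 64-tap grids, the 2-D
construction a 32 × 64 modulation grid — sizes at which the companion-root
causalization retains roughly 1e-9 relative magnitude accuracy; at a few
hundred taps the root-product reconstruction starts to lose precision,
which is why the grids stay at this scale. The empirical
unitary-invariance check uses 128 channels × 20,000
samples, at which the paired log-determinant estimates resolve the 1%
equality band with several-fold margin.

## Known limitations

* The linear-Gaussian optimum says nothing about static output
  nonlinearities or spike generation; only the kernel is modeled.
* The MTF magnitude is the theory's robust prediction; kernel *shapes*
  additionally depend on the phase convention (even in frequency,
  minimum-phase in time) and would differ under other information-neutral
  multiplexings.
* Lobe counts at very low SNR are sensitive to the 5% noise floor, because
  causalization of a sharply truncated gain profile leaves low-amplitude
  ringing.
* The spectrogram front-end is a windowed FFT on a log2 frequency axis —
  a deliberate simplification, not an auditory-filterbank model.
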