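---
title: "Approximate PCA for calcium-imaging movies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Approximate PCA for calcium-imaging movies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastpca)
```

## The problem

A calcium-imaging movie of the insect antennal lobe is an `m × n` matrix
`A`: `m` timepoints, `n` pixels, each column the fluorescence timeseries of
one pixel. Downstream analysis — source separation of glomerular signals,
artifact removal — is typically run in a rank-`k` PCA space,

`A ≈ A_k = T S`,

with `T` (`m × k`) the temporal loadings and `S` (`k × n`) the principal
component images. On large movies the PCA itself is the bottleneck. The
package computes an *approximate* PCA by running the iteration on a small,
deliberately chosen pixel subsample, exploiting one piece of prior
knowledge: a glomerulus spans several adjacent pixels that report the same
signal plus noise, so biologically relevant pixels covary with their
neighbours.

## Pixel sampling

Three probability distributions over pixels are supported.

* **Uniform** — the baseline, `p_j = 1/n`.
* **Norm** — `p_j = |A_j|² / ‖A‖_Fr²` on the centered movie. Under these
  probabilities, drawing `c` columns *with replacement* and rescaling each
  drawn column by `1/√(c·p_j)` (the Monte-Carlo scheme) makes `CC'` an
  unbiased estimate of `AA'` and yields the error bounds below.
* **Covariation** — norm sampling applied not to `A` but to the local
  covariance matrix `L = f(A'A)`, where `f` zeroes every entry whose pixel
  pair are not grid neighbours. The column norms
  `|L_j| = √( Σ_r (A_j·A_r)² )`, with `r` running over the Moore
  neighbourhood of `j`, are computed directly on the movie, one neighbour
  offset at a time, so the `n × n` matrix is never materialised; `‖L‖_Fr`
  accumulates in the same pass. Then `p_j = |L_j|² / ‖L‖_Fr²`. Pixels inside
  glomeruli get essentially all the mass; independent background noise gets
  next to none.

Covariation sampling uses draws *without replacement* (unscaled columns):
the point is coverage of the covarying structure, not an unbiased Gram
estimate, and duplicates would waste sample budget. The without-replacement
draw is sequential — each draw proportional to `p` renormalised over the
not-yet-selected pixels — which is exactly what base R's weighted
`sample(replace = FALSE)` implements, so that primitive is used rather than
a re-implementation. The loop in the source algorithm does not spell out
renormalisation; sequential renormalisation is the natural reading and is
what we adopt.

The **covariation energy** of a sample, `Σ_{j ∈ unique(R)} |L_j|² / ‖L‖_Fr²`,
is an a-priori quality readout: energy near 1 means the sample covers
essentially all neighbourhood-covarying signal. `adaptive_sample()` draws
until a target energy (default 0.95) is reached, so the sample size adapts
to how concentrated the movie's structure is; if the target is unreachable
it returns every positive-probability pixel. Duplicate indices (possible
under replacement) count once in the energy — the statistic measures
coverage, not draw frequency.

Degenerate inputs are errors, not silent fallbacks: an all-zero movie has
no norm probabilities, and a movie with exactly zero neighbourhood
covariation has no covariation probabilities. Pixels with `p_j = 0` are
never drawn.

## NIPALS PCA and reconstruction

`nipals()` extracts components sequentially: initialise `t` from the
residual column with maximal norm (ties broken by lowest index — the
source is silent on ties), iterate `s = C't/(t't)`, `t = Cs/(s's)`, and
deflate the rank-1 fit `t s'` before the next component. The deflation step
is written in the source algorithm as `C − t_l' s_l`, which is dimensionally
inconsistent; we read it as the rank-1 outer product `t_l s_l`. Convergence
is declared when the relative Euclidean change of `t` between iterations
drops below `tol` (default `1e-9`, `max_iter` 500 — typical movies converge
in a handful of iterations; the tight default buys the oracle-level
agreement with dense SVD that the tests require). If the residual vanishes
before `k` components, fewer are returned with a warning rather than
manufacturing noise components. Each converged `t` is sign-fixed so its
largest-magnitude entry is positive; PCA signs are arbitrary and a fixed
convention makes output reproducible.

For a sampled fit, full-size spatial components come from the pseudoinverse:
`S = T⁺A` (computed with `MASS::ginv`). The same formula is used for the
exact fit, for uniformity — for converged NIPALS on the full matrix it
coincides with the classical loadings up to normalisation.

## Error bounds and sample size

With norm probabilities and Algorithm-1 rescaling, two bounds connect the
sampled decomposition to the optimal one:

* deterministic, every run:
  `‖A − H_k H_k'A‖²_Fr ≤ ‖A − A_k‖²_Fr + 2√k · ‖AA' − CC'‖_Fr`;
* in expectation, for `c ≥ 4k/ε²` draws:
  `E‖A − H_k H_k'A‖²_Fr ≤ ‖A − A_k‖²_Fr + ε‖A‖²_Fr`.

`required_sample_size(k, epsilon)` returns the smallest integer satisfying
the rule (with a tiny relative fuzz before `ceiling()`, so analytically
integer values such as `4·20/0.05² = 32000` are not bumped up by floating
point). `verify_bounds()` checks both inequalities empirically: per run it
draws a rescaled sample, takes `H_k` as the *orthonormalised* NIPALS score
space of `C` (the bound is stated for orthonormal singular vectors; NIPALS
scores are orthogonal but not unit-norm, so a QR step is applied), and
computes the left side as `‖A‖² − ‖H_k'A‖²`. The optimal `‖A − A_k‖` comes
from a dense SVD — the independent baseline, not the package's own
iteration. Both sides are always reported, not just a pass/fail flag,
because the bound is known to be loose and the slack is informative. The
default of 30 repetitions gives a stabler empirical mean for the
expectation check than the 10 used in classical evaluation protocols.

## fastICA on the reduced movie

ICA is the application layer: in the rank-`k` space, statistically
independent component images (spatial mode, glomerulus maps) or independent
timecourses (temporal mode, e.g. isolating the bleaching artifact) are
estimated with the symmetric fixed-point fastICA iteration. Choices the
method name leaves open are fixed as: log-cosh contrast, symmetric
(parallel) estimation, tolerance `1e-6` on the unmixing rotation, `max_iter`
1000, and a seeded random orthogonal initial unmixing matrix — deflation
variants and other contrasts are deliberately not exposed. On
non-convergence the last iterate is returned with `converged = FALSE`.

The k-variable input is whitened exactly (eigendecomposition of its
centered covariance); the removed means are folded back through the
whitening, so `T_ica S_ica` equals `T S` to machine precision — ICA is a
pure rotation of the reduced space and never changes reconstruction error.
Components are ordered by decreasing log-cosh non-Gaussianity and sign-fixed
like the PCA components. `match_components()` pairs components of two
decompositions greedily by absolute correlation, since order and sign are
arbitrary; `component_pixels()` reads glomerulus positions off a component
image by thresholding |coefficients| at a quantile (default 0.99).

## The synthetic generator

`synthetic_movie()` builds movies with known ground truth:

* glomeruli as isotropic Gaussian blobs (sd = radius/2, truncated at the
  radius — real glomeruli are roughly round but no particular profile is
  canonical);
* one response transient per measurement — baseline 0, saturating
  exponential rise over `⌈3·τ_rise⌉` frames, exponential decay settling
  an `undershoot` fraction *below* baseline — scaled per measurement by a
  glomerulus-specific amplitude (different odors excite different
  glomeruli, which is what makes them separable); two odor pulses per
  measurement by default;
* a bleaching trend, exponential decay restarting at each measurement,
  shared by all pixels;
* independent Gaussian noise per pixel and frame.

Defaults are a desk-scale version of a real two-photon antennal-lobe
recording: 64 × 64 pixels, 6 measurements × 40 frames, three glomeruli of
radius ≈ 5 px, peak response amplitude ~2, bleach amplitude 0.3, noise sd
0.1. The noise level was fixed once, as a realistic mid-range SNR for
G-CaMP recordings, before any evaluation was run.

What the generator does *not* emulate: photon/shot-noise statistics (noise
is Gaussian and spatially independent — deliberately, so neighbourhood
covariation is a pure signal criterion), movement artifacts, optical
point-spread, and overlapping response kinetics across glomeruli (all share
one transient template, scaled). Consequently, passing tests demonstrate
the sampling and decomposition machinery under the model's assumptions;
they do not certify performance on recordings with correlated noise or
motion.

## Conventions and small decisions

* Pixel indices are 1-based (idiomatic R; a 0-based convention would fight
  every subscript in the language). Flattening is x-fastest over (z, y, x),
  and TIFF frames are read in exactly that order.
* Neighbourhoods are Moore (8 in 2D; generalised to 26 in 3D). Border
  pixels use truncated neighbourhoods — padding would inject artificial
  covariation at edges.
* Centering removes per-pixel temporal means: that is the convention under
  which right singular vectors are principal components of the pixel
  covariance. (Per-frame centering would change error magnitudes in the
  evaluation sweeps.)
* All randomness flows through explicit `seed` arguments, executed in an
  isolated RNG scope so library calls do not perturb user RNG state;
  repetition sweeps derive one sub-seed per cell.
* TIFF I/O is integer-based (16-bit), matching microscope output; exact
  float round trips use the plain-text matrix format.

## Problem sizes in the shipped checks

The test-suite and the acceptance script run everything at desk scale,
chosen so the full suite completes in minutes on one core while preserving
the structure of the full-size problem: the default 64 × 64 × 240-frame
movie (4096 pixels) for the strategy comparisons and the end-to-end
ICA-recovery check, a 100 × 1000 movie for the bound verification
(`k = 5`, `ε = 0.5`, so the prescribed `c = 80` fits inside `n = 1000`),
grids up to 8 × 8 for the materialised-`L` oracle, and 50 × 200 matrices
with separated spectra for the NIPALS-vs-SVD comparison.

## Limitations

The Monte-Carlo guarantees attach to norm sampling with replacement;
covariation sampling trades them for an empirical coverage statistic. The
bounds are loose in practice — useful as certificates, not as error
predictions. NIPALS assumes the leading singular values are separated;
degenerate spectra mix components within an eigenspace (reconstruction
error is unaffected). Spatial and temporal ICA treat the two aspects of the
data separately; a spatio-temporal criterion is out of scope.
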