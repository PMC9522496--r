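---
title: "Methods: dual-exposure fusion with a refined illumination map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-exposure fusion with a refined illumination map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relight)
```

## The model

A low-light capture `P` (RGB, internally a numeric `H x W x 3` array in
`[0, 1]`) is enhanced in four steps.

**1. Virtual second exposure.** A parametric brightness transfer function
(BTF) models how the same camera would have rendered the scene at an
exposure ratio `k`:

    g(P, k) = exp(b * (1 - k^a)) * P^(k^a)

with fixed generic camera constants `a = -0.3293`, `b = 1.1258` applied
identically to all channels (camera response curves are nearly
channel-independent). The model is exact under composition,
`g(g(P, k1), k2) = g(P, k1 * k2)`, which the tests exploit: darkening a
scene at ratio `k0 < 1` makes `k = 1/k0` the exact restoring exposure.
The working exposure `k_hat` maximizes the Shannon entropy of the
re-exposed luminance — a well-exposed image has a richer histogram than
an under- or over-exposed one. The luminance is the per-pixel channel
maximum (consistent with the illumination initialization below; the
channel mean is available as a switch), resized to 50 x 50 by bilinear
interpolation before the search purely for speed.

**2. Illumination map.** Retinex-style, the illumination is initialized
as `T_hat(x) = max_c P_c(x)` — at every pixel the illumination is at
least the strongest channel response — and refined by minimizing

    || T - T_hat ||_F^2 + alpha * || W o grad(T) ||_1

The 1-norm gradient penalty is made tractable by re-weighting a
quadratic at the initial map: each squared gradient is divided by
`|grad_d T_hat(x)| + epsilon`, so the unique stationarity condition is
one sparse symmetric positive-definite system

    (I + alpha * sum_d D_d' Diag(w_d~) D_d) t = t_hat

(`D_d` are forward-difference operators, identity plus a weighted graph
Laplacian, hence always solvable). The structure-awareness enters through
`W_d(x) = (sum_y G(x,y)) / (| sum_y G(x,y) grad_d T_hat(y) | + epsilon)`
with a truncated normalized Gaussian window `G`: where the pooled
gradient is small (texture, noise) the weight is large and the solver
flattens; across a consistent edge the pooled gradient is large, the
weight small, and the edge survives.

**3. Fusion.** The enhanced image is the per-pixel convex combination
`R_c = W o P_c + (1 - W) o g(P_c, k_hat)` with fusion weight
`W = T^mu`. Well-lit pixels (T near 1) keep the original and their
contrast; underexposed pixels take the synthesized exposure. The weight
map is normalized per pixel by construction (the two coefficients sum to
one), and the output always lies between the two inputs. Note the
gradient-pooling weights of step 2 and this fusion weight are different
objects serving different stages.

**4. Postprocessing.** A per-channel quantile stretch maps the 1%-99%
intensity range onto `[0, 1]` with gamma 0.9 (slightly lifting
mid-tones), then the luma channel (full-range BT.601 YUV) is denoised by
a two-stage BM3D and recombined as `R_f = R o T + R_d o (1 - T)`.
Enhancement amplifies noise most where the scene was darkest, so the
denoised rendition `R_d` is trusted exactly there (T small) while bright
regions keep the raw rendition and avoid over-smoothing.

## Tunable parameters

All knobs live in `pipeline_config()`; a YAML file with the same
structure can be loaded with `read_config()`.

| parameter | default | units | why |
|---|---|---|---|
| `k_lo`, `k_hi` | 1, 10 | exposure ratio | the method only brightens; well-exposed content is protected by fusion, so ratios below 1 are never useful, and 10 covers ~3.3 stops of underexposure |
| `n_bins` | 256 | bins | matches 8-bit quantization; entropy then ranges over `[0, 8]` bits |
| `solver$alpha` | 0.15 | — | fidelity/smoothness balance; common practice for this weighting strategy (tests verify total variation decreases monotonically in alpha) |
| `solver$epsilon` | 1e-3 | intensity | guards zero denominators; also the reciprocal of the weight ceiling in flat regions |
| `solver$sigma`, `window_radius` | 2 px, 2 | pixels | a 5 x 5 Gaussian window pools gradients over roughly one texture element |
| `mu` | 1 | — | fusion weight `W = T^mu`; 1 uses the illumination directly, smaller values blend more conservatively |
| `q_low`, `q_high`, `gamma_adjust` | 0.01, 0.99, 0.9 | quantiles, — | 1% tail saturation mirrors the default of the classic intensity-adjustment routine; gamma 0.9 gives the final tone lift |
| `denoise$*` | block 8, search 16, 16 matches, threshold 2.7 | pixels | the standard BM3D recipe; `sigma_noise = NULL` estimates the noise from the median absolute deviation of the finest diagonal detail band |
| `loe_size` | 100 | pixels/side | the order metric is quadratic in pixel count; 100 x 100 keeps it exact enough and fast |

## Numerical choices

* **Value range.** All equations are evaluated on `[0, 1]` floats: the
  BTF requires `P^(k^a)`, which is only well-behaved there. Images are
  clamped on load and write; illumination maps are floored at `1e-3`
  wherever they divide or blend.
* **Color.** Full-range BT.601 YUV with chroma centered at 0. The exact
  variant is an implementation choice; it makes gray images map to
  `(g, 0, 0)` exactly and the inverse exact to round-off.
* **Exposure search.** Entropy as a function of `k` typically rises then
  falls but is a step function of the histogram, so a golden-section
  search alone could stall; the search seeds a 101-point log-spaced grid
  and refines with Brent's method in the best bracket, keeping whichever
  is better. Constant images short-circuit to `k_hat = 1` with a warning.
* **Boundaries.** Gradients use forward differences with a zero last
  row/column, and the sparse operators use the same stencil, so the
  dense-oracle equivalence in the tests is exact. The Gaussian pooling
  window is clipped at the image border (absent neighbors contribute
  nothing to either sum). One Gaussian bandwidth serves both the
  numerator and denominator sums by default; a separate numerator
  bandwidth is exposed in `solver_params()` for experimentation.
* **Solver.** Sparse Cholesky (via `Matrix`) on the full system —
  deterministic, no iteration tolerance to tune. At the package's target
  sizes (up to ~1 Mpixel) direct factorization of the 5-point-Laplacian
  structure is comfortably fast, so no iterative fallback is provided.
* **BM3D.** Spatial transform is an orthonormal 8 x 8 DCT; the stack
  transform an orthonormal Haar, with group sizes rounded down to powers
  of two. The group DC coefficient is never thresholded. Aggregation
  weights are `1 / (number of retained coefficients)` (hard threshold)
  and `1 / ||shrinkage||^2` (Wiener). Reference blocks stride by 4 px
  with the last row/column always included, so every pixel is covered.
  An external BM3D can replace `bm3d_denoise_plane()` without touching
  the rest of the pipeline; the contract (no-op at zero noise,
  determinism) is what the pipeline relies on.
* **LOE.** Downsampling is nearest-neighbor so no new intensity
  orderings are invented by interpolation; ties count as `p >= q`; the
  sum over all ordered pairs is divided by the pixel count `m` (a
  per-pixel violation count; `normalization = "m2"` gives the fraction
  in `[0, 1]` instead). Published LOE values are only comparable at a
  known evaluation resolution, which is why both the size and the
  normalization are exposed.
* **VIF.** Pixel-domain, scalar Gaussian-scale-mixture approximation at
  four dyadic scales with visual-noise variance 2 on the 0-255 scale —
  deterministic and dependency-light, and it preserves the properties
  the tests rely on (exact self-fidelity of 1, monotone degradation
  under noise). Filtering uses mirrored borders so small images are
  handled; a wavelet-domain VIF with a vector GSM would give different
  absolute numbers and is out of scope.

## What the synthetic fixtures do and do not show

`make_scene()` renders deterministic scenes (gradients, checkerboards,
Gaussian blobs, a mixed quadrant scene) with full-range histograms;
`degrade()` darkens them through the *same* BTF the enhancer assumes
(optionally with a radial vignette for nonuniform lighting) and adds
seeded Gaussian noise. That gives exposure recovery an exact ground
truth and makes every stage testable offline, but it is deliberately a
best case: real low-light captures violate the BTF (saturation,
nonlinear ISP pipelines, quantization at very low signal), carry
signal-dependent Poisson noise rather than additive Gaussian noise, and
contain structure at scales the 128 x 128 test fixtures do not probe.
Passing fixtures therefore demonstrates internal consistency and the
claimed invariants, not photometric accuracy on real sensors. The test
suite runs the oracles on maps up to 12 x 12 (dense solver), 6 x 6
(gradient-weight brute force) and full pipelines at 64-128 px; the
acceptance script uses three 128 x 128 fixtures.

## Known limitations

* `k_hat` is global: a scene that is simultaneously over- and
  under-exposed gets one compromise exposure (fusion hides most of this,
  but strongly bimodal scenes may prefer a multi-exposure extension).
* The BTF is assumed; on cameras far from the generic `(a, b)` the
  synthesized exposure is biased, though entropy maximization partially
  compensates.
* The simplified BM3D trades the full reference implementation's Kaiser
  windows, prefiltered matching, and variance-adaptive thresholds for
  compactness; plug in an external backend for critical denoising.
* LOE's absolute scale depends on the evaluation resolution, so values
  are comparable only within a fixed `loe_size`.
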