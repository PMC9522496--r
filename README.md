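# relight

Low-light image enhancement for photographs and biological/medical
micrographs, with the no-reference and fidelity quality metrics used to
judge it.

Underexposed images hide exactly the detail a microscopist or clinician
needs. Naive fixes fail in opposite ways: global gamma or histogram
equalization over-amplifies the well-exposed parts, while Retinex-style
division by the illumination amplifies sensor noise in the dark parts.
`relight` takes a middle road built from four pieces:

1. **Entropy-optimal dual exposure.** A camera response model — the
   brightness transfer function (BTF)
   `g(P, k) = exp(b (1 − k^a)) · P^(k^a)` with generic parameters
   `a = −0.3293`, `b = 1.1258` — synthesizes a virtual second exposure of
   the same scene at ratio `k`. The ratio `k̂ = argmax_k H(g(B, k))` is
   chosen to maximize the Shannon entropy `H` of the re-exposed luminance
   `B` (computed on a 50×50 thumbnail), i.e. the exposure that reveals
   the most information.
2. **Illumination map refinement.** The illumination is initialized as
   the per-pixel channel maximum `T̂(x) = max_c P_c(x)` and refined by
   minimizing `‖T − T̂‖²_F + α ‖W ∘ ∇T‖₁`, relaxed to a single sparse
   symmetric positive-definite solve
   `(I + α Σ_d D_dᵀ Diag(w̃_d) D_d) t = t̂`, where the structure-aware
   weights `W_d(x) = Σ_y G_σ(x,y) / (|Σ_y G_σ(x,y) ∇_d T̂(y)| + ε)` keep
   major edges and flatten texture.
3. **Illumination-weighted fusion.** The enhanced image is the per-pixel
   convex blend `R_c = W ∘ P_c + (1 − W) ∘ g(P_c, k̂)` with `W = T^μ`:
   well-lit pixels keep the original, dark pixels take the synthesized
   exposure.
4. **Balanced postprocessing.** A quantile contrast stretch with gamma
   0.9, then BM3D denoising of the luma channel only, recombined as
   `R_f = R ∘ T + R_d ∘ (1 − T)` so bright regions are not over-smoothed
   while the noise-amplified dark regions are cleaned.

Quality is measured by the **lightness order error**
`LOE = (1/m) Σ_x Σ_y [U(Q(x),Q(y)) ⊕ U(Q_r(x),Q_r(y))]` (order
violations of the channel-max lightness; lower is better) and a
pixel-domain **visual information fidelity** `VIF = I(C;F) / I(C;E)`
(mutual-information ratio under a scalar Gaussian-scale-mixture model;
1 means perfect fidelity).

## Worked example

Everything is testable without external data: the fixture generator
renders a well-exposed synthetic scene, then darkens it through the same
BTF the enhancer assumes (so the optimal re-exposure has the exact
ground truth `1 / dark_k`) and adds sensor noise.

```r
library(relight)

spec  <- fixture_spec(seed = 7, size = 128, scene = "mixed",
                      dark_k = 0.33, noise_sigma = 0.02)
clean <- make_scene(spec)           # ground-truth well-exposed scene
dark  <- degrade(clean, spec)       # synthetic low-light capture

cfg <- pipeline_config(denoise = denoise_params(sigma_noise = 0.02))
res <- enhance(dark, cfg)
print(res)
#> enhanced image 128x128, k_hat = 2.969 (total 3.04s)

print(evaluate(dark, clean, cfg))       # before enhancement
#> LOE = 449.62 (eval 100px), VIF = 0.5708
print(evaluate(res$image, clean, cfg))  # after enhancement
#> LOE = 551.07 (eval 100px), VIF = 0.7024
```

The recovered exposure ratio `k_hat = 2.969` is within 2% of the ground
truth `1 / 0.33 = 3.03`, and the visual information fidelity against the
clean scene rises from 0.57 to 0.70 — the enhanced image carries more of
the reference's information than the dark capture did. (LOE here is
measured against the *clean* scene; against its own input the pipeline's
LOE is what the order metric is usually quoted on.)

A thin command-line front-end wraps the same functions:

```sh
Rscript inst/cli/relight.R fixtures --seed 7 --size 128 -o fx/
Rscript inst/cli/relight.R enhance  -i fx/degraded.png -o enhanced.png --no-denoise
Rscript inst/cli/relight.R evaluate -e enhanced.png -r fx/clean.png
```

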