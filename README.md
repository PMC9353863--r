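# clawmech

Structure–function analysis of insect claws from electron micrographs and
nanoindentation, in R.

Climbing weevils grip bamboo with a pair of sharp foreclaws whose measured
adhesion force (2–5 N) exceeds the insect's body weight by a factor of 67
or more. Understanding how the claw's geometry and cuticle mechanics
produce that grip requires four kinds of analysis, and `clawmech`
implements all of them as a tested, reusable pipeline for researchers in
attachment biomechanics and bioinspired robotics:

* **Denoising** of SEM images with non-local means (NLM),
  `NL[v](i) = C(i)⁻¹ Σⱼ w(i,j) v(j)`, under the classical patch weight
  `w = exp(−D/h²)` and an improved cosine-windowed weight
  `w = exp(−D/h₁²)·cos(πD/(2h₂))` that cuts off at finite patch distance,
  plus MSE/PSNR benchmarking against known-clean phantoms.
* **Edge detection** with a multiscale B-spline wavelet modulus-maxima
  detector (undecimated à-trous scheme, gradient modulus
  `[|WT⁽¹⁾|² + |WT⁽²⁾|²]^½`, directional non-maximum suppression,
  per-scale threshold λ) and the five classical baselines
  (Sobel, Roberts, Prewitt, LoG, Canny).
* **Boundary modelling**: tracing edge maps into ordered chains, fitting
  the four candidate families (second-order Fourier
  `f(x) = a₀ + Σ aᵢcos(ixw) + bᵢsin(ixw)`, two-term Gaussian, quadratic
  and cubic polynomials) by least squares with `R² = 1 − SSE/SST`
  selection, and profiling curvature `K = |y″|/(1+y′²)^{3/2}` from
  analytic derivatives to classify concave/convex segments.
* **Adhesion mechanics** of the claw tip on particulate surfaces:
  self-locking condition `θ = arctan(μ) − α`, pressure-angle geometry
  `sinα = (r+h)/(r+R)` (single particle) and `α = arccos(d/(2(R+r)))`
  (two particles), and the two-contact force distribution solved from the
  equilibrium system, including the limit load angle where the lower
  contact unloads.
* **Nanoindentation** analysis by the Oliver–Pharr method: power-law
  unloading fit `P = B(h−h_f)^m`, contact stiffness `S`, hardness
  `H = P_max/A_c`, reduced modulus `E_r = √π S/(2β√A_c)`, specimen
  modulus from the series-compliance relation, and dry/wet condition
  summaries.

No raw micrographs or indentation records are publicly deposited for this
system, so a first-class synthetic-data module generates every input with
known ground truth — claw phantoms with closed-form contours, boundary
points from known Fourier models, and indentation curves constructed so
that Oliver–Pharr analysis recovers the requested (H, E_r) exactly.

## Worked example

```r
library(clawmech)

# 1. phantom micrograph -> noise -> improved NLM denoising
phantom  <- generate_claw_phantom(phantom_spec())
noisy    <- add_noise(phantom, noise_spec(gaussian_sd = 10,
                                          impulse_fraction = 0.02, seed = 1))
denoised <- nlm_denoise(noisy, scheme = "improved")
psnr(mse(phantom, noisy))    # 20.25 dB
psnr(mse(phantom, denoised)) # 30.67 dB

# 2. wavelet edges -> boundary chain -> best-fitting family
maps   <- multiscale_edge_detect(denoised, scales = 1)
chains <- extract_boundary(maps$j1)
seg    <- split_monotone(chains[[1]])[[1]]
best   <- select_model(fit_all_families(seg))
glance(best)
#>   family   r.squared   sse    sst  nobs converged
#> 1 fourier2     0.999  15.4 16279.   126 TRUE

# 3. adhesion mechanics at the worked-example parameters
force_distribution(3, radians(10), radians(45), 0.5)[, c("Fp","Fv","N1","N2","k")]
#>       Fp     Fv    N1     N2      k
#>   0.5209 2.9544 0.656 2.1295 0.3081
degrees(limit_load_angle(radians(45), 0.5))
#> 18.43

# 4. synthetic indentation at the dry-condition means, analysed back
cur <- generate_indentation_curve(0.197, 1.105, noise_frac = 0.01, seed = 2)
analyze_indentation(cur)[, c("H_GPa", "Er_GPa", "E_GPa")]
#>    H_GPa Er_GPa  E_GPa
#>   0.1974 1.1046 1.0062
```

The denoised phantom gains about 10 dB of PSNR, the traced boundary is
captured by a second-order Fourier model with R² ≈ 0.999, the two-contact
grasp at α = 45°, μ = 0.5, F = 3 N carries most load on the upper particle
(k = N₁/N₂ ≈ 0.31) and releases its lower contact at θ ≈ 18.4°, and the
indentation round trip returns the generating hardness and reduced modulus
to well under 1%.

`run_claw_pipeline(pipeline_config(seed = 1))` chains the image stages end
to end with a checksummed, seed-deterministic manifest. Each result type
has an `autoplot()` method; fitted objects support `tidy()`/`glance()`.

## Package layout

| Area | Files |
|---|---|
| Synthetic data | `R/synthetic.R` |
| NLM denoising | `R/denoise.R`, `src/nlm.cpp` |
| Edge detection | `R/edges-classical.R`, `R/edges-wavelet.R`, `R/edge-benchmark.R` |
| Boundary + fitting | `R/boundary.R`, `R/fit.R` |
| Adhesion mechanics | `R/adhesion.R` |
| Nanoindentation | `R/indentation.R` |
| Pipeline, I/O, plots | `R/pipeline.R`, `R/image.R`, `R/plots.R` |

The methods vignette (`vignettes/claw-structure-function.Rmd`) documents
the models, parameter defaults, numerical choices and limitations.
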