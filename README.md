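# ctrecon

Iterative filtered back projection (FBP) for low-dose CT simulation
studies, in R.

CT reconstruction inverts the linear projection model `U = E R`: `R` is
the attenuation image (`h × w` pixels), `E` the system matrix of exact
ray–pixel intersection lengths over `X` view angles and `Y` detector
bins, and `U` the measured sinogram. The exact inverse is the
Moore–Penrose pseudo-inverse `E⁺`, which is too expensive to form at
realistic sizes. This package implements a first-order iterative
approximation of `E⁺`,

    P₀ = θ Eᵗ,   P_{K+1} = P_K + P₀ − P₀ E P_K,

convergent for `θ ∈ (0, 2 / λ₁(E Eᵗ))`, together with its practical
image-domain form in which FBP stands in for the pseudo-inverse action:

    R₀ = θ·FBP(U),   R_{K+1} = R_K + R₀ − θ·FBP(E R_K),

stopped when `‖R_{K+1} − R_K‖ ≤ φ`. Around that core it provides what a
simulation study needs end to end: seeded ellipse phantoms (including a
lesion morphology with a necrotic-focus and pseudocyst analogue), an
exact Siddon parallel-beam projector with its adjoint and an explicit
sparse system matrix, windowed-ramp FBP, a Poisson low-dose acquisition
simulator, image-quality metrics (MSE, ROI noise, SNR, contrast), and a
worked-example two-group outcome analysis from a printed contingency
table. It is aimed at people studying reconstruction algorithms on
synthetic data; no patient data are used or supported.

## Worked example

A sparse-view (60 of 180 angles) noiseless scan of a disk phantom,
reconstructed by FBP and then refined by the iterative loop:

```r
library(ctrecon)

ph  <- make_disk_phantom(128, 128, 0.3, 1.0)
sg  <- project(ph, ct_geometry(num_angles = 60))
res <- ifbp_reconstruct(sg, 128, 128,
                        config = recon_config(theta = 1, phi = 1e-4,
                                              max_iters = 50),
                        truth = ph)
glance(res)
#> # A tibble: 1 × 6
#>   iterations converged theta    phi final_delta final_mse
#>        <int> <lgl>     <dbl>  <dbl>       <dbl>     <dbl>
#> 1         50 FALSE         1 0.0001      0.0115   0.00191

mse(ph, fbp_reconstruct(sg, 128, 128))   # FBP baseline
#> [1] 0.002956444
mse(ph, res$image)                       # after 50 iterations
#> [1] 0.001912562
```

The iterative loop cuts the reconstruction MSE by about a third relative
to its own FBP initialization; `tidy(res)` gives the per-iteration
`delta` and `mse` trace and `autoplot(res)` plots it. The dose-dependence
of image noise is explored with `dose_ladder()`, which returns a tibble
of ROI noise, MSE and SNR per (dose fraction, method); survival-rate and
chi-square worked examples live in `sap_outcome_table()`,
`survival_rate()` and `chi_square_2x2()`.

A thin command-line wrapper over the same functions is installed at
`inst/cli/ctrecon.R` (subcommands `phantom`, `project`, `noise`, `fbp`,
`recon`, `dose-ladder`, `metrics`, `stats`, `run`).

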