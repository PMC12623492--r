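# pyrwave

Classical multiresolution image denoising, benchmarked end-to-end in R.

Medical and natural rasters (MRI, X-ray, smartphone photographs) carry
mixtures of signal-dependent and signal-independent noise. `pyrwave`
implements and compares two training-free multiscale denoisers on the 0–255
intensity scale, together with everything needed to evaluate them
reproducibly: a full-reference quality-metric suite, exact paired
significance tests, and a seeded synthetic generator of phantoms and noise,
so the whole benchmarking protocol runs from a clean session with no
downloads. It is aimed at researchers who need an interpretable,
training-free baseline pipeline — and a statistically defensible way to say
whether one denoiser beats another.

## Methods

**Gaussian-pyramid (GP) denoising.** The image is decomposed into an
*n*-level Gaussian pyramid: level 0 is the input, and
*I*<sub>*l*+1</sub>(x, y) = Σ<sub>i</sub>Σ<sub>j</sub> G(i, j)
*I*<sub>l</sub>(2x+i, 2y+j), with G a normalised Gaussian kernel
(G<sub>σ</sub>(x, y) ∝ exp(−(x²+y²)/2σ²)). Each level is filtered by a
scale-appropriate denoiser — by default, at depth 5: a bilateral filter
(neighbourhood 5, range σ 7) at the finest level, 3×3 median filters at
levels 1–2, and Gaussian filters (σ 0.7, 5×5) at levels 3–4. The filtered
levels are recombined coarse-to-fine by repeatedly upsampling the running
reconstruction and averaging it with the next finer filtered level
(`combine = "blend"`); an analytically exact telescoping rule
(`combine = "telescope"`, identity when no filtering is applied) is also
provided — see the methods vignette for why both exist.

**Wavelet-shrinkage baselines.** Separable orthogonal 2-D DWT (Haar, db4,
coif4, sym4) to depth *n*; the detail subbands LH/HL/HH are thresholded —
hard: keep w if |w| ≥ T else 0; soft: sign(w)·max(|w|−T, 0) — with T from
the universal rule T = σ̂·√(2 ln N), σ̂ = median(|HH₁|)/0.6745; then inverse
transform. Round trips are exact to machine precision for every image size.

**Evaluation.** MSE, RMSE, MAE, PSNR = 10·log₁₀(255²/MSE), windowed SSIM,
pixel-domain multi-scale VIF, Pratt's figure of merit
FOM = (1/max(N_ref, N_test)) Σ 1/(1+αd²), and wall time. Two methods are
compared on paired per-image metrics with the paired t-test and the *exact*
Wilcoxon signed-rank test (full 2ⁿ sign-assignment null, computed by
generating-function convolution).

**Synthetic data.** Four phantom kinds (CT-like ellipses, geometric shapes,
gradient + texture, edge grid) and nine noise families — Gaussian,
lognormal, uniform, exponential, Poisson, salt-and-pepper, Rayleigh,
speckle, Erlang — plus a composed camera model (fixed-pattern gain, Poisson
shot noise, Gaussian read noise, impulses). Everything is seeded and
bit-reproducible.

## Worked example

```r
library(pyrwave)

x <- make_phantom("shepp_like", c(256, 256), seed = 1)   # clean reference
y <- add_noise(x, "gaussian", list(sigma = 15), seed = 1)

gp  <- denoise_gp(y, n_levels = 5)                        # headline method
wav <- denoise_wavelet(y, family = "haar", n_levels = 2, mode = "soft")

rbind(evaluate_pair(x, y,        "phantom01", "noisy"),
      evaluate_pair(x, gp$image, "phantom01", "gp5"),
      evaluate_pair(x, wav,      "phantom01", "wavelet-haar-soft"))
```

```
             method psnr_db   ssim    mse    vif    fom    mae
1             noisy   24.58 0.3602 226.69 0.3131 0.6555 12.014
2               gp5   29.96 0.6475  65.67 0.3853 0.7849  6.248
3 wavelet-haar-soft   29.97 0.7913  65.50 0.3221 0.9085  4.604
```

The noisy input sits at 24.6 dB; five-level GP denoising gains about 5.4 dB
and improves every metric. On this purely Gaussian synthetic task the Haar
soft-shrinkage baseline is equally strong in PSNR (its advantage erodes on
impulsive and signal-dependent noise, where the GP's median levels and
edge-preserving bilateral pay off). A paired comparison over ten seeds makes
the tie explicit:

```r
# ra, rb: evaluate_pair() rows for the two methods over seeds 1..10
compare_methods(ra, rb)
```

```
gp5 vs wavelet-haar-soft on psnr_db (n = 10 pairs)
  paired t:  t = -2.3247, p = 0.0451384
  Wilcoxon:  W = 11, p = 0.10546875
  not-significant at alpha = 0.05
```

A thin command-line surface (`inst/cli/workbench.R`) chains the same steps:
`simulate`, `denoise`, `evaluate`, `compare`, `bench`.

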