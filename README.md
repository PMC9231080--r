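# thzamino

Terahertz time-domain spectroscopy (THz-TDS) measures the electric
field of a picosecond pulse transmitted through a sample, giving both
amplitude and phase and therefore two optical constants at once: the
absorption rate α(ω) and the refractive index n(ω). Crystalline amino
acids have low-lying vibrational absorption lines between 0.5 and
2.5 THz, so THz-TDS can identify them label-free — including
enantiomer (D-/L-) pairs whose spectra are nearly identical.

`thzamino` is an R package for people who want to study that
identification chain end to end without a spectrometer. It provides:

* **A physics-based forward model.** Twenty amino-acid tablet
  materials built as Lorentz-oscillator dielectrics from their
  measured peak frequencies, rendered into time-domain traces with
  Fabry–Pérot etalon echoes and averaging-dependent white noise,
  following the tablet measurement protocol (5 tablets per compound,
  60 Hz acquisition, records averaged over 100 / 20 / 10 shots).
* **Material-parameter extraction.** Zero-padded Fourier transforms,
  the sample/reference transfer function T(ω) = ρ(ω) e^{−iΔφ(ω)},
  phase unwrapping with branch anchoring, and the thick-slab
  inversion
  n(ω) = Δφ·c/(ωd) + 1,  α(ω) = (2/d)·ln[4n / (ρ(n+1)²)],
  cropped to the standard 240-point band (0.1–2.5 THz at 0.01 THz).
* **sym4 wavelet-shrinkage denoising** (5 levels, universal
  threshold).
* **Hybrid features.** The 240×2 stack of α and n (column-wise
  standardized from training data only), train/validation/test
  assembly over the averaging levels, and first-principal-component
  diagnostics.
* **An ECA-attention CNN classifier**, implemented natively (im2col
  convolutions in C++, BLAS matrix products, hand-verified
  backpropagation): a 1-D input block stacked into a 2-D feature map,
  two 3×3 convolution stages, a 1×1 expansion to 64 channels, the
  efficient-channel-attention module with adaptive kernel size
  k = |log2(C)/γ + b/γ|_odd (k = 3 at C = 64), dense layers 256/128,
  and softmax over 20 classes — plus the plain-CNN ablation variant.
  Training is SGD with Nesterov momentum, learning-rate decay, early
  stopping and a fine-tuning phase.
* **Evaluation**: confusion matrices, accuracy, per-class precision,
  JSON reports, and a command-line interface
  (`simulate`, `extract`, `train`, `evaluate`, `demo`).

## Worked example

Extract the optical constants of a simulated D-glutamic-acid tablet
and locate its absorption lines:

```r
library(thzamino)

instr <- instrument_spec(noise_sigma_single = 0)   # noise-free
mat   <- build_material_library()[["D-Glutamic acid"]]
s     <- simulate_sample_trace(mat, instr, n_echoes = 0)
r     <- simulate_reference(instr)
oc    <- extract_optical_constants(s, r, d = mat$thickness_d)

length(oc$f)          # 240 points on 0.10 .. 2.49 THz
range(oc$n)           # 1.723 .. 1.781 (dispersive steps at each line)
oc$f[which.max(oc$alpha)]   # 2.44
```

Local maxima of the extracted α appear at 1.22, 2.04 and 2.44 THz
(α ≈ 3.7, 5.1 and 6.0 mm⁻¹ on top of the quadratic baseline) — the
material's three programmed oscillators, each within one 0.01 THz grid
step of its centre and each mirrored by a dispersive step in n (the
Kramers–Kronig connection that motivates the hybrid feature map).

The scaled-down end-to-end study (simulate → extract → train →
evaluate, with the input-mode and attention ablations) runs in a few
minutes on one CPU:

```r
ab <- run_demo(seed = 1)
#> == ECA network, hybrid input ==
#> test20: accuracy 1.0000 (400 items)
#> test10: accuracy 0.9800 (400 items)
#> ...
#> == Ablation summary ==
#> hybrid             test20=1.0000  test10=0.9800
#> hybrid (plain CNN) test20=1.0000  test10=0.9550
#> absorption         test20=1.0000  test10=0.9600
#> refractive         test20=0.9175  test10=0.7850
```

Training records are clean 100-average spectra; the test groups are
noisier 20- and 10-average analogues, so the ablation shows the
robustness pattern of interest: on the noisiest records the hybrid
input beats either single metric and refractive-only trails far
behind, while all modes except refractive-only identify the cleaner
avg-20 set perfectly.

The same pipeline is scriptable from a shell:

```sh
inst/cli/thzamino demo --seed 1 --out demo_out --separable
```

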