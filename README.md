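# muellertomo

Layer-by-layer Mueller-matrix image reconstruction of tissue optical
anisotropy, for polarimetric tissue characterization and benign/malignant
discrimination studies.

A histological section transforms polarized light according to a per-pixel
4×4 Mueller matrix `M = exp(m)`.  The per-layer generator `m` carries six
mean anisotropy parameters — linear birefringence Φ₀,₉₀ and Φ₄₅,₁₃₅,
circular birefringence, and the three matching dichroism terms.  The package
implements:

* **Differential decomposition** — the principal matrix logarithm of each
  pixel's Mueller matrix, split by the Minkowski projection
  `m = (L − G Lᵀ G)/2`, `G = diag(1,−1,−1,−1)`, into the mean-anisotropy and
  depolarizing components; orientation-invariant observables
  `Φ_L = √(Φ₀,₉₀² + Φ₄₅,₁₃₅²)` and `Δ_L = √(Δ₀,₉₀² + Δ₄₅,₁₃₅²)`; the
  Gil–Bernabeu depolarization index in percent.
* **Off-axis polarization holography** — coherent six-probe simulation
  (per-pixel Jones propagation), Fourier-sideband demodulation, Stokes maps
  from analyzer field pairs, Mueller-map assembly from the six probes, and
  phase-plane selection of the reconstructed field.
* **Moment statistics and diagnosis** — the literal moment set
  `Z1 = mean(x)`, `Z2 = mean(x²)`, `Z3 = mean(x³)/Z2³`, `Z4 = mean(x⁴)/Z2⁴`
  of each observable map, cohort summaries, a k-fold stability check, and a
  single-threshold classifier reporting sensitivity, specificity and
  balanced accuracy `Ac = (Se+Sp)/2` with leave-one-out cross-validation.
* **Synthetic tissue phantoms** — a two-class generator (benign "adenoma"
  with developed fibrillar networks vs malignant "carcinoma" with smaller,
  sparser domains) with frozen presets that reproduce the reference cohort's
  first-moment cells and depolarization band, so the whole chain is testable
  without laboratory data.

## Worked example

```r
library(muellertomo)

# one phantom per class, reconstructed at the 0.6 rad phase plane
ade <- generate_phantom(phantom_preset("adenoma",   dim = c(128, 128), seed = 1))
car <- generate_phantom(phantom_preset("carcinoma", dim = c(128, 128), seed = 101))

maps <- layered_anisotropy(ade$mueller[[1]])
mm_moments(maps$phi_L, observable = "phi_L", phase_plane = 0.6)
#> Moments of phi_L at phi = 0.6 rad (P = 16384, literal)
#>      Z1      Z2      Z3      Z4
#> 0.57875 0.60973 3.31470 7.10920

# cohort study: 26 phantoms per class, Z3 of the linear birefringence map
rep <- run_pipeline(list(n = 26, observable = "phi_L", moment = 3))
rep
#> Diagnostic report: Z3 of phi_L at phi = 0.6 rad (loo, n = 26/class)
#>   Se = 96.2%  Sp = 100.0%  Ac = 98.1%  [Excellent]
```

The first block prints the four literal moments of the benign phantom's
linear-birefringence map: the mean level `Z1 ≈ 0.58` rad and mean square
`Z2`, plus the normalized higher moments `Z3`, `Z4` that serve as texture
markers.  The report block classifies the two 26-sample cohorts by a single
threshold on `Z3`: out-of-sample (leave-one-out) sensitivity, specificity
and balanced accuracy, graded on the standard scale (91–100% = Excellent).

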