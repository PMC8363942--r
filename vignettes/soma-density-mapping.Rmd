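---
title: "Mapping apparent neural soma density with B-tensor diffusion MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping apparent neural soma density with B-tensor diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(somamap)
```

## The biophysical model

Brain tissue in a diffusion MRI voxel is modelled as three water pools whose
volume fractions sum to one:

* **quasi-cylindrical neural projections** (axons, dendrites, glial
  processes): zero-radius sticks with parallel diffusivity
  $\lambda_{cyl}$ and negligible perpendicular diffusivity;
* **quasi-spherical neural soma** (neuronal and glial cell bodies): isotropic
  compartments with apparent diffusivity $\lambda_{sph} \le \lambda_{cyl}$,
  an effective quantity that folds together bulk diffusivity, restriction and
  exchange;
* **extra-cellular space**: a hindered axially symmetric tensor whose
  diffusivities follow a tortuosity power law in the cellular volume
  fractions,
  $\lambda^{ext}_{\parallel} = \lambda\, v_{ext}^{\frac{v_{sph}/2}{v_{sph}+v_{cyl}}}$ and
  $\lambda^{ext}_{\perp} = \lambda\, v_{ext}^{\frac{v_{sph}/2 + v_{cyl}}{v_{sph}+v_{cyl}}}$
  with $\lambda = \lambda_{cyl}$. When no cellular structures are present the
  extra-cellular pool reduces to free water, which is how CSF is absorbed in
  ventricle-like voxels.

Each microscopic environment ("microdomain") is Gaussian, so a measurement
with b-tensor $\mathbf{B}$ gives $h(\mathbf{B}, \phi) = \sum_i v_i
\exp(-\mathbf{B} : \mathbf{D}_i(\phi))$. Orientation dispersion is factored
out by powder averaging: rotating the encoding waveform over uniformly
distributed directions and averaging the signals. For an axially symmetric
b-tensor with b-value $b$ and shape $b_\Delta$ the powder mean of one
compartment has the closed form implemented in `compartment_powder_term()`:

$$\bar h = \frac{\sqrt{\pi}\,\mathrm{erf}(\sqrt{x})}{2\sqrt{x}}
\exp\!\Big(-b\Big[\tfrac{1-b_\Delta}{3}\lambda_\parallel +
\tfrac{2+b_\Delta}{3}\lambda_\perp\Big]\Big), \qquad
x = b\, b_\Delta (\lambda_\parallel - \lambda_\perp).$$

The package works throughout in diffusivity units of um^2/ms and internal
b-value units of ms/um^2, so $b\lambda$ is dimensionless; user-facing
constructors take b in s/mm^2.

Measuring with two b-tensor shapes is what makes the four parameters
($v_{cyl}, v_{sph}, \lambda_{cyl}, \lambda_{sph}$) identifiable at moderate
b-values: linear tensor encoding (LTE, $b_\Delta = 1$) retains sensitivity to
microscopic anisotropy through the error-function factor, while spherical
tensor encoding (STE, $b_\Delta = 0$) collapses every compartment to its mean
diffusivity and is sensitive purely to diffusivity heterogeneity. The default
protocol (`default_protocol()`) uses four STE shells at b = 500/1000/1500/2000
s/mm^2 and four LTE shells at b = 1000/2000/3500/5000 s/mm^2, 128 directions
per encoding split equally over its four shells, TE = 94 ms and 12 b = 0
volumes — acquisition parameters achievable on a standard 3 T scanner.

## The estimator

Parameters are estimated per voxel by a three-layer fully connected network
with rectified linear activations. Its inputs are the eight per-shell powder
means plus the per-measurement noise level $\sigma$; its outputs are four
unbounded logits,

$$z_1 = \mathrm{logit}(v_{cyl}+v_{sph}),\quad
z_2 = \mathrm{logit}\big(\tfrac{v_{cyl}}{v_{cyl}+v_{sph}}\big),\quad
z_3 = \mathrm{logit}\big(\tfrac{\lambda_{cyl}}{3}\big),\quad
z_4 = \mathrm{logit}\big(\tfrac{\lambda_{sph}}{\lambda_{cyl}}\big),$$

whose inverse transform produces estimates that satisfy every model
constraint by construction. Ratios are clipped to $[\epsilon, 1-\epsilon]$
with $\epsilon = 10^{-6}$ before the logit; continuous sampling hits the
boundaries with probability zero, but grid inputs do not.

Training data are purely synthetic. Volume fractions are uniform on the
2-simplex; diffusivities are uniform on the 2-simplex of scaled increments
$(\lambda_{sph}, \lambda_{cyl}-\lambda_{sph}, 3-\lambda_{cyl})/3$, the
uniform prior over the ordered constraint
$0 \le \lambda_{sph} \le \lambda_{cyl} \le 3$ um^2/ms. The noise level prior
is log-uniform on $[0.01, 1]$, a scale-invariant choice spanning
single-measurement SNR 1–100. Fresh Gaussian noise at each sample's
$\sigma/\sqrt{n_{dirs}}$ (the powder mean averages independent measurement
noise) is injected into every batch at every epoch, which prevents
overfitting and gives the estimator an intrinsic denoising behaviour.

### Training configuration at desk scale

The reference regimen for this architecture is constant-rate stochastic
gradient descent (learning rate 0.001, momentum 0.9) run for on the order of
$10^5$ epochs over $2^{20}$ samples — days of CPU time. The package's default
configuration is chosen to converge to an equivalent operating point within
about ten minutes on one CPU core: $2^{16}$ samples (75% train / 25%
validation), batches of 1024, hidden widths 128/128, and SGD with momentum
0.9 whose learning rate starts at 0.1 and is annealed by 0.2 at 70% and by
0.04 at 90% of the epoch budget (1100 epochs). The annealed schedule is
standard practice for SGD and reaches, in roughly $5\times10^4$ updates, the
same qualitative fit quality the constant-rate regimen reaches over orders of
magnitude more updates; with it the network recovers volume fractions in the
well-conditioned region (both cellular fractions at least 0.2,
$\lambda_{cyl} \ge 1.5$, $\lambda_{sph} \le 0.8$) with mean absolute error
below 0.05 from noise-free signals. All sizes, widths and schedule knobs are
exposed as arguments, and equal seeds reproduce bitwise-identical weights.

The hidden widths are not dictated by the model; three layers of width 128
suffice to capture the forward model's complexity at these protocol sizes,
and widths are configurable for studies of capacity effects.

A classical baseline, `fit_nlls()`, minimises variance-weighted residuals of
the same forward model in logit space (so constraints hold exactly) with
multiple restarts. On noise-free model-generated signals it recovers interior
parameters to three decimals, and it provides the independent cross-check for
the network on noisy data.

### Direction-count transfer

The network never sees individual gradient directions — only powder means and
$\sigma$ — so a model trained on the 128-direction protocol applies to
acquisitions with any direction budget that preserves the per-shell b-values,
shapes and relative splits. What changes is the powder-mean noise,
$\sigma/\sqrt{n_{dirs}}$ per shell; `estimate_params()` rescales the
$\sigma$ input by $\sqrt{n_{model}/n_{data}}$ so the network's noise
assumption matches the data. This is also how the direction-count sweep in
`run_sweep()` is simulated: per-measurement SNR held at 25, so the
powder-mean SNR grows with the direction count — which is precisely what
makes the sweep informative.

## Violation generators

`violated_powder_signal()` synthesises data from nine generative departures
from the idealised model; the estimator is never retrained on them. Where
compartments carry different T2 weights, the b = 0 reference is assumed to
carry the same weights (measured signals are T2-normalised), so effective
signal fractions are $f_i = v_i e^{-TE/T2_i} / \sum_j v_j e^{-TE/T2_j}$ at
TE = 94 ms.

* **CSF partial volume**: a fourth free-water compartment (3 um^2/ms) with
  T2 = 2 s against tissue T2 = 0.1 s. The extra-cellular gold standard
  becomes $v_{ext} + v_{CSF}$, since free water should be absorbed there.
* **Compartmental T2**: intra-cellular (stick + sphere) T2 fixed at 0.1 s,
  extra-cellular T2 swept over 0.03–0.1 s.
* **Non-zero perpendicular stick diffusivity**: swept over
  {0, 0.005, 0.01, 0.02, 0.05} um^2/ms by default; values below 0.01 are the
  biophysically typical range at clinical gradient strengths.
* **Myelin**: an MR-invisible volume fraction occupying space and counted
  among the hindering structures in adjusted tortuosity exponents; estimates
  are compared against fractions renormalised by $1/(1-v_{myelin})$.
* **Tortuosity perturbations**: $\lambda^{ext}_\perp$ scaled by $\alpha$, or
  both extra-cellular diffusivities scaled by $\beta$, each clipped at the
  free diffusivity, $\alpha, \beta \in [0.5, 1.5]$.
* **Gamma-distributed sphere diffusivities**: the sphere term becomes the
  mean signal over 10,000 gamma draws with mean $\lambda_{sph}$ and variance
  up to 0.1 (um^2/ms)^2; the implementation is validated against the
  analytic Laplace transform of the gamma distribution.
* **Kurtosis**: the sphere log-signal gains $+\tfrac{1}{6}K_T b^2
  \lambda_{sph}^2$ with $K_T \in [-0.7, 0.7]$; for positive $K_T$,
  $\lambda_{sph} \le 3/(b_{max} K_T)$ keeps the signal monotone up to
  $b_{max} = 5000$ s/mm^2, and the experiment harness clamps sampled
  $\lambda_{sph}$ accordingly.

## Numerical choices

* The anisotropy factor $\sqrt{\pi}\,\mathrm{erf}(\sqrt{x})/(2\sqrt{x})$
  switches to its series $1 - x/3 + x^2/10$ for $|x| < 10^{-6}$ to avoid
  0/0; for planar-like shapes ($b_\Delta < 0$, $x < 0$) the imaginary error
  function branch is used. Default protocols use only LTE and STE.
* Rician bias correction inverts the analytic Rician expectation (evaluated
  with exponentially scaled Bessel functions) by root bracketing; measured
  values at or below the noise floor $\sigma\sqrt{\pi/2}$ map to zero.
* Waveform b-tensors use trapezoidal quadrature with the spin-echo sign flip
  at the recorded refocusing index; waveforms must rephase to within
  $10^{-6}$ relative residual. Waveform *design* (slew-limited optimisation,
  Maxwell compensation) is out of scope: waveforms are validated and
  integrated only.
* Gamma draws are seeded per evaluation, making violation data sets exactly
  reproducible.
* The protocol fingerprint records the ordered shells, echo time and
  direction counts; estimators refuse data whose fingerprint is incompatible
  (different b-values, shapes, TE or relative splits).

## What the simulations do and do not show

The synthetic generator reproduces the study conditions: T2-normalised
powder means on the default 8-shell protocol, Gaussian (optionally Rician)
noise at SNR 25, parameters drawn uniformly over the constrained space, and
violation magnitudes over the published sweep ranges. Experiment harnesses
default to the study-scale counts (10,000 noise instances per grid point;
107,520 parameter draws per violation magnitude) with every count exposed;
the bundled tests and the acceptance script run the same estimators at
desk-scale counts (10,000 draws per violation magnitude, 2,000–3,000 per
trend point), which widens confidence intervals by roughly $\sqrt{k}$ but
leaves means unchanged up to sampling error.

Passing these simulations does **not** establish accuracy in real tissue:
the generator contains no time-dependent (restricted) diffusion, no
inter-compartment exchange, no orientation-coherent macrostructure beyond
what powder averaging removes, no imaging artefacts (motion, eddy currents,
Gibbs ringing), and spatially constant noise. The violation studies bound
the bias from specific, plausible departures — CSF contamination biases grow
with the stick fraction; T2 differences move signal from the extra-cellular
to the stick compartment; unseen myelin inflates the stick fraction — but
real tissue combines several departures at once.

## Known limitations

* $\lambda_{sph}$ is an apparent quantity; no cytometric meaning is claimed.
  Its estimates are unreliable where $v_{sph}$ is small (white matter), as
  the error-versus-fraction experiments quantify.
* The desk-scale network slightly amplifies the extreme-violation biases
  relative to a fully converged estimator (see the compartmental-T2
  experiment); the trend directions and moderate-violation magnitudes are
  unaffected.
* The phantom is a labelled-region stand-in, not anatomy; it exercises the
  estimator end-to-end (synthesis, powder form, masking, fitting, residuals)
  but carries no partial-volume geometry beyond its CSF-contaminated
  interface band.
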