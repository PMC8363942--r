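# somamap

Apparent neural soma density mapping from B-tensor diffusion MRI.

## What this package does

Conventional diffusion MRI models of brain tissue describe neural
projections (axons, dendrites, glial processes) as thin "sticks" but ignore
cell bodies, which limits their value in grey matter where soma are abundant.
`somamap` implements a clinically viable approach to disentangling the two
cell geometries: it combines **linear tensor encoding** (LTE, conventional
directional diffusion weighting, b-tensor shape b&Delta; = 1) and **spherical
tensor encoding** (STE, isotropic weighting, b&Delta; = 0) measurements,
collapses them to orientation-invariant **powder averages**, and fits a
three-compartment biophysical model per voxel:

- sticks with parallel diffusivity &lambda;<sub>cyl</sub> and volume fraction
  v<sub>cyl</sub> (neural projections),
- isotropic spheres with apparent diffusivity
  &lambda;<sub>sph</sub> &le; &lambda;<sub>cyl</sub> and fraction
  v<sub>sph</sub> (neural soma),
- an extra-cellular compartment (fraction v<sub>ext</sub> = 1 &minus;
  v<sub>cyl</sub> &minus; v<sub>sph</sub>) whose axially symmetric tensor
  follows a tortuosity power law in the cellular fractions.

The powder-averaged signal of each compartment has the closed form

    h(b, bD) = sqrt(pi)/2 * erf(sqrt(x))/sqrt(x)
               * exp(-b * ((1-bD)/3 * l_par + (2+bD)/3 * l_perp)),
    x = b * bD * (l_par - l_perp)

and the voxel signal is the volume-fraction-weighted sum over compartments.

Parameters are estimated voxel-wise by a three-layer fully connected neural
network trained **only on synthetic signals** drawn from uniform simplex
priors with a log-uniform noise prior; a logit output parameterisation
guarantees physically valid estimates. A classical multi-start
Levenberg–Marquardt fit (`fit_nlls()`) provides the independent baseline.
The package also ships the full simulation harness used to characterise the
estimator: bias/precision maps over the parameter simplex, SNR and
direction-count sweeps, and generators for systematic model violations (CSF
partial volume, compartmental T2 differences, non-zero perpendicular stick
diffusivity, MR-invisible myelin, tortuosity perturbations, gamma-distributed
sphere diffusivities, kurtosis), plus a synthetic 3-D phantom and NIfTI I/O
for volume-level fitting.

Intended users: diffusion MRI methods researchers who want soma-sensitive
parameter maps from standard 3 T B-tensor protocols, or who want to quantify
how modelling assumptions bias such maps.

## Worked example

Train an estimator on the default protocol (four STE shells at
b = 500–2000 s/mm², four LTE shells at b = 1000–5000 s/mm², 128 directions
per encoding, TE = 94 ms), then fit a synthetic phantom:

```r
library(somamap)

proto <- default_protocol()
model <- train_estimator(proto, seed = 1)   # ~10 min on one core
model
#> Soma-density estimator: 9 -> 128 -> 128 -> 4 network
#>   protocol: v1|te=94.000|500:0:32;1000:0:32;1500:0:32;2000:0:32;1000:1:32;2000:1:32;3500:1:32;5000:1:32
#>   final validation loss: 1.518

## a white-matter-like voxel at SNR 25
p <- tissue_params(v_cyl = 0.7, v_sph = 0.1,
                   lambda_cyl = 2.3, lambda_sph = 0.6)
s <- add_noise(powder_signal(p, proto),
               shell_sigma(proto, 1 / 25), seed = 2)
round(estimate_params(model, s, sigma = 1 / 25), 3)
#>   v_cyl v_sph v_ext lambda_cyl lambda_sph lambda_par_ext lambda_perp_ext
#> 1 0.749  0.11 0.141      2.324      0.947          2.049           0.371
```

The estimate recovers the volume fractions and the stick diffusivity to a
few hundredths; the sphere diffusivity is poorly determined in this voxel
because the soma fraction is small, exactly the regime where the simulation
studies show lambda_sph to be unreliable. The derived extra-cellular
diffusivities come from the tortuosity model. On a phantom with
white-matter-like, grey-matter-like and CSF-like regions:

```r
ph <- generate_phantom(default_phantom_spec(dims = c(32, 32, 4)), proto,
                       seed = 3)
maps <- fit_volume(model, ph$volume)
lab <- as.integer(ph$labels)
round(sapply(1:3, function(l)
  c(v_cyl = median(maps$v_cyl[lab == l]),
    v_sph = median(maps$v_sph[lab == l]))), 3)
#>        [,1]  [,2]  [,3]
#> v_cyl 0.752 0.281 0.008
#> v_sph 0.114 0.476 0.015
```

Column 1 is the white-matter-like region (high v<sub>cyl</sub>), column 2
grey-matter-like (high v<sub>sph</sub>), column 3 CSF-like (both fractions
near zero: free water is absorbed by the extra-cellular compartment).

The violation harness quantifies what happens when the data break the model
assumptions, e.g. distinct intra-/extra-cellular T2:

```r
run_violation_experiment(model, "compartmental_t2", magnitudes = 0.03,
                         n_samples = 10000, seed = 4)
```

reports, among the per-parameter error statistics, a mean overestimation of
v<sub>cyl</sub> and matching underestimation of v<sub>ext</sub> of roughly
0.13–0.15 when extra-cellular T2 drops to 30 ms against intra-cellular
100 ms at TE = 94 ms — extra-cellular signal masquerading as sticks.

A thin command-line wrapper is available at `exec/somamap` with subcommands
`train`, `simulate`, `powder`, `fit` and `experiment`.

## Methods

See the methods vignette (`vignettes/soma-density-mapping.Rmd`) for the
model, priors, training regimen, violation generators, numerical choices and
limitations.
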