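# fracpinn

Physics-informed inverse modelling of time-fractional systems in R: recover
the order and the concentration-dependent generalized diffusion coefficient of
a time-fractional diffusion equation from noisy concentration fields, and
calibrate fractional Maxwell viscoelastic parameters from stress-relaxation
rheology, predicting the relaxation modulus.

## Who this is for

Transport in crowded biological media is frequently *sub-diffusive*: the mean
squared displacement grows like `t^alpha` with `alpha < 1`, and the governing
model replaces the time derivative of Fick's law with a Caputo fractional
derivative,

    d^alpha c / dt^alpha = D(c) (c_xx + c_yy) + D'(c) (c_x^2 + c_y^2),

where `D(c)` is a concentration-dependent generalized diffusion coefficient
(units length²/time^alpha). Likewise, soft-tissue stress relaxation follows
broad power laws that a fractional Maxwell element captures with four
parameters,

    tau + eta d^mu tau / dt^mu = kappa d^nu eps / dt^nu,

whose step-strain relaxation modulus is
`G(t) = (kappa/eta) t^(mu-nu) E_{mu,1+mu-nu}(-t^mu/eta)` with the
two-parameter Mittag-Leffler function `E`. Estimating `alpha`, `D(c)` or
`(kappa, eta, mu, nu)` from noisy measurements is an inverse problem; fracpinn
solves it with physics-informed neural networks whose residuals are built from
the L1 finite-difference discretization of the Caputo derivative: small
network surrogates are regressed onto the data while a *consistency loss* —
the mismatch between the surrogate and its own one-step physics
reconstruction — identifies the physical parameters. All losses are scaled by
the variance of the observed data, so the method is unit-free, and everything
trains with full-batch Adam under a cosine learning-rate schedule, making runs
bit-reproducible for a fixed seed.

The package also contains the forward machinery needed to benchmark all of
this without external data: an implicit L1 solver for the 2-D time-fractional
diffusion equation, a law-consistent step-strain relaxation generator, a
robust real-axis Mittag-Leffler evaluator, seeded Gaussian noise, CSV-based
I/O, a noise-robustness experiment harness, and a command-line interface
(`inst/cli/fracpinn`).

## Worked example: recover a fractional order from noisy data

```r
library(fracpinn)

# forward problem: the built-in benchmark (unit square, 48 x 48 x 40,
# Gaussian bump initial condition, D(c) = 0.1 (1 + c^2)), true order 0.5
scenario <- diffusion_scenario(alpha = 0.5)
field <- solve_tfde(scenario)

# corrupt with 25% Gaussian noise and observe on a sparser spatial grid
noisy <- add_noise(field, noise_spec(0.25, seed = 101))
obs <- thin_field(noisy, 4L)

fit <- fit_anomalous_diffusion(
  obs, cfg = train_config(iterations = 3000, seed = 11),
  truth = list(alpha = 0.5, law = scenario$law))
fit
#> <fracpinn_fit> anomalous_diffusion
#>   alpha = 0.4723
#>   losses: data 5.9807e-02 + consistency 1.0196e-03 = 6.0827e-02
#>   relative errors: alpha 0.0555, dcoef 0.0495
```

The recovered order (0.472 for a true 0.5 under 25% noise, i.e. 5.6%
relative error) and the learned coefficient curve `fit$dcoef_fn` (5.0%
relative L2 error against the generating law over the observed concentration
range) mirror the noise robustness reported for this class of solvers. The
data loss floor (~0.06, the noise variance itself) dominates the total; the
consistency loss sits fifty times lower.

The rheology workflow is symmetric:

```r
truth <- fm_params(kappa = 2.0, eta = 0.8, mu = 0.7, nu = 0.2)
series <- generate_fm_dataset(truth, eps0 = 1)          # 200 samples, 10 s
fit <- fit_fractional_maxwell(series,
                              cfg = train_config(iterations = 40000, seed = 1),
                              truth = truth)
unlist(fit$rel_err)
#>       kappa         eta          mu          nu          gt
#> 0.008391881 0.028221722 0.005370378 0.020795718 0.005439503
```

all four parameters and the predicted relaxation modulus within 3% — the
regime reported for tissue-rheology calibrations of this model. From a CSV
(`time,stress,strain[,G_ref]`), use `predict_relaxation_workflow()` or the
CLI (`fracpinn fit-maxwell --in series.csv --out results/`).

## Layout

- `R/caputo.R`, `R/mittag_leffler.R` — discrete fractional operators, special functions
- `R/forward_models.R`, `R/tfde_solver.R`, `R/fm_generator.R`, `R/noise.R` — physics and synthetic data
- `R/autodiff.R`, `R/mlp.R`, `R/train.R` (+ `src/kernels.cpp`) — the training engine
- `R/pinn_diffusion.R`, `R/pinn_maxwell.R` — the two inverse solvers
- `R/experiments.R`, `R/cli.R`, `R/io.R` — experiment harness, CLI, file formats
- `vignettes/fractional-pinn-methods.Rmd` — models, assumptions, numerical choices, limitations
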