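---
title: "Inferring fiber-scale viscoelasticity from fascicle observations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring fiber-scale viscoelasticity from fascicle observations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fasciclefit)
```

## The problem

Tendons are hierarchical composites: fascicles (hundreds of micrometers)
are bundles of helically wound fibers (micrometers) embedded in a soft
non-collagenous matrix.  Mechanical experiments are feasible at the
fascicle scale -- elastic moduli, lateral contraction (Poisson's ratio),
and stress-relaxation curves -- but the design of fiber-based tissue
scaffolds needs the *fiber-scale* properties: the fiber elastic modulus
$E_f$, the effective viscosity of the embedded fibers $\eta_f$, and the
matrix modulus $E_m$.  None of these can be measured directly with useful
certainty.  `fasciclefit` treats them as a Bayesian inverse problem:
propagate candidate fiber-scale parameters through a forward model of the
fascicle, and score them against the fascicle-scale observations.

## Forward model

A fascicle model class fixes the geometry: the fiber area content $f_r$
and the helix angle $\theta$ (degrees from the plane perpendicular to the
tendon axis).  The study grid is $f_r \in \{0.35, 0.40, \dots, 0.65\}$ and
$\theta \in \{70, \dots, 76\}^\circ$, 49 classes
(`fascicle_classes()`).

Given a class, three observables are predicted from the parameter vector
$(E_f, \eta_f, E_m, r_\infty, \sigma_n)$:

* **Initial elastic modulus.**  The fascicle modulus at $t = 0$ uses a
  rule-of-mixtures surrogate
  $E_{fasc}^0 = f_r E_f\, g(\theta) + (1 - f_r) E_m$ with $g \equiv 1$.
  A full helical finite-element homogenization would resolve the angle
  dependence; the plain mixture reproduces the reported most-probable
  moduli at the content extremes to within a few percent, while simple
  angle penalties (powers of the cosine of the axial angle) overshoot.
  The angle factor `g` is an explicit function argument, so a richer
  elastic model can be plugged in without touching the inference
  machinery.  The price of $g \equiv 1$ is that the modest
  ($\sim$150 MPa) angle spread of the reported MAP surfaces is not
  reproduced.

* **Stress relaxation.**  Fibers follow a standard linear solid with a
  single viscosity: an equilibrium spring $E_\infty = r_\infty E_f$ in
  parallel with a Maxwell arm of modulus $E_R = (1 - r_\infty) E_f$ and
  viscosity $\eta_f$, giving
  $$E_{fasc}(t) = f_r\left(E_\infty + E_R\,
    e^{-(E_R/\eta_f)\,t}\right) + (1 - f_r) E_m,$$
  a single-exponential decay with time constant $\tau = \eta_f / E_R$.
  The matrix term is held constant in time: its stiffness is two orders of
  magnitude below the fibers', so fiber relaxation dominates the fascicle
  response.  The normalized curve is $\bar E(t) = E_{fasc}(t)/E_{fasc}(0)$.
  The retained fraction $r_\infty$ is a first-class inferred parameter:
  the three-vector $(E_f, \eta_f, E_m)$ alone cannot fix the relaxation
  asymptote, so the split of $E_f$ into $E_\infty$ and $E_R$ must either
  be inferred (the default, uniform prior on $[0.05, 0.95]$) or pinned
  from each curve's plateau by the user.

* **Poisson's ratio.**  Fascicle-scale lateral contraction ratios well
  above the isotropic bound (values of 1 up to 3 are reported) arise from
  the helical architecture combined with the extreme fiber/matrix
  stiffness contrast.  The package uses a closed-form surrogate
  $$\nu = \nu_m + \frac{\nu_h - \nu_m}{1 + \kappa x}, \qquad
    \nu_h = \cot^2(90^\circ - \theta), \quad
    x = \frac{E_m}{E_f}\,\frac{1 - f_r}{f_r},$$
  which interpolates between the near-incompressible matrix value
  $\nu_m = 0.5$ (stiff-matrix limit) and the inextensible-helix kinematic
  limit $\nu_h$ (rigid-fiber limit, e.g. $\cot^2 15^\circ \approx 13.9$ at
  $\theta = 75^\circ$).  It is a surrogate, not a homogenization result:
  its contract is the qualitative physics (strictly decreasing in $E_m$,
  strictly increasing in $\theta$, bounded by its two limits), and the
  blending constant $\kappa = 4\times10^4$ is calibrated once so that a
  fascicle Poisson value of 1 maps to a matrix modulus of a few tenths of
  an MPa at the study's reference class, consistent with the reported
  posterior location.  Tests assert only the contract, not surrogate
  values.

## Statistical model

All five parameters carry independent uniform priors on a closed box.
The physical bounds encode prior ignorance spanning the experimental
literature: $E_f \in [500, 2500]$ MPa, $\eta_f \in [0.1, 2500]$ GPa s,
$E_m \in [0.01, 5]$ MPa.  The two auxiliary parameters use
$r_\infty \in [0.05, 0.95]$ and $\sigma_n \in [0.001, 0.3]$.

Observations are modeled with a proportional error: datum $D_i$ is
Gaussian with mean $F_i$ (the forward prediction) and standard deviation
$\sigma_n F_i$, i.e. variance $\sigma_n^2 F_i^2$ -- measurement
uncertainty in this setting scales with the measured quantity, and a
single relative error scale can then be shared across observables of
entirely different magnitudes (moduli in hundreds of MPa, ratios of order
one).  One $\sigma_n$ is shared by all blocks and every datum carries
equal weight; per-block error scales would be a straightforward
extension but are deliberately not the default.  The likelihood of a
dataset is the product over its replicate elastic moduli (against $q_1$),
its Poisson value (against $q_2$) and its $\sim$30 relaxation points
(against $q_3$).  An `observables` flag restricts the blocks, so
elastic+relaxation-only inferences are reproducible independently of the
Poisson surrogate.

## Sampling: Transitional MCMC

`run_tmcmc()` anneals from the prior to the posterior through tempered
targets $p(\varphi)\,L(\varphi)^{p_j}$, $0 = p_0 < \dots < p_m = 1$.
Each stage chooses the largest admissible exponent step by bisection so
that the coefficient of variation of the plausibility weights stays at
the target (default 1.0), multinomially resamples, and applies a few
Metropolis-Hastings steps with Gaussian proposals whose covariance is
$\beta^2$ (default $\beta = 0.2$) times the weighted ensemble covariance.
The product of stage-mean weights estimates the model evidence
$p(D|M)$.

Two numerical choices deserve a note:

* **Chain length per stage.**  The default is 5 MH steps per sample per
  stage.  With a single step the resampled ensemble does not equilibrate
  at the new tempering level and the final ensemble retains a memory of
  the prior: on recovery fixtures the $E_f$ marginal came out several
  times too wide and shifted toward the prior bulk, and 95% intervals
  covered the truth only half the time.  Five steps are indistinguishable
  from eight or twelve on those diagnostics at negligible cost, so five
  is the default; it remains configurable.
* **Degeneracy guards.**  The proposal covariance carries a $10^{-10}$
  diagonal jitter; proposals leaving the prior box are rejected
  (equivalent to the $-\infty$ prior), not reflected; acceptance rates
  outside $[0.05, 0.95]$ emit a diagnostic message, not a failure.

The MAP estimate is the best retained sample, polished by a bounded
derivative-free search (Nelder-Mead with a steep finite penalty outside
the prior box; Brent in one dimension) that is accepted only if it
improves the log posterior.  Central 95% credible intervals come from the
final equally-weighted ensemble.  The MAP of a skewed posterior may
legitimately sit outside a central interval, so the grid table asserts
only interval ordering, never MAP containment.

Sampler validity is established on analytic targets rather than on the
application: exact evidence under a constant likelihood, moments and
evidence of a truncated Gaussian against closed forms over repeated
seeds, and a well-separated bimodal mixture in which both modes must
survive to the final ensemble with the evidence checked against grid
quadrature.

## Synthetic data and fixtures

No machine-readable relaxation curves accompany the study -- they exist
as figures only -- so `generate_dataset()` emulates the observation
process from a known ground truth: forward predictions at equally spaced
times, multiplied by $1 + \varepsilon$ noise with
$\varepsilon \sim N(0, \sigma_{gen}^2)$, exactly the structure the
likelihood assumes.  Noisy relaxation points are clipped into $(0, 1]$
but never re-monotonized; noise is the likelihood's job, not the data's.
What the generator does *not* emulate -- drift, preconditioning
transients, strain-rate dependence, correlated digitization error --
bounds what passing recovery tests can show: they validate the inference
machinery under its own assumptions, not the adequacy of the
standard-linear-solid model for real tendon.

`fixture_suite()` ships five datasets mirroring the study's structure:
every elastic block is the three reported fascicle moduli
$\{640, 480, 550\}$ MPa verbatim, the Poisson value is 1 except for the
second dataset (3), and the relaxation curves are generated from
versioned ground truths (fiber modulus 1400 MPa, viscosities 42-82 GPa s,
retained fractions 0.35-0.50, horizons 300-500 s) chosen once so that
every truth curve loses between 40% and 70% of its initial modulus over
its horizon -- the experimentally reported envelope.  The first two
datasets share one curve, as the corresponding study groups share one
relaxation experiment.  Ground truths are recorded in each dataset for
recovery testing.

## Problem sizes and reproducibility

The default sampler size is 1000 samples per stage; a five-parameter fit
of one dataset converges in 9-16 stages, well under a second.  The test
suite's recovery study uses 20 replicates at the reference truth
($E_f = 1400$ MPa, $\eta_f = 42$ GPa s, $E_m = 0.4$ MPa,
$r_\infty = 0.4$, 5% noise); measured mean absolute MAP errors are about
3% ($E_f$), 6% ($\eta_f$) and 10% ($E_m$), with 95%-interval coverage of
85-100% per parameter.  Every stochastic path is seed-controlled:
`tmcmc_control(seed = )` fixes a fit bit-for-bit, and grid runs derive a
deterministic per-cell seed from a master seed and the cell coordinates,
so sequential and (hypothetically concurrent) cell execution give
identical results.

```{r example, eval = FALSE}
truth <- material_params(1400, 42, 0.4, retained_fraction = 0.4,
                         error_scale = 0.05, viscosity_unit = "GPa.s")
cls <- fascicle_class(0.35, 75)
d <- generate_dataset(generator_spec(truth, cls, seed = 1), "demo")
fit <- fit_fascicle(d, cls, control = tmcmc_control(1000, seed = 1))
summary(fit)
plot(fit)
```

## Known limitations

* The elastic and Poisson surrogates are closed-form stand-ins with
  pinned constants, contract-tested on limits and monotonicity; MAP
  surfaces over the angle grid inherit their simplifications.
* A single relaxation time: multi-exponential spectra, strain-rate and
  strain-magnitude effects are out of scope, as is any geometric or
  material nonlinearity.
* The likelihood treats all data as independent; digitized curve points
  in real use would violate that mildly.
* Model evidence is reported per class but not used for model averaging
  or selection across the 49-class grid.
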