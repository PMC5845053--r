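---
title: "Population pharmacokinetics of dexmedetomidine infusions: model, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population pharmacokinetics of dexmedetomidine infusions: model, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dexpoppk)
```

## The problem and the model

Dexmedetomidine is given to mechanically ventilated ICU patients as a
continuous, weight-scaled intravenous infusion whose rate is titrated to
sedation depth. Arterial concentrations collected during and after such
infusions are sparse and unbalanced, so the natural analysis framework is a
population (nonlinear mixed-effects) model. This package implements that
analysis end to end: disposition model, estimation engine, covariate
screening, bootstrap uncertainty, and prediction-corrected visual
predictive checks, together with a synthetic-cohort generator that
reproduces the study design the package targets, so the whole pipeline can
be validated by simulation.

Disposition follows a two-compartment model driven by the infusion rate
$In(t)$ (micrograms/hour):

$$V_C \frac{dC_P}{dt} = In(t) - CL\,C_P - Q\,C_P + Q\,C_T, \qquad C_P(0)=0$$
$$V_T \frac{dC_T}{dt} = Q\,C_P - Q\,C_T, \qquad C_T(0)=0$$

with systemic clearance $CL$, inter-compartmental clearance $Q$, and
central/peripheral volumes $V_C$, $V_T$. Units are fixed package-wide:
doses in micrograms, volumes in litres, time in hours, concentrations in
micrograms/litre (numerically equal to ng/mL), so typical published
estimates plug in without conversion.

Between-subject variability is lognormal per parameter,
$P_i = \theta_P e^{\eta_{P,i}}$ with $\eta_{P,i} \sim N(0, \omega_P^2)$
(diagonal $\Omega$), and the residual model is proportional,
$C_{obs} = C_P (1 + \varepsilon)$ with $\varepsilon \sim N(0, \sigma^2)$.
An additive residual option exists mainly so that estimation can be
validated on analytically tractable sub-models.

## Closed-form disposition

Concentrations under an arbitrary piecewise-constant infusion schedule are
evaluated analytically: the two eigenvalue magnitudes
$\lambda_1 > \lambda_2 > 0$ of the disposition matrix satisfy
$\lambda_1\lambda_2 = k_{10}k_{21}$ and
$\lambda_1+\lambda_2 = k_{10}+k_{12}+k_{21}$
($k_{10}=CL/V_C$, $k_{12}=Q/V_C$, $k_{21}=Q/V_T$), and each constant-rate
segment contributes a two-exponential step response; the profile is the
superposition over segments and is exactly linear in the rates. Numerical
care: `expm1` is used for $1-e^{-\lambda\tau}$, the washout contribution is
rearranged so every term is non-negative (no catastrophic cancellation deep
in the washout), the smaller eigenvalue is computed from the product
identity, and a series/limit branch handles a near-degenerate eigenvalue
pair (relative gap below $10^{-9}$, reachable only in pathological
parameter corners). Requested times exactly at a segment boundary evaluate
the (continuous) solution there; only the derivative jumps.

An independent oracle integrates the same ODE system with `deSolve::lsoda`,
restarted at every segment boundary so the stepper never straddles a rate
discontinuity; closed form and oracle agree to within $10^{-8}$ relative
down to concentrations four orders of magnitude below the peak (beyond
that, the comparison is limited by the integrator's own accumulated error,
not by the analytic solution).

```{r closed-form}
p <- disposition_params(CL = 38.5, VC = 27.0, Q = 46.4, VT = 87.6)
s <- infusion_schedule(c(0, 24), c(24, 42), 75 * c(0.8, 0.5))
predict_concentrations(p, s, c(1, 8, 24, 42, 42.5, 44))
hybrid_constants(p)
```

## Estimation

The marginal likelihood integrates the random effects out of each
subject's contribution; the package approximates it with FOCE-with-
interaction (default) or a Laplace approximation. Both are built on the
same inner problem: minimizing the per-subject joint
$-2[\log p(\mathrm{dv}\mid\eta) + \log p(\eta)]$ over $\eta$. The inner
solver is Fisher-scoring Newton with backtracking line search and a
trust-region-style step cap, followed by exact-Hessian polishing steps that
drive the mode to machine accuracy. The polishing matters: the FOCE
objective is first-order sensitive to the linearization point, and solving
the inner problem only approximately leaves noise on the outer objective
that breaks finite-difference gradients. With polished modes the outer
objective is smooth and is minimized with `nlminb` in transformed space
($\log\theta$, $\log\omega^2$, $\log\sigma^2$; covariate coefficients
unconstrained), a cheap restart pass, and a terminal coordinate-probe check
that declares convergence only if no direction offers a meaningful descent.

Conventions, fixed for reproducibility:

* The OFV is $-2\log L$ *including* all $2\pi$ constants. Only
  differences between nested models matter for selection, but the absolute
  convention is documented and stable.
* Inter-individual variances are reported on the percent-CV scale using the
  exact lognormal CV, $100\sqrt{e^{\omega^2}-1}$; the first-order
  convention $100\sqrt{\omega^2}$ is also emitted. Residual error is
  reported as $100\sqrt{\sigma^2}$. Whenever the package both simulates and
  recovers a variability value, one convention is applied on both sides.
* Inner gradient tolerance $10^{-8}$ (then polished), outer relative
  tolerance $10^{-8}$.
* Default initial estimates are literature-magnitude dexmedetomidine
  values ($CL$ 39 L/h, a steady-state distribution volume of ~120 L split
  30/90 between $V_C$ and $V_T$, $Q$ 40 L/h), with initial variances of
  0.3 (about 59 %CV) and residual variance 0.04. The deliberately *high*
  initial variances reflect ICU-population variability; starting far below
  the true variability can steer the optimizer into a local optimum that
  trades central volume against distribution clearance. All initial values
  are user-overridable.

Standard errors come from the numerically differentiated Hessian of the
OFV at the optimum on the natural reporting scale
(covariance $= 2 H^{-1}$); a non-positive-definite Hessian yields missing
standard errors with a warning, never fabricated values. Shrinkage is
$100(1 - \mathrm{SD}(\hat\eta_P)/\omega_P)$ with the population
($n$-denominator) SD.

The engine was validated three ways: (i) on a log-linear sub-model with
additive error — a case linear and Gaussian in $\eta$ — FOCE, Laplace, a
41-node adaptive Gauss–Hermite oracle and the closed-form marginal
likelihood agree to $10^{-6}$; (ii) on a nonlinear one-random-effect PK
toy, the Laplace value tracks direct adaptive quadrature of the marginal
integral; (iii) compiled and reference R implementations of the same
approximations agree on simulated cohorts.

## Synthetic cohorts

The generator emulates the targeted study design: 27 subjects by default
(22 on a short sampling protocol, 5 on an extended one), weight 45–100 kg
(median 75), age 19–84 y (median 59.5), SOFA 5–16, infusion started at
0.8–1.0 μg/kg/h and maintained at 0.4–1.5 μg/kg/h with 0–3 recorded step
adjustments at random times, infusion durations 23.7–102 h (median ~43),
and sampling anchored to infusion start and stop exactly as in the two
protocols, with during-infusion samples beyond the actual stop dropped.
The generating model defaults to the published final estimates. Weight and
age use truncated normal distributions and duration a truncated lognormal,
calibrated to the reported medians and ranges — the published summary gives
only median and range, so the distributional shape is a declared
assumption, recorded in the configuration.

Two deliberate generator choices: pre-dose samples (true concentration
exactly zero) are emitted as missing-DV rows, because a proportional-error
likelihood is undefined at zero predictions and the study design implies
such samples carry no quantifiable drug; and simulated observations
falling below the assay's lower limit of quantification (0.05 ng/mL) are
likewise flagged missing, mirroring a dataset in which no below-LLOQ
measurement entered the analysis. Without the LLOQ floor, a handful of
deep-washout observations (10⁻³ ng/mL and below) make the subject-level
posterior bimodal and the proportional-error likelihood pathological —
conditions the original data could not contain.

What passing the simulation-based tests does *not* show: the generator
draws covariates independently (no weight–age correlation), keeps rates
constant between recorded adjustments, uses pretreatment SOFA only, and
contains no model misspecification — so parameter recovery demonstrates
the estimator is consistent under the design, not that the model is
correct for any real dataset.

## Covariate search

Screening admits only parameters whose $\eta$-shrinkage is strictly below
25% — above that, empirical Bayes estimates are too shrunken to carry
covariate information. Candidates are tested by stepwise forward selection
(include if the OFV drops by more than 3.84, the $\chi^2_1$ 5% point)
followed by backward elimination (retain only if removal costs more than
6.63, the 1% point). The published threshold notation is read in the
standard sense: inclusion requires the OFV drop to *exceed* 3.84 — the
literal opposite reading would select everything and contradict the stated
significance level. Continuous covariates are tried as both linear
($\theta(1+\beta(x-x_{ref}))$) and power ($\theta(x/x_{ref})^\beta$)
forms, the better form competing for inclusion; binary covariates enter
through indicator terms. Reference values default to in-sample medians so
$\theta$ remains the typical-patient value. Exact OFV ties are broken by
candidate order (parameters $CL, V_C, V_T, Q$; covariates as listed in the
configuration). Candidate fits that fail to converge are skipped and
logged, and every tested fit appears in the exported trace. Calibration is
verified by simulation: with a single null candidate tested at the 3.84
threshold, the inclusion rate over 200 scaled-down replicates sits inside
the binomial 95% band around 5%, and the 95th percentile of the
likelihood-ratio statistic falls in [3.3, 4.4].

## Bootstrap

Uncertainty uses the nonparametric case bootstrap: whole subjects
resampled with replacement at the original cohort size, each replicate
refitted from the base-model optimum (mirroring common practice and
reducing replicate failures), with 90% percentile intervals (5th–95th)
over converged replicates only. "Terminated early" maps to optimizer
non-convergence, a non-finite OFV, or a variance collapsing to the
boundary (below $10^{-4}$, i.e. 1 %CV); each failure is counted with its
reason, and a result with more than half of the replicates failing is
flagged unreliable. Resampled subjects enter under fresh ids; resampling
is unstratified by default with optional stratification by any
subject-level variable (e.g. sampling protocol).

## Prediction-corrected VPC

Because dosing is weight-scaled, titrated, and of variable duration,
concentrations from different subjects at the same time are not
comparable; the VPC therefore rescales observed and simulated values alike
by (bin reference population prediction)/(own population prediction).
The bin reference is the median population prediction by default — the
robust choice — with the mean selectable; the choice is recorded in the
output metadata. Correction uses population predictions (random effects at
zero), not individual predictions. Binning is quantile-based equal-count
across time with 10 bins by default (the bin count is a configurable
choice; nominal-time snapping is available when sampling times are close
to protocol times), bin assignments are computed once from observed times
and shared by observed and simulated values, and bins with fewer than
three observations are flagged. Summaries track the 10th, 50th and 90th
percentiles with 95% simulation bands. Calibration was checked by
simulating cohorts from the generating model and confirming the observed
percentiles fall inside their bands in well over 90% of bins on average,
and that pooling sub-cohorts dosed at very different rates still overlays
after correction — the property that motivates prediction correction.

## Problem sizes and numerical choices

The validation suite exercises the pipeline at deliberately chosen scales:
parameter recovery uses 20 cohorts of 100 subjects under the study design
(about 1,500 observations per cohort), large enough that median recovery
errors are dominated by estimator properties rather than Monte-Carlo
noise; covariate-search calibration uses 200 replicates of a 20-subject
one-compartment design, where each replicate needs two full fits and a
1-df likelihood-ratio test is exact enough to audit; the VPC calibration
uses 200 simulation replicates per cohort. Degenerate inputs are handled
explicitly: zero-variance random effects are pinned rather than estimated,
a zero-rate schedule yields identically zero concentrations, empty
candidate sets return the base model, and bins that cannot be filled are
collapsed with a warning.

## Known limitations

* Diagonal $\Omega$ only; correlated random effects are out of scope.
* No below-LLOQ likelihood (M3-style) handling; the targeted design
  reported no quantifiable censoring.
* No inter-occasion variability and no time-varying covariates
  (pretreatment SOFA only).
* FOCE-I carries the usual approximation bias at very high variability and
  very sparse designs; the Laplace option is exposed for comparison, and
  small-cohort fits from poor starting values can land in a local optimum
  (the distribution-phase trade-off discussed above) — the default
  initialization is chosen to avoid it under the targeted design. The
  central volume is the concrete casualty: with the first sample an hour
  after the start of infusion (distribution half-life ~12 minutes) and
  ~124 %CV between subjects, the simulation-and-refit experiment recovers
  the typical central volume with an upward bias of roughly a fifth to a
  quarter — partly a property of the exact maximum-likelihood estimator
  under this design (a profile of the exact marginal likelihood, computed
  by importance sampling, already prefers values above the generating one)
  and partly FOCE-I approximation error; Laplace roughly halves the
  excess. Clearance, the peripheral volume, the distribution clearance and
  the variability terms recover well within their expected precision.
* The bootstrap and VPC inherit whatever approximation the chosen
  estimation method carries; they quantify uncertainty, not model
  adequacy beyond the displayed checks.
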