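---
title: "A DAR-resolved semi-mechanistic population PK model for a DM4 antibody-drug conjugate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A DAR-resolved semi-mechanistic population PK model for a DM4 antibody-drug conjugate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darpk)
```

## The model

An antibody-drug conjugate (ADC) is administered as a mixture of species
that differ only in how many payload molecules each antibody carries — the
drug-to-antibody ratio (DAR), here 0 to 8 DM4 molecules attached through a
cleavable SPDB linker. `darpk` implements an integrated model in which
every DAR species is an explicit state:

* **Antibody disposition.** Each species DAR0–DAR8 follows a
  two-compartment model with common central volume $V_c$, peripheral
  volume $V_p$ and inter-compartmental clearance $Q$. Conjugated species
  (DAR $\geq 1$) share one proteolytic clearance $CL_{ADC}$; the naked
  antibody (NAB = DAR0) has its own clearance $CL_{NAB}$.
* **Deconjugation cascade.** Loss of one payload converts DAR$_n$ to
  DAR$_{n-1}$ as an irreversible first-order process in the central
  compartment with rate $k_{dec,n}$. DAR7 and DAR8 circulate at trace
  levels, so $k_{dec,7} = k_{dec,8} = k_{dec,6}$ is imposed structurally.
  Rates increase with payload load (0.0565/day for DAR1 up to 0.938/day
  for DAR $\geq$ 6): highly loaded conjugates are less stable.
* **Payload kinetics.** Every deconjugation event releases one molar
  equivalent of DM4 into a one-compartment pool with apparent clearance
  $CL_{DM4}$ (volume fixed to 1 L); a fraction $FR_{MeDM4}$ of DM4
  elimination forms the S-methylated metabolite MeDM4, eliminated at
  $CL_{MeDM4}$. Because $CL_{DM4}$ is enormous relative to the formation
  rate, both payload species show *formation-limited* kinetics: their
  terminal slope equals the slowest slope of the conjugate cascade, not
  their own elimination rate, and their volumes are not identifiable
  (hence fixed).
* **Dosing.** The administered solution is itself a DAR mixture; the dose
  is fractioned over the nine species by the measured administered
  fractions (mean administered DAR $\approx 3.3$ after renormalizing the
  published fractions, which print to 99.8%).

The 20 molar amounts (9 central, 9 peripheral, DM4, MeDM4) obey a linear
time-invariant system $\dot x = A x + u(t)$ with piecewise-constant
infusion input. `simulate_profile()` solves it *exactly* on each
constant-input segment with the matrix exponential of the augmented
system, in compiled code. Observables follow from the state:
$C_{ADC} = \sum_{i \geq 1} C_{DARi}$, $C_{TAB} = C_{ADC} + C_{NAB}$,
average DAR $= \sum_i i\,C_{DARi} / C_{TAB}$, and per-species relative
proportions.

```{r clearance}
params <- adc_params()   # published typical values
clearance_table(params)  # CL_ADC + kdec_i * V_c per DAR
```

## Stochastic layers

Inter-individual variability is log-normal, $P_i = P_{TV}
e^{\eta_i}$, with one *shared* random effect multiplying all eight
deconjugation rates (the published table reports a single 20.2%
variability spanning the $k_{dec}$ rows; we read that as one $\eta$). The
administered fractions DAR0–DAR7 are perturbed log-normally with the
batch coefficients of variation and DAR8 is back-calculated as one minus
their sum, so each subject's fractions still sum to one; infeasible draws
(negative closure) are rejected and redrawn.

Residual error is entity-specific on the assay scale: combined
$(a + b f)\sigma$ for the ADC concentration (µg/mL), proportional for
DM4, MeDM4 (ng/mL) and NAB, additive for the average DAR and the DAR
relative proportions (percent). Censoring reproduces the assays: 0.500
µg/mL for ADC, 0.2 ng/mL for the payloads, and a concentration-dependent
NAB limit — the NAB assay requires dilution until the co-measured ADC is
below 15 µg/mL, so the base 1 µg/mL limit inflates by the dilution factor
$\lceil C_{ADC}/15 \rceil$ up to the 9.60 µg/mL cap. The exact dilution
ladder of the assay is not public; this ceiling rule is our
reconstruction and reproduces the published 1–9.60 µg/mL range.

## The synthetic-trial generator

`generate_trial()` emulates the first-in-human study the model was built
on: 254 patients across a Q2W dose-escalation arm (5–150 mg/m²), a Q2W
arm with a cycle-1 loading dose, a Q3W arm, and a 100 mg/m² Q2W expansion
arm; body-surface area ~ N(1.8, 0.2²) truncated to [1.2, 2.4] m²; rich
sampling at cycles 1 and 4 (end of infusion, +1, +4, +8 h, days 1, 2, 4,
7, 10 and the trough) and troughs elsewhere; a geometric cycle-count
distribution with median 4 (truncated at 20 cycles); and DAR streams
(average DAR, proportions of NAB and DAR1–DAR7 — DAR8 is never reported)
in a random subset of 13 patients. The published per-dose counts of the
Q3W arm sum to 21 although the arm total is 15; we keep the stated arm
totals (254 patients overall) and allocate the Q3W doses proportionally.
Exact clinical sampling times are not published; the template above is
fixed and versioned so tests are stable.

What the generator does *not* emulate: dose delays and interruptions,
assay drift, inter-occasion variability, covariate structure beyond BSA.
Passing calibration tests on these virtual trials therefore demonstrates
internal consistency of the machinery, not fidelity to every feature of
real clinical data.

Under the default design the generated BLQ shares come out at roughly
1% (ADC), 36% (DM4), 13% (MeDM4) and 31% (NAB), reproducing the ordering
and magnitude of the study's censoring without any tuning — they follow
from the model, the LLOQ rules and the design.

## Estimation

`fit_saem()` implements stochastic approximation EM: per-subject MCMC on
the individual log-parameters (an independence kernel proposing from the
population prior, adaptive vector random-walk kernels, a periodic
componentwise sweep, and a grouped kernel that shifts all $k_{dec}$
components together — the natural slow direction of the posterior given
the cascade), stochastic-approximation sufficient statistics, and exact
M-steps for the log-normal typical values and variances. Censored rows
enter the likelihood through the M3 normal-CDF term and are imputed from
the truncated predictive distribution for the residual-error M-step.
During exploration the omegas may shrink by at most 3% per iteration
(simulated-annealing-style guard against premature collapse).

Two deliberate design choices:

* **Diagonal random-effect covariance.** The generating model shares one
  $\eta$ across the $k_{dec}$; an exact SAEM M-step for six fixed effects
  driven by one random effect is not conjugate, so the estimation model
  gives each estimated parameter its own $\eta$. The shared-effect truth
  is the perfect-correlation special case; the marginal distributions
  coincide and the typical values remain consistent.
* **Fixed fractions.** The administered DAR fractions are fixed at their
  drug-product values during estimation (as in the original analysis) and
  $k_{dec,7}, k_{dec,8}$ stay tied to $k_{dec,6}$, keeping the problem
  identifiable with concentration data plus a small DAR subset.

The estimation hot path solves the system by one eigendecomposition per
parameter proposal rather than per-segment matrix exponentials. The tied
$k_{dec}$ rates make $A$ defective, so they are split by a relative
$10^{-3}$ before decomposing; the induced error is ~$10^{-4}$ relative on
observed streams — far below residual noise — and the solver falls back
to the exact exponential path whenever the eigenvector matrix is
ill-conditioned. The user-facing simulator always uses the exact path.

`population_loglik()` estimates the marginal likelihood by importance
sampling around the empirical-Bayes modes and reports
$OF = -2 \log L$ and $BIC = OF + d \log N$ with $N$ the number of
subjects — the subject-count convention is deliberate and documented
here. `empirical_bayes()` is a gradient-free per-subject MAP.

The default estimation qualification runs SAEM on virtual trials of 100
richly sampled subjects (four Q2W cycles at 100 mg/m², DAR streams in 13
subjects) over five seeds, with initial values displaced by ±40% from the
truth; it checks median recovery of $CL_{ADC}$, $V_c$, $CL_{NAB}$,
$k_{dec,1}$ and $CL_{MeDM4}$. These sizes keep the experiment at desk
scale while leaving each parameter well informed.

## Qualification diagnostics

* `pwres_iwres()`: individual weighted residuals from empirical-Bayes
  predictions, and population residuals decorrelated per subject with the
  mean and Cholesky factor of simulation replicates.
* `pc_vpc()`: prediction-corrected VPC. Observations and simulations are
  multiplied by (median typical prediction in the time bin)/(typical
  prediction at the design point), which collapses the 5–190 mg/m²
  cohorts onto one comparison — exactly what dose-proportionality of a
  linear model promises. Binning is quantile-based (12 bins by default,
  configurable; the original analysis shows cycles 1 and 4, which is the
  `time_range` argument). Censored values are represented at their LLOQ
  symmetrically on both the observed and simulated side, and BLQ counts
  are reported per bin.
* `npde()`: normalized prediction distribution errors with half-rank tie
  breaking and clipping to $(1/2n_{sim}, 1 - 1/2n_{sim})$; BLQ rows are
  excluded.

Both calibration directions are tested: under the true model NPDE are
standard normal and the pc-VPC bands contain the observed percentiles;
under injected misspecification (clearance doubled, variability halved)
both diagnostics flag it.

## Numerical choices

* State order is fixed (DAR0–DAR8 central, DAR0–DAR8 peripheral, DM4,
  MeDM4) so matrices are reproducible bit for bit.
* Default simulation grid: 2000 points per dosing interval with the
  infusion-end kink always on the grid; trapezoidal interval AUCs then
  agree with the closed-form matrix-exponential integral to well under
  0.1% (and the closed form is available as `auc_closed_form()`).
* Terminal half-life is read by log-linear regression over days 90–180
  after a single dose. Every entity receives cascade inflow, so log
  curves approach the terminal asymptote from above; an earlier window
  (e.g. days 35–70) overestimates the ADC half-life by ~3% and the NAB
  half-life by ~30%. Days 90–180 is the earliest window in which all
  four entity regressions are log-linear ($R^2 > 0.999$) and stable, and
  it reproduces the published values; the window is configurable and the
  eigenvalue cross-check `half_life_eigen()` is provided.
* Steady state is declared by the 5% rule against the cycle-50 interval
  AUC, evaluated on the dense grid.
* Average DAR at zero total antibody (pre-dose) is undefined and returned
  as `NA` with a flag — observed DAR exists only post-dose.
* The infusion duration is never published; the default is 1 h,
  configurable. All acceptance-relevant outputs (ratios, half-lives,
  steady-state cycles, average DAR) are insensitive to it and to the
  body-surface-area assumption (default 1.8 m², molar conversion with
  molecular weight 150,000 g/mol; each entity converts with its own
  molecular weight).

## Known limitations

* Nonlinear (target-mediated) elimination, DAR-dependent proteolytic
  clearance, peripheral deconjugation and Weibull-shaped deconjugation
  are deliberately absent — they were evaluated and rejected in the
  original analysis; the parameter container leaves room to add them but
  no code path implements them.
* No covariate modelling and no inter-occasion variability.
* Standard errors of estimates are not computed from a Fisher information
  matrix; a nonparametric bootstrap over subjects can be assembled from
  `fit_saem()` on resampled datasets if needed.
* The absolute exposure scale depends on dose and body-surface area;
  only dose-invariant quantities (ratios, half-lives, steady-state
  cycles, DAR trajectories) are treated as reference outputs.

## A worked profile

```{r profile, fig.width = 6, fig.height = 4}
sim <- simulate_profile(params, adc_regimen(100, 14, 4), n_per_cycle = 400)
autoplot(sim)
plot_dar_average(sim)
```

```{r exposure}
exposure_summary(sim)
```
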