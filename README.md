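# darpk

Semi-mechanistic population pharmacokinetics of a DM4 antibody-drug
conjugate (ADC) with every drug-to-antibody-ratio (DAR) species modelled
explicitly.

## The problem

An ADC is dosed as a mixture of antibody species carrying 0–8 payload
molecules (DAR0–DAR8). In plasma the species interconvert: deconjugation
strips payloads one at a time (DAR*n* → DAR*n*−1), releasing the
cytotoxic payload (DM4), which is rapidly S-methylated to MeDM4. Assays
report the conjugated antibody (ADC, DAR ≥ 1), the naked antibody (NAB =
DAR0), free DM4 and MeDM4, and — in a patient subset — the average DAR
and per-species DAR proportions. Understanding each entity's exposure,
accumulation and variability requires fitting all of these streams with
one mechanistic model. `darpk` is for pharmacometricians who want that
model as tested, scriptable R: simulation, virtual-trial generation,
SAEM estimation with censored-data likelihood, and the standard
qualification diagnostics (pc-VPC, NPDE, weighted residuals).

## The model

Each species DAR*i* has two-compartment disposition (shared V_c, V_p, Q).
Conjugated species share proteolytic clearance CL_ADC and deconjugate in
the central compartment with first-order rates k_dec,i (k_dec,7 = k_dec,8
= k_dec,6 tied); DAR0 has its own clearance CL_NAB. Amounts (nmol) obey

    dA_DARi,c/dt = F_i·rate_in(t) − (CL_ADC/V_c + k_dec,i + Q/V_c)·A_DARi,c
                   + k_dec,i+1·A_DARi+1,c + (Q/V_p)·A_DARi,p
    dA_DM4/dt    = Σ_i k_dec,i·A_DARi,c − (CL_DM4/V_DM4)·A_DM4
    dA_MeDM4/dt  = FR_MeDM4·(CL_DM4/V_DM4)·A_DM4 − (CL_MeDM4/V_MeDM4)·A_MeDM4

with the administered dose split over DAR0–DAR8 by the measured
drug-product fractions. The 20-state linear system is solved exactly by
piecewise matrix exponentials in compiled code. Derived observables:
C_ADC = Σ_{i≥1} C_DARi, C_TAB = C_ADC + C_NAB, average DAR
= Σ i·C_DARi / C_TAB, per-species proportions. Inter-individual
variability is log-normal (one shared effect across all k_dec);
residual error is combined (ADC), proportional (NAB, DM4, MeDM4) or
additive (DAR streams); below-limit observations are handled as censored
(M3), including the concentration-dependent NAB limit (1–9.60 µg/mL).

## Worked example

```r
library(darpk)

params <- adc_params()          # published typical values
clearance_table(params)
#>   dar    proteolytic_cl deconjugation_cl global_cl
#> 1 DAR>=6          0.392            3.16      3.55
#> 2 DAR5            0.392            2.53      2.92
#> 3 DAR4            0.392            1.77      2.16
#> 4 DAR3            0.392            1.15      1.54
#> 5 DAR2            0.392            0.610     1.00
#> 6 DAR1            0.392            0.190     0.582
```

Proteolysis is shared; deconjugation clearance k_dec,i·V_c grows with
payload load, so highly loaded species are cleared ~6× faster than DAR1.

```r
sim <- simulate_profile(params, adc_regimen(100, 14, 50))  # 100 mg/m2 Q2W
exposure_summary(sim)   # columns abridged here
#>   entity auc_tau_cycle1 cmax_cycle1 auc_ratio_to_adc racc_auc ss_cycle
#> 1 ADC           1.68        0.329          1.000        1.43        3
#> 2 DM4           0.00661     0.00208        0.00393      1.19        2
#> 3 MeDM4         0.0579      0.00610        0.0345       1.36        3
#> 4 NAB           0.218       0.0252         0.130        2.90        6
```

Reading: the free payload circulates at ~0.4% of the conjugate's molar
exposure (MeDM4 ~3.5%, NAB ~13%); the conjugate reaches steady state at
cycle 3 with 1.4-fold accumulation, while the naked antibody — fed by
every deconjugation step — accumulates 2.9-fold and needs 6 cycles.

```r
single <- simulate_profile(params, adc_regimen(100, 14, 1),
                           washout_days = 200, n_per_cycle = 600)
terminal_half_life(single, "ADC")   # 8.8 days
half_life_eigen(params, "ADC")      # 8.8 days (eigenvalue cross-check)
terminal_half_life(single, "DM4")   # 8.7 days: formation-limited, not CL_DM4/V
```

A full virtual trial (254 patients, dose escalation + expansion, LLOQ
censoring, DAR subset of 13):

```r
trial <- generate_trial(trial_design(), adc_model(), seed = 1)
blq_summary(trial)
#> ADC ~1% BLQ, MeDM4 ~13%, NAB ~31%, DM4 ~36%  (matches the study's shares)

fit <- fit_saem(trial, init = adc_model())   # SAEM + M3, deterministic per seed
tidy(fit); glance(fit); autoplot(fit)

v <- pc_vpc(trial, fitted_model(fit), entity = "ADC", time_range = c(0, 14))
autoplot(v)
npde_summary(npde(trial, fitted_model(fit)))
```

A thin CLI wraps the same functions
(`inst/exec/darpk.R simulate|generate|fit|vpc|npde|tables`).

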