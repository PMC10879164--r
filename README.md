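# bioagefmd

Biological-age analysis of fasting-mimicking-diet (FMD) interventions:
Klemera–Doubal (KDM) biological age from seven clinical chemistry
biomarkers, Gompertz proportional-hazard mortality models for life
expectancy and 20-year (cause-specific) mortality risk, trial statistics,
and a lifecourse microsimulation of annual FMD use — all exercised
end-to-end on synthetic reference and trial cohorts with known ground
truth.

## Who this is for

Biostatisticians and epidemiologists who want a tested, reusable
implementation of the biological-age → mortality-risk → intervention
analysis chain: estimating a composite biological age from routine
clinical chemistry, converting it into survival quantities, quantifying a
paired pre/post intervention effect (with and without weight adjustment),
and projecting repeated annual intervention use over the lifecourse.

## The core quantities

**KDM biological age.** With each biomarker linear in age in a reference
population (`x_j = q_j + k_j age`, residual scale `s_j`),

```
BA_EC = [ Σ_j (x_j − q_j) k_j / s_j² + CA / s_BA² ]
        / [ Σ_j (k_j / s_j)² + 1 / s_BA² ]
```

a precision-weighted mean of the marker-implied ages and chronological
age CA. A person lying exactly on every line scores `BA_EC = CA`.

**Gompertz proportional hazards.** Hazard `h(t) = λ e^{γt}` with
`λ = exp(β_Age·Age + β_BioAge·BioAge [+ β_Weight·Weight] + const)` and
survival `s(t) = exp{(λ/γ)(1 − e^{γt})}`. Median remaining life
expectancy solves `s(t) = 0.5`; 20-year mortality risk is `1 − s(20)`;
cause-specific models treat other causes as censored.

**FMD lifecourse simulation.** Two published response surfaces drive each
simulated year — the change over three FMD cycles,
`0.1017 − 0.1906·BioAge + 0.1227·Age`, and the rebound,
`0.6687 − 0.5567·BioAge_A + 0.4008·BioAge_C + 0.1157·Age` — iterated to
age 70 with optional effect decay, coefficient-uncertainty draws, and
survey-weighted draw selection (weight / 548.5, rounded). The composed
one-year map is affine with fixed-point slope ≈ 0.680 years of biological
age per chronological year.

## Worked example

```r
library(bioagefmd)
rep <- run_pipeline(pipeline_config(seed = 1))
print(rep)
#> FMD biological-age analysis report
#>  reference n = 4000, trial n = 52, seed = 1
#>                               quantity      value
#>           median bioage change (years) -2.1394282
#>             mean bioage change (years) -2.1463840
#>                    non-responder count  8.0000000
#>                 non-responder fraction  0.1538462
#>            mean median-LE gain (years)  1.5612945
#>  all-cause risk relative reduction (%)  4.5000000
#>
#> 20-year mortality risks (cohort means):
#>            cause risk_baseline_pct risk_followup_pct relative_reduction_pct
#>              all         43.043217         41.089929                    4.5
#>            heart         31.649121         29.639584                    6.3
#>           cancer         29.412244         28.068417                    4.6
#>  cerebrovascular         13.312565         11.647729                   12.5
#>         diabetes          7.475522          6.287892                   15.9
#>            other         28.572056         26.651843                    6.7
```

The pipeline generated a 4000-person synthetic reference population, fit
the seven KDM marker regressions and `s_BA²` on it, built a 52-person
paired trial cohort with a −2.5-year biological-age intervention effect,
scored both time points, fit all-cause and cause-specific Gompertz
models, and compared survival quantities at baseline vs follow-up. The
median scored change (−2.1 years here) fluctuates around the −2.5-year
construction at n = 52; 8 of 52 participants show increased biological
age (non-responders, driven by measurement noise); the rejuvenation
translates into a 1.6-year mean gain in median life expectancy and a 4.5%
relative reduction in mean 20-year all-cause mortality risk under the
synthetic cohort's fitted mortality model.

Individual pieces are plain functions, e.g.:

```r
params <- kdm_parameters(k = c(m1 = 1, m2 = -2), q = c(m1 = 10, m2 = 100),
                         s = c(m1 = 5, m2 = 10), s_ba2 = 25)
kdm_bioage(data.frame(m1 = 65, m2 = 0), ca = 50, params)
#>      ba_ec ca    delta
#> 1 51.66667 50 1.666667

relative_reduction(2.30, 1.90)   # baseline vs follow-up risk, percent
#> [1] 17.4

traj <- simulate_person(40, 45, sim_config(horizon = 70, draws = 1))
head(traj$bioage_d)               # steep early decline, then ~0.68/yr
#> [1] 38.28413 34.69592 32.91272 32.17120 32.03084 32.23742
```

See `vignettes/bioage-fmd-methods.Rmd` for the models, assumptions,
parameter choices and limitations.

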