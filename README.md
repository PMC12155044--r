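# serorate

Estimate **seroincidence** — the rate λ at which new infections occur per
person-time — from a **single cross-sectional quantitative antibody
survey**, without a longitudinal cohort and without dichotomizing titres
into seropositive/seronegative.

The package is aimed at seroepidemiologists working with quantitative
assays (e.g. ELISA responses to the hemolysin E antigen in enteric-fever
surveillance) who have, for each antigen–antibody-isotype pair:

1. **Seroresponse parameters** — posterior draws of a two-phase within-host
   kinetics model (baseline `y0`, peak `y1`, time-to-peak `t1` days, decay
   rate `alpha`, decay shape `r`), previously fitted to longitudinal data
   on confirmed cases;
2. **Noise parameters** — biologic noise level `nu`, assay CV `eps`, and
   quantification limits `y_low`, `y_high`;
3. **Cross-sectional survey data** — subject `id`, `age` (years),
   `antigen_iso`, quantitative `value`, plus any stratification covariates.

## The model in brief

Antibodies rise log-linearly to a peak at `t1` and then decay as
`dy/dt = −α yʳ`. Exposure is a Poisson process with constant rate λ, so the
time τ since a subject's most recent seroconversion is exponential,
truncated at age, with an atom `exp(−λa)` on "never infected". A measured
value is

    Y = (y(τ) + B) · E,   B ~ Uniform(0, ν),   E ~ LogNormal(mean 1, CV ε),

with `y(τ) = 0` for never-infected subjects, and values outside
`[y_low, y_high]` interval-censored. The per-observation density

    p(y | λ, a) = e^{−λa} p(y | 0) + ∫₀ᵃ λe^{−λτ} (1/K) Σₖ p(y | f_{θₖ}(τ)) dτ

mixes over the K kinetics draws; log-likelihoods add across biomarkers
(independence assumption), and λ is estimated by bounded maximum likelihood
on log λ with analytic derivatives (Wald or profile CIs on the log scale).
A full generative simulator mirrors the same observation model, so every
stage is testable without external data. Details: the methods vignette,
`vignettes/seroincidence-methods.Rmd`.

## Worked example

```r
library(serorate)

# a synthetic two-biomarker survey with known rate 0.25/person-year
cfg <- sim_config(lambda = 0.25, n_subjects = 800, seed = 12)
pop <- simulate_pop_data(cfg)

est <- est_seroincidence(pop, cfg$sr_params, cfg$noise_params,
                         antigen_isos = c("HlyE_IgG", "HlyE_IgA"))
est
#> Seroincidence estimate
#>   biomarkers: HlyE_IgG + HlyE_IgA
#>   rate: 250.7 per 1000 person-years (95% CI 235.3-267.2)
#>   se(log lambda) = 0.0324; n = 800 subjects, 1600 observations

pop$agecat <- ifelse(pop$age < 8, "0-8", "8-15")
summary(est_seroincidence_by(pop, cfg$sr_params, cfg$noise_params, "agecat"))
#>   agecat      antigen_isos rate_per_1000py ci_low_per_1000py ci_high_per_1000py ...
#> 1    0-8 HlyE_IgG+HlyE_IgA        253.3541          230.6439           278.3004
#> 2   8-15 HlyE_IgG+HlyE_IgA        248.5679          228.0074           270.9824
```

The printed rate is λ̂ × 1000 in events per 1000 person-years; the interval
is `exp(log λ̂ ± 1.96 · se)`. Here the true simulated rate (250 per 1000
person-years) is recovered within sampling error, overall and within each
age stratum.

With real data the three inputs come from CSV files instead:

```r
pop   <- read_pop_data("pop_data.csv")
sr    <- read_sr_params("sr_params.csv")        # time_unit = "year" converts
noise <- read_noise_params("noise_params.csv")
validate_inputs(pop, sr, noise)
est_seroincidence(pop, sr, noise, c("HlyE_IgG", "HlyE_IgA"))
```

A command-line interface wraps the same functions
(`exec/serorate simulate|validate|estimate|estimate-by|summarize`); every
run writes a `run_config.json` provenance record.

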