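# smokehia

Dynamic multistate health impact assessment of tobacco-control scenarios.

Public-health agencies need to know not just how many deaths smoking causes
but how policy would change the number of years people live *without
disability*. `smokehia` answers that question with a dynamic multistate
life-table model: it estimates never/current/former smoking prevalence and
disability inputs from survey microdata, derives the net transition
probabilities that hold smoking prevalence stationary, projects the
population thirty years forward under counterfactual scenarios ("what if all
smokers quit?", "what if nobody starts before 18?"), and reports life
expectancy (LE), healthy life years (HLY) and unhealthy life years (ULY)
differences against a business-as-usual reference. It is aimed at
epidemiologists and health-economics modellers who want a transparent,
fully-testable implementation of this pipeline on their own (or synthetic)
inputs.

## The model

Three smoking states k ∈ {never, current, former} on a one-year age grid
0–95 (95 open-ended), fully stratified by sex:

* **Prevalence smoothing.** Fractional-polynomial logistic fits (powers
  from {−2, −1, −0.5, 0, 0.5, 1, 2, 3}, degree ≤ 2) of each state against
  age, internally normalized so p_never + p_current + p_former = 1 at every
  age.
* **Mortality partition.** With relative risks RR_k of death
  (RR_never = 1), q_never = q / (p_n + p_c·RR_c + p_f·RR_f) and
  q_k = RR_k·q_never, so the mixture reproduces baseline mortality exactly.
* **Net transitions.** Start / quit / restart probabilities solved per age
  step so that, combined with state-specific mortality, the age-specific
  smoking prevalence is *stationary* over calendar time — the defining
  assumption of the reference projection.
* **Disability linkage.** Given overall disability prevalence π(a,s) and
  odds ratios OR_k, the baseline log-odds β₀ solves
  Σ_k p_k · logit⁻¹(β₀ + log OR_k) = π (bisection, 1e-12); state-specific
  disability d_k honors the ORs exactly and mixes back to π.
* **Projection.** Partial microsimulation — stochastic smoking histories
  over 2500 individuals per age class and sex (480,000 total), deterministic
  fractional survival weights — with an exact deterministic recursion as
  oracle and fast path; common random numbers across scenarios.
* **Summary.** Sullivan (period) and cohort LE = Σ L(a)/l(a₀),
  ULY = Σ L(a)·π(a)/l(a₀), HLY = LE − ULY, with mid-interval deaths and the
  95+ class closed by 1/m.

Nine scenarios are built in: `reference`, `smoking_free`, `zero_restart`,
`all_quit`, `zero_restart_all_quit`, `low_prevalence`, `no_init_under_18`,
`quit_x1_3`, `quit_x2`.

See `vignettes/tobacco-hia-methods.Rmd` for assumptions, conventions and
numerical choices.

## Worked example

The `analysis/` directory is a numbered workflow over the package (run each
from the repository root). Step 1 writes a complete synthetic input set,
step 2 estimates the model inputs from the survey microdata:

```sh
$ Rscript analysis/01_synthesize_inputs.R
wrote 7 input files to results/inputs
survey: 200000 records aged 15-95; current smokers 15.7%, disabled 14.4%
population: 9413569 persons across 192 age-sex cells

$ Rscript analysis/02_estimate_inputs.R
male FP powers: never {1}, current {1,2}, former {0.5,1}
female FP powers: never {1}, current {0.5,2}, former {1,2}
max |estimated - generating| smoking prevalence, ages 20-80: 0.0059
male ORs (truth): current 1.87 (1.80), former 1.28 (1.30)
female ORs (truth): current 1.94 (2.00), former 1.39 (1.40)
```

The estimated prevalence curves land within 0.006 of the generating truth
and the disability odds ratios within a few percent. Step 3 projects all
nine scenarios and cross-checks the two engines; step 4 prints the headline
table — reference levels in years, scenarios as differences:

```sh
$ Rscript analysis/03_project_scenarios.R
projected 9 scenarios over 2018-2048
reference smoking prevalence drift over 30 years: 9.85e-16
microsim vs deterministic: max |LE gap| 0.017, |HLY gap| 0.019 years

$ Rscript analysis/04_expectancy_tables.R
== male, age 15 ==
              scenario HLY.2028 ULY.2028 LE.2028 HLY.2048 ULY.2048 LE.2048
     reference (level)    52.85     8.23   61.07    52.85     8.23   61.07
          smoking_free     2.66    -0.12    2.55     2.66    -0.12    2.55
          zero_restart     0.64    -0.02    0.61     1.44    -0.12    1.32
              all_quit     0.91    -0.17    0.75     0.89    -0.17    0.72
 zero_restart_all_quit     1.23    -0.15    1.08     1.70    -0.17    1.53
        low_prevalence     0.75    -0.11    0.63     0.75    -0.11    0.63
      no_init_under_18     0.07    -0.04    0.03     0.28    -0.11    0.17
             quit_x1_3     0.09    -0.01    0.08     0.14    -0.02    0.12
               quit_x2     0.26    -0.03    0.23     0.38    -0.06    0.32
```

Reading the table: a 15-year-old man in the synthetic reference population
in 2028 can expect 61.07 more years of life, 52.85 of them disability-free.
A smoking-free population would add 2.66 healthy life years; eliminating
initiation alone (`zero_restart`) gains little by 2028 (0.64 HLY) but
builds to 1.44 HLY by 2048 as protected adolescents reach the harmful ages,
whereas universal cessation (`all_quit`) acts immediately and stays flat —
the combination of the two is the strongest realistic scenario, and ULY
falls in every intervention. The zero drift line confirms stationarity:
under business-as-usual the age profile of smoking never moves.

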