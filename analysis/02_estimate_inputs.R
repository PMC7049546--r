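#!/usr/bin/env Rscript
# Step 2: estimate the model inputs from the survey microdata -- smoothed
# smoking-state prevalence (fractional-polynomial logistic fits, internally
# normalized), overall disability prevalence, and disability odds ratios by
# smoking state -- and compare them with the generating truth.
# Run after 01_synthesize_inputs.R: Rscript analysis/02_estimate_inputs.R

library(smokehia)

survey <- read_survey("results/inputs/survey.csv")
prev <- estimate_smoking_prevalence(survey)
dm <- estimate_disability_model(survey)

dir.create("results/estimates", showWarnings = FALSE, recursive = TRUE)
write_prevalence_table(prev, "results/estimates/prevalence_smoking.csv")
write_rate_table(dm$pi, "results/estimates/prevalence_disability.csv")
write_state_effects(dm$or, "results/estimates/or_disability.csv")

models <- attr(prev, "models")
for (s in c("male", "female")) {
  powers <- vapply(models[[s]], function(m) paste(m$powers, collapse = ","),
                   character(1L))
  cat(sprintf("%s FP powers: never {%s}, current {%s}, former {%s}\n",
              s, powers[["never"]], powers[["current"]], powers[["former"]]))
}

truth <- default_truth()
truth_tab <- truth_prevalence(truth)
sel <- prev$age >= 20 & prev$age <= 80
err <- max(abs(as.matrix(prev[sel, c("never", "current", "former")]) -
                 as.matrix(truth_tab[sel, c("never", "current", "former")])))
cat(sprintf("max |estimated - generating| smoking prevalence, ages 20-80: %.4f\n",
            err))
for (s in c("male", "female")) {
  cat(sprintf("%s ORs (truth): current %.2f (%.2f), former %.2f (%.2f)\n", s,
              dm$or[[s]][["current"]], truth$disability[[s]]$or_current,
              dm$or[[s]][["former"]], truth$disability[[s]]$or_former))
}
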