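#!/usr/bin/env Rscript
# Step 1: generate the full synthetic input-file set (survey microdata,
# population counts, mortality, newborn projection, relative risks and the
# low-smoking alternative prevalence) under results/inputs/.
# Run from the repository root: Rscript analysis/01_synthesize_inputs.R

library(smokehia)

indir <- "results/inputs"
files <- cmd_synth(indir, seed = 2018L, n_survey = 200000L)

sv <- read_survey(files[["survey"]])
cat(sprintf("wrote %d input files to %s\n", length(files), indir))
cat(sprintf("survey: %d records aged %d-%d; current smokers %.1f%%, disabled %.1f%%\n",
            nrow(sv), min(sv$age), max(sv$age),
            100 * mean(sv$smoking == "current"),
            100 * mean(sv$gali != "none")))
pop <- read_rate_table(files[["population"]], "rate")
cat(sprintf("population: %.0f persons across %d age-sex cells\n",
            sum(pop$value), nrow(pop)))
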