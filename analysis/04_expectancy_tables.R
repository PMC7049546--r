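#!/usr/bin/env Rscript
# Step 4: print the headline table -- Sullivan life expectancy (LE), healthy
# life years (HLY) and unhealthy life years (ULY) at age 15 in 2028 and 2048,
# reference scenario in levels and the eight alternatives as differences --
# from the files written by step 3.
# Run after 03: Rscript analysis/04_expectancy_tables.R

diffs <- utils::read.csv("results/run/differences.csv",
                         stringsAsFactors = FALSE)
sull <- diffs[diffs$measure_type == "sullivan", ]
for (s in c("male", "female")) {
  cat(sprintf("\n== %s, age 15 ==\n", s))
  wide <- reshape(sull[sull$sex == s,
                       c("scenario", "year", "HLY", "ULY", "LE")],
                  direction = "wide", idvar = "scenario", timevar = "year")
  print(wide, row.names = FALSE)
}
cat("\nreference rows are levels (years); scenario rows are differences vs reference\n")
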