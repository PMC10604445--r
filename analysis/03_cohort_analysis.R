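#!/usr/bin/env Rscript
# Runs the full statistics stage on the simulated cohort: demographics,
# FI-group comparisons per sex, sex-stratified Spearman matrices, the
# FI_Psoas multiple regression and lordosis by FI group.
# Reads results/cohort.csv (see 02_simulate_cohort.R); writes results/report/.

library(musclefi)
if (!file.exists("results/cohort.csv"))
  stop("run analysis/02_simulate_cohort.R first")

tab <- read_cohort("results/cohort.csv")
rep <- analyze_cohort(tab)
write_report_bundle(rep, "results/report")

cat("group comparisons (collapsed FI_PPM groups), FI_Psoas rows:\n")
print(subset(rep$muscle_comparison, variable == "FI_Psoas"), row.names = FALSE)
cat("\nSpearman rho(FI_PPM, FI_Psoas):",
    sprintf("female %.3f, male %.3f\n",
            rep$correlations$female$rho["FI", "FI"],
            rep$correlations$male$rho["FI", "FI"]))
cat("\n")
print(rep$regression)
cat("\nlordosis by FI group:\n")
print(rep$lordosis, row.names = FALSE)
cat("\nreport tables written under results/report/\n")
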