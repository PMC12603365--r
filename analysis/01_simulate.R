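#!/usr/bin/env Rscript
# Simulate a registry-scale synthetic cohort (600 elderly acute ischaemic
# stroke patients) with the planted exposure/mediator/outcome structure,
# plus toy lesion masks, and write the exchange files under results/.

suppressMessages(library(tmtstroke))
SEED <- 20260922 %% 2147483647

cfg <- sim_config(600, seed = SEED)
sim <- simulate_cohort(cfg)
les <- simulate_lesions(sim$cohort, cfg)
sim$cohort <- les$cohort

dir.create("results", showWarnings = FALSE)
write_cohort_csv(sim, "results/cohort")
atlas <- merge_atlases(les$atlases, c("brainstem_toy", "aal_toy", "jhu_toy"))
write_mapping_nifti(les$lesions, atlas, "results/imaging")

cat("Simulated", nrow(sim$cohort), "subjects.\n")
cat(sprintf("  male: %.1f%%, mean age %.1f y, mean TMT %.2f mm\n",
            100 * mean(sim$cohort$sex == "male"), mean(sim$cohort$age),
            mean((sim$cohort$tmt_left + sim$cohort$tmt_right) / 2)))
cat(sprintf("  lesion masks on a %s grid, median infarct %.3f%% of brain\n",
            paste(cfg$lesion_params$dim, collapse = "x"),
            median(sim$cohort$infarct_volume_pct, na.rm = TRUE)))
cat("Wrote results/cohort/{cohort,nihss}.csv and results/imaging/*.nii.gz\n")
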