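#!/usr/bin/env Rscript
## Stage 1 — simulate the study's raw material: 10 synthetic
## motor-eloquent-tumour scenes (5 to be presented with tractography,
## 5 anatomy-only) and one 19-trainee x 10-tumour planning cohort.
## Writes scene directories (NIfTI + .tck + manifest) and cohort.csv
## under results/run/.

library(trajsafe)

seed <- 1L
out <- "results/run"

sim <- run_simulate(out, seed = seed)
co <- sim$cohort

cat(sprintf("Simulated %d scenes and %d planning records (seed %d)\n",
            length(sim$scenes), nrow(co), seed))
cat(sprintf("  trainees: %d (tiers: %s)\n",
            length(unique(co$trainee_id)),
            paste(names(table(unique(co[, c('trainee_id', 'tier')])$tier)),
                  table(unique(co[, c('trainee_id', 'tier')])$tier),
                  collapse = ", ")))
cat(sprintf("  mean experience: %.2f years\n",
            mean(tapply(co$experience_years, co$trainee_id, mean))))
for (g in c("T-nBx", "A-nBx")) {
  d <- co[co$group == g, ]
  cat(sprintf("  %s: time %.1f s, %.2f trajectory changes, %.2f lobe changes\n",
              g, mean(d$planning_time_s), mean(d$n_trajectory_changes),
              mean(d$n_lobe_changes)))
}
cat("Outputs: ", sim$scenes_dir, " and ", sim$cohort_csv, "\n", sep = "")
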