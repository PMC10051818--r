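#!/usr/bin/env Rscript
## Stage 2 — score every planned trajectory against its scene: all
## distances and transgression flags, risk-zone classification, and
## the 0-4 Trajectory Safety Index. Writes per-trajectory reports and
## the component incidence summary under results/run/score/.

library(trajsafe)

run_dir <- "results/run"
res <- run_score(file.path(run_dir, "scenes"),
                 file.path(run_dir, "cohort.csv"),
                 file.path(run_dir, "score"), seed = 1L)

s <- res$summary
cat(sprintf("Scored %d trajectories\n", s$n))
cat("Component incidences (overall count, %% of evaluable records):\n")
for (i in seq_len(nrow(s$components))) {
  r <- s$components[i, ]
  cat(sprintf("  %-16s %3d/%3d (%.2f%%)  [T-nBx %d | A-nBx %d]\n",
              r$component, r$overall, r$n, r$pct, r$t_nbx, r$a_nbx))
}
cat("Per-group safety:\n")
for (i in seq_len(nrow(s$group_stats))) {
  g <- s$group_stats[i, ]
  cat(sprintf("  %s: TSI %.2f +- %.2f, length %.1f +- %.1f mm\n",
              g$group, g$mean_tsi, g$sem_tsi, g$mean_length_mm,
              g$sem_length_mm))
}
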