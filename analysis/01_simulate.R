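#!/usr/bin/env Rscript
# Simulate the aging experiment: a cohort of bead-labelled mother cells
# dividing as Poisson processes, ground-truth molecular trajectories for
# mother/daughter/dead cells, and three mixed-cell samples per harvest
# measured with lognormal noise and protein-specific bead losses.
source("analysis/00_config.R")
run_pipeline(CFG, stages = "simulate", outdir = OUTDIR, sim_args = SIM_ARGS)
v <- read_tsv(file.path(OUTDIR, "cohort_viability.tsv"))
cat(sprintf("cohort viability declines from %.2f at %.1f h to %.2f at %.1f h\n",
            v$viability[1], v$time_h[1], v$viability[nrow(v)],
            v$time_h[nrow(v)]))
comp <- read_tsv(file.path(OUTDIR, "r1_compositions.tsv"))
last <- comp[comp$time_h == max(comp$time_h), ]
cat("final-harvest compositions (mother/daughter/dead):\n")
print(last, row.names = FALSE)
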