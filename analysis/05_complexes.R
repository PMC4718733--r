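#!/usr/bin/env Rscript
# Protein-complex stoichiometry: per complex and harvest, the loss of
# stoichiometry is the interquartile range of member log2 fold changes;
# compared between the proteome and the transcriptome on shared genes.
source("analysis/00_config.R")
run_pipeline(CFG, stages = "complexes", outdir = OUTDIR)
sm <- read_tsv(file.path(OUTDIR, "stoichiometry_mean.tsv"))
cat("mean stoichiometry loss across complexes (first/last harvest):\n")
cat(sprintf("  proteome:      %.3f -> %.3f\n", sm$mean_iqr_proteome[1],
            sm$mean_iqr_proteome[nrow(sm)]))
cat(sprintf("  transcriptome: %.3f -> %.3f\n", sm$mean_iqr_transcriptome[1],
            sm$mean_iqr_transcriptome[nrow(sm)]))
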