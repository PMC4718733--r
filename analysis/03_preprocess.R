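#!/usr/bin/env Rscript
# Replicate fusion and filtering: per gene, the two replicate series are
# filtered by the between-replicate coefficient of variation (cutoff 0.3),
# fused with LOESS (span 0.75) resampled at the harvest times, and
# standardized to log2 fold changes versus the 7.8 h young reference.
source("analysis/00_config.R")
run_pipeline(CFG, stages = "preprocess", outdir = OUTDIR)
for (kind in c("proteome", "transcriptome")) {
  fitted <- read_tsv(file.path(OUTDIR, sprintf("%s_mother_fitted.tsv", kind)))
  cat(sprintf("%s: %d reproducible mother profiles retained\n", kind,
              nrow(fitted)))
}
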