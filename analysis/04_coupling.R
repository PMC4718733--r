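#!/usr/bin/env Rscript
# Proteome-transcriptome coupling: divergence from the young state,
# cross-level correlation over time (four statistics), the co-expression
# quadrant map at 72 h, relative protein overabundance, and the census of
# twofold changes per time point.
source("analysis/00_config.R")
run_pipeline(CFG, stages = "coupling", outdir = OUTDIR)
cc <- read_tsv(file.path(OUTDIR, "crosslevel_correlation.tsv"))
cat(sprintf("cross-level Spearman: %.3f at %.1f h -> %.3f at %.1f h\n",
            cc$spearman[1], cc$time_h[1], cc$spearman[nrow(cc)],
            cc$time_h[nrow(cc)]))
q <- read_tsv(file.path(OUTDIR, "quadrants.tsv"))
frac <- table(q$quadrant[q$quadrant != "axis"])
cat("quadrant fractions at 72 h:\n")
print(round(frac / sum(frac), 3))
cen <- read_tsv(file.path(OUTDIR, "census_proteome.tsv"))
fin <- cen[nrow(cen), ]
cat(sprintf("final census: %d changers, %d previously crossed (%.0f%% presaged)\n",
            fin$total_changed, fin$previous_up + fin$previous_down,
            100 * (fin$previous_up + fin$previous_down) /
              max(1, fin$total_changed)))
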