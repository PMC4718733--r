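# Shared settings for the analysis scripts: one synthetic aging experiment
# (two replicate campaigns, 12 exponentially spaced harvests from 7.8 h to
# 72 h) analysed end to end. Every script can be re-run independently once
# its upstream outputs exist under results/pipeline.
library(agemix)
OUTDIR <- "results/pipeline"
CFG <- pipeline_config(seed = 1L)
SIM_ARGS <- list(n_genes = 800, n_complexes = 20, noise_cv = 0.10)
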