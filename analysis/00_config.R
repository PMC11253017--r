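# Shared settings for the analysis scripts. Everything downstream of this
# file is deterministic given SEED.
library(gsblup)

SEED <- 1
OUT <- "results/study"
dir.create(OUT, recursive = TRUE, showWarnings = FALSE)

# Study-design panel: 149 inbred wheat lines x 11,405 array SNPs,
# 7 grain-element traits, 2 years x 2 replicates.
study_config <- panel_config(seed = SEED)
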