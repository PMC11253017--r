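#!/usr/bin/env Rscript
# Stage 3: genomic relationship matrix (Yang diagonal, SNP call
# rate >= 98%) among the QC-passed lines.
source("analysis/00_config.R")

panel <- read_plink(file.path(OUT, "panel_qc"), dialect = "binary")
grm <- compute_grm(panel, diagonal = "yang", grm_missing_max = 0.02)
print(grm)
off <- grm$A[upper.tri(grm$A)]
cat(sprintf("off-diagonal relatedness: mean %.4f, sd %.4f, range [%.3f, %.3f]\n",
            mean(off), sd(off), min(off), max(off)))
write_grm_tsv(grm, file.path(OUT, "grm.tsv"))
write_grm_bin(grm, file.path(OUT, "grm"))
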