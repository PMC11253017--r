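#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study panel.
# A diversity panel of 149 fully inbred lines, 11,405 SNPs with strong
# local LD on 21 chromosomes, and 7 correlated element-content traits
# measured 4 times each (596 records per trait).
source("analysis/00_config.R")

sim <- simulate_panel(study_config)
print(sim$panel)
cat(sprintf("phenotype records: %d (%d per trait)\n",
            nrow(sim$phenotypes), nrow(sim$phenotypes) / 7))
cat("realized heritability (Var(BV)/Var(line means)):\n")
print(round(sim$architecture$realized_h2, 3))

write_plink(sim$panel, file.path(OUT, "panel"), dialect = "binary")
write_phenotypes(sim$phenotypes, file.path(OUT, "phenotypes.tsv"))
write_panel_config(study_config, file.path(OUT, "panel_config.yaml"))
write.table(
  data.frame(line_id = rownames(sim$architecture$true_bv),
             sim$architecture$true_bv, check.names = FALSE),
  file.path(OUT, "true_breeding_values.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote panel + phenotypes + ground truth under", OUT, "\n")
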