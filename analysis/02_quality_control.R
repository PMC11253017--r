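#!/usr/bin/env Rscript
# Stage 2: array QC — SNP call rate >= 95%, MAF >= 1%, sample call
# rate >= 95% (in that fixed order).
source("analysis/00_config.R")

panel <- read_plink(file.path(OUT, "panel"), dialect = "binary")
res <- qc_filter(panel)
print(res$report)
write_plink(res$panel, file.path(OUT, "panel_qc"), dialect = "binary")
write_qc_report(res$report, file.path(OUT, "qc_report.json"))
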