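#!/usr/bin/env Rscript
# Simulate the six-line resequencing panel: two ICY-H, one ICY-L and three
# CY inbreds, with a 272-SNP diagnostic region planted at 27.60-27.88 Mb on
# chromosome 2 (plus the two small clusters on chromosomes 5 and 9) over
# shared/private background variation. Writes the VCF, the group
# assignments and the planted truth for the downstream steps.

suppressPackageStartupMessages(library(fleshmap))
dir.create("results", showWarnings = FALSE)

truth <- panel_truth(seed = 42)
panel <- gen_resequencing_panel(truth)
print(panel)

write_vcf(panel, "results/panel.vcf")
writeLines(paste(names(panel$groups), panel$groups, sep = "\t"),
           "results/groups.tsv")
write.table(panel$truth$sites, "results/panel_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("panel: %d sites (%d planted diagnostic), written to %s\n",
            nrow(panel$matrix$sites),
            sum(panel$truth$sites$kind == "diagnostic"),
            "results/panel.vcf"))
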