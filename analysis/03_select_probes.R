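#!/usr/bin/env Rscript
# RNA-seq-guided probe selection: for every multi-probe gene, keep the
# probe whose cell-line GEP values best correlate with the gene's RNA-seq
# row; exclude genes with no concordant probe (the BAD/HRK situation) and
# the a-priori exclusion BBC3 (microRNA cross-hybridization). Collapse the
# harmonized corpus to gene level through the chosen probes.

suppressPackageStartupMessages(library(bcl2panel))

sim <- "results/01_simulate"
har <- "results/02_harmonize"
out <- "results/03_select_probes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

gep <- read_expression_tsv(file.path(sim, "celllines_gep.tsv"))
rnaseq <- read_expression_tsv(file.path(sim, "celllines_rnaseq.tsv"))
probe_map <- read_annotation_tsv(file.path(sim, "probe_map.tsv"))
expr <- read_expression_tsv(file.path(har, "probes_normalized.tsv"))

sel <- select_probes(gep, rnaseq, probe_map, min_r = 0.5)
genes <- collapse_to_genes(expr, sel)

write_annotation_tsv(sel, file.path(out, "probe_selection.tsv"))
write_expression_tsv(genes, file.path(out, "genes.tsv"))
write_gct(genes[intersect(bcl2_family_genes(), rownames(genes)), ],
          file.path(out, "bcl2_family.gct"))

excl <- sel[sel$status == "excluded", ]
message(sprintf("%d genes selected, %d excluded (%s)",
                sum(sel$status == "selected"), nrow(excl),
                paste(head(excl$gene, 5), collapse = ", ")))
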