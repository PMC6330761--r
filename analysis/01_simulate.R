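#!/usr/bin/env Rscript
# Simulate the pooled study corpus: 1,200 patient samples across 10 mature
# B-cell malignancies and their normal counterparts (5,000 probes, two
# series per entity), plus the matched 19-line GEP/RNA-seq cell panel used
# later for probe selection. Writes the probe matrix, annotation, probe
# map and ground truth under results/01_simulate/.

suppressPackageStartupMessages(library(bcl2panel))

seed <- 2024
out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(seed = seed)
d <- generate_dataset(cfg)
cl <- generate_cellline_panel(cfg)

write_expression_tsv(d$expr, file.path(out, "probes.tsv"))
write_annotation_tsv(d$ann, file.path(out, "annotation.tsv"))
write_annotation_tsv(d$probe_map, file.path(out, "probe_map.tsv"))
write_expression_tsv(cl$gep, file.path(out, "celllines_gep.tsv"))
write_expression_tsv(cl$rnaseq, file.path(out, "celllines_rnaseq.tsv"))
write_ground_truth_json(d$truth, file.path(out, "ground_truth.json"))

message(sprintf("corpus: %d probes x %d samples over %d entities",
                nrow(d$expr), ncol(d$expr), length(unique(d$ann$entity))))
message(sprintf("implied ORR range: %.0f-%.0f%% across %d trial entities",
                min(d$truth$implied_orr), max(d$truth$implied_orr),
                length(d$truth$implied_orr)))
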