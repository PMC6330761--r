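#!/usr/bin/env Rscript
# The biomarker stage: enumerate all 49 efficacy/resistance ratio
# candidates, rank them by correlation with entity-level venetoclax ORR,
# and profile the winning ratio across tissues and molecular subgroups.

suppressPackageStartupMessages(library(bcl2panel))

sim <- "results/01_simulate"
ind <- "results/03_select_probes"
har <- "results/02_harmonize"
out <- "results/07_ratio"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genes <- read_expression_tsv(file.path(ind, "genes.tsv"))
ann <- read_annotation_tsv(file.path(har, "annotation.tsv"))
truth <- jsonlite::read_json(file.path(sim, "ground_truth.json"))
orr <- unlist(truth$implied_orr)

ranking <- rank_ratio_candidates(genes, ann, orr)
write_annotation_tsv(as.data.frame(ranking), file.path(out, "ranking.tsv"))

best <- attr(ranking, "specs")[[1]]
scores <- ratio_score(genes, best)
write_annotation_tsv(data.frame(sample_id = names(scores), score = scores),
                     file.path(out, "scores.tsv"))

message(sprintf("best candidate: %s (r = %.3f, p = %.2g over %d samples)",
                format(best), ranking$r[1], ranking$p[1], ranking$n[1]))

# niche and subgroup comparisons of the winning ratio
mcl <- ann$sample_id[ann$entity == "MCL"]
niche <- compare_ratio_by_group(scores[mcl], ann, "tissue")
write_annotation_tsv(niche, file.path(out, "mcl_tissue_comparison.tsv"))
mm <- ann$sample_id[ann$entity == "MM"]
subgroup <- compare_ratio_by_group(scores[mm], ann, "subtype")
write_annotation_tsv(subgroup, file.path(out, "mm_subtype_comparison.tsv"))

med_mm <- sort(tapply(scores[mm], ann$subtype[match(mm, ann$sample_id)],
                      median), decreasing = TRUE)
message(sprintf("highest-ratio MM subgroup: %s (median %.2f)",
                names(med_mm)[1], med_mm[1]))
ln_pb <- niche[(niche$group_a == "LN" & niche$group_b == "PB") |
                 (niche$group_a == "PB" & niche$group_b == "LN"), ][1, ]
message(sprintf("MCL LN vs PB ratio: medians %.2f vs %.2f, p = %.2g",
                ln_pb$median_a, ln_pb$median_b, ln_pb$p))
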