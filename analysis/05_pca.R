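#!/usr/bin/env Rscript
# PCA factor map of the 12-gene BCL2-family profiles: per-sample scores on
# the first components, variable correlation circle, and 95% barycenter
# confidence ellipses per entity.

suppressPackageStartupMessages(library(bcl2panel))

ind <- "results/03_select_probes"
har <- "results/02_harmonize"
out <- "results/05_pca"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genes <- read_expression_tsv(file.path(ind, "genes.tsv"))
ann <- read_annotation_tsv(file.path(har, "annotation.tsv"))
fam <- intersect(bcl2_family_genes(), rownames(genes))

model <- pca_fit(genes[fam, ])
scores <- data.frame(sample_id = rownames(model$scores),
                     entity = ann$entity[match(rownames(model$scores),
                                               ann$sample_id)],
                     model$scores[, 1:2])
write_annotation_tsv(scores, file.path(out, "scores.tsv"))
write_annotation_tsv(variable_correlation_circle(model, genes[fam, ]),
                     file.path(out, "correlation_circle.tsv"))

ells <- group_ellipses(model, setNames(ann$entity, ann$sample_id))
jsonlite::write_json(
  lapply(ells, function(e) e[c("label", "center", "semi_axes", "angle",
                               "level", "n")]),
  file.path(out, "ellipses.json"), auto_unbox = TRUE, digits = NA)

message(sprintf("PC1 %.1f%%, PC2 %.1f%% of variance; %d entity ellipses",
                100 * model$var_explained[1], 100 * model$var_explained[2],
                length(ells)))
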