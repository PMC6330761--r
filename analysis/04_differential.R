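#!/usr/bin/env Rscript
# Nonparametric differential profiling of the BCL2 family: each malignancy
# against its normal B-cell counterpart (the entity heat-map view), the
# tumor-niche contrasts (LN/BM/SPL vs PB within entity), and z-scored
# median profiles for heat-map plotting.

suppressPackageStartupMessages(library(bcl2panel))

ind <- "results/03_select_probes"
har <- "results/02_harmonize"
out <- "results/04_differential"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genes <- read_expression_tsv(file.path(ind, "genes.tsv"))
ann <- read_annotation_tsv(file.path(har, "annotation.tsv"))
fam <- intersect(bcl2_family_genes(), rownames(genes))

cmap <- default_counterpart_map()
contrasts <- list()
for (e in intersect(names(cmap), unique(ann$entity))) {
  if (!cmap[[e]] %in% ann$entity) next
  contrasts[[paste0(e, "_vs_", cmap[[e]])]] <-
    list(a = ann$sample_id[ann$entity == e],
         b = ann$sample_id[ann$entity == cmap[[e]]])
}
de_counterpart <- compare_profiles(genes, ann, contrasts, genes = fam)
write_annotation_tsv(de_counterpart, file.path(out, "counterpart_contrasts.tsv"))

# niche contrasts within the entities sampled from several tissues
tissue_rows <- list()
for (e in c("MCL", "FL", "CLL", "SMZL")) {
  sub <- ann[ann$entity == e, ]
  for (t in setdiff(unique(sub$tissue), "PB")) {
    if (sum(sub$tissue == t) < 3 || sum(sub$tissue == "PB") < 3) next
    tissue_rows[[paste0(e, "_", t, "_vs_PB")]] <-
      list(a = sub$sample_id[sub$tissue == t],
           b = sub$sample_id[sub$tissue == "PB"])
  }
}
de_tissue <- compare_profiles(genes, ann, tissue_rows, genes = fam)
write_annotation_tsv(de_tissue, file.path(out, "tissue_contrasts.tsv"))

prof <- median_profile(genes[fam, ], setNames(ann$entity, ann$sample_id),
                       z_score = TRUE)
write_expression_tsv(prof, file.path(out, "median_profiles_z.tsv"))

sig <- subset(de_counterpart, p < 0.05)
message(sprintf("%d/%d counterpart gene contrasts significant; BCL2L11 repressed in LN for %d/%d entities",
                nrow(sig), nrow(de_counterpart),
                sum(de_tissue$gene == "BCL2L11" & grepl("LN", de_tissue$contrast) &
                      de_tissue$median_a < de_tissue$median_b),
                sum(de_tissue$gene == "BCL2L11" & grepl("LN", de_tissue$contrast))))
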