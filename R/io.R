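#' Read/write expression matrices and annotations as TSV
#'
#' Matrices are stored with the feature id in the first column
#' (`feature_id`) and one column per sample. GCT 1.2 export is available
#' for interoperability with heat-map viewers.
#'
#' @param m numeric matrix with rownames (features) and colnames
#'   (samples).
#' @param path output file.
#' @return `write_*` return `path` invisibly; `read_expression_tsv`
#'   returns a numeric matrix.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname write_expression_tsv
#' @export
write_gct <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  df <- data.frame(NAME = rownames(m), Description = rownames(m), m,
                   check.names = FALSE)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param ann annotation data.frame.
#' @export
write_annotation_tsv <- function(ann, path) {
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_annotation_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Serialize ground truth (without the latent matrix) as JSON
#'
#' @param truth a `ground_truth` from [generate_dataset()].
#' @param path output file.
#' @param include_latent also embed the latent gene-by-sample matrix
#'   (large; off by default).
#' @export
write_ground_truth_json <- function(truth, path, include_latent = FALSE) {
  x <- list(
    planted_ratio = list(numerator = truth$planted_ratio$numerator,
                         denominator = truth$planted_ratio$denominator),
    implied_orr = as.list(truth$implied_orr),
    batch_offsets = as.list(truth$batch_offsets),
    fidelity = as.list(truth$fidelity),
    entity_effects = as.data.frame(truth$entity_effects))
  if (include_latent) x$latent <- truth$latent
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
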