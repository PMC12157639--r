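#' Write a numeric matrix as tab-separated text
#'
#' Header row of sample ids, first column of feature/subject ids.
#'
#' @param matrix Numeric matrix with dimnames.
#' @param path Output file.
#' @param id_column Name of the first (row-id) column.
#' @export
write_matrix_tsv <- function(matrix, path, id_column = "id") {
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a features-x-samples abundance matrix from TSV
#'
#' @param path TSV with the first column holding feature ids.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Export a dendrogram as Newick text
#'
#' @param hc An [stats::hclust()] object.
#' @param path Output file.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Write all simulated study inputs to a directory
#'
#' Emits the Ct table, abundance matrices, sample annotations and trait
#' table as TSV, and the planted ground truth as a JSON sidecar.
#'
#' @param sim A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_matrix_tsv(sim$ct$ct, file.path(dir, "ct_table.tsv"), "subject_id")
  write_matrix_tsv(sim$proteome$abundance, file.path(dir, "proteome.tsv"),
                   "feature")
  write_matrix_tsv(sim$kd$abundance, file.path(dir, "kd_proteome.tsv"),
                   "feature")
  write.table(sim$cohort$meta, file.path(dir, "sample_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$cohort$traits, file.path(dir, "traits.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$proteome$annot, file.path(dir, "proteome_annot.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- list(
      latent_burden = as.list(sim$cohort$truth$latent_burden),
      true_subtype = as.list(as.character(sim$cohort$truth$true_subtype)),
      module_membership = as.list(sim$proteome$truth$module_membership),
      concordant_set = as.list(sim$proteome$truth$concordant_set),
      kd_log2fc = as.list(sim$kd$log2fc))
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
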