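# Delimited-text interchange: per-subject time-series tables with a cohort
# manifest, connectivity matrices, decomposition coefficient matrices,
# graph edge lists and partitions. Everything is plain TSV so runs can be
# audited and re-fed to the pipeline without binary formats.

#' Write a cohort as delimited text
#'
#' Writes one TSV per subject (rows = timepoints, columns = regions, with a
#' header of region labels) plus a `manifest.tsv` listing subject id, group
#' and TR. This is the same format [read_cohort()] and hence the pipeline
#' reads.
#'
#' @param cohort A `"wbnet_cohort"` (see [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "wbnet_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cohort$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in cohort$manifest$subject) {
    utils::write.table(cohort$data[[id]], file.path(dir, paste0(id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort from delimited text
#'
#' Reads the `manifest.tsv` + per-subject TSV layout written by
#' [write_cohort()].
#'
#' @param dir Directory containing `manifest.tsv` and one
#'   `<subject>.tsv` per subject.
#' @return A `"wbnet_cohort"` (without ground truth).
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  data <- lapply(manifest$subject, function(id) {
    as.matrix(utils::read.table(file.path(dir, paste0(id, ".tsv")),
                                header = TRUE, sep = "\t"))
  })
  names(data) <- manifest$subject
  structure(list(data = data, manifest = manifest, truth = NULL),
            class = "wbnet_cohort")
}

#' Write a square matrix as delimited text
#'
#' Dense TSV with a header row of region labels; provenance attributes
#' (scale, method, filter) are written to a `<path>.meta` sidecar.
#'
#' @param m Matrix (e.g. from [wavelet_cor()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  if (is.null(colnames(m))) colnames(m) <- sprintf("R%02d", seq_len(ncol(m)))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(scale = attr(m, "scale"), method = attr(m, "method"),
            filter = attr(m, "filter"))
  if (length(meta)) {
    writeLines(paste(names(meta), meta, sep = "\t"), paste0(path, ".meta"))
  }
  invisible(path)
}

#' Read a square matrix written by [write_matrix_tsv()]
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, header = TRUE, sep = "\t"))
}

#' Export a binary graph as an edge list
#'
#' Two-column (i, j) TSV of the upper-triangular edges of a 0/1 adjacency
#' matrix.
#'
#' @param A Binary adjacency matrix.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(A, path) {
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  utils::write.table(data.frame(i = idx[, 1], j = idx[, 2]), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a partition as node, community delimited text
#' @param partition Integer membership vector.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(data.frame(node = seq_along(partition),
                                community = as.integer(partition)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export per-scale decomposition coefficients as delimited text
#'
#' Writes one TSV per scale (`W1.tsv`, ..., `WJ.tsv`, `V.tsv`) under `dir`.
#'
#' @param d A [modwt()] or [dwt()] decomposition.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_decomposition <- function(d, dir) {
  stopifnot(inherits(d, "wavelet_decomp"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (j in seq_len(d$n.levels)) {
    utils::write.table(.as_coef_matrix(d$W[[j]]),
                       file.path(dir, sprintf("W%d.tsv", j)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  utils::write.table(.as_coef_matrix(d$V), file.path(dir, "V.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(dir)
}
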