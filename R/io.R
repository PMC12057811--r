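#' Read and write GRNs as TSV
#'
#' Two plain-text formats are supported. The dense format is an `n x n`
#' tab-separated matrix with a header row of gene identifiers (row order
#' matches the header). The edge-list format has three columns
#' `source`, `target`, `weight` with a header line; genes absent from any
#' edge can be declared through `gene_ids` so isolated genes survive the
#' round trip. Both round-trip losslessly for finite weights.
#'
#' @param file path of the TSV file.
#' @param include_diagonal diagonal policy of the returned [grn()].
#' @return For readers, a [grn()]; writers return the file path invisibly.
#' @name grn_io
NULL

#' @rdname grn_io
#' @param x a [grn()] object to write.
#' @export
write_grn_tsv <- function(x, file) {
  stopifnot(inherits(x, "grn"))
  utils::write.table(x$matrix, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(file)
}

#' @rdname grn_io
#' @export
read_grn_tsv <- function(file, include_diagonal = FALSE) {
  m <- as.matrix(utils::read.table(file, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  grn(m, gene_ids = colnames(m), include_diagonal = include_diagonal)
}

#' @rdname grn_io
#' @export
write_edge_list_tsv <- function(x, file) {
  stopifnot(inherits(x, "grn"))
  idx <- which(x$matrix != 0, arr.ind = TRUE)
  edges <- data.frame(
    source = x$gene_ids[idx[, 1]],
    target = x$gene_ids[idx[, 2]],
    weight = x$matrix[idx],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(edges$source, edges$target), ]
  utils::write.table(edges, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname grn_io
#' @param gene_ids gene universe for the edge-list reader; defaults to the
#'   genes appearing in the edges (sorted).
#' @export
read_edge_list_tsv <- function(file, gene_ids = NULL,
                               include_diagonal = FALSE) {
  edges <- utils::read.table(file, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  if (!all(c("source", "target", "weight") %in% names(edges))) {
    stop_grnsparse("invalid_input",
                   "edge list needs columns source, target, weight")
  }
  if (is.null(gene_ids)) {
    gene_ids <- sort(unique(c(edges$source, edges$target)))
  }
  n <- length(gene_ids)
  m <- matrix(0, n, n, dimnames = list(gene_ids, gene_ids))
  m[cbind(match(edges$source, gene_ids), match(edges$target, gene_ids))] <-
    edges$weight
  grn(m, gene_ids = gene_ids, include_diagonal = include_diagonal)
}

#' Write a simulated expression dataset
#'
#' Writes the fold-change matrix `Y` and the perturbation design `P` as TSV
#' files plus a JSON sidecar recording the target and realized SNR, the noise
#' variance and the seed.
#'
#' @param dataset an [simulate_expression()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default `"dataset"`).
#' @return Invisibly, the three file paths.
#' @export
write_expression_dataset <- function(dataset, dir, prefix = "dataset") {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_Y.tsv", "_P.tsv", ".json")))
  utils::write.table(dataset$Y, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(dataset$design$matrix, paths[2], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(snr_target = dataset$snr_target,
         snr_realized = dataset$snr_realized,
         noise_var = dataset$noise_var,
         replicates = dataset$design$replicates,
         seed = dataset$seed),
    paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a simulated expression dataset
#'
#' Inverse of [write_expression_dataset()].
#'
#' @param dir directory holding the files.
#' @param prefix file-name prefix used at write time.
#' @return An `"expression_dataset"` object.
#' @export
read_expression_dataset <- function(dir, prefix = "dataset") {
  paths <- file.path(dir, paste0(prefix, c("_Y.tsv", "_P.tsv", ".json")))
  Y <- as.matrix(utils::read.table(paths[1], sep = "\t"))
  P <- as.matrix(utils::read.table(paths[2], sep = "\t"))
  dimnames(Y) <- dimnames(P) <- NULL
  meta <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  design <- structure(list(matrix = P, replicates = meta$replicates),
                      class = "perturbation_design")
  structure(
    list(Y = Y, design = design, snr_target = meta$snr_target,
         snr_realized = meta$snr_realized, noise_var = meta$noise_var,
         seed = meta$seed),
    class = "expression_dataset"
  )
}
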