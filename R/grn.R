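#' Gene regulatory network
#'
#' Container for a directed, signed gene regulatory network (GRN). The network
#' is stored as a square interaction matrix `A` where element `A[i, j]` is the
#' regulatory effect of gene `i` on gene `j`; a zero entry means "no link".
#' All degree and sparsity computations in this package are out-degree based
#' (nonzero entries per row) and, by default, exclude the diagonal:
#' self-degradation terms are not regulatory out-links and would add a uniform
#' +1 to every out-degree, distorting the power-law fit. Set
#' `include_diagonal = TRUE` to count self-links, e.g. when a dominant negative
#' diagonal has deliberately been added to both an inferred network and its
#' gold standard.
#'
#' @param matrix square numeric matrix of regulatory effects, `n >= 2` rows,
#'   all entries finite.
#' @param gene_ids optional character vector of `n` gene labels; defaults to
#'   the matrix dimnames or `G1...Gn`.
#' @param include_diagonal logical; count diagonal entries as links in degree
#'   and sparsity computations. Default `FALSE`.
#' @return An object of class `"grn"`: a list with elements `matrix`,
#'   `gene_ids` and `include_diagonal`.
#' @examples
#' a <- matrix(c(0, 1.5, -2, 0, 0, 0, 0.3, 0, 0), 3, 3, byrow = TRUE)
#' net <- grn(a)
#' sparsity_of(net)
#' @seealso [degree_distribution()], [sparsity_of()], [read_grn_tsv()]
#' @export
grn <- function(matrix, gene_ids = NULL, include_diagonal = FALSE) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop_grnsparse("invalid_input", "`matrix` must be a numeric matrix")
  }
  n <- nrow(matrix)
  if (ncol(matrix) != n) {
    stop_grnsparse("invalid_input", "interaction matrix must be square")
  }
  if (n < 2) {
    stop_grnsparse("invalid_input", "a GRN needs at least 2 genes")
  }
  if (!all(is.finite(matrix))) {
    stop_grnsparse("invalid_input", "interaction matrix entries must be finite")
  }
  if (is.null(gene_ids)) {
    gene_ids <- rownames(matrix)
    if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(n))
  }
  if (length(gene_ids) != n || anyDuplicated(gene_ids)) {
    stop_grnsparse("invalid_input", "`gene_ids` must be ", n, " unique labels")
  }
  dimnames(matrix) <- list(gene_ids, gene_ids)
  structure(
    list(matrix = matrix, gene_ids = as.character(gene_ids),
         include_diagonal = isTRUE(include_diagonal)),
    class = "grn"
  )
}

#' @export
print.grn <- function(x, ...) {
  n <- length(x$gene_ids)
  cat(sprintf("<grn> %d genes, %d links, sparsity %.3f links/node%s\n",
              n, n_links(x), sparsity_of(x),
              if (x$include_diagonal) " (diagonal counted)" else ""))
  invisible(x)
}

#' @export
dim.grn <- function(x) dim(x$matrix)

# link support as a logical matrix under the diagonal policy
link_support <- function(x) {
  s <- x$matrix != 0
  if (!x$include_diagonal) diag(s) <- FALSE
  s
}

n_links <- function(x) sum(link_support(x))

#' Out-degree distribution of a GRN
#'
#' Computes the out-degree of each gene (number of nonzero entries in its row
#' of the interaction matrix, diagonal excluded unless the network's
#' `include_diagonal` policy says otherwise), the frequency table
#' \eqn{x_d = \#\{i : c_i = d\}} for degrees \eqn{1 \le d \le n}, and the count
#' \eqn{n_g} of genes with a positive out-degree. These statistics are the sole
#' input of the power-law metrics: they depend only on the sign pattern of the
#' matrix, never on the magnitude of its entries.
#'
#' Zeros are detected by exact comparison with 0; inference methods are
#' expected to emit explicit zeros, thresholding being the job of the sparsity
#' sweep, not of the counter.
#'
#' @param x a [grn()] object.
#' @return An object of class `"degree_distribution"`: list with
#'   `out_degrees` (named integer vector \eqn{c_i}), `counts` (named integer
#'   vector, frequency \eqn{x_d} for each observed positive degree `d`),
#'   `n_genes` (matrix dimension `n`), `n_positive` (\eqn{n_g}) and `kmin`
#'   (fixed at 1).
#' @examples
#' a <- matrix(c(0, 1.5, -2, 0, 0, 0, 0.3, 0, 0), 3, 3, byrow = TRUE)
#' degree_distribution(grn(a))
#' @export
degree_distribution <- function(x) {
  stopifnot(inherits(x, "grn"))
  deg <- rowSums(link_support(x))
  storage.mode(deg) <- "integer"
  pos <- deg[deg > 0L]
  counts <- integer(0)
  if (length(pos)) {
    tab <- table(pos)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
  }
  structure(
    list(out_degrees = deg, counts = counts,
         n_genes = nrow(x$matrix), n_positive = length(pos), kmin = 1L),
    class = "degree_distribution"
  )
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat(sprintf("<degree_distribution> n = %d genes, n_g = %d with out-degree > 0\n",
              x$n_genes, x$n_positive))
  if (length(x$counts)) {
    cat("  d:  ", paste(names(x$counts), collapse = " "), "\n")
    cat("  x_d:", paste(x$counts, collapse = " "), "\n")
  }
  invisible(x)
}

#' Degree distribution from a degree sequence
#'
#' Builds a [degree_distribution()] directly from an integer out-degree
#' sequence, bypassing the matrix representation — convenient for evaluating
#' the power-law metrics on sampled or published degree sequences.
#'
#' @param degrees vector of non-negative integer out-degrees, one per gene.
#' @param n_genes total gene count `n` (defaults to `length(degrees)`; may be
#'   larger, in which case the remaining genes count as zero-degree).
#' @return A `"degree_distribution"` object.
#' @examples
#' fit_alpha_ml(degree_distribution_from_degrees(c(1, 1, 2, 3, 5)))
#' @export
degree_distribution_from_degrees <- function(degrees, n_genes = length(degrees)) {
  stopifnot(all(degrees >= 0), n_genes >= length(degrees))
  deg <- as.integer(degrees)
  pos <- deg[deg > 0L]
  counts <- integer(0)
  if (length(pos)) {
    tab <- table(pos)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
  }
  structure(
    list(out_degrees = deg, counts = counts,
         n_genes = as.integer(n_genes), n_positive = length(pos), kmin = 1L),
    class = "degree_distribution"
  )
}

# coerce grn -> degree_distribution, pass degree_distribution through
as_degree_distribution <- function(x) {
  if (inherits(x, "degree_distribution")) return(x)
  if (inherits(x, "grn")) return(degree_distribution(x))
  stop_grnsparse("invalid_input",
                 "expected a 'grn' or 'degree_distribution' object")
}

#' Sparsity of a GRN
#'
#' The sparsity of a network is its average number of out-links per gene,
#' i.e. the number of counted nonzero links divided by the number of genes.
#' It equals the arithmetic mean of the out-degrees and follows the same
#' diagonal policy as [degree_distribution()]. This is the quantity the
#' selection metrics try to match to the (unknown) true network's sparsity.
#'
#' @param x a [grn()] object.
#' @return Mean out-links per gene (non-negative real).
#' @export
sparsity_of <- function(x) {
  stopifnot(inherits(x, "grn"))
  n_links(x) / nrow(x$matrix)
}

# internal condition helper: all package errors carry class
# grnsparse_<type> so callers (and the benchmark loop) can catch precisely
stop_grnsparse <- function(type, ...) {
  msg <- paste0(...)
  cond <- structure(
    class = c(paste0("grnsparse_", type), "grnsparse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}
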