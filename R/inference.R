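#' @title P-based GRN inference methods
#' @description
#' All four methods infer regulatory structure from single-gene perturbation
#' data under the steady-state model \eqn{A Y = -P}: given fold changes `Y`
#' and the known design `P`, each row \eqn{a_i} of the interaction matrix
#' satisfies \eqn{a_i Y = -p_i}. [infer_lasso()] returns a native
#' hyperparameter path (a ready-made sparsity sweep); the others return a
#' dense confidence matrix to be thresholded with [sweep_from_confidence()].
#' @name inference
NULL

inference_result <- function(method_name, sweep = NULL, confidence = NULL) {
  stopifnot(xor(is.null(sweep), is.null(confidence)))
  structure(
    list(kind = if (is.null(sweep)) "confidence" else "path",
         sweep = sweep, confidence = confidence, method_name = method_name),
    class = "inference_result"
  )
}

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf("<inference_result> %s (%s)\n", x$method_name, x$kind))
  invisible(x)
}

#' Turn an inference result into a sparsity sweep
#'
#' Path methods already carry a sweep; confidence methods are thresholded at
#' `n_grids` cutoffs.
#'
#' @param result an `inference_result`.
#' @param n_grids cutoff count for confidence matrices (default 100).
#' @param ... passed to [sweep_from_confidence()].
#' @return A [sparsity_sweep()].
#' @export
as_sparsity_sweep <- function(result, n_grids = 100L, ...) {
  stopifnot(inherits(result, "inference_result"))
  if (result$kind == "path") return(result$sweep)
  sweep_from_confidence(result$confidence, n_grids = n_grids, ...)
}

check_YP <- function(Y, P) {
  if (inherits(P, "perturbation_design")) P <- P$matrix
  if (!is.matrix(Y) || !is.matrix(P) || nrow(Y) != nrow(P) ||
      ncol(Y) != ncol(P)) {
    stop_grnsparse("invalid_input", "`Y` and `P` must be matrices of equal shape")
  }
  if (stats::sd(Y) == 0) {
    stop_grnsparse("invalid_input", "`Y` has zero variance; nothing to infer")
  }
  P
}

#' LASSO inference along a lambda path
#'
#' Per-row L1-regularised regression of the steady-state model: for each gene
#' `i`, minimises \eqn{\|Y^\top a_i^\top + p_i^\top\|_2^2/(2M) + \lambda \|a_i\|_1}
#' over a shared lambda grid, yielding one network per lambda. The grid runs
#' log-spaced from the global \eqn{\lambda_{max}} (smallest lambda with an
#' all-zero solution across rows) down to `lambda_min_ratio * lambda_max`,
#' so member sparsity spans empty to near-dense.
#'
#' @param Y N x M fold-change matrix.
#' @param P perturbation design (matrix or [make_perturbation_design()]).
#' @param lambdas optional explicit descending lambda grid; overrides
#'   `nlambda`/`lambda_min_ratio`.
#' @param nlambda grid size (default 100).
#' @param lambda_min_ratio grid floor relative to \eqn{\lambda_{max}}
#'   (default 1e-3).
#' @param thresh glmnet convergence threshold (default 1e-10).
#' @return An `inference_result` of kind `"path"` carrying the sweep.
#' @export
infer_lasso <- function(Y, P, lambdas = NULL, nlambda = 100L,
                        lambda_min_ratio = 1e-3, thresh = 1e-10) {
  P <- check_YP(Y, P)
  n <- nrow(Y)
  M <- ncol(Y)
  x <- t(Y)
  if (is.null(lambdas)) {
    lambda_max <- max(abs(Y %*% t(P))) / M
    lambdas <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                       length.out = nlambda))
  }
  coef_rows <- lapply(seq_len(n), function(i) {
    fit <- glmnet::glmnet(x, -P[i, ], family = "gaussian", lambda = lambdas,
                          intercept = FALSE, standardize = FALSE,
                          thresh = thresh)
    as.matrix(fit$beta)   # n x length(lambdas)
  })
  members <- lapply(seq_along(lambdas), function(g) {
    A <- t(vapply(coef_rows, function(b) b[, g], numeric(n)))
    grn(A)
  })
  inference_result("lasso", sweep = sparsity_sweep(members, lambdas))
}

#' Zscore inference
#'
#' Distance-based confidence scores from replicate-averaged perturbation
#' responses. The mean response of gene `i` across the columns perturbing
#' gene `j` is z-normalised per gene `i` across all perturbations:
#' link confidence is the magnitude of the resulting z-score (large
#' standardized responses mark likely regulators). The signed z matrix is
#' returned so thresholded sweep members retain signs. Genes with zero
#' response variance get all-zero scores (with a warning) rather than NaNs.
#'
#' @inheritParams infer_lasso
#' @return An `inference_result` of kind `"confidence"` (signed z-scores;
#'   confidence is their magnitude).
#' @export
infer_zscore <- function(Y, P) {
  P <- check_YP(Y, P)
  n <- nrow(Y)
  group <- apply(P, 2, which.max)          # perturbed gene per experiment
  m <- vapply(seq_len(n), function(j) {
    rowMeans(Y[, group == j, drop = FALSE])
  }, numeric(n))                           # m[i, j]: response of i to perturbing j
  mu <- rowMeans(m)
  sdev <- apply(m, 1, stats::sd)
  flat <- sdev == 0
  if (any(flat)) {
    warning(sum(flat), " gene(s) with zero response variance; ",
            "their z-scores were set to 0")
    sdev[flat] <- Inf
  }
  z <- (m - mu) / sdev
  inference_result("zscore", confidence = z)
}

#' LSCON inference
#'
#' Least-squares inversion of the steady-state model with row normalisation:
#' the base estimate is \eqn{A_{LS} = -P Y^\top (Y Y^\top)^{-1}} (the
#' Moore--Penrose pseudoinverse is used as a fallback when \eqn{Y Y^\top} is
#' numerically singular). Rows dominated by extreme values — largest magnitude
#' exceeding `kappa` times the median of row maxima, an artifact of
#' near-zero-variance genes — are divided by their largest magnitude before
#' ranking. The signed normalised estimate is returned; link confidence is
#' its magnitude.
#'
#' @inheritParams infer_lasso
#' @param kappa row-domination factor triggering normalisation (default 10).
#' @param pseudoinverse allow the pseudoinverse fallback (default `TRUE`);
#'   with `FALSE`, a rank-deficient `Y` is an error.
#' @return An `inference_result` of kind `"confidence"`.
#' @export
infer_lscon <- function(Y, P, kappa = 10, pseudoinverse = TRUE) {
  P <- check_YP(Y, P)
  G <- Y %*% t(Y)
  A <- tryCatch(
    -P %*% t(Y) %*% solve(G),
    error = function(e) {
      if (!pseudoinverse) {
        stop_grnsparse("rank_deficient",
                       "Y Y^T is singular and pseudoinverse fallback is disabled")
      }
      -P %*% MASS::ginv(Y)
    }
  )
  row_max <- apply(abs(A), 1, max)
  med <- stats::median(row_max)
  dominate <- med > 0 & row_max > kappa * med
  if (any(dominate)) {
    A[dominate, ] <- A[dominate, ] / row_max[dominate]
  }
  inference_result("lscon", confidence = A)
}

#' GENIE3-style tree-ensemble inference
#'
#' For each target gene, a random-forest regression of its expression on the
#' expression of all other genes across experiments; the impurity importance
#' of regulator `i` in the forest for target `j` becomes the confidence of
#' link `i -> j`. Requires the optional `ranger` package; when it is missing a
#' `grnsparse_feature_unavailable` error names the three always-available
#' methods instead.
#'
#' @inheritParams infer_lasso
#' @param num_trees trees per target-gene forest (default 100).
#' @param seed integer seed; each target forest is seeded deterministically
#'   from it.
#' @param mtry candidate regulators per split (default `sqrt(n - 1)`).
#' @return An `inference_result` of kind `"confidence"` (non-negative
#'   importances).
#' @export
infer_genie3 <- function(Y, P, num_trees = 100L, seed = 1L, mtry = NULL) {
  P <- check_YP(Y, P)
  if (!requireNamespace("ranger", quietly = TRUE)) {
    stop_grnsparse("feature_unavailable",
                   "infer_genie3() needs the optional 'ranger' package; ",
                   "infer_lasso(), infer_zscore() and infer_lscon() are ",
                   "available without it")
  }
  n <- nrow(Y)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(n - 1L)))
  conf <- matrix(0, n, n)
  for (j in seq_len(n)) {
    y <- Y[j, ]
    if (stats::sd(y) == 0) next   # constant target: no importances
    x <- t(Y[-j, , drop = FALSE])
    colnames(x) <- paste0("g", seq_len(n)[-j])
    rf <- ranger::ranger(x = x, y = y, num.trees = num_trees,
                         importance = "impurity", mtry = mtry,
                         num.threads = 1L, seed = seed + j,
                         verbose = FALSE)
    conf[-j, j] <- rf$variable.importance
  }
  if (all(conf == 0)) {
    warning("all tree importances are zero; downstream sweeps will fail")
  }
  inference_result("genie3", confidence = conf)
}
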