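#' Simulation configuration
#'
#' Bundles the parameters of one simulated benchmark condition: network size,
#' target sparsity (average out-links per gene), signal-to-noise ratio of the
#' expression data, number of replicates per perturbed gene, and a seed.
#' Defaults mirror the benchmark design: 100 genes, sparsity 3, SNR 0.1,
#' 3 replicates.
#'
#' @param n_genes number of genes (>= 10).
#' @param target_sparsity desired mean out-degree (>= 1, < `n_genes - 1`).
#' @param snr target signal-to-noise ratio (> 0).
#' @param replicates perturbation replicates per gene (>= 1).
#' @param seed integer seed driving network generation and noise.
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 100L, target_sparsity = 3,
                              snr = 0.1, replicates = 3L, seed = 1L) {
  if (n_genes < 10L) stop_grnsparse("invalid_input", "`n_genes` must be >= 10")
  if (target_sparsity < 1) {
    stop_grnsparse("invalid_input", "`target_sparsity` must be >= 1")
  }
  if (target_sparsity > n_genes - 1L) {
    stop_grnsparse("invalid_input",
                   "target sparsity exceeds the ", n_genes - 1L,
                   " possible out-links per gene")
  }
  if (snr <= 0) stop_grnsparse("invalid_input", "`snr` must be positive")
  if (replicates < 1L) {
    stop_grnsparse("invalid_input", "`replicates` must be >= 1")
  }
  structure(
    list(n_genes = as.integer(n_genes), target_sparsity = target_sparsity,
         snr = snr, replicates = as.integer(replicates),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# exponent of the truncated discrete power law (support 1..n-1) whose mean
# equals the target sparsity
solve_alpha_for_mean <- function(target, n_genes) {
  d <- seq_len(n_genes - 1L)
  mean_at <- function(a) sum(d^(1 - a)) / sum(d^(-a))
  if (target <= mean_at(50)) return(50)
  stats::uniroot(function(a) mean_at(a) - target,
                 lower = 1.0001, upper = 50, tol = 1e-10)$root
}

#' Generate a stable scale-free GRN
#'
#' Draws a random gene regulatory network whose out-degree sequence follows a
#' truncated discrete power law with mean equal to the target sparsity, and
#' whose dynamics are stable. Construction:
#' \enumerate{
#'   \item Solve for the exponent of the discrete power law on `1..n-1` whose
#'     mean equals `target_sparsity`; sample one out-degree per gene from it
#'     (re-drawing the sequence until its mean is within 0.5 links/node of the
#'     target).
#'   \item For each gene, assign that many regulatory targets uniformly
#'     without replacement among the other genes; link weights have uniform
#'     magnitude in `[0.5, 1.5]` and random sign.
#'   \item Add a uniform negative diagonal (self-degradation) shifting every
#'     eigenvalue so that all real parts are at most `-1`; the resulting
#'     matrix is strictly stable and invertible.
#' }
#' The diagonal is excluded from degree and sparsity accounting (the default
#' [grn()] policy), so the degree distribution is exactly the sampled
#' power-law sequence. This generator emulates the behaviour of scale-free GRN
#' simulators used in perturbation benchmarks; it is not a re-implementation
#' of any particular one.
#'
#' @param config a [simulation_config()].
#' @return A stable [grn()], reproducible from `config$seed`.
#' @examples
#' net <- generate_scalefree_grn(simulation_config(n_genes = 50, seed = 7))
#' max(Re(eigen(net$matrix)$values)) < 0
#' @export
generate_scalefree_grn <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_genes
  set.seed(config$seed)
  alpha <- solve_alpha_for_mean(config$target_sparsity, n)
  d <- seq_len(n - 1L)
  pmf <- d^(-alpha)
  pmf <- pmf / sum(pmf)
  best <- NULL
  for (attempt in 1:100) {
    deg <- sample(d, n, replace = TRUE, prob = pmf)
    err <- abs(mean(deg) - config$target_sparsity)
    if (is.null(best) || err < best$err) best <- list(deg = deg, err = err)
    if (err <= 0.5) break
  }
  deg <- best$deg
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    targets <- sample(setdiff(seq_len(n), i), deg[i])
    A[i, targets] <- stats::runif(deg[i], 0.5, 1.5) *
      sample(c(-1, 1), deg[i], replace = TRUE)
  }
  # diagonal shift: eigenvalues of A + c*I are eigenvalues of A plus c,
  # so a uniform diagonal of -(max Re eig + 1) guarantees stability exactly
  shift <- max(Re(eigen(A, only.values = TRUE)$values))
  diag(A) <- -(shift + 1)
  stopifnot(max(Re(eigen(A, only.values = TRUE)$values)) < 0)
  grn(A, gene_ids = sprintf("G%03d", seq_len(n)))
}

#' Perturbation design matrix
#'
#' Builds the binary design `P` of a single-gene perturbation experiment:
#' `n_genes` rows by `n_genes * replicates` columns, where each column has
#' exactly one 1 marking the perturbed gene and each gene is perturbed in
#' exactly `replicates` consecutive columns.
#'
#' @param n_genes number of genes.
#' @param replicates perturbations per gene (>= 1).
#' @return Object of class `"perturbation_design"`: list with the 0/1 `matrix`
#'   and `replicates`.
#' @examples
#' make_perturbation_design(3, 1)$matrix   # the 3x3 identity
#' @export
make_perturbation_design <- function(n_genes, replicates = 3L) {
  if (replicates < 1L) {
    stop_grnsparse("invalid_input", "`replicates` must be >= 1")
  }
  P <- diag(n_genes) %x% matrix(1, 1, replicates)
  structure(list(matrix = P, replicates = as.integer(replicates)),
            class = "perturbation_design")
}

#' @export
print.perturbation_design <- function(x, ...) {
  cat(sprintf("<perturbation_design> %d genes x %d experiments (%d replicates/gene)\n",
              nrow(x$matrix), ncol(x$matrix), x$replicates))
  invisible(x)
}

#' Signal-to-noise ratio of perturbation data
#'
#' Evaluates the SNR definition used throughout the simulator:
#' \deqn{\mathrm{SNR} = \frac{\sigma_{min}(Y)}{\sqrt{\chi^2_{1-a}(NM)\,\lambda}},}
#' where \eqn{\sigma_{min}(Y)} is the smallest singular value of the
#' fold-change matrix, \eqn{\chi^2_{1-a}(NM)} the chi-squared quantile at
#' level \eqn{1-a} with one degree of freedom per matrix entry, and
#' \eqn{\lambda} the variance of the Gaussian measurement noise.
#'
#' @param Y numeric matrix of (clean or measured) fold changes.
#' @param noise_var Gaussian noise variance \eqn{\lambda}.
#' @param level quantile tail level `a` (default 0.01).
#' @return The scalar SNR.
#' @export
snr_of <- function(Y, noise_var, level = 0.01) {
  if (noise_var <= 0) stop_grnsparse("invalid_input", "`noise_var` must be > 0")
  smin <- min(svd(Y, nu = 0, nv = 0)$d)
  smin / sqrt(stats::qchisq(1 - level, df = length(Y)) * noise_var)
}

#' Simulate perturbation expression data
#'
#' Generates steady-state fold-change data from the linear response model
#' \deqn{Y = -A^{-1} P + E,} where `A` is the interaction matrix, `P` the
#' perturbation design and `E` i.i.d. Gaussian noise. The noise standard
#' deviation is solved from the SNR definition (see [snr_of()]) applied to the
#' clean signal \eqn{-A^{-1}P}, so that the requested `snr` holds by
#' construction; the realized SNR (recomputed from the empirical variance of
#' the drawn noise) is recorded alongside.
#'
#' @param grn a stable, invertible [grn()].
#' @param design a [make_perturbation_design()] object.
#' @param snr target signal-to-noise ratio (> 0).
#' @param seed integer seed for the noise draw.
#' @param level chi-squared tail level of the SNR definition (default 0.01).
#' @return Object of class `"expression_dataset"`: list with `Y` (N x M
#'   fold changes), `design`, `snr_target`, `snr_realized`, `noise_var`
#'   (the calibrated \eqn{\lambda}) and `seed`.
#' @export
simulate_expression <- function(grn, design, snr, seed = 1L, level = 0.01) {
  stopifnot(inherits(grn, "grn"), inherits(design, "perturbation_design"))
  if (snr <= 0) stop_grnsparse("invalid_input", "`snr` must be positive")
  A <- grn$matrix
  P <- design$matrix
  if (nrow(P) != nrow(A)) {
    stop_grnsparse("invalid_input", "design and GRN dimensions disagree")
  }
  Y_clean <- tryCatch(-solve(A, P), error = function(e) {
    stop_grnsparse("singular_matrix",
                   "interaction matrix is singular: ", conditionMessage(e))
  })
  dimnames(Y_clean) <- NULL
  smin <- min(svd(Y_clean, nu = 0, nv = 0)$d)
  q <- stats::qchisq(1 - level, df = length(Y_clean))
  noise_var <- smin^2 / (snr^2 * q)   # lambda solving the SNR identity
  set.seed(seed)
  E <- matrix(stats::rnorm(length(Y_clean), sd = sqrt(noise_var)),
              nrow(Y_clean), ncol(Y_clean))
  Y <- Y_clean + E
  snr_realized <- snr_of(Y_clean, mean(E^2), level = level)
  structure(
    list(Y = Y, design = design, snr_target = snr,
         snr_realized = snr_realized, noise_var = noise_var,
         seed = as.integer(seed)),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %d genes x %d experiments, target SNR %.3g (realized %.3g)\n",
              nrow(x$Y), ncol(x$Y), x$snr_target, x$snr_realized))
  invisible(x)
}
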