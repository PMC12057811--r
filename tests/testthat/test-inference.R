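# noise-free square dataset: one experiment per gene makes Y invertible,
# so the model Y = -A^{-1}P can be inverted exactly
square_dataset <- function(n = 12, seed = 4) {
  net <- generate_scalefree_grn(simulation_config(n_genes = n, seed = seed))
  design <- make_perturbation_design(n, 1)
  Y <- -solve(net$matrix, design$matrix)
  list(net = net, design = design, Y = Y)
}

test_that("least-squares inference inverts noise-free data exactly", {
  d <- square_dataset()
  res <- infer_lscon(d$Y, d$design)
  expect_equal(res$kind, "confidence")
  expect_lt(max(abs(res$confidence - d$net$matrix)), 1e-8)
})

test_that("lscon ranking is scale-equivariant and falls back to pseudoinverse", {
  d <- square_dataset(seed = 6)
  base <- infer_lscon(d$Y, d$design)$confidence
  scaled <- infer_lscon(d$Y * 3.7, d$design)$confidence
  # the estimate is exactly equivariant, so rankings coincide
  expect_equal(scaled * 3.7, base, tolerance = 1e-8)

  # rank-deficient Y: duplicated experiments with M < N
  net <- generate_scalefree_grn(simulation_config(n_genes = 12, seed = 8))
  P <- make_perturbation_design(12, 1)$matrix[, 1:6]
  Y <- -solve(net$matrix, P)
  Yr <- cbind(Y, Y)
  Pr <- cbind(P, P)
  design <- structure(list(matrix = Pr, replicates = 1L),
                      class = "perturbation_design")
  expect_error(infer_lscon(Yr, design, pseudoinverse = FALSE),
               class = "grnsparse_rank_deficient")
  expect_silent(infer_lscon(Yr, design, pseudoinverse = TRUE))
})

test_that("lasso recovers the network as regularisation vanishes", {
  d <- square_dataset()
  lmax <- max(abs(d$Y %*% t(d$design$matrix))) / ncol(d$Y)
  res <- infer_lasso(d$Y, d$design, lambdas = c(lmax, lmax * 1e-8),
                     thresh = 1e-14)
  sw <- res$sweep
  # at lambda >= lambda_max the off-diagonal support is empty
  sparse_member <- sw$members[[which.max(sw$hyperparams)]]
  expect_equal(sparsity_of(sparse_member), 0)
  # at lambda -> 0 the estimate converges to the generating network
  dense_member <- sw$members[[which.min(sw$hyperparams)]]
  expect_lt(max(abs(dense_member$matrix - d$net$matrix)), 1e-6)
})

test_that("lasso paths sweep monotonically from empty to dense", {
  net <- generate_scalefree_grn(simulation_config(n_genes = 60, seed = 12))
  design <- make_perturbation_design(60, 3)
  dat <- simulate_expression(net, design, snr = 0.1, seed = 13)
  sw <- as_sparsity_sweep(infer_lasso(dat$Y, dat$design, nlambda = 50))
  expect_true(all(diff(sw$sparsities) >= 0))
  expect_lt(min(sw$sparsities), 0.5)
  expect_gt(max(sw$sparsities), 5)
  expect_error(infer_lasso(matrix(0, 5, 5), diag(5)),
               class = "grnsparse_invalid_input")
})

test_that("zscore confidences rank true links above chance", {
  net <- generate_scalefree_grn(simulation_config(n_genes = 40, seed = 21))
  design <- make_perturbation_design(40, 3)
  Y <- -solve(net$matrix, design$matrix)       # noise-free responses
  z <- infer_zscore(Y, design)$confidence
  truth <- link_support <- net$matrix != 0
  diag(truth) <- FALSE
  score <- abs(z); diag(score) <- 0
  top <- order(score, decreasing = TRUE)[1:sum(truth)]
  precision <- mean(truth[top])
  baseline <- mean(truth)
  expect_gt(precision, 2 * baseline)
})

test_that("zscore is invariant to replicate order and rejects flat data", {
  net <- generate_scalefree_grn(simulation_config(n_genes = 20, seed = 31))
  design <- make_perturbation_design(20, 3)
  dat <- simulate_expression(net, design, 0.1, seed = 32)
  z1 <- infer_zscore(dat$Y, design)$confidence
  # permute experiment columns inside each perturbation group
  perm <- as.vector(sapply(seq(1, 60, by = 3), function(i) i + c(2, 0, 1)))
  z2 <- infer_zscore(dat$Y[, perm], design)$confidence
  expect_equal(z1, z2, tolerance = 1e-12)
  expect_error(infer_zscore(matrix(1, 20, 60), design),
               class = "grnsparse_invalid_input")
})

test_that("tree-ensemble inference is seeded and better than random", {
  net <- generate_scalefree_grn(simulation_config(n_genes = 30, seed = 41))
  design <- make_perturbation_design(30, 3)
  dat <- simulate_expression(net, design, 0.1, seed = 42)
  a <- infer_genie3(dat$Y, design, num_trees = 50, seed = 5)
  b <- infer_genie3(dat$Y, design, num_trees = 50, seed = 5)
  expect_identical(a$confidence, b$confidence)

  truth <- net$matrix != 0
  diag(truth) <- FALSE
  score <- a$confidence
  diag(score) <- 0
  off <- row(score) != col(score)
  # rank-sum AUROC of confidences against the true links
  rk <- rank(score[off])
  pos <- truth[off]
  auroc <- (mean(rk[pos]) - (sum(pos) + 1) / 2) / sum(!pos)
  expect_gt(auroc, 0.5)
})
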