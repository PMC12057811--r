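# Independent brute-force oracles used across the suite. Each one is written
# from the defining formula with explicit loops / elementary calls so it never
# shares code paths with the implementation it checks.

# Hurwitz zeta by truncated summation plus a midpoint-corrected integral tail
oracle_zeta <- function(alpha, kmin = 1, terms = 1e5) {
  k <- seq(kmin, kmin + terms - 1)
  sum(k^(-alpha)) + (kmin + terms - 0.5)^(1 - alpha) / (alpha - 1)
}

# out-degree recount with explicit per-element loops
oracle_degrees <- function(m, include_diagonal = FALSE) {
  n <- nrow(m)
  deg <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j && !include_diagonal) next
      if (m[i, j] != 0) deg[i] <- deg[i] + 1L
    }
  }
  deg
}

# goodness-of-fit Q from a degree sequence, two explicit loops, scalar zeta
oracle_q <- function(degrees, n_genes = length(degrees)) {
  stopifnot(all(degrees >= 1))
  m <- length(degrees)
  alpha <- 1 + n_genes / sum(log(degrees / 0.5))
  z <- oracle_zeta(alpha)
  q <- 0
  for (d in seq_len(n_genes)) {
    x_d <- 0
    for (c in degrees) if (c == d) x_d <- x_d + 1
    expected <- m * d^(-alpha) / z
    q <- q + (x_d - expected)^2 / expected
  }
  q
}

# textbook Pearson correlation + two-sided t-test p-value on the log-log table
oracle_loglin <- function(degrees) {
  tab <- table(degrees[degrees > 0])
  x <- log(as.numeric(names(tab)))   # log d
  y <- log(as.numeric(tab))          # log x_d
  m <- length(x)
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(m)) {
    sxy <- sxy + (x[i] - mean(x)) * (y[i] - mean(y))
    sxx <- sxx + (x[i] - mean(x))^2
    syy <- syy + (y[i] - mean(y))^2
  }
  r <- sxy / sqrt(sxx * syy)
  t_stat <- r * sqrt((m - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t_stat), m - 2))
}

# OLS slope/intercept/R^2 of log x_d on log d from the closed normal equations
oracle_r2 <- function(degrees) {
  tab <- table(degrees[degrees > 0])
  x <- log(as.numeric(names(tab)))
  y <- log(as.numeric(tab))
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - beta * mean(x)
  1 - sum((y - (a + beta * x))^2) / sum((y - mean(y))^2)
}

# random all-positive degree table (every gene regulates something), for
# metric-vs-oracle comparisons
random_degree_table <- function(seed, n_min = 8, n_max = 60) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1)
  # mixture gives varied frequency tables with repeated and isolated degrees
  degrees <- pmax(1L, stats::rpois(n, sample(1:4, 1)) +
                    sample(0:2, n, replace = TRUE))
  degrees
}

# small random GRN helper
random_grn <- function(n, density = 0.1, seed = 1) {
  set.seed(seed)
  m <- matrix(0, n, n)
  links <- which(row(m) != col(m))
  keep <- sample(links, max(2, round(density * length(links))))
  m[keep] <- runif(length(keep), -2, 2)
  grn(m)
}
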