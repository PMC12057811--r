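#' Hurwitz zeta function
#'
#' Computes \eqn{\zeta(\alpha, k_{min}) = \sum_{n=0}^{\infty} (n + k_{min})^{-\alpha}},
#' the normalising constant of the discrete power-law probability mass function
#' \eqn{p_X(k) = k^{-\alpha} / \zeta(\alpha, k_{min})} for \eqn{k \ge k_{min}}.
#' Evaluated by direct summation of the first terms plus an Euler--Maclaurin
#' tail correction, accurate to well below `1e-10` for the exponents that occur
#' in degree-distribution fitting (`1 < alpha <= ~50`).
#'
#' @param alpha exponent, must be `> 1` (the series diverges otherwise).
#' @param kmin positive integer offset (`1` for degree distributions).
#' @return The value of the Hurwitz zeta function.
#' @examples
#' hurwitz_zeta(2, 1)      # pi^2 / 6
#' hurwitz_zeta(3, 1)      # Apery's constant
#' @export
hurwitz_zeta <- function(alpha, kmin = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha)) {
    stop_grnsparse("invalid_input", "`alpha` must be a finite scalar")
  }
  if (alpha <= 1) {
    stop_grnsparse("divergence",
                   "Hurwitz zeta diverges for alpha <= 1 (alpha = ", alpha, ")")
  }
  if (kmin < 1 || kmin != round(kmin)) {
    stop_grnsparse("invalid_input", "`kmin` must be a positive integer")
  }
  # sum kmin..(kmin+N-1) directly, Euler-Maclaurin for the tail from t = kmin+N
  N <- 30L
  head <- sum((kmin + 0:(N - 1L))^(-alpha))
  t <- kmin + N
  a <- alpha
  tail <- t^(1 - a) / (a - 1) + t^(-a) / 2 +
    a * t^(-a - 1) / 12 -
    a * (a + 1) * (a + 2) * t^(-a - 3) / 720 +
    a * (a + 1) * (a + 2) * (a + 3) * (a + 4) * t^(-a - 5) / 30240
  head + tail
}

#' Discrete power-law pmf
#'
#' Probability mass function \eqn{p_X(k) = k^{-\alpha}/\zeta(\alpha, k_{min})}
#' on integers \eqn{k \ge k_{min}}, the model the scale-free topology
#' hypothesis assumes for node out-degrees.
#'
#' @param k vector of positive integers.
#' @param alpha exponent `> 1`.
#' @param kmin support minimum (default 1).
#' @return Vector of probabilities (0 for `k < kmin`).
#' @export
dpowerlaw <- function(k, alpha, kmin = 1L) {
  z <- hurwitz_zeta(alpha, kmin)
  p <- ifelse(k >= kmin, k^(-alpha) / z, 0)
  p
}

#' Sample from the discrete power law
#'
#' Exact inverse-CDF sampling from \eqn{p_X(k) \propto k^{-\alpha}},
#' \eqn{k \ge k_{min}}. The CDF is tabulated up to `kmax`; draws falling in the
#' (tiny) remaining tail mass are resolved with the continuous-tail inverse
#' \eqn{k = \lceil k_{max} (1-v)^{-1/(\alpha-1)} \rceil}.
#'
#' @param n number of draws.
#' @param alpha exponent `> 1`.
#' @param kmin support minimum.
#' @param kmax CDF tabulation bound (default `1e5`).
#' @return Integer vector of `n` draws.
#' @export
rpowerlaw <- function(n, alpha, kmin = 1L, kmax = 1e5L) {
  z <- hurwitz_zeta(alpha, kmin)
  k <- seq.int(kmin, kmax)
  p <- k^(-alpha) / z
  cdf <- cumsum(p)
  u <- stats::runif(n)
  out <- k[pmin(findInterval(u, cdf) + 1L, length(k))]
  over <- u > cdf[length(cdf)]
  if (any(over)) {
    v <- stats::runif(sum(over))
    out[over] <- as.integer(ceiling(kmax * (1 - v)^(-1 / (alpha - 1))))
  }
  as.integer(out)
}

#' Approximate maximum-likelihood power-law exponent
#'
#' Fits the exponent of a discrete power law to the positive out-degrees of a
#' network using the closed-form continuous approximation of the discrete
#' maximum-likelihood estimator,
#' \deqn{\hat\alpha = 1 + n_g \Big[\sum_{i : c_i \ge 1}
#'   \ln\frac{c_i}{k_{min} - 1/2}\Big]^{-1},}
#' with \eqn{k_{min} = 1}. The sum runs over all \eqn{n} genes: a gene with
#' zero out-degree contributes \eqn{\ln 0 = -\infty}, degenerating
#' \eqn{\hat\alpha} to 1, where the zeta normalisation diverges — the fit
#' (and hence the goodness-of-fit statistic) is therefore only defined when
#' every gene has at least one out-link. This is deliberate: it is what makes
#' the goodness-of-fit selector skip fragmentary networks whose tiny frequency
#' tables would otherwise score deceptively small chi-squared values (see the
#' methods vignette). The estimator depends only on the degree sequence, never
#' on link weights. Note it is an approximation: at \eqn{k_{min} = 1} it
#' systematically underestimates steep exponents, a property inherited from
#' the closed form itself.
#'
#' @param x a [grn()] or [degree_distribution()] object.
#' @return Object of class `"powerlaw_fit"`: list with `alpha`, `kmin`,
#'   `zeta_value` (\eqn{\zeta(\hat\alpha, k_{min})}) and `n_obs`
#'   (\eqn{n_g}).
#' @examples
#' dd <- degree_distribution(grn(matrix(c(0, 1, 1, 0), 2, 2)))
#' fit_alpha_ml(dd)$alpha   # all degrees 1 -> 1 + 1/log(2)
#' @export
fit_alpha_ml <- function(x) {
  dd <- as_degree_distribution(x)
  if (dd$n_positive == 0L) {
    stop_grnsparse("undefined_fit",
                   "no gene has a positive out-degree; exponent undefined")
  }
  if (dd$n_positive < dd$n_genes) {
    # ln(0) terms push the estimate to alpha = 1 where zeta diverges
    stop_grnsparse("undefined_fit",
                   dd$n_genes - dd$n_positive, " gene(s) with zero ",
                   "out-degree degenerate the exponent estimate to 1")
  }
  kmin <- dd$kmin
  deg <- dd$out_degrees[dd$out_degrees > 0L]
  s <- sum(log(deg / (kmin - 0.5)))
  alpha <- 1 + dd$n_genes / s
  structure(
    list(alpha = alpha, kmin = kmin,
         zeta_value = hurwitz_zeta(alpha, kmin), n_obs = dd$n_positive),
    class = "powerlaw_fit"
  )
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> alpha = %.4f (kmin = %d, n = %d, zeta = %.6f)\n",
              x$alpha, x$kmin, x$n_obs, x$zeta_value))
  invisible(x)
}

#' Goodness-of-fit metric Q
#'
#' Pearson chi-squared-type statistic comparing the observed out-degree
#' frequencies of a network with the expected counts under the fitted discrete
#' power law:
#' \deqn{Q = \sum_{d=1}^{n} \frac{(x_d - n_g\, p(d))^2}{n_g\, p(d)},}
#' where \eqn{p(d) = d^{-\hat\alpha}/\zeta(\hat\alpha, 1)} uses the
#' [fit_alpha_ml()] exponent and \eqn{n_g} is the number of genes with a
#' positive out-degree. The sum runs over the full degree range `1..n`
#' (matrix dimension); empty cells contribute their expected count, so no cell
#' pooling is applied and no division by zero can occur. Small `Q` means the
#' degree distribution is close to a power law; the goodness-of-fit selector
#' minimises `Q` over a sparsity sweep.
#'
#' The metric is undefined (`defined = FALSE`) whenever the exponent fit is
#' undefined: in particular for any network in which some gene has no out-link at all
#' (see [fit_alpha_ml()]). Such networks — typically the sparse end of a
#' sweep — are skipped by the selector, never chosen; in plots their `Q` is
#' conventionally shown capped at a large value, which does not affect the
#' argmin.
#'
#' @param x a [grn()] or [degree_distribution()] object.
#' @return Object of class `"gof_metric"`: list with `q`, `n_positive`, `fit`
#'   (the [fit_alpha_ml()] result or `NULL`) and `defined`.
#' @export
gof_metric <- function(x) {
  dd <- as_degree_distribution(x)
  undefined <- structure(
    list(q = NA_real_, n_positive = dd$n_positive, fit = NULL,
         defined = FALSE),
    class = "gof_metric"
  )
  if (dd$n_positive < 2L) return(undefined)
  fit <- tryCatch(fit_alpha_ml(dd),
                  grnsparse_undefined_fit = function(e) NULL)
  if (is.null(fit)) return(undefined)
  if (max(as.integer(names(dd$counts))) > dd$n_genes) {
    stop_grnsparse("invalid_input",
                   "out-degrees exceed the stated gene count; the frequency ",
                   "cells d = 1..n cannot hold them")
  }
  d <- seq_len(dd$n_genes)
  expected <- dd$n_positive * d^(-fit$alpha) / fit$zeta_value
  observed <- numeric(dd$n_genes)
  idx <- as.integer(names(dd$counts))
  observed[idx] <- dd$counts
  q <- sum((observed - expected)^2 / expected)
  structure(
    list(q = q, n_positive = dd$n_positive, fit = fit, defined = TRUE),
    class = "gof_metric"
  )
}

#' @export
print.gof_metric <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<gof_metric> Q = %.4f (n_g = %d, alpha = %.4f)\n",
                x$q, x$n_positive, x$fit$alpha))
  } else {
    cat("<gof_metric> undefined (fewer than 2 genes with out-degree > 0)\n")
  }
  invisible(x)
}

#' Logarithmic-linearity metric
#'
#' Pearson correlation between \eqn{\log x_d} and \eqn{\log d} over the
#' support \eqn{D = \{d : x_d > 0\}} of the out-degree frequency table,
#' together with the two-sided p-value of the no-correlation null via the
#' t-transform \eqn{t = r\sqrt{(m-2)/(1-r^2)}} with \eqn{m - 2} degrees of
#' freedom, \eqn{m = |D|}. A scale-free network shows a strong negative
#' log-log trend (\eqn{r} near \eqn{-1}); the logarithmic-linearity selector
#' minimises the p-value subject to \eqn{r < -0.5}. An exactly log-linear
#' table maps to \eqn{p = 0}.
#'
#' Undefined (`defined = FALSE`) when fewer than 3 support points exist or the
#' log-frequencies are constant (correlation has no meaning there); undefined
#' sweep members are skipped by the selector.
#'
#' @param x a [grn()] or [degree_distribution()] object.
#' @return Object of class `"loglin_metric"`: list with `r`, `p_value`,
#'   `n_points` (\eqn{|D|}) and `defined`.
#' @examples
#' # frequencies 64 * d^-2 on d in {1,2,4,8}: exactly log-linear
#' dd <- degree_distribution_from_table(c(`1` = 64, `2` = 16, `4` = 4, `8` = 1))
#' loglin_metric(dd)
#' @export
loglin_metric <- function(x) {
  dd <- as_degree_distribution(x)
  undefined <- structure(
    list(r = NA_real_, p_value = NA_real_,
         n_points = length(dd$counts), defined = FALSE),
    class = "loglin_metric"
  )
  m <- length(dd$counts)
  if (m < 3L) return(undefined)
  la <- log(as.numeric(dd$counts))        # alpha_d = log x_d
  lb <- log(as.numeric(names(dd$counts))) # beta_d  = log d
  if (stats::sd(la) == 0) return(undefined)
  r <- sum((la - mean(la)) * (lb - mean(lb))) /
    sqrt(sum((la - mean(la))^2) * sum((lb - mean(lb))^2))
  r <- max(-1, min(1, r))
  if (1 - r^2 < .Machine$double.eps * 100) {
    p <- 0
  } else {
    t_stat <- r * sqrt((m - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), df = m - 2)
  }
  structure(
    list(r = r, p_value = p, n_points = m, defined = TRUE),
    class = "loglin_metric"
  )
}

#' @export
print.loglin_metric <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<loglin_metric> r = %.4f, p = %.4g (%d support points)\n",
                x$r, x$p_value, x$n_points))
  } else {
    cat("<loglin_metric> undefined (< 3 support points or constant log-frequencies)\n")
  }
  invisible(x)
}

#' Scale-freeness R-squared
#'
#' Coefficient of determination of the ordinary least-squares regression of
#' \eqn{\log x_d} on \eqn{\log d} over the frequency-table support — a
#' descriptive scale-freeness score (1 = perfectly log-linear). For a simple
#' regression this equals the squared Pearson correlation of
#' [loglin_metric()].
#'
#' @param x a [grn()] or [degree_distribution()] object.
#' @return R-squared in `[0, 1]`.
#' @export
scale_freeness_r2 <- function(x) {
  dd <- as_degree_distribution(x)
  if (length(dd$counts) < 3L) {
    stop_grnsparse("undefined_metric",
                   "scale-freeness R^2 needs at least 3 support points")
  }
  la <- log(as.numeric(dd$counts))
  lb <- log(as.numeric(names(dd$counts)))
  fit <- stats::lm.fit(cbind(1, lb), la)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((la - mean(la))^2)
  if (ss_tot == 0) {
    stop_grnsparse("undefined_metric",
                   "constant log-frequencies: R^2 undefined")
  }
  1 - ss_res / ss_tot
}

#' Degree distribution from a frequency table
#'
#' Convenience constructor turning a named frequency table (names = degrees,
#' values = gene counts \eqn{x_d}) into a [degree_distribution()] object, e.g.
#' for metric evaluation on published tables.
#'
#' @param counts named numeric vector; names are positive integer degrees.
#' @param n_genes total gene count `n` (defaults to the number of genes with
#'   positive degree, i.e. `sum(counts)`).
#' @return A `"degree_distribution"` object.
#' @export
degree_distribution_from_table <- function(counts, n_genes = sum(counts)) {
  d <- as.integer(names(counts))
  if (any(is.na(d)) || any(d < 1L)) {
    stop_grnsparse("invalid_input",
                   "frequency table names must be positive integer degrees")
  }
  degrees <- rep(d, times = as.integer(counts))
  degree_distribution_from_degrees(degrees, n_genes = n_genes)
}
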