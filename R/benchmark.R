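#' F-beta accuracy of a predicted network
#'
#' Link-level precision/recall of a predicted network against a gold
#' standard, combined as
#' \deqn{F_\beta = (1+\beta^2)\frac{\mathrm{precision}\cdot\mathrm{recall}}
#'   {\beta^2\,\mathrm{precision} + \mathrm{recall}}.}
#' Links are directed and sign-ignored (a predicted repression matching a true
#' activation still counts as a true positive); diagonals follow each
#' network's policy. `beta = 2` weights recall twice as heavily as precision,
#' appropriate when false positives vastly outnumber true positives in sparse
#' networks. Returns 0 when precision and recall are both zero.
#'
#' @param predicted,truth [grn()] objects of equal dimension.
#' @param beta recall weight (> 0, default 2).
#' @return F-beta score in `[0, 1]`.
#' @examples
#' a <- matrix(c(0, 1, 1, 0), 2, 2); b <- matrix(c(0, 1, 0, 0), 2, 2)
#' f_beta_score(grn(b), grn(a))
#' @export
f_beta_score <- function(predicted, truth, beta = 2) {
  stopifnot(inherits(predicted, "grn"), inherits(truth, "grn"))
  if (beta <= 0) stop_grnsparse("invalid_input", "`beta` must be positive")
  if (!identical(dim(predicted$matrix), dim(truth$matrix))) {
    stop_grnsparse("invalid_input", "predicted and truth dimensions differ")
  }
  ps <- link_support(predicted)
  ts <- link_support(truth)
  tp <- sum(ps & ts)
  n_pred <- sum(ps)
  n_true <- sum(ts)
  if (n_true == 0L) return(if (n_pred == 0L) 1 else 0)
  precision <- if (n_pred == 0L) 0 else tp / n_pred
  recall <- tp / n_true
  if (precision + recall == 0) return(0)
  (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
}

#' Benchmark configuration
#'
#' Defines the simulation/inference grid of the selection benchmark. The
#' defaults reproduce the reference design: networks of 100 genes at true
#' sparsities 3 and 5 links/node (3 networks each), perturbation data with 3
#' replicates per gene at SNRs 0.1 and 0.01, four inference methods, and
#' 100-member sparsity sweeps — 48 dataset-by-method combinations in total.
#'
#' @param n_genes genes per network (default 100).
#' @param sparsities true sparsities (default `c(3, 5)`).
#' @param snrs signal-to-noise ratios (default `c(0.1, 0.01)`).
#' @param n_networks networks per sparsity (default 3).
#' @param replicates perturbation replicates per gene (default 3).
#' @param n_grids sweep members per confidence matrix / lambda path
#'   (default 100).
#' @param methods inference methods to run; `"genie3"` is dropped with a
#'   message when the optional `ranger` package is missing.
#' @param beta F-beta recall weight (default 2).
#' @param genie3_trees trees per GENIE3-style forest (default 100).
#' @param seed master seed; every network, noise draw and forest derives its
#'   own seed from it.
#' @return Object of class `"benchmark_config"`.
#' @export
benchmark_config <- function(n_genes = 100L, sparsities = c(3, 5),
                             snrs = c(0.1, 0.01), n_networks = 3L,
                             replicates = 3L, n_grids = 100L,
                             methods = c("lasso", "zscore", "lscon", "genie3"),
                             beta = 2, genie3_trees = 100L, seed = 1L) {
  methods <- match.arg(methods, c("lasso", "zscore", "lscon", "genie3"),
                       several.ok = TRUE)
  if ("genie3" %in% methods && !requireNamespace("ranger", quietly = TRUE)) {
    message("optional 'ranger' package not installed; dropping genie3 from the grid")
    methods <- setdiff(methods, "genie3")
  }
  structure(
    list(n_genes = as.integer(n_genes), sparsities = sparsities, snrs = snrs,
         n_networks = as.integer(n_networks),
         replicates = as.integer(replicates), n_grids = as.integer(n_grids),
         methods = methods, beta = beta,
         genie3_trees = as.integer(genie3_trees), seed = as.integer(seed)),
    class = "benchmark_config"
  )
}

#' Enumerate the benchmark grid
#'
#' One row per (true sparsity, network replicate, SNR, inference method)
#' combination; with the default configuration and all four methods this is
#' `2 * 3 * 2 * 4 = 48` rows.
#'
#' @param config a [benchmark_config()].
#' @return `data.frame` with columns `sparsity`, `network`, `snr`, `method`.
#' @export
benchmark_grid <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  g <- expand.grid(method = config$methods, snr = config$snrs,
                   network = seq_len(config$n_networks),
                   sparsity = config$sparsities,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g[, c("sparsity", "network", "snr", "method")]
}

run_one_inference <- function(method, Y, P, config, seed) {
  switch(method,
    lasso = infer_lasso(Y, P, nlambda = config$n_grids),
    zscore = infer_zscore(Y, P),
    lscon = infer_lscon(Y, P),
    genie3 = infer_genie3(Y, P, num_trees = config$genie3_trees, seed = seed),
    stop_grnsparse("invalid_input", "unknown method: ", method)
  )
}

#' Run the sparsity-selection benchmark
#'
#' Executes the full grid of [benchmark_config()]: for every combination it
#' simulates a scale-free network and SNR-controlled perturbation data, infers
#' a sparsity sweep, applies both selectors, and compares each selection with
#' the sweep member whose sparsity is closest to the gold standard's (ties
#' toward the denser member). Two records are produced per combination, one
#' per selector, each with the selected and closest sparsities, their F-beta
#' scores and both deltas. Selector failures (e.g. no sweep member with
#' `r < -0.5`) are recorded with `failed = TRUE`; unexpected per-combination
#' errors are logged to stderr and recorded likewise, never aborting the grid.
#' The whole table is reproducible from the master seed.
#'
#' @param config a [benchmark_config()].
#' @param progress log per-combination progress to stderr (default `TRUE`).
#' @return `data.frame` of benchmark records; see Details for columns.
#' @details Columns: `grn_id`, `true_sparsity` (nominal), `realized_sparsity`
#'   (gold standard's actual links/node), `snr`, `method_name`,
#'   `selector_name`, `selected_sparsity`, `closest_sparsity`,
#'   `delta_sparsity` (= selected − closest), `f2_selected`, `f2_closest`,
#'   `delta_f2`, `failed`, `outlier` (`|delta_sparsity| > 10`).
#' @export
run_benchmark <- function(config, progress = TRUE) {
  stopifnot(inherits(config, "benchmark_config"))
  set.seed(config$seed)
  n_nets <- length(config$sparsities) * config$n_networks
  seed_pool <- sample.int(.Machine$integer.max,
                          n_nets * (1L + length(config$snrs) * 2L))
  next_seed <- local({ i <- 0L; function() { i <<- i + 1L; seed_pool[i] } })
  design <- make_perturbation_design(config$n_genes, config$replicates)
  records <- list()
  note <- function(...) if (progress) message(...)

  for (s in config$sparsities) {
    for (k in seq_len(config$n_networks)) {
      grn_seed <- next_seed()
      truth <- generate_scalefree_grn(simulation_config(
        n_genes = config$n_genes, target_sparsity = s,
        snr = config$snrs[1], replicates = config$replicates,
        seed = grn_seed))
      realized <- sparsity_of(truth)
      grn_id <- sprintf("s%g_net%d", s, k)
      for (snr in config$snrs) {
        noise_seed <- next_seed()
        method_seed <- next_seed()
        dat <- simulate_expression(truth, design, snr, seed = noise_seed)
        for (method in config$methods) {
          note(sprintf("[grnsparse] %s snr=%g %s", grn_id, snr, method))
          rec <- benchmark_one(dat, truth, realized, method, config,
                               method_seed, grn_id, s, snr)
          records <- c(records, rec)
        }
      }
    }
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

benchmark_one <- function(dat, truth, realized, method, config,
                          method_seed, grn_id, s, snr) {
  base <- data.frame(
    grn_id = grn_id, true_sparsity = s, realized_sparsity = realized,
    snr = snr, method_name = method, selector_name = NA_character_,
    selected_sparsity = NA_real_, closest_sparsity = NA_real_,
    delta_sparsity = NA_real_, f2_selected = NA_real_,
    f2_closest = NA_real_, delta_f2 = NA_real_,
    failed = TRUE, outlier = FALSE, stringsAsFactors = FALSE
  )
  sweep <- tryCatch({
    res <- run_one_inference(method, dat$Y, dat$design, config, method_seed)
    as_sparsity_sweep(res, n_grids = config$n_grids)
  }, error = function(e) {
    message("[grnsparse] inference failed (", grn_id, ", ", method, "): ",
            conditionMessage(e))
    NULL
  })
  if (is.null(sweep)) {
    recs <- lapply(c("goodness_of_fit", "logarithmic_linearity"), function(sel) {
      r <- base; r$selector_name <- sel; r
    })
    return(recs)
  }
  metrics <- sweep_metrics(sweep)
  # closest-to-true member: nearest sparsity, ties toward the denser member
  dist <- abs(sweep$sparsities - realized)
  cand <- which(dist == min(dist))
  closest_idx <- cand[which.max(sweep$sparsities[cand])]
  f2_closest <- f_beta_score(sweep$members[[closest_idx]], truth,
                             beta = config$beta)
  selectors <- list(goodness_of_fit = select_gof,
                    logarithmic_linearity = select_loglin)
  lapply(names(selectors), function(sel_name) {
    r <- base
    r$selector_name <- sel_name
    sel <- tryCatch(selectors[[sel_name]](sweep, metrics),
                    grnsparse_selection_failure = function(e) {
                      message("[grnsparse] ", sel_name, " failed (", grn_id,
                              ", ", method, "): ", conditionMessage(e))
                      NULL
                    })
    if (is.null(sel)) return(r)
    r$failed <- FALSE
    r$selected_sparsity <- sel$selected_sparsity
    r$closest_sparsity <- sweep$sparsities[closest_idx]
    r$delta_sparsity <- r$selected_sparsity - r$closest_sparsity
    r$f2_selected <- f_beta_score(sel$selected_grn, truth, beta = config$beta)
    r$f2_closest <- f2_closest
    r$delta_f2 <- r$f2_selected - r$f2_closest
    r$outlier <- abs(r$delta_sparsity) > 10
    r
  })
}

#' Summarise benchmark records
#'
#' Median absolute sparsity deviation per (selector, method) cell:
#' `median_abs_delta` is the median of `|delta_sparsity|` over all non-failed
#' records in the cell, `median_abs_delta_no_outlier` additionally drops
#' records with `|delta_sparsity| > 10` (rare catastrophic selections of very
#' dense networks), and `n`, `n_failed`, `n_outlier` count the cell's records.
#' Empty cells are reported with `NA` medians, not zero.
#'
#' @param records output of [run_benchmark()].
#' @return `data.frame`, one row per (selector, method).
#' @export
summarize_benchmark <- function(records) {
  stopifnot(is.data.frame(records))
  cells <- unique(records[, c("selector_name", "method_name")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- records[records$selector_name == cells$selector_name[i] &
                     records$method_name == cells$method_name[i], ]
    ok <- sub[!sub$failed, ]
    data.frame(
      selector_name = cells$selector_name[i],
      method_name = cells$method_name[i],
      n = nrow(sub),
      n_failed = sum(sub$failed),
      n_outlier = sum(ok$outlier),
      median_abs_delta = if (nrow(ok)) stats::median(abs(ok$delta_sparsity))
                         else NA_real_,
      median_abs_delta_no_outlier =
        if (any(!ok$outlier)) stats::median(abs(ok$delta_sparsity[!ok$outlier]))
        else NA_real_,
      median_delta_f2 = if (nrow(ok)) stats::median(ok$delta_f2) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out[order(out$selector_name, out$method_name), ]
}
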