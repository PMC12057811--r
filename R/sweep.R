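#' Sparsity sweep
#'
#' An ordered family of GRNs of varying sparsity, produced either by an
#' inference method's native hyperparameter path (e.g. a LASSO lambda grid) or
#' by thresholding a link-confidence matrix ([sweep_from_confidence()]).
#' Members are stored in non-decreasing order of sparsity so that tie-breaking
#' "toward lower sparsity" is simply "toward the earlier member".
#'
#' @param members list of [grn()] objects (same dimension).
#' @param hyperparams optional vector of per-member hyperparameter values
#'   (lambda or confidence cutoff); reordered together with the members.
#' @return Object of class `"sparsity_sweep"`: list with `members`,
#'   `sparsities` and `hyperparams`.
#' @export
sparsity_sweep <- function(members, hyperparams = NULL) {
  if (length(members) < 2L) {
    stop_grnsparse("invalid_input", "a sparsity sweep needs >= 2 members")
  }
  if (!all(vapply(members, inherits, logical(1), "grn"))) {
    stop_grnsparse("invalid_input", "all sweep members must be 'grn' objects")
  }
  n <- nrow(members[[1]]$matrix)
  if (!all(vapply(members, function(g) nrow(g$matrix), integer(1)) == n)) {
    stop_grnsparse("invalid_input", "sweep members must share dimensions")
  }
  if (is.null(hyperparams)) hyperparams <- rep(NA_real_, length(members))
  if (length(hyperparams) != length(members)) {
    stop_grnsparse("invalid_input", "one hyperparameter per member required")
  }
  sparsities <- vapply(members, sparsity_of, numeric(1))
  ord <- order(sparsities)
  structure(
    list(members = members[ord], sparsities = sparsities[ord],
         hyperparams = hyperparams[ord]),
    class = "sparsity_sweep"
  )
}

#' @export
print.sparsity_sweep <- function(x, ...) {
  cat(sprintf("<sparsity_sweep> %d members, sparsity %.3f .. %.3f links/node\n",
              length(x$members), min(x$sparsities), max(x$sparsities)))
  invisible(x)
}

#' @export
length.sparsity_sweep <- function(x) length(x$members)

#' Build a sparsity sweep by thresholding a confidence matrix
#'
#' Creates `n_grids` networks of decreasing density from a link-confidence
#' matrix by varying the minimum-confidence cutoff from the maximum observed
#' magnitude down to the minimum. Member `g` keeps every link with
#' `|confidence| >= threshold_g`, retaining the signed confidence values as
#' link weights, so sparser members' supports are nested inside denser ones.
#'
#' Two threshold grids are available: `"rank"` (default) places cutoffs at
#' evenly spaced ranks of the sorted unique magnitudes, which guarantees
#' members of distinct sparsity whenever enough distinct magnitudes exist;
#' `"linear"` spaces cutoffs linearly in magnitude, which concentrates members
#' at the sparse end for heavy-tailed confidence distributions.
#'
#' @param confidence square numeric matrix of link confidences (sign allowed).
#' @param n_grids number of cutoffs (>= 2, default 100).
#' @param gene_ids optional gene labels.
#' @param include_diagonal diagonal policy for the resulting networks.
#' @param grid `"rank"` or `"linear"` threshold spacing.
#' @return A [sparsity_sweep()] whose `hyperparams` are the cutoffs.
#' @export
sweep_from_confidence <- function(confidence, n_grids = 100L, gene_ids = NULL,
                                  include_diagonal = FALSE,
                                  grid = c("rank", "linear")) {
  grid <- match.arg(grid)
  if (!is.matrix(confidence) || nrow(confidence) != ncol(confidence)) {
    stop_grnsparse("invalid_input", "`confidence` must be a square matrix")
  }
  if (!all(is.finite(confidence))) {
    stop_grnsparse("invalid_input", "`confidence` entries must be finite")
  }
  if (n_grids < 2L) {
    stop_grnsparse("invalid_input", "`n_grids` must be >= 2")
  }
  mag <- abs(confidence)
  if (!include_diagonal) diag(mag) <- 0   # never thresholds on self-links
  u <- sort(unique(mag[mag > 0]), decreasing = TRUE)
  if (length(u) == 0L) {
    stop_grnsparse("empty_confidence",
                   "all-zero confidence matrix: no sweep possible")
  }
  thresholds <- switch(grid,
    rank = u[unique(round(seq(1, length(u), length.out = n_grids)))],
    linear = seq(u[1], u[length(u)], length.out = n_grids)
  )
  members <- lapply(thresholds, function(th) {
    m <- confidence
    m[mag < th] <- 0
    grn(m, gene_ids = gene_ids, include_diagonal = include_diagonal)
  })
  sparsity_sweep(members, hyperparams = thresholds)
}

#' Per-member metric table of a sparsity sweep
#'
#' Evaluates both selection metrics on every sweep member and returns one row
#' per member: hyperparameter, sparsity, number of genes with positive
#' out-degree, fitted exponent, goodness-of-fit `Q`, log-log correlation `r`
#' with p-value, and the scale-freeness R-squared. Undefined metrics are `NA`.
#'
#' @param sweep a [sparsity_sweep()].
#' @return `data.frame` with columns `index`, `hyperparam`, `sparsity`,
#'   `n_positive`, `alpha`, `q`, `r`, `p_value`, `r_squared`.
#' @export
sweep_metrics <- function(sweep) {
  stopifnot(inherits(sweep, "sparsity_sweep"))
  rows <- lapply(seq_along(sweep$members), function(i) {
    dd <- degree_distribution(sweep$members[[i]])
    g <- gof_metric(dd)
    l <- loglin_metric(dd)
    data.frame(
      index = i,
      hyperparam = sweep$hyperparams[i],
      sparsity = sweep$sparsities[i],
      n_positive = dd$n_positive,
      alpha = if (g$defined) g$fit$alpha else NA_real_,
      q = if (g$defined) g$q else NA_real_,
      r = if (l$defined) l$r else NA_real_,
      p_value = if (l$defined) l$p_value else NA_real_,
      r_squared = if (l$defined) l$r^2 else NA_real_
    )
  })
  do.call(rbind, rows)
}

selection_result <- function(index, sweep, metrics, method_name) {
  structure(
    list(selected_index = index,
         selected_sparsity = sweep$sparsities[index],
         selected_grn = sweep$members[[index]],
         metric_values = metrics,
         method_name = method_name),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: member %d of %d, sparsity %.3f links/node\n",
              x$method_name, x$selected_index, nrow(x$metric_values),
              x$selected_sparsity))
  invisible(x)
}

#' Goodness-of-fit sparsity selection
#'
#' Selects the sweep member minimising the goodness-of-fit statistic `Q`
#' ([gof_metric()]) over all members where it is defined. Exact ties are
#' broken toward the lower-sparsity member (parsimony). Any strictly monotone
#' rescaling of the `Q` series (such as capping and min-max scaling used for
#' plotting) leaves the argmin, and hence the selection, unchanged.
#'
#' @param sweep a [sparsity_sweep()].
#' @param metrics optional precomputed [sweep_metrics()] table (computed if
#'   missing).
#' @return A `"selection_result"` with `method_name = "goodness_of_fit"`.
#' @export
select_gof <- function(sweep, metrics = NULL) {
  stopifnot(inherits(sweep, "sparsity_sweep"))
  if (is.null(metrics)) metrics <- sweep_metrics(sweep)
  ok <- which(!is.na(metrics$q))
  if (length(ok) == 0L) {
    stop_grnsparse("selection_failure",
                   "no sweep member has a defined goodness-of-fit metric")
  }
  cand <- ok[metrics$q[ok] == min(metrics$q[ok])]
  idx <- cand[which.min(metrics$sparsity[cand])]
  selection_result(idx, sweep, metrics, "goodness_of_fit")
}

#' Logarithmic-linearity sparsity selection
#'
#' Among sweep members whose log-log degree correlation is defined and
#' satisfies `r < r_max` (default `-0.5`, filtering out members without a
#' clear negative trend), selects the member with the smallest correlation
#' p-value. Exact ties are broken toward the lower-sparsity member. If no
#' member passes the correlation constraint a `grnsparse_selection_failure`
#' error is signalled — callers such as [run_benchmark()] record the failure
#' rather than silently substituting a member.
#'
#' @param sweep a [sparsity_sweep()].
#' @param metrics optional precomputed [sweep_metrics()] table.
#' @param r_max correlation constraint (default `-0.5`).
#' @return A `"selection_result"` with `method_name = "logarithmic_linearity"`.
#' @export
select_loglin <- function(sweep, metrics = NULL, r_max = -0.5) {
  stopifnot(inherits(sweep, "sparsity_sweep"))
  if (is.null(metrics)) metrics <- sweep_metrics(sweep)
  ok <- which(!is.na(metrics$r) & metrics$r < r_max)
  if (length(ok) == 0L) {
    stop_grnsparse("selection_failure",
                   "no sweep member satisfies r < ", r_max,
                   "; logarithmic-linearity selection failed")
  }
  cand <- ok[metrics$p_value[ok] == min(metrics$p_value[ok])]
  idx <- cand[which.min(metrics$sparsity[cand])]
  selection_result(idx, sweep, metrics, "logarithmic_linearity")
}

#' Write a sweep's metric table with selection flags
#'
#' Serialises the per-member metric series as TSV (one row per member:
#' hyperparameter, sparsity, Q, r, p-value, selection flags) and, optionally,
#' a small JSON summary of the two selections.
#'
#' @param sweep a [sparsity_sweep()].
#' @param file TSV output path.
#' @param json optional path for a JSON summary (skipped if `NULL`).
#' @return Invisibly, the annotated metric table.
#' @export
write_sweep_tsv <- function(sweep, file, json = NULL) {
  metrics <- sweep_metrics(sweep)
  sel_g <- tryCatch(select_gof(sweep, metrics), grnsparse_error = function(e) NULL)
  sel_l <- tryCatch(select_loglin(sweep, metrics), grnsparse_error = function(e) NULL)
  metrics$selected_gof <- seq_len(nrow(metrics)) ==
    (if (is.null(sel_g)) 0L else sel_g$selected_index)
  metrics$selected_loglin <- seq_len(nrow(metrics)) ==
    (if (is.null(sel_l)) 0L else sel_l$selected_index)
  utils::write.table(metrics, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json)) {
    summary <- list(
      n_members = length(sweep$members),
      goodness_of_fit = if (is.null(sel_g)) NULL else
        list(index = sel_g$selected_index, sparsity = sel_g$selected_sparsity),
      logarithmic_linearity = if (is.null(sel_l)) NULL else
        list(index = sel_l$selected_index, sparsity = sel_l$selected_sparsity)
    )
    jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(metrics)
}
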