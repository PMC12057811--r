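make_confidence_3x3 <- function() {
  # 6 distinct off-diagonal magnitudes
  m <- matrix(0, 3, 3)
  m[row(m) != col(m)] <- c(0.9, -0.5, 0.3, 0.8, -0.2, 0.6)
  m
}

test_that("confidence thresholding spans sparsest to densest member", {
  m <- make_confidence_3x3()
  sw <- sweep_from_confidence(m, n_grids = 6)
  expect_length(sw, 6)
  expect_equal(sw$sparsities, (1:6) / 3)   # strictly monotone, 1/3 .. 2
  # signed values are retained
  dense <- sw$members[[6]]
  expect_equal(unname(dense$matrix), m)

  two <- sweep_from_confidence(m, n_grids = 2)
  expect_equal(two$sparsities, c(1 / 3, 2))       # top link only vs all links
  expect_equal(which(two$members[[1]]$matrix != 0),
               which(abs(m) == max(abs(m))))

  expect_error(sweep_from_confidence(matrix(0, 3, 3)),
               class = "grnsparse_empty_confidence")
})

test_that("sweep supports are nested: sparser members sit inside denser ones", {
  set.seed(8)
  conf <- matrix(rnorm(100 * 100), 100, 100)
  sw <- sweep_from_confidence(conf, n_grids = 100)
  supports <- lapply(sw$members, function(g) which(g$matrix != 0))
  for (i in seq_len(length(sw) - 1)) {
    expect_true(all(supports[[i]] %in% supports[[i + 1]]))
  }
})

test_that("goodness-of-fit selector takes the Q argmin, ties toward sparser", {
  sw <- sweep_from_confidence(make_confidence_3x3(), n_grids = 3)
  metrics <- sweep_metrics(sw)

  metrics$q <- c(5.0, 1.2, 7.3)
  expect_equal(select_gof(sw, metrics)$selected_index, 2L)

  metrics$q <- c(2.0, 2.0, 3.0)
  sel <- select_gof(sw, metrics)
  expect_equal(sel$selected_index, 1L)   # tie broken toward lower sparsity
  expect_equal(sel$selected_sparsity, min(sw$sparsities[1:2]))

  metrics$q <- rep(NA_real_, 3)
  expect_error(select_gof(sw, metrics),
               class = "grnsparse_selection_failure")
})

test_that("log-linearity selector minimises p subject to r < -0.5", {
  sw <- sweep_from_confidence(make_confidence_3x3(), n_grids = 3)
  metrics <- sweep_metrics(sw)

  metrics$r <- c(-0.9, -0.6, 0.2)
  metrics$p_value <- c(0.04, 0.01, 0.5)
  expect_equal(select_loglin(sw, metrics)$selected_index, 2L)

  metrics$r <- c(-0.4, -0.5, 0.9)     # nothing strictly below -0.5
  expect_error(select_loglin(sw, metrics),
               class = "grnsparse_selection_failure")

  metrics$r <- c(-0.7, -1.0, -0.8)
  metrics$p_value <- c(0.2, 0.0, 0.1)  # an exactly log-linear member wins
  expect_equal(select_loglin(sw, metrics)$selected_index, 2L)
})

test_that("selection is stable under monotone rescaling and member removal", {
  set.seed(15)
  conf <- matrix(rnorm(40 * 40), 40, 40)
  sw <- sweep_from_confidence(conf, n_grids = 25)
  metrics <- sweep_metrics(sw)
  sel <- select_gof(sw, metrics)

  # strictly monotone transform of the metric series leaves the argmin alone
  rescaled <- metrics
  rescaled$q <- pmin(metrics$q, 1e4)
  rescaled$q <- (rescaled$q - min(rescaled$q, na.rm = TRUE)) /
    diff(range(rescaled$q, na.rm = TRUE))
  expect_equal(select_gof(sw, rescaled)$selected_index, sel$selected_index)

  # dropping non-selected members never changes the winner
  keep <- sort(c(sel$selected_index,
                 setdiff(seq_along(sw$members), sel$selected_index)[1:10]))
  sub <- sparsity_sweep(sw$members[keep], sw$hyperparams[keep])
  sub_sel <- select_gof(sub)
  expect_equal(sub_sel$selected_sparsity, sel$selected_sparsity)
})

test_that("sweep metric tables serialise with selection flags", {
  sw <- sweep_from_confidence(make_confidence_3x3(), n_grids = 4)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  tab <- write_sweep_tsv(sw, tsv, json = json)
  back <- read.delim(tsv)
  expect_equal(nrow(back), length(sw))
  expect_true(all(c("sparsity", "q", "r", "p_value",
                    "selected_gof", "selected_loglin") %in% names(back)))
  expect_true(file.exists(json))
})
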