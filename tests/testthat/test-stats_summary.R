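fake_results <- function(cb, reliable = TRUE, dataset = "experimental",
                         cfg = analysis_config()) {
  reliable <- rep(reliable, length.out = length(cb))
  dataset <- rep(dataset, length.out = length(cb))
  category <- ifelse(is.na(cb), "undefined",
              ifelse(!reliable, "unreliable",
              ifelse(cb < cfg$theta_elim, "eliminated",
              ifelse(cb < cfg$theta_under, "under_represented",
              ifelse(cb < 1, "reduced",
              ifelse(cb == 1, "near_expected", "over_represented"))))))
  data.frame(genome_id = sprintf("g%d", seq_along(cb)),
             site = rep("GATC", length(cb)), cb = cb,
             reliable = reliable & !is.na(cb),
             category = category, dataset = dataset,
             stringsAsFactors = FALSE)
}

test_that("representation summary tallies CB fractions per group", {
  s <- summarize_representation(fake_results(c(0.5, 1.2, 0.97)))
  expect_equal(s$n_pairs, 3L)
  expect_equal(s$n_cb_lt1, 2L)
  expect_equal(s$n_cb_gt1, 1L)
  expect_equal(s$pct_cb_lt1, 100 * 2 / 3)
  expect_equal(s$n_cb_eq1_or_undefined, 0L)

  s2 <- summarize_representation(fake_results(c(0.05, 0.5, 0.85, 1.3)))
  expect_equal(s2$n_under, 2L)   # eliminated counts as under-represented too
  expect_equal(s2$n_elim, 1L)

  # CB exactly 1 and undefined fall in neither tail
  s3 <- summarize_representation(fake_results(c(1, NA, 0.3)))
  expect_equal(s3$n_cb_lt1 + s3$n_cb_gt1 + s3$n_cb_eq1_or_undefined,
               s3$n_pairs)
  expect_equal(s3$n_cb_eq1_or_undefined, 2L)

  empty <- summarize_representation(fake_results(numeric(0)))
  expect_equal(nrow(empty), 0L)
  expect_error(summarize_representation(fake_results(0.5), "no_such_column"),
               "no_such_column")
})

test_that("summary counts are permutation-invariant and stratified", {
  set.seed(201)
  res <- fake_results(runif(40, 0, 2),
                      dataset = sample(c("experimental", "control1"), 40, TRUE))
  a <- summarize_representation(res, "dataset")
  b <- summarize_representation(res[sample(nrow(res)), ], "dataset")
  expect_equal(a, b)
  expect_equal(sum(a$n_pairs), 40L)
  expect_equal(a$pct_under, 100 * a$n_under / a$n_pairs)
})

test_that("reliable_only policy drops unreliable pairs from the denominators", {
  res <- fake_results(c(0.5, 0.5, 1.5), reliable = c(TRUE, FALSE, TRUE))
  all_p <- summarize_representation(res, filter_policy = "all_pairs")
  rel <- summarize_representation(res, filter_policy = "reliable_only")
  expect_equal(all_p$n_pairs, 3L)
  expect_equal(rel$n_pairs, 2L)
  expect_equal(rel$n_under, 1L)
})

test_that("Fisher's exact test reproduces enumerated two-sided p-values", {
  expect_equal(fisher_exact(matrix(c(2, 2, 2, 2), 2)), 1)
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)), 34 / 70,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)), 2 / 252,
               tolerance = 1e-12)
  expect_warning(p <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "zero margin")
  expect_equal(p, 1)
})

test_that("Fisher p-values match hypergeometric enumeration and stats::fisher.test", {
  set.seed(202)
  for (i in 1:100) {
    tab <- matrix(sample(0:15, 4, TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact(tab)
    expect_equal(p, fisher_enum(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 tolerance = 1e-12)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("group comparisons build the right table and detect differences", {
  a <- summarize_representation(fake_results(c(rep(0.5, 90), rep(1.5, 10))))
  b <- summarize_representation(fake_results(c(rep(0.5, 10), rep(1.5, 90))))
  cmp <- compare_fractions(a, b, "cb_lt1")
  expect_equal(cmp$table[1, ], c(cb_lt1 = 90, rest = 10))
  expect_lt(cmp$p_value, 1e-10)
  expect_true(cmp$significant)
  same <- compare_fractions(a, a, "under")
  expect_equal(same$p_value, 1)
  expect_error(compare_fractions(a, b, "cb_gt2"))
})

test_that("CB histograms use left-closed bins of the configured width", {
  h <- cb_histogram(fake_results(c(0.05, 0.15, 0.95)))
  expect_equal(h$bin_left, c(0, 0.1, 0.9))
  expect_equal(h$count, c(1L, 1L, 1L))
  expect_equal(sum(h$fraction), 1)

  h1 <- cb_histogram(fake_results(c(1, 1, 1)))
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$bin_left, 1)
  expect_equal(h1$bin_right, 1.1)

  expect_warning(h0 <- cb_histogram(fake_results(NA_real_)), "no defined")
  expect_equal(nrow(h0), 0L)
  expect_equal(attr(h0, "n_undefined"), 1L)

  expect_error(cb_histogram(fake_results(0.5),
                            analysis_config(histogram_bin_width = -1)))
  hg <- cb_histogram(fake_results(c(0.5, 1.5), dataset = c("a", "b")),
                     group = "dataset")
  expect_setequal(hg$group, c("a", "b"))
  expect_true(all(hg$fraction == 1))
})
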