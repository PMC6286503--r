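test_that("degenerate-pattern counting matches hand-enumerated windows", {
  expect_equal(count_occurrences("GAATTCAAGAATTC", "GAATTC"), 2L)
  expect_equal(count_occurrences("AAAAA", "AAA"), 3L)  # overlaps allowed
  expect_equal(count_occurrences("GCAGCTGCTGC", "GCWGC"), 3L)
  expect_equal(count_occurrences("GGATGCATCC", "GGATG", "combined"), 2L)
  expect_equal(count_occurrences("GGATGCATCC", "GGATG", "reverse_strand"), 1L)
  expect_warning(n <- count_occurrences("ACG", "GAATTC"), "longer than genome")
  expect_equal(n, 0L)
  # ambiguous genome letters match nothing, not even N in the pattern
  expect_equal(count_occurrences("GANTC", "GANTC"), 0L)
  expect_equal(count_occurrences("GAATC", "GANTC"), 1L)
})

test_that("subsite expectation reproduces hand-computed small cases", {
  expect_equal(expected_count("ACGTACGTACGT", "CG"), 3 * 3 / 11)
  expect_equal(expected_count("ACGCGT", "CG"), 0.8)
})

test_that("expectation approaches the i.i.d. analytic limit on long genomes", {
  set.seed(21)
  g <- generate_background(1e5)
  e <- expected_count(g, "GATC")
  expect_lt(abs(e - 1e5 / 256) / (1e5 / 256), 0.05)
})

test_that("optimized counting and expectation agree with naive oracles", {
  set.seed(31)
  for (i in 1:300) {
    seq <- random_dna(sample(50:2000, 1))
    site <- random_site()
    orient <- sample(c("given_strand", "reverse_strand", "combined"), 1)
    expect_equal(count_occurrences(seq, site, orient),
                 regex_count_oriented(seq, site, orient))
    e_opt <- expected_count(seq, site, orient)
    e_naive <- naive_expected(seq, site, orient)
    if (is.nan(e_naive)) {
      expect_true(is.nan(e_opt))
    } else if (e_naive == 0) {
      expect_equal(e_opt, 0)
    } else {
      expect_lt(abs(e_opt - e_naive) / e_naive, 1e-9)
    }
  }
})

test_that("CB is invariant to count-vs-frequency normalisation", {
  # exponents sum to zero, so dividing every subsite count by the window
  # count leaves the product unchanged
  set.seed(41)
  for (i in 1:30) {
    seq <- random_dna(sample(200:2000, 1))
    site <- random_site()
    r <- compositional_bias(seq, site, "given_strand")
    if (is.na(r$cb) || r$observed == 0) next
    p <- parse_site(site)
    subs <- enumerate_subsites(p)
    W <- nchar(seq) - p$length + 1
    cb_freq <- prod(vapply(seq_len(nrow(subs)), function(j) {
      (regex_count(seq, subs$pattern[j]) / W)^subs$exponent[j]
    }, numeric(1)))
    expect_lt(abs(r$cb - cb_freq) / cb_freq, 1e-9)
  }
})

test_that("classification applies the avoidance thresholds half-open", {
  cfg <- analysis_config()
  cls <- function(obs, exp) sitecb:::.classify_cb(obs, exp, cfg)
  expect_equal(cls(1, 20)$category, "eliminated")          # cb 0.05
  expect_equal(cls(5, 10)$category, "unreliable")          # expected <= 15
  expect_equal(cls(85, 100)$category, "reduced")           # cb 0.85 fails 0.8
  expect_equal(cls(16, 20)$category, "reduced")            # cb exactly 0.8
  expect_equal(cls(2, 20)$category, "under_represented")   # cb exactly 0.1
  expect_equal(cls(20, 20)$category, "near_expected")      # cb exactly 1
  expect_equal(cls(30, 20)$category, "over_represented")
  z <- cls(0, 20)
  expect_equal(z$category, "eliminated")                   # observed 0, cb 0
  expect_equal(z$cb, 0)
  expect_equal(cls(0, NaN)$category, "undefined")
  expect_equal(cls(0, 0)$category, "undefined")
})

test_that("compositional_bias assembles observed, expected and category", {
  r <- compositional_bias("ACGTACGTACGT", "CG")
  expect_equal(r$observed, 3L)
  expect_equal(r$expected, 3 * 3 / 11)
  expect_equal(r$cb, 3 / (3 * 3 / 11))
  expect_false(r$reliable)
  expect_equal(r$category, "unreliable")
  expect_equal(r$orientation, "given_strand")  # palindromic default
  r2 <- compositional_bias("ACGTACGTACGT", "GGATG")
  expect_equal(r2$orientation, "combined")     # asymmetric default
})

test_that("palindromic sites count identically on both strands", {
  set.seed(51)
  g <- random_dna(5000)
  for (site in c("GAATTC", "GGCC", "GCNNGC", "GCWGC")) {
    expect_identical(count_occurrences(g, site, "given_strand"),
                     count_occurrences(g, site, "reverse_strand"))
  }
})

test_that("strand asymmetry detects one-strand elimination and rejects palindromes", {
  expect_error(strand_asymmetry(random_dna(100), "GAATTC"), "palindromic")
  set.seed(61)
  g <- random_dna(60000)
  # destroy every given-strand GGATG, leave CATCC (its complement) alone
  repeat {
    hits <- gregexpr("(?=GGATG)", g, perl = TRUE)[[1L]]
    if (hits[1L] == -1L) break
    for (at in hits) substr(g, at + 2L, at + 2L) <- "C"  # GGATG -> GGCTG
  }
  res <- strand_asymmetry(genome_record("asym", g), "GGATG")
  expect_equal(res$given_strand$observed, 0L)
  expect_equal(res$given_strand$category, "eliminated")
  expect_gt(res$reverse_strand$cb, 0.7)
  expect_lt(res$reverse_strand$cb, 1.3)
})

test_that("CB of a spacer site is invariant to re-trimming and re-parsing", {
  set.seed(71)
  g <- random_dna(20000)
  a <- compositional_bias(g, "GCNGC")
  b <- compositional_bias(g, parse_site("NGCNGCN"))
  expect_equal(a$cb, b$cb)
  expect_equal(a$observed, b$observed)
})

test_that("the batch driver filters short and degenerate sites with warnings", {
  set.seed(81)
  gs <- list(genome_record("g1", random_dna(3000)),
             genome_record("g2", random_dna(3000)))
  expect_warning(tab <- compute_cb_table(gs, c("GATC", "GA", "GGATG")),
                 "shorter than 3")
  expect_warning(compute_cb_table(gs, "A", enforce_min_length = FALSE),
                 "fewer than 2 specified")
  expect_setequal(unique(tab$site), c("GATC", "GGATG"))
  expect_equal(nrow(tab), 4L)  # 2 genomes x 2 usable sites
  expect_equal(unique(tab$orientation[tab$site == "GATC"]), "given_strand")
  expect_equal(unique(tab$orientation[tab$site == "GGATG"]), "combined")
  cfg <- analysis_config(orientation_policy = "per_strand")
  tab2 <- compute_cb_table(gs, "GGATG", cfg)
  expect_setequal(tab2$orientation, c("given_strand", "reverse_strand"))
})
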