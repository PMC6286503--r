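# Compositional bias: degenerate-pattern counting, subsite-based expectation,
# avoidance classification.

CB_CATEGORIES <- c("unreliable", "eliminated", "under_represented", "reduced",
                   "near_expected", "over_represented", "undefined")

#' Analysis configuration
#'
#' Houses the thresholds and conventions used across the pipeline.
#'
#' @param theta_under CB below which a reliable site is called
#'   under-represented (default 0.8).
#' @param theta_elim CB below which a reliable site is called eliminated
#'   (default 0.1).
#' @param min_expected Reliability filter: a CB value is reliable only when
#'   the expected count exceeds this (default 15).
#' @param min_site_length Minimum literal (N-trimmed) site length admitted to
#'   the pair datasets; sites of length 2 or less are excluded (default 3).
#' @param identity_threshold Genomes with estimated sequence identity above
#'   this are grouped during dereplication (default 0.99).
#' @param histogram_bin_width Bin width for CB histograms (default 0.1).
#' @param orientation_policy `"combined_for_asymmetric"` evaluates asymmetric
#'   sites on both strands combined (palindromic sites are always evaluated
#'   on the given strand only); `"per_strand"` emits one evaluation per
#'   strand for asymmetric sites.
#' @param significance_alpha Significance level for Fisher's exact
#'   comparisons (default 0.01).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(theta_under = 0.8, theta_elim = 0.1,
                            min_expected = 15, min_site_length = 3L,
                            identity_threshold = 0.99,
                            histogram_bin_width = 0.1,
                            orientation_policy = c("combined_for_asymmetric",
                                                   "per_strand"),
                            significance_alpha = 0.01) {
  orientation_policy <- match.arg(orientation_policy)
  stopifnot(theta_elim > 0, theta_elim < theta_under, theta_under < 1,
            min_expected > 0, min_site_length >= 1,
            identity_threshold > 0, identity_threshold < 1,
            histogram_bin_width > 0,
            significance_alpha > 0, significance_alpha < 1)
  structure(
    list(theta_under = theta_under, theta_elim = theta_elim,
         min_expected = min_expected,
         min_site_length = as.integer(min_site_length),
         identity_threshold = identity_threshold,
         histogram_bin_width = histogram_bin_width,
         orientation_policy = orientation_policy,
         significance_alpha = significance_alpha),
    class = "analysis_config"
  )
}

.as_codes <- function(g) {
  if (inherits(g, "genome_record")) encode_genome(g$sequence)
  else if (is.character(g) && length(g) == 1L) encode_genome(toupper(g))
  else if (is.integer(g)) g
  else stop("`g` must be a genome_record or a sequence string")
}

.genome_id_of <- function(g) {
  if (inherits(g, "genome_record")) g$genome_id else NA_character_
}

# Count one oriented pattern on a pre-encoded genome.
.count_oriented <- function(codes, text, orientation) {
  switch(orientation,
    given_strand = count_windows_(codes, encode_pattern(text)),
    reverse_strand = count_windows_(codes, encode_pattern(reverse_complement(text))),
    combined = count_windows_(codes, encode_pattern(text)) +
      count_windows_(codes, encode_pattern(reverse_complement(text))),
    stop(sprintf("unknown orientation '%s'", orientation))
  )
}

#' Count occurrences of an IUPAC pattern in a genome
#'
#' Counts overlapping windows (step 1) matching the pattern under IUPAC set
#' semantics: a genome letter matches a pattern letter only when it is a
#' concrete base contained in that letter's set, so ambiguous genome letters
#' (including `N`) match nothing. Orientation `"given_strand"` scans the
#' sequence as stored, `"reverse_strand"` scans for the reverse complement of
#' the pattern on the stored sequence, `"combined"` returns their sum.
#'
#' @param g A [genome_record()] or a plain sequence string.
#' @param p An IUPAC pattern string or `nucleotide_pattern`.
#' @param orientation One of `"given_strand"`, `"reverse_strand"`,
#'   `"combined"`.
#' @return Integer count (0 with a warning when the pattern is longer than
#'   the genome).
#' @examples
#' count_occurrences("GAATTCAAGAATTC", "GAATTC", "given_strand")  # 2
#' count_occurrences("AAAAA", "AAA", "given_strand")              # 3
#' @export
count_occurrences <- function(g, p, orientation = c("given_strand",
                                                    "reverse_strand",
                                                    "combined")) {
  orientation <- match.arg(orientation)
  text <- if (inherits(p, "nucleotide_pattern")) p$text else {
    validate_iupac(toupper(p)); toupper(p)
  }
  codes <- .as_codes(g)
  if (nchar(text) > length(codes)) {
    warning(sprintf("pattern '%s' longer than genome (%d nt); count is 0",
                    text, length(codes)))
    return(0L)
  }
  .count_oriented(codes, text, orientation)
}

# All subsite counts for a site on a pre-encoded genome, in the order of
# enumerate_subsites(). Returns list(counts, subsites).
.subsite_counts <- function(codes, p, orientation) {
  subs <- enumerate_subsites(p)
  counts <- vapply(subs$pattern, function(s) .count_oriented(codes, s, orientation),
                   numeric(1), USE.NAMES = FALSE)
  list(counts = counts, subsites = subs)
}

# Expected count from subsite counts:
#   E = prod over proper subsets S of N(p_S)^(-exponent(S))
# computed in log space. Returns 0 when a positive-power (numerator) count
# is zero, NaN when only a negative-power (denominator) count is zero.
.expected_from_counts <- function(counts, subsites) {
  proper <- subsites$n_retained < max(subsites$n_retained)
  numer <- proper & subsites$exponent == -1L
  denom <- proper & subsites$exponent == +1L
  if (any(counts[numer] == 0)) return(0)
  if (any(counts[denom] == 0)) return(NaN)
  exp(sum(log(counts[numer])) - sum(log(counts[denom])))
}

#' Expected count of a site under the subsite model
#'
#' The expectation behind the compositional bias is an inclusion-exclusion
#' over all subsites of the site: with `P` the set of specified positions and
#' `N(p_S)` the count of the pattern masked down to subset `S` (full literal
#' length, same orientation), the expected count is
#' `E = prod over proper subsets S of N(p_S)^(-(-1)^(|P|-|S|))`.
#' The all-`N` subsite count equals the number of fully concrete windows
#' (`G - L + 1` on a plain genome; doubled for combined orientation), and
#' because the exponents sum to zero the same value is obtained whether
#' counts or window-normalised frequencies are used.
#'
#' @inheritParams count_occurrences
#' @return Non-negative expected count; 0 when a numerator subsite is absent
#'   from the genome, `NaN` when the expectation is undefined (a denominator
#'   subsite count of zero).
#' @export
expected_count <- function(g, p, orientation = c("given_strand",
                                                 "reverse_strand",
                                                 "combined")) {
  orientation <- match.arg(orientation)
  p <- as_pattern(p)
  codes <- .as_codes(g)
  if (p$length > length(codes))
    stop("genome shorter than the site's literal length")
  sc <- .subsite_counts(codes, p, orientation)
  .expected_from_counts(sc$counts, sc$subsites)
}

.classify_cb <- function(observed, expected, cfg) {
  if (!is.finite(expected) || expected == 0)
    return(list(cb = NA_real_, reliable = FALSE, category = "undefined"))
  cb <- observed / expected
  reliable <- expected > cfg$min_expected
  category <- if (!reliable) "unreliable"
  else if (cb < cfg$theta_elim) "eliminated"
  else if (cb < cfg$theta_under) "under_represented"
  else if (cb < 1) "reduced"
  else if (cb == 1) "near_expected"
  else "over_represented"
  list(cb = cb, reliable = reliable, category = category)
}

#' Compositional bias of a site in a genome
#'
#' Computes the observed count, the subsite-model expected count and their
#' ratio, the compositional bias (CB), then classifies the site. CB below
#' `theta_under` (0.8) with an expected count above `min_expected` (15) is
#' *under-represented*; CB below `theta_elim` (0.1) is *eliminated*. Values
#' whose expectation does not exceed `min_expected` are flagged unreliable.
#' Boundaries are half-open: CB exactly 0.8 is "reduced", exactly 0.1 is
#' "under_represented", exactly 1 is "near_expected". An observed count of 0
#' with a reliable expectation gives CB 0, category "eliminated".
#'
#' By default palindromic sites are evaluated on the given strand only (both
#' strands carry the same physical duplex site) and asymmetric sites on both
#' strands combined.
#'
#' @inheritParams count_occurrences
#' @param orientation Orientation, or `NULL` to pick by palindromy.
#' @param cfg An [analysis_config()].
#' @return An object of class `cb_result`: fields `genome_id`, `site_text`,
#'   `orientation`, `observed`, `expected`, `cb`, `reliable`, `category`.
#' @export
compositional_bias <- function(g, p, orientation = NULL,
                               cfg = analysis_config()) {
  p <- as_pattern(p)
  if (is.null(orientation))
    orientation <- if (p$is_palindrome) "given_strand" else "combined"
  orientation <- match.arg(orientation,
                           c("given_strand", "reverse_strand", "combined"))
  codes <- .as_codes(g)
  if (p$length > length(codes))
    stop("genome shorter than the site's literal length")
  sc <- .subsite_counts(codes, p, orientation)
  observed <- sc$counts[sc$subsites$n_retained == p$effective_length]
  expected <- .expected_from_counts(sc$counts, sc$subsites)
  cls <- .classify_cb(observed, expected, cfg)
  structure(
    list(genome_id = .genome_id_of(g), site_text = p$text,
         orientation = orientation, observed = as.integer(observed),
         expected = expected, cb = cls$cb, reliable = cls$reliable,
         category = cls$category),
    class = "cb_result"
  )
}

#' @export
print.cb_result <- function(x, ...) {
  cat(sprintf("<cb %s in %s (%s)> observed %d, expected %.3f, cb %s, %s\n",
              x$site_text, x$genome_id %||% "?", x$orientation, x$observed,
              x$expected,
              if (is.na(x$cb)) "NA" else sprintf("%.3f", x$cb), x$category))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Per-strand compositional bias of an asymmetric site
#'
#' Type I and Type III systems often need head-to-head site pairs to cleave,
#' so a phage can escape by removing the site from just one strand. This
#' evaluates an asymmetric site independently on each strand; palindromic
#' input is an error, as the two strands carry identical sites.
#'
#' @inheritParams compositional_bias
#' @return A list with elements `given_strand` and `reverse_strand`, each a
#'   `cb_result`.
#' @export
strand_asymmetry <- function(g, p, cfg = analysis_config()) {
  p <- as_pattern(p)
  if (p$is_palindrome)
    stop(sprintf("site '%s' is palindromic; per-strand analysis is meaningless",
                 p$text))
  list(
    given_strand = compositional_bias(g, p, "given_strand", cfg),
    reverse_strand = compositional_bias(g, p, "reverse_strand", cfg)
  )
}

#' Compositional bias for many (genome, site) evaluations
#'
#' Vectorised driver: evaluates each site in each genome under the
#' configured orientation policy and returns one row per evaluation.
#' Sites shorter than `cfg$min_site_length` (literal N-trimmed length) are
#' skipped with a warning; so are sites with fewer than two specified
#' positions, for which the subsite expectation is undefined.
#'
#' @param genomes List of [genome_record()] objects.
#' @param sites Character vector of site strings (deduplicated).
#' @param cfg An [analysis_config()].
#' @param enforce_min_length Apply the minimum-site-length filter.
#' @return A data.frame with columns `genome_id`, `site`, `orientation`,
#'   `observed`, `expected`, `cb`, `reliable`, `category`.
#' @export
compute_cb_table <- function(genomes, sites, cfg = analysis_config(),
                             enforce_min_length = TRUE) {
  sites <- unique(toupper(sites))
  patterns <- list()
  for (s in sites) {
    p <- tryCatch(parse_site(s), error = function(e) NULL)
    if (is.null(p)) { warning(sprintf("site '%s' unparsable; skipped", s)); next }
    if (enforce_min_length && p$length < cfg$min_site_length) {
      warning(sprintf("site '%s' shorter than %d nt; skipped", s,
                      cfg$min_site_length))
      next
    }
    if (p$effective_length < 2L) {
      warning(sprintf("site '%s' has fewer than 2 specified positions; skipped", s))
      next
    }
    patterns[[p$text]] <- p
  }
  rows <- vector("list", length(genomes) * length(patterns) * 2L)
  k <- 0L
  for (g in genomes) {
    codes <- encode_genome(g$sequence)
    for (p in patterns) {
      if (p$length > length(codes)) next
      orientations <- if (p$is_palindrome) "given_strand"
      else if (cfg$orientation_policy == "per_strand")
        c("given_strand", "reverse_strand")
      else "combined"
      for (orient in orientations) {
        sc <- .subsite_counts(codes, p, orient)
        observed <- sc$counts[sc$subsites$n_retained == p$effective_length]
        expected <- .expected_from_counts(sc$counts, sc$subsites)
        cls <- .classify_cb(observed, expected, cfg)
        k <- k + 1L
        rows[[k]] <- data.frame(
          genome_id = g$genome_id, site = p$text, orientation = orient,
          observed = as.integer(observed), expected = expected, cb = cls$cb,
          reliable = cls$reliable, category = cls$category,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (k == 0L)
    return(data.frame(genome_id = character(0), site = character(0),
                      orientation = character(0), observed = integer(0),
                      expected = numeric(0), cb = numeric(0),
                      reliable = logical(0), category = character(0)))
  do.call(rbind, rows[seq_len(k)])
}
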