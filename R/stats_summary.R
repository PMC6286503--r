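# Aggregation of CB results into fraction tables, histograms and Fisher's
# exact comparisons.

#' Join CB results to pair and genome metadata
#'
#' Attaches `dataset`, `rm_types`, `evidence_best` (from the pair table) and
#' `genome_class`, `lifestyle`, `anti_restriction` (from the genome records)
#' to a CB result table, so any of those fields can stratify a summary.
#'
#' @param cb_table Data.frame from [compute_cb_table()].
#' @param pairs Data.frame from the dataset builders.
#' @param genomes Optional list of [genome_record()]s.
#' @return The joined data.frame (one row per CB evaluation matched to a
#'   pair).
#' @export
join_results <- function(cb_table, pairs, genomes = NULL) {
  out <- merge(cb_table, pairs, by = c("genome_id", "site"))
  if (!is.null(genomes)) {
    meta <- data.frame(
      genome_id = vapply(genomes, `[[`, character(1), "genome_id"),
      genome_class = vapply(genomes, `[[`, character(1), "genome_class"),
      lifestyle = vapply(genomes, `[[`, character(1), "lifestyle"),
      anti_restriction = vapply(genomes, `[[`, character(1), "anti_restriction"),
      stringsAsFactors = FALSE
    )
    out <- merge(out, meta, by = "genome_id")
  }
  out
}

#' Summarise site representation per group
#'
#' Tallies, for every combination of the stratifier values, the number of
#' pairs with CB below 1, above 1, and exactly 1 or undefined, plus the
#' under-represented (category `under_represented` or `eliminated`) and
#' eliminated counts, together with the corresponding percentages
#' (denominator: all pairs in the group). With
#' `filter_policy = "reliable_only"` the tallies are restricted to results
#' whose expected count passed the reliability filter.
#'
#' @param results Data.frame of CB results joined to pair metadata
#'   ([join_results()]).
#' @param stratifiers Character vector of column names to group by (e.g.
#'   `c("dataset", "genome_class")`); empty for one overall row.
#' @param filter_policy `"all_pairs"` or `"reliable_only"`.
#' @return A data.frame with one row per group: the stratifier columns,
#'   `n_pairs`, `n_cb_lt1`, `n_cb_gt1`, `n_cb_eq1_or_undefined`, `n_under`,
#'   `n_elim` and percentage columns `pct_*`.
#' @export
summarize_representation <- function(results, stratifiers = character(0),
                                     filter_policy = c("all_pairs",
                                                       "reliable_only")) {
  filter_policy <- match.arg(filter_policy)
  cols <- c(stratifiers, "n_pairs", "n_cb_lt1", "n_cb_gt1",
            "n_cb_eq1_or_undefined", "n_under", "n_elim",
            "pct_cb_lt1", "pct_cb_gt1", "pct_under", "pct_elim")
  if (nrow(results) == 0L) {
    empty <- as.data.frame(setNames(rep(list(character(0)), length(stratifiers)),
                                    stratifiers), stringsAsFactors = FALSE)
    for (cn in setdiff(cols, stratifiers)) empty[[cn]] <- numeric(0)
    return(empty)
  }
  unknown <- setdiff(stratifiers, names(results))
  if (length(unknown))
    stop(sprintf("unknown stratifier(s): %s", paste(unknown, collapse = ", ")))
  if (filter_policy == "reliable_only") results <- results[results$reliable, ]
  dt <- data.table::as.data.table(results)
  cb <- category <- NULL  # NSE notes
  tally <- function(sd) {
    n <- nrow(sd)
    lt1 <- sum(!is.na(sd$cb) & sd$cb < 1)
    gt1 <- sum(!is.na(sd$cb) & sd$cb > 1)
    und <- sum(sd$category %in% c("under_represented", "eliminated"))
    eli <- sum(sd$category == "eliminated")
    list(n_pairs = n, n_cb_lt1 = lt1, n_cb_gt1 = gt1,
         n_cb_eq1_or_undefined = n - lt1 - gt1, n_under = und, n_elim = eli,
         pct_cb_lt1 = 100 * lt1 / n, pct_cb_gt1 = 100 * gt1 / n,
         pct_under = 100 * und / n, pct_elim = 100 * eli / n)
  }
  agg <- if (length(stratifiers) == 0L) dt[, tally(.SD)]
  else dt[, tally(.SD), by = stratifiers]
  out <- as.data.frame(agg, stringsAsFactors = FALSE)
  if (length(stratifiers))
    out <- out[do.call(order, out[stratifiers]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value under the point-probability criterion: the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' point probability does not exceed that of the observed table (within
#' relative tolerance 1e-7), computed with log-factorials.
#'
#' @param tab A 2x2 matrix of non-negative integer counts, or the four
#'   counts `a, b, c, d` (row-wise).
#' @param a,b,c,d Alternative scalar interface.
#' @return P-value in `[0, 1]`. A zero row or column margin returns 1 with a
#'   warning.
#' @examples
#' fisher_exact(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))  # 34/70
#' @export
fisher_exact <- function(tab = NULL, a = NULL, b = NULL, c = NULL, d = NULL) {
  if (is.null(tab)) tab <- matrix(c(a, b, c, d), 2L, 2L, byrow = TRUE)
  if (!is.matrix(tab) || !all(dim(tab) == 2L) || any(tab < 0) ||
      any(tab != round(tab)))
    stop("`tab` must be a 2x2 matrix of non-negative integers")
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L]); n <- sum(tab)
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2L]) == 0) {
    warning("a zero margin; p-value 1 by convention")
    return(1)
  }
  x <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  obs <- logp[x == tab[1L, 1L]]
  sum(exp(logp[logp <= obs + log1p(1e-7)]))
}

#' Compare an avoidance fraction between two groups
#'
#' Builds the 2x2 contingency table (outcome count vs the rest, per group)
#' from two single-group summaries and tests the difference with
#' [fisher_exact()].
#'
#' @param summary_a,summary_b Single-row data.frames from
#'   [summarize_representation()].
#' @param outcome `"cb_lt1"`, `"under"` or `"elim"`.
#' @param cfg An [analysis_config()]; supplies the significance level.
#' @return A list with `table` (2x2 matrix), `p_value` and `significant`.
#' @export
compare_fractions <- function(summary_a, summary_b,
                              outcome = c("cb_lt1", "under", "elim"),
                              cfg = analysis_config()) {
  outcome <- match.arg(outcome)
  col <- paste0("n_", outcome)
  stopifnot(nrow(summary_a) == 1L, nrow(summary_b) == 1L)
  tab <- matrix(c(summary_a[[col]], summary_a$n_pairs - summary_a[[col]],
                  summary_b[[col]], summary_b$n_pairs - summary_b[[col]]),
                2L, 2L, byrow = TRUE,
                dimnames = list(c("group_a", "group_b"),
                                c(outcome, "rest")))
  p <- fisher_exact(tab)
  list(table = tab, p_value = p, significant = p < cfg$significance_alpha)
}

#' Histogram of CB values
#'
#' Bins CB values into left-closed bins of width
#' `cfg$histogram_bin_width` starting at 0, per group, normalised to
#' fractions within each group. Undefined CB values are excluded and their
#' count reported as attribute `n_undefined`.
#'
#' @param results Data.frame with a `cb` column (and the grouping column, if
#'   any).
#' @param cfg An [analysis_config()].
#' @param group Optional name of a column to group by.
#' @return A data.frame with columns `group`, `bin_left`, `bin_right`,
#'   `count`, `fraction` (occupied bins only).
#' @export
cb_histogram <- function(results, cfg = analysis_config(), group = NULL) {
  w <- cfg$histogram_bin_width
  if (w <= 0) stop("histogram bin width must be positive")
  n_undef <- sum(is.na(results$cb))
  res <- results[!is.na(results$cb), , drop = FALSE]
  if (nrow(res) == 0L) {
    warning("no defined CB values to histogram")
    out <- data.frame(group = character(0), bin_left = numeric(0),
                      bin_right = numeric(0), count = integer(0),
                      fraction = numeric(0))
    attr(out, "n_undefined") <- n_undef
    return(out)
  }
  grp <- if (is.null(group)) rep("all", nrow(res)) else as.character(res[[group]])
  idx <- floor(res$cb / w)
  pieces <- lapply(split(idx, grp), function(ix) {
    tb <- table(ix)
    data.frame(bin_left = as.numeric(names(tb)) * w,
               bin_right = (as.numeric(names(tb)) + 1) * w,
               count = as.integer(tb),
               fraction = as.integer(tb) / length(ix))
  })
  out <- do.call(rbind, Map(function(g, df) cbind(group = g, df),
                            names(pieces), pieces))
  rownames(out) <- NULL
  attr(out, "n_undefined") <- n_undef
  out
}
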