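# Recognition-site patterns and the subsite family behind the CB expectation.

#' Parse an IUPAC recognition site
#'
#' Builds a `nucleotide_pattern` object from a recognition-site string:
#' uppercases, validates against the IUPAC alphabet, trims flanking `N`
#' (they carry no constraint), records which positions are specified
#' (letter other than `N`) and whether the site is palindromic, i.e. equal
#' to its own reverse complement under IUPAC complementation.
#'
#' @param text A non-empty recognition-site string, e.g. `"GAATTC"`,
#'   `"GCNGC"`, `"CAGAG"`. Bipartite sites must be pre-expanded to plain
#'   IUPAC (`"GACNNNNNGTC"`, not `"GAC(N5)GTC"`).
#' @return An object of class `nucleotide_pattern` with fields `text`,
#'   `length` (literal length after trimming), `specified_positions`
#'   (1-based), `effective_length` and `is_palindrome`.
#' @examples
#' parse_site("gaattc")
#' parse_site("GCNGC")$specified_positions  # 1 2 4 5
#' parse_site("NGATCN")$text                # "GATC"
#' @export
parse_site <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("`text` must be a single non-empty string")
  text <- toupper(text)
  validate_iupac(text)
  trimmed <- gsub("^N+|N+$", "", text)
  if (!nzchar(trimmed))
    stop(sprintf("site '%s' has no specified position (all N)", text))
  chars <- strsplit(trimmed, "", fixed = TRUE)[[1L]]
  spec <- which(chars != "N")
  structure(
    list(
      text = trimmed,
      length = nchar(trimmed),
      specified_positions = spec,
      effective_length = length(spec),
      is_palindrome = identical(trimmed, reverse_complement(trimmed))
    ),
    class = "nucleotide_pattern"
  )
}

#' @export
print.nucleotide_pattern <- function(x, ...) {
  cat(sprintf("<site %s> length %d, %d specified, %s\n", x$text, x$length,
              x$effective_length,
              if (x$is_palindrome) "palindromic" else "asymmetric"))
  invisible(x)
}

as_pattern <- function(p) {
  if (inherits(p, "nucleotide_pattern")) p else parse_site(p)
}

#' Is a site palindromic?
#'
#' A site is palindromic when its text equals its reverse complement under
#' the IUPAC complement table (e.g. `GAATTC`, `GCNNGC`); Type I and Type III
#' sites such as `CAGAG` are asymmetric.
#'
#' @param p A `nucleotide_pattern` or a site string.
#' @return Logical scalar.
#' @export
is_palindrome <- function(p) {
  as_pattern(p)$is_palindrome
}

#' Enumerate the subsites of a recognition site
#'
#' The compositional-bias expectation is an inclusion-exclusion over all
#' subsites of a site: every pattern obtained by masking a subset of the
#' specified positions to `N`, keeping the literal length. For a site with
#' `k` specified positions there are `2^k` subsites, one per subset `S`,
#' each carrying the exponent `(-1)^(k - |S|)`. Internal `N` spacers (as in
#' `GCNGC`) are permanent and never enumerated over; degenerate letters
#' (`W`, `S`, ...) count as specified and are carried verbatim.
#'
#' @param p A `nucleotide_pattern` or site string with at least two
#'   specified positions.
#' @return A data.frame with columns `pattern` (IUPAC string of the parent's
#'   literal length), `n_retained` (number of specified positions kept) and
#'   `exponent` (+1 or -1), ordered by subset size then lexicographically by
#'   retained positions. The last row is the parent itself; the first is the
#'   all-`N` pattern.
#' @examples
#' enumerate_subsites("CG")    # CG +1, CN -1, NG -1, NN +1
#' nrow(enumerate_subsites("GCNGC"))  # 16
#' @export
enumerate_subsites <- function(p) {
  p <- as_pattern(p)
  k <- p$effective_length
  if (k < 2L) stop("subsite enumeration needs at least 2 specified positions")
  if (k > 16L) stop(sprintf("site '%s' has %d specified positions; refusing > 16", p$text, k))
  chars <- strsplit(p$text, "", fixed = TRUE)[[1L]]
  spec <- p$specified_positions
  patterns <- character(2L^k)
  n_ret <- integer(2L^k)
  idx <- 0L
  for (size in 0:k) {
    subsets <- if (size == 0L) list(integer(0)) else
      asplit(combn(spec, size), 2L)
    for (S in subsets) {
      idx <- idx + 1L
      masked <- chars
      masked[setdiff(spec, S)] <- "N"
      patterns[idx] <- paste(masked, collapse = "")
      n_ret[idx] <- size
    }
  }
  data.frame(
    pattern = patterns,
    n_retained = n_ret,
    exponent = as.integer((-1L)^(k - n_ret)),
    stringsAsFactors = FALSE
  )
}
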