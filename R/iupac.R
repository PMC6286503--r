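# IUPAC nucleotide algebra shared by all modules.

#' IUPAC nucleotide alphabet
#'
#' Named list mapping each IUPAC letter to the set of concrete bases it
#' stands for. `N` stands for any base.
#'
#' @format A named list of character vectors.
#' @export
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- names(IUPAC_SETS)

# bit encoding: A=1, C=2, G=4, T=8; an IUPAC letter is the union of its bases
.base_bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
IUPAC_MASK <- vapply(IUPAC_SETS, function(b) sum(.base_bit[b]), integer(1))

.complement_map <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", V = "B",
  D = "H", H = "D", N = "N"
)

#' Reverse complement of an IUPAC string
#'
#' Extends the Watson-Crick complement to the full ambiguity alphabet
#' (A-T, C-G, R-Y, K-M, B-V, D-H; S, W and N are self-complementary) and
#' reverses the result. Applying the function twice returns the input.
#'
#' @param text Character vector of IUPAC nucleotide strings (uppercase or
#'   lowercase; the result is uppercase).
#' @return Character vector of reverse-complemented strings.
#' @examples
#' reverse_complement("GAATTC")  # palindromic: "GAATTC"
#' reverse_complement("GGATG")   # "CATCC"
#' @export
reverse_complement <- function(text) {
  if (!is.character(text)) stop("`text` must be a character vector")
  text <- toupper(text)
  bad <- regexpr(sprintf("[^%s]", paste(IUPAC_LETTERS, collapse = "")), text)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-IUPAC letter '%s' at position %d of element %d",
                 substr(text[i], bad[i], bad[i]), bad[i], i))
  }
  comp <- chartr(paste(names(.complement_map), collapse = ""),
                 paste(.complement_map, collapse = ""), text)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname reverse_complement
#' @param x Character vector to validate.
#' @return `validate_iupac()` returns its input invisibly, erroring on any
#'   letter outside the IUPAC alphabet.
#' @export
validate_iupac <- function(x) {
  bad <- regexpr(sprintf("[^%s]", paste(IUPAC_LETTERS, collapse = "")), x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("non-IUPAC character '%s' at position %d",
                 substr(x[i], bad[i], bad[i]), bad[i]))
  }
  invisible(x)
}

# Encode a genome sequence as an integer bit vector. Concrete bases keep
# their bit; every ambiguity letter (including N) encodes to 0 so that it
# matches no pattern letter: counting is conservative on ambiguous assemblies
# and a single N acts as a window barrier between concatenated segments.
encode_genome <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  codes <- unname(.base_bit[chars])
  codes[is.na(codes)] <- 0L
  codes
}

# Encode a pattern as the full IUPAC bit masks (N = 15).
encode_pattern <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  m <- unname(IUPAC_MASK[chars])
  if (anyNA(m)) stop(sprintf("invalid IUPAC letter in pattern '%s'", text))
  m
}
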