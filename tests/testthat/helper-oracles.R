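# Independent oracles and fixture builders used across the suite.

IUPAC_CONCRETE <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# Reverse complement through Biostrings, independent of the package's own
# complement table.
bio_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Naive overlapping-window counter via a PCRE lookahead whose character
# classes hold concrete bases only, so ambiguous genome letters never match.
regex_count <- function(seq, pattern) {
  classes <- vapply(strsplit(pattern, "", fixed = TRUE)[[1L]], function(ch) {
    paste0("[", paste(IUPAC_CONCRETE[[ch]], collapse = ""), "]")
  }, character(1))
  rx <- paste0("(?=", paste(classes, collapse = ""), ")")
  hits <- gregexpr(rx, seq, perl = TRUE)[[1L]]
  if (length(hits) == 1L && hits[1L] == -1L) 0L else length(hits)
}

regex_count_oriented <- function(seq, pattern, orientation) {
  switch(orientation,
         given_strand = regex_count(seq, pattern),
         reverse_strand = regex_count(seq, bio_revcomp(pattern)),
         combined = regex_count(seq, pattern) +
           regex_count(seq, bio_revcomp(pattern)))
}

# Direct evaluation of the subset-product expectation from naive counts:
# subsets enumerated by bit masks, product taken directly (no log space).
naive_expected <- function(seq, pattern, orientation = "given_strand") {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  spec <- which(chars != "N")
  k <- length(spec)
  cnts <- numeric(0); expos <- numeric(0)
  for (bits in 0:(2^k - 2L)) {     # all proper subsets of specified positions
    keep <- spec[bitwAnd(bits, 2L^(seq_len(k) - 1L)) > 0L]
    masked <- chars
    masked[setdiff(spec, keep)] <- "N"
    cnts <- c(cnts, regex_count_oriented(seq, paste(masked, collapse = ""),
                                         orientation))
    expos <- c(expos, (-1)^(k - length(keep)))
  }
  # an absent numerator term forces expectation 0; otherwise an absent
  # denominator term leaves it undefined
  if (any(cnts[expos == -1] == 0)) return(0)
  if (any(cnts[expos == +1] == 0)) return(NaN)
  prod(cnts^(-expos))
}

# Two-sided Fisher p by full hypergeometric enumeration through dhyper().
fisher_enum <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  x <- max(0, c1 - r2):min(r1, c1)
  p <- stats::dhyper(x, r1, r2, c1)
  sum(p[p <= p[x == a] * (1 + 1e-7)])
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Random IUPAC site with 2-6 specified positions, possibly with internal N
# spacers and degenerate letters.
random_site <- function() {
  k <- sample(2:6, 1L)
  letters_pool <- c("A", "C", "G", "T", "W", "S", "R", "Y")
  core <- sample(letters_pool, k, TRUE, prob = c(rep(0.2, 4), rep(0.05, 4)))
  if (k >= 3 && runif(1) < 0.3) {
    at <- sample(2:k, 1L)
    core <- append(core, rep("N", sample(1:2, 1L)), after = at - 1L)
  }
  paste(core, collapse = "")
}

# Substitute a fraction of positions with random different bases.
mutate_seq <- function(seq, rate, seed) {
  set.seed(seed)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  at <- sample(length(chars), round(rate * length(chars)))
  for (i in at) chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

tiny_phage_table <- function(path, ids,
                             hosts = "escherichia_coli",
                             lifestyle = "non_temperate",
                             genome_class = "dsDNA") {
  write_tsv(data.frame(
    genome_id = ids, genome_class = genome_class, lifestyle = lifestyle,
    host_species = hosts, anti_restriction = "none",
    taxon_id = paste0("tx", seq_along(ids)), reference_flag = "yes",
    stringsAsFactors = FALSE
  ), path)
}

tiny_rease_table <- function(path,
                             enzymes = data.frame(
                               enzyme_name = c("MboI", "HaeIII"),
                               rm_type = c("II", "II"),
                               recognition_site = c("GATC", "GGCC"),
                               organism_species = "escherichia_coli",
                               evidence = "proved",
                               stringsAsFactors = FALSE)) {
  write_tsv(enzymes, path)
}
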