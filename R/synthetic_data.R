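# Synthetic genomes with controlled site depletion, plus consistent
# metadata fixture tables, so the whole pipeline runs with no download.

.default_enzymes <- function() {
  data.frame(
    enzyme_name = c("EcoRI", "BamHI", "EcoKI", "EcoP15I"),
    rm_type = c("II", "II", "I", "III"),
    recognition_site = c("GAATTC", "GGATCC", "AACNNNNNNGTGC", "CAGCAG"),
    organism_species = "escherichia_coli",
    evidence = c("proved", "proved", "predicted", "proved"),
    stringsAsFactors = FALSE
  )
}

#' Specification for a synthetic fixture
#'
#' Describes a deterministic synthetic dataset: background genomes of given
#' length and composition, per-site depletion targets applied to every
#' genome, and the phage/enzyme metadata stamped onto them. Defaults emulate
#' a small panel of dsDNA coliphage-like genomes: 10 genomes of 200 kb with
#' uniform base composition, one site driven to near-elimination (GAATTC,
#' target CB 0.05) and one left untouched (GGATCC, target 1), hosts all
#' *Escherichia coli*, and an enzyme roster spanning Type I, orthodox Type
#' II and Type III systems.
#'
#' @param n_genomes Number of genomes.
#' @param genome_length Genome length in nt.
#' @param composition Either 4 base frequencies (A, C, G, T; summing to 1)
#'   or a 4x4 first-order Markov transition matrix (rows summing to 1).
#' @param seed Single integer seed; all stochastic steps draw from one
#'   stream seeded once, so fixtures are byte-reproducible.
#' @param depletion_targets Named numeric vector: site text -> target CB in
#'   `[0, 1]`, applied to every genome in the given order.
#' @param genome_class,lifestyle,anti_restriction Label vectors recycled
#'   over genomes.
#' @param host_species Character vector (or list of vectors) of host species
#'   per genome, recycled.
#' @param enzymes Data.frame with columns `enzyme_name`, `rm_type`,
#'   `recognition_site`, `organism_species`, `evidence`.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genomes = 10L, genome_length = 2e5L,
                           composition = c(A = 0.25, C = 0.25,
                                           G = 0.25, T = 0.25),
                           seed = 1L,
                           depletion_targets = c(GAATTC = 0.05, GGATCC = 1.0),
                           genome_class = "dsDNA",
                           lifestyle = c("non_temperate", "temperate"),
                           anti_restriction = "none",
                           host_species = "escherichia_coli",
                           enzymes = .default_enzymes()) {
  .validate_composition(composition)
  if (length(depletion_targets) &&
      (is.null(names(depletion_targets)) ||
       any(!nzchar(names(depletion_targets)))))
    stop("`depletion_targets` must be a named vector (site -> target CB)")
  if (any(depletion_targets < 0 | depletion_targets > 1))
    stop("depletion targets must lie in [0, 1]")
  structure(
    list(n_genomes = as.integer(n_genomes),
         genome_length = as.integer(genome_length),
         composition = composition, seed = as.integer(seed),
         depletion_targets = depletion_targets,
         genome_class = genome_class, lifestyle = lifestyle,
         anti_restriction = anti_restriction,
         host_species = if (is.list(host_species)) host_species
         else list(host_species),
         enzymes = enzymes),
    class = "synthetic_spec"
  )
}

.validate_composition <- function(composition) {
  if (is.matrix(composition)) {
    if (!all(dim(composition) == 4L) || any(composition < 0) ||
        any(abs(rowSums(composition) - 1) > 1e-9))
      stop("transition matrix must be 4x4 with rows summing to 1")
  } else {
    if (length(composition) != 4L || any(composition < 0) ||
        abs(sum(composition) - 1) > 1e-9)
      stop("base frequencies must be 4 non-negative values summing to 1")
  }
  invisible(composition)
}

#' Generate a background genome
#'
#' Draws a pseudo-random sequence, either i.i.d. from base frequencies or
#' from a first-order Markov chain (initial base from the stationary
#' distribution). Identical `(seed, parameters)` give identical sequences.
#'
#' @param length Sequence length in nt (>= 1).
#' @param composition Base frequencies or 4x4 transition matrix (A, C, G, T
#'   order).
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @param genome_id Id for the returned record.
#' @return A [genome_record()].
#' @export
generate_background <- function(length, composition = c(A = 0.25, C = 0.25,
                                                        G = 0.25, T = 0.25),
                                seed = NULL, genome_id = "synthetic") {
  if (length < 1L) stop("`length` must be at least 1")
  .validate_composition(composition)
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  if (is.matrix(composition)) {
    ev <- eigen(t(composition))
    stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
    stat <- stat / sum(stat)
    cum <- t(apply(composition, 1L, cumsum))
    u <- runif(length)
    states <- integer(length)
    states[1L] <- findInterval(u[1L], cumsum(stat)) + 1L
    for (i in seq_len(length - 1L))
      states[i + 1L] <- findInterval(u[i + 1L], cum[states[i], ]) + 1L
    seq <- paste(bases[pmin(states, 4L)], collapse = "")
  } else {
    seq <- paste(sample(bases, length, replace = TRUE, prob = composition),
                 collapse = "")
  }
  genome_record(genome_id, seq)
}

# CB of a pattern on pre-encoded codes (internal fast path for depletion).
.cb_of_codes <- function(codes, p, orientation, cfg) {
  sc <- .subsite_counts(codes, p, orientation)
  observed <- sc$counts[sc$subsites$n_retained == p$effective_length]
  expected <- .expected_from_counts(sc$counts, sc$subsites)
  list(observed = observed, expected = expected,
       cb = if (is.finite(expected) && expected > 0) observed / expected
       else NA_real_)
}

#' Deplete a site from a genome down to a target CB
#'
#' Emulates the selection that restriction pressure exerts on a phage
#' genome: existing matches of the site are destroyed one point mutation at
#' a time, leaving the background composition nearly intact so the
#' subsite-based expectation stays calibrated. Each sweep mutates a random
#' 20% (at least one) of the remaining matches - a random specified
#' position of the match is changed to a random base outside that pattern
#' letter's set - then the CB is recomputed; sweeps stop as soon as CB falls
#' to or below `target_cb`, or no matches remain. Palindromic sites are
#' tracked on the given strand, asymmetric sites on both strands combined.
#'
#' @param g A [genome_record()].
#' @param p Site string or `nucleotide_pattern`.
#' @param target_cb Target CB in `[0, 1]`; 1 returns the genome unmodified,
#'   0 removes every match.
#' @param seed Integer seed, or `NULL` to draw from the current stream.
#' @param cfg An [analysis_config()].
#' @param sweep_fraction Fraction of remaining matches mutated per sweep.
#' @return The modified [genome_record()], with attribute `n_mutations`.
#' @export
deplete_site <- function(g, p, target_cb, seed = NULL,
                         cfg = analysis_config(), sweep_fraction = 0.2) {
  stopifnot(target_cb >= 0, target_cb <= 1)
  p <- as_pattern(p)
  if (!is.null(seed)) set.seed(seed)
  if (target_cb >= 1) return(g)
  orientation <- if (p$is_palindrome) "given_strand" else "combined"
  chars <- strsplit(g$sequence, "", fixed = TRUE)[[1L]]
  codes <- encode_genome(g$sequence)
  texts <- if (orientation == "combined") c(p$text, reverse_complement(p$text))
  else p$text
  masks <- lapply(texts, encode_pattern)
  spec_of <- lapply(texts, function(tx)
    which(strsplit(tx, "", fixed = TRUE)[[1L]] != "N"))
  find_matches <- function() {
    hits <- lapply(seq_along(masks), function(i)
      match_positions_(codes, masks[[i]]))
    data.frame(pos = unlist(hits),
               which = rep(seq_along(masks), lengths(hits)))
  }
  m <- find_matches()
  if (nrow(m) == 0L) {
    if (target_cb > 0)
      warning(sprintf("site '%s' absent from genome '%s'; returned unchanged",
                      p$text, g$genome_id))
    attr(g, "n_mutations") <- 0L
    return(g)
  }
  n_mut <- 0L
  bases <- c("A", "C", "G", "T")
  repeat {
    st <- .cb_of_codes(codes, p, orientation, cfg)
    if (is.na(st$cb) || st$cb <= target_cb || nrow(m) == 0L) break
    take <- sample.int(nrow(m), max(1L, ceiling(sweep_fraction * nrow(m))))
    for (r in take) {
      i <- m$which[r]
      sp <- spec_of[[i]]
      j <- if (length(sp) == 1L) sp else sample(sp, 1L)
      letter <- substr(texts[i], j, j)
      breakers <- setdiff(bases, IUPAC_SETS[[letter]])
      newb <- if (length(breakers) == 1L) breakers else sample(breakers, 1L)
      at <- m$pos[r] + j - 1L
      chars[at] <- newb
      codes[at] <- unname(.base_bit[newb])
      n_mut <- n_mut + 1L
    }
    m <- find_matches()
  }
  g$sequence <- paste(chars, collapse = "")
  attr(g, "n_mutations") <- n_mut
  g
}

#' Generate a complete synthetic fixture
#'
#' Produces, deterministically for a given spec, the exact file formats the
#' pipeline consumes: a multi-FASTA of depleted genomes, the phage and
#' enzyme metadata TSVs, and a truth table recording each genome's intended
#' per-site target CB for parameter-recovery tests.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the four file paths and the in-memory
#'   `genomes` list.
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  n <- spec$n_genomes
  ids <- sprintf("SYN%03d", seq_len(n))
  rec <- function(x, i) x[[((i - 1L) %% length(x)) + 1L]]
  genomes <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generate_background(spec$genome_length, spec$composition,
                             genome_id = ids[i])
    for (s in names(spec$depletion_targets))
      g <- deplete_site(g, s, spec$depletion_targets[[s]])
    g$genome_class <- rec(as.list(spec$genome_class), i)
    g$lifestyle <- rec(as.list(spec$lifestyle), i)
    g$anti_restriction <- rec(as.list(spec$anti_restriction), i)
    g$host_species <- normalize_species(rec(spec$host_species, i))
    g$taxon_id <- sprintf("tax%03d", i)
    genomes[[i]] <- g
    if (length(spec$depletion_targets))
      truth[[i]] <- data.frame(genome_id = ids[i],
                               site = names(spec$depletion_targets),
                               target_cb = unname(spec$depletion_targets),
                               stringsAsFactors = FALSE)
  }
  roster_species <- normalize_species(spec$enzymes$organism_species)
  assigned <- unique(unlist(lapply(genomes, `[[`, "host_species")))
  if (length(setdiff(roster_species, assigned)))
    warning("enzyme roster references species with no assigned genomes: ",
            paste(setdiff(roster_species, assigned), collapse = ", "))
  fasta <- file.path(out_dir, "genomes.fasta")
  phage_tsv <- file.path(out_dir, "phage_table.tsv")
  rease_tsv <- file.path(out_dir, "rease_table.tsv")
  truth_tsv <- file.path(out_dir, "truth_table.tsv")
  write_fasta(genomes, fasta)
  phage_df <- data.frame(
    genome_id = ids,
    genome_class = vapply(genomes, `[[`, character(1), "genome_class"),
    lifestyle = vapply(genomes, `[[`, character(1), "lifestyle"),
    host_species = vapply(genomes, function(g)
      paste(g$host_species, collapse = ";"), character(1)),
    anti_restriction = vapply(genomes, `[[`, character(1), "anti_restriction"),
    taxon_id = vapply(genomes, `[[`, character(1), "taxon_id"),
    reference_flag = "yes",
    stringsAsFactors = FALSE
  )
  write.table(phage_df, phage_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(spec$enzymes, rease_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth_df <- if (length(truth)) do.call(rbind, truth)
  else data.frame(genome_id = character(0), site = character(0),
                  target_cb = numeric(0))
  write.table(truth_df, truth_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fasta = fasta, phage_table = phage_tsv,
                 rease_table = rease_tsv, truth_table = truth_tsv,
                 genomes = genomes))
}
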