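# Experimental and control (site, genome) pair datasets; genome
# dereplication; R-M type attribution.

RM_TYPES <- c("I", "II", "IIG", "IIM", "III", "IV")

#' Map a raw R-M type token to its effective type
#'
#' Centralises the orthodox-Type-II convention: Type II here means Type II
#' excluding subtypes IIG and IIM, which keep their own values. Raw subtype
#' tokens of orthodox Type II systems (e.g. `IIP`, `IIS`) fold into `II`;
#' anything unrecognised is an error.
#'
#' @param token Raw type string, e.g. `"II"`, `"IIP"`, `"IIG"`.
#' @return One of `"I"`, `"II"`, `"IIG"`, `"IIM"`, `"III"`, `"IV"`.
#' @examples
#' assign_effective_type("IIP")  # "II"
#' assign_effective_type("IIG")  # "IIG"
#' @export
assign_effective_type <- function(token) {
  token <- toupper(trimws(token))
  if (token %in% RM_TYPES) return(token)
  if (grepl("^II[A-FH-LN-Z]$", token)) return("II")
  stop(sprintf("unmappable R-M type token '%s'", token))
}

#' Construct a restriction-enzyme record
#'
#' @param enzyme_name Enzyme name, e.g. `"EcoRI"`.
#' @param rm_type R-M system type token (folded by
#'   [assign_effective_type()]).
#' @param site Recognition site, an IUPAC string (parsed by [parse_site()]).
#' @param organism_species Species encoding the enzyme.
#' @param evidence `"proved"` or `"predicted"` specificity.
#' @return An object of class `rease_record`.
#' @export
rease_record <- function(enzyme_name, rm_type, site, organism_species,
                         evidence = c("proved", "predicted")) {
  evidence <- match.arg(evidence)
  structure(
    list(enzyme_name = enzyme_name,
         rm_type = assign_effective_type(rm_type),
         site = parse_site(site),
         organism_species = normalize_species(organism_species),
         evidence = evidence),
    class = "rease_record"
  )
}

#' @export
print.rease_record <- function(x, ...) {
  cat(sprintf("<rease %s> Type %s, site %s, %s, %s\n", x$enzyme_name,
              x$rm_type, x$site$text, x$organism_species, x$evidence))
  invisible(x)
}

#' Build the experimental (site, genome) pair dataset
#'
#' Pairs each genome with every distinct recognition site of a restriction
#' enzyme encoded by at least one of the genome's host species: such a site
#' is expected to be under selective pressure in that genome. Host matching
#' is exact string equality on normalised species names. The same site can
#' be recognised by systems of several types, so each pair carries the union
#' of R-M types of all matching enzymes, and evidence `"proved"` as soon as
#' one matching enzyme is proved. Sites with literal (N-trimmed) length
#' below `cfg$min_site_length` are excluded; genomes with no known host
#' contribute nothing.
#'
#' @param genomes List of [genome_record()] objects with `host_species` set.
#' @param reases List of [rease_record()] objects.
#' @param cfg An [analysis_config()].
#' @return A data.frame with columns `genome_id`, `site`, `dataset`
#'   (`"experimental"`), `rm_types` (comma-joined, sorted) and
#'   `evidence_best`.
#' @export
build_experimental_pairs <- function(genomes, reases, cfg = analysis_config()) {
  empty <- data.frame(genome_id = character(0), site = character(0),
                      dataset = character(0), rm_types = character(0),
                      evidence_best = character(0), stringsAsFactors = FALSE)
  if (length(genomes) == 0L || length(reases) == 0L) return(empty)
  re <- data.table::data.table(
    species = vapply(reases, `[[`, character(1), "organism_species"),
    site = vapply(reases, function(r) r$site$text, character(1)),
    site_len = vapply(reases, function(r) r$site$length, integer(1)),
    rm_type = vapply(reases, `[[`, character(1), "rm_type"),
    evidence = vapply(reases, `[[`, character(1), "evidence")
  )
  re <- re[re$site_len >= cfg$min_site_length, ]
  if (nrow(re) == 0L) return(empty)
  hosts <- data.table::rbindlist(lapply(genomes, function(g) {
    if (length(g$host_species) == 0L) return(NULL)
    data.table::data.table(genome_id = g$genome_id,
                           species = normalize_species(g$host_species))
  }))
  if (is.null(hosts) || nrow(hosts) == 0L) return(empty)
  joined <- merge(hosts, re, by = "species", allow.cartesian = TRUE)
  if (nrow(joined) == 0L) return(empty)
  site <- rm_type <- evidence <- genome_id <- NULL  # NSE notes
  agg <- joined[, list(
    rm_types = paste(sort(unique(rm_type)), collapse = ","),
    evidence_best = if (any(evidence == "proved")) "proved" else "predicted"
  ), by = list(genome_id, site)]
  out <- as.data.frame(agg, stringsAsFactors = FALSE)
  out$dataset <- "experimental"
  out <- out[order(out$genome_id, out$site),
             c("genome_id", "site", "dataset", "rm_types", "evidence_best")]
  rownames(out) <- NULL
  out
}

#' Build a control pair dataset as a full Cartesian product
#'
#' Control datasets pair every catalogued recognition site with every genome
#' regardless of host, so the pair count is exactly
#' `length(sites) x length(genomes)`.
#'
#' @param genomes List of [genome_record()] objects, or a character vector of
#'   genome ids.
#' @param site_catalog Character vector of site strings (deduplicated on
#'   their N-trimmed text) or a list of `nucleotide_pattern`s.
#' @param dataset_label `"control1"` (e.g. phage genomes) or `"control2"`
#'   (e.g. eukaryotic-virus genomes).
#' @return A data.frame like [build_experimental_pairs()], with empty
#'   `rm_types` and `evidence_best` `"n/a"`.
#' @export
build_control_pairs <- function(genomes, site_catalog,
                                dataset_label = c("control1", "control2")) {
  dataset_label <- match.arg(dataset_label)
  ids <- if (is.character(genomes)) genomes
  else vapply(genomes, `[[`, character(1), "genome_id")
  sites <- if (is.list(site_catalog) &&
               all(vapply(site_catalog, inherits, logical(1), "nucleotide_pattern")))
    vapply(site_catalog, `[[`, character(1), "text")
  else vapply(unique(toupper(site_catalog)),
              function(s) parse_site(s)$text, character(1), USE.NAMES = FALSE)
  sites <- unique(sites)
  grid <- data.table::CJ(genome_id = ids, site = sites, sorted = FALSE)
  out <- as.data.frame(grid, stringsAsFactors = FALSE)
  out$dataset <- dataset_label
  out$rm_types <- ""
  out$evidence_best <- "n/a"
  out
}

# Canonical k-mer set of a sequence: each k-mer or its reverse complement,
# whichever is lexicographically smaller; windows with ambiguity letters are
# dropped.
.canonical_kmers <- function(sequence, k) {
  G <- nchar(sequence)
  if (G < k) return(character(0))
  kmers <- substring(sequence, 1:(G - k + 1L), k:G)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  if (length(kmers) == 0L) return(character(0))
  rc <- vapply(kmers, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
  unique(pmin(kmers, rc))
}

#' Dereplicate genomes by taxon and k-mer sequence identity
#'
#' Two-stage dereplication mirroring representative-genome selection. Stage
#' 1 keeps the longest genome per `taxon_id` (genomes without a taxon pass
#' through). Stage 2 estimates pairwise sequence identity from the Jaccard
#' similarity `J` of canonical 21-mer sets via the Mash distance
#' `d = -(1/k) * log(2J / (1 + J))`, identity `= 1 - d`, then single-linkage
#' clusters genomes with identity above `cfg$identity_threshold` and keeps
#' the longest member of each cluster (ties broken by the lexicographically
#' smallest id). All input genomes are returned with `is_representative`
#' set; the result is independent of input order.
#'
#' @param genomes List of [genome_record()] objects with non-empty sequences.
#' @param cfg An [analysis_config()].
#' @param k K-mer size for the identity estimate.
#' @return The input list with `is_representative` flags set.
#' @export
dereplicate <- function(genomes, cfg = analysis_config(), k = 21L) {
  n <- length(genomes)
  if (n == 0L) return(genomes)
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  lens <- vapply(genomes, `[[`, integer(1), "length")
  taxa <- vapply(genomes, function(g) g$taxon_id %||% NA_character_, character(1))

  # stage 1: longest genome per taxon id
  alive <- rep(TRUE, n)
  for (tx in unique(taxa[!is.na(taxa)])) {
    grp <- which(taxa == tx & !is.na(taxa))
    if (length(grp) < 2L) next
    best <- grp[order(-lens[grp], ids[grp])][1L]
    alive[setdiff(grp, best)] <- FALSE
  }

  # stage 2: single-linkage clustering at the identity threshold
  cand <- which(alive)
  kmer_sets <- vector("list", n)
  for (i in cand) {
    kmer_sets[[i]] <- .canonical_kmers(genomes[[i]]$sequence, k)
    if (length(kmer_sets[[i]]) == 0L)
      warning(sprintf("genome '%s' shorter than k = %d; kept as its own cluster",
                      ids[i], k))
  }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (length(cand) > 1L) {
    for (a in seq_along(cand)[-length(cand)]) {
      i <- cand[a]
      if (length(kmer_sets[[i]]) == 0L) next
      for (b in seq((a + 1L), length(cand))) {
        j <- cand[b]
        if (length(kmer_sets[[j]]) == 0L) next
        inter <- length(intersect(kmer_sets[[i]], kmer_sets[[j]]))
        if (inter == 0L) next
        J <- inter / (length(kmer_sets[[i]]) + length(kmer_sets[[j]]) - inter)
        d <- -(1 / k) * log(2 * J / (1 + J))
        if (1 - d > cfg$identity_threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  cluster <- vapply(seq_len(n), find, integer(1))
  for (i in seq_len(n)) genomes[[i]]$is_representative <- FALSE
  for (cl in unique(cluster[alive])) {
    grp <- which(cluster == cl & alive)
    best <- grp[order(-lens[grp], ids[grp])][1L]
    genomes[[best]]$is_representative <- TRUE
  }
  genomes
}

#' Keep only representative genomes
#'
#' @param genomes List of [genome_record()]s already run through
#'   [dereplicate()].
#' @return The sub-list with `is_representative == TRUE`.
#' @export
representatives <- function(genomes) {
  genomes[vapply(genomes, `[[`, logical(1), "is_representative")]
}

#' Write a pair table to TSV
#'
#' @param pairs Data.frame from [build_experimental_pairs()] or
#'   [build_control_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
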