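# Genome records, FASTA input/output and metadata-table ingestion.

GENOME_CLASSES <- c("dsDNA", "ssDNA", "dsRNA", "ssRNA", "unknown")
LIFESTYLES <- c("temperate", "non_temperate", "unknown")
ANTI_RESTRICTION <- c("hydroxymethylase", "none", "unknown")

#' Construct a genome record
#'
#' One viral genome sequence plus the metadata used downstream: genome class
#' (dsDNA/ssDNA/dsRNA/ssRNA), lifestyle (temperate/non-temperate), host
#' species and anti-restriction status. Metadata default to unknown/empty and
#' are usually joined later with [load_metadata_tables()].
#'
#' @param genome_id Opaque identifier.
#' @param sequence Uppercase IUPAC string (RNA already transliterated U->T).
#' @param description Free-text description.
#' @param genome_class,lifestyle,anti_restriction Enum strings; see details.
#' @param host_species Character vector of host species names (possibly empty).
#' @param taxon_id Optional taxon identifier (`NA` when unknown).
#' @param is_representative Logical; set by [dereplicate()].
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(genome_id, sequence, description = "",
                          genome_class = "unknown", lifestyle = "unknown",
                          host_species = character(0),
                          anti_restriction = "unknown",
                          taxon_id = NA_character_,
                          is_representative = FALSE) {
  sequence <- toupper(sequence)
  validate_iupac(sequence)
  genome_class <- match.arg(genome_class, GENOME_CLASSES)
  lifestyle <- match.arg(lifestyle, LIFESTYLES)
  anti_restriction <- match.arg(anti_restriction, ANTI_RESTRICTION)
  structure(
    list(
      genome_id = as.character(genome_id),
      description = description,
      sequence = sequence,
      length = nchar(sequence),
      genome_class = genome_class,
      lifestyle = lifestyle,
      host_species = as.character(host_species),
      anti_restriction = anti_restriction,
      taxon_id = taxon_id,
      is_representative = is_representative
    ),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome %s> %d nt, %s, %s, hosts: %s\n", x$genome_id, x$length,
              x$genome_class, x$lifestyle,
              if (length(x$host_species)) paste(x$host_species, collapse = ";")
              else "none"))
  invisible(x)
}

#' Read viral genomes from a FASTA file
#'
#' Sequences are uppercased and `U` is transliterated to `T`, so RNA phage
#' genomes are analysed as DNA text by the same counting engine. The genome
#' id is the first whitespace-delimited token of the header. Multiple
#' records sharing one id (segmented genomes, e.g. dsRNA Cystoviridae) are
#' concatenated with a single `N` separator; `N` matches no pattern letter,
#' so no counting window ever spans a segment junction.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A list of [genome_record()] objects in file order, metadata at
#'   defaults.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file '%s' does not exist", path))
  if (file.size(path) == 0L) {
    warning(sprintf("FASTA file '%s' is empty", path))
    return(list())
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning(sprintf("FASTA file '%s' contains no records", path))
    return(list())
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  for (i in seq_along(seqs)) {
    bad <- regexpr(sprintf("[^%s]", paste(IUPAC_LETTERS, collapse = "")), seqs[i])
    if (bad > 0L)
      stop(sprintf("record '%s': non-IUPAC character '%s' at position %d",
                   ids[i], substr(seqs[i], bad, bad), bad))
  }
  out <- list()
  for (id in unique(ids)) {
    take <- which(ids == id)
    seq <- paste(seqs[take], collapse = "N")
    out[[length(out) + 1L]] <- genome_record(
      genome_id = id,
      sequence = seq,
      description = sub("^\\S+\\s*", "", headers[take[1L]])
    )
  }
  out
}

#' Write genome records to FASTA
#'
#' @param genomes List of [genome_record()] objects.
#' @param path Output file path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (g in genomes) {
    header <- if (nzchar(g$description))
      paste(g$genome_id, g$description) else g$genome_id
    writeLines(paste0(">", header), con, sep = "\n")
    starts <- seq(1L, g$length, by = width)
    writeLines(substring(g$sequence, starts, pmin(starts + width - 1L, g$length)),
               con, sep = "\n")
  }
  invisible(path)
}

# Normalize a species name: case- and separator-insensitive exact matching.
normalize_species <- function(x) {
  x <- tolower(trimws(x))
  gsub("[ _]+", "_", x)
}

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")))
}

#' Load phage and restriction-enzyme metadata tables
#'
#' Joins a tab-separated phage table onto genome records and parses a
#' restriction-enzyme table into `rease_record` objects.
#'
#' The phage table must have columns `genome_id`, `genome_class`,
#' `lifestyle`, `host_species` (semicolon-separated), `anti_restriction`,
#' `taxon_id`, `reference_flag`. The enzyme table must have `enzyme_name`,
#' `rm_type`, `recognition_site`, `organism_species`, `evidence`. Raw Type II
#' subtype tokens such as `IIP` are folded into orthodox `II` by
#' [assign_effective_type()]; `IIG` and `IIM` keep their own values.
#' Enzyme rows with an empty recognition site are skipped with a warning;
#' phage rows referencing absent genomes are counted and reported.
#'
#' @param phage_table,rease_table Paths to the TSV files.
#' @param genomes List of [genome_record()] objects to annotate.
#' @return A list with elements `genomes` (annotated records) and `reases`
#'   (list of `rease_record` objects).
#' @export
load_metadata_tables <- function(phage_table, rease_table, genomes) {
  ph <- read.delim(phage_table, sep = "\t", header = TRUE,
                   colClasses = "character", na.strings = NULL)
  .check_columns(ph, c("genome_id", "genome_class", "lifestyle",
                       "host_species", "anti_restriction"), "phage table")
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  n_unmatched <- 0L
  for (r in seq_len(nrow(ph))) {
    row <- ph[r, ]
    i <- match(row$genome_id, ids)
    if (is.na(i)) { n_unmatched <- n_unmatched + 1L; next }
    for (field in c("genome_class", "lifestyle", "anti_restriction")) {
      allowed <- switch(field, genome_class = GENOME_CLASSES,
                        lifestyle = LIFESTYLES,
                        anti_restriction = ANTI_RESTRICTION)
      val <- row[[field]]
      if (!nzchar(val)) val <- "unknown"
      if (!val %in% allowed)
        stop(sprintf("phage table row %d: unknown %s token '%s'", r, field, val))
      genomes[[i]][[field]] <- val
    }
    hosts <- trimws(strsplit(row$host_species, ";", fixed = TRUE)[[1L]])
    genomes[[i]]$host_species <- normalize_species(hosts[nzchar(hosts)])
    if ("taxon_id" %in% names(ph) && nzchar(row$taxon_id))
      genomes[[i]]$taxon_id <- row$taxon_id
  }
  if (n_unmatched > 0L)
    warning(sprintf("phage table: %d row(s) reference genomes absent from the FASTA",
                    n_unmatched))
  re <- read.delim(rease_table, sep = "\t", header = TRUE,
                   colClasses = "character", na.strings = NULL)
  .check_columns(re, c("enzyme_name", "rm_type", "recognition_site",
                       "organism_species", "evidence"), "rease table")
  reases <- list()
  n_skipped <- 0L
  for (r in seq_len(nrow(re))) {
    row <- re[r, ]
    if (!nzchar(trimws(row$recognition_site))) { n_skipped <- n_skipped + 1L; next }
    if (!row$evidence %in% c("proved", "predicted"))
      stop(sprintf("rease table row %d: unknown evidence token '%s'", r, row$evidence))
    reases[[length(reases) + 1L]] <- rease_record(
      enzyme_name = row$enzyme_name,
      rm_type = assign_effective_type(row$rm_type),
      site = row$recognition_site,
      organism_species = row$organism_species,
      evidence = row$evidence
    )
  }
  if (n_skipped > 0L)
    warning(sprintf("rease table: %d row(s) with empty recognition site skipped",
                    n_skipped))
  list(genomes = genomes, reases = reases)
}
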