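#' Read a FASTA file
#'
#' Reads nucleotide or protein FASTA. Record ids are the first
#' whitespace-delimited token of each header; the remainder of the header is
#' kept as the `description` attribute. Sequences are uppercased and returned
#' in file order.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record ids), with a
#'   `description` attribute holding the rest of each header line.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a some gene", "ACGT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  attr(seqs, "description") <- desc
  seqs
}

#' Write sequences to FASTA
#'
#' @param x Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.null(names(x)) || any(names(x) == ""))
    stop("all sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Load a strain metadata table
#'
#' Reads a TSV/CSV with columns `id`, `species` and `role`. Roles must be
#' one of `train`, `test` or `query`. An empty species field is allowed only
#' for `query` strains and is recorded as `"unknown"`. Additional columns
#' are preserved.
#'
#' @param path Path to a tab- or comma-separated table with a header.
#' @return A data frame of strains with columns `id`, `species`, `role`
#'   (class `strain_table`).
#' @export
load_strain_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "")
  if (!"id" %in% names(tab)) stop("strain table is missing the 'id' column")
  if (!"role" %in% names(tab)) stop("strain table is missing the 'role' column")
  if (!"species" %in% names(tab)) tab$species <- NA_character_
  if (anyDuplicated(tab$id))
    stop("duplicate strain id(s): ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  tab$role <- tolower(trimws(as.character(tab$role)))
  bad <- setdiff(unique(tab$role), c("train", "test", "query"))
  if (length(bad) > 0L)
    stop("invalid role(s): ", paste(bad, collapse = ", "),
         " (must be train, test or query)")
  tab$species <- trimws(as.character(tab$species))
  missing_sp <- is.na(tab$species) | tab$species == ""
  if (any(missing_sp & tab$role != "query"))
    stop("species missing for non-query strain(s): ",
         paste(tab$id[missing_sp & tab$role != "query"], collapse = ", "))
  tab$species[missing_sp] <- "unknown"
  class(tab) <- c("strain_table", "data.frame")
  tab
}

#' Construct a genome record
#'
#' @param strain_id Strain identifier.
#' @param contigs Named character vector of contig sequences.
#' @param cds Optional data frame of gene records with columns `gene_id`,
#'   `nuc` and (optionally) `prot`. When `prot` is absent it is derived by
#'   translating `nuc`.
#' @return An object of class `genome`.
#' @export
genome <- function(strain_id, contigs, cds = NULL) {
  stopifnot(is.character(strain_id), length(strain_id) == 1L)
  contigs <- toupper(contigs)
  if (is.null(names(contigs)))
    names(contigs) <- paste0("contig_", seq_along(contigs))
  if (sum(nchar(contigs)) == 0L) stop("genome has zero total length")
  if (!is.null(cds)) {
    cds <- as.data.frame(cds, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "nuc") %in% names(cds)))
      stop("cds needs columns gene_id and nuc")
    cds$nuc <- toupper(cds$nuc)
    if (anyDuplicated(cds$gene_id))
      stop("duplicate gene id(s) in CDS of ", strain_id)
    if (is.null(cds$prot)) cds$prot <- translate_cds(cds$nuc)
  }
  structure(list(strain_id = strain_id, contigs = contigs, cds = cds),
            class = "genome")
}

#' Translate coding sequences to protein
#'
#' Standard genetic code; internal stops appear as `*`. Lengths must be
#' multiples of three.
#'
#' @param nuc Character vector of in-frame nucleotide CDS.
#' @return Character vector of protein sequences.
#' @export
translate_cds <- function(nuc) {
  if (any(nchar(nuc) %% 3L != 0L))
    stop("CDS length(s) not a multiple of 3")
  as.character(Biostrings::translate(Biostrings::DNAStringSet(nuc),
                                     if.fuzzy.codon = "X"))
}

#' Bundle strains and genomes into a strain set
#'
#' @param strains A `strain_table` (or data frame with `id`, `species`,
#'   `role`).
#' @param genomes Named list of [genome()] objects, one per strain id.
#' @param outgroups Character vector of strain ids treated as outgroups.
#' @return An object of class `strain_set`.
#' @export
strain_set <- function(strains, genomes, outgroups = character()) {
  strains <- as.data.frame(strains, stringsAsFactors = FALSE)
  if (anyDuplicated(strains$id)) stop("strain ids must be unique")
  miss <- setdiff(strains$id, names(genomes))
  if (length(miss) > 0L)
    stop("no genome for strain(s): ", paste(miss, collapse = ", "))
  if (!all(outgroups %in% strains$id))
    stop("outgroups must be a subset of strain ids")
  structure(list(strains = strains, genomes = genomes[strains$id],
                 outgroups = outgroups),
            class = "strain_set")
}

#' @export
print.strain_set <- function(x, ...) {
  cat("strain_set:", nrow(x$strains), "strains")
  if (length(x$outgroups)) cat(" (", length(x$outgroups), "outgroups)")
  cat("\n")
  sp <- table(x$strains$species)
  cat("  species:", paste(sprintf("%s (%d)", names(sp), sp), collapse = ", "),
      "\n")
  invisible(x)
}

#' Validate a strain set
#'
#' Report-only screen: flags strains without CDS, genomes containing
#' non-ACGT characters (with the offending fraction), and duplicate gene
#' ids. A clean set yields a zero-row report.
#'
#' @param s A [strain_set()].
#' @return Data frame with columns `strain`, `issue`, `value`.
#' @export
validate_strainset <- function(s) {
  stopifnot(inherits(s, "strain_set"))
  out <- list()
  for (id in s$strains$id) {
    g <- s$genomes[[id]]
    if (is.null(g$cds) || nrow(g$cds) == 0L)
      out[[length(out) + 1L]] <- data.frame(
        strain = id, issue = "missing_cds", value = NA_real_)
    seqs <- paste(g$contigs, collapse = "")
    n_bad <- nchar(seqs) - sum(vapply(
      c("A", "C", "G", "T"),
      function(b) lengths(regmatches(seqs, gregexpr(b, seqs, fixed = TRUE))),
      numeric(1)))
    if (n_bad > 0L)
      out[[length(out) + 1L]] <- data.frame(
        strain = id, issue = "non_acgt", value = n_bad / nchar(seqs))
    if (!is.null(g$cds) && anyDuplicated(g$cds$gene_id))
      out[[length(out) + 1L]] <- data.frame(
        strain = id, issue = "duplicate_gene_ids", value = NA_real_)
  }
  if (length(out) == 0L)
    return(data.frame(strain = character(), issue = character(),
                      value = numeric()))
  do.call(rbind, out)
}

# Proteome of a strain as a named character vector; errors if absent.
proteome_of <- function(set, id) {
  g <- set$genomes[[id]]
  if (is.null(g) || is.null(g$cds) || nrow(g$cds) == 0L)
    stop("strain lacks a proteome: ", id)
  setNames(g$cds$prot, g$cds$gene_id)
}
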