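#' Read plastome sequences from a FASTA file
#'
#' Reads one or more genome sequences, normalising each to upper case with
#' RNA `U` mapped to `T`. Only `A`, `C`, `G`, `T`, `N` are accepted in a
#' genome sequence; anything else (including alignment gaps) is a hard
#' error naming the offending record.
#'
#' @param path path to a FASTA file.
#' @return a tibble with one row per record: `species` (the FASTA header up
#'   to the first whitespace), `sequence`, `length`.
#' @seealso [read_alignment_fasta()] for gapped, aligned input.
#' @export
read_plastome_fasta <- function(path) {
  recs <- read_fasta_normalised(path, allow_gaps = FALSE)
  tibble(species = names(recs), sequence = unname(recs),
         length = nchar(unname(recs)))
}

#' Read a multiple sequence alignment from FASTA
#'
#' Rows are normalised like [read_plastome_fasta()] but the gap character
#' `-` is allowed; all rows must have equal length.
#'
#' @param path path to an aligned FASTA file.
#' @return a tibble with columns `taxon`, `sequence`; all sequences have
#'   equal length.
#' @export
read_alignment_fasta <- function(path) {
  recs <- read_fasta_normalised(path, allow_gaps = TRUE)
  len <- nchar(recs)
  if (length(unique(len)) > 1L) {
    abort(paste0("Alignment rows differ in length: ",
                 paste(unique(len), collapse = ", ")))
  }
  tibble(taxon = names(recs), sequence = unname(recs))
}

# Shared FASTA reader: parse with Biostrings, then apply the package's
# normalisation contract (case, U->T, alphabet check, duplicate ids).
read_fasta_normalised <- function(path, allow_gaps = FALSE) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(paste0("Empty FASTA file: ", path))
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate FASTA identifiers: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  alphabet <- if (allow_gaps) "ACGTN-" else "ACGTN"
  bad <- !grepl(paste0("^[", alphabet, "]*$"), seqs)
  if (any(bad)) {
    offending <- gsub(paste0("[", alphabet, "]"), "", seqs[bad][1])
    abort(paste0("Record '", ids[bad][1], "' contains characters outside {",
                 paste(strsplit(alphabet, "")[[1]], collapse = ","),
                 "}: ", substr(offending, 1, 10)))
  }
  if (any(nchar(seqs) == 0L)) {
    abort(paste0("Record '", ids[nchar(seqs) == 0L][1], "' is empty."))
  }
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param x a named character vector of sequences, or a tibble with the
#'   first column holding names (`species` or `taxon`) and a `sequence`
#'   column.
#' @param path output path.
#' @param width line wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  if (is.data.frame(x)) {
    stopifnot("sequence" %in% names(x))
    x <- setNames(x$sequence, x[[1]])
  }
  stopifnot(is.character(x), !is.null(names(x)))
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

#' Read gene annotations from GFF3
#'
#' Imports gene-like features (`gene`, `tRNA`, `rRNA`, `pseudogene`) for one
#' sequence. Coordinates are 1-based inclusive, the GFF3 convention used
#' throughout this package.
#'
#' @param path path to a GFF3 file.
#' @param seq_id sequence identifier to filter on (GFF3 column 1); `NULL`
#'   keeps all.
#' @param genome_length optional; if given, features extending past it are
#'   an error.
#' @return a tibble: `gene_id`, `start`, `end`, `strand`, `feature_class`
#'   (`protein_coding`, `tRNA`, `rRNA`, `pseudogene`).
#' @export
read_gene_gff3 <- function(path, seq_id = NULL, genome_length = NULL) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  keep_types <- c(gene = "protein_coding", tRNA = "tRNA", rRNA = "rRNA",
                  pseudogene = "pseudogene")
  df <- df[as.character(df$type) %in% names(keep_types), , drop = FALSE]
  if (!is.null(seq_id)) {
    df <- df[as.character(df$seqnames) == seq_id, , drop = FALSE]
  }
  if (nrow(df) == 0L) {
    return(tibble(gene_id = character(), start = integer(), end = integer(),
                  strand = character(), feature_class = character()))
  }
  strand <- as.character(df$strand)
  if (any(!strand %in% c("+", "-"))) {
    abort(paste0("Feature with unknown strand '",
                 strand[!strand %in% c("+", "-")][1], "' in ", path))
  }
  ids <- if ("ID" %in% names(df)) as.character(df$ID) else NA_character_
  if ("Name" %in% names(df)) {
    nm <- as.character(df$Name)
    ids <- ifelse(is.na(nm) | !nzchar(nm), ids, nm)
  }
  out <- tibble(
    gene_id = ids,
    start = as.integer(df$start),
    end = as.integer(df$end),
    strand = strand,
    feature_class = unname(keep_types[as.character(df$type)])
  )
  if (any(out$end < out$start)) {
    abort("GFF3 feature with end < start.")
  }
  if (!is.null(genome_length) && any(out$end > genome_length | out$start < 1)) {
    bad <- out$gene_id[out$end > genome_length | out$start < 1][1]
    abort(paste0("Feature '", bad, "' extends outside [1, ",
                 genome_length, "]."))
  }
  arrange(out, .data$start, .data$end)
}

#' Write a tibble as a tab-separated file
#'
#' UTF-8, tab-delimited, header row — the package's tabular output format.
#'
#' @param x a data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
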