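#' Read a genome reference from FASTA
#'
#' Loads all records of a FASTA file into a `DNAStringSet`, normalizing the
#' sequence to uppercase. Record names are truncated at the first whitespace,
#' must be unique, and sequences may only use the A/C/G/T/N alphabet.
#'
#' @param path path to a FASTA file
#' @return a named [Biostrings::DNAStringSet] (the package's genome container)
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format("FASTA file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(first, ">"))
    stop_format("malformed FASTA (missing '>' header): %s", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop_format("empty FASTA: %s", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop_format("duplicate sequence names in FASTA: %s",
                paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  bad <- grepl("[^ACGTN]", as.character(seqs))
  if (any(bad))
    stop_format("sequence alphabet outside A/C/G/T/N in record(s): %s",
                paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' Write a genome reference to FASTA
#'
#' @param genome named `DNAStringSet` (see [read_fasta()])
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

# fetch genome[chrom][start..end] (1-based inclusive) as a character string
genome_subseq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop_format("chromosome not in genome: %s", chrom)
  len <- length(genome[[chrom]])
  if (start < 1L || end > len)
    stop_format("coordinates [%d,%d] outside chromosome %s (length %d)",
                start, end, chrom, len)
  as.character(Biostrings::subseq(genome[[chrom]], start, end))
}

# vectorized 2-mer extraction at 'start' positions on one chromosome
genome_kmers <- function(genome, chrom, starts, k = 2L) {
  stopifnot(length(unique(chrom)) <= 1L)
  if (length(starts) == 0L) return(character(0))
  v <- Biostrings::Views(genome[[chrom[1L]]],
                         start = as.integer(starts),
                         end = as.integer(starts) + k - 1L)
  as.character(v)
}
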