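#' Transcript annotation container
#'
#' Builds the package's annotation object from an exon table. Internal
#' coordinates are 1-based inclusive throughout (the GTF/GRanges convention);
#' a junction is the intron interval from its first to its last base.
#'
#' @param exons data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `gene_id`, `transcript_id`; one row per exon, 1-based
#'   inclusive coordinates.
#' @param min_intron minimum intron length in bp; adjacent-exon gaps shorter
#'   than this trigger a warning (junctions are still recorded).
#' @return an object of class `"annotation"`: a list with elements `exons`
#'   (sorted exon table), `transcripts` (per-transcript summary), `genes`
#'   (per-gene spans) and `junctions` (the unique known-junction table).
#' @export
annotation <- function(exons, min_intron = 42L) {
  need <- c("chrom", "start", "end", "strand", "gene_id", "transcript_id")
  missing_cols <- setdiff(need, names(exons))
  if (length(missing_cols))
    stop_format("exon table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  exons <- as.data.frame(exons)[need]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons) == 0L) stop_format("annotation has no exons")
  if (any(is.na(exons$transcript_id)) || any(is.na(exons$gene_id)))
    stop_format("exon feature lacking gene_id/transcript_id")
  if (!all(exons$strand %in% c("+", "-")))
    stop_format("exon strand must be '+' or '-'")
  if (any(exons$end < exons$start)) stop_format("exon with end < start")
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  dt <- data.table::as.data.table(exons)
  # per-transcript consistency: one chrom/strand, strictly increasing, disjoint
  chk <- dt[, list(
    one_chrom = length(unique(chrom)) == 1L,
    one_strand = length(unique(strand)) == 1L,
    disjoint = all(start[-1L] > end[-length(end)]) || .N == 1L
  ), by = "transcript_id"]
  if (!all(chk$one_chrom) || !all(chk$one_strand))
    stop_format("transcript(s) with exons on multiple chromosomes/strands: %s",
                paste(chk$transcript_id[!(chk$one_chrom & chk$one_strand)], collapse = ", "))
  if (!all(chk$disjoint))
    stop_format("overlapping or unsorted exons within transcript(s): %s",
                paste(chk$transcript_id[!chk$disjoint], collapse = ", "))
  g2t <- unique(dt[, c("transcript_id", "gene_id")])
  if (anyDuplicated(g2t$transcript_id))
    stop_format("transcript assigned to more than one gene: %s",
                paste(g2t$transcript_id[duplicated(g2t$transcript_id)], collapse = ", "))

  transcripts <- as.data.frame(dt[, list(
    gene_id = gene_id[1L], chrom = chrom[1L], strand = strand[1L],
    n_exons = .N, exonic_len = sum(end - start + 1L),
    start = min(start), end = max(end)
  ), by = "transcript_id"])
  genes <- as.data.frame(dt[, list(
    chrom = chrom[1L], strand = strand[1L],
    start = min(start), end = max(end)
  ), by = "gene_id"])

  # known junctions: introns between adjacent exons of each transcript
  jdt <- dt[, if (.N > 1L) list(
    chrom = chrom[1L], start = end[-.N] + 1L, end = start[-1L] - 1L,
    strand = strand[1L], gene_id = gene_id[1L]
  ), by = "transcript_id"]
  if (nrow(jdt)) {
    short <- jdt$end - jdt$start + 1L < min_intron
    if (any(short))
      warning(sprintf("%d junction(s) shorter than min_intron = %d bp",
                      sum(short), min_intron))
    juncs <- unique(as.data.frame(
      jdt[, c("chrom", "start", "end", "strand", "gene_id")]))
    juncs <- juncs[order(juncs$chrom, juncs$start, juncs$end), , drop = FALSE]
    rownames(juncs) <- NULL
    juncs$key <- junction_key(juncs$chrom, juncs$start, juncs$end)
  } else {
    juncs <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        gene_id = character(0), key = character(0))
  }
  structure(list(exons = exons, transcripts = transcripts, genes = genes,
                 junctions = juncs, min_intron = as.integer(min_intron)),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("annotation: %d gene(s), %d transcript(s), %d exon(s), %d known junction(s)\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons), nrow(x$junctions)))
  invisible(x)
}

#' Read transcript models from GTF
#'
#' Parses `exon` features (other feature types are ignored), requiring
#' `gene_id` and `transcript_id` attributes, and converts them into the
#' package annotation container. GTF coordinates are 1-based inclusive and
#' are kept as-is internally.
#'
#' @param path path to a GTF file
#' @inheritParams annotation
#' @return an [annotation] object
#' @export
read_gtf <- function(path, min_intron = 42L) {
  if (!file.exists(path)) stop_format("GTF file not found: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(gr) == 0L) stop_format("no exon features in GTF: %s", path)
  tx <- as.character(S4Vectors::mcols(gr)$transcript_id %||% rep(NA_character_, length(gr)))
  gid <- as.character(S4Vectors::mcols(gr)$gene_id %||% rep(NA_character_, length(gr)))
  if (any(is.na(tx)) || any(is.na(gid)))
    stop_format("exon feature lacking gene_id/transcript_id in %s", path)
  annotation(data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gid, transcript_id = tx), min_intron = min_intron)
}

#' Write an annotation to GTF
#'
#' Emits one `exon` feature per exon with `gene_id` and `transcript_id`
#' attributes; `read_gtf(write_gtf(ann, f))` reproduces `ann`.
#'
#' @param ann an [annotation] object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gtf <- function(ann, path) {
  ex <- ann$exons
  gr <- GenomicRanges::GRanges(
    seqnames = ex$chrom,
    ranges = IRanges::IRanges(ex$start, ex$end),
    strand = ex$strand,
    type = "exon", source = "spliceward",
    gene_id = ex$gene_id, transcript_id = ex$transcript_id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Junctions of transcripts with donor/acceptor motifs
#'
#' Returns one row per adjacent exon pair per transcript. When a genome is
#' supplied, donor and acceptor dinucleotides are read from the reference and
#' reported strand-oriented: an annotated canonical intron reports donor
#' `"GT"`, acceptor `"AG"` on either genomic strand.
#'
#' @param ann an [annotation] object
#' @param genome optional genome `DNAStringSet` (see [read_fasta()])
#' @param transcript_id optional subset of transcript ids
#' @return data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `key` and, with a genome, `donor`, `acceptor`
#' @export
junctions_of <- function(ann, genome = NULL, transcript_id = NULL) {
  dt <- data.table::as.data.table(ann$exons)
  if (!is.null(transcript_id)) dt <- dt[dt$transcript_id %in% transcript_id]
  j <- dt[, if (.N > 1L) list(
    gene_id = gene_id[1L], chrom = chrom[1L],
    start = end[-.N] + 1L, end = start[-1L] - 1L, strand = strand[1L]
  ), by = "transcript_id"]
  j <- as.data.frame(j)
  if (nrow(j) == 0L) {
    j <- data.frame(transcript_id = character(0), gene_id = character(0),
                    chrom = character(0), start = integer(0), end = integer(0),
                    strand = character(0))
  }
  j$key <- junction_key(j$chrom, j$start, j$end)
  if (!is.null(genome) && nrow(j)) {
    m <- junction_motifs(genome, j$chrom, j$start, j$end, j$strand)
    j$donor <- m$donor
    j$acceptor <- m$acceptor
  }
  j
}

#' Strand-oriented donor/acceptor motifs for junction coordinates
#'
#' @param genome genome `DNAStringSet`
#' @param chrom,start,end junction coordinates (1-based inclusive intron)
#' @param strand `"+"`, `"-"`; `"*"`/`NA` is treated as `"+"` (forward
#'   orientation reported)
#' @return list with character vectors `donor`, `acceptor`,
#'   `donor_fwd`, `acceptor_fwd` (forward-strand 2-mers)
#' @export
junction_motifs <- function(genome, chrom, start, end, strand) {
  n <- length(chrom)
  donor_fwd <- acceptor_fwd <- character(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    len <- length(genome[[ch]])
    if (any(start[i] < 1L) || any(end[i] > len))
      stop_format("junction coordinates outside chromosome %s", ch)
    donor_fwd[i] <- genome_kmers(genome, ch, start[i])
    acceptor_fwd[i] <- genome_kmers(genome, ch, end[i] - 1L)
  }
  minus <- !is.na(strand) & strand == "-"
  donor <- donor_fwd
  acceptor <- acceptor_fwd
  if (any(minus)) {
    donor[minus] <- revcomp_chr(acceptor_fwd[minus])
    acceptor[minus] <- revcomp_chr(donor_fwd[minus])
  }
  list(donor = donor, acceptor = acceptor,
       donor_fwd = donor_fwd, acceptor_fwd = acceptor_fwd)
}
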