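#' Read spliced alignments from SAM/BAM
#'
#' SAM input is converted on the fly; mapped records are returned as a
#' `GAlignments` object for the quantification routines.
#'
#' @param path SAM or BAM file
#' @return a [GenomicAlignments::GAlignments] object
#' @export
read_alignments <- function(path) {
  bam <- ensure_bam(path)
  GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))
}

# per-read alignment blocks as a data.table (read, chrom, start, end)
alignment_blocks <- function(gal) {
  grl <- GenomicAlignments::grglist(gal)
  u <- BiocGenerics::unlist(grl, use.names = FALSE)
  data.table::data.table(
    read = rep(seq_along(grl), S4Vectors::elementNROWS(grl)),
    chrom = as.character(GenomeInfoDb::seqnames(u)),
    start = GenomicRanges::start(u),
    end = GenomicRanges::end(u))
}

#' Extract junction observations from spliced alignments
#'
#' Every alignment gap (CIGAR `N`) of at least `min_intron` bp yields one
#' junction observation keyed by the gap interval; observations whose
#' flanking matched blocks are shorter than `min_overhang` are discarded. A
#' read spanning k junctions contributes k observations; the anchors of an
#' interior gap are the matched blocks immediately flanking it.
#'
#' @param aln a `GAlignments` or a SAM/BAM path
#' @param min_overhang minimum anchor length in bp (default 8)
#' @param min_intron minimum gap length treated as an intron (default 42)
#' @return data.frame with one row per observation: `chrom`, `start`, `end`
#'   (intron, 1-based inclusive), `left`, `right` (anchor lengths), `key`
#' @export
extract_spliced_alignments <- function(aln, min_overhang = 8L, min_intron = 42L) {
  if (is.character(aln)) aln <- read_alignments(aln)
  stopifnot(min_overhang >= 1L)
  bl <- alignment_blocks(aln)
  obs <- bl[, if (.N > 1L) {
    w <- end - start + 1L
    list(chrom = chrom[-.N], start = end[-.N] + 1L, end = start[-1L] - 1L,
         left = w[-.N], right = w[-1L])
  }, by = "read"]
  obs <- obs[(end - start + 1L) >= min_intron &
             left >= min_overhang & right >= min_overhang]
  obs <- as.data.frame(obs)
  obs$key <- junction_key(obs$chrom, obs$start, obs$end)
  obs
}

#' Shannon entropy of alignment offsets
#'
#' `H = -sum(p_i log2 p_i)` over the distinct offsets of the reads
#' supporting a junction; `p_i` is the fraction of supporting reads with
#' offset i. Low entropy indicates stacked, low-complexity support; at
#' least four distinct equally weighted offsets are needed to reach H = 2.
#'
#' @param offsets integer vector (multiset) of alignment offsets, e.g. the
#'   left-anchor lengths of the supporting reads
#' @return entropy in bits
#' @export
offset_entropy <- function(offsets) {
  if (length(offsets) == 0L) stop_format("entropy of an empty offset multiset is undefined")
  p <- table(offsets) / length(offsets)
  -sum(p * log2(p))
}

#' Minimum match on either side (MMES)
#'
#' Per supporting read, the shorter of its two anchors; the junction-level
#' MMES is the maximum of these per-read minima.
#'
#' @param left,right integer anchor lengths per supporting read
#' @return junction MMES in bp
#' @export
mmes <- function(left, right) {
  stopifnot(length(left) == length(right), length(left) >= 1L)
  max(pmin(left, right))
}

#' Exon/intron shoulder repeat identity
#'
#' Compares, per junction, the `window` bp upstream of the donor with the
#' `window` bp upstream of the acceptor (donor side), and the `window` bp
#' downstream of the donor with the `window` bp downstream of the acceptor
#' (acceptor side), reporting Levenshtein percent identity
#' `100 * (w - edit distance) / w`. Windows are truncated symmetrically at
#' contig edges. High identity betrays gapped alignments induced by
#' repetitive sequence rather than splicing.
#'
#' @param genome genome `DNAStringSet`
#' @param chrom,start,end junction coordinates (vectorized)
#' @param window window size in bp (default 10)
#' @return data.frame with columns `donor_side`, `acceptor_side` (percent)
#' @export
repeat_identity <- function(genome, chrom, start, end, window = 10L) {
  n <- length(start)
  ds <- as <- numeric(n)
  clen <- setNames(Biostrings::width(genome), names(genome))
  pid <- function(a, b, w) {
    if (w <= 0L) return(NA_real_)
    100 * (w - adist(a, b)[1L, 1L]) / w
  }
  for (i in seq_len(n)) {
    len <- clen[[chrom[i]]]
    w_up <- min(window, start[i] - 1L)
    w_dn <- min(window, len - end[i])
    up_don <- genome_subseq(genome, chrom[i], start[i] - w_up, start[i] - 1L)
    up_acc <- genome_subseq(genome, chrom[i], end[i] - w_up + 1L, end[i])
    dn_don <- genome_subseq(genome, chrom[i], start[i], start[i] + w_dn - 1L)
    dn_acc <- genome_subseq(genome, chrom[i], end[i] + 1L, end[i] + w_dn)
    ds[i] <- pid(up_don, up_acc, w_up)
    as[i] <- pid(dn_don, dn_acc, w_dn)
  }
  data.frame(donor_side = ds, acceptor_side = as)
}

#' Infer junction strand from interior donor/acceptor motifs
#'
#' For non-strand-specific libraries, strand is read off the intron's
#' terminal dinucleotides: GT-AG, then GC-AG, then AT-AC are checked on the
#' forward orientation, then their reverse complements (CT-AC, CT-GC,
#' GT-AT) on the reverse orientation; the first match wins.
#'
#' @param donor_fwd,acceptor_fwd forward-genomic-strand 2-mers at the intron
#'   5' and 3' ends (vectorized)
#' @return data.frame with columns `strand` (`"+"`, `"-"`, `"*"` unknown)
#'   and `motif_class` (`GT-AG`, `GC-AG`, `AT-AC`, `other`)
#' @export
infer_strand <- function(donor_fwd, acceptor_fwd) {
  keymap <- c("GT AG" = "+ GT-AG", "GC AG" = "+ GC-AG", "AT AC" = "+ AT-AC",
              "CT AC" = "- GT-AG", "CT GC" = "- GC-AG", "GT AT" = "- AT-AC")
  hit <- keymap[paste(donor_fwd, acceptor_fwd)]
  hit[is.na(hit)] <- "* other"
  parts <- strsplit(unname(hit), " ", fixed = TRUE)
  data.frame(strand = vapply(parts, `[`, "", 1L),
             motif_class = vapply(parts, `[`, "", 2L))
}

#' Gene assignment for junctions
#'
#' Assigns each junction end to the gene whose span overlaps it on a
#' compatible strand (ties broken toward the gene with the greatest exonic
#' overlap within `min_overhang` bp of the site; remaining ties are treated
#' as no assignment) and requires both ends to agree: disagreement yields
#' `"ambiguous"`, an end with no gene yields `"unassigned"`.
#'
#' @param juncs data.frame with `chrom`, `start`, `end`, `strand`
#'   (junction strand; `"*"` is compatible with both)
#' @param ann an [annotation]
#' @param min_overhang tie-break window (bp)
#' @return data.frame with columns `gene_donor`, `gene_acceptor`,
#'   `gene_assignment`
#' @export
assign_gene <- function(juncs, ann, min_overhang = 8L) {
  n <- nrow(juncs)
  genes <- ann$genes
  gene_gr <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$start, genes$end))
  ex <- ann$exons
  ex_gr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end))

  end_gene <- function(pos) {
    pts <- GenomicRanges::GRanges(juncs$chrom, IRanges::IRanges(pos, pos))
    hits <- GenomicRanges::findOverlaps(pts, gene_gr)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    compat <- juncs$strand[qh] == "*" | is.na(juncs$strand[qh]) |
      juncs$strand[qh] == genes$strand[sh]
    qh <- qh[compat]; sh <- sh[compat]
    out <- rep(NA_character_, n)
    if (length(qh) == 0L) return(out)
    multi <- unique(qh[duplicated(qh)])
    single <- setdiff(unique(qh), multi)
    out[single] <- genes$gene_id[sh[match(single, qh)]]
    for (q in multi) {
      cand <- sh[qh == q]
      win <- GenomicRanges::GRanges(juncs$chrom[q],
                                    IRanges::IRanges(max(1L, pos[q] - min_overhang),
                                                     pos[q] + min_overhang))
      ov <- vapply(cand, function(g) {
        exi <- ex_gr[ex$gene_id == genes$gene_id[g]]
        sum(IRanges::width(GenomicRanges::intersect(
          GenomicRanges::reduce(exi), win)))
      }, numeric(1))
      best <- cand[ov == max(ov)]
      if (length(best) == 1L) out[q] <- genes$gene_id[best]
    }
    out
  }
  gd <- end_gene(juncs$start)
  ga <- end_gene(juncs$end)
  assignment <- ifelse(is.na(gd) | is.na(ga), "unassigned",
                       ifelse(gd == ga, gd, "ambiguous"))
  data.frame(gene_donor = gd, gene_acceptor = ga, gene_assignment = assignment)
}

#' Intron read-through counts at junction boundaries
#'
#' Counts ungapped read alignments spanning each exon/intron boundary with
#' at least `min_overhang` bp on both sides of the boundary — evidence of
#' intron retention. The same overhang is applied as in junction calling.
#'
#' @param aln `GAlignments` or SAM/BAM path
#' @param juncs data.frame with `chrom`, `start`, `end` (intron intervals)
#' @param min_overhang boundary overhang in bp
#' @return data.frame with columns `rt_left`, `rt_right`
#' @export
intron_readthrough <- function(aln, juncs, min_overhang = 8L) {
  if (is.character(aln)) aln <- read_alignments(aln)
  o <- as.integer(min_overhang)
  ungapped <- aln[GenomicAlignments::njunc(aln) == 0L]
  cov_gr <- GenomicRanges::granges(ungapped, use.mcols = FALSE)
  win_l <- GenomicRanges::GRanges(juncs$chrom,
                                  IRanges::IRanges(juncs$start - o, juncs$start + o - 1L))
  win_r <- GenomicRanges::GRanges(juncs$chrom,
                                  IRanges::IRanges(juncs$end - o + 1L, juncs$end + o))
  data.frame(
    rt_left = GenomicRanges::countOverlaps(win_l, cov_gr, type = "within"),
    rt_right = GenomicRanges::countOverlaps(win_r, cov_gr, type = "within"))
}

#' Junction coverage with alignment diagnostics
#'
#' Streams spliced alignments and produces the per-junction table at the
#' heart of the quantification step: spanning-read coverage, number of
#' distinct alignment offsets, offset Shannon entropy, MMES, donor/acceptor
#' motifs with inferred strand, annotation status, shoulder repeat
#' identities, gene assignment and intron read-through counts. With
#' `include_annotated = TRUE`, annotated junctions that received no spanning
#' read are retained as zero-coverage rows (their read-through counts are
#' still quantified), so retained-intron events remain quantifiable.
#'
#' @param aln `GAlignments` or SAM/BAM path
#' @param ann an [annotation]
#' @param genome genome `DNAStringSet`
#' @param min_overhang anchor/boundary overhang in bp (default 8)
#' @param min_intron minimum intron length (default 42)
#' @param include_annotated keep undetected annotated junctions as
#'   zero-coverage rows?
#' @return data.frame, one row per junction (see Details in the vignette)
#' @export
junction_stats <- function(aln, ann, genome, min_overhang = 8L,
                           min_intron = 42L, include_annotated = TRUE) {
  if (is.character(aln)) aln <- read_alignments(aln)
  obs <- extract_spliced_alignments(aln, min_overhang, min_intron)
  od <- data.table::as.data.table(obs)
  tab <- od[, list(coverage = .N,
                   n_offsets = length(unique(left)),
                   entropy = offset_entropy(left),
                   mmes = mmes(left, right)),
            by = c("chrom", "start", "end")]
  tab <- as.data.frame(tab)
  if (include_annotated && nrow(ann$junctions)) {
    kt <- junction_key(tab$chrom, tab$start, tab$end)
    miss <- ann$junctions[!ann$junctions$key %in% kt,
                          c("chrom", "start", "end"), drop = FALSE]
    if (nrow(miss)) {
      miss$coverage <- 0L; miss$n_offsets <- 0L
      miss$entropy <- NA_real_; miss$mmes <- NA_integer_
      tab <- rbind(tab, miss)
    }
  }
  if (nrow(tab) == 0L)
    return(cbind(tab, data.frame(key = character(0))))
  tab <- tab[order(tab$chrom, tab$start, tab$end), , drop = FALSE]
  rownames(tab) <- NULL
  tab$key <- junction_key(tab$chrom, tab$start, tab$end)

  m <- junction_motifs(genome, tab$chrom, tab$start, tab$end,
                       rep("+", nrow(tab)))
  inf <- infer_strand(m$donor_fwd, m$acceptor_fwd)
  tab$inferred_strand <- inf$strand
  tab$motif_class <- inf$motif_class
  ak <- match(tab$key, ann$junctions$key)
  tab$annotated <- !is.na(ak)
  tab$strand <- ifelse(tab$annotated, ann$junctions$strand[ak], inf$strand)
  mo <- junction_motifs(genome, tab$chrom, tab$start, tab$end, tab$strand)
  tab$donor <- mo$donor
  tab$acceptor <- mo$acceptor
  rid <- repeat_identity(genome, tab$chrom, tab$start, tab$end)
  tab$repeat_id_donor <- rid$donor_side
  tab$repeat_id_acceptor <- rid$acceptor_side
  tab <- cbind(tab, assign_gene(tab, ann, min_overhang))
  tab <- cbind(tab, intron_readthrough(aln, tab, min_overhang))
  tab
}

#' Apply junction filters
#'
#' Sets per-junction flags against the diagnosed error classes and a `pass`
#' column for the chosen filtering mode. Flags (non-destructive; coverage
#' values are never altered):
#' \describe{
#'   \item{minor_unannotated}{minor or non-canonical motif class (GC-AG,
#'     AT-AC, other) and not annotated}
#'   \item{ambiguous_gene}{gene assignment `"ambiguous"` or `"unassigned"`
#'     (wrong-strand calls and paralog joins)}
#'   \item{repeat_like}{either shoulder repeat identity above
#'     `max_repeat_identity`}
#'   \item{low_entropy}{offset entropy below `min_entropy` (quantitative
#'     mode only)}
#' }
#' Mode `"qualitative"` uses the first three flags, `"quantitative"` the
#' entropy cutoff alone, `"both"` all four, `"none"` none.
#'
#' @param stats a [junction_stats()] table
#' @param mode `"qualitative"`, `"quantitative"`, `"both"` or `"none"`
#' @param min_entropy entropy threshold in bits (default 2)
#' @param max_repeat_identity repeat identity threshold in percent
#'   (default 80; junctions strictly above are flagged)
#' @return `stats` with added logical columns `minor_unannotated`,
#'   `ambiguous_gene`, `repeat_like`, `low_entropy`, `pass`
#' @export
apply_filters <- function(stats, mode = c("qualitative", "quantitative",
                                          "both", "none"),
                          min_entropy = 2, max_repeat_identity = 80) {
  mode <- match.arg(mode)
  s <- stats
  s$minor_unannotated <- s$motif_class %in% c("GC-AG", "AT-AC", "other") & !s$annotated
  s$ambiguous_gene <- s$gene_assignment %in% c("ambiguous", "unassigned")
  rep_max <- pmax(s$repeat_id_donor, s$repeat_id_acceptor, na.rm = TRUE)
  s$repeat_like <- !is.na(rep_max) & rep_max > max_repeat_identity
  s$low_entropy <- !is.na(s$entropy) & s$entropy < min_entropy
  qual <- !(s$minor_unannotated | s$ambiguous_gene | s$repeat_like)
  quant <- !s$low_entropy
  s$pass <- switch(mode,
                   qualitative = qual,
                   quantitative = quant,
                   both = qual & quant,
                   none = rep(TRUE, nrow(s)))
  s
}

#' Evaluate detections against simulation truth
#'
#' Classifies each detected junction absent from the truth into the
#' diagnosed false-positive error classes, and splits false negatives into
#' alignment failures (a spanning read was generated but the junction was
#' not detected) versus sampling (no spanning read was generated).
#' Classification precedence: `incorrect_strand` (within `shift_window` of
#' a truth junction, opposite inferred strand), `minor_form` (unannotated
#' minor motif near a truth junction, strand agreeing), `paralog_join`
#' (ends assigned to two different genes), `repeat_induced` (repeat-like
#' shoulders), `shifted` (same strand, either end within `shift_window` of
#' a truth junction), else `unidentified`.
#'
#' @param stats a [junction_stats()] table (optionally after
#'   [apply_filters()]; rows with `coverage > 0` count as detections)
#' @param truth a [truth_junction_coverage()] table
#' @param ann an [annotation]
#' @param max_repeat_identity repeat threshold used for the
#'   `repeat_induced` class
#' @param shift_window matching window in bp (default 50)
#' @return list with data.frames `fp` (detected junction keys with `class`),
#'   `fn` (missed truth/annotated junction keys with `class`), and `summary`
#'   (per-class counts)
#' @export
evaluate_vs_truth <- function(stats, truth, ann, max_repeat_identity = 80,
                              shift_window = 50L) {
  if (is.null(truth) || nrow(truth) == 0L) stop_format("truth table required")
  det <- stats[stats$coverage > 0L, , drop = FALSE]
  fp <- det[!det$key %in% truth$key, , drop = FALSE]

  near_truth <- function(chrom, pos1, pos2) {
    # index of a truth junction with either end within shift_window
    vapply(seq_along(chrom), function(i) {
      cand <- which(truth$chrom == chrom[i] &
                    (abs(truth$start - pos1[i]) <= shift_window |
                     abs(truth$end - pos2[i]) <= shift_window))
      if (length(cand)) cand[1L] else NA_integer_
    }, integer(1))
  }
  cls <- character(nrow(fp))
  if (nrow(fp)) {
    ti <- near_truth(fp$chrom, fp$start, fp$end)
    truth_strand <- ann$junctions$strand[match(truth$key[ti], ann$junctions$key)]
    rep_max <- pmax(fp$repeat_id_donor, fp$repeat_id_acceptor, na.rm = TRUE)
    wrong_strand <- !is.na(ti) & !is.na(truth_strand) &
      fp$inferred_strand != "*" & fp$inferred_strand != truth_strand
    minor <- !is.na(ti) & !fp$annotated &
      fp$motif_class %in% c("GC-AG", "AT-AC") &
      (is.na(truth_strand) | fp$inferred_strand == truth_strand)
    paralog <- !is.na(fp$gene_donor) & !is.na(fp$gene_acceptor) &
      fp$gene_donor != fp$gene_acceptor
    repeat_ind <- !is.na(rep_max) & rep_max > max_repeat_identity
    shifted <- !is.na(ti) & !is.na(truth_strand) &
      fp$inferred_strand == truth_strand
    cls <- rep("unidentified", nrow(fp))
    cls[shifted] <- "shifted"
    cls[repeat_ind] <- "repeat_induced"
    cls[paralog] <- "paralog_join"
    cls[minor] <- "minor_form"
    cls[wrong_strand] <- "incorrect_strand"
  }
  fp_out <- data.frame(key = fp$key, class = cls, stringsAsFactors = FALSE)

  det_keys <- det$key
  miss <- ann$junctions[!ann$junctions$key %in% det_keys, , drop = FALSE]
  fn_class <- ifelse(miss$key %in% truth$key, "alignment", "sampling")
  fn_out <- data.frame(key = miss$key, class = fn_class, stringsAsFactors = FALSE)

  count_classes <- function(kind, classes) {
    tb <- table(classes)
    data.frame(kind = rep(kind, length(tb)), class = names(tb),
               n = as.integer(tb), stringsAsFactors = FALSE)
  }
  list(fp = fp_out, fn = fn_out,
       summary = rbind(count_classes("fp", fp_out$class),
                       count_classes("fn", fn_out$class)))
}
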