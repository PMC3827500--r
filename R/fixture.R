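#' Toy fixture configuration
#'
#' Describes a synthetic genome + annotation used to exercise the pipeline
#' end-to-end: a set of genes laid out on one chromosome, a configurable mix
#' of two-isoform alternative-splicing events, optional planted paralog pairs
#' and optional planted "decoy" junction sites that emulate the diagnosed
#' aligner error classes (wrong strand, minor motif, paralog joining,
#' repeat-induced gaps).
#'
#' `event_mix` gives, per event type, the fraction of genes that carry one
#' such two-isoform event; the remainder are constitutively spliced
#' single-isoform genes. Event types: `exonskip`, `altdonor`, `altacceptor`,
#' `retintron`, `mutexcl`, `AltFE`, `AltLE` (donor/acceptor are in the
#' transcript sense, i.e. strand-aware).
#'
#' @param n_genes number of genes
#' @param exons_per_gene integer range `c(min, max)` of exons per gene
#'   (raised internally where an event type needs more exons)
#' @param exon_len,intron_len,intergenic bp ranges `c(min, max)`
#' @param event_mix named numeric vector of per-type gene fractions, summing
#'   to at most 1
#' @param paralog_pair plant a duplicated copy of one gene proximally?
#' @param decoys plant decoy error-class junction sites (implies
#'   `paralog_pair` for the paralog-join decoy)?
#' @param chrom chromosome name
#' @param min_intron minimum intron length (bp)
#' @return a list of class `"fixture_config"`
#' @export
fixture_config <- function(n_genes = 20L,
                           exons_per_gene = c(3L, 6L),
                           exon_len = c(90L, 240L),
                           intron_len = c(70L, 220L),
                           intergenic = c(300L, 700L),
                           event_mix = c(exonskip = 0.20, altdonor = 0.10,
                                         altacceptor = 0.10, retintron = 0.10,
                                         mutexcl = 0.10, AltFE = 0.10,
                                         AltLE = 0.05),
                           paralog_pair = FALSE,
                           decoys = FALSE,
                           chrom = "chrS",
                           min_intron = 42L) {
  types <- c("exonskip", "altdonor", "altacceptor", "retintron", "mutexcl",
             "AltFE", "AltLE")
  if (length(event_mix)) {
    if (is.null(names(event_mix)) || !all(names(event_mix) %in% types))
      stop_format("event_mix names must be among: %s", paste(types, collapse = ", "))
    if (any(event_mix < 0) || sum(event_mix) > 1 + 1e-9)
      stop_format("event_mix fractions must be >= 0 and sum to <= 1")
  }
  if (n_genes < 1L) stop_format("n_genes must be >= 1")
  if (intron_len[1L] < min_intron)
    stop_format("infeasible config: intron_len minimum %d < min_intron %d",
                intron_len[1L], min_intron)
  if (decoys && intron_len[1L] < min_intron + 14L)
    stop_format("infeasible config: decoys need intron_len minimum >= %d",
                min_intron + 14L)
  if (exon_len[1L] < 60L)
    stop_format("infeasible config: exon_len minimum must be >= 60 bp")
  structure(list(n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_len = as.integer(exon_len),
                 intron_len = as.integer(intron_len),
                 intergenic = as.integer(intergenic),
                 event_mix = event_mix,
                 paralog_pair = isTRUE(paralog_pair) || isTRUE(decoys),
                 decoys = isTRUE(decoys),
                 chrom = chrom,
                 min_intron = as.integer(min_intron)),
            class = "fixture_config")
}

rand_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# sample one element of x (safe for length-1 x, unlike sample())
sample1 <- function(x) x[sample.int(length(x), 1L)]

# minimum exon count an event type needs
type_min_exons <- c(none = 1L, exonskip = 3L, altdonor = 2L, altacceptor = 2L,
                    retintron = 2L, mutexcl = 4L, AltFE = 2L, AltLE = 2L)

#' Generate a deterministic toy genome + annotation fixture
#'
#' Lays out genes with randomized exon/intron structure, derives one or two
#' transcript isoforms per gene according to `config$event_mix`, fills the
#' chromosome with random sequence, plants strand-oriented GT-AG motifs at
#' every annotated intron, then (optionally) plants a proximal paralog copy
#' of one gene and decoy junction sites for the four diagnosable error
#' classes. Exon/intron shoulder windows of true junctions are actively
#' de-similarized so that no true junction trips the repeat-identity filter.
#' Output is byte-identical for a fixed `(config, seed)`.
#'
#' @param config a [fixture_config()]
#' @param seed integer RNG seed
#' @return a list of class `"toy_fixture"` with elements `genome`
#'   (`DNAStringSet`), `annotation` ([annotation]), and `manifest` — a list
#'   of data.frames `genes`, `events` (planted event per gene), `paralogs`
#'   (`gene_src`, `gene_copy`, `offset`) and `decoys` (planted error sites
#'   with `kind` in `wrong_strand`, `minor_form`, `repeat_induced`,
#'   `paralog_join`)
#' @export
make_toy_fixture <- function(config = fixture_config(), seed = 1L) {
  stopifnot(inherits(config, "fixture_config"))
  with_seed(seed, build_fixture(config, seed))
}

build_fixture <- function(cfg, seed) {
  n <- cfg$n_genes
  types <- assign_event_types(n, cfg$event_mix)
  strands <- sample(c("+", "-"), n, replace = TRUE)

  cursor <- 1001L
  exon_rows <- list()
  gene_rows <- list()
  event_rows <- list()
  for (i in seq_len(n)) {
    gid <- sprintf("g%03d", i)
    gap <- sample1(seq(cfg$intergenic[1L], cfg$intergenic[2L]))
    cursor <- cursor + gap
    g <- build_gene(gid, cfg$chrom, strands[i], types[i], cursor, cfg)
    cursor <- max(g$exons$end) + 1L
    exon_rows[[i]] <- g$exons
    gene_rows[[i]] <- data.frame(gene_id = gid, chrom = cfg$chrom,
                                 strand = strands[i], start = min(g$exons$start),
                                 end = max(g$exons$end),
                                 type = types[i], stringsAsFactors = FALSE)
    if (types[i] != "none")
      event_rows[[i]] <- data.frame(gene_id = gid, type = types[i],
                                    tx1 = paste0(gid, ".1"),
                                    tx2 = paste0(gid, ".2"),
                                    stringsAsFactors = FALSE)
  }
  exons <- do.call(rbind, exon_rows)
  genes <- do.call(rbind, gene_rows)
  events <- if (length(event_rows)) do.call(rbind, event_rows[!vapply(event_rows, is.null, TRUE)])
            else NULL
  if (is.null(events))
    events <- data.frame(gene_id = character(0), type = character(0),
                         tx1 = character(0), tx2 = character(0))

  # paralog: duplicate the first multi-exon '+' gene proximally
  paralogs <- data.frame(gene_src = character(0), gene_copy = character(0),
                         offset = integer(0))
  if (cfg$paralog_pair) {
    cand <- genes$gene_id[genes$strand == "+" &
                          vapply(genes$gene_id, function(g)
                            sum(exons$gene_id == g &
                                exons$transcript_id == paste0(g, ".1")) >= 2L, TRUE)]
    if (length(cand) == 0L) stop_format("infeasible config: no '+' multi-exon gene to duplicate")
    src <- cand[1L]
    src_ex <- exons[exons$gene_id == src & exons$transcript_id == paste0(src, ".1"), ]
    offset <- cursor + sample1(200:400) - min(src_ex$start)
    par_id <- paste0(src, "p")
    par_ex <- src_ex
    par_ex$start <- par_ex$start + offset
    par_ex$end <- par_ex$end + offset
    par_ex$gene_id <- par_id
    par_ex$transcript_id <- paste0(par_id, ".1")
    exons <- rbind(exons, par_ex)
    genes <- rbind(genes, data.frame(gene_id = par_id, chrom = cfg$chrom,
                                     strand = "+", start = min(par_ex$start),
                                     end = max(par_ex$end), type = "paralog"))
    paralogs <- data.frame(gene_src = src, gene_copy = par_id, offset = offset)
    cursor <- max(par_ex$end) + 1L
  }

  glen <- cursor + 1500L
  gseq <- rand_bases(glen)
  protected <- logical(glen)

  ann <- annotation(exons, min_intron = cfg$min_intron)

  # plant strand-oriented GT..AG motifs at every annotated intron
  jt <- ann$junctions
  for (r in seq_len(nrow(jt))) {
    s <- jt$start[r]; e <- jt$end[r]
    if (jt$strand[r] == "+") {
      gseq[s:(s + 1L)] <- c("G", "T"); gseq[(e - 1L):e] <- c("A", "G")
    } else {
      gseq[s:(s + 1L)] <- c("C", "T"); gseq[(e - 1L):e] <- c("A", "C")
    }
    protected[c(s, s + 1L, e - 1L, e)] <- TRUE
  }

  # paralog copy: duplicate the source gene body so the two are true paralogs
  if (nrow(paralogs)) {
    cp_rng <- genes[genes$gene_id == paralogs$gene_copy, ]
    gseq[cp_rng$start:cp_rng$end] <-
      gseq[(cp_rng$start - paralogs$offset):(cp_rng$end - paralogs$offset)]
  }

  # decoy error-class junction sites inside real introns
  decoys <- data.frame(kind = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       host_gene = character(0))
  if (cfg$decoys) {
    host_introns <- function(gene_ids, n_needed) {
      cand <- jt[jt$gene_id %in% gene_ids &
                 (jt$end - jt$start + 1L) >= cfg$min_intron + 14L, ]
      if (nrow(cand) < n_needed) stop_format("infeasible config: too few decoy host introns")
      cand
    }
    plus_genes <- genes$gene_id[genes$strand == "+" & genes$type != "paralog"]
    hosts <- host_introns(plus_genes, 3L)
    hosts <- hosts[!duplicated(hosts$gene_id), ]
    if (nrow(hosts) < 3L) stop_format("infeasible config: need 3 distinct '+' host genes for decoys")

    plant_decoy <- function(kind, host, d5, d3) {
      a <- host$start; b <- host$end
      ds <- a + 6L; de <- b - 6L
      gseq[ds:(ds + 1L)] <<- d5; gseq[(de - 1L):de] <<- d3
      protected[c(ds, ds + 1L, de - 1L, de)] <<- TRUE
      data.frame(kind = kind, chrom = cfg$chrom, start = ds, end = de,
                 host_gene = host$gene_id)
    }
    d1 <- plant_decoy("wrong_strand", hosts[1L, ], c("C", "T"), c("A", "C"))
    d2 <- plant_decoy("minor_form", hosts[2L, ], c("G", "C"), c("A", "G"))
    d3 <- plant_decoy("repeat_induced", hosts[3L, ], c("G", "T"), c("A", "G"))
    # make the repeat decoy's upstream shoulder windows identical:
    # 10 bp upstream of its donor == 10 bp upstream of its acceptor
    w1 <- (d3$start - 10L):(d3$start - 1L)
    w2 <- (d3$end - 9L):d3$end
    for (k in 1:10) {
      if (!protected[w2[k]]) gseq[w2[k]] <- gseq[w1[k]]
      else if (!protected[w1[k]]) gseq[w1[k]] <- gseq[w2[k]]
    }
    protected[c(w1, w2)] <- TRUE
    d4 <- NULL
    if (nrow(paralogs)) {
      src_j <- jt[jt$gene_id == paralogs$gene_src, ]
      sj <- src_j[nrow(src_j), ]            # last intron of the source gene
      ds <- sj$start + 6L
      de <- sj$end + paralogs$offset - 6L   # acceptor inside the paralog copy
      gseq[ds:(ds + 1L)] <- c("G", "T"); gseq[(de - 1L):de] <- c("A", "G")
      protected[c(ds, ds + 1L, de - 1L, de)] <- TRUE
      d4 <- data.frame(kind = "paralog_join", chrom = cfg$chrom,
                       start = ds, end = de, host_gene = paralogs$gene_src)
    }
    decoys <- rbind(d1, d2, d3, d4)
  }

  # de-similarize shoulder windows of every true junction so that no true
  # junction exceeds the repeat-identity threshold
  gseq <- desimilarize_junction_windows(gseq, protected, jt)

  genome <- Biostrings::DNAStringSet(setNames(paste(gseq, collapse = ""), cfg$chrom))
  structure(list(genome = genome, annotation = ann,
                 manifest = list(genes = genes, events = events,
                                 paralogs = paralogs, decoys = decoys),
                 config = cfg, seed = seed),
            class = "toy_fixture")
}

#' @export
print.toy_fixture <- function(x, ...) {
  cat(sprintf("toy_fixture: %d gene(s) on %s (%d bp), %d planted event(s), %d decoy site(s)\n",
              nrow(x$manifest$genes), names(x$genome)[1L],
              Biostrings::width(x$genome)[1L],
              nrow(x$manifest$events), nrow(x$manifest$decoys)))
  invisible(x)
}

assign_event_types <- function(n, mix) {
  counts <- if (length(mix)) round(mix * n) else integer(0)
  types <- rep("none", n)
  pos <- 1L
  for (t in names(counts)) {
    k <- min(counts[[t]], n - pos + 1L)
    if (k > 0L) {
      types[pos:(pos + k - 1L)] <- t
      pos <- pos + k
    }
  }
  sample(types)
}

# build exon tables for the (1 or 2) isoforms of one gene
build_gene <- function(gid, chrom, strand, type, cursor, cfg) {
  k <- sample1(seq(max(type_min_exons[[type]], cfg$exons_per_gene[1L]),
                   max(type_min_exons[[type]], cfg$exons_per_gene[2L])))
  elen <- sample(seq(cfg$exon_len[1L], cfg$exon_len[2L]), k, replace = TRUE)
  ilen <- if (k > 1L) sample(seq(cfg$intron_len[1L], cfg$intron_len[2L]),
                             k - 1L, replace = TRUE) else integer(0)
  starts <- integer(k); ends <- integer(k)
  pos <- cursor
  for (j in seq_len(k)) {
    starts[j] <- pos; ends[j] <- pos + elen[j] - 1L
    pos <- ends[j] + (if (j < k) ilen[j] else 0L) + 1L
  }
  tx <- function(suffix, s, e) data.frame(
    chrom = chrom, start = s, end = e, strand = strand,
    gene_id = gid, transcript_id = paste0(gid, ".", suffix),
    stringsAsFactors = FALSE)

  delta <- 25L
  if (type == "none") {
    ex <- tx(1L, starts, ends)
  } else if (type == "exonskip") {
    j <- sample1(2:(k - 1L))
    ex <- rbind(tx(1L, starts, ends), tx(2L, starts[-j], ends[-j]))
  } else if (type == "altdonor" || type == "altacceptor") {
    i <- if (k >= 3L) sample1(2:(k - 1L)) else 1L
    # intron i lies between exons i and i+1; move its transcript-5' edge for
    # altdonor, its transcript-3' edge for altacceptor (strand-aware)
    move_left_edge <- (type == "altdonor") == (strand == "+")
    s2 <- starts; e2 <- ends
    if (move_left_edge) e2[i] <- e2[i] - delta else s2[i + 1L] <- s2[i + 1L] + delta
    ex <- rbind(tx(1L, starts, ends), tx(2L, s2, e2))
  } else if (type == "retintron") {
    i <- if (k >= 3L) sample1(2:(k - 1L)) else 1L
    s2 <- starts[-(i + 1L)]; e2 <- ends[-i]
    ex <- rbind(tx(1L, starts, ends), tx(2L, s2, e2))
  } else if (type == "mutexcl") {
    j <- sample1(2:(k - 2L))
    ex <- rbind(tx(1L, starts[-(j + 1L)], ends[-(j + 1L)]),
                tx(2L, starts[-j], ends[-j]))
  } else if (type == "AltFE" || type == "AltLE") {
    # an alternative terminal exon placed beyond the shared exons, at the
    # transcript 5' end (AltFE) or 3' end (AltLE)
    at_left <- (type == "AltFE") == (strand == "+")
    alt_len <- sample1(seq(cfg$exon_len[1L], cfg$exon_len[2L]))
    gap <- sample1(seq(cfg$intron_len[1L], cfg$intron_len[2L]))
    if (at_left) {
      shift <- alt_len + gap
      starts <- starts + shift; ends <- ends + shift
      alt_s <- cursor; alt_e <- cursor + alt_len - 1L
      ex <- rbind(tx(1L, starts, ends),
                  tx(2L, c(alt_s, starts[-1L]), c(alt_e, ends[-1L])))
    } else {
      alt_s <- ends[k] + gap + 1L; alt_e <- alt_s + alt_len - 1L
      ex <- rbind(tx(1L, starts, ends),
                  tx(2L, c(starts[-k], alt_s), c(ends[-k], alt_e)))
    }
  } else stop_format("unknown event type: %s", type)
  list(exons = ex)
}

# force the four shoulder windows of each true junction apart so that
# Levenshtein identity stays well below the 80% repeat filter threshold
desimilarize_junction_windows <- function(gseq, protected, jt) {
  window_pairs <- function(s, e) list(
    up = list((s - 10L):(s - 1L), (e - 9L):e),      # upstream of donor vs acceptor
    down = list(s:(s + 9L), (e + 1L):(e + 10L)))    # downstream of donor vs acceptor
  other <- c(A = "C", C = "G", G = "T", T = "A")
  for (r in seq_len(nrow(jt))) {
    for (pair in window_pairs(jt$start[r], jt$end[r])) {
      w1 <- pair[[1L]]; w2 <- pair[[2L]]
      if (any(w1 < 1L) || any(w2 > length(gseq))) next
      for (attempt in 1:10) {
        id <- 100 * (10L - adist(paste(gseq[w1], collapse = ""),
                                 paste(gseq[w2], collapse = ""))[1L, 1L]) / 10L
        if (id <= 50) break
        for (k in 1:10) {
          if (gseq[w1[k]] == gseq[w2[k]]) {
            if (!protected[w2[k]]) gseq[w2[k]] <- other[[gseq[w1[k]]]]
            else if (!protected[w1[k]]) gseq[w1[k]] <- other[[gseq[w2[k]]]]
          }
        }
        # randomize free bases if positional mismatching was not enough
        free <- c(w1[!protected[w1]], w2[!protected[w2]])
        if (attempt > 1L && length(free)) gseq[free] <- rand_bases(length(free))
      }
    }
  }
  gseq
}

#' Synthetic spliced alignments over planted decoy junction sites
#'
#' Builds perfect gapped alignment records (as rows for [write_sam()])
#' supporting each planted decoy junction of a fixture, with a spread of
#' distinct alignment offsets. These emulate the false-positive spliced
#' alignments an aligner would produce at the planted error sites, and are
#' meant to be mixed with true reads when testing the junction filters.
#'
#' @param fixture a [make_toy_fixture()] result with planted decoys
#' @param n_per reads per decoy junction
#' @param read_len read length (bp)
#' @param seed RNG seed
#' @return data.frame of alignment fields (`qname`, `flag`, `chrom`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual`)
#' @export
decoy_alignments <- function(fixture, n_per = 12L, read_len = 76L, seed = 1L) {
  dk <- fixture$manifest$decoys
  if (nrow(dk) == 0L) stop_format("fixture has no planted decoys")
  genome <- fixture$genome
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(dk)), function(i) {
      ds <- dk$start[i]; de <- dk$end[i]; ch <- dk$chrom[i]
      lefts <- sample(10:(read_len - 10L), n_per, replace = TRUE)
      lefts[1:4] <- c(15L, 25L, 35L, 45L)   # guarantee >= 4 distinct offsets
      data.frame(
        qname = sprintf("decoy|%s|%d|%d", dk$kind[i], i, seq_len(n_per)),
        flag = 0L, chrom = ch, pos = ds - lefts, mapq = 50L,
        cigar = sprintf("%dM%dN%dM", lefts, de - ds + 1L, read_len - lefts),
        seq = NA_character_,
        qual = strrep("I", read_len),
        stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    # fill sequences: left anchor (ends at ds-1) spliced to right anchor (from de+1)
    lefts <- as.integer(sub("M.*$", "", out$cigar))
    out$seq <- vapply(seq_len(nrow(out)), function(i) {
      ds <- out$pos[i] + lefts[i]
      de <- ds + as.integer(sub("^.*M(\\d+)N.*$", "\\1", out$cigar[i])) - 1L
      paste0(genome_subseq(genome, out$chrom[i], out$pos[i], ds - 1L),
             genome_subseq(genome, out$chrom[i], de + 1L,
                           de + read_len - lefts[i]))
    }, character(1))
    out
  })
}
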