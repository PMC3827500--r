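#' Simulation configuration
#'
#' Exactly one of `coverage`, `rpk` or `table` sets transcript abundances:
#' `coverage` X gives each transcript `round(X * length / (2 * read_length))`
#' read pairs (X-fold base coverage of the spliced template by both mates);
#' `rpk` gives `round(rpk * length_kb)` pairs; `table` is a data.frame with
#' columns `transcript_id` and `rpk` for custom per-transcript abundances.
#'
#' @param coverage per-transcript fold coverage (X)
#' @param rpk reads per kilobase of spliced transcript
#' @param table data.frame (`transcript_id`, `rpk`)
#' @param read_length read length in bp (default 76)
#' @param frag_mean,frag_sd fragment length normal distribution (bp; defaults
#'   200 and 20)
#' @param intron_retention fraction of pairs drawn from the unspliced
#'   (introns-included) template of the parent gene (default 0.20)
#' @param error_model an `"error_model"`, a built-in model name
#'   (`"uniform"`, `"ramp"`), a model file path, or `NULL` for error-free
#'   reads
#' @param seed integer seed; all stochastic choices in a run flow from it
#' @return a list of class `"sim_config"`
#' @export
sim_config <- function(coverage = NULL, rpk = NULL, table = NULL,
                       read_length = 76L, frag_mean = 200, frag_sd = 20,
                       intron_retention = 0.20, error_model = "uniform",
                       seed = 1L) {
  modes <- c(!is.null(coverage), !is.null(rpk), !is.null(table))
  if (sum(modes) != 1L)
    stop_format("exactly one of coverage, rpk, table must be given")
  if (!is.null(coverage) && coverage <= 0) stop_format("coverage must be > 0")
  if (!is.null(rpk) && rpk <= 0) stop_format("rpk must be > 0")
  if (frag_mean < read_length)
    stop_format("frag_mean (%g) must be >= read_length (%d)", frag_mean, read_length)
  if (intron_retention < 0 || intron_retention > 1)
    stop_format("intron_retention must lie in [0,1]")
  structure(list(coverage = coverage, rpk = rpk, table = table,
                 read_length = as.integer(read_length),
                 frag_mean = frag_mean, frag_sd = frag_sd,
                 intron_retention = intron_retention,
                 error_model = error_model, seed = as.integer(seed)),
            class = "sim_config")
}

resolve_error_model <- function(em, read_length) {
  if (is.null(em)) return(NULL)
  if (inherits(em, "error_model")) return(em)
  if (is.character(em) && length(em) == 1L) {
    if (file.exists(em)) return(read_error_model(em))
    return(builtin_error_model(em, read_length))
  }
  stop_format("error_model must be a model object, built-in name or file path")
}

#' Simulate paired-end RNA-Seq reads with truth reporting
#'
#' Draws fragments from each transcript's spliced template (or, for an
#' `intron_retention` fraction of pairs, the unspliced introns-included
#' template), extracts 2 x `read_length` mate sequences (mate 2 reverse
#' complement of the fragment 3' end), injects sequencing errors from the
#' configured error model, and records the genomic coordinates of origin of
#' every read both in its identifier and in a perfect-alignment truth SAM.
#' Fragment lengths are normal(`frag_mean`, `frag_sd`), redrawn up to 100
#' times when they exceed the template (the transcript is skipped, with a
#' warning, if a valid draw cannot be obtained); fragment start positions
#' are uniform. Transcripts shorter than `read_length` are skipped with a
#' warning. Runs are byte-reproducible for a fixed config.
#'
#' @param ann an [annotation]
#' @param genome genome `DNAStringSet`
#' @param cfg a [sim_config()]
#' @return an object of class `"sim_result"`: list with `pairs`
#'   (per-pair truth: id, transcript, template kind, fragment), `mates`
#'   (per-mate truth alignment fields incl. errored sequence), `blocks`
#'   (per-mate genomic alignment blocks), `transcript_counts`, and `config`
#' @export
simulate_reads <- function(ann, genome, cfg) {
  stopifnot(inherits(ann, "annotation"), inherits(cfg, "sim_config"))
  if (nrow(ann$transcripts) == 0L) stop_format("empty annotation")
  model <- resolve_error_model(cfg$error_model, cfg$read_length)
  with_seed(cfg$seed, simulate_reads_impl(ann, genome, cfg, model))
}

simulate_reads_impl <- function(ann, genome, cfg, model) {
  L <- cfg$read_length
  txs <- ann$transcripts
  if (!is.null(cfg$table)) {
    tb <- cfg$table
    stopifnot(all(c("transcript_id", "rpk") %in% names(tb)))
    txs <- txs[txs$transcript_id %in% tb$transcript_id, , drop = FALSE]
    txs$rpk <- tb$rpk[match(txs$transcript_id, tb$transcript_id)]
  }
  exdt <- data.table::as.data.table(ann$exons)
  data.table::setkey(exdt, transcript_id)

  pair_list <- list(); mate_list <- list(); block_list <- list()
  serial0 <- 0L
  for (ti in seq_len(nrow(txs))) {
    tx <- txs[ti, ]
    ex <- exdt[tx$transcript_id]
    splen <- tx$exonic_len
    if (splen < L) {
      warning(sprintf("transcript %s shorter than read length; skipped", tx$transcript_id))
      next
    }
    n_pairs <- if (!is.null(cfg$coverage)) round(cfg$coverage * splen / (2 * L))
               else if (!is.null(cfg$rpk)) round(cfg$rpk * splen / 1000)
               else round(tx$rpk * splen / 1000)
    if (n_pairs < 1L) next

    sim_tx <- simulate_one_transcript(tx, ex, genome, cfg, model, n_pairs, serial0)
    if (is.null(sim_tx)) next
    serial0 <- serial0 + n_pairs
    pair_list[[length(pair_list) + 1L]] <- sim_tx$pairs
    mate_list[[length(mate_list) + 1L]] <- sim_tx$mates
    block_list[[length(block_list) + 1L]] <- sim_tx$blocks
  }
  if (length(pair_list) == 0L) stop_format("no pairs simulated (all transcripts skipped?)")
  pairs <- data.table::rbindlist(pair_list)
  mates <- data.table::rbindlist(mate_list)
  blocks <- data.table::rbindlist(block_list)
  # global mate row index for block bookkeeping
  mates[, row := .I]
  blocks[, row := rep(mates$row, mates$nblocks)]

  tc <- pairs[, list(n_pairs = .N, n_unspliced = sum(kind == "U")),
              by = c("transcript_id", "gene_id")]
  structure(list(pairs = as.data.frame(pairs), mates = mates, blocks = blocks,
                 transcript_counts = as.data.frame(tc), config = cfg,
                 chrom_lengths = setNames(Biostrings::width(genome), names(genome))),
            class = "sim_result")
}

# one transcript: vectorized fragment draws, template extraction, block
# mapping and error injection for all its pairs
simulate_one_transcript <- function(tx, ex, genome, cfg, model, n_pairs, serial0) {
  L <- cfg$read_length
  minus <- tx$strand == "-"
  widths <- ex$end - ex$start + 1L
  cumw0 <- c(0L, cumsum(widths))
  splen <- sum(widths)
  gspan <- c(min(ex$start), max(ex$end))
  ulen <- gspan[2L] - gspan[1L] + 1L

  seq_spliced <- paste(vapply(seq_len(nrow(ex)), function(j)
    genome_subseq(genome, tx$chrom, ex$start[j], ex$end[j]), character(1)),
    collapse = "")
  seq_unspliced <- genome_subseq(genome, tx$chrom, gspan[1L], gspan[2L])
  if (minus) {
    seq_spliced <- revcomp_chr(seq_spliced)
    seq_unspliced <- revcomp_chr(seq_unspliced)
  }

  kind <- ifelse(runif(n_pairs) < cfg$intron_retention, "U", "S")
  tlen <- ifelse(kind == "U", ulen, splen)
  frag <- round(rnorm(n_pairs, cfg$frag_mean, cfg$frag_sd))
  bad <- frag > tlen | frag < L
  tries <- 0L
  while (any(bad) && tries < 100L) {
    frag[bad] <- round(rnorm(sum(bad), cfg$frag_mean, cfg$frag_sd))
    bad <- frag > tlen | frag < L
    tries <- tries + 1L
  }
  if (any(bad)) {
    warning(sprintf("transcript %s: no valid fragment draw in 100 tries; skipped",
                    tx$transcript_id))
    return(NULL)
  }
  tstart <- 1L + floor(runif(n_pairs) * (tlen - frag + 1))

  # mate template intervals (template orientation)
  a1 <- tstart; b1 <- tstart + L - 1L
  a2 <- tstart + frag - L; b2 <- tstart + frag - 1L
  template <- ifelse(kind == "U", seq_unspliced, seq_spliced)
  m1 <- substring(template, a1, b1)
  m2 <- revcomp_chr(substring(template, a2, b2))

  # per-mate genomic block layout, fully vectorized in long format
  sp <- kind == "S"
  mate_layout <- function(a, b) {
    if (minus) {
      ta <- a
      tl <- ifelse(sp, splen, ulen)
      a <- tl - b + 1L
      b <- tl - ta + 1L
    }
    i1 <- i2 <- rep(1L, n_pairs)
    gs <- as.integer(gspan[1L] + a - 1L)
    ge <- as.integer(gspan[1L] + b - 1L)
    if (any(sp)) {
      cumw <- cumw0[-1L]
      i1[sp] <- findInterval(a[sp] - 1L, cumw) + 1L
      i2[sp] <- findInterval(b[sp] - 1L, cumw) + 1L
      gs[sp] <- as.integer(ex$start[i1[sp]] + (a[sp] - 1L - cumw0[i1[sp]]))
      ge[sp] <- as.integer(ex$start[i2[sp]] + (b[sp] - 1L - cumw0[i2[sp]]))
    }
    nb <- i2 - i1 + 1L
    exi <- sequence(nb) - 1L + rep(i1, nb)
    s <- ex$start[exi]; e <- ex$end[exi]
    lasts <- cumsum(nb); firsts <- lasts - nb + 1L
    s[firsts] <- gs; e[lasts] <- ge
    w <- e - s + 1L
    is_first <- logical(length(s)); is_first[firsts] <- TRUE
    gapN <- c(0L, s[-1L] - e[-length(e)] - 1L)
    tok <- ifelse(is_first, paste0(w, "M"), paste0(gapN, "N", w, "M"))
    ldt <- data.table::data.table(r = rep(seq_len(n_pairs), nb), tok = tok,
                                  bs = paste0(s, "-", e))
    agg <- ldt[, list(cigar = paste(tok, collapse = ""),
                      bstr = paste(bs, collapse = ";")), by = "r"]
    list(pos = s[firsts], endp = e[lasts], nb = nb,
         cigar = agg$cigar, bstr = agg$bstr,
         blocks = data.table::data.table(start = s, end = e))
  }
  L1 <- mate_layout(a1, b1)
  L2 <- mate_layout(a2, b2)

  # error injection on both mates at once
  seqs <- c(m1, m2)
  if (!is.null(model)) {
    stopifnot(model$read_length == L)
    inj <- inject_errors(model, seqs)
    seqs <- inj$seqs
    quals <- inj$quals
    n_mm <- inj$n_mm
  } else {
    quals <- rep(strrep("I", L), length(seqs))
    n_mm <- integer(length(seqs))
  }

  serial <- serial0 + seq_len(n_pairs)
  ids <- sprintf("sim|%s|%s|%s|%s|%s|%d", tx$transcript_id, kind, tx$chrom,
                 L1$bstr, L2$bstr, serial)

  # SAM orientation: mate1 follows transcript strand
  rev1 <- minus; rev2 <- !minus
  sam_seq <- c(if (rev1) revcomp_chr(seqs[1:n_pairs]) else seqs[1:n_pairs],
               if (rev2) revcomp_chr(seqs[(n_pairs + 1):(2 * n_pairs)])
               else seqs[(n_pairs + 1):(2 * n_pairs)])
  revq <- function(q) {   # cache distinct quality strings before reversing
    u <- unique(q)
    r <- vapply(u, function(x) intToUtf8(rev(utf8ToInt(x))), character(1),
                USE.NAMES = FALSE)
    r[match(q, u)]
  }
  sam_qual <- c(if (rev1) revq(quals[1:n_pairs]) else quals[1:n_pairs],
                if (rev2) revq(quals[(n_pairs + 1):(2 * n_pairs)])
                else quals[(n_pairs + 1):(2 * n_pairs)])
  flag1 <- if (minus) 83L else 99L   # paired, proper, first-in-pair
  flag2 <- if (minus) 163L else 147L

  span <- pmax(L1$endp, L2$endp) - pmin(L1$pos, L2$pos) + 1L
  tlen1 <- ifelse(L1$pos <= L2$pos, span, -span)

  mates <- data.table::data.table(
    qname = rep(ids, 2L),
    mate = rep(1:2, each = n_pairs),
    flag = rep(c(flag1, flag2), each = n_pairs),
    chrom = tx$chrom,
    pos = c(L1$pos, L2$pos),
    cigar = c(L1$cigar, L2$cigar),
    pnext = c(L2$pos, L1$pos),
    tlen = c(tlen1, -tlen1),
    seq = sam_seq, qual = sam_qual,
    read_seq = seqs, read_qual = quals,
    n_mismatch = n_mm,
    nblocks = c(L1$nb, L2$nb))

  bl <- data.table::rbindlist(list(L1$blocks, L2$blocks))

  pairs <- data.table::data.table(
    pair_id = ids, transcript_id = tx$transcript_id, gene_id = tx$gene_id,
    chrom = tx$chrom, strand = tx$strand, kind = kind,
    frag_len = as.integer(frag), template_start = as.integer(tstart))
  list(pairs = pairs, mates = mates, blocks = bl)
}

# weighted-random error injection for a batch of equal-length reads
inject_errors <- function(model, seqs) {
  L <- model$read_length
  n <- length(seqs)
  k <- draw_mismatch_counts(model, n)
  quals <- rep(model$qual_match, n)
  affected <- which(k > 0L)
  if (length(affected) == 0L)
    return(list(seqs = seqs, quals = quals, n_mm = k))

  rate <- model$mismatch_rate_by_pos
  if (sum(rate) <= 0) rate <- rep(1, L)
  # positions: fast path for single-mismatch reads, loop for the rest
  pos_list <- vector("list", length(affected))
  one <- k[affected] == 1L
  pos_list[one] <- as.list(sample.int(L, sum(one), replace = TRUE, prob = rate))
  for (j in which(!one))
    pos_list[[j]] <- draw_mismatch_positions(model, k[affected[j]])
  reps <- lengths(pos_list)
  mm_read <- rep(affected, reps)
  mm_pos <- unlist(pos_list)
  mm_ref <- substring(seqs[mm_read], mm_pos, mm_pos)

  # substitutions via cumulative row lookup on the (position, ref) weights
  Wm <- matrix(model$sub_weights, nrow = L * 4L)
  zero <- rowSums(Wm) <= 0
  if (any(zero)) {
    unif <- matrix(1 / 3, sum(zero), 4L)
    refb <- ((which(zero) - 1L) %/% L) + 1L
    unif[cbind(seq_len(sum(zero)), refb)] <- 0
    Wm[zero, ] <- unif
  }
  Wc <- t(apply(Wm, 1L, cumsum))
  ri <- match(mm_ref, BASES)
  known <- !is.na(ri)
  mm_alt <- character(length(mm_ref))
  if (any(known)) {
    row <- mm_pos[known] + (ri[known] - 1L) * L
    u <- runif(sum(known)) * Wc[row, 4L]
    mm_alt[known] <- BASES[rowSums(Wc[row, , drop = FALSE] < u) + 1L]
  }
  if (any(!known)) mm_alt[!known] <- sample(BASES, sum(!known), replace = TRUE)

  # apply substitutions and mismatch-consensus qualities in waves over the
  # j-th mismatch of each read (mm_read is grouped by read)
  qm <- strsplit(model$qual_mismatch, "")[[1L]]
  wave <- sequence(reps)
  for (w in seq_len(max(reps))) {
    ii <- which(wave == w)
    r <- mm_read[ii]
    s2 <- seqs[r]
    substring(s2, mm_pos[ii], mm_pos[ii]) <- mm_alt[ii]
    seqs[r] <- s2
    q2 <- quals[r]
    substring(q2, mm_pos[ii], mm_pos[ii]) <- qm[mm_pos[ii]]
    quals[r] <- q2
  }
  list(seqs = seqs, quals = quals, n_mm = k)
}

#' Origin-encoding read identifiers
#'
#' Each simulated pair's identifier encodes its transcript of origin, the
#' template kind (`"S"` spliced / `"U"` unspliced), and the genomic
#' alignment blocks of both mates, plus a serial suffix guaranteeing
#' uniqueness: `sim|<tx>|<kind>|<chrom>|<m1 blocks>|<m2 blocks>|<serial>`
#' with blocks rendered `start-end[;start-end...]` (1-based inclusive).
#' `decode_origin()` inverts the encoding.
#'
#' @param transcript_id,kind,chrom,serial per-pair fields (vectorized)
#' @param blocks1,blocks2 lists of `list(starts, ends)` per pair
#' @return `encode_origin()`: character vector of ids; `decode_origin()`:
#'   data.frame with columns `transcript_id`, `kind`, `chrom`, `serial` and
#'   list-columns `blocks1`, `blocks2`
#' @export
encode_origin <- function(transcript_id, kind, chrom, blocks1, blocks2, serial) {
  fmt <- function(bl) vapply(bl, function(x)
    paste(sprintf("%d-%d", x$starts, x$ends), collapse = ";"), character(1))
  sprintf("sim|%s|%s|%s|%s|%s|%d", transcript_id, kind, chrom,
          fmt(blocks1), fmt(blocks2), as.integer(serial))
}

#' @rdname encode_origin
#' @param id character vector of encoded read ids
#' @export
decode_origin <- function(id) {
  parts <- strsplit(id, "|", fixed = TRUE)
  ok <- lengths(parts) == 7L & vapply(parts, `[`, "", 1L) == "sim"
  if (!all(ok)) stop_format("malformed origin-encoded read id: %s",
                            paste(head(id[!ok], 3L), collapse = ", "))
  parse_blocks <- function(s) {
    iv <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "-", fixed = TRUE)
    if (any(lengths(iv) != 2L)) stop_format("malformed block spec: %s", s)
    list(starts = as.integer(vapply(iv, `[`, "", 1L)),
         ends = as.integer(vapply(iv, `[`, "", 2L)))
  }
  data.frame(
    transcript_id = vapply(parts, `[`, "", 2L),
    kind = vapply(parts, `[`, "", 3L),
    chrom = vapply(parts, `[`, "", 4L),
    serial = as.integer(vapply(parts, `[`, "", 7L)),
    blocks1 = I(lapply(parts, function(p) parse_blocks(p[5L]))),
    blocks2 = I(lapply(parts, function(p) parse_blocks(p[6L]))),
    stringsAsFactors = FALSE)
}

#' True per-junction spanning-read coverage of a simulation
#'
#' A read contributes to a junction when one of its genomic block gaps
#' equals the junction's intron and both flanking blocks are at least
#' `min_overhang` long.
#'
#' @param sim a `"sim_result"`
#' @param min_overhang minimum anchor length (bp; default 8)
#' @return data.frame `chrom`, `start`, `end`, `truth_count`, `key`
#' @export
truth_junction_coverage <- function(sim, min_overhang = 8L) {
  bl <- sim$blocks
  mt <- sim$mates[, c("row", "chrom")]
  gaps <- bl[, if (.N > 1L) list(
    start = end[-.N] + 1L, end = start[-1L] - 1L,
    left = (end - start + 1L)[-.N], right = (end - start + 1L)[-1L]
  ), by = "row"]
  gaps <- gaps[gaps$left >= min_overhang & gaps$right >= min_overhang]
  gaps <- merge(gaps, mt, by = "row")
  tab <- gaps[, list(truth_count = .N), by = c("chrom", "start", "end")]
  tab <- as.data.frame(tab[order(chrom, start, end)])
  tab$key <- junction_key(tab$chrom, tab$start, tab$end)
  tab
}

#' Write simulated output files
#'
#' Writes the paired FASTQ files, the perfect-alignment truth SAM and the
#' tab-separated truth tables of a simulation.
#'
#' @param sim a `"sim_result"`
#' @param dir output directory (created if needed)
#' @param prefix file name prefix
#' @param min_overhang anchor requirement used for the junction truth table
#' @return named character vector of written paths, invisibly
#' @export
write_sim <- function(sim, dir, prefix = "sim", min_overhang = 8L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, paste0(prefix, f))
  mt <- sim$mates
  for (m in 1:2) {
    mm <- mt[mt$mate == m]
    writeLines(c(rbind(paste0("@", mm$qname, "/", m), mm$read_seq, "+", mm$read_qual)),
               p(sprintf("_%d.fastq", m)))
  }
  write_sam(data.frame(qname = mt$qname, flag = mt$flag, chrom = mt$chrom,
                       pos = mt$pos, mapq = 255L, cigar = mt$cigar,
                       rnext = "=", pnext = mt$pnext, tlen = mt$tlen,
                       seq = mt$seq, qual = mt$qual),
            sim$chrom_lengths, p("_truth.sam"))
  tt <- sim$transcript_counts
  utils::write.table(tt, p("_transcript_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jt <- truth_junction_coverage(sim, min_overhang)
  utils::write.table(jt, p("_junction_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(fastq1 = p("_1.fastq"), fastq2 = p("_2.fastq"),
              truth_sam = p("_truth.sam"),
              transcript_truth = p("_transcript_truth.tsv"),
              junction_truth = p("_junction_truth.tsv")))
}

#' Write alignment records as SAM
#'
#' Minimal SAM text writer for synthetic alignment records. `records` needs
#' columns `qname`, `flag`, `chrom`, `pos`, `cigar`, `seq`, `qual`;
#' `mapq`, `rnext`, `pnext`, `tlen` default to `255`, `"*"`, `0`, `0`.
#'
#' @param records data.frame of SAM fields
#' @param chrom_lengths named integer vector for the `@SQ` header lines
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sam <- function(records, chrom_lengths, path) {
  r <- as.data.frame(records)
  n <- nrow(r)
  fill <- function(col, default) {
    if (is.null(col)) return(rep(default, n))
    col[is.na(col)] <- default
    col
  }
  r$mapq <- fill(r$mapq, 255L)
  r$rnext <- fill(r$rnext, "*")
  r$pnext <- fill(r$pnext, 0L)
  r$tlen <- fill(r$tlen, 0L)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  body <- paste(r$qname, r$flag, r$chrom, r$pos, r$mapq, r$cigar,
                r$rnext, r$pnext, r$tlen, r$seq, r$qual, sep = "\t")
  if (!is.null(r$md)) body <- paste0(body, "\tMD:Z:", r$md)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Truth alignment records of a simulation
#'
#' The per-mate perfect-alignment records as a [write_sam()]-ready
#' data.frame, convenient for mixing simulated truth with synthetic error
#' records before quantification.
#'
#' @param sim a `"sim_result"`
#' @return data.frame of SAM fields
#' @export
truth_sam_records <- function(sim) {
  mt <- sim$mates
  data.frame(qname = mt$qname, flag = mt$flag, chrom = mt$chrom,
             pos = mt$pos, mapq = 255L, cigar = mt$cigar, rnext = "=",
             pnext = mt$pnext, tlen = mt$tlen, seq = mt$seq, qual = mt$qual,
             stringsAsFactors = FALSE)
}

#' Simulate equal-abundance null pools
#'
#' Simulates `n_pools` read pools with every annotated transcript at the
#' same reads-per-kilobase abundance, so that the expected PSI difference of
#' every splicing event between any two pools is zero.
#'
#' @param ann,genome annotation and genome
#' @param rpk common abundance (reads per kilobase)
#' @param n_pools number of pools
#' @param seeds integer vector of per-pool seeds (length `n_pools`)
#' @param ... further arguments to [sim_config()]
#' @return list of `"sim_result"` objects
#' @export
simulate_null_pools <- function(ann, genome, rpk = 300, n_pools = 2L,
                                seeds = seq_len(n_pools), ...) {
  stopifnot(length(seeds) == n_pools)
  lapply(seq_len(n_pools), function(i)
    simulate_reads(ann, genome, sim_config(rpk = rpk, seed = seeds[i], ...)))
}

#' Simulate two pools with a designed PSI difference
#'
#' For a set of isolated two-isoform events, sets the inclusion- and
#' exclusion-form transcript abundances in ratio `psi : (1 - psi)` of
#' `total_rpk` in each pool, yielding a designed per-event
#' `delta PSI = psi_b - psi_a`. Events whose transcripts participate in more
#' than one event are rejected (cross-talk would distort the designed PSI),
#' as are boundary `psi` values 0 and 1.
#'
#' @param ann,genome annotation and genome
#' @param events data.frame with columns `event_id`, `inc_tx`, `exc_tx`
#'   (one inclusion and one exclusion transcript per event, as produced by
#'   [enumerate_events()] on two-isoform genes)
#' @param psi_a,psi_b designed PSI in pool A and pool B, in (0, 1)
#' @param total_rpk per-event total abundance split between the two forms
#' @param seeds length-2 integer vector of pool seeds
#' @param ... further arguments to [sim_config()]
#' @return list with `"sim_result"` elements `pool_a`, `pool_b` and the
#'   abundance `design` table
#' @export
simulate_delta_psi <- function(ann, genome, events, psi_a, psi_b,
                               total_rpk = 2500, seeds = c(1L, 2L), ...) {
  stopifnot(all(c("inc_tx", "exc_tx") %in% names(events)))
  if (psi_a <= 0 || psi_a >= 1 || psi_b <= 0 || psi_b >= 1)
    stop_format("designed psi values must lie strictly inside (0,1)")
  all_tx <- c(events$inc_tx, events$exc_tx)
  dup <- unique(all_tx[duplicated(all_tx)])
  if (length(dup))
    stop_format("event transcripts shared across events (cross-talk): %s",
                paste(head(dup, 5L), collapse = ", "))
  design <- data.frame(
    transcript_id = c(events$inc_tx, events$exc_tx),
    rpk_a = c(rep(total_rpk * psi_a, nrow(events)),
              rep(total_rpk * (1 - psi_a), nrow(events))),
    rpk_b = c(rep(total_rpk * psi_b, nrow(events)),
              rep(total_rpk * (1 - psi_b), nrow(events))))
  pool_a <- simulate_reads(ann, genome, sim_config(
    table = data.frame(transcript_id = design$transcript_id, rpk = design$rpk_a),
    seed = seeds[1L], ...))
  pool_b <- simulate_reads(ann, genome, sim_config(
    table = data.frame(transcript_id = design$transcript_id, rpk = design$rpk_b),
    seed = seeds[2L], ...))
  list(pool_a = pool_a, pool_b = pool_b, design = design)
}
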