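BASES <- c("A", "C", "G", "T")

#' Empirical sequencing-error model
#'
#' An error model captures, from a permissive ungapped alignment of real
#' reads: the per-position mismatch frequency along the read, per-position
#' base-substitution weights conditioned on the reference base, the empirical
#' distribution of per-read total mismatch counts, and two consensus quality
#' strings (one for matched, one for mismatched positions). The model drives
#' the read simulator's weighted-random error injection.
#'
#' `build_error_model()` accepts a SAM/BAM file (MD tag required; only
#' ungapped, full-length alignments are tallied), a bowtie map-format text
#' file, or an alignment stream built with [alignment_stream()]. Mismatch
#' positions, substitutions and qualities of reverse-strand alignments are
#' reflected back into read orientation before tallying.
#'
#' @param aln path to a SAM/BAM (`.sam`/`.bam`) or bowtie map file, or an
#'   [alignment_stream()] object
#' @param read_length expected uniform read length L (bp)
#' @param sparse_min minimum per-(position, reference-base) observation count
#'   below which substitution weights fall back to the position-marginal
#'   substitution matrix
#' @return an object of class `"error_model"`: a list with
#'   `read_length`, `n_reads`, `mismatch_rate_by_pos` (length L),
#'   `sub_weights` (L x 4 x 4 array, reference base x called base, rows
#'   normalized where observed), `sub_marginal` (4 x 4),
#'   `mismatch_count_dist` (named probabilities over per-read mismatch
#'   counts), `qual_match`, `qual_mismatch` (length-L strings)
#' @export
build_error_model <- function(aln, read_length, sparse_min = 10L) {
  stream <- if (inherits(aln, "alignment_stream")) aln else alignment_stream(aln)
  L <- as.integer(read_length)
  n <- stream$n_reads
  if (n == 0L) stop_format("empty alignment stream: cannot build an error model")
  if (any(stream$read_len != L))
    stop_format("mixed read lengths: expected %d, found %s", L,
                paste(unique(stream$read_len[stream$read_len != L]), collapse = ","))

  mm <- stream$mm
  quals <- stream$qual
  # reflect reverse-strand records into read orientation
  rev <- stream$strand == "-"
  if (any(rev)) {
    quals[rev] <- vapply(quals[rev], function(q)
      intToUtf8(rev(utf8ToInt(q))), character(1))
    if (nrow(mm)) {
      flip <- mm$read %in% which(rev)
      mm$pos[flip] <- L + 1L - mm$pos[flip]
      mm$ref[flip] <- COMPLEMENT[mm$ref[flip]]
      mm$alt[flip] <- COMPLEMENT[mm$alt[flip]]
    }
  }

  rate <- tabulate(mm$pos, nbins = L) / n
  counts_per_read <- tabulate(mm$read, nbins = n)
  kd <- table(counts_per_read) / n
  count_dist <- setNames(as.numeric(kd), names(kd))

  sub_counts <- array(0, dim = c(L, 4L, 4L),
                      dimnames = list(NULL, BASES, BASES))
  if (nrow(mm)) {
    keep <- mm$ref %in% BASES & mm$alt %in% BASES
    mk <- mm[keep, , drop = FALSE]
    idx <- cbind(mk$pos, match(mk$ref, BASES), match(mk$alt, BASES))
    agg <- data.table::data.table(p = idx[, 1L], r = idx[, 2L], a = idx[, 3L])
    agg <- agg[, list(n = .N), by = c("p", "r", "a")]
    sub_counts[cbind(agg$p, agg$r, agg$a)] <- agg$n
  }
  marg_counts <- apply(sub_counts, c(2L, 3L), sum)
  sub_marginal <- normalize_rows(marg_counts)
  sub_weights <- sub_counts
  for (b in 1:4) {
    tot <- rowSums(sub_counts[, b, , drop = FALSE][, 1L, ])
    use_marg <- tot < sparse_min & sum(marg_counts[b, ]) > 0
    norm <- tot >= sparse_min
    if (any(norm))
      sub_weights[norm, b, ] <- sub_counts[norm, b, ] / tot[norm]
    if (any(use_marg))
      sub_weights[use_marg, b, ] <- matrix(sub_marginal[b, ], sum(use_marg), 4L,
                                           byrow = TRUE)
  }

  qm <- consensus_quals(quals, mm, L, n)
  model <- structure(list(
    read_length = L, n_reads = n,
    mismatch_rate_by_pos = rate,
    sub_weights = sub_weights,
    sub_marginal = sub_marginal,
    mismatch_count_dist = count_dist,
    qual_match = qm$match, qual_mismatch = qm$mismatch),
    class = "error_model")
  validate_error_model(model)
  model
}

normalize_rows <- function(m) {
  s <- rowSums(m)
  out <- m
  out[s > 0, ] <- m[s > 0, , drop = FALSE] / s[s > 0]
  out
}

# per-position modal quality characters for matched and mismatched positions;
# ties broken toward the higher quality; positions with no mismatch
# observations inherit the match consensus
consensus_quals <- function(quals, mm, L, n) {
  codes <- matrix(utf8ToInt(paste(quals, collapse = "")), nrow = L)
  lo <- min(codes); hi <- max(codes)
  nq <- hi - lo + 1L
  tot <- matrix(0L, L, nq)
  for (p in seq_len(L)) {
    tb <- tabulate(codes[p, ] - lo + 1L, nbins = nq)
    tot[p, ] <- tb
  }
  mmc <- matrix(0L, L, nq)
  if (nrow(mm)) {
    q_at_mm <- codes[cbind(mm$pos, mm$read)] - lo + 1L
    agg <- data.table::data.table(p = mm$pos, q = q_at_mm)[, list(n = .N), by = c("p", "q")]
    mmc[cbind(agg$p, agg$q)] <- agg$n
  }
  matc <- tot - mmc
  modal <- function(m, fallback = NULL) {
    vapply(seq_len(L), function(p) {
      row <- m[p, ]
      if (all(row == 0L)) {
        if (is.null(fallback)) return(NA_integer_)
        return(fallback[p])
      }
      # which.max of reversed row -> highest quality among ties
      nq - which.max(rev(row)) + 1L
    }, integer(1))
  }
  match_code <- modal(matc)
  if (anyNA(match_code)) match_code[is.na(match_code)] <- which.max(colSums(tot))
  mm_code <- modal(mmc, fallback = match_code)
  list(match = intToUtf8(match_code + lo - 1L),
       mismatch = intToUtf8(mm_code + lo - 1L))
}

validate_error_model <- function(m) {
  stopifnot(inherits(m, "error_model"))
  assert_that(all(m$mismatch_rate_by_pos >= 0 & m$mismatch_rate_by_pos <= 1),
              "mismatch rates must lie in [0,1]")
  assert_that(abs(sum(m$mismatch_count_dist) - 1) < 1e-9,
              "mismatch count distribution must sum to 1")
  rs <- apply(m$sub_weights, c(1L, 2L), sum)
  assert_that(all(abs(rs[rs > 0] - 1) < 1e-9),
              "substitution weight rows with observations must sum to 1")
  assert_that(nchar(m$qual_match) == m$read_length &&
              nchar(m$qual_mismatch) == m$read_length,
              "consensus quality strings must have length L")
  invisible(m)
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("error_model: L=%d, built from %d read(s), mean per-read mismatches %.3f\n",
              x$read_length, x$n_reads,
              sum(as.numeric(names(x$mismatch_count_dist)) * x$mismatch_count_dist)))
  invisible(x)
}

#' Normalized ungapped-alignment stream for error-model building
#'
#' Normalizes either a SAM/BAM file (MD tag required) or a bowtie map-format
#' text file into the internal mismatch-record stream: per read its strand,
#' stored (genome-oriented) quality string, and the mismatch records
#' (position along the stored sequence, reference base, called base). Gapped
#' or clipped SAM records are skipped; multi-mapped records are counted as
#' they appear.
#'
#' @param x path to `.sam`/`.bam` (by extension) or bowtie map text file
#' @return an object of class `"alignment_stream"`
#' @export
alignment_stream <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  ext <- tolower(tools::file_ext(x))
  if (ext %in% c("sam", "bam")) alignment_stream_bam(x)
  else alignment_stream_bowtie(x)
}

as_alignment_stream <- function(strand, qual, mm, read_len) {
  structure(list(n_reads = length(strand), strand = strand, qual = qual,
                 mm = mm, read_len = read_len),
            class = "alignment_stream")
}

alignment_stream_bam <- function(path) {
  bam <- ensure_bam(path)
  param <- Rsamtools::ScanBamParam(
    what = c("seq", "qual", "flag", "cigar"), tag = "MD",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  cig <- res$cigar
  ok <- grepl("^[0-9]+M$", cig)
  if (!any(ok)) stop_format("no ungapped alignments in %s", path)
  seqs <- as.character(res$seq[ok])
  quals <- as.character(res$qual[ok])
  strand <- ifelse(bitwAnd(res$flag[ok], 16L) > 0L, "-", "+")
  md <- res$tag$MD[ok]
  if (is.null(md) || anyNA(md))
    stop_format("MD tag required on all ungapped records in %s", path)
  mm <- md_mismatches(md, seqs)
  as_alignment_stream(strand, quals, mm, nchar(seqs))
}

# MD tags of ungapped alignments: alternating match-lengths and ref bases
md_mismatches <- function(md, seqs) {
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Z]+|[A-Z]", md))
  out <- vector("list", length(md))
  for (i in seq_along(md)) {
    pos <- 0L
    rows <- list()
    for (t in toks[[i]]) {
      if (grepl("^\\d+$", t)) pos <- pos + as.integer(t)
      else if (startsWith(t, "^")) stop_format("deletion in MD tag of ungapped record")
      else {
        pos <- pos + 1L
        rows[[length(rows) + 1L]] <- c(pos, t)
      }
    }
    if (length(rows))
      out[[i]] <- data.frame(read = i, pos = as.integer(vapply(rows, `[`, "", 1L)),
                             ref = vapply(rows, `[`, "", 2L), stringsAsFactors = FALSE)
  }
  mm <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(mm))
    return(data.frame(read = integer(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  mm$alt <- substring(seqs[mm$read], mm$pos, mm$pos)
  mm
}

# bowtie map format: name, strand, ref, offset, seq, quals, reserved,
# comma-separated mismatch descriptors "offset:ref>alt" (0-based, reference
# orientation, i.e. along the stored sequence)
alignment_stream_bowtie <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_format("empty bowtie map file: %s", path)
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 7L)) stop_format("malformed bowtie map line(s) in %s", path)
  strand <- vapply(f, `[`, "", 2L)
  seqs <- vapply(f, `[`, "", 5L)
  quals <- vapply(f, `[`, "", 6L)
  desc <- vapply(f, function(x) if (length(x) >= 8L) x[8L] else "", "")
  mm_rows <- lapply(seq_along(desc), function(i) {
    if (!nzchar(desc[i])) return(NULL)
    parts <- strsplit(desc[i], ",", fixed = TRUE)[[1L]]
    m <- regmatches(parts, regexec("^(\\d+):([ACGTN])>([ACGTN])$", parts))
    if (any(lengths(m) != 4L))
      stop_format("malformed mismatch descriptor '%s' in %s", desc[i], path)
    data.frame(read = i,
               pos = as.integer(vapply(m, `[`, "", 2L)) + 1L,
               ref = vapply(m, `[`, "", 3L),
               alt = vapply(m, `[`, "", 4L), stringsAsFactors = FALSE)
  })
  mm <- do.call(rbind, mm_rows[!vapply(mm_rows, is.null, TRUE)])
  if (is.null(mm))
    mm <- data.frame(read = integer(0), pos = integer(0),
                     ref = character(0), alt = character(0))
  as_alignment_stream(strand, quals, mm, nchar(seqs))
}

# SAM path -> sorted BAM (cached next to a tempdir), BAM path -> itself
ensure_bam <- function(path) {
  if (tolower(tools::file_ext(path)) == "bam") return(path)
  dest <- tempfile(fileext = "")
  Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = TRUE)
}

#' Sample per-read errors from an error model
#'
#' Draws a total mismatch count from the model's empirical count
#' distribution, then that many distinct read positions (weighted by the
#' per-position mismatch rate), then one substitution per position from the
#' position- and reference-base-conditional weights. A position whose
#' reference base has no observed substitutions falls back to a uniform
#' choice over the three alternatives.
#'
#' @param model an [build_error_model()] result (class `"error_model"`)
#' @param ref_seq the error-free read sequence (single string of length L)
#' @return list with integer vector `pos` (1-based read positions), and
#'   character vectors `ref`, `alt`
#' @export
sample_read_errors <- function(model, ref_seq) {
  L <- model$read_length
  stopifnot(nchar(ref_seq) == L)
  k <- draw_mismatch_counts(model, 1L)
  if (k == 0L) return(list(pos = integer(0), ref = character(0), alt = character(0)))
  pos <- draw_mismatch_positions(model, k)
  ref <- substring(ref_seq, pos, pos)
  alt <- draw_substitutions(model, pos, ref)
  list(pos = pos, ref = ref, alt = alt)
}

draw_mismatch_counts <- function(model, n) {
  ks <- as.integer(names(model$mismatch_count_dist))
  k <- sample(ks, n, replace = TRUE, prob = model$mismatch_count_dist)
  over <- k > model$read_length
  if (any(over)) {
    warning("drawn mismatch count exceeds read length; capped at L")
    k[over] <- model$read_length
  }
  k
}

draw_mismatch_positions <- function(model, k) {
  rate <- model$mismatch_rate_by_pos
  if (sum(rate) <= 0) rate <- rep(1, model$read_length)
  support <- sum(rate > 0)
  if (k > support) rate <- rate + 1e-12   # degenerate model, still honor k
  sort(sample.int(model$read_length, k, replace = FALSE, prob = rate))
}

draw_substitutions <- function(model, pos, ref) {
  n <- length(pos)
  alt <- character(n)
  ri <- match(ref, BASES)
  for (i in seq_len(n)) {
    if (is.na(ri[i])) { alt[i] <- sample(BASES, 1L); next }
    w <- model$sub_weights[pos[i], ri[i], ]
    if (sum(w) <= 0) {
      alt[i] <- sample(BASES[-ri[i]], 1L)
    } else {
      alt[i] <- sample(BASES, 1L, prob = w)
    }
  }
  alt
}

#' Consensus quality string for a read
#'
#' Position i receives the mismatch-consensus quality character if i is in
#' `mismatch_positions`, else the match-consensus character.
#'
#' @param model an `"error_model"`
#' @param mismatch_positions integer vector of 1-based mismatched positions
#' @return a quality string of length L (Phred+33)
#' @export
consensus_quality_string <- function(model, mismatch_positions = integer(0)) {
  if (length(mismatch_positions) == 0L) return(model$qual_match)
  stopifnot(all(mismatch_positions >= 1L & mismatch_positions <= model$read_length))
  q <- strsplit(model$qual_match, "")[[1L]]
  qm <- strsplit(model$qual_mismatch, "")[[1L]]
  q[mismatch_positions] <- qm[mismatch_positions]
  paste(q, collapse = "")
}

#' Built-in error models
#'
#' `builtin_error_model("uniform")` has a constant per-position mismatch
#' rate, uniform substitution weights and a Poisson mismatch-count
#' distribution truncated at L. `builtin_error_model("ramp")` mimics the
#' error profile typical of Illumina reads: a slight elevation over the
#' first five cycles and rates rising steadily through the 3' end.
#'
#' @param name `"uniform"` or `"ramp"`
#' @param read_length read length L (default 76)
#' @param rate per-position mismatch rate for `"uniform"` (default 0.01)
#' @return an `"error_model"`
#' @export
builtin_error_model <- function(name, read_length = 76L, rate = 0.01) {
  L <- as.integer(read_length)
  rates <- switch(name,
    uniform = rep(rate, L),
    ramp = {
      i <- seq_len(L)
      0.002 + 0.003 * exp(-(i - 1) / 2) + 0.018 * (i / L)^4
    },
    stop_format("unknown built-in error model: '%s'", name))
  lambda <- sum(rates)
  kd <- dpois(0:L, lambda)
  kd <- kd / sum(kd)
  names(kd) <- 0:L
  sub <- array(1 / 3, dim = c(L, 4L, 4L), dimnames = list(NULL, BASES, BASES))
  for (b in 1:4) sub[, b, b] <- 0
  model <- structure(list(
    read_length = L, n_reads = 0L,
    mismatch_rate_by_pos = rates,
    sub_weights = sub,
    sub_marginal = matrix(1 / 3, 4, 4, dimnames = list(BASES, BASES)) -
      diag(4) / 3,
    mismatch_count_dist = kd,
    qual_match = strrep("I", L), qual_mismatch = strrep("#", L)),
    class = "error_model")
  validate_error_model(model)
  model
}

#' @rdname builtin_error_model
#' @export
builtin_models <- function(read_length = 76L, rate = 0.01) {
  list(uniform = builtin_error_model("uniform", read_length, rate),
       ramp = builtin_error_model("ramp", read_length, rate))
}

#' Serialize / load an error model
#'
#' Flat, versioned tab-separated text representation.
#'
#' @param model an `"error_model"`
#' @param path file path
#' @return `write_error_model()`: `path` invisibly; `read_error_model()`:
#'   the model
#' @export
write_error_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  w("#spliceward_error_model\tv1")
  w("read_length\t", model$read_length)
  w("n_reads\t", model$n_reads)
  w("mismatch_rate\t", paste(format(model$mismatch_rate_by_pos, digits = 17), collapse = " "))
  w("count_dist\t", paste(sprintf("%s:%s", names(model$mismatch_count_dist),
                                  format(model$mismatch_count_dist, digits = 17)),
                          collapse = " "))
  w("qual_match\t", model$qual_match)
  w("qual_mismatch\t", model$qual_mismatch)
  for (b in 1:4)
    w("marginal\t", BASES[b], "\t",
      paste(format(model$sub_marginal[b, ], digits = 17), collapse = " "))
  for (p in seq_len(model$read_length)) for (b in 1:4) {
    row <- model$sub_weights[p, b, ]
    if (any(row > 0))
      w("sub\t", p, "\t", BASES[b], "\t", paste(format(row, digits = 17), collapse = " "))
  }
  invisible(path)
}

#' @rdname write_error_model
#' @export
read_error_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "#spliceward_error_model"))
    stop_format("not a spliceward error model file: %s", path)
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  get1 <- function(key) {
    i <- which(vapply(fields, `[`, "", 1L) == key)
    fields[[i[1L]]]
  }
  L <- as.integer(get1("read_length")[2L])
  nums <- function(s) as.numeric(strsplit(trimws(s), " +")[[1L]])
  kd_tok <- strsplit(trimws(get1("count_dist")[2L]), " +")[[1L]]
  kd <- vapply(strsplit(kd_tok, ":", fixed = TRUE), function(x) as.numeric(x[2L]), 0)
  names(kd) <- vapply(strsplit(kd_tok, ":", fixed = TRUE), `[`, "", 1L)
  sub <- array(0, dim = c(L, 4L, 4L), dimnames = list(NULL, BASES, BASES))
  marg <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (fl in fields) {
    if (fl[1L] == "sub")
      sub[as.integer(fl[2L]), match(fl[3L], BASES), ] <- nums(fl[4L])
    if (fl[1L] == "marginal")
      marg[match(fl[2L], BASES), ] <- nums(fl[3L])
  }
  model <- structure(list(
    read_length = L, n_reads = as.integer(get1("n_reads")[2L]),
    mismatch_rate_by_pos = nums(get1("mismatch_rate")[2L]),
    sub_weights = sub, sub_marginal = marg,
    mismatch_count_dist = kd,
    qual_match = get1("qual_match")[2L],
    qual_mismatch = get1("qual_mismatch")[2L]), class = "error_model")
  validate_error_model(model)
  model
}
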