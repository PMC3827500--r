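#' Splice graph of one gene
#'
#' Decomposes a gene's transcript models into splice-site nodes (exon
#' boundaries, plus left/right terminal markers) connected by exon and
#' intron edges; every transcript is a path through the graph. Node roles
#' are genomic: `"L"`/`"R"` terminal, `"d"` donor-side boundary (exon end,
#' intron to the right), `"a"` acceptor-side boundary (exon start, intron to
#' the left). On the minus strand the genomic `"a"` role is the
#' transcript-sense donor and vice versa; classification re-orients.
#'
#' @param ann an [annotation]
#' @param gene_id gene to build the graph for
#' @return list of class `"splice_graph"` with `gene_id`, `chrom`, `strand`,
#'   `nodes` (data.frame `coord`, `role`, `node`) and `paths` (named list of
#'   per-transcript node data.frames in genomic order)
#' @export
build_splice_graph <- function(ann, gene_id) {
  ex <- ann$exons[ann$exons$gene_id == gene_id, , drop = FALSE]
  if (nrow(ex) == 0L) stop_format("gene not in annotation: %s", gene_id)
  if (length(unique(ex$strand)) > 1L)
    stop_format("gene %s has transcripts on mixed strands", gene_id)
  paths <- lapply(split(ex, ex$transcript_id), tx_nodes)
  nodes <- unique(do.call(rbind, paths))
  nodes <- nodes[order(nodes$coord, nodes$role), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(gene_id = gene_id, chrom = ex$chrom[1L], strand = ex$strand[1L],
                 nodes = nodes, paths = paths),
            class = "splice_graph")
}

# node path of one transcript, genomic order
tx_nodes <- function(ex) {
  ex <- ex[order(ex$start), , drop = FALSE]
  k <- nrow(ex)
  coord <- integer(2L * k)
  role <- character(2L * k)
  coord[seq(1L, 2L * k, 2L)] <- ex$start
  coord[seq(2L, 2L * k, 2L)] <- ex$end
  role[seq(1L, 2L * k, 2L)] <- "a"
  role[seq(2L, 2L * k, 2L)] <- "d"
  role[1L] <- "L"
  role[2L * k] <- "R"
  data.frame(coord = coord, role = role,
             node = paste0(coord, role), stringsAsFactors = FALSE)
}

# junctions implied by a genomic-ordered node sequence: consecutive d -> a
junctions_of_nodes <- function(nodes, chrom) {
  if (nrow(nodes) < 2L) return(character(0))
  i <- which(nodes$role[-nrow(nodes)] == "d" & nodes$role[-1L] == "a")
  if (length(i) == 0L) return(character(0))
  junction_key(chrom, nodes$coord[i] + 1L, nodes$coord[i + 1L] - 1L)
}

# orient a genomic-order node block into transcript order with
# AStalavista-style symbols: ^ donor, - acceptor, [ 5' terminus, ] 3' terminus
orient_nodes <- function(nodes, strand) {
  if (nrow(nodes) == 0L)
    return(data.frame(coord = integer(0), sym = character(0)))
  if (strand == "+") {
    sym <- c(a = "-", d = "^", L = "[", R = "]")[nodes$role]
    data.frame(coord = nodes$coord, sym = unname(sym))
  } else {
    sym <- c(a = "^", d = "-", L = "]", R = "[")[nodes$role]
    data.frame(coord = rev(nodes$coord), sym = unname(rev(sym)))
  }
}

#' Enumerate pairwise splicing events of a gene or annotation
#'
#' For every pair of transcript isoforms of a gene, finds the maximal
#' "bubbles": regions bounded by nodes shared by both isoform paths with no
#' common interior nodes, where the two subpaths differ. Each bubble is a
#' pairwise splicing event with two mutually exclusive paths; the
#' inclusion path is the one with more interrogating junctions (ties broken
#' by interior node count, then lexicographic structure code). Terminal
#' regions yield events only when a splice site differs — overlapping first
#' exons that differ only in their 5' ends (and likewise bare 3'-end
#' differences) are not splicing events. Events are deduplicated across
#' transcript pairs by gene, flanks and structure; supporting transcripts
#' accumulate per path.
#'
#' @param ann an [annotation]
#' @param gene_id optional gene subset (default: all multi-isoform genes)
#' @return data.frame of class `"splicing_events"`, one row per event:
#'   `event_id`, `gene_id`, `chrom`, `strand`, `event_type`,
#'   `structure_code`, `flank_left`, `flank_right`, `is_internal`,
#'   `inc_tx`, `exc_tx`, `inc_junc`, `exc_junc` (junction key lists,
#'   `";"`-separated), `retained_key` (retained-intron events: the spliced
#'   junction quantifying the exclusion side via read-through)
#' @export
enumerate_events <- function(ann, gene_id = NULL) {
  gids <- gene_id %||% ann$genes$gene_id
  rows <- list()
  for (g in gids) {
    graph <- build_splice_graph(ann, g)
    txids <- names(graph$paths)
    if (length(txids) < 2L) next
    acc <- list()   # keyed by structure for dedup
    for (i in seq_len(length(txids) - 1L)) for (j in (i + 1L):length(txids)) {
      bubbles <- path_bubbles(graph$paths[[txids[i]]], graph$paths[[txids[j]]])
      for (b in bubbles) {
        ev <- make_event(b, graph, txids[i], txids[j])
        if (is.null(ev)) next
        key <- ev$dedup_key
        if (is.null(acc[[key]])) acc[[key]] <- ev
        else {
          acc[[key]]$inc_tx <- union(acc[[key]]$inc_tx, ev$inc_tx)
          acc[[key]]$exc_tx <- union(acc[[key]]$exc_tx, ev$exc_tx)
        }
      }
    }
    if (length(acc)) {
      ord <- order(vapply(acc, function(e) e$flank_left_coord, numeric(1)),
                   vapply(acc, function(e) e$structure_code, character(1)))
      acc <- acc[ord]
      for (k in seq_along(acc)) {
        e <- acc[[k]]
        rows[[length(rows) + 1L]] <- data.frame(
          event_id = sprintf("%s.ev%d", g, k),
          gene_id = g, chrom = graph$chrom, strand = graph$strand,
          event_type = e$event_type, structure_code = e$structure_code,
          flank_left = e$flank_left_coord, flank_right = e$flank_right_coord,
          is_internal = e$is_internal,
          inc_tx = paste(sort(e$inc_tx), collapse = ";"),
          exc_tx = paste(sort(e$exc_tx), collapse = ";"),
          inc_junc = paste(e$inc_junc, collapse = ";"),
          exc_junc = paste(e$exc_junc, collapse = ";"),
          retained_key = e$retained_key,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = character(0), gene_id = character(0),
               chrom = character(0), strand = character(0),
               event_type = character(0), structure_code = character(0),
               flank_left = numeric(0), flank_right = numeric(0),
               is_internal = logical(0), inc_tx = character(0),
               exc_tx = character(0), inc_junc = character(0),
               exc_junc = character(0), retained_key = character(0))
  class(out) <- c("splicing_events", "data.frame")
  out
}

# maximal bubbles between two node paths: segments between consecutive
# shared nodes (plus the two terminal segments) where the subpaths differ
path_bubbles <- function(pA, pB) {
  shared <- intersect(pA$node, pB$node)
  posA <- match(shared, pA$node)
  posB <- match(shared, pB$node)
  ord <- order(posA)
  posA <- posA[ord]; posB <- posB[ord]
  # shared nodes must appear in the same order in both paths (true for
  # coordinate-sorted paths on one strand)
  stopifnot(!is.unsorted(posB))
  bounds_a <- c(0L, posA, nrow(pA) + 1L)
  bounds_b <- c(0L, posB, nrow(pB) + 1L)
  out <- list()
  for (s in seq_len(length(bounds_a) - 1L)) {
    ia <- bounds_a[s]; ja <- bounds_a[s + 1L]
    ib <- bounds_b[s]; jb <- bounds_b[s + 1L]
    intA <- if (ja - ia > 1L) pA[(ia + 1L):(ja - 1L), , drop = FALSE] else pA[0L, ]
    intB <- if (jb - ib > 1L) pB[(ib + 1L):(jb - 1L), , drop = FALSE] else pB[0L, ]
    if (nrow(intA) == 0L && nrow(intB) == 0L) next
    terminal_l <- ia == 0L
    terminal_r <- ja == nrow(pA) + 1L
    # terminal bubbles need a differing splice site, not just a boundary
    if ((terminal_l || terminal_r) &&
        !any(c(intA$role, intB$role) %in% c("a", "d"))) next
    nodesA <- pA[max(ia, 1L):min(ja, nrow(pA)), , drop = FALSE]
    nodesB <- pB[max(ib, 1L):min(jb, nrow(pB)), , drop = FALSE]
    out[[length(out) + 1L]] <- list(
      flank_l = if (terminal_l) NULL else pA[ia, ],
      flank_r = if (terminal_r) NULL else pA[ja, ],
      intA = intA, intB = intB, nodesA = nodesA, nodesB = nodesB,
      terminal_l = terminal_l, terminal_r = terminal_r)
  }
  out
}

# assemble one event from a bubble; returns NULL if neither path is
# interrogated by any junction unique to it
make_event <- function(b, graph, txA, txB) {
  chrom <- graph$chrom; strand <- graph$strand
  jA <- junctions_of_nodes(b$nodesA, chrom)
  jB <- junctions_of_nodes(b$nodesB, chrom)
  common <- intersect(jA, jB)
  jA <- setdiff(jA, common)
  jB <- setdiff(jB, common)

  cA <- chain_code(b$intA, strand)
  cB <- chain_code(b$intB, strand)
  # inclusion = more junctions, then more interior nodes, then smaller code
  a_first <- if (length(jA) != length(jB)) length(jA) > length(jB)
             else if (nrow(b$intA) != nrow(b$intB)) nrow(b$intA) > nrow(b$intB)
             else cA$abs <= cB$abs
  if (a_first) {
    inc <- list(j = jA, int = b$intA, tx = txA, chain = cA)
    exc <- list(j = jB, int = b$intB, tx = txB, chain = cB)
  } else {
    inc <- list(j = jB, int = b$intB, tx = txB, chain = cB)
    exc <- list(j = jA, int = b$intA, tx = txA, chain = cA)
  }
  if (length(inc$j) == 0L && length(exc$j) == 0L) return(NULL)

  cls <- classify_event_chains(inc$int, exc$int, strand,
                               b$terminal_l, b$terminal_r)
  code <- relative_code(inc$int, exc$int, strand)
  retained_key <- if (cls == "retintron" && length(inc$j) == 1L) inc$j else NA_character_
  flank_coords <- c(
    if (is.null(b$flank_l)) -Inf else b$flank_l$coord,
    if (is.null(b$flank_r)) Inf else b$flank_r$coord)
  list(event_type = cls, structure_code = code,
       flank_left_coord = flank_coords[1L], flank_right_coord = flank_coords[2L],
       is_internal = !(b$terminal_l || b$terminal_r),
       inc_tx = inc$tx, exc_tx = exc$tx,
       inc_junc = inc$j, exc_junc = exc$j,
       retained_key = retained_key,
       dedup_key = paste(flank_coords[1L], flank_coords[2L],
                         inc$chain$abs, exc$chain$abs, sep = "|"))
}

# transcript-oriented chain of one interior: absolute (coords) and symbols
chain_code <- function(int, strand) {
  o <- orient_nodes(int, strand)
  list(abs = paste0(o$coord, o$sym, collapse = ""), syms = paste(o$sym, collapse = ""))
}

# AStalavista-style relative structure code: interior sites of both paths
# indexed in transcript order; empty chain rendered "0"
relative_code <- function(intI, intE, strand) {
  oI <- orient_nodes(intI, strand)
  oE <- orient_nodes(intE, strand)
  coords <- unique(c(oI$coord, oE$coord))
  coords <- if (strand == "+") sort(coords) else sort(coords, decreasing = TRUE)
  idx <- function(o) if (nrow(o) == 0L) "0" else
    paste0(match(o$coord, coords), o$sym, collapse = "")
  paste(idx(oI), idx(oE), sep = ",")
}

#' Classify a pairwise event
#'
#' Pattern-matches the transcript-oriented interior splice-site chains of
#' the two paths to the named event types: `exonskip`, `skip2exons`,
#' `retintron`, `altdonor`, `altacceptor`, `altda` (alternative donor and
#' acceptor), `mutexcl`, `AltFE`, `AltLE`; anything else is
#' `"Unclassified"` (its structure code still describes the graph pattern).
#'
#' @param intI,intE genomic-order interior node data.frames of the
#'   inclusion and exclusion paths
#' @param strand gene strand
#' @param terminal_l,terminal_r does the bubble touch the left/right path
#'   terminus?
#' @return a single event-type string
#' @keywords internal
classify_event_chains <- function(intI, intE, strand, terminal_l, terminal_r) {
  five_prime_terminal <- (strand == "+" && terminal_l) || (strand == "-" && terminal_r)
  three_prime_terminal <- (strand == "+" && terminal_r) || (strand == "-" && terminal_l)
  if (five_prime_terminal && three_prime_terminal) return("Unclassified")
  if (five_prime_terminal) return("AltFE")
  if (three_prime_terminal) return("AltLE")
  sI <- chain_code(intI, strand)$syms
  sE <- chain_code(intE, strand)$syms
  pat <- paste(sI, sE, sep = ",")
  switch(pat,
    "-^," = "exonskip",
    "-^-^," = "skip2exons",
    "^-," = "retintron",
    "^,^" = "altdonor",
    "-,-" = "altacceptor",
    "^-,^-" = "altda",
    "-^,-^" = "mutexcl",
    "Unclassified")
}

#' Quantify events: PSI from junction coverage
#'
#' For each event, sums the coverage of the junctions interrogating each
#' path and computes percent spliced in as reads-per-junction of the
#' inclusion path over the summed reads-per-junction of both paths:
#' `psi = (inc/n_inc) / (inc/n_inc + exc/n_exc)`. A retained-intron event
#' has no exclusion junction; its exclusion reads-per-junction is the mean
#' of the left and right intron read-through counts at the spliced
#' junction. PSI is `NA` when both normalized terms are zero or when a path
#' has no interrogating junction (and no read-through surrogate). Also
#' reports first-order neighbor coverage: junctions connecting an interior
#' exon of either path to exons outside the event's flanks, which may
#' confound the two paths' counts.
#'
#' @param events a [enumerate_events()] table
#' @param stats a [junction_stats()] table (post-filter subset or full
#'   table; missing junctions count as zero coverage)
#' @return `events` with added columns `inc_total`, `exc_total`, `inc_n`,
#'   `exc_n`, `psi`, `neighbor_coverage`, `quantifiable`
#' @export
quantify_events <- function(events, stats) {
  n <- nrow(events)
  inc_total <- exc_total <- integer(n)
  inc_n <- exc_n <- integer(n)
  psi <- rep(NA_real_, n)
  neighbor <- integer(n)
  quantifiable <- logical(n)
  cov_of <- function(keys) {
    if (length(keys) == 0L) return(integer(0))
    cv <- stats$coverage[match(keys, stats$key)]
    cv[is.na(cv)] <- 0L
    cv
  }
  split_keys <- function(s) if (is.na(s) || !nzchar(s)) character(0) else
    strsplit(s, ";", fixed = TRUE)[[1L]]
  for (i in seq_len(n)) {
    jI <- split_keys(events$inc_junc[i])
    jE <- split_keys(events$exc_junc[i])
    cI <- cov_of(jI); cE <- cov_of(jE)
    inc_total[i] <- sum(cI); exc_total[i] <- sum(cE)
    inc_n[i] <- length(jI); exc_n[i] <- length(jE)
    retintron <- !is.na(events$retained_key[i])
    rpj_inc <- if (inc_n[i] > 0L) inc_total[i] / inc_n[i] else NA_real_
    rpj_exc <- if (exc_n[i] > 0L) {
      exc_total[i] / exc_n[i]
    } else if (retintron) {
      row <- match(events$retained_key[i], stats$key)
      if (!is.na(row)) mean(c(stats$rt_left[row], stats$rt_right[row])) else 0
    } else NA_real_
    if (retintron && exc_n[i] == 0L) {
      exc_total[i] <- round(rpj_exc %||% 0)
      exc_n[i] <- 1L
    }
    quantifiable[i] <- !is.na(rpj_inc) && !is.na(rpj_exc)
    if (quantifiable[i] && (rpj_inc + rpj_exc) > 0)
      psi[i] <- rpj_inc / (rpj_inc + rpj_exc)

    # neighbor confounding: junctions with exactly one exonic end strictly
    # inside the flanks, excluding the event's own junctions
    fl <- events$flank_left[i]; fr <- events$flank_right[i]
    cand <- stats[stats$chrom == events$chrom[i] &
                  !stats$key %in% c(jI, jE) & stats$coverage > 0L, , drop = FALSE]
    if (nrow(cand)) {
      don_in <- (cand$start - 1L) > fl & (cand$start - 1L) < fr
      acc_in <- (cand$end + 1L) > fl & (cand$end + 1L) < fr
      neighbor[i] <- sum(cand$coverage[xor(don_in, acc_in)])
    }
  }
  events$inc_total <- inc_total
  events$exc_total <- exc_total
  events$inc_n <- inc_n
  events$exc_n <- exc_n
  events$psi <- psi
  events$neighbor_coverage <- neighbor
  events$quantifiable <- quantifiable
  events
}

#' Parse AStalavista-style event definitions
#'
#' Reads pairwise splicing events from an AStalavista-dialect GTF: one
#' `as_event` feature per event with attributes `transcript_id`
#' (`"incTx1,incTx2/excTx1"` — inclusion group, `/`, exclusion group),
#' `flanks` (`"1187^,1440-"`; `"null"` for a transcript terminus),
#' `splice_chain` (absolute interior site chains of the two paths,
#' inclusion first, `/`-separated, sites rendered `coord` + `^` donor /
#' `-` acceptor in transcript orientation) and `structure` (the relative
#' code). Events are mapped onto the same representation as
#' [enumerate_events()]; records that cannot be parsed or that reference
#' unknown transcripts are reported in the `errors` attribute (and a
#' warning), never silently dropped.
#'
#' @param path event GTF file
#' @param ann the matching [annotation]
#' @return a `"splicing_events"` data.frame (see [enumerate_events()]);
#'   attribute `errors` holds a data.frame of rejected records
#' @export
parse_astalavista <- function(path, ann) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- list(); errors <- list()
  rec_err <- function(i, msg) {
    errors[[length(errors) + 1L]] <<- data.frame(line = i, error = msg,
                                                 stringsAsFactors = FALSE)
  }
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) { rec_err(i, "fewer than 9 GTF fields"); next }
    if (f[3L] != "as_event") next
    attrs <- parse_gtf_attrs(f[9L])
    need <- c("gene_id", "transcript_id", "flanks", "splice_chain", "structure")
    if (!all(need %in% names(attrs))) {
      rec_err(i, paste("missing attribute(s):",
                       paste(setdiff(need, names(attrs)), collapse = ",")))
      next
    }
    strand <- f[7L]
    chrom <- f[1L]
    tx_groups <- strsplit(attrs[["transcript_id"]], "/", fixed = TRUE)[[1L]]
    if (length(tx_groups) != 2L) { rec_err(i, "transcript_id must have two '/'-separated groups"); next }
    txs <- strsplit(tx_groups, ",", fixed = TRUE)
    unknown <- setdiff(unlist(txs), ann$transcripts$transcript_id)
    if (length(unknown)) {
      rec_err(i, paste("unknown transcript(s):", paste(unknown, collapse = ",")))
      next
    }
    fl <- strsplit(attrs[["flanks"]], ",", fixed = TRUE)[[1L]]
    if (length(fl) != 2L) { rec_err(i, "flanks must have two ','-separated tokens"); next }
    chains <- strsplit(attrs[["splice_chain"]], "/", fixed = TRUE)[[1L]]
    if (length(chains) == 1L) chains <- c(chains, "")
    if (length(chains) != 2L) { rec_err(i, "splice_chain must have two '/'-separated chains"); next }
    parsed <- tryCatch({
      flank_sites <- lapply(fl, parse_site_token, allow_null = TRUE)
      ints <- lapply(chains, parse_site_chain)
      build_parsed_event(chrom, strand, attrs[["gene_id"]], txs,
                         flank_sites, ints, attrs[["structure"]], i)
    }, error = function(e) { rec_err(i, conditionMessage(e)); NULL })
    if (!is.null(parsed)) rows[[length(rows) + 1L]] <- parsed
  }
  out <- if (length(rows)) do.call(rbind, rows) else enumerate_events(ann)[0L, ]
  class(out) <- c("splicing_events", "data.frame")
  err <- if (length(errors)) do.call(rbind, errors) else
    data.frame(line = integer(0), error = character(0))
  if (nrow(err))
    warning(sprintf("%d event record(s) could not be parsed", nrow(err)))
  attr(out, "errors") <- err
  out
}

parse_gtf_attrs <- function(s) {
  toks <- regmatches(s, gregexpr('(\\w+) "([^"]*)"', s))[[1L]]
  m <- regmatches(toks, regexec('(\\w+) "([^"]*)"', toks))
  setNames(vapply(m, `[`, "", 3L), vapply(m, `[`, "", 2L))
}

# "1187^" / "1440-" / "null" -> list(coord, sym) or NULL
parse_site_token <- function(tok, allow_null = FALSE) {
  tok <- trimws(tok)
  if (tok == "null") {
    if (allow_null) return(NULL)
    stop("unexpected 'null' site")
  }
  m <- regexec("^(\\d+)([\\^-])$", tok)[[1L]]
  if (m[1L] == -1L) stop(sprintf("malformed site token '%s'", tok))
  g <- regmatches(tok, regexec("^(\\d+)([\\^-])$", tok))[[1L]]
  list(coord = as.integer(g[2L]), sym = g[3L])
}

# "1250-1349^" -> list of site tokens (coordinates ascending or descending)
parse_site_chain <- function(chain) {
  chain <- trimws(chain)
  if (!nzchar(chain)) return(list())
  toks <- regmatches(chain, gregexpr("\\d+[\\^-]", chain))[[1L]]
  if (!identical(paste(toks, collapse = ""), gsub("\\s", "", chain)))
    stop(sprintf("malformed splice chain '%s'", chain))
  lapply(toks, parse_site_token)
}

# transcript-sense symbol -> genomic node role
sym_to_role <- function(sym, strand) {
  if (strand == "+") c("^" = "d", "-" = "a")[[sym]]
  else c("^" = "a", "-" = "d")[[sym]]
}

build_parsed_event <- function(chrom, strand, gene_id, txs, flank_sites,
                               ints, structure, line_no) {
  # flanks arrive in transcript order; map to genomic left/right
  site_node <- function(x) if (is.null(x)) NULL else
    data.frame(coord = x$coord, role = sym_to_role(x$sym, strand),
               stringsAsFactors = FALSE)
  f5 <- site_node(flank_sites[[1L]])
  f3 <- site_node(flank_sites[[2L]])
  if (strand == "+") { fl <- f5; fr <- f3 } else { fl <- f3; fr <- f5 }
  int_nodes <- lapply(ints, function(sites) {
    if (length(sites) == 0L)
      return(data.frame(coord = integer(0), role = character(0)))
    df <- do.call(rbind, lapply(sites, site_node))
    df[order(df$coord), , drop = FALSE]
  })
  path_nodes <- lapply(int_nodes, function(int) {
    nodes <- rbind(fl, int, fr)
    nodes[order(nodes$coord), , drop = FALSE]
  })
  jI <- junctions_of_nodes(path_nodes[[1L]], chrom)
  jE <- junctions_of_nodes(path_nodes[[2L]], chrom)
  common <- intersect(jI, jE)
  jI <- setdiff(jI, common); jE <- setdiff(jE, common)
  terminal_l <- is.null(fl); terminal_r <- is.null(fr)
  cls <- classify_event_chains(
    int_nodes[[1L]], int_nodes[[2L]], strand,
    terminal_l = terminal_l, terminal_r = terminal_r)
  retained_key <- if (cls == "retintron" && length(jI) == 1L) jI else NA_character_
  data.frame(
    event_id = sprintf("%s.ast%d", gene_id, line_no),
    gene_id = gene_id, chrom = chrom, strand = strand,
    event_type = cls, structure_code = structure,
    flank_left = if (terminal_l) -Inf else fl$coord,
    flank_right = if (terminal_r) Inf else fr$coord,
    is_internal = !(terminal_l || terminal_r),
    inc_tx = paste(sort(txs[[1L]]), collapse = ";"),
    exc_tx = paste(sort(txs[[2L]]), collapse = ";"),
    inc_junc = paste(jI, collapse = ";"),
    exc_junc = paste(jE, collapse = ";"),
    retained_key = retained_key,
    stringsAsFactors = FALSE)
}

#' Write events in the AStalavista-style dialect
#'
#' Renders a [enumerate_events()] table in the event-GTF dialect read by
#' [parse_astalavista()], mainly for interoperability tests.
#'
#' @param events a `"splicing_events"` data.frame
#' @param ann the matching [annotation]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_astalavista <- function(events, ann, path) {
  lines <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    strand <- ev$strand
    # reconstruct interior chains from the junction sets and flanks
    int_chain <- function(jkeys_s) {
      keys <- if (nzchar(jkeys_s)) strsplit(jkeys_s, ";", fixed = TRUE)[[1L]] else character(0)
      if (length(keys) == 0L) return("")
      m <- regmatches(keys, regexec("^(.+):(\\d+)-(\\d+)$", keys))
      don <- as.integer(vapply(m, `[`, "", 3L)) - 1L  # exon end before intron
      acc <- as.integer(vapply(m, `[`, "", 4L)) + 1L  # exon start after intron
      sites <- data.frame(coord = c(don, acc),
                          role = rep(c("d", "a"), each = length(keys)))
      keep <- !(sites$coord %in% c(ev$flank_left, ev$flank_right))
      sites <- sites[keep, , drop = FALSE]
      o <- orient_nodes(sites[order(sites$coord), , drop = FALSE], strand)
      paste0(o$coord, o$sym, collapse = "")
    }
    flank_tok <- function(coord, role) {
      if (!is.finite(coord)) return("null")
      sym <- if (strand == "+") c(d = "^", a = "-")[[role]]
             else c(d = "-", a = "^")[[role]]
      paste0(coord, sym)
    }
    # flank roles: left flank of a bubble is donor-side (exon end) unless it
    # is an exon start shared by both paths; infer from junction sets
    infer_role <- function(coord, side) {
      keys <- c(strsplit(ev$inc_junc, ";", fixed = TRUE)[[1L]],
                strsplit(ev$exc_junc, ";", fixed = TRUE)[[1L]])
      keys <- keys[nzchar(keys)]
      m <- regmatches(keys, regexec("^(.+):(\\d+)-(\\d+)$", keys))
      don <- as.integer(vapply(m, `[`, "", 3L)) - 1L
      acc <- as.integer(vapply(m, `[`, "", 4L)) + 1L
      # a flank in no event junction is an exon-interior boundary: exon
      # start on the left, exon end on the right
      if (coord %in% don) "d" else if (coord %in% acc) "a"
      else if (side == "l") "a" else "d"
    }
    tok_l <- flank_tok(ev$flank_left,
                       if (is.finite(ev$flank_left)) infer_role(ev$flank_left, "l") else "d")
    tok_r <- flank_tok(ev$flank_right,
                       if (is.finite(ev$flank_right)) infer_role(ev$flank_right, "r") else "a")
    flanks <- if (strand == "+") c(tok_l, tok_r) else c(tok_r, tok_l)
    span <- range(c(ev$flank_left, ev$flank_right)[is.finite(c(ev$flank_left, ev$flank_right))],
                  na.rm = TRUE)
    attrs <- sprintf('gene_id "%s"; transcript_id "%s/%s"; flanks "%s,%s"; splice_chain "%s/%s"; structure "%s";',
                     ev$gene_id, gsub(";", ",", ev$inc_tx), gsub(";", ",", ev$exc_tx),
                     flanks[1L], flanks[2L],
                     int_chain(ev$inc_junc), int_chain(ev$exc_junc),
                     ev$structure_code)
    lines[i] <- paste(ev$chrom, "spliceward", "as_event",
                      span[1L], span[2L], ".", strand, ".", attrs, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
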