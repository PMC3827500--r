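# shared fixtures, built once per test run and memoized

.fx_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fx_cache, inherits = FALSE))
    assign(name, expr, envir = .fx_cache)
  get(name, envir = .fx_cache, inherits = FALSE)
}

toy <- function() cached("toy",
  make_toy_fixture(fixture_config(n_genes = 10, decoys = TRUE), seed = 5))

toy_sim <- function() cached("toy_sim",
  simulate_reads(toy()$annotation, toy()$genome,
                 sim_config(coverage = 10, seed = 3)))

toy_truth_sam <- function() cached("toy_truth_sam", {
  path <- tempfile(fileext = ".sam")
  write_sam(truth_sam_records(toy_sim()), toy_sim()$chrom_lengths, path)
  path
})

toy_stats <- function() cached("toy_stats",
  junction_stats(toy_truth_sam(), toy()$annotation, toy()$genome))

# truth reads mixed with planted decoy alignments, qualitatively filtered
mixed_stats <- function() cached("mixed_stats", {
  dec <- decoy_alignments(toy(), n_per = 12, seed = 9)
  rec <- data.table::rbindlist(list(truth_sam_records(toy_sim()), dec),
                               fill = TRUE)
  sam <- tempfile(fileext = ".sam")
  write_sam(rec, toy_sim()$chrom_lengths, sam)
  apply_filters(junction_stats(sam, toy()$annotation, toy()$genome),
                "qualitative")
})

decoy_keys <- function() {
  dk <- toy()$manifest$decoys
  setNames(junction_key(dk$chrom, dk$start, dk$end), dk$kind)
}

# quick annotation builder: rows = list(list(tx, starts, ends, strand), ...)
tiny_ann <- function(rows, chrom = "c", gene = "g") {
  annotation(do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = chrom, start = r[[2]], end = r[[3]], strand = r[[4]],
               gene_id = if (length(r) >= 5) r[[5]] else gene,
               transcript_id = r[[1]], stringsAsFactors = FALSE))))
}

# independent two-sided FET oracle: exhaustive hypergeometric enumeration
oracle_fet <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  k <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(k, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# quantify one pool against an annotation+events via its truth alignments
quantify_pool <- function(sim, ann, genome, events, filter = "qualitative") {
  sam <- tempfile(fileext = ".sam")
  write_sam(truth_sam_records(sim), sim$chrom_lengths, sam)
  st <- apply_filters(junction_stats(sam, ann, genome), filter)
  quantify_events(events, st[st$pass, , drop = FALSE])
}
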