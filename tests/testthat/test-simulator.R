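test_that("pair counts follow the coverage and RPK definitions", {
  g <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 500)))  # 2 kb
  ann <- tiny_ann(list(list("t1", 1, 1000, "+")), chrom = "c1")
  sim <- simulate_reads(ann, g, sim_config(coverage = 10, seed = 1,
                                           error_model = NULL))
  # coverage X: round(X * len / (2L)) = round(10 * 1000 / 152) = 66
  expect_equal(nrow(sim$pairs), 66L)

  sim_rpk <- simulate_reads(ann, g, sim_config(rpk = 300, seed = 1,
                                               error_model = NULL))
  expect_equal(nrow(sim_rpk$pairs), 300L)   # round(300 * 1.0 kb)
})

test_that("same config and seed reproduce byte-identical output", {
  fx <- toy()
  cfg <- sim_config(coverage = 5, seed = 77)
  s1 <- simulate_reads(fx$annotation, fx$genome, cfg)
  s2 <- simulate_reads(fx$annotation, fx$genome, cfg)
  expect_identical(s1$mates$seq, s2$mates$seq)
  expect_identical(s1$mates$qual, s2$mates$qual)
  expect_identical(s1$pairs, s2$pairs)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- write_sim(s1, d1); f2 <- write_sim(s2, d2)
  expect_identical(readLines(f1[["fastq1"]]), readLines(f2[["fastq1"]]))
  expect_identical(readLines(f1[["truth_sam"]]), readLines(f2[["truth_sam"]]))
})

test_that("zero intron retention never yields intron-overlapping truth reads", {
  # constitutive genes only: with alternative isoforms one isoform's exon
  # can legitimately cover another's intron
  fx <- make_toy_fixture(fixture_config(n_genes = 6, event_mix = numeric(0)),
                         seed = 3)
  sim <- simulate_reads(fx$annotation, fx$genome,
                        sim_config(coverage = 5, seed = 2,
                                   intron_retention = 0, error_model = NULL))
  expect_true(all(sim$pairs$kind == "S"))
  jt <- fx$annotation$junctions
  introns <- GenomicRanges::GRanges(jt$chrom, IRanges::IRanges(jt$start, jt$end))
  bl <- sim$blocks
  blocks <- GenomicRanges::GRanges("chrS", IRanges::IRanges(bl$start, bl$end))
  expect_equal(sum(GenomicRanges::countOverlaps(blocks, introns)), 0L)
})

test_that("origin encoding round-trips and ids are unique", {
  b1 <- list(list(starts = c(150L), ends = c(189L)))
  b2 <- list(list(starts = c(150L, 250L), ends = c(189L, 285L)))
  id <- encode_origin("txA", "S", "chr1", b2, b1, 17L)
  dec <- decode_origin(id)
  expect_equal(dec$transcript_id, "txA")
  expect_equal(dec$kind, "S")
  expect_equal(dec$blocks1[[1]], list(starts = c(150L, 250L), ends = c(189L, 285L)))
  expect_equal(dec$blocks2[[1]], list(starts = 150L, ends = 189L))
  expect_equal(dec$serial, 17L)
  # a junction-spanning mate implies the intron between its blocks
  expect_equal(dec$blocks1[[1]]$ends[1] + 1L, 190L)
  expect_equal(dec$blocks1[[1]]$starts[2] - 1L, 249L)
  expect_error(decode_origin("not|an|id"), "malformed")

  sim <- toy_sim()
  expect_false(anyDuplicated(sim$pairs$pair_id) > 0)
  dec_all <- decode_origin(sim$pairs$pair_id[1:50])
  expect_equal(dec_all$transcript_id, sim$pairs$transcript_id[1:50])
})

test_that("truth junction coverage counts spanning reads with anchors", {
  # constructed pool: 17 spanning mates over one junction
  sim <- toy_sim()
  tr <- truth_junction_coverage(sim, min_overhang = 8)
  # recompute independently from decoded read ids
  dec <- decode_origin(sim$pairs$pair_id)
  count <- 0L
  for (bl in c(dec$blocks1, dec$blocks2)) {
    if (length(bl$starts) < 2L) next
    w <- bl$ends - bl$starts + 1L
    for (k in seq_len(length(bl$starts) - 1L)) {
      if (w[k] >= 8 && w[k + 1] >= 8 &&
          bl$starts[k + 1] - bl$ends[k] - 1L >= 42) count <- count + 1L
    }
  }
  expect_equal(sum(tr$truth_count), count)
  # truth SAM quantification agrees exactly with the truth table
  st <- toy_stats()
  mrg <- merge(st[st$coverage > 0, ], tr, by = "key")
  expect_equal(nrow(mrg), nrow(tr))
  expect_equal(mrg$coverage, mrg$truth_count)
})

test_that("per-transcript truth counts conserve the simulated pairs", {
  sim <- toy_sim()
  expect_equal(sum(sim$transcript_counts$n_pairs), nrow(sim$pairs))
  files <- write_sim(sim, tempfile())
  fq1 <- readLines(files[["fastq1"]])
  expect_equal(length(fq1) / 4L, nrow(sim$pairs))
  sam <- readLines(files[["truth_sam"]])
  expect_equal(sum(!startsWith(sam, "@")), 2L * nrow(sim$pairs))
})

test_that("fragment model and intron retention match their settings", {
  g <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 2000)))
  ann <- tiny_ann(list(list("t1", 1, 6000, "+")), chrom = "c1")
  sim <- simulate_reads(ann, g, sim_config(rpk = 2500, seed = 5,
                                           error_model = NULL))
  n <- nrow(sim$pairs)
  expect_gte(n, 10000L)
  expect_lt(abs(mean(sim$pairs$frag_len) - 200), 3 * 20 / sqrt(n))
  expect_lt(abs(sd(sim$pairs$frag_len) - 20), 1.5)
  frac_u <- mean(sim$pairs$kind == "U")
  expect_lt(abs(frac_u - 0.20), 3 * sqrt(0.2 * 0.8 / n))
})

test_that("mate geometry: mate2 is the fragment 3' end, reverse complement", {
  g <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 500)))
  ann <- tiny_ann(list(list("t1", 1, 2000, "+")), chrom = "c1")
  sim <- simulate_reads(ann, g, sim_config(coverage = 2, seed = 9,
                                           intron_retention = 0,
                                           error_model = NULL))
  tmpl <- as.character(g[["c1"]])[1]
  tmpl <- substr(tmpl, 1, 2000)
  p <- sim$pairs[1, ]
  m1 <- sim$mates[sim$mates$mate == 1][1, ]
  m2 <- sim$mates[sim$mates$mate == 2][1, ]
  expect_equal(m1$read_seq, substr(tmpl, p$template_start, p$template_start + 75))
  frag_end <- p$template_start + p$frag_len - 1L
  expect_equal(m2$read_seq,
               as.character(Biostrings::reverseComplement(Biostrings::DNAString(
                 substr(tmpl, frag_end - 75L, frag_end)))))
  expect_equal(abs(m1$tlen), p$frag_len)
})

test_that("designed delta-PSI pools and null pools enforce preconditions", {
  fx <- toy()
  ev <- enumerate_events(fx$annotation)
  expect_error(simulate_delta_psi(fx$annotation, fx$genome, ev,
                                  psi_a = 1.0, psi_b = 0.5),
               "strictly inside")
  dup_ev <- rbind(ev, ev)
  expect_error(simulate_delta_psi(fx$annotation, fx$genome, dup_ev,
                                  psi_a = 0.25, psi_b = 0.75),
               "cross-talk")
  pools <- simulate_null_pools(fx$annotation, fx$genome, rpk = 50,
                               n_pools = 2, seeds = c(3, 4),
                               error_model = NULL)
  expect_length(pools, 2L)
  expect_false(identical(pools[[1]]$mates$seq, pools[[2]]$mates$seq))
  # equal RPK: per-transcript pair counts match round(rpk * kb) in each pool
  for (p in pools) {
    tc <- merge(p$transcript_counts, fx$annotation$transcripts,
                by = "transcript_id")
    expect_equal(tc$n_pairs, round(50 * tc$exonic_len / 1000))
  }
})

test_that("transcripts shorter than the read length are skipped with warning", {
  g <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 300)))
  ann <- tiny_ann(list(list("t1", 1, 50, "+"), list("t2", 1, 1000, "+")),
                  chrom = "c1")
  expect_warning(
    sim <- simulate_reads(ann, g, sim_config(coverage = 5, seed = 1,
                                             error_model = NULL)),
    "shorter than read length")
  expect_equal(unique(sim$pairs$transcript_id), "t2")
})
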