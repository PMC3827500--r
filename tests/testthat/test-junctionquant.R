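# one-chromosome genome whose sequence is all A except planted motifs
plain_genome <- function(len = 2000L) {
  Biostrings::DNAStringSet(c(c1 = strrep("A", len)))
}

sam_with <- function(records, len = 2000L) {
  path <- tempfile(fileext = ".sam")
  write_sam(records, c(c1 = len), path)
  path
}

gapped <- function(qname, pos, cigar, len = 76L) {
  data.frame(qname = qname, flag = 0L, chrom = "c1", pos = pos, mapq = 50L,
             cigar = cigar, seq = strrep("A", len), qual = strrep("I", len),
             stringsAsFactors = FALSE)
}

test_that("alignment gaps become junction observations with anchors", {
  # blocks 101..150 and 251..300: intron occupies 151..250, left anchor 50
  sam <- sam_with(gapped("r1", 101L, "50M100N26M"))
  obs <- extract_spliced_alignments(sam, min_overhang = 8)
  expect_equal(nrow(obs), 1L)
  expect_equal(obs$start, 151L)
  expect_equal(obs$end, 250L)
  expect_equal(obs$left, 50L)
  expect_equal(obs$right, 26L)

  # short anchor discarded under the overhang requirement
  sam2 <- sam_with(gapped("r2", 146L, "5M100N71M"))
  expect_equal(nrow(extract_spliced_alignments(sam2, min_overhang = 8)), 0L)
  expect_equal(nrow(extract_spliced_alignments(sam2, min_overhang = 5)), 1L)

  # a two-gap read contributes two observations with interior anchors
  sam3 <- sam_with(gapped("r3", 101L, "20M100N26M150N30M"))
  obs3 <- extract_spliced_alignments(sam3, min_overhang = 8)
  expect_equal(nrow(obs3), 2L)
  expect_equal(obs3$start, c(121L, 247L))
  expect_equal(obs3$left, c(20L, 26L))
  expect_equal(obs3$right, c(26L, 30L))

  # gaps below the minimum intron length are not junctions
  sam4 <- sam_with(gapped("r4", 101L, "38M30N38M"))
  expect_equal(nrow(extract_spliced_alignments(sam4)), 0L)
})

test_that("offset entropy follows the Shannon definition", {
  expect_equal(offset_entropy(rep(12L, 40)), 0)
  expect_equal(offset_entropy(c(1L, 2L, 3L, 4L)), 2)
  expect_equal(offset_entropy(c(5L, 5L, 9L, 13L)), 1.5)   # counts {2,1,1}
  # scale invariance and the distinct-offset upper bound
  o <- c(1L, 1L, 2L, 7L, 7L, 7L, 30L)
  expect_equal(offset_entropy(rep(o, 3L)), offset_entropy(o))
  expect_lte(offset_entropy(o), log2(length(unique(o))))
  # fewer than four equally weighted offsets can never reach 2 bits
  expect_lt(offset_entropy(1:3), 2)
  expect_error(offset_entropy(integer(0)), "undefined")
})

test_that("MMES is the max over reads of per-read min anchor", {
  expect_equal(mmes(50L, 26L), 26L)
  expect_equal(mmes(c(8L, 60L, 14L), c(30L, 20L, 70L)), 20L)
  expect_equal(mmes(10L, 10L), 10L)
})

test_that("repeat identity compares shoulder windows by edit distance", {
  # windows: 10bp upstream of donor vs upstream of acceptor (donor side),
  # 10bp downstream of each (acceptor side)
  up <- "GATTACAGGT"
  dn <- "CCGGTTAACC"
  # layout: up at 91..100, dn at 101..110, filler, up at 131..140,
  # dn at 141..150; junction intron = 101..140 so both window pairs match
  s <- paste0(strrep("A", 90), up, dn, strrep("C", 20), up, dn, strrep("T", 50))
  g <- Biostrings::DNAStringSet(c(c1 = s))
  start <- 101L
  end <- 140L
  ri <- repeat_identity(g, "c1", start, end)
  expect_equal(ri$donor_side, 100)
  expect_equal(ri$acceptor_side, 100)

  # two substitutions in ten positions -> 80%
  up2 <- "GATTACAGGT"; up2_mut <- "GTTTACAGGA"
  s2 <- paste0(strrep("A", 90), up2, strrep("C", 30), up2_mut, strrep("G", 60))
  g2 <- Biostrings::DNAStringSet(c(c1 = s2))
  ri2 <- repeat_identity(g2, "c1", 101L, 140L)
  expect_equal(ri2$donor_side, 80)

  # dissimilar windows score low
  s3 <- paste0(strrep("A", 100), strrep("C", 39), "G", strrep("T", 60))
  ri3 <- repeat_identity(Biostrings::DNAStringSet(c(c1 = s3)), "c1", 101L, 140L)
  expect_lte(ri3$donor_side, 10)
})

test_that("strand inference follows the motif precedence table", {
  tab <- infer_strand(
    c("GT", "GC", "AT", "CT", "CT", "GT", "AA"),
    c("AG", "AG", "AC", "AC", "GC", "AT", "TT"))
  expect_equal(tab$strand, c("+", "+", "+", "-", "-", "-", "*"))
  expect_equal(tab$motif_class,
               c("GT-AG", "GC-AG", "AT-AC", "GT-AG", "GC-AG", "AT-AC", "other"))
})

test_that("gene assignment requires agreement of both ends", {
  fx <- toy()
  st <- toy_stats()
  ann_j <- fx$annotation$junctions
  hit <- st[st$annotated & st$coverage > 0, ]
  expect_true(all(hit$gene_assignment ==
                  ann_j$gene_id[match(hit$key, ann_j$key)]))
  # junction joining two different genes -> ambiguous
  dk <- decoy_keys()
  ms <- mixed_stats()
  expect_equal(ms$gene_assignment[ms$key == dk[["paralog_join"]]], "ambiguous")
  # wrong inferred strand inside a '+' gene -> no compatible gene
  expect_true(ms$gene_assignment[ms$key == dk[["wrong_strand"]]]
              %in% c("ambiguous", "unassigned"))
})

test_that("intron read-through counts boundary-spanning ungapped reads", {
  # junction with intron 151..250; ungapped reads across the left boundary
  recs <- rbind(
    gapped("sp", 101L, "50M100N26M"),
    gapped("rt1", 120L, "76M"),     # covers 151-o..151+o-1 for o=8
    gapped("rt2", 144L, "76M"),     # starts at 144 <= 143? no: see below
    gapped("no", 152L, "76M"))      # starts inside the intron
  sam <- sam_with(recs)
  juncs <- data.frame(chrom = "c1", start = 151L, end = 250L)
  rt <- intron_readthrough(sam, juncs, min_overhang = 8)
  # left window is 143..158: rt1 (120..195) covers it; rt2 (144..219) does
  # not reach 143; "no" misses it
  expect_equal(rt$rt_left, 1L)
  # right window is 243..258: rt2 (144..219) no, "no" (152..227) no
  expect_equal(rt$rt_right, 0L)

  # read ending exactly at the boundary with overhang o-1 is not counted
  recs2 <- rbind(gapped("edge", 136L, "76M"))   # covers 136..211? ends 211
  sam2 <- sam_with(rbind(recs2, gapped("x", 144L, "7M200N69M"))) # keep SAM nonempty
  rt2 <- intron_readthrough(sam2, data.frame(chrom = "c1", start = 204L,
                                             end = 290L), min_overhang = 8)
  # left window 196..211: read 136..211 covers it exactly; with start 205
  # the window 197..212 would not be covered
  expect_equal(rt2$rt_left, 1L)
  rt3 <- intron_readthrough(sam2, data.frame(chrom = "c1", start = 205L,
                                             end = 290L), min_overhang = 8)
  expect_equal(rt3$rt_left, 0L)
})

test_that("filters flag the diagnosed error classes and spare true junctions", {
  ms <- mixed_stats()
  dk <- decoy_keys()
  flags <- ms[match(dk, ms$key), ]
  expect_true(flags$ambiguous_gene[flags$key == dk[["wrong_strand"]]])
  expect_true(flags$minor_unannotated[flags$key == dk[["minor_form"]]])
  expect_true(flags$repeat_like[flags$key == dk[["repeat_induced"]]])
  expect_true(flags$ambiguous_gene[flags$key == dk[["paralog_join"]]])
  expect_false(any(flags$pass))
  expect_true(all(ms$pass[ms$annotated]))

  # filtering is non-destructive: coverage identical pre/post
  st <- junction_stats(toy_truth_sam(), toy()$annotation, toy()$genome)
  stf <- apply_filters(st, "both")
  expect_equal(stf$coverage, st$coverage)

  # quantitative mode keys on entropy alone
  stq <- apply_filters(st, "quantitative", min_entropy = 2)
  expect_equal(stq$pass, !(!is.na(st$entropy) & st$entropy < 2))
  stn <- apply_filters(st, "none")
  expect_true(all(stn$pass))
})

test_that("coverage is conserved from observations to the junction table", {
  obs <- extract_spliced_alignments(toy_truth_sam())
  st <- toy_stats()
  expect_equal(sum(st$coverage), nrow(obs))
  expect_true(all(st$coverage[match(unique(obs$key), st$key)] > 0))
  # entropy bounds on every detected junction
  det <- st[st$coverage > 0, ]
  expect_true(all(det$entropy >= 0 & det$entropy <= log2(pmax(det$n_offsets, 1)) + 1e-9))
  expect_true(all((det$entropy == 0) == (det$n_offsets == 1)))
})

test_that("truth evaluation classifies planted error classes and FN causes", {
  ms <- mixed_stats()
  tr <- truth_junction_coverage(toy_sim())
  evt <- evaluate_vs_truth(ms, tr, toy()$annotation)
  dk <- decoy_keys()
  got <- setNames(evt$fp$class[match(dk, evt$fp$key)], names(dk))
  expect_equal(unname(got[c("wrong_strand", "minor_form",
                            "repeat_induced", "paralog_join")]),
               c("incorrect_strand", "minor_form",
                 "repeat_induced", "paralog_join"))
  # perfect detection: no false positives beyond the planted decoys
  expect_setequal(evt$fp$key, unname(dk))
  # annotated junctions without any generated spanning read are FN-sampling
  missed <- evt$fn
  if (nrow(missed))
    expect_true(all(missed$class[!missed$key %in% tr$key] == "sampling"))
  expect_error(evaluate_vs_truth(ms, NULL, toy()$annotation), "truth")
})
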