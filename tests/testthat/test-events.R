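test_that("splice graph maps transcripts to coordinate-ordered node paths", {
  ann <- tiny_ann(list(list("t1", c(1, 201, 401), c(100, 300, 500), "+")))
  g <- build_splice_graph(ann, "g")
  expect_equal(nrow(g$nodes), 6L)
  expect_equal(g$paths[["t1"]]$role, c("L", "d", "a", "d", "a", "R"))
  # duplicate transcript adds nothing
  ann2 <- tiny_ann(list(list("t1", c(1, 201, 401), c(100, 300, 500), "+"),
                        list("t2", c(1, 201, 401), c(100, 300, 500), "+")))
  g2 <- build_splice_graph(ann2, "g")
  expect_equal(g2$nodes, g$nodes)
  expect_equal(nrow(enumerate_events(ann2)), 0L)
  # mixed strands within a gene are rejected
  expect_error(build_splice_graph(tiny_ann(list(
    list("t1", 1, 100, "+"), list("t2", 1, 100, "-"))), "g"), "mixed strands")
})

test_that("the cassette exon is enumerated with its canonical junction sets", {
  ann <- tiny_ann(list(
    list("t1", c(1, 201, 401), c(100, 300, 500), "+"),
    list("t2", c(1, 401), c(100, 500), "+")))
  ev <- enumerate_events(ann)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "exonskip")
  expect_equal(ev$structure_code, "1-2^,0")
  expect_setequal(strsplit(ev$inc_junc, ";")[[1]],
                  c("c:101-200", "c:301-400"))
  expect_equal(ev$exc_junc, "c:101-400")
  expect_true(ev$is_internal)
  expect_equal(ev$inc_tx, "t1")
  expect_equal(ev$exc_tx, "t2")
})

test_that("event types classify by their interior splice-site patterns", {
  # two skipped exons
  sk2 <- enumerate_events(tiny_ann(list(
    list("t1", c(1, 201, 401, 601), c(100, 300, 500, 700), "+"),
    list("t2", c(1, 601), c(100, 700), "+"))))
  expect_equal(sk2$event_type, "skip2exons")
  expect_equal(sk2$structure_code, "1-2^3-4^,0")

  # retained intron: spliced form is the inclusion path, exclusion has no
  # junction and is quantified by read-through
  ri <- enumerate_events(tiny_ann(list(
    list("t1", c(1, 201), c(100, 300), "+"),
    list("t2", 1, 300, "+"))))
  expect_equal(ri$event_type, "retintron")
  expect_equal(ri$inc_junc, "c:101-200")
  expect_equal(ri$exc_junc, "")
  expect_equal(ri$retained_key, "c:101-200")

  # mutually exclusive exons
  mx <- enumerate_events(tiny_ann(list(
    list("t1", c(1, 201, 601), c(100, 300, 700), "+"),
    list("t2", c(1, 401, 601), c(100, 500, 700), "+"))))
  expect_equal(mx$event_type, "mutexcl")

  # alternative donor and acceptor in one bubble
  da <- enumerate_events(tiny_ann(list(
    list("t1", c(1, 201), c(100, 300), "+"),
    list("t2", c(1, 231), c(130, 300), "+"))))
  expect_equal(da$event_type, "altda")

  # strand-awareness: moving an exon start genomically is an alternative
  # donor on the minus strand
  ad_minus <- enumerate_events(tiny_ann(list(
    list("t1", c(1, 201), c(100, 300), "-"),
    list("t2", c(1, 226), c(100, 300), "-"))))
  expect_equal(ad_minus$event_type, "altdonor")
  ad_plus <- enumerate_events(tiny_ann(list(
    list("t1", c(1, 201), c(100, 300), "+"),
    list("t2", c(1, 226), c(100, 300), "+"))))
  expect_equal(ad_plus$event_type, "altacceptor")
})

test_that("first exons differing only in their 5' ends yield no event", {
  ann <- tiny_ann(list(
    list("t1", c(1, 201), c(100, 300), "+"),
    list("t2", c(40, 201), c(100, 300), "+")))
  expect_equal(nrow(enumerate_events(ann)), 0L)
  # but alternative first exons with different donors do
  afe <- enumerate_events(tiny_ann(list(
    list("t1", c(1, 401), c(100, 500), "+"),
    list("t2", c(181, 401), c(280, 500), "+"))))
  expect_equal(afe$event_type, "AltFE")
  expect_false(afe$is_internal)
})

test_that("enumeration recovers exactly the planted fixture events", {
  for (s in c(5, 21)) {
    fx <- make_toy_fixture(fixture_config(n_genes = 14, decoys = FALSE),
                           seed = s)
    ev <- enumerate_events(fx$annotation)
    m <- fx$manifest$events
    expect_equal(nrow(ev), nrow(m))
    got <- ev$event_type[match(m$gene_id, ev$gene_id)]
    expect_equal(got, m$type)
  }
})

test_that("event junction sets are disjoint and within the flanks", {
  ev <- enumerate_events(toy()$annotation)
  for (i in seq_len(nrow(ev))) {
    jI <- strsplit(ev$inc_junc[i], ";")[[1]]
    jE <- strsplit(ev$exc_junc[i], ";")[[1]]
    jI <- jI[nzchar(jI)]; jE <- jE[nzchar(jE)]
    expect_length(intersect(jI, jE), 0L)
    coords <- as.integer(unlist(regmatches(c(jI, jE),
                                           gregexpr("\\d+", c(jI, jE)))))
    coords <- coords[coords > 1000]   # strip the chrom-name-free parts
    expect_true(all(coords >= ev$flank_left[i] & coords <= ev$flank_right[i]))
  }
})

test_that("PSI follows the reads-per-junction formula", {
  ann <- tiny_ann(list(
    list("t1", c(1, 201, 401), c(100, 300, 500), "+"),
    list("t2", c(1, 401), c(100, 500), "+")))
  ev <- enumerate_events(ann)
  stats <- data.frame(key = c("c:101-200", "c:301-400", "c:101-400"),
                      chrom = "c", start = c(101L, 301L, 101L),
                      end = c(200L, 400L, 400L),
                      coverage = c(14L, 16L, 5L),
                      rt_left = 0L, rt_right = 0L)
  q <- quantify_events(ev, stats)
  # inc 30 reads over 2 junctions, exc 5 over 1: 15 / (15 + 5) = 0.75
  expect_equal(q$psi, 0.75)
  expect_equal(q$inc_total, 30L)
  expect_equal(q$exc_total, 5L)

  # symmetric coverage gives PSI 0.5; zero exclusion gives PSI 1
  stats$coverage <- c(10L, 10L, 10L)
  expect_equal(quantify_events(ev, stats)$psi, 0.5)
  stats$coverage <- c(10L, 10L, 0L)
  expect_equal(quantify_events(ev, stats)$psi, 1)
  # both paths silent: undefined
  stats$coverage <- c(0L, 0L, 0L)
  expect_true(is.na(quantify_events(ev, stats)$psi))
})

test_that("retained-intron exclusion uses mean read-through as its denominator", {
  ann <- tiny_ann(list(
    list("t1", c(1, 201), c(100, 300), "+"),
    list("t2", 1, 300, "+")))
  ev <- enumerate_events(ann)
  stats <- data.frame(key = "c:101-200", chrom = "c", start = 101L,
                      end = 200L, coverage = 30L,
                      rt_left = 8L, rt_right = 12L)
  q <- quantify_events(ev, stats)
  # inc rpj 30, exc rpj mean(8, 12) = 10 -> 30 / 40
  expect_equal(q$psi, 0.75)
  expect_equal(q$exc_total, 10L)
})

test_that("neighbor confounding totals joins escaping the event flanks", {
  ann <- tiny_ann(list(
    list("t1", c(1, 201, 401), c(100, 300, 500), "+"),
    list("t2", c(1, 401), c(100, 500), "+")))
  ev <- enumerate_events(ann)
  # planted extra junction from the cassette exon to a distal acceptor
  stats <- data.frame(
    key = c("c:101-200", "c:301-400", "c:101-400", "c:301-700"),
    chrom = "c", start = c(101L, 301L, 101L, 301L),
    end = c(200L, 400L, 400L, 700L),
    coverage = c(10L, 10L, 10L, 7L), rt_left = 0L, rt_right = 0L)
  q <- quantify_events(ev, stats)
  expect_equal(q$neighbor_coverage, 7L)
  # an isolated event reports zero
  q0 <- quantify_events(ev, stats[1:3, ])
  expect_equal(q0$neighbor_coverage, 0L)
})

test_that("PSI swap symmetry and bounds hold across fixture quantifications", {
  fx <- toy()
  ev <- enumerate_events(fx$annotation)
  st <- toy_stats()
  q <- quantify_events(ev, st)
  defined <- !is.na(q$psi)
  expect_true(all(q$psi[defined] >= 0 & q$psi[defined] <= 1))
  # swapping the two paths complements PSI
  swapped <- ev
  swapped$inc_junc <- ev$exc_junc
  swapped$exc_junc <- ev$inc_junc
  swapped$retained_key <- NA_character_
  both <- !is.na(ev$retained_key)
  qs <- quantify_events(swapped[!both, ], st)
  expect_equal(qs$psi, 1 - q$psi[!both], tolerance = 1e-12)
})

test_that("the AStalavista dialect parses to the native representation", {
  fx <- make_toy_fixture(fixture_config(n_genes = 14), seed = 11)
  ev <- enumerate_events(fx$annotation)
  f <- tempfile(fileext = ".gtf")
  write_astalavista(ev, fx$annotation, f)
  ev2 <- parse_astalavista(f, fx$annotation)
  ord <- order(ev$gene_id, ev$flank_left, ev$structure_code)
  ord2 <- order(ev2$gene_id, ev2$flank_left, ev2$structure_code)
  for (col in c("event_type", "inc_junc", "exc_junc", "flank_left",
                "flank_right", "retained_key", "is_internal"))
    expect_equal(ev2[[col]][ord2], ev[[col]][ord])

  # a hand-written cassette-exon record parses to the canonical event
  hand <- tempfile(fileext = ".gtf")
  writeLines(paste("c", "x", "as_event", 100, 401, ".", "+", ".",
                   paste0('gene_id "g"; transcript_id "t1/t2"; ',
                          'flanks "100^,401-"; splice_chain "201-300^/"; ',
                          'structure "1-2^,0";'), sep = "\t"), hand)
  ann <- tiny_ann(list(
    list("t1", c(1, 201, 401), c(100, 300, 500), "+"),
    list("t2", c(1, 401), c(100, 500), "+")))
  pe <- parse_astalavista(hand, ann)
  expect_equal(pe$event_type, "exonskip")
  expect_setequal(strsplit(pe$inc_junc, ";")[[1]], c("c:101-200", "c:301-400"))
  expect_equal(pe$exc_junc, "c:101-400")

  # unknown transcripts and malformed chains become record errors
  bad <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("c", "x", "as_event", 100, 401, ".", "+", ".",
          'gene_id "g"; transcript_id "tX/t2"; flanks "100^,401-"; splice_chain "201-300^/"; structure "1-2^,0";',
          sep = "\t"),
    paste("c", "x", "as_event", 100, 401, ".", "+", ".",
          'gene_id "g"; transcript_id "t1/t2"; flanks "100^,401-"; splice_chain "@bad/"; structure "1-2^,0";',
          sep = "\t")), bad)
  expect_warning(pb <- parse_astalavista(bad, ann), "could not be parsed")
  expect_equal(nrow(pb), 0L)
  expect_equal(nrow(attr(pb, "errors")), 2L)

  # empty file -> empty event list
  empty <- tempfile(); writeLines(character(0), empty)
  expect_equal(nrow(parse_astalavista(empty, ann)), 0L)
})
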