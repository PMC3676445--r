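test_that("junctions come from gaps of unique reads with full anchors", {
  recs <- make_records(list(
    list(qname = "r1", chrom = "chr1", blocks = c(0, 50, 250, 300)),
    list(qname = "r2", chrom = "chr1", blocks = c(10, 50, 250, 310)),
    list(qname = "short_anchor", chrom = "chr1", blocks = c(45, 50, 250, 300)),
    list(qname = "m", chrom = "chr1", blocks = c(0, 50, 250, 300),
         mult = "multi"),
    list(qname = "plain", chrom = "chr1", blocks = c(400, 490))),
    c(chr1 = 1000L))
  jn <- extract_junctions(recs)
  expect_equal(nrow(jn), 1L)
  expect_equal(jn$donor, 50L)
  expect_equal(jn$acceptor, 250L)
  expect_equal(jn$support, 2L)  # r1 + r2; short anchor and multi excluded
  expect_equal(nrow(extract_junctions(recs[recs$qname == "plain", ])), 0L)
})

test_that("junctions are assigned to genes containing both boundaries", {
  ann <- toy_annotation(list(id = "g1", exons = c(100, 200, 400, 500)),
                        list(id = "g2", exons = c(450, 600, 800, 900)),
                        list(id = "far", exons = c(5000, 6000)))
  jn <- data.frame(chrom = "chr1",
                   donor = c(200L, 2000L, 455L),
                   acceptor = c(400L, 2400L, 495L),
                   support = 5L)
  asg <- assign_junctions_to_genes(jn, ann)
  expect_equal(asg$gene_id[asg$donor == 200], "g1")
  expect_false(any(asg$donor == 2000))  # intergenic junction dropped
  both <- asg[asg$donor == 455, ]       # inside both overlapping spans
  expect_setequal(both$gene_id, c("g1", "g2"))
  expect_true(all(both$ambiguous))
})

test_that("shared-boundary junction pairs get strand-aware labels", {
  jn <- data.frame(chrom = "chr1", donor = c(100L, 100L),
                   acceptor = c(500L, 600L), support = 5L)
  plus <- toy_annotation(list(id = "g", exons = c(50, 100, 700, 800)))
  minus <- toy_annotation(list(id = "g", strand = "-",
                               exons = c(50, 100, 700, 800)))
  ep <- classify_as_events("g", jn, plus)
  em <- classify_as_events("g", jn, minus)
  expect_equal(ep$type, "alt_3ss")
  expect_equal(em$type, "alt_5ss")
  # shared acceptor mirrors the labels
  jn2 <- data.frame(chrom = "chr1", donor = c(100L, 150L),
                    acceptor = c(600L, 600L), support = 5L)
  expect_equal(classify_as_events("g", jn2, plus)$type, "alt_5ss")
  expect_equal(classify_as_events("g", jn2, minus)$type, "alt_3ss")
})

test_that("exon skipping needs a spanning junction plus inclusion evidence", {
  # toy 3-exon gene: exons [100,200) [300,400) [500,600)
  g3 <- toy_annotation(list(id = "g", exons = c(100, 200, 300, 400,
                                                500, 600)))
  skip_only <- data.frame(chrom = "chr1", donor = 200L, acceptor = 500L,
                          support = 4L)
  expect_equal(nrow(classify_as_events("g", skip_only, g3)), 0L)
  with_incl <- rbind(skip_only,
                     data.frame(chrom = "chr1", donor = c(200L, 400L),
                                acceptor = c(300L, 500L), support = 4L))
  ev <- classify_as_events("g", with_incl, g3)
  es <- ev[ev$type == "exon_skipping", ]
  expect_equal(nrow(es), 1L)
  expect_equal(c(es$exon_start, es$exon_end), c(300L, 400L))
  # coverage over the exon is an alternative inclusion proof
  depth <- integer(1000)
  depth[301:400] <- 5L
  ev2 <- classify_as_events("g", skip_only, g3, depth = depth)
  expect_equal(ev2$type[ev2$exon_start == 300], "exon_skipping")
})

test_that("intron retention needs full intron coverage and a spliced form", {
  g2 <- toy_annotation(list(id = "g", exons = c(100, 200, 400, 500)))
  jn <- data.frame(chrom = "chr1", donor = 200L, acceptor = 400L,
                   support = 3L)
  covered <- integer(1000)
  covered[101:500] <- 4L
  ev <- classify_as_events("g", jn, g2, depth = covered)
  ir <- ev[ev$type == "intron_retention", ]
  expect_equal(nrow(ir), 1L)
  expect_equal(c(ir$intron_start, ir$intron_end), c(200L, 400L))
  # a one-base coverage hole in the intron kills the call
  holey <- covered
  holey[300] <- 1L
  ev2 <- classify_as_events("g", jn, g2, depth = holey)
  expect_equal(sum(ev2$type == "intron_retention"), 0L)
  # no spliced junction -> no retention either
  ev3 <- classify_as_events("g", jn[0, ], g2, depth = covered)
  expect_equal(nrow(ev3), 0L)
})

test_that("classification ignores junction input order and low support", {
  g3 <- toy_annotation(list(id = "g", exons = c(100, 200, 300, 400,
                                                500, 600)))
  jn <- data.frame(chrom = "chr1",
                   donor = c(200L, 200L, 400L, 200L),
                   acceptor = c(300L, 500L, 500L, 320L),
                   support = c(4L, 4L, 4L, 1L))
  ev1 <- classify_as_events("g", jn, g3)
  set.seed(1)
  ev2 <- classify_as_events("g", jn[sample(nrow(jn)), ], g3)
  expect_equal(ev1[order(ev1$type, ev1$j1_donor, ev1$j1_acceptor), ],
               ev2[order(ev2$type, ev2$j1_donor, ev2$j1_acceptor), ],
               ignore_attr = TRUE)
  # the support-1 junction (acceptor 320) contributes no event
  expect_false(any(stats::na.omit(c(ev1$j1_acceptor, ev1$j2_acceptor)) ==
                     320))
})

test_that("planted AS events of all four types are recovered", {
  cs <- clean_sim()
  ev <- find_as_events(cs$al$alignments$emb135, cs$sim$annotation)
  tr <- cs$al$truth$as_events
  for (i in seq_len(nrow(tr)))
    expect_true(any(ev$gene_id == tr$gene_id[i] & ev$type == tr$type[i]),
                label = paste(tr$gene_id[i], tr$type[i]))
  # every event's defining junctions re-validate against raw junctions
  jn <- extract_junctions(cs$al$alignments$emb135)
  key <- paste(jn$chrom, jn$donor, jn$acceptor)
  pairs <- ev[!is.na(ev$j2_donor), ]
  expect_true(all(paste(pairs$chrom, pairs$j1_donor, pairs$j1_acceptor)
                  %in% key))
  expect_true(all(paste(pairs$chrom, pairs$j2_donor, pairs$j2_acceptor)
                  %in% key))
})

test_that("the AS summary aggregates events, genes and intron sizes", {
  ev <- data.frame(
    gene_id = c("g1", "g2", "g2", "g3"),
    type = c("alt_3ss", "alt_3ss", "exon_skipping", "intron_retention"),
    chrom = "chr1", j1_donor = 1L, j1_acceptor = 2L,
    j2_donor = NA, j2_acceptor = NA, exon_start = NA, exon_end = NA,
    intron_start = c(NA, NA, NA, 200L), intron_end = c(NA, NA, NA, 500L),
    support = 4L)
  s <- summarize_as(ev)
  tc <- stats::setNames(s$type_counts$events, s$type_counts$type)
  expect_equal(tc[["alt_3ss"]], 2L)
  gc <- stats::setNames(s$type_counts$genes, s$type_counts$type)
  expect_equal(gc[["alt_3ss"]], 2L)
  expect_equal(s$multi_event_fraction, 1 / 3)
  expect_equal(s$retained_intron_size$mean, 300)
  # a single gene with two event types is fully multi-event
  one <- ev[2:3, ]
  expect_equal(summarize_as(one)$multi_event_fraction, 1)
})
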