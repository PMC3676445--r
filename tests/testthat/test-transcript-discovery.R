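test_that("coverage counts unique aligned blocks, splice gaps excluded", {
  recs <- make_records(list(
    list(qname = "a", chrom = "chr1", blocks = c(0, 10)),
    list(qname = "b", chrom = "chr1", blocks = c(5, 15)),
    list(qname = "gapped", chrom = "chr1", blocks = c(20, 30, 50, 60)),
    list(qname = "multi", chrom = "chr1", blocks = c(0, 10),
         mult = "multi")), c(chr1 = 100L))
  d <- compute_coverage(recs, "chr1", 100L)
  expect_equal(d[1:5], rep(1L, 5))
  expect_equal(d[6:10], rep(2L, 5))
  expect_equal(d[11:15], rep(1L, 5))
  expect_equal(d[31:50], rep(0L, 20))   # inside the splice gap
  expect_equal(d[51:60], rep(1L, 10))
  expect_equal(compute_coverage(recs[0, ], "chr1", 50L), integer(50))
  bad <- make_records(list(list(qname = "x", chrom = "chr1",
                                blocks = c(90, 120))), c(chr1 = 100L))
  expect_error(compute_coverage(bad, "chr1", 100L), "outside")
})

test_that("coverage equals the brute-force membership oracle", {
  ns <- noisy_sim()
  a <- ns$al$alignments$adult30m
  sub <- a[a$multiplicity == "unique" & a$chrom == "chrS1", ][1:200, ]
  attr(sub, "chrom_lengths") <- attr(a, "chrom_lengths")
  L <- 150000L
  expect_equal(compute_coverage(sub, "chrS1", L),
               coverage_oracle(sub, "chrS1", L))
})

test_that("detect_tars finds maximal runs at the depth threshold", {
  tars <- detect_tars(c(0, 1, 2, 2, 3, 1, 2, 2), 2, "c")
  expect_equal(tars$start, c(2L, 6L))
  expect_equal(tars$end, c(5L, 8L))
  expect_equal(tars$min_cov, c(2L, 2L))
  one <- detect_tars(rep(5L, 10), 2, "c")
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(0L, 10L))
  expect_equal(nrow(detect_tars(rep(1L, 10), 2, "c")), 0L)
})

test_that("detect_tars matches the linear-scan oracle on random vectors", {
  set.seed(42)
  for (i in 1:100) {
    depth <- stats::rpois(2000, sample(c(0.5, 1.5, 2.5), 1))
    tars <- detect_tars(depth, 2, "c")
    orc <- tar_oracle(depth, 2)
    expect_equal(nrow(tars), if (is.null(orc)) 0L else nrow(orc))
    if (!is.null(orc)) {
      expect_equal(tars$start, orc[, 1])
      expect_equal(tars$end, orc[, 2])
    }
    # maximality and non-overlap
    if (nrow(tars) > 1)
      expect_true(all(tars$start[-1] > tars$end[-nrow(tars)]))
    for (j in seq_len(nrow(tars))) {
      if (tars$start[j] > 0) expect_lt(depth[tars$start[j]], 2)
      if (tars$end[j] < length(depth)) expect_lt(depth[tars$end[j] + 1], 2)
    }
  }
})

test_that("intergenic regions apply the 200 bp buffers", {
  ann <- toy_annotation(list(id = "g1", exons = c(1000, 2000)),
                        list(id = "g2", exons = c(5000, 6000)))
  iv <- intergenic_regions(ann)
  expect_true(any(iv$start == 2200 & iv$end == 4800))
  expect_true(any(iv$start == 0 & iv$end == 800))       # left flank
  expect_true(any(iv$start == 6200 & iv$end == 10000))  # right flank
  # gap of exactly 400 bp or less yields no interval
  ann2 <- toy_annotation(list(id = "g1", exons = c(1000, 2000)),
                         list(id = "g2", exons = c(2400, 3000)))
  iv2 <- intergenic_regions(ann2)
  expect_false(any(iv2$start > 2000 & iv2$end < 2400))
})

test_that("intergenic regions equal the buffered-complement oracle", {
  sim <- noisy_sim()$sim
  iv <- intergenic_regions(sim$annotation)
  for (chrom in names(sim$annotation$chromosomes)) {
    L <- sim$annotation$chromosomes[[chrom]]
    free <- rep(TRUE, L)
    g <- sim$annotation$genes[sim$annotation$genes$chrom == chrom, ]
    for (i in seq_len(nrow(g)))
      free[max(1, g$start[i] + 1 - 200):min(L, g$end[i] + 200)] <- FALSE
    orc <- tar_oracle(as.integer(free), 1) # runs of free bases
    got <- iv[iv$chrom == chrom, ]
    expect_equal(got$start, orc[, 1])
    expect_equal(got$end, orc[, 2])
  }
})

test_that("pair links connect TARs into transcript units transitively", {
  tars <- data.frame(tar_id = paste0("T", 1:4), chrom = "chr1",
                     start = c(0, 100, 200, 300),
                     end = c(50, 150, 250, 350),
                     min_cov = 2L, mean_cov = c(4, 6, 2, 2))
  # no pairs -> singletons
  none <- make_records(list(), c(chr1 = 1000L))[0, ]
  expect_equal(nrow(join_tars(tars, none)), 4L)
  # T1-T2 and T2-T3 links merge transitively; T4 stays alone
  recs <- make_records(list(
    list(qname = "p1", chrom = "chr1", blocks = c(10, 30), mate = 1),
    list(qname = "p1", chrom = "chr1", blocks = c(110, 130), mate = 2),
    list(qname = "p2", chrom = "chr1", blocks = c(120, 140), mate = 1),
    list(qname = "p2", chrom = "chr1", blocks = c(210, 230), mate = 2)),
    c(chr1 = 1000L))
  units <- join_tars(tars, recs)
  expect_equal(nrow(units), 2L)
  big <- units[units$n_tars == 3, ]
  expect_equal(sort(big$members[[1]]), c("T1", "T2", "T3"))
  expect_equal(big$total_length, 150L)
  expect_equal(big$mean_cov, (4 * 50 + 6 * 50 + 2 * 50) / 150)
})

test_that("unit membership equals the brute-force component oracle", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(3:12, 1)
    tars <- data.frame(tar_id = paste0("T", 1:n), chrom = "chr1",
                       start = (0:(n - 1)) * 100L,
                       end = (0:(n - 1)) * 100L + 50L,
                       min_cov = 2L, mean_cov = 3)
    n_pairs <- sample(0:8, 1)
    frag_tars <- lapply(seq_len(n_pairs), function(i) sample(n, 2))
    reads <- unlist(lapply(seq_len(n_pairs), function(i) {
      lapply(1:2, function(m) list(
        qname = paste0("p", i), mate = m, chrom = "chr1",
        blocks = c(tars$start[frag_tars[[i]][m]] + 5,
                   tars$start[frag_tars[[i]][m]] + 25)))
    }), recursive = FALSE)
    recs <- make_records(reads, c(chr1 = 10000L))
    units <- join_tars(tars, recs)
    orc <- component_oracle(n, frag_tars)
    got <- integer(n)
    for (u in seq_len(nrow(units)))
      got[match(units$members[[u]], tars$tar_id)] <- u
    expect_equal(length(unique(orc)), nrow(units))
    # same partition up to labels
    expect_true(all(tapply(got, orc, function(x) length(unique(x))) == 1))
  }
})

test_that("novelty filters apply the intergenic rules and are conjunctive", {
  ann <- toy_annotation(list(id = "g1", exons = c(1000, 2000)))
  inter <- intergenic_regions(ann)
  mk_unit <- function(start, end, mean_cov = 5) {
    tars <- data.frame(tar_id = "T1", chrom = "chr1", start = start,
                       end = end, min_cov = 2L, mean_cov = mean_cov)
    list(tars = tars, units = {
      u <- data.frame(unit_id = "U1", chrom = "chr1", start = start,
                      end = end, n_tars = 1L,
                      total_length = end - start, mean_cov = mean_cov)
      u$members <- list("T1")
      u
    })
  }
  # length 149 -> rejected
  x <- mk_unit(3000L, 3149L)
  expect_equal(nrow(call_novel_tus(x$units, x$tars, ann, inter)), 0L)
  flags <- call_novel_tus(x$units, x$tars, ann, inter, keep_all = TRUE)
  expect_false(flags$long_enough)
  expect_true(flags$no_gene_overlap && flags$in_intergenic)
  # 1 bp overlap with the gene span -> rejected
  y <- mk_unit(1800L, 2001L)
  fy <- call_novel_tus(y$units, y$tars, ann, inter, keep_all = TRUE)
  expect_false(fy$no_gene_overlap)
  expect_false(fy$novel)
  # mean coverage below 2 -> rejected
  z <- mk_unit(3000L, 3400L, mean_cov = 1.5)
  fz <- call_novel_tus(z$units, z$tars, ann, inter, keep_all = TRUE)
  expect_false(fz$covered_enough)
  # passing unit: all four flags true
  w <- mk_unit(3000L, 3400L)
  fw <- call_novel_tus(w$units, w$tars, ann, inter, keep_all = TRUE)
  expect_true(all(fw[, c("no_gene_overlap", "in_intergenic", "long_enough",
                         "covered_enough", "novel")]))
})

test_that("all planted novel TUs are recovered without false positives", {
  cs <- clean_sim()
  for (cond in c("emb135", "adult30m")) {
    d <- discover_transcripts(cs$al$alignments[[cond]], cs$sim$annotation)
    expect_equal(nrow(d$novel), length(cs$sim$novel_tus))
    rl <- cs$sim$config$read_length
    for (tu in cs$sim$novel_tus) {
      hit <- d$novel[d$novel$chrom == tu$chrom &
                       abs(d$novel$start - min(tu$blocks$start)) <= rl &
                       abs(d$novel$end - max(tu$blocks$end)) <= rl, ]
      expect_equal(nrow(hit), 1L, label = tu$tu_id)
      expect_equal(hit$n_tars, nrow(tu$blocks))
    }
  }
})

test_that("gene boundary refinement measures strand-aware protrusions", {
  ann <- toy_annotation(list(id = "g1", exons = c(1000, 1400, 1700, 2000)))
  tars <- data.frame(tar_id = "T1", chrom = "chr1", start = 900L,
                     end = 2300L, min_cov = 2L, mean_cov = 5)
  ext <- refine_boundaries(ann, tars)
  expect_equal(ext$extension[ext$end == "5prime"], 100L)
  expect_equal(ext$extension[ext$end == "3prime"], 300L)
  # same coordinates on the minus strand swap the labels
  annm <- toy_annotation(list(id = "g1", strand = "-",
                              exons = c(1000, 1400, 1700, 2000)))
  extm <- refine_boundaries(annm, tars)
  expect_equal(extm$extension[extm$end == "3prime"], 100L)
  expect_equal(extm$extension[extm$end == "5prime"], 300L)
  # TAR strictly inside the gene yields no extension
  inside <- data.frame(tar_id = "T2", chrom = "chr1", start = 1100L,
                       end = 1900L, min_cov = 2L, mean_cov = 5)
  expect_equal(nrow(refine_boundaries(ann, inside)), 0L)
})
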