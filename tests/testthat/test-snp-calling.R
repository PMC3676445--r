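test_that("pileups stack aligned bases and skip splice gaps", {
  genome <- c(chr1 = strrep("A", 300))
  recs <- make_records(list(
    list(qname = "r1", chrom = "chr1", blocks = c(0, 4), seq = "ACGT",
         qual = "IIII"),
    list(qname = "sp", chrom = "chr1", blocks = c(10, 12, 112, 114),
         seq = "GGTT", qual = "IIII")), c(chr1 = 300L))
  pu <- build_pileup(recs, genome)
  expect_equal(pu$pos[pu$qname == "r1 1"], 0:3)
  expect_equal(pu$base[pu$qname == "r1 1"], c("A", "C", "G", "T"))
  expect_equal(pu$qual[1], 40L)  # "I" is Phred 40
  sp <- pu[pu$qname == "sp 1", ]
  expect_equal(sp$pos, c(10L, 11L, 112L, 113L))  # nothing inside the gap
  expect_equal(sp$base, c("G", "G", "T", "T"))
  bad <- make_records(list(list(qname = "x", chrom = "chr1",
                                blocks = c(290, 310))), c(chr1 = 300L))
  expect_error(build_pileup(bad, genome), "beyond")
})

test_that("pileup depths equal the brute-force base-count oracle", {
  cs <- clean_sim()
  a <- cs$al$alignments$emb135
  sub <- a[a$chrom == "chrS1", ][1:50, ]
  pu <- build_pileup(sub, cs$sim$genome)
  depth_oracle <- coverage_oracle(sub, "chrS1", 150000L)
  tab <- table(pu$pos)
  expect_equal(as.integer(tab),
               depth_oracle[as.integer(names(tab)) + 1L])
  expect_equal(sum(depth_oracle > 0), length(tab))
})

test_that("genotype priors are proper and favour transitions", {
  pr <- genotype_prior()
  for (ref in c("A", "C", "G", "T")) {
    p <- prior_probs(pr, ref)
    expect_equal(sum(p), 1)
    expect_true(all(p > 0))
  }
  p <- prior_probs(pr, "A")
  expect_equal(p[["AG"]] / p[["AC"]], 2)       # ts:tv weighting
  expect_gt(p[["AA"]], 0.99)
})

test_that("posterior genotypes match the exhaustive enumeration oracle", {
  pr <- genotype_prior()
  # clear reference homozygote
  col <- list(chrom = "c", pos = 1L, ref = "A", bases = rep("A", 10),
              quals = rep(30, 10), depth = 10L)
  gp <- genotype_posterior(col, pr)
  expect_equal(gp$genotype, "AA")
  expect_gte(gp$quality, 20)
  # hom-alt and het spot checks against the oracle
  col2 <- list(chrom = "c", pos = 1L, ref = "A", bases = rep("G", 6),
               quals = rep(30, 6), depth = 6L)
  o2 <- posterior_oracle(col2$bases, col2$quals, "A")
  expect_equal(genotype_posterior(col2, pr)$genotype, "GG")
  expect_equal(names(which.max(o2)), "GG")
  col3 <- list(chrom = "c", pos = 1L, ref = "A",
               bases = rep(c("A", "G"), 5), quals = rep(30, 10),
               depth = 10L)
  expect_equal(genotype_posterior(col3, pr)$genotype, "AG")
  # random columns, depth <= 15: full posterior equality
  set.seed(77)
  for (i in 1:100) {
    depth <- sample(1:15, 1)
    bases <- sample(c("A", "C", "G", "T"), depth, replace = TRUE,
                    prob = c(0.55, 0.25, 0.15, 0.05))
    quals <- sample(c(10, 20, 30, 40), depth, replace = TRUE)
    ref <- sample(c("A", "C", "G", "T"), 1)
    col <- list(chrom = "c", pos = 1L, ref = ref, bases = bases,
                quals = quals, depth = depth)
    gp <- genotype_posterior(col, pr)
    orc <- posterior_oracle(bases, quals, ref)
    expect_equal(gp$posterior, orc, tolerance = 1e-10)
    expect_equal(sum(gp$posterior), 1, tolerance = 1e-12)
    expect_equal(gp$genotype, names(which.max(orc)))
  }
})

test_that("adding an alt observation never hurts alt genotypes", {
  pr <- genotype_prior()
  set.seed(5)
  for (i in 1:20) {
    depth <- sample(2:10, 1)
    bases <- sample(c("A", "G"), depth, replace = TRUE)
    quals <- rep(30, depth)
    col1 <- list(ref = "A", bases = bases, quals = quals, depth = depth)
    col2 <- list(ref = "A", bases = c(bases, "G"), quals = c(quals, 30),
                 depth = depth + 1L)
    p1 <- genotype_posterior(col1, pr)$posterior
    p2 <- genotype_posterior(col2, pr)$posterior
    alt_g <- grepl("G", names(p1))
    expect_gte(sum(p2[alt_g]), sum(p1[alt_g]) - 1e-12)
  }
})

test_that("SNP filters enforce alt support and consensus quality", {
  genome <- c(chr1 = strrep("A", 100))
  mk_pileup <- function(n_alt, n_ref, q = 30) {
    reads <- c(
      lapply(seq_len(n_alt), function(i)
        list(qname = paste0("alt", i), chrom = "chr1", blocks = c(10, 11),
             seq = "G", qual = rawToChar(as.raw(q + 33)))),
      lapply(seq_len(n_ref), function(i)
        list(qname = paste0("ref", i), chrom = "chr1", blocks = c(10, 11),
             seq = "A", qual = rawToChar(as.raw(q + 33)))))
    build_pileup(make_records(reads, c(chr1 = 100L)), genome)
  }
  # a single supporting read fails the >=2 unique-read rule whatever the q
  one <- call_snps(mk_pileup(1, 0, q = 40), genome)
  expect_equal(nrow(one), 1L)
  expect_false(one$pass)
  expect_match(one$fail_reasons, "alt2")
  # five alt reads: called, and the quality gate tracks min_quality
  five <- call_snps(mk_pileup(5, 5), genome)
  expect_true(five$pass)
  strict <- call_snps(mk_pileup(5, 5), genome,
                      min_quality = five$quality + 1)
  expect_false(strict$pass)
  expect_match(strict$fail_reasons, "q20")
  expect_equal(strict$alt_support, 5L)
})

test_that("bulk calling agrees with the per-column posterior", {
  cs <- clean_sim()
  vv <- cs$sim$variants
  pu <- build_pileup(cs$al$alignments$adult30m, cs$sim$genome)
  calls <- call_snps(pu, cs$sim$genome)
  pr <- genotype_prior()
  for (i in seq_len(min(10, nrow(calls)))) {
    col <- pileup_column(pu, calls$chrom[i], calls$pos[i], cs$sim$genome)
    gp <- genotype_posterior(col, pr)
    expect_equal(calls$genotype[i], gp$genotype)
    expect_equal(calls$quality[i], gp$quality, tolerance = 1e-6)
  }
})

test_that("planted variants are recovered exactly on error-free data", {
  cs <- clean_sim()
  vv <- cs$sim$variants
  pu <- build_pileup(cs$al$alignments$adult30m, cs$sim$genome)
  calls <- call_snps(pu, cs$sim$genome)
  passing <- calls[calls$pass, ]
  key <- paste(passing$chrom, passing$pos)
  truth_key <- paste(vv$chrom, vv$pos)
  expect_setequal(key, truth_key)            # 30/30, no false sites
  m <- merge(passing, vv, by = c("chrom", "pos"))
  want <- ifelse(m$genotype.y == "hom", paste0(m$alt, m$alt),
                 apply(cbind(m$ref.x, m$alt), 1,
                       function(r) paste(sort(r), collapse = "")))
  expect_equal(m$genotype.x, want)
  expect_true(all(m$alt_support >= 2))
  expect_true(all(m$quality >= 20))
})

test_that("false-positive rate on error-bearing reference sites is tiny", {
  set.seed(31)
  n_sites <- 5000L
  depth <- 10L
  err <- 1e-3
  genome <- c(chr1 = strrep("A", n_sites))
  bases <- matrix("A", n_sites, depth)
  flips <- which(matrix(stats::runif(n_sites * depth) < err, n_sites, depth))
  bases[flips] <- sample(c("C", "G", "T"), length(flips), replace = TRUE)
  pu <- data.frame(chrom = "chr1",
                   pos = rep(0:(n_sites - 1L), depth),
                   base = as.vector(bases), qual = 30L,
                   qname = paste0("r", rep(seq_len(depth), each = n_sites)))
  class(pu) <- c("bovtx_pileup", "data.frame")
  calls <- call_snps(pu, genome)
  fp <- sum(calls$pass)
  # a passing false call needs >=2 identical miscalls at one site
  expected <- n_sites * choose(depth, 2) * 3 * (err / 3)^2
  expect_lte(fp, max(3, 5 * expected))
})
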