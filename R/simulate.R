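#' Simulation configuration
#'
#' Bundles every knob of the synthetic study: a toy multi-gene genome, two
#' conditions ("emb135", embryonic day 135; "adult30m", 30-month adult) of
#' spliced paired-end alignments with per-gene expression levels and planted
#' fold changes, planted intergenic novel transcript units, planted
#' alternative-splicing events of the four classified types, planted variant
#' sites, and configurable unique / multi-mapped / unmapped read fractions.
#'
#' Defaults emulate the study design at desk scale: 90 bp paired-end reads
#' (the per-read base count implied by the alignment summary), fragments
#' within the 200-700 nt library range, a Poisson count model per gene so the
#' exact count test's assumptions hold, and mapped-category fractions of the
#' order seen in deep bovine muscle libraries.
#'
#' @param seed integer RNG seed; identical seed + config gives byte-identical
#'   output files.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param n_genes number of genes, laid out with >400 bp between gene spans.
#' @param exons_per_gene integer range `c(min, max)` of exons per gene.
#' @param exon_length,intron_length integer ranges (bp).
#' @param gene_mean_pairs expected read pairs per gene in the adult30m
#'   baseline library (scalar or per-gene vector).
#' @param fold_changes per-gene expression fold of emb135 relative to
#'   adult30m; `NULL` plants fold `de_fold` up in the first two genes and down
#'   in the next two.
#' @param de_fold fold change used for the auto-planted DE genes.
#' @param n_novel_tu number of planted intergenic novel transcript units
#'   (alternating single-block and two-block structures).
#' @param novel_tu_length range of total novel-TU lengths (bp).
#' @param novel_tu_depth target read depth over planted novel TUs.
#' @param as_events named integer vector of planted event counts per type
#'   (`exon_skipping`, `intron_retention`, `alt_5ss`, `alt_3ss`).
#' @param n_variants number of planted exonic variant sites (alternating
#'   heterozygous / homozygous-alt).
#' @param frac_multi,frac_unmapped per-read probabilities of the multi-mapped
#'   and unmapped categories (remainder is unique).
#' @param frac_mismatch probability that a mapped read carries 1-3 planted
#'   substitutions (the simulator emulates an aligner that reports only
#'   alignments with at most 3 mismatches).
#' @param read_length read length (bp).
#' @param fragment_mean,fragment_sd fragment-size distribution (bp).
#' @param base_quality constant per-base Phred quality.
#' @param sequencing_errors if `TRUE`, bases are miscalled at rate
#'   `10^(-base_quality/10)`.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_lengths = c(chrS1 = 150000L,
                                                chrS2 = 150000L),
                              n_genes = 20L,
                              exons_per_gene = c(3L, 6L),
                              exon_length = c(120L, 400L),
                              intron_length = c(200L, 800L),
                              gene_mean_pairs = 120,
                              fold_changes = NULL,
                              de_fold = 4,
                              n_novel_tu = 8L,
                              novel_tu_length = c(300L, 800L),
                              novel_tu_depth = 10,
                              as_events = c(exon_skipping = 2L,
                                            intron_retention = 2L,
                                            alt_5ss = 2L, alt_3ss = 2L),
                              n_variants = 30L,
                              frac_multi = 0.05,
                              frac_unmapped = 0.20,
                              frac_mismatch = 0.25,
                              read_length = 90L,
                              fragment_mean = 300,
                              fragment_sd = 50,
                              base_quality = 30L,
                              sequencing_errors = TRUE) {
  if (is.null(fold_changes)) {
    fold_changes <- rep(1, n_genes)
    if (n_genes >= 4) fold_changes[1:4] <- c(de_fold, de_fold,
                                             1 / de_fold, 1 / de_fold)
  }
  gene_mean_pairs <- rep_len(gene_mean_pairs, n_genes)
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_length = as.integer(intron_length),
              gene_mean_pairs = gene_mean_pairs,
              fold_changes = fold_changes,
              n_novel_tu = as.integer(n_novel_tu),
              novel_tu_length = as.integer(novel_tu_length),
              novel_tu_depth = novel_tu_depth,
              as_events = as_events, n_variants = as.integer(n_variants),
              frac_multi = frac_multi, frac_unmapped = frac_unmapped,
              frac_mismatch = frac_mismatch,
              read_length = as.integer(read_length),
              fragment_mean = fragment_mean, fragment_sd = fragment_sd,
              base_quality = as.integer(base_quality),
              sequencing_errors = isTRUE(sequencing_errors))
  stopifnot(all(c(cfg$frac_multi, cfg$frac_unmapped, cfg$frac_mismatch) >= 0),
            all(c(cfg$frac_multi, cfg$frac_unmapped, cfg$frac_mismatch) <= 1),
            cfg$frac_multi + cfg$frac_unmapped <= 1,
            all(cfg$chrom_lengths > 0), all(cfg$exon_length > 0),
            all(cfg$intron_length > 0), cfg$read_length > 0,
            all(cfg$fold_changes > 0),
            length(cfg$fold_changes) == cfg$n_genes)
  if (cfg$n_novel_tu > 0 && cfg$novel_tu_length[1] < 150)
    stop("planted novel TUs must satisfy the >=150 bp length filter")
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a toy annotated genome
#'
#' Generates random chromosome sequences, lays out genes (each with one
#' annotated canonical transcript) so that all pairwise gene gaps exceed
#' 400 bp, reserves intergenic space (with the 200 bp buffers respected) for
#' the planted novel transcript units, constructs unannotated alternative
#' isoforms for the planted AS events, and plants exonic variant sites.
#'
#' @param config a [simulation_config()].
#' @return A list of class `simulated_genome` with elements `genome` (named
#'   character vector), `annotation` ([genome_annotation()], canonical
#'   transcripts only), `genes` (per-gene layout incl. alternative isoforms),
#'   `novel_tus`, `variants`, and `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cl <- config$chrom_lengths
  genome <- vapply(cl, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    "")
  # lay out genes round-robin over chromosomes with gaps of 500-900 bp
  genes <- vector("list", config$n_genes)
  cursors <- stats::setNames(rep(1000L, length(cl)), names(cl))
  ci <- 1L
  for (g in seq_len(config$n_genes)) {
    k <- sample(seq(config$exons_per_gene[1], config$exons_per_gene[2]), 1L)
    elens <- sample(seq(config$exon_length[1], config$exon_length[2]), k,
                    replace = TRUE)
    ilens <- if (k > 1)
      sample(seq(config$intron_length[1], config$intron_length[2]), k - 1L,
             replace = TRUE) else integer(0)
    glen <- sum(elens) + sum(ilens)
    placed <- FALSE
    for (try in seq_along(cl)) {
      chrom <- names(cl)[ci]
      if (cursors[chrom] + glen < cl[chrom] - 60000L) { # keep tail space free
        placed <- TRUE
        break
      }
      ci <- ci %% length(cl) + 1L
    }
    if (!placed) stop("requested genes cannot fit the chromosome lengths")
    start <- cursors[chrom]
    starts <- start + cumsum(c(0L, head_int(elens, -1L) + ilens))
    exons <- data.frame(start = starts, end = starts + elens)
    strand <- sample(c("+", "-"), 1L)
    genes[[g]] <- list(gene_id = sprintf("GSIM%03d", g), chrom = chrom,
                       strand = strand, exons = exons,
                       start = min(exons$start), end = max(exons$end),
                       fold = config$fold_changes[g],
                       mean_pairs = config$gene_mean_pairs[g],
                       as_type = NA_character_, alt_exons = NULL)
    cursors[chrom] <- max(exons$end) + sample(500:900, 1L)
    ci <- ci %% length(cl) + 1L
  }
  # plant AS events on distinct eligible genes (>=3 exons, fold 1)
  as_plan <- rep(names(config$as_events), times = config$as_events)
  eligible <- which(vapply(genes, function(g)
    nrow(g$exons) >= 3 && g$fold == 1, TRUE))
  if (length(as_plan) > length(eligible))
    stop("not enough eligible genes for the requested AS events")
  as_truth <- list()
  for (i in seq_along(as_plan)) {
    g <- eligible[i]
    genes[[g]] <- plant_as_event(genes[[g]], as_plan[i])
    as_truth[[i]] <- genes[[g]]$as_truth
  }
  # novel transcript units in the gene-free chromosome tails
  novel <- list()
  if (config$n_novel_tu > 0) {
    tail_cursors <- cursors + 200L # 200 bp buffer beyond the last gene
    tci <- 1L
    for (t in seq_len(config$n_novel_tu)) {
      tlen <- sample(seq(config$novel_tu_length[1],
                         config$novel_tu_length[2]), 1L)
      two_block <- t %% 2L == 0L
      span <- if (two_block) tlen + 250L else tlen
      placed <- FALSE
      for (try in seq_along(cl)) {
        chrom <- names(cl)[tci]
        if (tail_cursors[chrom] + span < cl[chrom] - 500L) {
          placed <- TRUE
          break
        }
        tci <- tci %% length(cl) + 1L
      }
      if (!placed) stop("planted novel TUs cannot fit the chromosome tails")
      s <- tail_cursors[chrom]
      blocks <- if (two_block) {
        l1 <- tlen %/% 2L
        data.frame(start = c(s, s + l1 + 250L),
                   end = c(s + l1, s + tlen + 250L))
      } else data.frame(start = s, end = s + tlen)
      novel[[t]] <- list(tu_id = sprintf("NTU%03d", t), chrom = chrom,
                         blocks = blocks, total_length = tlen)
      tail_cursors[chrom] <- max(blocks$end) + 500L
      tci <- tci %% length(cl) + 1L
    }
  }
  # exonic variant sites, alternating het / hom-alt
  variants <- data.frame(chrom = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         genotype = character(0), gene_id = character(0))
  if (config$n_variants > 0) {
    host <- sample(seq_along(genes), config$n_variants, replace = TRUE)
    taken <- character(0)
    rows <- list()
    for (v in seq_len(config$n_variants)) {
      g <- genes[[host[v]]]
      lens <- g$exons$end - g$exons$start
      cum0 <- cumsum(c(0L, lens))
      tlen <- sum(lens)
      repeat {
        ei <- sample(nrow(g$exons), 1L)
        e <- g$exons[ei, ]
        pos <- sample(seq(e$start + 5L, e$end - 6L), 1L)
        # keep sites one read length inside the transcript ends so planted
        # depth reflects the gene's expression, not the coverage ramp
        toff <- cum0[ei] + (pos - e$start)
        if (toff < config$read_length ||
            toff >= tlen - config$read_length) next
        key <- paste(g$chrom, pos)
        if (!key %in% taken) break
      }
      taken <- c(taken, key)
      ref <- substring(genome[[g$chrom]], pos + 1L, pos + 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      rows[[v]] <- data.frame(chrom = g$chrom, pos = pos, ref = ref,
                              alt = alt,
                              genotype = if (v %% 2L == 1L) "het" else "hom",
                              gene_id = g$gene_id)
    }
    variants <- do.call(rbind, rows)
    variants <- variants[order(variants$chrom, variants$pos), ]
    rownames(variants) <- NULL
  }
  ann <- layout_to_annotation(genes, cl)
  structure(list(genome = genome, annotation = ann, genes = genes,
                 novel_tus = novel, variants = variants, config = config),
            class = "simulated_genome")
}

#' @noRd
head_int <- function(x, n) if (length(x) == 0) x else utils::head(x, n)

# construct the unannotated alternative isoform realising one AS event;
# shifts are strand-aware so the planted type matches the classifier's labels
#' @noRd
plant_as_event <- function(g, type) {
  ex <- g$exons
  d <- 30L # splice-site shift for A5SS/A3SS
  alt <- ex
  chrom <- g$chrom
  if (type == "exon_skipping") {
    alt <- ex[-2L, ]
    truth <- data.frame(gene_id = g$gene_id, type = type, chrom = chrom,
                        exon_start = ex$start[2], exon_end = ex$end[2],
                        donor = ex$end[1], acceptor = ex$start[3])
  } else if (type == "intron_retention") {
    alt <- rbind(data.frame(start = ex$start[1], end = ex$end[2]),
                 ex[-(1:2), ])
    truth <- data.frame(gene_id = g$gene_id, type = type, chrom = chrom,
                        intron_start = ex$end[1], intron_end = ex$start[2])
  } else if (type == "alt_5ss") {
    if (g$strand == "+") { # donor (end of exon 1) shifts inward
      alt$end[1] <- ex$end[1] - d
      truth <- data.frame(gene_id = g$gene_id, type = type, chrom = chrom,
                          donor = ex$end[1], acceptor = ex$start[2],
                          alt_donor = ex$end[1] - d,
                          alt_acceptor = ex$start[2])
    } else {             # transcript-5' site is the genomic right boundary
      alt$start[2] <- ex$start[2] + d
      truth <- data.frame(gene_id = g$gene_id, type = type, chrom = chrom,
                          donor = ex$end[1], acceptor = ex$start[2],
                          alt_donor = ex$end[1],
                          alt_acceptor = ex$start[2] + d)
    }
  } else if (type == "alt_3ss") {
    if (g$strand == "+") {
      alt$start[2] <- ex$start[2] + d
      truth <- data.frame(gene_id = g$gene_id, type = type, chrom = chrom,
                          donor = ex$end[1], acceptor = ex$start[2],
                          alt_donor = ex$end[1],
                          alt_acceptor = ex$start[2] + d)
    } else {
      alt$end[1] <- ex$end[1] - d
      truth <- data.frame(gene_id = g$gene_id, type = type, chrom = chrom,
                          donor = ex$end[1], acceptor = ex$start[2],
                          alt_donor = ex$end[1] - d,
                          alt_acceptor = ex$start[2])
    }
  } else stop("unknown AS type: ", type)
  g$as_type <- type
  g$alt_exons <- alt
  g$as_truth <- truth
  g
}

#' @noRd
layout_to_annotation <- function(genes, chrom_lengths) {
  if (length(genes) == 0) {
    return(genome_annotation(
      chromosomes = chrom_lengths,
      genes = data.frame(gene_id = character(0), chrom = character(0),
                         strand = character(0), start = integer(0),
                         end = integer(0)),
      transcripts = data.frame(transcript_id = character(0),
                               gene_id = character(0)),
      exons = data.frame(transcript_id = character(0), gene_id = character(0),
                         chrom = character(0), strand = character(0),
                         start = integer(0), end = integer(0))))
  }
  gtab <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
               start = g$start, end = g$end)))
  ex <- do.call(rbind, lapply(genes, function(g)
    data.frame(transcript_id = paste0(g$gene_id, ".t1"), gene_id = g$gene_id,
               chrom = g$chrom, strand = g$strand,
               start = g$exons$start, end = g$exons$end)))
  tx <- unique(ex[, c("transcript_id", "gene_id")])
  rownames(gtab) <- rownames(ex) <- rownames(tx) <- NULL
  genome_annotation(chromosomes = chrom_lengths, genes = gtab,
                    transcripts = tx, exons = ex)
}

#' Simulate two-condition spliced paired-end alignments
#'
#' Draws per-gene read-pair counts from a Poisson model (fold changes applied
#' to the emb135 mean), emits spliced fragments from canonical and planted
#' alternative isoforms (50/50 for AS genes), tiles read pairs over planted
#' novel TUs at the configured depth, substitutes planted variant alleles at
#' genotype-consistent rates (het 50% per fragment haplotype, hom 100%),
#' applies sequencing errors and planted mismatches, and assigns each read a
#' multiplicity category at the configured fractions. Deterministic given
#' seed + config.
#'
#' @param sim a [simulate_genome()] result.
#' @return list with `alignments` (named list of `bovtx_alignments` for
#'   `emb135` and `adult30m`) and `truth` (gene counts, per-read categories,
#'   novel TUs, AS events, variants).
#' @export
simulate_alignments <- function(sim) {
  stopifnot(inherits(sim, "simulated_genome"))
  cfg <- sim$config
  conds <- c("emb135", "adult30m")
  out <- list()
  gene_counts <- list()
  read_cats <- list()
  for (w in seq_along(conds)) {
    cond <- conds[w]
    set.seed(cfg$seed + 101L * w)
    acc_df <- list()
    acc_blocks <- list()
    for (g in sim$genes) {
      mean_pairs <- g$mean_pairs * if (cond == "emb135") g$fold else 1
      n_pairs <- stats::rpois(1L, mean_pairs)
      gene_counts[[length(gene_counts) + 1L]] <-
        data.frame(gene_id = g$gene_id, condition = cond,
                   true_pairs = n_pairs)
      if (n_pairs == 0L) next
      isoforms <- list(g$exons)
      if (!is.na(g$as_type)) isoforms <- c(isoforms, list(g$alt_exons))
      r <- emit_fragments(sim, cfg, cond, g$gene_id, g$chrom, isoforms,
                          n_pairs, tiled = FALSE)
      acc_df[[length(acc_df) + 1L]] <- r$df
      acc_blocks[[length(acc_blocks) + 1L]] <- r$blocks
    }
    for (tu in sim$novel_tus) {
      tlen <- tu$total_length
      rl <- cfg$read_length
      n_pairs <- as.integer(ceiling(cfg$novel_tu_depth * tlen / (2 * rl)))
      r <- emit_fragments(sim, cfg, cond, tu$tu_id, tu$chrom,
                          list(tu$blocks), n_pairs, tiled = TRUE)
      acc_df[[length(acc_df) + 1L]] <- r$df
      acc_blocks[[length(acc_blocks) + 1L]] <- r$blocks
    }
    df <- do.call(rbind, acc_df)
    df$blocks <- do.call(c, acc_blocks)
    class(df) <- c("bovtx_alignments", "data.frame")
    attr(df, "chrom_lengths") <- cfg$chrom_lengths
    out[[cond]] <- df
    read_cats[[w]] <- data.frame(condition = cond, qname = df$qname,
                                 mate = df$mate,
                                 category = df$multiplicity,
                                 nm = df$nm)
  }
  truth <- list(
    gene_counts = do.call(rbind, gene_counts),
    read_categories = do.call(rbind, read_cats),
    novel_tus = sim$novel_tus,
    as_events = do.call(rbind, lapply(sim$genes, function(g)
      if (!is.na(g$as_type))
        data.frame(gene_id = g$gene_id, type = g$as_type) else NULL)),
    variants = sim$variants)
  list(alignments = out, truth = truth)
}

# emit n_pairs paired reads from a set of isoforms (exon data.frames);
# tiled = TRUE lays fragment starts deterministically for guaranteed coverage
#' @noRd
emit_fragments <- function(sim, cfg, cond, src_id, chrom, isoforms, n_pairs,
                           tiled = FALSE) {
  rl <- cfg$read_length
  chromseq <- sim$genome[[chrom]]
  vv <- sim$variants[sim$variants$chrom == chrom, , drop = FALSE]
  tx_lens <- vapply(isoforms, function(e) sum(e$end - e$start), 0L)
  if (any(tx_lens < rl))
    stop("read length ", rl, " exceeds the span of isoform of ", src_id)
  if (tiled) {
    tlen <- tx_lens[1]
    frag <- max(rl, min(cfg$fragment_mean, (tlen + 160L) %/% 2L, tlen))
    n_half <- max(ceiling(n_pairs / 2),
                  if (tlen > frag) ceiling((tlen - frag) / rl) + 1L else 1L)
    s_one <- if (tlen == frag) rep(0L, n_half) else
      as.integer(round(seq(0L, tlen - frag, length.out = max(n_half, 2L))))
    starts <- rep(s_one, 2L)
    frags <- rep(frag, length(starts))
    iso_idx <- rep(1L, length(starts))
    n_pairs <- length(starts)
  } else {
    iso_idx <- if (length(isoforms) > 1)
      sample(seq_along(isoforms), n_pairs, replace = TRUE) else
        rep(1L, n_pairs)
    frags <- pmin(pmax(as.integer(round(stats::rnorm(
      n_pairs, cfg$fragment_mean, cfg$fragment_sd))), rl),
      tx_lens[iso_idx], 700L)
    starts <- as.integer(floor(stats::runif(n_pairs) *
                                 (tx_lens[iso_idx] - frags + 1L)))
  }
  qnames <- sprintf("%s_%s_p%06d", cond, src_id, seq_len(n_pairs))
  probs <- c(unmapped = cfg$frac_unmapped, multi = cfg$frac_multi)
  err <- if (cfg$sequencing_errors) 10^(-cfg$base_quality / 10) else 0
  qualstr <- strrep(rawToChar(as.raw(cfg$base_quality + 33L)), rl)
  n <- 2L * n_pairs
  df <- data.frame(qname = rep(qnames, each = 2L), flag = integer(n),
                   chrom = rep(chrom, n), pos = integer(n),
                   mapq = integer(n), strand = rep(c("+", "-"), n_pairs),
                   multiplicity = character(n), nm = integer(n),
                   mate = rep(c(1L, 2L), n_pairs), orphan = FALSE,
                   seq = character(n), qual = rep(qualstr, n))
  blocks <- vector("list", n)
  for (i in seq_len(n_pairs)) {
    exons <- isoforms[[iso_idx[i]]]
    for (m in 1:2) {
      hap_alt <- stats::runif(1) < 0.5 # read drawn from the het-alt haplotype
      row <- 2L * (i - 1L) + m
      a <- if (m == 1L) starts[i] else starts[i] + frags[i] - rl
      b <- a + rl
      bl <- tx_to_blocks(a, b, exons)
      read <- build_read_seq(chromseq, bl, vv, hap_alt, err, cfg, rl)
      u <- stats::runif(1)
      cat <- if (u < probs["unmapped"]) "unmapped"
             else if (u < sum(probs)) "multi" else "unique"
      df$multiplicity[row] <- cat
      df$seq[row] <- read$seq
      if (cat == "unmapped") {
        df$nm[row] <- NA_integer_
        df$pos[row] <- NA_integer_
        df$chrom[row] <- NA_character_
        df$mapq[row] <- 0L
        blocks[[row]] <- empty_blocks()
      } else {
        df$nm[row] <- read$nm
        df$pos[row] <- bl[1, "ref_start"]
        df$mapq[row] <- if (cat == "multi") 0L else 60L
        blocks[[row]] <- bl
      }
    }
    m1u <- df$multiplicity[2L * i - 1L] == "unmapped"
    m2u <- df$multiplicity[2L * i] == "unmapped"
    both <- !m1u && !m2u
    df$flag[2L * i - 1L] <- 1L + 64L + 32L + (if (both) 2L else 0L) +
      (if (m1u) 4L else 0L) + (if (m2u) 8L else 0L)
    df$flag[2L * i] <- 1L + 128L + 16L + (if (both) 2L else 0L) +
      (if (m2u) 4L else 0L) + (if (m1u) 8L else 0L)
  }
  list(df = df, blocks = blocks)
}

# transcript-coordinate interval [a, b) -> genomic blocks over exons
#' @noRd
tx_to_blocks <- function(a, b, exons) {
  lens <- exons$end - exons$start
  cum0 <- cumsum(c(0L, lens))
  res <- list()
  for (i in seq_len(nrow(exons))) {
    lo <- max(a, cum0[i])
    hi <- min(b, cum0[i + 1L])
    if (hi > lo)
      res[[length(res) + 1L]] <- c(exons$start[i] + (lo - cum0[i]),
                                   exons$start[i] + (hi - cum0[i]), lo - a)
  }
  m <- do.call(rbind, res)
  storage.mode(m) <- "integer"
  colnames(m) <- c("ref_start", "ref_end", "q_start")
  m
}

# reference sequence for blocks + variant alleles + planted mismatches +
# sequencing errors, capping total mismatches at 3 (aligner emulation)
#' @noRd
build_read_seq <- function(chromseq, bl, vv, hap_alt, err, cfg, rl) {
  refseq <- paste(substring(chromseq, bl[, "ref_start"] + 1L,
                            bl[, "ref_end"]), collapse = "")
  chars <- strsplit(refseq, "")[[1]]
  # planted variant alleles (het: only on the alt haplotype)
  if (nrow(vv) > 0) {
    for (k in seq_len(nrow(vv))) {
      p <- vv$pos[k]
      hit <- which(bl[, "ref_start"] <= p & p < bl[, "ref_end"])
      if (length(hit) == 1L && (vv$genotype[k] == "hom" || hap_alt))
        chars[bl[hit, "q_start"] + (p - bl[hit, "ref_start"]) + 1L] <-
          vv$alt[k]
    }
  }
  nm <- sum(chars != strsplit(refseq, "")[[1]])
  # planted mismatches then sequencing errors, never exceeding 3 total
  n_plant <- if (nm < 3L && stats::runif(1) < cfg$frac_mismatch)
    sample.int(3L - nm, 1L) else 0L
  n_err <- if (err > 0) stats::rbinom(1L, rl, err) else 0L
  n_sub <- min(n_plant + n_err, 3L - nm)
  if (n_sub > 0L) {
    at <- sample.int(rl, n_sub)
    for (p in at)
      chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  seq <- paste(chars, collapse = "")
  list(seq = seq,
       nm = sum(chars != strsplit(refseq, "")[[1]]))
}

#' Run the simulator and write its files
#'
#' Convenience wrapper writing `genome.fa`, `genes.gtf`, `emb135.sam`,
#' `adult30m.sam` and `truth/*.tsv` into a directory.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created if needed).
#' @return the [simulate_alignments()] result, invisibly.
#' @export
simulate_to_files <- function(config, outdir) {
  dir.create(file.path(outdir, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  sim <- simulate_genome(config)
  res <- simulate_alignments(sim)
  write_genome(sim$genome, file.path(outdir, "genome.fa"))
  write_gtf(sim$annotation, file.path(outdir, "genes.gtf"))
  write_sam(res$alignments$emb135, file.path(outdir, "emb135.sam"))
  write_sam(res$alignments$adult30m, file.path(outdir, "adult30m.sam"))
  write_tsv(res$truth$gene_counts, file.path(outdir, "truth",
                                             "gene_counts.tsv"))
  write_tsv(res$truth$read_categories,
            file.path(outdir, "truth", "read_categories.tsv"))
  if (!is.null(res$truth$as_events))
    write_tsv(res$truth$as_events, file.path(outdir, "truth",
                                             "as_events.tsv"))
  write_tsv(res$truth$variants, file.path(outdir, "truth", "variants.tsv"))
  ntu <- do.call(rbind, lapply(res$truth$novel_tus, function(t)
    data.frame(tu_id = t$tu_id, chrom = t$chrom,
               start = min(t$blocks$start), end = max(t$blocks$end),
               total_length = t$total_length)))
  if (!is.null(ntu))
    write_tsv(ntu, file.path(outdir, "truth", "novel_tus.tsv"))
  invisible(res)
}
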