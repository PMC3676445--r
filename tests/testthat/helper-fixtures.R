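# shared fixtures and independent oracles used across test files

# hand-construct an alignment table; each read is
# list(qname, chrom, blocks = matrix(c(s1,e1, s2,e2,...), ncol=2, byrow=TRUE),
#      mult, nm, seq, qual, mate, strand)
make_records <- function(reads, chrom_lengths) {
  if (length(reads) == 0) {
    out <- data.frame(qname = character(0), flag = integer(0),
                      chrom = character(0), pos = integer(0),
                      mapq = integer(0), strand = character(0),
                      multiplicity = character(0), nm = integer(0),
                      mate = integer(0), orphan = logical(0),
                      seq = character(0), qual = character(0))
    out$blocks <- list()
    class(out) <- c("bovtx_alignments", "data.frame")
    attr(out, "chrom_lengths") <- chrom_lengths
    return(out)
  }
  rows <- lapply(seq_along(reads), function(i) {
    r <- reads[[i]]
    mult <- r$mult %||% "unique"
    bl <- if (mult == "unmapped" || is.null(r$blocks)) {
      matrix(integer(0), ncol = 3,
             dimnames = list(NULL, c("ref_start", "ref_end", "q_start")))
    } else {
      b <- matrix(as.integer(r$blocks), ncol = 2, byrow = TRUE)
      lens <- b[, 2] - b[, 1]
      cbind(ref_start = b[, 1], ref_end = b[, 2],
            q_start = as.integer(cumsum(c(0L, lens))[seq_along(lens)]))
    }
    len <- if (nrow(bl)) sum(bl[, 2] - bl[, 1]) else nchar(r$seq %||% "A")
    seq <- r$seq %||% strrep("A", len)
    mate <- r$mate %||% 1L
    flag <- if (mult == "unmapped") bitwOr(1L, 4L) else 0L
    flag <- bitwOr(flag, if (!is.null(r$mate)) {
      bitwOr(1L, if (mate == 1L) 64L else 128L)
    } else 0L)
    df <- data.frame(qname = r$qname, flag = flag,
                     chrom = if (mult == "unmapped") NA_character_ else
                       r$chrom,
                     pos = if (nrow(bl)) bl[1, 1] else NA_integer_,
                     mapq = if (mult == "multi") 0L else 60L,
                     strand = r$strand %||% "+",
                     multiplicity = mult, nm = r$nm %||% 0L,
                     mate = mate,
                     orphan = FALSE, seq = seq,
                     qual = r$qual %||% strrep("?", nchar(seq)))
    list(df = df, bl = bl)
  })
  out <- do.call(rbind, lapply(rows, `[[`, "df"))
  out$blocks <- lapply(rows, `[[`, "bl")
  class(out) <- c("bovtx_alignments", "data.frame")
  attr(out, "chrom_lengths") <- chrom_lengths
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-gene-per-call annotation builder; exons = matrix(c(s,e,...), byrow)
toy_annotation <- function(..., chrom_lengths = c(chr1 = 10000L)) {
  genes <- list(...)
  ex <- do.call(rbind, lapply(seq_along(genes), function(i) {
    g <- genes[[i]]
    b <- matrix(as.integer(g$exons), ncol = 2, byrow = TRUE)
    data.frame(transcript_id = paste0(g$id, ".t1"), gene_id = g$id,
               chrom = g$chrom %||% "chr1", strand = g$strand %||% "+",
               start = b[, 1], end = b[, 2])
  }))
  gtab <- do.call(rbind, lapply(split(ex, ex$gene_id), function(g)
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               strand = g$strand[1], start = min(g$start), end = max(g$end))))
  rownames(gtab) <- NULL
  genome_annotation(chromosomes = chrom_lengths, genes = gtab,
                    transcripts = unique(ex[, c("transcript_id", "gene_id")]),
                    exons = ex)
}

# independent linear-scan TAR oracle: walk the depth vector base by base
tar_oracle <- function(depth, min_depth = 2) {
  out <- list()
  s <- NA
  for (i in seq_along(depth)) {
    if (depth[i] >= min_depth && is.na(s)) s <- i - 1L
    if (depth[i] < min_depth && !is.na(s)) {
      out[[length(out) + 1L]] <- c(s, i - 1L)
      s <- NA
    }
  }
  if (!is.na(s)) out[[length(out) + 1L]] <- c(s, length(depth))
  do.call(rbind, out)
}

# brute-force per-base coverage oracle
coverage_oracle <- function(records, chrom, L) {
  depth <- integer(L)
  u <- records[records$multiplicity == "unique" & !is.na(records$chrom) &
                 records$chrom == chrom, , drop = FALSE]
  for (bl in u$blocks)
    for (j in seq_len(nrow(bl)))
      for (p in seq(bl[j, "ref_start"] + 1L, bl[j, "ref_end"]))
        depth[p] <- depth[p] + 1L
  depth
}

# brute-force connected components over fragment-link cliques
component_oracle <- function(n_tars, frag_tars) {
  comp <- seq_len(n_tars)
  repeat {
    changed <- FALSE
    for (ts in frag_tars) {
      ts <- unique(ts)
      if (length(ts) < 2) next
      m <- min(comp[ts])
      if (any(comp[ts] != m)) {
        comp[ts] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# exhaustive-enumeration posterior oracle over the 10 diploid genotypes,
# computed in plain probability space with nested loops
posterior_oracle <- function(bases, quals, ref, het = 1e-3, hom_alt = 5e-4,
                             titv = 2) {
  gts <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")
  b4 <- c("A", "C", "G", "T")
  ts <- function(a, b) (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
  alts <- setdiff(b4, ref)
  w <- vapply(alts, function(a) if (ts(ref, a)) titv else 1, 0)
  w <- w / sum(w)
  prior <- numeric(10)
  for (i in 1:10) {
    a <- substr(gts[i], 1, 1); b <- substr(gts[i], 2, 2)
    prior[i] <- if (a == ref && b == ref) 1 - het - hom_alt
      else if (a == ref) het * w[[b]]
      else if (b == ref) het * w[[a]]
      else if (a == b) hom_alt * w[[a]]
      else het * hom_alt * w[[a]] * w[[b]]
  }
  prior <- prior / sum(prior)
  lik <- numeric(10)
  for (i in 1:10) {
    a <- substr(gts[i], 1, 1); b <- substr(gts[i], 2, 2)
    L <- 1
    for (o in seq_along(bases)) {
      e <- 10^(-quals[o] / 10)
      pa <- if (bases[o] == a) 1 - e else e / 3
      pb <- if (bases[o] == b) 1 - e else e / 3
      L <- L * (pa / 2 + pb / 2)
    }
    lik[i] <- L
  }
  post <- lik * prior
  stats::setNames(post / sum(post), gts)
}

# noise-free simulation shared by the planted-recovery tests; built once
clean_sim_env <- new.env()
clean_sim <- function() {
  if (is.null(clean_sim_env$res)) {
    cfg <- simulation_config(seed = 11, frac_multi = 0, frac_unmapped = 0,
                             frac_mismatch = 0, sequencing_errors = FALSE,
                             gene_mean_pairs = 300)
    sim <- simulate_genome(cfg)
    clean_sim_env$res <- list(sim = sim, al = simulate_alignments(sim))
  }
  clean_sim_env$res
}

# default (noisy) simulation shared by summary/io tests
noisy_sim_env <- new.env()
noisy_sim <- function() {
  if (is.null(noisy_sim_env$res)) {
    cfg <- simulation_config(seed = 5)
    sim <- simulate_genome(cfg)
    noisy_sim_env$res <- list(sim = sim, al = simulate_alignments(sim))
  }
  noisy_sim_env$res
}
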