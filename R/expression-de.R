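#' Count reads per gene
#'
#' A uniquely mapped read increments a gene when any of its aligned blocks
#' overlaps the gene's exon union by >= 1 bp; a read overlapping exons of two
#' genes increments both and is flagged ambiguous in the attribute
#' `n_ambiguous`.
#'
#' @param records a `bovtx_alignments` table.
#' @param annotation a [genome_annotation()].
#' @return named integer vector of counts, one per annotated gene.
#' @export
count_reads_per_gene <- function(records, annotation) {
  genes <- annotation$genes$gene_id
  counts <- stats::setNames(integer(length(genes)), genes)
  u <- unique_records(records)
  n_amb <- 0L
  if (nrow(u) > 0 && length(genes) > 0) {
    eu <- exon_union(annotation)
    nb <- vapply(u$blocks, nrow, 0L)
    bl <- do.call(rbind, u$blocks)
    owner <- rep(seq_len(nrow(u)), nb)
    bchrom <- u$chrom[owner]
    pairs <- list()
    for (chrom in unique(bchrom)) {
      bi <- which(bchrom == chrom)
      ei <- which(eu$chrom == chrom)
      if (length(ei) == 0) next
      hits <- overlap_hits0(bl[bi, "ref_start"], bl[bi, "ref_end"],
                            eu$start[ei], eu$end[ei])
      if (nrow(hits) > 0)
        pairs[[chrom]] <- unique(data.frame(
          read = owner[bi[hits$query]],
          gene = eu$gene_id[ei[hits$subject]]))
    }
    hit <- do.call(rbind, pairs)
    if (!is.null(hit) && nrow(hit) > 0) {
      tab <- table(factor(hit$gene, levels = genes))
      counts[names(tab)] <- as.integer(tab)
      n_amb <- sum(table(hit$read) > 1)
    }
  }
  attr(counts, "n_ambiguous") <- n_amb
  counts
}

#' RPKM
#'
#' Reads per kilobase of exon model per million mapped reads:
#' `count / ((total_mapped/1e6) * (exon_length_bp/1e3))`.
#'
#' @param count read count(s).
#' @param exon_length_bp exon-union length(s) in bp (> 0).
#' @param total_mapped library size, total mapped reads (> 0).
#' @return RPKM value(s); 0 exactly when `count` is 0.
#' @export
rpkm <- function(count, exon_length_bp, total_mapped) {
  if (any(exon_length_bp <= 0)) stop("exon length must be positive")
  if (any(total_mapped <= 0)) stop("library size must be positive")
  count / ((total_mapped / 1e6) * (exon_length_bp / 1e3))
}

#' Build a two-library gene count table
#'
#' @param records_a,records_b `bovtx_alignments` tables for the two libraries
#'   (by pipeline convention a = emb135, b = adult30m).
#' @param annotation a [genome_annotation()].
#' @param library_size `"total_mapped"` (all mapped reads, the default) or
#'   `"gene_mapped"` (reads counted to genes).
#' @return data.frame of class `gene_count_table`: `gene_id`, `exon_length`,
#'   `count_a`, `count_b`, `rpkm_a`, `rpkm_b`; library sizes in attributes
#'   `N1`, `N2`.
#' @export
build_count_table <- function(records_a, records_b, annotation,
                              library_size = c("total_mapped",
                                               "gene_mapped")) {
  library_size <- match.arg(library_size)
  ca <- count_reads_per_gene(records_a, annotation)
  cb <- count_reads_per_gene(records_b, annotation)
  eu <- exon_union(annotation)
  len <- tapply(eu$end - eu$start, eu$gene_id, sum)[names(ca)]
  N1 <- if (library_size == "total_mapped")
    sum(records_a$multiplicity != "unmapped") else sum(ca)
  N2 <- if (library_size == "total_mapped")
    sum(records_b$multiplicity != "unmapped") else sum(cb)
  gene_count_table(names(ca), as.integer(ca), as.integer(cb),
                   as.integer(len), N1, N2)
}

#' Construct a gene count table from raw counts
#'
#' @param gene_id gene identifiers.
#' @param count_a,count_b per-gene read counts in the two libraries.
#' @param exon_length exon-union length per gene (bp).
#' @param N1,N2 library sizes (total mapped reads).
#' @return data.frame of class `gene_count_table` (see
#'   [build_count_table()]).
#' @export
gene_count_table <- function(gene_id, count_a, count_b, exon_length, N1, N2) {
  stopifnot(all(count_a >= 0), all(count_b >= 0), all(exon_length > 0),
            N1 > 0, N2 > 0)
  out <- data.frame(gene_id = gene_id, exon_length = exon_length,
                    count_a = count_a, count_b = count_b,
                    rpkm_a = rpkm(count_a, exon_length, N1),
                    rpkm_b = rpkm(count_b, exon_length, N2))
  class(out) <- c("gene_count_table", "data.frame")
  attr(out, "N1") <- N1
  attr(out, "N2") <- N2
  out
}

#' Audic-Claverie exact count test
#'
#' Two-sided exact test for a difference between the counts `x` and `y` of
#' one gene in two libraries of sizes `N1` and `N2`, under the Poisson
#' sampling model. The conditional mass of `y` given `x` is
#' `p(y|x) = (N2/N1)^y * (x+y)! / (x! y! (1+N2/N1)^(x+y+1))`; the two-sided
#' p-value doubles the smaller of the two tails and is capped at 1. Sums are
#' accumulated in log space, so extreme counts never underflow to a zero
#' p-value.
#'
#' @param x,y non-negative integer counts (vectorised).
#' @param N1,N2 positive library sizes.
#' @return p-value(s) in (0, 1].
#' @export
audic_claverie_p <- function(x, y, N1, N2) {
  stopifnot(all(x >= 0), all(y >= 0), N1 > 0, N2 > 0)
  n <- max(length(x), length(y))
  x <- rep_len(x, n)
  y <- rep_len(y, n)
  vapply(seq_len(n), function(i) ac_p_scalar(x[i], y[i], N1, N2), 0)
}

#' @noRd
ac_p_scalar <- function(x, y, N1, N2) {
  logr <- log(N2) - log(N1)
  log1pr <- log1p(N2 / N1)
  lpmf <- function(k) k * logr + lgamma(x + k + 1) - lgamma(x + 1) -
    lgamma(k + 1) - (x + k + 1) * log1pr
  lo <- exp(logsumexp(lpmf(0:y)))
  # upper tail: terms decay geometrically beyond the conditional mode, so a
  # finite sum with a relative cut-off is exact to double precision
  mode_k <- (x + 1) * exp(logr)
  hi <- if (y <= mode_k) {
    1 - lo + exp(lpmf(y))
  } else {
    lmax <- lpmf(y)
    k <- y
    acc <- 0
    repeat {
      lt <- lpmf(k)
      acc <- acc + exp(lt - lmax)
      if (k > mode_k && exp(lt - lmax) < 1e-18 * acc) break
      k <- k + 1
      if (k > y + 1e7) break
    }
    exp(lmax) * acc
  }
  max(min(1, 2 * min(lo, hi)), .Machine$double.xmin)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity (via
#' [stats::p.adjust()]); the q-value of a gene is the smallest FDR at which
#' it would be called.
#'
#' @param p_values vector of p-values in (0, 1].
#' @return q-values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes
#'
#' Per gene: the Audic-Claverie p-value on the raw counts with the two
#' library sizes (the model's own normalisation), BH q-values, and a
#' library-size-normalised log2 ratio (both counts scaled to the mean library
#' size, pseudocount 1 added to the normalised counts only for the ratio,
#' never for the test). A gene is called up (higher in library a = emb135)
#' or down when `q <= fdr_max` and `|log2 ratio| >= lfc_min`.
#'
#' @param table a [gene_count_table()].
#' @param fdr_max FDR threshold (default 0.001).
#' @param lfc_min minimum |log2 ratio| (default 1).
#' @return data.frame of class `de_result`: the count table plus
#'   `log2_ratio`, `p`, `q`, `call` (`"up"`/`"down"`/`"not-DE"`); summary
#'   counts in attributes `n_up`, `n_down`.
#' @export
call_de <- function(table, fdr_max = 0.001, lfc_min = 1.0) {
  stopifnot(inherits(table, "gene_count_table"))
  N1 <- attr(table, "N1")
  N2 <- attr(table, "N2")
  Nbar <- (N1 + N2) / 2
  na <- table$count_a / N1 * Nbar
  nb <- table$count_b / N2 * Nbar
  log2_ratio <- log2((na + 1) / (nb + 1))
  p <- audic_claverie_p(table$count_a, table$count_b, N1, N2)
  q <- bh_fdr(p)
  call <- ifelse(q <= fdr_max & log2_ratio >= lfc_min, "up",
          ifelse(q <= fdr_max & log2_ratio <= -lfc_min, "down", "not-DE"))
  out <- cbind(as.data.frame(table),
               data.frame(log2_ratio = log2_ratio, p = p, q = q,
                          call = call))
  class(out) <- c("de_result", "data.frame")
  attr(out, "n_up") <- sum(call == "up")
  attr(out, "n_down") <- sum(call == "down")
  attr(out, "fdr_max") <- fdr_max
  attr(out, "lfc_min") <- lfc_min
  out
}
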