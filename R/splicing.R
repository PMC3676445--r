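#' Extract splice junctions from gapped alignments
#'
#' One junction per distinct (chromosome, donor, acceptor), where the donor
#' boundary is the end of the upstream aligned block and the acceptor boundary
#' the start of the downstream block (0-based). Only uniquely mapped reads
#' contribute, gaps must be positive, and both flanking blocks must anchor
#' with at least `min_anchor` aligned bases.
#'
#' @param records a `bovtx_alignments` table.
#' @param min_anchor minimum anchor length on each side (default 8).
#' @return data.frame with `chrom`, `donor`, `acceptor`, `support` (number of
#'   distinct supporting unique reads), sorted by coordinate.
#' @export
extract_junctions <- function(records, min_anchor = 8L) {
  u <- unique_records(records)
  rows <- list()
  for (i in seq_len(nrow(u))) {
    b <- u$blocks[[i]]
    if (nrow(b) < 2) next
    for (j in seq_len(nrow(b) - 1L)) {
      gap <- b[j + 1L, "ref_start"] - b[j, "ref_end"]
      if (gap <= 0) next
      if (b[j, "ref_end"] - b[j, "ref_start"] < min_anchor) next
      if (b[j + 1L, "ref_end"] - b[j + 1L, "ref_start"] < min_anchor) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = u$chrom[i], donor = b[j, "ref_end"],
        acceptor = b[j + 1L, "ref_start"], read = paste(u$qname[i], u$mate[i]))
    }
  }
  if (length(rows) == 0)
    return(data.frame(chrom = character(0), donor = integer(0),
                      acceptor = integer(0), support = integer(0)))
  all <- do.call(rbind, rows)
  key <- paste(all$chrom, all$donor, all$acceptor)
  agg <- tapply(all$read, key, function(r) length(unique(r)))
  first <- all[!duplicated(key), , drop = FALSE]
  out <- data.frame(chrom = first$chrom, donor = first$donor,
                    acceptor = first$acceptor,
                    support = as.integer(agg[paste(first$chrom, first$donor,
                                                   first$acceptor)]))
  out <- out[order(out$chrom, out$donor, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign junctions to genes
#'
#' A junction is assigned to every gene whose span contains both of its
#' boundaries; junctions inside no gene span are dropped from AS calling.
#' Junctions falling into several overlapping genes are assigned to each and
#' flagged ambiguous.
#'
#' @param junctions data.frame from [extract_junctions()].
#' @param annotation a [genome_annotation()].
#' @return data.frame of junction rows with added `gene_id` and `ambiguous`.
#' @export
assign_junctions_to_genes <- function(junctions, annotation) {
  g <- annotation$genes
  out <- list()
  for (chrom in unique(junctions$chrom)) {
    ji <- which(junctions$chrom == chrom)
    gi <- which(g$chrom == chrom)
    if (length(gi) == 0) next
    for (j in ji) {
      inside <- gi[g$start[gi] <= junctions$donor[j] &
                     junctions$acceptor[j] <= g$end[gi]]
      if (length(inside) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = junctions$chrom[j], donor = junctions$donor[j],
        acceptor = junctions$acceptor[j], support = junctions$support[j],
        gene_id = g$gene_id[inside],
        ambiguous = length(inside) > 1)
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(chrom = character(0), donor = integer(0),
               acceptor = integer(0), support = integer(0),
               gene_id = character(0), ambiguous = logical(0))
  rownames(res) <- NULL
  res
}

#' Classify alternative-splicing events for one gene
#'
#' The four implemented types, from the gene's junction set (support >=
#' `min_support`) and, for coverage-based evidence, a depth vector:
#' \describe{
#'   \item{alt_5ss / alt_3ss}{two junctions sharing one boundary and differing
#'     at the other; the label names the transcript-side splice site that
#'     varies, so it is strand-aware (a shared donor on the plus strand is an
#'     alternative 3' site; on the minus strand the same pair is an
#'     alternative 5' site).}
#'   \item{exon_skipping}{a junction spanning a complete annotated internal
#'     exon whose inclusion is independently supported (a junction ending at
#'     its start or starting at its end, or exon coverage >= `min_depth` at
#'     every base).}
#'   \item{intron_retention}{an annotated intron with every base covered >=
#'     `min_depth` while a junction also supports its spliced form.}
#' }
#'
#' @param gene_id gene identifier.
#' @param junctions assigned junctions for this gene (as from
#'   [assign_junctions_to_genes()], already or not yet subset to the gene).
#' @param annotation a [genome_annotation()].
#' @param depth depth vector for the gene's chromosome (required for
#'   intron retention and coverage-based exon inclusion; may be `NULL`).
#' @param min_support minimum junction support (default 2).
#' @param min_depth coverage threshold for retention/inclusion (default 2).
#' @return data.frame with one row per event: `gene_id`, `type`, `chrom`,
#'   junction coordinates `j1_donor`, `j1_acceptor`, `j2_donor`,
#'   `j2_acceptor` (NA where unused), `exon_start`/`exon_end` (skipping),
#'   `intron_start`/`intron_end` (retention), `support`.
#' @export
classify_as_events <- function(gene_id, junctions, annotation, depth = NULL,
                               min_support = 2L, min_depth = 2) {
  if ("gene_id" %in% names(junctions))
    junctions <- junctions[junctions$gene_id == gene_id, , drop = FALSE]
  jn <- junctions[junctions$support >= min_support, , drop = FALSE]
  jn <- jn[order(jn$donor, jn$acceptor), , drop = FALSE]
  g <- annotation$genes[annotation$genes$gene_id == gene_id, ]
  stopifnot(nrow(g) == 1)
  strand <- g$strand
  ev <- list()
  add <- function(type, j1d, j1a, j2d = NA, j2a = NA, exs = NA, exe = NA,
                  ins = NA, ine = NA, support = NA) {
    ev[[length(ev) + 1L]] <<- data.frame(
      gene_id = gene_id, type = type, chrom = g$chrom,
      j1_donor = j1d, j1_acceptor = j1a, j2_donor = j2d, j2_acceptor = j2a,
      exon_start = exs, exon_end = exe, intron_start = ins, intron_end = ine,
      support = support)
  }
  if (nrow(jn) >= 2) {
    for (d in unique(jn$donor)) { # shared donor, different acceptor
      grp <- jn[jn$donor == d, , drop = FALSE]
      if (nrow(grp) < 2) next
      type <- if (strand == "+") "alt_3ss" else "alt_5ss"
      cmb <- utils::combn(nrow(grp), 2)
      for (k in seq_len(ncol(cmb)))
        add(type, grp$donor[cmb[1, k]], grp$acceptor[cmb[1, k]],
            grp$donor[cmb[2, k]], grp$acceptor[cmb[2, k]],
            support = grp$support[cmb[1, k]] + grp$support[cmb[2, k]])
    }
    for (a in unique(jn$acceptor)) { # shared acceptor, different donor
      grp <- jn[jn$acceptor == a, , drop = FALSE]
      if (nrow(grp) < 2) next
      type <- if (strand == "+") "alt_5ss" else "alt_3ss"
      cmb <- utils::combn(nrow(grp), 2)
      for (k in seq_len(ncol(cmb)))
        add(type, grp$donor[cmb[1, k]], grp$acceptor[cmb[1, k]],
            grp$donor[cmb[2, k]], grp$acceptor[cmb[2, k]],
            support = grp$support[cmb[1, k]] + grp$support[cmb[2, k]])
    }
  }
  ex <- annotation$exons[annotation$exons$gene_id == gene_id, , drop = FALSE]
  internal <- list()
  introns <- list()
  for (tx in split(ex, ex$transcript_id)) {
    tx <- tx[order(tx$start), ]
    k <- nrow(tx)
    if (k >= 3)
      for (i in 2:(k - 1))
        internal[[length(internal) + 1L]] <- c(tx$start[i], tx$end[i])
    if (k >= 2)
      for (i in seq_len(k - 1))
        introns[[length(introns) + 1L]] <- c(tx$end[i], tx$start[i + 1])
  }
  covered <- function(s, e) {
    !is.null(depth) && e <= length(depth) && min(depth[(s + 1):e]) >= min_depth
  }
  if (nrow(jn) >= 1 && length(internal) > 0) {
    for (e in unique(internal)) {
      skips <- jn[jn$donor <= e[1] & jn$acceptor >= e[2], , drop = FALSE]
      if (nrow(skips) == 0) next
      included <- any(jn$acceptor == e[1]) || any(jn$donor == e[2]) ||
        covered(e[1], e[2])
      if (!included) next
      for (k in seq_len(nrow(skips)))
        add("exon_skipping", skips$donor[k], skips$acceptor[k],
            exs = e[1], exe = e[2], support = skips$support[k])
    }
  }
  if (nrow(jn) >= 1 && length(introns) > 0) {
    for (iv in unique(introns)) {
      spliced <- jn[jn$donor == iv[1] & jn$acceptor == iv[2], , drop = FALSE]
      if (nrow(spliced) == 0) next
      if (!covered(iv[1], iv[2])) next
      add("intron_retention", iv[1], iv[2], ins = iv[1], ine = iv[2],
          support = spliced$support[1])
    }
  }
  res <- do.call(rbind, ev) %||% data.frame(
    gene_id = character(0), type = character(0), chrom = character(0),
    j1_donor = integer(0), j1_acceptor = integer(0), j2_donor = integer(0),
    j2_acceptor = integer(0), exon_start = integer(0), exon_end = integer(0),
    intron_start = integer(0), intron_end = integer(0), support = integer(0))
  res <- unique(res)
  rownames(res) <- NULL
  res
}

#' Classify AS events over all genes of an alignment set
#'
#' Convenience wrapper: junction extraction, gene assignment and per-gene
#' classification, computing per-chromosome coverage for the
#' retention/inclusion evidence.
#'
#' @param records a `bovtx_alignments` table.
#' @param annotation a [genome_annotation()].
#' @inheritParams classify_as_events
#' @param min_anchor minimum junction anchor (default 8).
#' @return data.frame of events (see [classify_as_events()]).
#' @export
find_as_events <- function(records, annotation, min_support = 2L,
                           min_depth = 2, min_anchor = 8L) {
  jn <- extract_junctions(records, min_anchor)
  asg <- assign_junctions_to_genes(jn, annotation)
  depths <- list()
  out <- list()
  for (gid in unique(asg$gene_id)) {
    chrom <- annotation$genes$chrom[annotation$genes$gene_id == gid]
    if (is.null(depths[[chrom]]))
      depths[[chrom]] <- compute_coverage(records, chrom,
                                          annotation$chromosomes[[chrom]])
    out[[length(out) + 1L]] <- classify_as_events(
      gid, asg, annotation, depths[[chrom]], min_support, min_depth)
  }
  res <- do.call(rbind, out) %||% classify_as_events_empty()
  rownames(res) <- NULL
  res
}

#' @noRd
classify_as_events_empty <- function() {
  data.frame(gene_id = character(0), type = character(0),
             chrom = character(0), j1_donor = integer(0),
             j1_acceptor = integer(0), j2_donor = integer(0),
             j2_acceptor = integer(0), exon_start = integer(0),
             exon_end = integer(0), intron_start = integer(0),
             intron_end = integer(0), support = integer(0))
}

#' Summarise alternative-splicing events
#'
#' Per-type event and gene counts, the distribution of events per gene, the
#' multi-event gene fraction, and retained-intron size statistics.
#'
#' @param events data.frame from [find_as_events()].
#' @return list with `type_counts` (data.frame `type`, `events`, `genes`),
#'   `events_per_gene` (named integer table), `multi_event_fraction`
#'   (genes with >= 2 events / genes with >= 1), and `retained_intron_size`
#'   (`mean`, `min`, `max`, or NULL without retention events).
#' @export
summarize_as <- function(events) {
  types <- c("exon_skipping", "intron_retention", "alt_5ss", "alt_3ss")
  tc <- data.frame(
    type = types,
    events = vapply(types, function(t) sum(events$type == t), 0L),
    genes = vapply(types, function(t)
      length(unique(events$gene_id[events$type == t])), 0L))
  rownames(tc) <- NULL
  per_gene <- if (nrow(events) > 0) table(events$gene_id) else
    table(character(0))
  n1 <- sum(per_gene >= 1)
  ir <- events[events$type == "intron_retention", , drop = FALSE]
  list(type_counts = tc,
       events_per_gene = per_gene,
       multi_event_fraction = if (n1 > 0) sum(per_gene >= 2) / n1 else NA,
       retained_intron_size = if (nrow(ir) > 0) {
         sz <- ir$intron_end - ir$intron_start
         list(mean = mean(sz), min = min(sz), max = max(sz))
       } else NULL)
}
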