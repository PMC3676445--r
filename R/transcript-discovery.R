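#' Per-base read coverage of a chromosome
#'
#' Depth of uniquely mapped aligned blocks at every base. Splice gaps
#' (and any other inter-block gap) contribute nothing.
#'
#' @param records a `bovtx_alignments` table (only `multiplicity == "unique"`
#'   records contribute).
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp; defaults to the table's
#'   `chrom_lengths` attribute.
#' @return integer vector of length `chrom_length`; element `i` is the depth
#'   at 0-based position `i - 1`.
#' @export
compute_coverage <- function(records, chrom, chrom_length = NULL) {
  chrom_length <- chrom_length %||% attr(records, "chrom_lengths")[[chrom]]
  stopifnot(!is.null(chrom_length), chrom_length > 0)
  u <- unique_records(records)
  u <- u[!is.na(u$chrom) & u$chrom == chrom, , drop = FALSE]
  if (nrow(u) == 0) return(integer(chrom_length))
  bl <- do.call(rbind, u$blocks)
  if (any(bl[, "ref_start"] < 0 | bl[, "ref_end"] > chrom_length))
    stop("aligned block outside chromosome ", chrom)
  add <- tabulate(bl[, "ref_start"] + 1L, nbins = chrom_length + 1L)
  rem <- tabulate(bl[, "ref_end"] + 1L, nbins = chrom_length + 1L)
  cumsum(add - rem)[seq_len(chrom_length)]
}

#' Detect transcriptionally active regions
#'
#' A TAR is a maximal run of bases each covered by at least `min_depth`
#' unique reads.
#'
#' @param depth integer depth vector (as from [compute_coverage()]).
#' @param min_depth minimum per-base depth (default 2).
#' @param chrom chromosome label attached to the output.
#' @return data.frame with `tar_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `min_cov`, `mean_cov`; sorted, non-overlapping, maximal.
#' @export
detect_tars <- function(depth, min_depth = 2, chrom = NA_character_) {
  r <- rle(depth >= min_depth)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- which(r$values)
  if (length(keep) == 0)
    return(data.frame(tar_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      min_cov = integer(0), mean_cov = numeric(0)))
  s <- starts[keep]
  e <- ends[keep]
  data.frame(tar_id = sprintf("%s:TAR%04d", chrom, seq_along(s)),
             chrom = chrom, start = s, end = e,
             min_cov = vapply(seq_along(s), function(i)
               min(depth[(s[i] + 1L):e[i]]), numeric(1)),
             mean_cov = vapply(seq_along(s), function(i)
               mean(depth[(s[i] + 1L):e[i]]), 0))
}

#' Intergenic regions with 200 bp buffers
#'
#' The space between 200 bp downstream of one gene span and 200 bp upstream
#' of the next (merged) gene span; adjacent spans closer than 400 bp yield no
#' interval. Chromosome-end flanks are included with the 200 bp buffer on the
#' gene side only.
#'
#' @param annotation a [genome_annotation()].
#' @param buffer buffer size in bp (default 200).
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
intergenic_regions <- function(annotation, buffer = 200L) {
  out <- list()
  for (chrom in names(annotation$chromosomes)) {
    L <- annotation$chromosomes[[chrom]]
    g <- annotation$genes[annotation$genes$chrom == chrom, , drop = FALSE]
    if (nrow(g) == 0) {
      out[[chrom]] <- data.frame(chrom = chrom, start = 0L, end = L)
      next
    }
    m <- reduce_intervals0(g$start, g$end)
    iv <- list()
    if (m$start[1] - buffer > 0)
      iv[[length(iv) + 1L]] <- c(0L, m$start[1] - buffer)
    if (nrow(m) > 1) {
      for (i in seq_len(nrow(m) - 1L)) {
        gap <- m$start[i + 1L] - m$end[i]
        if (gap > 2L * buffer)
          iv[[length(iv) + 1L]] <- c(m$end[i] + buffer,
                                     m$start[i + 1L] - buffer)
      }
    }
    if (m$end[nrow(m)] + buffer < L)
      iv[[length(iv) + 1L]] <- c(m$end[nrow(m)] + buffer, L)
    if (length(iv) > 0) {
      ivm <- do.call(rbind, iv)
      out[[chrom]] <- data.frame(chrom = chrom, start = ivm[, 1],
                                 end = ivm[, 2])
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  rownames(res) <- NULL
  res
}

#' Connect TARs into transcript units via paired-end links
#'
#' Two TARs belong to the same transcript unit when some fragment (read pair)
#' has aligned blocks in both; singleton TARs form singleton units. Connected
#' components are taken over the link graph.
#'
#' @param tars data.frame from [detect_tars()] (possibly several chromosomes
#'   concatenated).
#' @param records a `bovtx_alignments` table; unique records only are used,
#'   and all TARs touched by the two mates of one fragment are linked.
#' @return data.frame with `unit_id`, `chrom`, `start`, `end` (span),
#'   `n_tars`, `total_length` (sum of member TAR lengths), `mean_cov`
#'   (depth averaged over member-TAR bases), and a list-column `members` of
#'   member `tar_id`s.
#' @export
join_tars <- function(tars, records) {
  if (nrow(tars) == 0)
    return(data.frame(unit_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_tars = integer(0), total_length = integer(0),
                      mean_cov = numeric(0)))
  u <- unique_records(records)
  edges <- list()
  if (nrow(u) > 0) {
    nb <- vapply(u$blocks, nrow, 0L)
    bl <- do.call(rbind, u$blocks)
    frag <- rep(u$qname, nb)
    bchrom <- rep(u$chrom, nb)
    touched <- rep(NA_integer_, length(frag))
    for (chrom in unique(tars$chrom)) {
      ti <- which(tars$chrom == chrom)
      bi <- which(bchrom == chrom)
      if (length(ti) == 0 || length(bi) == 0) next
      hits <- overlap_hits0(bl[bi, "ref_start"], bl[bi, "ref_end"],
                            tars$start[ti], tars$end[ti])
      touched[bi[hits$query]] <- ti[hits$subject]
    }
    byfrag <- split(touched[!is.na(touched)], frag[!is.na(touched)])
    for (ts in byfrag) {
      ts <- unique(ts)
      if (length(ts) > 1)
        edges[[length(edges) + 1L]] <- cbind(ts[-length(ts)], ts[-1L])
    }
  }
  gr <- igraph::make_empty_graph(n = nrow(tars), directed = FALSE)
  if (length(edges) > 0)
    gr <- igraph::add_edges(gr, t(do.call(rbind, edges)))
  comp <- igraph::components(gr)$membership
  out <- lapply(sort(unique(comp)), function(cc) {
    m <- which(comp == cc)
    tlen <- sum(tars$end[m] - tars$start[m])
    data.frame(unit_id = sprintf("TU%04d", cc),
               chrom = tars$chrom[m[1]],
               start = min(tars$start[m]), end = max(tars$end[m]),
               n_tars = length(m), total_length = tlen,
               mean_cov = sum(tars$mean_cov[m] *
                                (tars$end[m] - tars$start[m])) / tlen)
  })
  res <- do.call(rbind, out)
  res$members <- lapply(sort(unique(comp)),
                        function(cc) tars$tar_id[comp == cc])
  rownames(res) <- NULL
  res
}

#' Call novel transcript units
#'
#' A transcript unit is novel when (i) none of its member TARs overlaps any
#' annotated gene span, (ii) its span lies within an intergenic interval,
#' (iii) its total length (sum of member TAR lengths) is >= `min_length`, and
#' (iv) its mean coverage over member-TAR bases is >= `min_mean_cov`.
#' Filter outcomes are recorded per unit.
#'
#' @param units data.frame from [join_tars()].
#' @param tars the TAR table the units were built from (for filter (i)).
#' @param annotation a [genome_annotation()].
#' @param intergenic data.frame from [intergenic_regions()].
#' @param min_length minimum total length (default 150).
#' @param min_mean_cov minimum mean coverage (default 2).
#' @param keep_all if `TRUE`, return all units with their filter flags;
#'   otherwise only the passing (novel) units.
#' @return `units` rows with added logical columns `no_gene_overlap`,
#'   `in_intergenic`, `long_enough`, `covered_enough`, `novel`.
#' @export
call_novel_tus <- function(units, tars, annotation, intergenic,
                           min_length = 150, min_mean_cov = 2,
                           keep_all = FALSE) {
  if (nrow(units) == 0) {
    units$no_gene_overlap <- logical(0)
    units$in_intergenic <- logical(0)
    units$long_enough <- logical(0)
    units$covered_enough <- logical(0)
    units$novel <- logical(0)
    return(units)
  }
  g <- annotation$genes
  no_overlap <- vapply(seq_len(nrow(units)), function(i) {
    m <- tars[tars$tar_id %in% units$members[[i]], , drop = FALSE]
    gi <- which(g$chrom == units$chrom[i])
    if (length(gi) == 0) return(TRUE)
    nrow(overlap_hits0(m$start, m$end, g$start[gi], g$end[gi])) == 0
  }, TRUE)
  in_inter <- vapply(seq_len(nrow(units)), function(i) {
    ii <- which(intergenic$chrom == units$chrom[i])
    any(intergenic$start[ii] <= units$start[i] &
          units$end[i] <= intergenic$end[ii])
  }, TRUE)
  units$no_gene_overlap <- no_overlap
  units$in_intergenic <- in_inter
  units$long_enough <- units$total_length >= min_length
  units$covered_enough <- units$mean_cov >= min_mean_cov
  units$novel <- units$no_gene_overlap & units$in_intergenic &
    units$long_enough & units$covered_enough
  if (keep_all) units else units[units$novel, , drop = FALSE]
}

#' Refine annotated gene boundaries from TARs
#'
#' A TAR overlapping a gene's terminal exon and protruding beyond the
#' annotated gene span extends that end; the end is labelled 5'/3' by strand
#' and the extension length is the protrusion in bp. When several TARs
#' protrude at one end the longest protrusion is reported.
#'
#' @param annotation a [genome_annotation()].
#' @param tars data.frame from [detect_tars()].
#' @return data.frame with `gene_id`, `end` (`"5prime"`/`"3prime"`),
#'   `extension` (bp, > 0), `tar_id`.
#' @export
refine_boundaries <- function(annotation, tars) {
  out <- list()
  for (gi in seq_len(nrow(annotation$genes))) {
    g <- annotation$genes[gi, ]
    ex <- annotation$exons[annotation$exons$gene_id == g$gene_id, ,
                           drop = FALSE]
    if (nrow(ex) == 0) next
    ti <- which(tars$chrom == g$chrom)
    if (length(ti) == 0) next
    left_ex <- ex[which.min(ex$start), ]
    right_ex <- ex[which.max(ex$end), ]
    hit_l <- ti[overlap_hits0(tars$start[ti], tars$end[ti],
                              left_ex$start, left_ex$end)$query]
    hit_r <- ti[overlap_hits0(tars$start[ti], tars$end[ti],
                              right_ex$start, right_ex$end)$query]
    prot_l <- g$start - tars$start[hit_l]
    prot_r <- tars$end[hit_r] - g$end
    if (length(prot_l) > 0 && max(prot_l) > 0) {
      b <- hit_l[which.max(prot_l)]
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g$gene_id,
        end = if (g$strand == "+") "5prime" else "3prime",
        extension = max(prot_l), tar_id = tars$tar_id[b])
    }
    if (length(prot_r) > 0 && max(prot_r) > 0) {
      b <- hit_r[which.max(prot_r)]
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g$gene_id,
        end = if (g$strand == "+") "3prime" else "5prime",
        extension = max(prot_r), tar_id = tars$tar_id[b])
    }
  }
  res <- do.call(rbind, out) %||%
    data.frame(gene_id = character(0), end = character(0),
               extension = integer(0), tar_id = character(0))
  rownames(res) <- NULL
  res
}

#' Full novel-transcript-unit stage
#'
#' Coverage, TAR detection, pair connection and the intergenic novelty
#' filters, over every chromosome of an alignment set.
#'
#' @param records a `bovtx_alignments` table.
#' @param annotation a [genome_annotation()].
#' @param min_depth per-base TAR depth threshold (default 2).
#' @param min_length,min_mean_cov novel-TU filters (defaults 150 bp, 2).
#' @return list with `tars`, `units`, `intergenic`, `novel` (passing units).
#' @export
discover_transcripts <- function(records, annotation, min_depth = 2,
                                 min_length = 150, min_mean_cov = 2) {
  tars <- do.call(rbind, lapply(names(annotation$chromosomes), function(ch) {
    depth <- compute_coverage(records, ch,
                              annotation$chromosomes[[ch]])
    detect_tars(depth, min_depth, ch)
  }))
  units <- join_tars(tars, records)
  inter <- intergenic_regions(annotation)
  novel <- call_novel_tus(units, tars, annotation, inter,
                          min_length, min_mean_cov)
  list(tars = tars, units = units, intergenic = inter, novel = novel)
}
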