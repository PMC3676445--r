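#' Percentage of a total, rounded half-up to 2 decimals
#'
#' The rounding convention of alignment-summary tables: `100 * count / total`
#' with halves rounded up, printed to 2 decimals.
#'
#' @param count non-negative count, `<= total`.
#' @param total positive total.
#' @return numeric percentage with 2-decimal half-up rounding. `total = 0` is
#'   an error (undefined percentage).
#' @export
percentage <- function(count, total) {
  if (any(total == 0)) stop("percentage undefined for total = 0")
  stopifnot(all(count >= 0), all(count <= total))
  round_half_up(100 * count / total, 2)
}

#' Alignment-category summary
#'
#' Reproduces the standard read-accounting table for a set of alignments:
#' total reads and base pairs, mapped, perfectly matched, mismatched (<=3 bp),
#' uniquely matched, multi-position and unmapped, each with its percentage of
#' total reads. With `scope = "genes"` a read counts as mapped when any
#' aligned block overlaps an annotated exon by >= 1 bp; reads without such an
#' overlap (including genome-unmapped reads) count as unmapped at gene scope.
#'
#' @param records a `bovtx_alignments` table.
#' @param scope `"genome"` or `"genes"`.
#' @param annotation a [genome_annotation()]; required for gene scope.
#' @return data.frame of class `mapping_summary` with columns `category`,
#'   `count`, `percentage`. For an empty record set all counts are 0,
#'   percentages are reported as 0 and attribute `empty_input` is `TRUE`.
#' @export
summarize_mapping <- function(records, scope = c("genome", "genes"),
                              annotation = NULL) {
  scope <- match.arg(scope)
  total <- nrow(records)
  total_bp <- sum(nchar(records$seq))
  if (scope == "genome") {
    mapped_mask <- records$multiplicity != "unmapped"
  } else {
    if (is.null(annotation)) stop("gene scope requires an annotation")
    mapped_mask <- reads_overlap_exons(records, annotation)
  }
  uniq <- mapped_mask & records$multiplicity == "unique"
  multi <- mapped_mask & records$multiplicity == "multi"
  nm <- records$nm
  perfect <- mapped_mask & !is.na(nm) & nm == 0L
  mm3 <- mapped_mask & !is.na(nm) & nm >= 1L & nm <= 3L
  counts <- c(total_reads = total,
              total_base_pairs = total_bp,
              mapped = sum(mapped_mask),
              perfect_match = sum(perfect),
              mismatch_le3 = sum(mm3),
              unique_match = sum(uniq),
              multi_position = sum(multi),
              unmapped = total - sum(mapped_mask))
  pct <- if (total == 0) rep(0, length(counts)) else
    c(100, 100, percentage(counts[-(1:2)], total))
  out <- data.frame(category = names(counts), count = as.numeric(counts),
                    percentage = as.numeric(pct))
  class(out) <- c("mapping_summary", "data.frame")
  attr(out, "scope") <- scope
  attr(out, "empty_input") <- total == 0
  out
}

# logical mask: does any aligned block of each record overlap any exon?
#' @noRd
reads_overlap_exons <- function(records, annotation) {
  out <- rep(FALSE, nrow(records))
  ex <- annotation$exons
  if (nrow(ex) == 0 || nrow(records) == 0) return(out)
  mapped <- which(records$multiplicity != "unmapped")
  if (length(mapped) == 0) return(out)
  nb <- vapply(records$blocks[mapped], nrow, 0L)
  bl <- do.call(rbind, records$blocks[mapped])
  owner <- rep(mapped, nb)
  bchrom <- records$chrom[owner]
  for (chrom in unique(bchrom)) {
    bi <- which(bchrom == chrom)
    ei <- which(ex$chrom == chrom)
    if (length(ei) == 0) next
    hits <- overlap_hits0(bl[bi, "ref_start"], bl[bi, "ref_end"],
                          ex$start[ei], ex$end[ei])
    out[unique(owner[bi[hits$query]])] <- TRUE
  }
  out
}
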