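#' Genome annotation container
#'
#' The coordinate backbone of the pipeline: chromosome lengths and a
#' gene -> transcript -> exon hierarchy. All internal coordinates are 0-based
#' half-open; conversion to/from the 1-based closed convention happens only at
#' file boundaries ([read_gtf()], [write_gtf()], [write_vcf()]).
#'
#' @param chromosomes named integer vector of chromosome lengths (bp).
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `start`, `end` (gene span, 0-based half-open).
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`.
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open).
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(chromosomes, genes, transcripts, exons) {
  ann <- structure(
    list(chromosomes = chromosomes,
         genes = as.data.frame(genes),
         transcripts = as.data.frame(transcripts),
         exons = as.data.frame(exons)),
    class = "genome_annotation")
  validate_annotation(ann)
  ann
}

#' Validate a genome_annotation
#'
#' Checks the structural invariants: exons within chromosome bounds, exons of
#' a transcript non-overlapping and coordinate-ordered, every transcript
#' referencing an existing gene.
#'
#' @param ann a `genome_annotation`.
#' @return `ann`, invisibly; errors describe the first violation found.
#' @export
validate_annotation <- function(ann) {
  stopifnot(inherits(ann, "genome_annotation"))
  ex <- ann$exons
  if (nrow(ex) > 0) {
    if (any(!ex$chrom %in% names(ann$chromosomes)))
      stop("exon on undeclared chromosome: ",
           ex$chrom[!ex$chrom %in% names(ann$chromosomes)][1])
    len <- ann$chromosomes[ex$chrom]
    if (any(ex$start < 0 | ex$end > len))
      stop("exon outside chromosome bounds: ",
           ex$transcript_id[which(ex$start < 0 | ex$end > len)[1]])
    if (any(ex$end <= ex$start))
      stop("empty or inverted exon interval")
    for (tx in split(ex, ex$transcript_id)) {
      o <- order(tx$start)
      if (any(tx$start[o][-1] < tx$end[o][-nrow(tx)]))
        stop("overlapping exons in transcript ", tx$transcript_id[1])
    }
  }
  if (nrow(ann$transcripts) > 0 &&
      any(!ann$transcripts$gene_id %in% ann$genes$gene_id))
    stop("transcript references unknown gene")
  invisible(ann)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", length(x$chromosomes), "chromosome(s),",
      nrow(x$genes), "gene(s),", nrow(x$transcripts), "transcript(s),",
      nrow(x$exons), "exon(s)\n")
  invisible(x)
}

#' Read a GTF file into a genome_annotation
#'
#' Parses exon features from a GTF (1-based closed coordinates) and converts
#' them to the internal 0-based half-open convention. Gene spans are the
#' min-start/max-end over each gene's exons. Chromosome lengths are taken from
#' `chrom_lengths` when supplied, otherwise inferred as the maximum exon end
#' per chromosome.
#'
#' @param path path to a GTF file.
#' @param chrom_lengths optional named integer vector of chromosome lengths;
#'   exons beyond a declared length are an error.
#' @return A [genome_annotation()].
#' @export
read_gtf <- function(path, chrom_lengths = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(genome_annotation(
      chromosomes = chrom_lengths %||% integer(0),
      genes = data.frame(gene_id = character(0), chrom = character(0),
                         strand = character(0), start = integer(0),
                         end = integer(0)),
      transcripts = data.frame(transcript_id = character(0),
                               gene_id = character(0)),
      exons = data.frame(transcript_id = character(0), gene_id = character(0),
                         chrom = character(0), strand = character(0),
                         start = integer(0), end = integer(0))))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9))
    stop("malformed GTF line ", idx[which(nf < 9)[1]],
         ": expected 9 tab-separated fields, got ", nf[which(nf < 9)[1]])
  feat <- vapply(fields, `[`, "", 3L)
  exi <- which(feat == "exon")
  get_attr <- function(attr, key, line) {
    m <- regmatches(attr, regexec(paste0(key, ' "([^"]+)"'), attr))[[1]]
    if (length(m) < 2)
      stop("malformed GTF line ", line, ": missing ", key)
    m[2]
  }
  ex <- do.call(rbind, lapply(exi, function(i) {
    f <- fields[[i]]
    start1 <- suppressWarnings(as.integer(f[4]))
    end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1) || start1 < 1 || end1 < start1)
      stop("malformed GTF line ", idx[i], ": bad coordinates")
    data.frame(transcript_id = get_attr(f[9], "transcript_id", idx[i]),
               gene_id = get_attr(f[9], "gene_id", idx[i]),
               chrom = f[1], strand = f[7],
               start = start1 - 1L, end = end1)
  }))
  if (is.null(ex))
    ex <- data.frame(transcript_id = character(0), gene_id = character(0),
                     chrom = character(0), strand = character(0),
                     start = integer(0), end = integer(0))
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(ex$end, ex$chrom), max, 0L)
  } else {
    bad <- ex$chrom %in% names(chrom_lengths) &
      ex$end > chrom_lengths[ex$chrom]
    if (any(bad))
      stop("exon beyond declared chromosome length (line near ",
           idx[exi[which(bad)[1]]], ")")
  }
  ex <- ex[order(ex$chrom, ex$transcript_id, ex$start), , drop = FALSE]
  rownames(ex) <- NULL
  genes <- do.call(rbind, lapply(split(ex, ex$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               strand = g$strand[1], start = min(g$start), end = max(g$end))
  }))
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  tx <- unique(ex[, c("transcript_id", "gene_id")])
  rownames(tx) <- NULL
  genome_annotation(chromosomes = chrom_lengths, genes = genes,
                    transcripts = tx, exons = ex)
}

#' Write a genome_annotation to GTF
#'
#' Emits one `exon` feature line per exon, converting internal 0-based
#' half-open intervals back to the GTF 1-based closed convention.
#'
#' @param ann a `genome_annotation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  validate_annotation(ann)
  ex <- ann$exons
  lines <- if (nrow(ex) == 0) character(0) else
    sprintf('%s\tbovtx\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id,
            ex$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' Per-gene exon unions
#'
#' Collapses each gene's exons (across all transcripts) into a disjoint set of
#' intervals; the exon model used for read counting and for the RPKM length.
#'
#' @param ann a `genome_annotation`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open, disjoint within gene).
#' @export
exon_union <- function(ann) {
  if (nrow(ann$exons) == 0)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0)))
  out <- lapply(split(ann$exons, ann$exons$gene_id), function(g) {
    u <- reduce_intervals0(g$start, g$end)
    data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
               start = u$start, end = u$end)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
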