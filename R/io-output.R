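#' Write intervals to BED
#'
#' BED is 0-based half-open, the same as the internal convention, so
#' coordinates pass through unchanged.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name` and `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) > 0 && any(intervals$end <= intervals$start))
    stop("empty or inverted interval in BED output")
  name <- intervals$name %||% rep(".", nrow(intervals))
  score <- intervals$score %||% rep(0, nrow(intervals))
  lines <- if (nrow(intervals) == 0) character(0) else
    sprintf("%s\t%d\t%d\t%s\t%s", intervals$chrom,
            as.integer(intervals$start), as.integer(intervals$end),
            as.character(name), format(score, trim = TRUE))
  writeLines(lines, path)
  invisible(path)
}

#' Strict BED re-parser
#'
#' @param path a BED file written by [write_bed()].
#' @return data.frame with `chrom`, `start`, `end`, `name`, `score`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0)))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 3)) stop("malformed BED line")
  out <- data.frame(chrom = vapply(f, `[`, "", 1),
                    start = as.integer(vapply(f, `[`, "", 2)),
                    end = as.integer(vapply(f, `[`, "", 3)),
                    name = vapply(f, function(x) x[4] %||% ".", ""),
                    score = vapply(f, function(x)
                      suppressWarnings(as.numeric(x[5] %||% "0")), 0))
  if (any(is.na(out$start) | is.na(out$end) | out$end <= out$start))
    stop("malformed BED coordinates")
  out
}

#' Write SNP calls to VCF
#'
#' Emits a minimal VCF 4.2 with `GT`, `GQ` and `DP`; internal 0-based
#' positions are shifted to the VCF 1-based convention. An empty call set
#' yields a valid header-only file.
#'
#' @param snps data.frame of SNP calls as produced by [call_snps()] (columns
#'   `chrom`, `pos`, `ref`, `genotype`, `quality`, `alt_support`, `depth`,
#'   `pass`, `fail_reasons`).
#' @param path output path.
#' @param chrom_lengths named integer vector for `##contig` lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snps, path, chrom_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bovtx",
           if (!is.null(chrom_lengths))
             sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
                     as.integer(chrom_lengths)),
           '##FILTER=<ID=q20,Description="Consensus quality below threshold">',
           '##FILTER=<ID=alt2,Description="Fewer than required unique reads supporting the non-reference allele">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Consensus quality">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample")
  lines <- character(0)
  if (!is.null(snps) && nrow(snps) > 0) {
    lines <- vapply(seq_len(nrow(snps)), function(i) {
      alleles <- strsplit(snps$genotype[i], "")[[1]]
      alts <- unique(alleles[alleles != snps$ref[i]])
      gt_idx <- match(alleles, c(snps$ref[i], alts)) - 1L
      paste(snps$chrom[i], snps$pos[i] + 1L, ".", snps$ref[i],
            paste(alts, collapse = ","),
            format(round(snps$quality[i], 2), trim = TRUE),
            if (snps$pass[i]) "PASS" else snps$fail_reasons[i],
            sprintf("DP=%d", snps$depth[i]), "GT:GQ:DP",
            sprintf("%s:%d:%d", paste(sort(gt_idx), collapse = "/"),
                    as.integer(round(snps$quality[i])), snps$depth[i]),
            sep = "\t")
    }, "")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Strict VCF re-parser
#'
#' Reads back a VCF written by [write_vcf()]; positions return to the internal
#' 0-based convention.
#'
#' @param path a VCF path.
#' @return data.frame with `chrom`, `pos` (0-based), `ref`, `alt`, `qual`,
#'   `filter`, `genotype`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || lines[1] != "##fileformat=VCFv4.2")
    stop("not a VCF 4.2 file")
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      qual = numeric(0), filter = character(0),
                      genotype = character(0)))
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) < 10)) stop("malformed VCF record")
  gt <- vapply(f, function(x) sub(":.*", "", x[10]), "")
  data.frame(chrom = vapply(f, `[`, "", 1),
             pos = as.integer(vapply(f, `[`, "", 2)) - 1L,
             ref = vapply(f, `[`, "", 4),
             alt = vapply(f, `[`, "", 5),
             qual = as.numeric(vapply(f, `[`, "", 6)),
             filter = vapply(f, `[`, "", 7),
             genotype = gt)
}

#' Write a table to TSV with header
#'
#' @param table a data.frame (list-columns are collapsed with commas).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(table, path) {
  tab <- as.data.frame(table)
  for (j in seq_along(tab))
    if (is.list(tab[[j]]))
      tab[[j]] <- vapply(tab[[j]], function(x) paste(x, collapse = ","), "")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genome FASTA as a named character vector
#'
#' @param path FASTA path.
#' @return named character vector of upper-case sequences.
#' @export
read_genome <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(dss)), names(dss))
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = 70L)
  invisible(path)
}
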