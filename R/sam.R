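#' Read a SAM file into an alignment table
#'
#' Parses a text SAM file into one row per record. CIGAR `M`/`=`/`X` operations
#' consume reference and query and build aligned blocks; `N` closes a block and
#' opens a splice gap; `I`/`D` split blocks so that within every block the
#' query offset maps affinely onto the reference; `S`/`H`/`P` never produce
#' aligned bases. Soft-clipped bases shift the query offset only.
#'
#' Multiplicity is taken from the record, never recomputed: the unmapped flag
#' (0x4) gives `"unmapped"`; otherwise an `NH` tag > 1 (or, absent `NH`,
#' mapping quality 0) gives `"multi"`, else `"unique"`. Mismatch counts come
#' from the `NM` tag. Mates are paired by read name; a paired-flag record whose
#' mate is missing from the file is kept but flagged `orphan`.
#'
#' @param path path to a SAM file with an `@SQ` header.
#' @return A data.frame of class `bovtx_alignments` with columns `qname`,
#'   `flag`, `chrom`, `pos` (0-based leftmost), `mapq`, `strand`,
#'   `multiplicity`, `nm`, `mate` (1, 2 or NA), `orphan`, `seq`, `qual`, and a
#'   list-column `blocks` of integer matrices with columns `ref_start`,
#'   `ref_end` (0-based half-open) and `q_start` (0-based query offset).
#'   Chromosome lengths from the header are attached as attribute
#'   `chrom_lengths`.
#' @export
read_sam <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  is_hdr <- grepl("^@", lines)
  hdr <- lines[is_hdr]
  sq <- hdr[grepl("^@SQ", hdr)]
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  chrom_lengths <- stats::setNames(ln, sn)
  body <- lines[!is_hdr & nzchar(lines)]
  if (length(body) == 0L) {
    out <- empty_alignments()
    attr(out, "chrom_lengths") <- chrom_lengths
    return(out)
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11))
    stop("malformed SAM record at line ", which(!is_hdr)[which(nf < 11)[1]])
  getf <- function(i) vapply(fields, `[`, "", i)
  qname <- getf(1L)
  flag <- as.integer(getf(2L))
  rname <- getf(3L)
  pos1 <- as.integer(getf(4L))
  mapq <- as.integer(getf(5L))
  cigar <- getf(6L)
  seq <- getf(10L)
  qual <- getf(11L)
  unmapped <- bitwAnd(flag, 4L) > 0L
  if (any(!unmapped & !(rname %in% names(chrom_lengths))))
    stop("SAM record references chromosome absent from header: ",
         rname[!unmapped & !(rname %in% names(chrom_lengths))][1])
  tagval <- function(tag) {
    pat <- paste0("^", tag, ":i:")
    vapply(fields, function(f) {
      if (length(f) <= 11L) return(NA_integer_)
      hit <- f[-(1:11)][startsWith(f[-(1:11)], paste0(tag, ":i:"))]
      if (length(hit) == 0L) NA_integer_ else as.integer(sub(pat, "", hit[1]))
    }, 1L)
  }
  nh <- tagval("NH")
  nm <- tagval("NM")
  multiplicity <- ifelse(unmapped, "unmapped",
                  ifelse(!is.na(nh), ifelse(nh > 1L, "multi", "unique"),
                         ifelse(mapq == 0L, "multi", "unique")))
  blocks <- vector("list", length(body))
  cig_ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))
  for (i in seq_along(body)) {
    if (unmapped[i]) {
      blocks[[i]] <- empty_blocks()
      next
    }
    blocks[[i]] <- cigar_blocks(cig_ops[[i]], pos1[i] - 1L)
    if (nrow(blocks[[i]]) == 0L)
      stop("mapped SAM record with no aligned bases: ", qname[i])
  }
  mate <- ifelse(bitwAnd(flag, 1L) > 0L,
                 ifelse(bitwAnd(flag, 64L) > 0L, 1L, 2L), NA_integer_)
  key <- paste(qname, mate)
  mate_key <- paste(qname, 3L - mate)
  orphan <- !is.na(mate) & !(mate_key %in% key)
  out <- data.frame(qname = qname, flag = flag,
                    chrom = ifelse(unmapped, NA_character_, rname),
                    pos = ifelse(unmapped, NA_integer_, pos1 - 1L),
                    mapq = mapq,
                    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                    multiplicity = multiplicity,
                    nm = ifelse(unmapped, NA_integer_, ifelse(is.na(nm), 0L, nm)),
                    mate = mate, orphan = orphan, seq = seq, qual = qual)
  out$blocks <- blocks
  class(out) <- c("bovtx_alignments", "data.frame")
  attr(out, "chrom_lengths") <- chrom_lengths
  out
}

#' @noRd
empty_blocks <- function() {
  matrix(integer(0), ncol = 3,
         dimnames = list(NULL, c("ref_start", "ref_end", "q_start")))
}

#' @noRd
empty_alignments <- function() {
  out <- data.frame(qname = character(0), flag = integer(0),
                    chrom = character(0), pos = integer(0), mapq = integer(0),
                    strand = character(0), multiplicity = character(0),
                    nm = integer(0), mate = integer(0), orphan = logical(0),
                    seq = character(0), qual = character(0))
  out$blocks <- list()
  class(out) <- c("bovtx_alignments", "data.frame")
  out
}

# walk CIGAR ops from 0-based reference position r0; returns the blocks matrix
#' @noRd
cigar_blocks <- function(ops, r0) {
  lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  kind <- substring(ops, nchar(ops))
  r <- r0
  q <- 0L
  res <- list()
  cur <- NULL # c(ref_start, ref_end, q_start)
  for (i in seq_along(ops)) {
    L <- lens[i]
    k <- kind[i]
    if (k %in% c("M", "=", "X")) {
      if (is.null(cur)) cur <- c(r, r + L, q)
      else cur[2] <- cur[2] + L
      r <- r + L
      q <- q + L
    } else if (k == "N") {
      if (!is.null(cur)) { res[[length(res) + 1L]] <- cur; cur <- NULL }
      r <- r + L
    } else if (k == "D") {
      if (!is.null(cur)) { res[[length(res) + 1L]] <- cur; cur <- NULL }
      r <- r + L
    } else if (k == "I") {
      if (!is.null(cur)) { res[[length(res) + 1L]] <- cur; cur <- NULL }
      q <- q + L
    } else if (k == "S") {
      q <- q + L
    } # H, P: no-op
  }
  if (!is.null(cur)) res[[length(res) + 1L]] <- cur
  if (length(res) == 0L) return(empty_blocks())
  m <- do.call(rbind, res)
  storage.mode(m) <- "integer"
  colnames(m) <- c("ref_start", "ref_end", "q_start")
  m
}

#' Write an alignment table to SAM
#'
#' Inverse of [read_sam()] for records produced by this package (contiguous
#' query within blocks). Gaps between consecutive blocks are emitted as `N`
#' operations; mapped records carry `NM` and `NH` tags, unmapped records get
#' flag bit 0x4 with `*` placeholders.
#'
#' @param records a `bovtx_alignments` table.
#' @param path output path.
#' @param chrom_lengths named integer vector for the `@SQ` header; defaults to
#'   the table's `chrom_lengths` attribute.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, chrom_lengths = NULL) {
  chrom_lengths <- chrom_lengths %||% attr(records, "chrom_lengths")
  stopifnot(!is.null(chrom_lengths))
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  n <- nrow(records)
  lines <- character(n)
  for (i in seq_len(n)) {
    if (records$multiplicity[i] == "unmapped") {
      lines[i] <- paste(records$qname[i], records$flag[i], "*", 0L, 0L, "*",
                        "*", 0L, 0L, records$seq[i], records$qual[i],
                        sep = "\t")
    } else {
      b <- records$blocks[[i]]
      parts <- sprintf("%dM", b[, "ref_end"] - b[, "ref_start"])
      if (nrow(b) > 1L) {
        gaps <- b[-1L, "ref_start"] - b[-nrow(b), "ref_end"]
        gapops <- ifelse(gaps > 0L, sprintf("%dN", gaps), "")
        cig <- paste0(paste0(parts[-length(parts)], gapops, collapse = ""),
                      parts[length(parts)])
      } else cig <- parts
      nh <- if (records$multiplicity[i] == "multi") 2L else 1L
      lines[i] <- paste(records$qname[i], records$flag[i], records$chrom[i],
                        b[1L, "ref_start"] + 1L, records$mapq[i], cig,
                        "*", 0L, 0L, records$seq[i], records$qual[i],
                        sprintf("NM:i:%d", records$nm[i]),
                        sprintf("NH:i:%d", nh), sep = "\t")
    }
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Keep uniquely mapped records
#'
#' Unmapped and multi-position records are excluded from every downstream
#' stage (coverage, junctions, counting, pileups), mirroring the standard
#' unique-read filter.
#'
#' @param records a `bovtx_alignments` table.
#' @return The subset with `multiplicity == "unique"`.
#' @export
unique_records <- function(records) {
  records[records$multiplicity == "unique", , drop = FALSE]
}
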