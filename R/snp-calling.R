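GENOTYPES10 <- c("AA", "AC", "AG", "AT", "CC", "CG", "CT", "GG", "GT", "TT")
BASES4 <- c("A", "C", "G", "T")

#' Diploid genotype prior
#'
#' Prior over the 10 unordered diploid genotypes given the reference base:
#' the heterozygous-site rate is shared over the three reference-containing
#' heterozygotes and the homozygous-alternative rate over the three
#' alternative homozygotes, both weighted by transition/transversion
#' preference; heterozygotes containing no reference allele get the product
#' of the two rates (times the allele weights). The vector is renormalised to
#' sum to 1.
#'
#' @param het heterozygous-site rate (default 1e-3).
#' @param hom_alt homozygous-alternative rate (default 5e-4).
#' @param titv transition:transversion weighting (default 2).
#' @return object of class `genotype_prior`.
#' @export
genotype_prior <- function(het = 1e-3, hom_alt = 5e-4, titv = 2) {
  stopifnot(het > 0, het < 1, hom_alt > 0, hom_alt < 1, titv > 0)
  structure(list(het = het, hom_alt = hom_alt, titv = titv),
            class = "genotype_prior")
}

# is a->b a transition?
#' @noRd
is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

#' Prior probabilities of the 10 genotypes for one reference base
#'
#' @param prior a [genotype_prior()].
#' @param ref reference base (`"A"/"C"/"G"/"T"`).
#' @return named numeric vector over [GENOTYPES10], summing to 1.
#' @export
prior_probs <- function(prior, ref) {
  stopifnot(inherits(prior, "genotype_prior"), ref %in% BASES4)
  alts <- setdiff(BASES4, ref)
  w <- ifelse(is_transition(ref, alts), prior$titv, 1)
  w <- w / sum(w)
  names(w) <- alts
  p <- stats::setNames(numeric(10), GENOTYPES10)
  for (g in GENOTYPES10) {
    a <- substr(g, 1, 1)
    b <- substr(g, 2, 2)
    p[g] <- if (a == ref && b == ref) {
      1 - prior$het - prior$hom_alt
    } else if (a == ref || b == ref) {
      alt <- if (a == ref) b else a
      prior$het * w[alt]
    } else if (a == b) {
      prior$hom_alt * w[a]
    } else {
      prior$het * prior$hom_alt * w[a] * w[b]
    }
  }
  p / sum(p)
}

#' Build a pileup from unique alignments
#'
#' One observation per aligned base of every uniquely mapped read; splice
#' gaps contribute nothing. Base and quality are taken at the aligned query
#' offset of each block.
#'
#' @param records a `bovtx_alignments` table.
#' @param genome named character vector of chromosome sequences (as from
#'   [read_genome()]).
#' @return data.frame of class `bovtx_pileup` with columns `chrom`, `pos`
#'   (0-based), `base`, `qual` (Phred), `qname`, sorted by position.
#' @export
build_pileup <- function(records, genome) {
  u <- unique_records(records)
  rows <- vector("list", nrow(u))
  for (i in seq_len(nrow(u))) {
    b <- u$blocks[[i]]
    L <- nchar(genome[[u$chrom[i]]])
    if (nrow(b) > 0 && max(b[, "ref_end"]) > L)
      stop("aligned block beyond end of chromosome ", u$chrom[i])
    seqc <- strsplit(u$seq[i], "")[[1]]
    qualc <- utf8ToInt(u$qual[i]) - 33L
    per <- vector("list", nrow(b))
    for (j in seq_len(nrow(b))) {
      len <- b[j, "ref_end"] - b[j, "ref_start"]
      off <- b[j, "q_start"] + seq_len(len)
      per[[j]] <- data.frame(chrom = u$chrom[i],
                             pos = b[j, "ref_start"] + seq_len(len) - 1L,
                             base = seqc[off], qual = qualc[off],
                             qname = paste(u$qname[i], u$mate[i]))
    }
    rows[[i]] <- do.call(rbind, per)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(chrom = character(0), pos = integer(0), base = character(0),
               qual = integer(0), qname = character(0))
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bovtx_pileup", "data.frame")
  out
}

#' Extract one pileup column
#'
#' @param pileup a `bovtx_pileup`.
#' @param chrom,pos site (0-based position).
#' @param genome named character vector of chromosome sequences.
#' @return list with `chrom`, `pos`, `ref`, `bases`, `quals`, `qnames`,
#'   `depth`.
#' @export
pileup_column <- function(pileup, chrom, pos, genome) {
  i <- which(pileup$chrom == chrom & pileup$pos == pos)
  list(chrom = chrom, pos = pos,
       ref = substring(genome[[chrom]], pos + 1L, pos + 1L),
       bases = pileup$base[i], quals = pileup$qual[i],
       qnames = pileup$qname[i], depth = length(i))
}

# observation x allele probability matrix: P(b_i | allele a)
#' @noRd
obs_allele_probs <- function(bases, quals) {
  eps <- 10^(-quals / 10)
  m <- matrix(rep(eps / 3, 4), ncol = 4, dimnames = list(NULL, BASES4))
  idx <- match(bases, BASES4)
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1 - eps[ok]
  m
}

#' Posterior genotype at one pileup column
#'
#' Likelihoods are `P(D|aa) = prod_i [1-eps_i if b_i=a else eps_i/3]` and
#' `P(D|ab) = prod_i [P(b_i|a)/2 + P(b_i|b)/2]` with `eps_i = 10^(-Q_i/10)`;
#' the posterior combines them with the diploid prior for the column's
#' reference base. Ties are broken toward reference-containing genotypes,
#' then lexicographically. The consensus quality is
#' `-10 log10(1 - posterior_best)`, capped at 99.
#'
#' @param column a [pileup_column()] (depth >= 1).
#' @param prior a [genotype_prior()].
#' @return list with `genotype` (e.g. `"AG"`), `quality`, and the full
#'   named `posterior` vector (sums to 1).
#' @export
genotype_posterior <- function(column, prior) {
  stopifnot(column$depth >= 1)
  pm <- obs_allele_probs(column$bases, column$quals)
  ll <- genotype_logliks(pm)
  lp <- log(prior_probs(prior, column$ref))
  post_l <- ll + lp
  post <- exp(post_l - logsumexp(post_l))
  contains_ref <- grepl(column$ref, GENOTYPES10, fixed = TRUE)
  ord <- order(-post, !contains_ref, GENOTYPES10)
  best <- ord[1]
  list(genotype = GENOTYPES10[best],
       quality = min(99, -10 * log10(max(1 - post[best], 1e-10))),
       posterior = stats::setNames(post, GENOTYPES10))
}

#' @noRd
genotype_logliks <- function(pm) {
  vapply(GENOTYPES10, function(g) {
    a <- substr(g, 1, 1)
    b <- substr(g, 2, 2)
    sum(log(0.5 * pm[, a] + 0.5 * pm[, b]))
  }, 0)
}

#' Call SNPs from a pileup
#'
#' Computes the posterior genotype at every covered site and reports those
#' whose consensus differs from homozygous reference. A call passes when the
#' consensus quality is at least `min_quality` and at least `min_alt_reads`
#' distinct unique reads carry a non-reference allele of the called genotype;
#' failing calls are kept with their reasons.
#'
#' @param pileup a `bovtx_pileup` (see [build_pileup()]).
#' @param genome named character vector of chromosome sequences.
#' @param prior a [genotype_prior()].
#' @param min_quality consensus-quality threshold (default 20).
#' @param min_alt_reads minimum distinct supporting reads (default 2).
#' @return data.frame of class `snp_calls`: `chrom`, `pos` (0-based), `ref`,
#'   `genotype`, `quality`, `depth`, `alt_support`, `pass`, `fail_reasons`.
#' @export
call_snps <- function(pileup, genome, prior = genotype_prior(),
                      min_quality = 20, min_alt_reads = 2) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), genotype = character(0),
                      quality = numeric(0), depth = integer(0),
                      alt_support = integer(0), pass = logical(0),
                      fail_reasons = character(0))
  class(empty) <- c("snp_calls", "data.frame")
  if (nrow(pileup) == 0) return(empty)
  site <- factor(paste(pileup$chrom, pileup$pos))
  si <- as.integer(site)
  n_sites <- nlevels(site)
  first <- !duplicated(si)
  schrom <- pileup$chrom[first][order(si[first])]
  spos <- pileup$pos[first][order(si[first])]
  sref <- vapply(seq_len(n_sites), function(s)
    substring(genome[[schrom[s]]], spos[s] + 1L, spos[s] + 1L), "")
  pm <- obs_allele_probs(pileup$base, pileup$qual)
  ll <- vapply(GENOTYPES10, function(g) {
    a <- substr(g, 1, 1)
    b <- substr(g, 2, 2)
    as.numeric(rowsum(log(0.5 * pm[, a] + 0.5 * pm[, b]), si))
  }, numeric(n_sites))
  ll <- matrix(ll, nrow = n_sites, ncol = 10,
               dimnames = list(NULL, GENOTYPES10))
  lp <- t(vapply(BASES4, function(r) log(prior_probs(prior, r)),
                 numeric(10)))
  valid <- sref %in% BASES4
  post_l <- ll
  post_l[valid, ] <- ll[valid, , drop = FALSE] +
    lp[match(sref[valid], BASES4), , drop = FALSE]
  # normalised posterior; tiny bonus implements the reference-then-
  # lexicographic tie preference without affecting non-tied sites
  mx <- apply(post_l, 1, max)
  post <- exp(post_l - mx) / rowSums(exp(post_l - mx))
  bonus <- outer(sref, GENOTYPES10,
                 function(r, g) grepl_fixed_vec(r, g) * 1e-12) +
    matrix(rep((10:1) * 1e-15, each = n_sites), nrow = n_sites)
  best <- max.col(post + bonus, ties.method = "first")
  called <- which(valid & GENOTYPES10[best] !=
                    paste0(sref, sref))
  if (length(called) == 0) return(empty)
  obs_by_site <- split(seq_len(nrow(pileup)), si)
  rows <- lapply(called, function(s) {
    gt <- GENOTYPES10[best[s]]
    alts <- setdiff(unique(strsplit(gt, "")[[1]]), sref[s])
    oi <- obs_by_site[[s]]
    alt_support <- length(unique(pileup$qname[oi][pileup$base[oi] %in% alts]))
    quality <- min(99, -10 * log10(max(1 - post[s, best[s]], 1e-10)))
    reasons <- c(if (quality < min_quality) "q20",
                 if (alt_support < min_alt_reads) "alt2")
    data.frame(chrom = schrom[s], pos = spos[s], ref = sref[s],
               genotype = gt, quality = quality, depth = length(oi),
               alt_support = alt_support, pass = length(reasons) == 0,
               fail_reasons = paste(reasons, collapse = ";"))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("snp_calls", "data.frame")
  out
}

#' @noRd
grepl_fixed_vec <- function(r, g) {
  vapply(seq_along(r), function(i) grepl(r[i], g[i], fixed = TRUE), TRUE)
}
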