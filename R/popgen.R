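# Windowed diversity and differentiation on the diploid unique-genotype
# panel: 100-kb bins with >= 3 SNPs, per-site nucleotide diversity,
# Tajima's D, Weir-Cockerham Fst.

#' Tile sites into fixed-width genomic bins
#'
#' Half-open bins of `width` bp per chromosome; bins holding fewer than
#' `min_snps` SNPs are excluded.
#'
#' @param sites Data frame with `chrom` and 1-based `pos`.
#' @param width Bin width in bp (default 100 kb).
#' @param min_snps Minimum SNPs for a bin to be reported (default 3).
#' @return Data frame `chrom`, `start`, `end` (1-based inclusive
#'   coordinates), `n_snps`, plus a list column `site_idx` of row indices
#'   into `sites`.
#' @export
make_bins <- function(sites, width = 1e5, min_snps = 3L) {
  bin0 <- (sites$pos - 1L) %/% width
  key <- paste(sites$chrom, bin0, sep = "\r")
  groups <- split(seq_len(nrow(sites)), key)
  keep <- vapply(groups, length, 1L) >= min_snps
  groups <- groups[keep]
  if (!length(groups)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_snps = integer(0)))
  }
  parts <- strsplit(names(groups), "\r", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    start = as.integer(as.integer(vapply(parts, `[`, "", 2L)) *
                                         width + 1L),
                    stringsAsFactors = FALSE)
  out$end <- as.integer(out$start + width - 1L)
  out$n_snps <- vapply(groups, length, 1L)
  out$site_idx <- unname(groups)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

## per-site allele summary from a loci-in-columns 012 matrix
site_counts <- function(m) {
  n_called <- colSums(!is.na(m))
  alt <- colSums(m, na.rm = TRUE)
  list(copies = 2L * n_called, alt = alt)
}

#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity `pi_s = m / (m - 1) * 2 p q` over the
#' `m` observed allele copies - identical to the mean pairwise difference
#' among the copies.
#'
#' @param m Individuals x loci 012 matrix (NA allowed).
#' @return Numeric vector, one value per locus (NA when fewer than two
#'   copies are observed).
#' @export
site_pi <- function(m) {
  sc <- site_counts(m)
  p <- sc$alt / sc$copies
  out <- ifelse(sc$copies >= 2,
                sc$copies / (sc$copies - 1) * 2 * p * (1 - p), NA_real_)
  unname(out)
}

#' Binned nucleotide diversity
#'
#' Mean per-site pi over the SNPs of each bin; with `per_bp = TRUE` the
#' sum of site pi is divided by the bin width instead, echoing the
#' per-base-pair normalisation of whole-genome tools.
#'
#' @param m Individuals x loci 012 matrix for one population.
#' @param bins Output of [make_bins()] over the matching site table.
#' @param per_bp Report pi per base pair of the bin (default FALSE:
#'   per analyzed SNP).
#' @param width Bin width used for the per-bp denominator.
#' @return `bins` with a `pi` column appended.
#' @export
nucleotide_diversity <- function(m, bins, per_bp = FALSE, width = 1e5) {
  ps <- site_pi(m)
  bins$pi <- vapply(bins$site_idx, function(idx) {
    v <- ps[idx]
    if (per_bp) sum(v, na.rm = TRUE) / width else mean(v, na.rm = TRUE)
  }, numeric(1))
  bins
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D over a set of sites
#'
#' `D = (k - S / a1) / sqrt(e1 S + e2 S (S - 1))` with `k` the mean
#' pairwise difference among allele copies, `S` the number of segregating
#' sites, and Tajima's constants computed at the (rounded) mean number of
#' observed copies over segregating sites. Undefined (NA) when `S = 0`.
#'
#' @param m Individuals x loci 012 matrix restricted to the sites of
#'   interest (e.g. one bin).
#' @return Tajima's D, or NA.
#' @export
tajimas_d <- function(m) {
  sc <- site_counts(m)
  seg <- sc$copies >= 2 & sc$alt > 0 & sc$alt < sc$copies
  S <- sum(seg)
  if (S == 0L) return(NA_real_)
  j <- sc$alt[seg]; mm <- sc$copies[seg]
  k <- sum(j * (mm - j) / choose(mm, 2))
  n <- round(mean(mm))
  if (n < 2) return(NA_real_)
  cst <- tajima_constants(n)
  denom <- sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)
  (k - S / cst$a1) / denom
}

#' Binned Tajima's D
#'
#' @param m Individuals x loci 012 matrix for one population.
#' @param bins Output of [make_bins()].
#' @return `bins` with a `tajima_d` column appended.
#' @export
binned_tajimas_d <- function(m, bins) {
  bins$tajima_d <- vapply(bins$site_idx, function(idx)
    tajimas_d(m[, idx, drop = FALSE]), numeric(1))
  bins
}

#' Weir-Cockerham Fst between two populations
#'
#' Per-site variance components `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals) of the
#' classical two-level estimator for `r = 2` populations, using observed
#' heterozygosities; the mean is the ratio of sums `sum(a) / sum(a+b+c)`
#' over usable sites. Negative per-site values are possible and retained.
#'
#' @param m1,m2 Individuals x loci 012 matrices for the two populations
#'   (same loci, NA allowed).
#' @return List: `per_site` (vector of per-site Fst), `mean` (ratio of
#'   sums), `a`, `b`, `c` component vectors.
#' @export
weir_cockerham_fst <- function(m1, m2) {
  stopifnot(ncol(m1) == ncol(m2))
  n1 <- colSums(!is.na(m1)); n2 <- colSums(!is.na(m2))
  if (all(n1 < 2) || all(n2 < 2))
    stop("each population needs at least 2 genotyped individuals")
  p1 <- colMeans(m1, na.rm = TRUE) / 2; p2 <- colMeans(m2, na.rm = TRUE) / 2
  h1 <- colMeans(m1 == 1, na.rm = TRUE); h2 <- colMeans(m2 == 1, na.rm = TRUE)
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  use <- n1 >= 2 & n2 >= 2 & (a + b + cc) != 0 & !is.na(a + b + cc)
  per_site <- rep(NA_real_, ncol(m1))
  per_site[use] <- (a / (a + b + cc))[use]
  list(per_site = per_site,
       mean = sum(a[use]) / sum((a + b + cc)[use]),
       a = a, b = b, c = cc)
}

#' Binned Weir-Cockerham Fst
#'
#' @param m1,m2 Individuals x loci 012 matrices for the two populations.
#' @param bins Output of [make_bins()].
#' @return `bins` with an `fst` column (ratio of component sums per bin).
#' @export
binned_fst <- function(m1, m2, bins) {
  wc <- weir_cockerham_fst(m1, m2)
  tot <- wc$a + wc$b + wc$c
  bins$fst <- vapply(bins$site_idx, function(idx) {
    use <- !is.na(tot[idx]) & tot[idx] != 0
    sum(wc$a[idx][use]) / sum(tot[idx][use])
  }, numeric(1))
  bins
}
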