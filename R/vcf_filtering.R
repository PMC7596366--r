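# VCF loading, site filtering (two regimes: full and SFS-grade), 012
# encoding with mean imputation.

#' Site-filter thresholds
#'
#' The default regime keeps biallelic SNPs with per-cell read depth >= 8,
#' minor-allele count >= 3, minor-allele frequency >= 0.05 and at most 10%
#' missing calls. The SFS-grade regime (`sfs_filter_params()`) is identical
#' but keeps rare variants by disabling the frequency filter.
#'
#' @param min_depth Per-cell read depth below which a call is masked.
#' @param min_allele_count Minimum minor-allele count (counted after depth
#'   masking).
#' @param min_maf Minimum minor-allele frequency; `0` disables the filter.
#' @param biallelic_only Drop sites with more than one alternate allele.
#' @param max_missing Maximum fraction of missing calls per site.
#' @return A `filter_params` list.
#' @export
filter_params <- function(min_depth = 8L, min_allele_count = 3L,
                          min_maf = 0.05, biallelic_only = TRUE,
                          max_missing = 0.10) {
  if (min_maf < 0 || min_maf >= 0.5) stop("min_maf must lie in [0, 0.5)")
  if (max_missing < 0 || max_missing > 1)
    stop("max_missing must lie in [0, 1]")
  structure(list(min_depth = as.integer(min_depth),
                 min_allele_count = as.integer(min_allele_count),
                 min_maf = min_maf, biallelic_only = isTRUE(biallelic_only),
                 max_missing = max_missing),
            class = "filter_params")
}

#' @rdname filter_params
#' @export
sfs_filter_params <- function() filter_params(min_maf = 0)

#' Load a VCF with genotype and read-count fields
#'
#' Parses a VCF 4.2 through \pkg{vcfR} and returns the package's read-count
#' table. Coordinates stay 1-based; records with more than one alternate
#' allele are retained but flagged `biallelic = FALSE` (their AD is reduced
#' to ref plus first alternate).
#'
#' @param path VCF file path.
#' @return An `rc_table` with `sites`, `samples`, `ref_reads`, `alt_reads`,
#'   `depth` and `gt` (0/1/2/NA diploid-style codes: any heterozygous call
#'   maps to 1, homozygous alternate to 2).
#' @export
load_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  fmt <- unique(v@gt[, "FORMAT"])
  if (!all(grepl("(^|:)GT(:|$)", fmt))) stop("VCF lacks a GT FORMAT field")
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      id = fix[, "ID"], ref = fix[, "REF"],
                      alt = fix[, "ALT"],
                      biallelic = !grepl(",", fix[, "ALT"]),
                      stringsAsFactors = FALSE)
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  gt <- matrix(NA_integer_, nrow(gt_chr), ncol(gt_chr),
               dimnames = dimnames(gt_chr))
  a1 <- substr(gt_chr, 1L, 1L)
  a2 <- substr(gt_chr, 3L, 3L)
  called <- !is.na(gt_chr) & a1 != "." & a2 != "."
  gt[called] <- (a1[called] != "0") + (a2[called] != "0")
  have_ad <- all(grepl("(^|:)AD(:|$)", fmt))
  if (have_ad) {
    ad <- vcfR::extract.gt(v, element = "AD")
    ref_reads <- vcfR::masplit(ad, record = 1L, sort = FALSE)
    alt_reads <- vcfR::masplit(ad, record = 2L, sort = FALSE)
    ref_reads[is.na(ref_reads)] <- 0L
    alt_reads[is.na(alt_reads)] <- 0L
  } else {
    ref_reads <- alt_reads <- matrix(0L, nrow(gt), ncol(gt),
                                     dimnames = dimnames(gt))
  }
  if (all(grepl("(^|:)DP(:|$)", fmt))) {
    depth <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    depth[is.na(depth)] <- 0L
    storage.mode(depth) <- "integer"
  } else depth <- ref_reads + alt_reads
  storage.mode(ref_reads) <- "integer"
  storage.mode(alt_reads) <- "integer"
  new_rc_table(sites, colnames(gt), ref_reads, alt_reads, depth, gt)
}

#' Apply site filters in the fixed order of the pipeline
#'
#' Cells with depth below `min_depth` are masked (set missing) before any
#' site-level test; sites then fail, in order: non-biallelic, minor-allele
#' count, minor-allele frequency, missingness. Allele counts and
#' frequencies are computed on the non-missing calls that survive the depth
#' mask. Removal counts per criterion are attached as attribute
#' `"removed"`; filtering is idempotent.
#'
#' @param rct An `rc_table`.
#' @param params A [filter_params()].
#' @return The filtered `rc_table` (masked cells missing), with attribute
#'   `removed` = named integer vector of sites dropped per criterion.
#' @export
apply_site_filters <- function(rct, params = filter_params()) {
  stopifnot(inherits(rct, "rc_table"), inherits(params, "filter_params"))
  gt <- rct$gt
  masked_cells <- !is.na(gt) & rct$depth < params$min_depth
  gt[masked_cells] <- NA_integer_
  n_called <- rowSums(!is.na(gt))
  alt_copies <- rowSums(gt, na.rm = TRUE)
  minor <- pmin(alt_copies, 2L * n_called - alt_copies)
  maf <- ifelse(n_called > 0L, minor / (2 * n_called), 0)
  miss <- rowMeans(is.na(gt))

  keep <- rep(TRUE, nrow(rct$sites))
  removed <- c(depth_mask_cells = sum(masked_cells), biallelic = 0L,
               mac = 0L, maf = 0L, missingness = 0L)
  if (params$biallelic_only) {
    fail <- keep & !rct$sites$biallelic
    removed["biallelic"] <- sum(fail); keep <- keep & !fail
  }
  fail <- keep & minor < params$min_allele_count
  removed["mac"] <- sum(fail); keep <- keep & !fail
  if (params$min_maf > 0) {
    fail <- keep & maf < params$min_maf
    removed["maf"] <- sum(fail); keep <- keep & !fail
  }
  fail <- keep & miss > params$max_missing
  removed["missingness"] <- sum(fail); keep <- keep & !fail
  if (!any(keep)) warning("no sites survive filtering")

  out <- new_rc_table(rct$sites[keep, , drop = FALSE], rct$samples,
                      rct$ref_reads[keep, , drop = FALSE],
                      rct$alt_reads[keep, , drop = FALSE],
                      rct$depth[keep, , drop = FALSE],
                      gt[keep, , drop = FALSE])
  attr(out, "removed") <- removed
  out
}

#' Extract the 012 genotype matrix (individuals x loci)
#'
#' @param rct An `rc_table`.
#' @return Numeric matrix, rows = samples, columns = loci named
#'   `chrom:pos`, entries in \{0, 1, 2, NA\}.
#' @export
geno012 <- function(rct) {
  stopifnot(inherits(rct, "rc_table"))
  m <- t(rct$gt)
  colnames(m) <- paste0(rct$sites$chrom, ":", rct$sites$pos)
  storage.mode(m) <- "double"
  m
}

#' Impute missing 012 codes with per-locus means
#'
#' Missing cells are replaced by the mean of the observed codes at the same
#' locus (equal to twice the locus allele frequency), so imputed values are
#' fractional on the 0-2 scale. Loci with no observed call are dropped with
#' a warning.
#'
#' @param m Individuals x loci 012 matrix with NA for missing.
#' @return The imputed matrix (no missing values).
#' @export
encode_012_impute <- function(m) {
  all_na <- colSums(!is.na(m)) == 0L
  if (any(all_na)) {
    warning(sum(all_na), " loci with no observed call dropped")
    m <- m[, !all_na, drop = FALSE]
  }
  mu <- colMeans(m, na.rm = TRUE)
  idx <- which(is.na(m))
  if (length(idx)) m[idx] <- mu[(idx - 1L) %/% nrow(m) + 1L]
  m
}
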