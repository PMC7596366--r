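# Shared fixtures and small independent oracles.

# build an rc_table directly from matrices (sites x samples)
toy_rc_table <- function(gt, ref = NULL, alt = NULL, depth = NULL,
                         chrom = NULL, pos = NULL) {
  n_sites <- nrow(gt)
  n_samp <- ncol(gt)
  if (is.null(ref)) ref <- matrix(10L, n_sites, n_samp)
  if (is.null(alt)) alt <- matrix(10L, n_sites, n_samp)
  if (is.null(depth)) depth <- ref + alt
  if (is.null(chrom)) chrom <- rep("chr1", n_sites)
  if (is.null(pos)) pos <- seq_len(n_sites) * 100L
  sites <- data.frame(chrom = chrom, pos = pos,
                      id = paste0("s", seq_len(n_sites)),
                      ref = "A", alt = "T", biallelic = TRUE,
                      stringsAsFactors = FALSE)
  samples <- paste0("ind", seq_len(n_samp))
  dimnames(gt) <- dimnames(ref) <- dimnames(alt) <- dimnames(depth) <-
    list(sites$id, samples)
  mixploid:::new_rc_table(sites, samples, ref, alt, depth, gt)
}

# adjusted Rand index between two labellings
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  e <- b * cc / choose(n, 2)
  (a - e) / ((b + cc) / 2 - e)
}

# independent scalar-loop transcription of the two-population
# variance-components Fst (per-site), kept free of the vectorised code path
wc_fst_oracle <- function(g1, g2) {
  L <- ncol(g1)
  out <- numeric(L)
  for (l in seq_len(L)) {
    x1 <- g1[, l][!is.na(g1[, l])]
    x2 <- g2[, l][!is.na(g2[, l])]
    n1 <- length(x1); n2 <- length(x2)
    p1 <- sum(x1) / (2 * n1); p2 <- sum(x2) / (2 * n2)
    h1 <- sum(x1 == 1) / n1; h2 <- sum(x2 == 1) / n2
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1 * n1 + n2 * n2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r -
                              hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar * (2 * nbar - 1) / (4 * nbar))
    cterm <- hbar / 2
    out[l] <- a / (a + b + cterm)
  }
  out
}

# brute-force mean pairwise difference among allele copies at one site
site_pi_bruteforce <- function(genos) {
  copies <- unlist(lapply(genos, function(g) c(rep(1L, g), rep(0L, 2L - g))))
  pairs <- utils::combn(length(copies), 2L)
  mean(copies[pairs[1L, ]] != copies[pairs[2L, ]])
}
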