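# Clonal structure: Manhattan kinship with a normal-law significance
# threshold, PLINK-style method-of-moments IBD (pi-hat), valley-based clone
# threshold, multi-locus lineage partition, genotypic richness, Fis,
# network export.

#' Manhattan kinship matrix
#'
#' `kinship(i, j) = 1 - sum |M_i - M_j| / (2 L)` on an imputed 012 matrix
#' with `L` loci: the fraction of shared allele copies.
#'
#' @param m Individuals x loci imputed 012 matrix (no missing values).
#' @return Symmetric matrix in \[0, 1\] with unit diagonal.
#' @export
kinship_matrix <- function(m) {
  if (ncol(m) == 0L) stop("no loci")
  if (anyNA(m)) stop("kinship_matrix expects an imputed matrix; see encode_012_impute()")
  d <- as.matrix(stats::dist(m, method = "manhattan"))
  k <- 1 - d / (2 * ncol(m))
  diag(k) <- 1
  k
}

#' Normal-law significance threshold on a kinship distribution
#'
#' Fits a normal distribution to kinship values between independent
#' individuals (via [fitdistrplus::fitdist()]) and returns the upper
#' one-sided quantile `mu + z(1 - p) * sd`.
#'
#' @param values Kinship values between independent pairs (>= 10).
#' @param p Significance level (default 0.05, i.e. the 95% quantile).
#' @return List: `threshold`, `mu`, `sd`, `fit` (the fitdist object, or
#'   NULL when the values are degenerate).
#' @export
significance_threshold <- function(values, p = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 10L) stop("need at least 10 independent pairs")
  if (stats::sd(values) == 0) {
    return(list(threshold = mean(values), mu = mean(values), sd = 0,
                fit = NULL))
  }
  fit <- fitdistrplus::fitdist(values, "norm")
  mu <- unname(fit$estimate["mean"])
  sd <- unname(fit$estimate["sd"])
  list(threshold = mu + stats::qnorm(1 - p) * sd, mu = mu, sd = sd,
       fit = fit)
}

#' Method-of-moments IBD sharing (pi-hat) for all pairs
#'
#' Estimates, for every sample pair, the probabilities of sharing 0, 1 or 2
#' alleles identical by descent from the observed identity-by-state counts
#' and the panel allele frequencies, then `pihat = P1 / 2 + P2`. The
#' moment equations use the classical IBS-given-IBD expectations with
#' sample allele frequencies and no small-sample correction; probabilities
#' are clipped to \[0, 1\] and renormalised. Monomorphic loci are excluded.
#'
#' @param m Individuals x loci 012 matrix, NA allowed.
#' @param freqs Optional per-locus alternate-allele frequencies; defaults
#'   to frequencies computed from `m`.
#' @return List of symmetric matrices `P0`, `P1`, `P2`, `pihat` and the
#'   locus count matrix `n_loci` (loci observed in both members).
#' @export
ibd_pihat <- function(m, freqs = NULL) {
  if (is.null(freqs)) freqs <- colMeans(m, na.rm = TRUE) / 2
  poly <- !is.na(freqs) & freqs > 0 & freqs < 1
  if (!any(poly)) stop("no polymorphic loci")
  m <- m[, poly, drop = FALSE]
  p <- freqs[poly]
  q <- 1 - p
  ## per-locus IBS-given-IBD expectations
  e0_0 <- 2 * p^2 * q^2                 # P(IBS0 | IBD0)
  e1_0 <- 4 * p^3 * q + 4 * p * q^3     # P(IBS1 | IBD0)
  e2_0 <- p^4 + q^4 + 4 * p^2 * q^2     # P(IBS2 | IBD0)
  e1_1 <- 2 * p * q                     # P(IBS1 | IBD1)
  e2_1 <- p^2 + q^2                     # P(IBS2 | IBD1)
  obs <- !is.na(m)
  a0 <- (!is.na(m) & m == 0) * 1; a1 <- (!is.na(m) & m == 1) * 1
  a2 <- (!is.na(m) & m == 2) * 1
  n2 <- tcrossprod(a0) + tcrossprod(a1) + tcrossprod(a2)  # IBS2 counts
  n0 <- tcrossprod(a0, a2); n0 <- n0 + t(n0)              # IBS0 counts
  nl <- tcrossprod(obs * 1)
  n1 <- nl - n0 - n2
  ow <- function(w) tcrossprod(sweep(obs * 1, 2L, w, "*"), obs * 1)
  s0 <- ow(e0_0); s10 <- ow(e1_0); s20 <- ow(e2_0)
  s11 <- ow(e1_1); s21 <- ow(e2_1)
  P0 <- n0 / s0
  P1 <- (n1 - P0 * s10) / s11
  P2 <- (n2 - P0 * s20 - P1 * s21) / nl
  clip <- function(x) pmin(pmax(x, 0), 1)
  P0 <- clip(P0); P1 <- clip(P1); P2 <- clip(P2)
  tot <- P0 + P1 + P2
  P0 <- P0 / tot; P1 <- P1 / tot; P2 <- P2 / tot
  pihat <- P1 / 2 + P2
  diag(pihat) <- 1; diag(P2) <- 1; diag(P1) <- 0; diag(P0) <- 0
  list(P0 = P0, P1 = P1, P2 = P2, pihat = pihat, n_loci = nl)
}

upper_values <- function(m) m[upper.tri(m)]

#' Clone threshold from the valley of the pi-hat density
#'
#' Locates the minimum of a kernel-smoothed density of pairwise `pihat`
#' between the clone peak (near 1) and the nearest lower peak - in a
#' collection with sib cohorts, the parent-offspring peak near 0.5. When
#' sib-cohort labels are supplied, the search is restricted above the
#' median within-cohort `pihat`, so the valley cannot fall below the
#' sibling range. If the density is unimodal the normal-law
#' [significance_threshold()] on the values is used instead.
#'
#' @param pihat_values Vector of pairwise pihat values (upper triangle).
#' @param cohorts Optional data frame/list with per-pair cohort sharing, or
#'   a numeric vector of within-cohort pihat values.
#' @return List: `threshold`, `method` (`"valley"` or `"normal_fallback"`),
#'   `density` (the density object).
#' @export
clone_threshold_from_cohorts <- function(pihat_values, cohorts = NULL) {
  v <- pihat_values[!is.na(pihat_values)]
  dens <- stats::density(v, from = max(0, min(v) - 0.05),
                         to = min(1.05, max(v) + 0.05), n = 512L)
  y <- dens$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  ## merge peaks closer than 0.1 (keep the higher): the clone cluster can
  ## split into twin peaks through granularity of the pihat values
  if (length(is_max) > 1L) {
    px <- dens$x[is_max]; py <- y[is_max]
    repeat {
      gaps <- diff(px)
      k <- which(gaps < 0.1)
      if (!length(k)) break
      k <- k[1L]
      drop <- if (py[k] >= py[k + 1L]) k + 1L else k
      px <- px[-drop]; py <- py[-drop]
    }
    is_max <- vapply(px, function(p) which.min(abs(dens$x - p)), 1L)
  }
  if (length(is_max) < 2L) {
    thr <- significance_threshold(v)
    return(list(threshold = thr$threshold, method = "normal_fallback",
                density = dens))
  }
  peaks <- dens$x[is_max]
  top <- peaks[length(peaks)]                 # clone peak (rightmost)
  lower <- peaks[length(peaks) - 1L]          # next peak down
  if (!is.null(cohorts)) {
    sib <- if (is.numeric(cohorts)) cohorts else unlist(cohorts)
    lower <- max(lower, stats::median(sib, na.rm = TRUE))
  }
  seg <- dens$x > lower & dens$x < top
  if (!any(seg)) {
    thr <- significance_threshold(v)
    return(list(threshold = thr$threshold, method = "normal_fallback",
                density = dens))
  }
  valley <- dens$x[seg][which.min(y[seg])]
  list(threshold = valley, method = "valley", density = dens)
}

#' Partition samples into multi-locus lineages
#'
#' Builds a graph with an edge for every pair whose similarity exceeds the
#' threshold and takes connected components: components of two or more
#' samples are multi-locus lineages (MLLs), singletons are unique genotypes
#' (UGs). Component semantics (not cliques) let chains of near-identical
#' somatic variants stay in one lineage. One representative per MLL is
#' chosen deterministically (first member in sorted order).
#'
#' @param sim Symmetric similarity matrix (`pihat` or kinship) with sample
#'   names on its dimensions.
#' @param threshold Clone threshold; pairs strictly above it are linked.
#' @return An `mll_partition`: `membership` (named lineage id per sample),
#'   `mlls` (list of members per multi-sample lineage), `unique_genotypes`
#'   (singleton sample ids), `G` (distinct genotypes = number of
#'   components), `N`, `R` ([genotypic_richness()]), `representatives`,
#'   `threshold`.
#' @export
mll_partition <- function(sim, threshold) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  ids <- rownames(sim)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(sim)))
  adj <- (sim > threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  member <- split(ids, comp$membership)
  member <- member[order(vapply(member, min, character(1)))]
  names(member) <- sprintf("MLL%03d", seq_along(member))
  sizes <- vapply(member, length, 1L)
  mlls <- member[sizes >= 2L]
  ugs <- unlist(member[sizes == 1L], use.names = FALSE)
  membership <- stats::setNames(rep(names(member), sizes),
                                unlist(member, use.names = FALSE))[ids]
  G <- length(member)
  N <- length(ids)
  reps <- vapply(member, function(s) sort(s)[1L], character(1))
  structure(list(membership = membership, mlls = mlls,
                 unique_genotypes = sort(ugs), G = G, N = N,
                 R = genotypic_richness(G, N),
                 representatives = reps, threshold = threshold),
            class = "mll_partition")
}

#' @export
print.mll_partition <- function(x, ...) {
  cat(sprintf("mll_partition: N = %d, G = %d (%d MLLs + %d UGs), R = %.3f, threshold = %.3f\n",
              x$N, x$G, length(x$mlls), length(x$unique_genotypes), x$R,
              x$threshold))
  invisible(x)
}

#' Genotypic richness
#'
#' `R = (G - 1) / (N - 1)`: 0 when every sample belongs to one clone, 1
#' when every sample is a distinct genotype.
#'
#' @param G Number of distinct multi-locus genotypes.
#' @param N Sample size.
#' @return R in \[0, 1\]; NA when `N < 2`.
#' @export
genotypic_richness <- function(G, N) {
  if (N < 2) return(NA_real_)
  (G - 1) / (N - 1)
}

#' Inbreeding coefficient Fis of a group
#'
#' Per polymorphic locus `Fis = 1 - Ho / He` with `Ho` the observed
#' heterozygote frequency and `He = 2 p q` from the observed allele
#' frequencies; the group value is the mean over polymorphic loci.
#' Negative values indicate excess heterozygosity, the signature of clonal
#' propagation.
#'
#' @param m Individuals x loci 012 matrix (NA allowed) for one group.
#' @return Mean Fis; NA when no locus is polymorphic.
#' @export
fis <- function(m) {
  p <- colMeans(m, na.rm = TRUE) / 2
  ho <- colMeans(m == 1, na.rm = TRUE)
  he <- 2 * p * (1 - p)
  poly <- !is.na(he) & he > 0
  if (!any(poly)) return(NA_real_)
  mean(1 - ho[poly] / he[poly])
}

#' Export the significant-kinship network
#'
#' Writes the pairs whose similarity exceeds the threshold as a TSV edge
#' list and a GraphML file (node attributes: population, ploidy), ready for
#' external layout software.
#'
#' @param sim Symmetric similarity matrix with sample names.
#' @param threshold Significance threshold.
#' @param path_prefix Output prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>.graphml`.
#' @param node_attrs Optional data frame with `sample_id` plus attribute
#'   columns (e.g. `pop`, `ploidy`).
#' @return Invisible list of the two paths.
#' @export
export_network <- function(sim, threshold, path_prefix, node_attrs = NULL) {
  ids <- rownames(sim)
  ut <- which(upper.tri(sim) & sim > threshold, arr.ind = TRUE)
  edges <- data.frame(sample_i = ids[ut[, 1L]], sample_j = ids[ut[, 2L]],
                      kinship = sim[ut], stringsAsFactors = FALSE)
  edge_path <- paste0(path_prefix, "_edges.tsv")
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  if (!is.null(node_attrs)) {
    idx <- match(ids, node_attrs$sample_id)
    for (col in setdiff(names(node_attrs), "sample_id")) {
      g <- igraph::set_vertex_attr(g, col, value = node_attrs[idx, col])
    }
  }
  gml_path <- paste0(path_prefix, ".graphml")
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(list(edges = edge_path, graphml = gml_path))
}
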