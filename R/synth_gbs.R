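# Synthetic mixed-ploidy GBS generator: diploid founders from diverged gene
# pools, polyploids via unreduced gametes, clonal expansion with somatic
# mutation, binomial read sampling, VCF/truth export.

#' Configuration for synthetic gene pools
#'
#' Describes the demographic backdrop of the simulated diploid founders:
#' how many gene pools, how long ago each one separated from the rest, its
#' effective size, and a symmetric migration rate that attenuates drift.
#'
#' @param n_pops Number of gene pools.
#' @param split_times Generations since each pool diverged (length `n_pops`,
#'   or a single value recycled). Strictly positive; interpreted as the
#'   drift time on each pool's private branch.
#' @param pop_sizes Diploid effective size per pool (recycled).
#' @param migration_rate Per-generation, per-lineage migration probability
#'   between pools; attenuates divergence as `F / (1 + 4 N m)`.
#' @param n_sites Number of biallelic SNP sites.
#' @param n_chroms Number of linkage groups the sites are spread over
#'   (default 20).
#' @param chrom_len Chromosome length in bp used to draw site positions.
#' @param ancestral_freq Optional vector of ancestral alternate-allele
#'   frequencies (length 1 or `n_sites`). When `NULL`, frequencies are drawn
#'   from a U-shaped Beta(0.5, 0.5) spectrum.
#' @param seed Integer seed governing all randomness of the generator.
#' @return A `pop_config` list.
#' @export
pop_config <- function(n_pops, split_times, pop_sizes, migration_rate = 0,
                       n_sites = 1000, n_chroms = 20, chrom_len = 1e6,
                       ancestral_freq = NULL, seed = 1L) {
  stopifnot(n_pops >= 1, n_sites >= 1, n_chroms >= 1)
  split_times <- rep_len(as.numeric(split_times), n_pops)
  pop_sizes <- rep_len(as.numeric(pop_sizes), n_pops)
  if (any(split_times < 0)) stop("split_times must be non-negative")
  if (is.unsorted(split_times)) stop("split_times must be non-decreasing")
  if (migration_rate < 0) stop("migration_rate must be >= 0")
  if (any(pop_sizes <= 0)) stop("pop_sizes must be positive")
  if (!is.null(ancestral_freq)) {
    ancestral_freq <- rep_len(as.numeric(ancestral_freq), n_sites)
    if (any(ancestral_freq < 0 | ancestral_freq > 1))
      stop("ancestral_freq must lie in [0, 1]")
  }
  structure(list(n_pops = n_pops, split_times = split_times,
                 pop_sizes = pop_sizes, migration_rate = migration_rate,
                 n_sites = as.integer(n_sites),
                 n_chroms = as.integer(n_chroms),
                 chrom_len = as.integer(chrom_len),
                 ancestral_freq = ancestral_freq, seed = as.integer(seed)),
            class = "pop_config")
}

#' Read-depth model for synthetic GBS sequencing
#'
#' @param mean_depth Mean reads per site per sample.
#' @param depth_distribution `"poisson"` (default) or `"fixed"`.
#' @param error_rate Per-read probability of reading the wrong allele.
#' @param missing_rate Per-cell probability that a cell is not sequenced at
#'   all (depth 0, missing genotype).
#' @return A `depth_model` list.
#' @export
depth_model <- function(mean_depth = 60, depth_distribution = c("poisson", "fixed"),
                        error_rate = 0.005, missing_rate = 0) {
  depth_distribution <- match.arg(depth_distribution)
  stopifnot(mean_depth >= 0)
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  structure(list(mean_depth = mean_depth,
                 depth_distribution = depth_distribution,
                 error_rate = error_rate, missing_rate = missing_rate),
            class = "depth_model")
}

new_accession_set <- function(dosage, truth, sites) {
  stopifnot(ncol(dosage) == nrow(truth), nrow(dosage) == nrow(sites))
  colnames(dosage) <- truth$sample_id
  structure(list(dosage = dosage, truth = truth, sites = sites),
            class = "accession_set")
}

#' @export
print.accession_set <- function(x, ...) {
  tab <- table(x$truth$ploidy)
  cat(sprintf("accession_set: %d accessions x %d sites (%s)\n",
              nrow(x$truth), nrow(x$sites),
              paste(sprintf("%sx:%d", names(tab), as.integer(tab)),
                    collapse = " ")))
  invisible(x)
}

site_table <- function(n_sites, n_chroms, chrom_len) {
  chrom <- sort(rep_len(seq_len(n_chroms), n_sites))
  pos <- integer(n_sites)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- sort(sample.int(chrom_len, length(idx)))
  }
  data.frame(chrom = paste0("chr", chrom), pos = pos,
             id = paste0("snp", seq_len(n_sites)),
             ref = "A", alt = "T", biallelic = TRUE,
             stringsAsFactors = FALSE)
}

## Balding-Nichols draw of a pool frequency around ancestral p with
## divergence F; degenerate cases (F = 0 or fixed p) pass through.
drift_freq <- function(p, f) {
  out <- p
  ok <- f > 0 & p > 0 & p < 1
  if (any(ok)) {
    a <- p[ok] * (1 - f) / f
    b <- (1 - p[ok]) * (1 - f) / f
    out[ok] <- stats::rbeta(sum(ok), a, b)
  }
  out
}

#' Simulate diploid founders from diverged gene pools
#'
#' Draws per-pool allele frequencies around a shared ancestral frequency
#' under a Balding-Nichols drift model with per-pool divergence
#' `F = (1 - exp(-t / 2N)) / (1 + 4 N m)`, then samples diploid genotypes in
#' Hardy-Weinberg proportions. `F` equals the expected pairwise Fst between
#' pools drifting on branches of length `t`.
#'
#' @param cfg A [pop_config()].
#' @param n_per_pop Diploid accessions per gene pool (recycled).
#' @return An `accession_set`: `dosage` (sites x samples matrix of
#'   alternate-allele dosages in 0..2), `truth` (sample_id, pop, ploidy,
#'   clone_id) and `sites`.
#' @export
simulate_founders <- function(cfg, n_per_pop = 20) {
  stopifnot(inherits(cfg, "pop_config"))
  if (cfg$n_sites < 1) stop("need at least one site")
  n_per_pop <- rep_len(as.integer(n_per_pop), cfg$n_pops)
  set.seed(cfg$seed)
  sites <- site_table(cfg$n_sites, cfg$n_chroms, cfg$chrom_len)
  p0 <- if (is.null(cfg$ancestral_freq)) {
    stats::rbeta(cfg$n_sites, 0.5, 0.5)
  } else cfg$ancestral_freq
  f_pop <- (1 - exp(-cfg$split_times / (2 * cfg$pop_sizes))) /
    (1 + 4 * cfg$pop_sizes * cfg$migration_rate)
  dosage <- matrix(0L, cfg$n_sites, sum(n_per_pop))
  pop_lab <- character(sum(n_per_pop))
  k <- 0L
  for (p in seq_len(cfg$n_pops)) {
    fp <- drift_freq(p0, f_pop[p])
    for (i in seq_len(n_per_pop[p])) {
      k <- k + 1L
      dosage[, k] <- stats::rbinom(cfg$n_sites, 2L, fp)
      pop_lab[k] <- paste0("pop", p)
    }
  }
  truth <- data.frame(
    sample_id = sprintf("%s_d%03d", pop_lab, stats::ave(seq_len(k),
                        pop_lab, FUN = seq_along)),
    pop = pop_lab, ploidy = 2L,
    clone_id = NA_character_, stringsAsFactors = FALSE)
  truth$clone_id <- truth$sample_id
  new_accession_set(dosage, truth, sites)
}

#' Derive triploids and tetraploids through unreduced gametes
#'
#' A triploid receives one reduced (meiotic) gamete from parent A - one
#' allele drawn per site from A's two copies - plus parent B's full somatic
#' dosage (an unreduced gamete). A tetraploid receives the full dosage of
#' both parents. Parents are drawn, without selfing, from the same gene
#' pool, matching the origin of natural autopolyploids.
#'
#' @param founders An `accession_set` of diploids.
#' @param triploid_fraction,tetraploid_fraction Number of new polyploids to
#'   create, as fractions of the diploid count; must be non-negative and sum
#'   to at most 1.
#' @param seed Integer seed.
#' @return An `accession_set` containing the diploids plus the new
#'   polyploid accessions.
#' @export
make_polyploids <- function(founders, triploid_fraction = 0.15,
                            tetraploid_fraction = 0.05, seed = 1L) {
  stopifnot(inherits(founders, "accession_set"))
  if (triploid_fraction < 0 || tetraploid_fraction < 0)
    stop("ploidy fractions must be >= 0")
  if (triploid_fraction + tetraploid_fraction > 1)
    stop("ploidy fractions must sum to <= 1")
  set.seed(seed)
  dip <- which(founders$truth$ploidy == 2L)
  n_tri <- round(triploid_fraction * length(dip))
  n_tet <- round(tetraploid_fraction * length(dip))
  if (n_tri + n_tet == 0L) return(founders)
  pools <- split(dip, founders$truth$pop[dip])
  pools <- pools[vapply(pools, length, 1L) >= 2L]
  if (!length(pools)) stop("need at least 2 diploids in some gene pool")
  n_sites <- nrow(founders$sites)
  new_dos <- matrix(0L, n_sites, n_tri + n_tet)
  new_truth <- vector("list", n_tri + n_tet)
  for (j in seq_len(n_tri + n_tet)) {
    pool <- pools[[sample.int(length(pools), 1L)]]
    par <- sample(pool, 2L)
    a <- founders$dosage[, par[1L]]
    b <- founders$dosage[, par[2L]]
    tet <- j > n_tri
    gam_a <- if (tet) a else stats::rbinom(n_sites, 1L, a / 2)
    new_dos[, j] <- gam_a + b
    pl <- if (tet) 4L else 3L
    id <- sprintf("%s_%s%03d", founders$truth$pop[par[1L]],
                  if (tet) "t4_" else "t3_", j)
    new_truth[[j]] <- data.frame(sample_id = id,
                                 pop = founders$truth$pop[par[1L]],
                                 ploidy = pl, clone_id = id,
                                 stringsAsFactors = FALSE)
  }
  new_accession_set(cbind(founders$dosage, new_dos),
                    rbind(founders$truth, do.call(rbind, new_truth)),
                    founders$sites)
}

#' Cross two diploid accessions
#'
#' Produces sexual offspring: one reduced gamete from each diploid parent
#' (an allele drawn per site), so full sibs share on average half their
#' genome with each parent and with one another.
#'
#' @param acc An `accession_set`.
#' @param parent_a,parent_b Sample ids of two diploid parents.
#' @param n_offspring Number of offspring to append.
#' @param seed Integer seed.
#' @param cohort Cohort label stored in the offspring clone_id prefix.
#' @return The `accession_set` with offspring appended (each its own
#'   clone_id).
#' @export
make_offspring <- function(acc, parent_a, parent_b, n_offspring, seed = 1L,
                           cohort = "F1") {
  stopifnot(inherits(acc, "accession_set"))
  ia <- match(parent_a, acc$truth$sample_id)
  ib <- match(parent_b, acc$truth$sample_id)
  if (anyNA(c(ia, ib))) stop("unknown parent id")
  if (any(acc$truth$ploidy[c(ia, ib)] != 2L))
    stop("parents must be diploid")
  set.seed(seed)
  n_sites <- nrow(acc$sites)
  off <- matrix(0L, n_sites, n_offspring)
  for (j in seq_len(n_offspring)) {
    off[, j] <- stats::rbinom(n_sites, 1L, acc$dosage[, ia] / 2) +
      stats::rbinom(n_sites, 1L, acc$dosage[, ib] / 2)
  }
  ids <- sprintf("%s_o%02d", cohort, seq_len(n_offspring))
  new_truth <- data.frame(sample_id = ids, pop = acc$truth$pop[ia],
                          ploidy = 2L, clone_id = ids,
                          stringsAsFactors = FALSE)
  new_accession_set(cbind(acc$dosage, off), rbind(acc$truth, new_truth),
                    acc$sites)
}

#' Clonally expand one accession with somatic mutation
#'
#' Each ramet differs from the founder at `Poisson(somatic_mu * n_sites)`
#' sites; a somatic mutation moves the dosage by one allele copy (reflected
#' at 0 and at the ploidy). All ramets share the founder's `clone_id`.
#'
#' @param acc An `accession_set`.
#' @param sample_id Founder to expand.
#' @param n_ramets Number of ramets to add.
#' @param somatic_mu Per-site somatic mutation probability per ramet.
#' @param seed Integer seed.
#' @return The `accession_set` with ramets appended.
#' @export
clonal_expand <- function(acc, sample_id, n_ramets, somatic_mu = 0, seed = 1L) {
  stopifnot(inherits(acc, "accession_set"))
  if (somatic_mu < 0) stop("somatic_mu must be >= 0")
  i <- match(sample_id, acc$truth$sample_id)
  if (is.na(i)) stop("unknown sample_id: ", sample_id)
  set.seed(seed)
  n_sites <- nrow(acc$sites)
  pl <- acc$truth$ploidy[i]
  ram <- matrix(rep(acc$dosage[, i], n_ramets), n_sites, n_ramets)
  for (j in seq_len(n_ramets)) {
    n_mut <- stats::rpois(1L, somatic_mu * n_sites)
    if (n_mut > 0L) {
      at <- sample.int(n_sites, min(n_mut, n_sites))
      step <- sample(c(-1L, 1L), length(at), replace = TRUE)
      d <- ram[at, j] + step
      d <- ifelse(d < 0L, 1L, ifelse(d > pl, pl - 1L, d))  # reflect
      ram[at, j] <- d
    }
  }
  new_truth <- data.frame(
    sample_id = sprintf("%s_r%02d", sample_id, seq_len(n_ramets)),
    pop = acc$truth$pop[i], ploidy = pl,
    clone_id = acc$truth$clone_id[i], stringsAsFactors = FALSE)
  new_accession_set(cbind(acc$dosage, ram), rbind(acc$truth, new_truth),
                    acc$sites)
}

#' Sample sequencing reads over an accession set
#'
#' Per cell, a read depth `d` is drawn from the depth model (0 with
#' probability `missing_rate`); alternate reads follow
#' `Binomial(d, (1 - e) * dosage / ploidy + e * (1 - dosage / ploidy))`.
#' The genotype is called heterozygous when both alleles are seen with at
#' least `min_allele_reads` reads; homozygous when only one allele reaches
#' that count; missing otherwise (including depth 0).
#'
#' @param acc An `accession_set`.
#' @param dm A [depth_model()].
#' @param seed Integer seed.
#' @param min_allele_reads Reads of an allele required to accept it in the
#'   genotype call (default 2).
#' @return A `rc_table`: site table, sample ids, and sites x samples
#'   matrices `ref_reads`, `alt_reads`, `depth` and `gt`
#'   (0 = hom ref, 1 = het, 2 = hom alt, NA = missing).
#' @export
sample_reads <- function(acc, dm = depth_model(), seed = 1L,
                         min_allele_reads = 2L) {
  stopifnot(inherits(acc, "accession_set"), inherits(dm, "depth_model"))
  set.seed(seed)
  n_sites <- nrow(acc$sites)
  n_samp <- nrow(acc$truth)
  n_cell <- n_sites * n_samp
  depth <- if (dm$depth_distribution == "fixed") {
    matrix(as.integer(round(dm$mean_depth)), n_sites, n_samp)
  } else {
    matrix(stats::rpois(n_cell, dm$mean_depth), n_sites, n_samp)
  }
  if (dm$missing_rate > 0)
    depth[stats::runif(n_cell) < dm$missing_rate] <- 0L
  frac <- sweep(acc$dosage, 2L, acc$truth$ploidy, "/")
  p_alt <- (1 - dm$error_rate) * frac + dm$error_rate * (1 - frac)
  alt <- matrix(stats::rbinom(n_cell, depth, p_alt), n_sites, n_samp)
  ref <- depth - alt
  gt <- matrix(NA_integer_, n_sites, n_samp)
  gt[ref >= min_allele_reads & alt >= min_allele_reads] <- 1L
  gt[ref >= min_allele_reads & alt < min_allele_reads] <- 0L
  gt[ref < min_allele_reads & alt >= min_allele_reads] <- 2L
  dimnames(ref) <- dimnames(alt) <- dimnames(depth) <- dimnames(gt) <-
    list(acc$sites$id, acc$truth$sample_id)
  new_rc_table(acc$sites, acc$truth$sample_id, ref, alt, depth, gt)
}

new_rc_table <- function(sites, samples, ref, alt, depth, gt) {
  structure(list(sites = sites, samples = samples, ref_reads = ref,
                 alt_reads = alt, depth = depth, gt = gt),
            class = "rc_table")
}

#' @export
print.rc_table <- function(x, ...) {
  cat(sprintf("rc_table: %d sites x %d samples, %.1f%% missing calls\n",
              nrow(x$sites), length(x$samples),
              100 * mean(is.na(x$gt))))
  invisible(x)
}

gt_string <- function(code) {
  out <- rep("./.", length(code))
  out[!is.na(code) & code == 0L] <- "0/0"
  out[!is.na(code) & code == 1L] <- "0/1"
  out[!is.na(code) & code == 2L] <- "1/1"
  out
}

#' Write a read-count table as a VCF 4.2 file
#'
#' Emits plain-text VCF 4.2 with GT:AD:DP per cell and one `##contig` header
#' line per chromosome. Missing cells are written `./.` with `DP=0`.
#'
#' @param rct An `rc_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(rct, path) {
  stopifnot(inherits(rct, "rc_table"))
  con <- file(path, "w")
  on.exit(close(con))
  chroms <- unique(rct$sites$chrom)
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=mixploid_synth_gbs",
    sprintf("##contig=<ID=%s>", chroms),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rct$samples), collapse = "\t")), con)
  gt <- matrix(gt_string(rct$gt), nrow(rct$sites))
  cells <- matrix(sprintf("%s:%d,%d:%d", gt, rct$ref_reads, rct$alt_reads,
                          rct$depth), nrow(rct$sites))
  body <- paste(rct$sites$chrom, rct$sites$pos, rct$sites$id,
                rct$sites$ref, rct$sites$alt, ".", "PASS", ".",
                "GT:AD:DP",
                apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Write the truth table of an accession set as TSV
#'
#' @param acc An `accession_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(acc, path) {
  stopifnot(inherits(acc, "accession_set"))
  utils::write.table(acc$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Simulate a clonally structured diploid panel with known partition
#'
#' Builds the reference clonality fixture: diploid founders from one
#' gene pool at drift-mutation equilibrium, of which `n_mlls` are clonally
#' expanded (with light somatic mutation) to `n_clone_members` total ramets
#' while `n_ugs` stay unique genotypes, plus two full-sib progenies sharing
#' one parent (the cohorts used to calibrate the clone threshold). The
#' planted panel is `panel_ids` (clone groups + singletons); the parents
#' and progenies are extra samples carried for threshold calibration.
#'
#' @param n_mlls Clone groups planted.
#' @param n_ugs Singleton unique genotypes.
#' @param n_clone_members Total members across clone groups.
#' @param n_sites SNP loci.
#' @param progeny_size Offspring per sib cohort (two cohorts).
#' @param somatic_mu Per-site somatic mutation rate per ramet.
#' @param dm [depth_model()] for read sampling.
#' @param seed Integer seed.
#' @return List: `acc` (accession_set), `rct` (rc_table), `panel_ids`
#'   (the planted clone-structure panel), `cohort_ids` (list of the two
#'   progenies), `parent_ids` (shared parent first), `truth_clone` (named
#'   clone_id vector over `panel_ids`).
#' @export
simulate_clonal_panel <- function(n_mlls = 40L, n_ugs = 53L,
                                  n_clone_members = 247L, n_sites = 5000L,
                                  progeny_size = 15L, somatic_mu = 2e-4,
                                  dm = depth_model(30, "poisson", 0.005,
                                                   missing_rate = 0.02),
                                  seed = 1L) {
  n_founders <- n_mlls + n_ugs + 3L   # +3 progeny parents
  cfg <- pop_config(1, split_times = 0, pop_sizes = 1000,
                    n_sites = n_sites, seed = seed)
  acc <- simulate_founders(cfg, n_per_pop = n_founders)
  set.seed(seed + 1L)
  sizes <- pmax(2L, as.integer(stats::rmultinom(1L, n_clone_members - n_mlls,
                                                rep(1, n_mlls)) + 1L))
  while (sum(sizes) > n_clone_members)
    sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  while (sum(sizes) < n_clone_members)
    sizes[which.min(sizes)] <- sizes[which.min(sizes)] + 1L
  founder_ids <- acc$truth$sample_id[seq_len(n_mlls)]
  for (i in seq_len(n_mlls)) {
    acc <- clonal_expand(acc, founder_ids[i], sizes[i] - 1L,
                         somatic_mu = somatic_mu, seed = seed + 10L + i)
  }
  parents <- acc$truth$sample_id[n_mlls + n_ugs + 1:3]
  acc <- make_offspring(acc, parents[1L], parents[2L], progeny_size,
                        seed = seed + 2L, cohort = "C1")
  acc <- make_offspring(acc, parents[1L], parents[3L], progeny_size,
                        seed = seed + 3L, cohort = "C2")
  rct <- sample_reads(acc, dm, seed = seed + 4L)
  panel_ids <- c(acc$truth$sample_id[seq_len(n_mlls + n_ugs)],
                 acc$truth$sample_id[grepl("_r[0-9]+$",
                                           acc$truth$sample_id)])
  cohort_ids <- list(C1 = acc$truth$sample_id[grepl("^C1_o",
                                                    acc$truth$sample_id)],
                     C2 = acc$truth$sample_id[grepl("^C2_o",
                                                    acc$truth$sample_id)])
  truth_clone <- stats::setNames(acc$truth$clone_id,
                                 acc$truth$sample_id)[panel_ids]
  list(acc = acc, rct = rct, panel_ids = panel_ids,
       cohort_ids = cohort_ids, parent_ids = parents,
       truth_clone = truth_clone)
}

#' Simulate a single accession with a known number of heterozygous sites
#'
#' Convenience generator for the ploidy-inference stage: builds one
#' accession of the requested ploidy whose dosages at `n_het_sites` sites
#' are drawn from the heterozygous-dosage distribution at allele frequency
#' `p` (truncated Binomial(ploidy, p) excluding 0 and ploidy), then samples
#' reads over it.
#'
#' @param ploidy 2, 3 or 4.
#' @param n_het_sites Number of heterozygous sites.
#' @param dm A [depth_model()].
#' @param p Allele frequency shaping the dosage mix (default 0.5).
#' @param seed Integer seed.
#' @return An `rc_table` with one sample (`sample_id` "acc1").
#' @export
simulate_ploidy_accession <- function(ploidy, n_het_sites = 2000,
                                      dm = depth_model(), p = 0.5, seed = 1L) {
  stopifnot(ploidy %in% 2:4)
  set.seed(seed)
  w <- stats::dbinom(1:(ploidy - 1L), ploidy, p)
  dos <- sample(1:(ploidy - 1L), n_het_sites, replace = TRUE, prob = w)
  sites <- site_table(n_het_sites, 1L, as.integer(10 * n_het_sites))
  truth <- data.frame(sample_id = "acc1", pop = "pop1",
                      ploidy = as.integer(ploidy), clone_id = "acc1",
                      stringsAsFactors = FALSE)
  acc <- new_accession_set(matrix(as.integer(dos), ncol = 1L), truth, sites)
  sample_reads(acc, dm, seed = seed + 1L)
}
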