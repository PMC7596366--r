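# Synthetic GBS generator: founder drift, polyploid formation, clonal
# expansion, read sampling, VCF round trips.

test_that("founders inherit no variation when the ancestral frequency is zero", {
  cfg <- pop_config(1, split_times = 100, pop_sizes = 500, n_sites = 200,
                    ancestral_freq = 0, seed = 1)
  acc <- simulate_founders(cfg, n_per_pop = 10)
  expect_true(all(acc$dosage == 0))
})

test_that("heterozygote fraction matches Hardy-Weinberg at p = 0.5", {
  n_sites <- 5000
  cfg <- pop_config(1, split_times = 0, pop_sizes = 1000, n_sites = n_sites,
                    ancestral_freq = 0.5, seed = 2)
  acc <- simulate_founders(cfg, n_per_pop = 40)
  het <- mean(acc$dosage == 1)
  se <- sqrt(0.25 / (n_sites * 40))
  expect_lt(abs(het - 0.5), 3 * se)
})

test_that("pool divergence follows the drift approximation 1 - exp(-t/2N)", {
  fst <- sapply(c(100, 300, 600), function(t) {
    cfg <- pop_config(2, split_times = t, pop_sizes = 1000, n_sites = 4000,
                      seed = 5 + t)
    acc <- simulate_founders(cfg, n_per_pop = 30)
    m <- t(acc$dosage); storage.mode(m) <- "double"
    weir_cockerham_fst(m[acc$truth$pop == "pop1", ],
                       m[acc$truth$pop == "pop2", ])$mean
  })
  theory <- 1 - exp(-c(100, 300, 600) / 2000)
  expect_true(all(abs(fst - theory) < 0.03))
  expect_true(all(diff(fst) > 0))   # monotone in split time
})

test_that("pools are exchangeable at split time zero", {
  cfg <- pop_config(2, split_times = 0, pop_sizes = 1000, n_sites = 4000,
                    seed = 3)
  acc <- simulate_founders(cfg, n_per_pop = 30)
  m <- t(acc$dosage); storage.mode(m) <- "double"
  fst <- weir_cockerham_fst(m[acc$truth$pop == "pop1", ],
                            m[acc$truth$pop == "pop2", ])$mean
  expect_lt(abs(fst), 0.01)
})

test_that("unreduced-gamete arithmetic bounds polyploid dosages", {
  cfg <- pop_config(1, split_times = 0, pop_sizes = 500, n_sites = 300,
                    ancestral_freq = 0.5, seed = 4)
  acc <- simulate_founders(cfg, n_per_pop = 10)
  acc2 <- make_polyploids(acc, 0.4, 0.3, seed = 7)
  expect_true(all(acc2$dosage <= rep(acc2$truth$ploidy,
                                     each = nrow(acc2$sites))))
  # parent B homozygous alt: triploid offspring carries at least dosage 2
  accH <- acc
  accH$dosage[, ] <- 2L   # every diploid homozygous alt
  acc3 <- make_polyploids(accH, 0.5, 0.3, seed = 8)
  tri <- acc3$truth$ploidy == 3
  expect_true(all(acc3$dosage[, tri] %in% 2:3))
  # both parents homozygous ref -> tetraploid dosage 0
  accR <- acc
  accR$dosage[, ] <- 0L
  acc4 <- make_polyploids(accR, 0, 0.5, seed = 9)
  expect_true(all(acc4$dosage[, acc4$truth$ploidy == 4] == 0))
})

test_that("triploid dosage law is the Bernoulli x diploid convolution at p = 0.5", {
  cfg <- pop_config(1, split_times = 0, pop_sizes = 1000, n_sites = 20000,
                    ancestral_freq = 0.5, seed = 10)
  acc <- simulate_founders(cfg, n_per_pop = 12)
  acc2 <- make_polyploids(acc, 1 / 12, 0, seed = 11)
  tri <- which(acc2$truth$ploidy == 3)
  expect_length(tri, 1L)
  emp <- tabulate(acc2$dosage[, tri] + 1L, nbins = 4L) / nrow(acc2$sites)
  conv <- stats::dbinom(0:3, 3, 0.5)   # Bern(1/2) * Binom(2, 1/2)
  se <- sqrt(conv * (1 - conv) / nrow(acc2$sites))
  expect_true(all(abs(emp - conv) < 4 * se + 0.01))
})

test_that("somatic mutation counts follow the Poisson expectation", {
  cfg <- pop_config(1, split_times = 0, pop_sizes = 500, n_sites = 1000,
                    ancestral_freq = 0.5, seed = 12)
  acc <- simulate_founders(cfg, n_per_pop = 2)
  f <- acc$truth$sample_id[1]
  # mu * n_sites = 5
  acc2 <- clonal_expand(acc, f, 60, somatic_mu = 0.005, seed = 13)
  ram <- acc2$dosage[, grepl("_r", acc2$truth$sample_id)]
  diffs <- colSums(ram != acc2$dosage[, 1])
  expect_lt(abs(mean(diffs) - 5), 3 * sqrt(5 / 60))
  # two ramets differ at ~ 2 x 5 sites
  pair_diff <- mean(utils::combn(ncol(ram), 2, function(ij)
    sum(ram[, ij[1]] != ram[, ij[2]])))
  expect_lt(abs(pair_diff - 10), 1.5)
  # mu = 0 -> identical; clone_id shared; ploidy shared
  acc0 <- clonal_expand(acc, f, 5, somatic_mu = 0, seed = 14)
  ram0 <- acc0$dosage[, grepl("_r", acc0$truth$sample_id)]
  expect_true(all(ram0 == acc0$dosage[, 1]))
  expect_true(all(acc0$truth$clone_id[grepl("_r", acc0$truth$sample_id)] ==
                    acc0$truth$clone_id[1]))
  expect_error(clonal_expand(acc, f, 2, somatic_mu = -1), "somatic_mu")
})

test_that("read sampling follows the error-adjusted binomial mixture", {
  # dosage 0 with no error never yields alternate reads
  gt <- matrix(0L, 50, 1)
  truth <- data.frame(sample_id = "a", pop = "p", ploidy = 2L,
                      clone_id = "a", stringsAsFactors = FALSE)
  sites <- mixploid:::site_table(50, 1, 10000)
  acc <- mixploid:::new_accession_set(matrix(0L, 50, 1), truth, sites)
  rct <- sample_reads(acc, depth_model(30, "fixed", error_rate = 0), seed = 1)
  expect_true(all(rct$alt_reads == 0))
  # triploid dosage 2 at high depth concentrates near the 2/3 mode
  acc3 <- mixploid:::new_accession_set(matrix(2L, 50, 1),
                                       transform(truth, ploidy = 3L), sites)
  rct3 <- sample_reads(acc3, depth_model(500, "fixed", error_rate = 0),
                       seed = 2)
  fr <- rct3$alt_reads / rct3$depth
  expect_true(all(abs(fr - 2 / 3) < 0.1))
  # mixture mean: dosage 2 of ploidy 3, e = 0.01, d = 100
  n <- 5000
  sitesN <- mixploid:::site_table(n, 1, 10 * n)
  accM <- mixploid:::new_accession_set(matrix(2L, n, 1),
                                       transform(truth, ploidy = 3L), sitesN)
  rctM <- sample_reads(accM, depth_model(100, "fixed", error_rate = 0.01),
                       seed = 3)
  frM <- mean(rctM$alt_reads / rctM$depth)
  expected <- 0.99 * (2 / 3) + 0.01 * (1 / 3)
  expect_lt(abs(frM - expected), 3 * sqrt(expected * (1 - expected) / (100 * n)))
})

test_that("VCF writing round-trips through the parser", {
  cfg <- pop_config(2, split_times = 100, pop_sizes = 500, n_sites = 120,
                    n_chroms = 20, seed = 20)
  acc <- simulate_founders(cfg, n_per_pop = 4)
  rct <- sample_reads(acc, depth_model(25, "poisson", 0.005,
                                       missing_rate = 0.1), seed = 21)
  tf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(rct, tf)
  rct2 <- load_vcf(tf)
  expect_identical(unname(rct$gt), unname(rct2$gt))
  expect_identical(unname(rct$ref_reads), unname(rct2$ref_reads))
  expect_identical(unname(rct$alt_reads), unname(rct2$alt_reads))
  expect_identical(unname(rct$depth), unname(rct2$depth))
  expect_identical(rct$sites$pos, rct2$sites$pos)
  # missing cells encoded ./.
  miss <- is.na(rct$gt)
  expect_true(any(miss))
  lines <- readLines(tf)
  expect_equal(sum(grepl("^##contig", lines)), 20L)
  expect_true(any(grepl("\\./\\.", lines)))
  # truth TSV round trip
  tt <- withr::local_tempfile(fileext = ".tsv")
  write_truth(acc, tt)
  tr <- utils::read.delim(tt, stringsAsFactors = FALSE)
  expect_identical(tr$sample_id, acc$truth$sample_id)
})

test_that("generator guards reject invalid configurations", {
  expect_error(pop_config(2, c(100, 50), 500), "non-decreasing")
  expect_error(pop_config(1, 100, 500, migration_rate = -1), "migration")
  expect_error(depth_model(error_rate = 0.6), "error_rate")
  cfg <- pop_config(1, 0, 500, n_sites = 50, ancestral_freq = 0.5, seed = 1)
  acc <- simulate_founders(cfg, n_per_pop = 1)
  expect_error(make_polyploids(acc, 1, 0), "at least 2 diploids")
})
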