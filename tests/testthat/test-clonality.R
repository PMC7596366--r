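# Kinship, IBD sharing, clone thresholds, MLL partitioning, richness, Fis,
# network export.

test_that("Manhattan kinship matches hand arithmetic and stays bounded", {
  m <- rbind(a = rep(0, 10), b = rep(0, 10), c = rep(2, 10))
  m["b", 1] <- 1   # one heterozygote difference in L = 10
  k <- kinship_matrix(m)
  expect_equal(k["a", "b"], 1 - 1 / 20)
  expect_equal(k["a", "c"], 0)
  expect_equal(diag(k), c(a = 1, b = 1, c = 1))
  expect_true(isSymmetric(k))
  # random imputed matrices keep the invariants
  set.seed(50)
  for (i in 1:5) {
    mr <- matrix(runif(200, 0, 2), 10, 20)
    kr <- kinship_matrix(mr)
    expect_true(all(kr >= 0 & kr <= 1))
    expect_true(isSymmetric(kr))
  }
})

test_that("normal-law significance threshold matches the closed form", {
  set.seed(51)
  v <- rnorm(4000, 0.70, 0.05)
  thr <- significance_threshold(v)
  expect_lt(abs(thr$threshold - (0.70 + qnorm(0.95) * 0.05)), 0.005)
  # zero-variance input: threshold is the mean
  expect_equal(significance_threshold(rep(0.4, 20))$threshold, 0.4)
  expect_error(significance_threshold(rnorm(5)), "at least 10")
  # by construction ~5% of independent pairs exceed the threshold
  expect_lt(abs(mean(v > thr$threshold) - 0.05), 0.015)
})

test_that("pi-hat hits the pedigree expectations", {
  cfg <- pop_config(1, split_times = 0, pop_sizes = 1000, n_sites = 5000,
                    seed = 52)
  acc <- simulate_founders(cfg, n_per_pop = 30)
  acc <- make_offspring(acc, acc$truth$sample_id[1], acc$truth$sample_id[2],
                        2, seed = 53)
  acc <- clonal_expand(acc, acc$truth$sample_id[3], 1, somatic_mu = 0,
                       seed = 54)
  m <- t(acc$dosage)
  storage.mode(m) <- "double"
  rownames(m) <- acc$truth$sample_id
  ib <- ibd_pihat(m)
  ph <- ib$pihat
  clone_pair <- ph[acc$truth$sample_id[3], paste0(acc$truth$sample_id[3], "_r01")]
  po_pair <- ph[acc$truth$sample_id[1], "F1_o01"]
  unrel_pair <- ph[acc$truth$sample_id[4], acc$truth$sample_id[5]]
  expect_gt(clone_pair, 0.95)
  expect_lt(abs(po_pair - 0.5), 0.05)
  expect_lt(abs(unrel_pair), 0.05)
  expect_true(all(ib$P0 >= 0 & ib$P0 <= 1))
  expect_true(all(abs(ib$P0 + ib$P1 + ib$P2 - 1) < 1e-12))
  expect_error(ibd_pihat(matrix(0, 4, 10)), "polymorphic")
})

test_that("valley threshold separates clones from lower-relatedness peaks", {
  set.seed(55)
  v <- c(rnorm(400, 0.2, 0.04), rnorm(120, 0.97, 0.015))
  thr <- clone_threshold_from_cohorts(v)
  expect_identical(thr$method, "valley")
  expect_gt(thr$threshold, 0.4)
  expect_lt(thr$threshold, 0.9)
  # unimodal input falls back to the normal-law threshold
  thr2 <- clone_threshold_from_cohorts(rnorm(200, 0.95, 0.01))
  expect_identical(thr2$method, "normal_fallback")
  # cohort values push the search interval above the sibling range
  thr3 <- clone_threshold_from_cohorts(
    c(rnorm(300, 0.2, 0.04), rnorm(100, 0.5, 0.03), rnorm(120, 0.97, 0.015)),
    cohorts = rnorm(50, 0.5, 0.03))
  expect_gt(thr3$threshold, 0.5)
  expect_lt(thr3$threshold, 0.97)
})

test_that("MLL partition uses connected components and fixed tie-breaking", {
  sim <- diag(4)
  rownames(sim) <- colnames(sim) <- c("a", "b", "c", "d")
  sim["a", "b"] <- sim["b", "a"] <- 0.99
  sim["b", "c"] <- sim["c", "b"] <- 0.98
  sim["a", "c"] <- sim["c", "a"] <- 0.10   # chain, not clique
  part <- mll_partition(sim, 0.9)
  expect_length(part$mlls, 1L)
  expect_setequal(part$mlls[[1]], c("a", "b", "c"))
  expect_identical(part$unique_genotypes, "d")
  expect_identical(part$G, 2L)
  expect_equal(part$R, (2 - 1) / (4 - 1))
  # no edges -> all singletons
  part0 <- mll_partition(diag(4) + 0, 0.9)
  expect_identical(part0$G, 4L)
  expect_length(part0$mlls, 0L)
  # invariant to sample order
  perm <- c(3, 1, 4, 2)
  partp <- mll_partition(sim[perm, perm], 0.9)
  expect_setequal(partp$mlls[[1]], c("a", "b", "c"))
  expect_identical(partp$unique_genotypes, "d")
})

test_that("planted clone structure is recovered exactly with the valley threshold", {
  panel <- simulate_clonal_panel(n_mlls = 8, n_ugs = 10,
                                 n_clone_members = 40, n_sites = 3000,
                                 seed = 60)
  m <- geno012(panel$rct)
  ph <- ibd_pihat(m)$pihat
  ph <- ph[panel$panel_ids, panel$panel_ids]
  thr <- clone_threshold_from_cohorts(ph[upper.tri(ph)])
  part <- mll_partition(ph, thr$threshold)
  expect_equal(adjusted_rand(panel$truth_clone, part$membership), 1)
  expect_identical(length(part$mlls), 8L)
  expect_identical(length(part$unique_genotypes), 10L)
})

test_that("richness and Fis follow their definitions", {
  expect_equal(genotypic_richness(41, 118), 40 / 117)
  expect_equal(genotypic_richness(1, 50), 0)
  expect_equal(genotypic_richness(50, 50), 1)
  expect_true(is.na(genotypic_richness(1, 1)))
  # all-heterozygote locus at p = 0.5: Fis = 1 - 1/0.5 = -1
  m <- matrix(1, 6, 4)
  expect_equal(fis(m), -1)
  # fully homozygous polymorphic group: Fis = 1
  m2 <- rbind(matrix(0, 3, 5), matrix(2, 3, 5))
  expect_equal(fis(m2), 1)
  # Hardy-Weinberg simulation: Fis near 0
  set.seed(61)
  m3 <- matrix(rbinom(200 * 400, 2, 0.4), 200, 400)
  expect_lt(abs(fis(m3)), 0.02)
  expect_true(is.na(fis(matrix(0, 5, 3))))
  # clonal groups freeze heterozygosity: negative Fis
  panel <- simulate_clonal_panel(n_mlls = 5, n_ugs = 0,
                                 n_clone_members = 40, n_sites = 2000,
                                 seed = 62)
  mg <- geno012(panel$rct)[panel$panel_ids, ]
  expect_lt(fis(mg), 0)
})

test_that("network export writes edges once and round-trips through GraphML", {
  sim <- diag(3)
  rownames(sim) <- colnames(sim) <- c("x", "y", "z")
  sim[upper.tri(sim)] <- sim[lower.tri(sim)] <- 0.95   # triangle of clones
  prefix <- withr::local_tempfile()
  paths <- export_network(sim, 0.9, prefix,
                          node_attrs = data.frame(sample_id = c("x", "y", "z"),
                                                  pop = c("p1", "p1", "p2")))
  edges <- utils::read.delim(paths$edges)
  expect_identical(nrow(edges), 3L)
  g <- igraph::read_graph(paths$graphml, format = "graphml")
  expect_equal(igraph::gsize(g), 3)
  expect_setequal(igraph::V(g)$pop, c("p1", "p1", "p2"))
  # empty significant set -> header-only edge list, no edges in graph
  prefix2 <- withr::local_tempfile()
  paths2 <- export_network(sim, 0.99, prefix2)
  expect_identical(nrow(utils::read.delim(paths2$edges)), 0L)
  g2 <- igraph::read_graph(paths2$graphml, format = "graphml")
  expect_equal(igraph::gsize(g2), 0)
  expect_equal(igraph::vcount(g2), 3)
})
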