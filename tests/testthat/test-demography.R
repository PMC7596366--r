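# Joint SFS projection, coalescent simulation, composite likelihood, AIC
# model comparison.

test_that("hypergeometric projection matches the pmf and conserves mass", {
  # one site: 3 alt of 6 copies in each pop, projected to 4 copies
  m1 <- matrix(c(2, 1, 0), 3, 1)   # 3 alt / 6
  m2 <- matrix(c(1, 1, 1), 3, 1)
  sfs <- build_joint_sfs(m1, m2, project_to = c(4, 4))
  marg1 <- rowSums(sfs$matrix)
  pmf <- dhyper(0:4, 3, 3, 4)
  expect_equal(unname(marg1), pmf, tolerance = 1e-12)
  expect_equal(unname(pmf[2:4]), c(0.2, 0.6, 0.2))
  expect_equal(sum(sfs$matrix), sfs$n_sites_used)
  # full-size projection with no missing data equals direct counting
  set.seed(80)
  g1 <- matrix(rbinom(4 * 50, 2, 0.3), 4, 50)
  g2 <- matrix(rbinom(4 * 50, 2, 0.6), 4, 50)
  sfs_full <- build_joint_sfs(g1, g2, project_to = c(8, 8))
  direct <- table(factor(colSums(g1), levels = 0:8),
                  factor(colSums(g2), levels = 0:8))
  expect_equal(unname(sfs_full$matrix), unname(unclass(direct)),
               ignore_attr = TRUE)
  # sites with too few observed copies are dropped and counted
  g1miss <- g1; g1miss[1:3, 1] <- NA
  sfs_miss <- build_joint_sfs(g1miss, g2, project_to = c(4, 4))
  expect_identical(sfs_miss$n_sites_dropped, 1L)
  expect_equal(sum(sfs_miss$matrix), 49)
  expect_error(build_joint_sfs(g1, g2, project_to = c(1, 4)), ">= 2")
})

test_that("single-population spectrum follows the 1/i neutral expectation", {
  s1 <- demographic_scenario(pops = "A", params = c(N_A = 1000),
                             splits = list(), label = "panmictic")
  sim <- simulate_scenario_sfs(s1, c(A = 8), n_loci = 10000, seed = 81)
  q <- (1 / (1:7)) / sum(1 / (1:7))
  cnt <- sim$counts[2:8]
  se <- sqrt(10000 * q * (1 - q))
  expect_true(all(abs(cnt - 10000 * q) < 3 * se))
  # branch-length expectation agrees even more tightly
  e <- sim$expected[2:8]
  expect_true(all(abs(e - 10000 * q) / (10000 * q) < 0.1))
})

test_that("deep isolation concentrates mass on private/fixed margins", {
  s2 <- demographic_scenario(
    pops = c("A", "B"), params = c(N_A = 500, N_B = 500, N_ANC = 500,
                                   T1 = 20000),
    splits = list(list(time = "T1", derived = "B", into = "A",
                       size_after = "N_ANC")), label = "deep")
  sim <- simulate_scenario_sfs(s2, c(A = 6, B = 6), n_loci = 3000, seed = 82)
  m <- sim$expected
  margin <- sum(m[1, ]) + sum(m[, 1]) + sum(m[7, ]) + sum(m[, 7]) -
    m[1, 1] - m[1, 7] - m[7, 1] - m[7, 7]
  expect_gt(margin / sum(m), 0.9)
})

test_that("migration pulls the two-population spectrum off the margins", {
  base <- c(N_A = 500, N_B = 500, N_ANC = 500, T1 = 2000, GF = 0.005)
  splits <- list(list(time = "T1", derived = "B", into = "A",
                      size_after = "N_ANC"))
  iso <- demographic_scenario(c("A", "B"), base, splits, label = "iso")
  mig <- demographic_scenario(c("A", "B"), base, splits,
                              migration = list(list(between = c("A", "B"),
                                                    rate = "GF")),
                              label = "mig")
  off_diag_dist <- function(sfs) {
    idx <- which(sfs > 0, arr.ind = TRUE)
    w <- sfs[idx]
    sum(w * abs((idx[, 1] - 1) / 6 - (idx[, 2] - 1) / 6)) / sum(w)
  }
  d_iso <- off_diag_dist(simulate_scenario_sfs(iso, c(A = 6, B = 6),
                                               5000, seed = 83)$expected)
  d_mig <- off_diag_dist(simulate_scenario_sfs(mig, c(A = 6, B = 6),
                                               5000, seed = 83)$expected)
  expect_lt(d_mig, d_iso)
})

test_that("composite log-likelihood follows the multinomial form", {
  obs <- matrix(c(3, 1), 1, 2)
  p <- matrix(c(0.75, 0.25), 1, 2)
  ll <- composite_loglik(obs, p, exclude_corners = FALSE)
  expect_equal(ll, 3 * log(0.75) + log(0.25), tolerance = 1e-12)
  expect_equal(round(ll, 4), -2.2493)
  # Gibbs inequality: matching proportions maximise logL over rearrangements
  set.seed(84)
  e <- matrix(runif(12, 0.5, 2), 3, 4)
  o <- 100 * e / sum(e)
  ll_match <- composite_loglik(o, e, exclude_corners = FALSE)
  for (i in 1:10) {
    perm <- matrix(o[sample(12)], 3, 4)
    expect_lte(ll_match, composite_loglik(o, e, exclude_corners = FALSE) + 1e-9)
    expect_gte(ll_match, composite_loglik(perm, e, exclude_corners = FALSE))
  }
  # zero expected entry with observed sites stays finite via the floor
  e0 <- matrix(c(1, 0, 1, 1), 2, 2)
  o0 <- matrix(c(5, 2, 1, 1), 2, 2)
  ll0 <- composite_loglik(o0, e0, exclude_corners = FALSE)
  expect_true(is.finite(ll0))
  # corner exclusion drops the monomorphic cells
  oc <- matrix(c(100, 1, 1, 100), 2, 2)
  ec <- matrix(c(100, 1, 1, 100), 2, 2)
  expect_gt(composite_loglik(oc, ec, exclude_corners = TRUE),
            composite_loglik(oc, ec, exclude_corners = FALSE))
  expect_error(composite_loglik(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
})

test_that("scenario fitting recovers a known parameter and is monotone in restarts", {
  base <- c(N_A = 500, N_B = 500, N_ANC = 500, T1 = 1500)
  splits <- list(list(time = "T1", derived = "B", into = "A",
                      size_after = "N_ANC"))
  truth_s <- demographic_scenario(c("A", "B"), base, splits, label = "truth")
  obs <- simulate_scenario_sfs(truth_s, c(A = 8, B = 8), n_loci = 5000,
                               seed = 85)$counts
  # all parameters fixed: single deterministic evaluation
  f0 <- fit_scenario(obs, truth_s, c(A = 8, B = 8), n_loci_sim = 3000,
                     seed = 86)
  f0b <- fit_scenario(obs, truth_s, c(A = 8, B = 8), n_loci_sim = 3000,
                      seed = 86)
  expect_identical(f0$n_eval, 1L)
  expect_identical(f0$k, 0L)
  expect_equal(f0$logL, f0b$logL, tolerance = 1e-12)
  # one free parameter starting 2x off: recovered within +/- 25%
  start <- base
  start["T1"] <- 3000
  fit_s <- demographic_scenario(c("A", "B"), start, splits, free = "T1",
                                label = "fit")
  ft <- fit_scenario(obs, fit_s, c(A = 8, B = 8), n_loci_sim = 4000,
                     maxit = 25, seed = 87)
  expect_lt(abs(ft$params["T1"] - 1500) / 1500, 0.25)
  # two free parameters: more restarts never lower the best logL
  fit2 <- demographic_scenario(c("A", "B"), start, splits,
                               free = c("T1", "N_ANC"), label = "fit2")
  g1 <- fit_scenario(obs, fit2, c(A = 8, B = 8), n_loci_sim = 1500,
                     n_restarts = 1, maxit = 10, seed = 88)
  g2 <- fit_scenario(obs, fit2, c(A = 8, B = 8), n_loci_sim = 1500,
                     n_restarts = 2, maxit = 10, seed = 88)
  expect_gte(g2$logL, g1$logL - 1e-9)
})

test_that("AIC table ranks models and penalises parameters", {
  base <- c(N_A = 400, N_B = 400, N_ANC = 400, T1 = 1200)
  splits <- list(list(time = "T1", derived = "B", into = "A",
                      size_after = "N_ANC"))
  s_true <- demographic_scenario(c("A", "B"), base, splits, label = "true")
  shallow <- base
  shallow["T1"] <- 120
  s_wrong <- demographic_scenario(c("A", "B"), shallow, splits,
                                  label = "wrong")
  obs <- simulate_scenario_sfs(s_true, c(A = 6, B = 6), n_loci = 4000,
                               seed = 90)$counts
  cmp <- compare_models(obs, list(s_true, s_wrong), c(A = 6, B = 6),
                        n_loci_sim = 3000, seed = 91)
  expect_identical(cmp$model[1], "true")
  expect_equal(cmp$AIC, 2 * cmp$k - 2 * cmp$logL)
  expect_equal(cmp$dAIC[1], 0)
  expect_true(all(cmp$dAIC >= 0))
  expect_error(compare_models(obs, list(), c(A = 6, B = 6)), "empty")
  # split-time ordering enforced
  bad <- demographic_scenario(
    c("A", "B", "C"), c(N_A = 100, N_B = 100, N_C = 100, T1 = 50, T2 = 50),
    list(list(time = "T1", derived = "B", into = "A"),
         list(time = "T2", derived = "C", into = "A")), label = "bad")
  expect_error(simulate_scenario_sfs(bad, c(A = 2, B = 2, C = 2), 10),
               "strictly increasing")
})

test_that("pairwise marginals agree with single-pair simulations structurally", {
  tmpl <- scenario_templates("africa")
  expect_named(tmpl, c("A_africa_from_inp", "B_africa_from_pac",
                       "C_africa_from_inp_geneflow"))
  topo <- scenario_templates("topologies")
  expect_length(topo, 6L)
  ss <- c(MSEA = 4, InP = 4, Pac = 4, Afr = 4)
  sim <- simulate_scenario_sfs(tmpl$A_africa_from_inp, ss, n_loci = 2000,
                               seed = 92)
  prs <- pairwise_sfs(sim$expected, tmpl$A_africa_from_inp$pops)
  expect_length(prs, 6L)
  expect_equal(sum(prs[["MSEA-InP"]]), sum(sim$expected), tolerance = 1e-9)
  expect_identical(dim(prs[["InP-Pac"]]), c(5L, 5L))
})
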