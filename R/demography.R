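# Joint site-frequency spectra with hypergeometric projection,
# split-and-migration coalescent scenarios, composite likelihood and AIC
# model comparison.

#' Joint 2-D site-frequency spectrum with missing-data projection
#'
#' Per site, the observed alternate-allele count in each population is
#' projected down to `project_to` allele copies by the expectation over
#' hypergeometric subsamples; a site observed with fewer copies than the
#' projection target in either population is dropped (and counted). The
#' alternate allele is treated as derived; `folded = TRUE` folds onto minor
#' allele counts.
#'
#' @param m1,m2 Individuals x loci 012 matrices (same loci, NA allowed).
#' @param project_to Length-2 integer vector of target allele copies;
#'   defaults to the smallest observed copy number per population.
#' @param folded Fold the spectrum over the minor allele (default FALSE).
#' @return A `joint_sfs`: `matrix` ((k1+1) x (k2+1) expected site counts),
#'   `project_to`, `n_sites_used`, `n_sites_dropped`, `folded`.
#' @export
build_joint_sfs <- function(m1, m2, project_to = NULL, folded = FALSE) {
  stopifnot(ncol(m1) == ncol(m2))
  c1 <- site_counts(m1); c2 <- site_counts(m2)
  if (is.null(project_to))
    project_to <- c(min(c1$copies), min(c2$copies))
  project_to <- as.integer(project_to)
  if (any(project_to < 2)) stop("project_to must be >= 2 copies")
  k1 <- project_to[1L]; k2 <- project_to[2L]
  ok <- c1$copies >= k1 & c2$copies >= k2
  sfs <- matrix(0, k1 + 1L, k2 + 1L,
                dimnames = list(0:k1, 0:k2))
  proj <- function(j, m, k) stats::dhyper(0:k, j, m - j, k)
  for (s in which(ok)) {
    w1 <- proj(c1$alt[s], c1$copies[s], k1)
    w2 <- proj(c2$alt[s], c2$copies[s], k2)
    sfs <- sfs + outer(w1, w2)
  }
  if (folded) sfs <- fold_sfs(sfs)
  structure(list(matrix = sfs, project_to = project_to,
                 n_sites_used = sum(ok), n_sites_dropped = sum(!ok),
                 folded = folded),
            class = "joint_sfs")
}

## fold a 2-D spectrum onto total minor-allele orientation
fold_sfs <- function(sfs) {
  k1 <- nrow(sfs) - 1L; k2 <- ncol(sfs) - 1L
  out <- matrix(0, k1 + 1L, k2 + 1L, dimnames = dimnames(sfs))
  for (i in 0:k1) for (j in 0:k2) {
    ii <- i + 1L; jj <- j + 1L
    if (2 * (i + j) < (k1 + k2) ||
        (2 * (i + j) == (k1 + k2) && i <= k1 - i)) {
      out[ii, jj] <- out[ii, jj] + sfs[ii, jj]
    } else {
      out[k1 - i + 1L, k2 - j + 1L] <- out[k1 - i + 1L, k2 - j + 1L] +
        sfs[ii, jj]
    }
  }
  out
}

#' Define a split-and-migration demographic scenario
#'
#' Populations coalesce backwards in time: at each split time the derived
#' population's lineages merge into its source, whose size may change.
#' Migration entries are symmetric backward per-generation, per-lineage
#' rates, active until either population has merged away. Parameters are
#' referenced by name so any of them can be declared free for fitting.
#'
#' @param pops Character vector of population labels.
#' @param params Named numeric vector of all parameter values: population
#'   sizes (diploid), split times (generations), migration rates.
#' @param splits List of `list(time =, derived =, into =, size_after =)`;
#'   `time` and `size_after` are parameter names (`size_after` optional).
#' @param migration List of `list(between = c(a, b), rate =)` with `rate` a
#'   parameter name.
#' @param sizes Named character vector mapping each population to its size
#'   parameter.
#' @param free Character vector of free (fitted) parameter names.
#' @param lower,upper Optional named bounds for free parameters.
#' @param label Scenario name.
#' @return A `demographic_scenario`.
#' @export
demographic_scenario <- function(pops, params, splits, migration = list(),
                                 sizes = NULL, free = character(),
                                 lower = NULL, upper = NULL,
                                 label = "scenario") {
  if (is.null(sizes))
    sizes <- stats::setNames(paste0("N_", pops), pops)
  need <- unique(c(unname(sizes),
                   vapply(splits, `[[`, "", "time"),
                   unlist(lapply(splits, function(s) s$size_after)),
                   vapply(migration, `[[`, "", "rate")))
  missing <- setdiff(need, names(params))
  if (length(missing)) stop("params missing: ", paste(missing, collapse = ", "))
  if (!all(free %in% names(params)))
    stop("free parameters must appear in params")
  structure(list(pops = pops, params = params, splits = splits,
                 migration = migration, sizes = sizes, free = free,
                 lower = lower, upper = upper, label = label),
            class = "demographic_scenario")
}

#' @export
print.demographic_scenario <- function(x, ...) {
  cat(sprintf("demographic_scenario '%s': %d pops, %d splits, %d migration pairs, %d free (%s)\n",
              x$label, length(x$pops), length(x$splits),
              length(x$migration), length(x$free),
              paste(x$free, collapse = ", ")))
  invisible(x)
}

resolve_scenario <- function(s, params = s$params) {
  K <- length(s$pops)
  if (K > 8L) stop("at most 8 populations supported")
  pid <- stats::setNames(seq_len(K), s$pops)
  times <- vapply(s$splits, function(sp) unname(params[sp$time]), numeric(1))
  if (any(diff(times) <= 0))
    stop("split times must be strictly increasing")
  if (any(times <= 0)) stop("split times must be positive")
  merges <- matrix(0, length(s$splits), 4L)
  for (i in seq_along(s$splits)) {
    sp <- s$splits[[i]]
    size_after <- if (!is.null(sp$size_after)) params[sp$size_after] else
      params[s$sizes[sp$into]]
    merges[i, ] <- c(times[i], pid[sp$derived] - 1L, pid[sp$into] - 1L,
                     size_after)
  }
  mig <- matrix(0, K, K)
  for (mg in s$migration) {
    i <- pid[mg$between[1L]]; j <- pid[mg$between[2L]]
    mig[i, j] <- mig[i, j] + unname(params[mg$rate])
    mig[j, i] <- mig[j, i] + unname(params[mg$rate])
  }
  if (any(mig < 0)) stop("migration rates must be >= 0")
  sz <- unname(params[s$sizes[s$pops]])
  if (any(sz <= 0)) stop("population sizes must be positive")
  list(pop_sizes = sz, mig = mig, merges = merges, pid = pid)
}

#' Simulate the joint SFS expected under a scenario
#'
#' Runs the event-driven structured coalescent (exponential coalescence and
#' migration, population mergers at split times) for `n_loci` independent
#' loci, with mutations placed uniformly on the trees (infinite sites).
#' Returns the branch-length expectation (low variance; scaled so its
#' total equals `n_loci`) and a sampled spectrum of `n_loci` segregating
#' sites - a multinomial draw over the accumulated branch lengths, so loci
#' carry sites in proportion to their tree length.
#'
#' @param s A [demographic_scenario()].
#' @param sample_sizes Named integer vector: allele copies sampled per
#'   population (names must match `s$pops`).
#' @param n_loci Number of independent loci.
#' @param seed Integer seed.
#' @param params Optional parameter override (for fitting).
#' @return List: `expected` (array over allele-count bins, one dimension
#'   per population), `counts` (integer array), `pops`, `sample_sizes`.
#' @export
simulate_scenario_sfs <- function(s, sample_sizes, n_loci = 10000L,
                                  seed = NULL, params = s$params) {
  stopifnot(inherits(s, "demographic_scenario"))
  if (is.null(names(sample_sizes)))
    names(sample_sizes) <- s$pops
  ss <- as.integer(sample_sizes[s$pops])
  if (anyNA(ss) || sum(ss) < 2) stop("invalid sample sizes")
  r <- resolve_scenario(s, params)
  if (!is.null(seed)) set.seed(seed)
  out <- coal_sfs_cpp(ss, r$pop_sizes, r$mig, r$merges, as.integer(n_loci))
  lens <- out$branch_lengths
  expected <- lens / sum(lens) * n_loci
  counts <- array(stats::rmultinom(1L, as.integer(n_loci),
                                   as.vector(lens) / sum(lens)),
                  dim = dim(lens))
  list(expected = expected, counts = counts, pops = s$pops,
       sample_sizes = stats::setNames(ss, s$pops))
}

#' Pairwise 2-D marginals of a joint SFS array
#'
#' @param arr Array over allele-count bins, one dimension per population.
#' @param pops Population labels, one per dimension.
#' @return Named list of 2-D matrices, one per unordered population pair.
#' @export
pairwise_sfs <- function(arr, pops = names(dim(arr))) {
  K <- length(dim(arr))
  if (is.null(pops)) pops <- paste0("pop", seq_len(K))
  if (K == 2L) {
    return(stats::setNames(list(arr), paste(pops[1L], pops[2L], sep = "-")))
  }
  pairs <- utils::combn(K, 2L, simplify = FALSE)
  out <- lapply(pairs, function(pr) apply(arr, pr, sum))
  stats::setNames(out, vapply(pairs, function(pr)
    paste(pops[pr], collapse = "-"), character(1)))
}

#' Multinomial composite log-likelihood of an observed SFS
#'
#' `logL = sum(obs * log(p))` over SFS entries, with `p` the expected
#' proportions. The two monomorphic corner entries are excluded by default
#' (SNP-only data carry no invariant-site information); expected
#' proportions are floored at `floor` (default 1e-10) so entries the
#' simulation never visited stay finite, without renormalisation.
#'
#' @param obs Observed SFS (matrix/array of counts, or `joint_sfs`).
#' @param expected Expected SFS on the same shape (counts or proportions).
#' @param exclude_corners Drop the all-ancestral and all-derived corners.
#' @param floor Pseudo-probability for empty expected entries.
#' @return Composite log-likelihood (scalar).
#' @export
composite_loglik <- function(obs, expected, exclude_corners = TRUE,
                             floor = 1e-10) {
  if (inherits(obs, "joint_sfs")) obs <- obs$matrix
  if (inherits(expected, "joint_sfs")) expected <- expected$matrix
  if (!identical(dim(obs), dim(expected)) ||
      length(obs) != length(expected))
    stop("observed and expected SFS shapes differ")
  o <- as.vector(obs); e <- as.vector(expected)
  keep <- rep(TRUE, length(o))
  if (exclude_corners) keep[c(1L, length(o))] <- FALSE
  o <- o[keep]; e <- e[keep]
  p <- e / sum(e)
  p[p < floor] <- floor
  sum(o * log(p))
}

## composite logL of a multi-pop observation against a scenario's
## simulated expectation, summed over pairwise 2-D marginals
scenario_loglik <- function(obs_pairs, s, sample_sizes, n_loci_sim,
                            sim_seed, params = s$params) {
  sim <- simulate_scenario_sfs(s, sample_sizes, n_loci_sim,
                               seed = sim_seed, params = params)
  exp_pairs <- pairwise_sfs(sim$expected, s$pops)
  if (is.matrix(obs_pairs) || is.array(obs_pairs))
    obs_pairs <- pairwise_sfs(obs_pairs, s$pops)
  sum(vapply(names(obs_pairs), function(nm)
    composite_loglik(obs_pairs[[nm]], exp_pairs[[nm]],
                     exclude_corners = FALSE), numeric(1)))
}

#' Fit a scenario's free parameters by maximum composite likelihood
#'
#' Multi-restart Nelder-Mead search over the log-scaled free parameters.
#' Each objective evaluation re-simulates the expected SFS with a fixed
#' seed (common random numbers), making the search surface deterministic
#' for a given `seed`. With no free parameters the scenario is evaluated
#' once.
#'
#' @param obs Observed joint SFS: array over the scenario's populations,
#'   or list of pairwise matrices as from [pairwise_sfs()].
#' @param s A [demographic_scenario()].
#' @param sample_sizes Named allele-copy counts per population (must match
#'   the observation's shape).
#' @param n_loci_sim Simulated loci per objective evaluation.
#' @param n_restarts Number of jittered restarts.
#' @param maxit Nelder-Mead iterations per restart.
#' @param seed Integer seed for the simulation stream and the jitter.
#' @return List: `logL`, `params` (full vector at the optimum), `k`
#'   (number of free parameters), `n_eval`, `label`.
#' @export
fit_scenario <- function(obs, s, sample_sizes, n_loci_sim = 10000L,
                         n_restarts = 3L, maxit = 30L, seed = 1L) {
  stopifnot(inherits(s, "demographic_scenario"))
  sim_seed <- seed
  n_eval <- 0L
  free <- s$free
  if (!length(free)) {
    ll <- scenario_loglik(obs, s, sample_sizes, n_loci_sim, sim_seed)
    return(list(logL = ll, params = s$params, k = 0L, n_eval = 1L,
                label = s$label))
  }
  lower <- s$lower
  upper <- s$upper
  if (is.null(lower)) lower <- s$params[free] / 100
  if (is.null(upper)) upper <- s$params[free] * 100
  objective <- function(logth) {
    n_eval <<- n_eval + 1L
    th <- exp(logth)
    if (any(th < lower[free] | th > upper[free])) return(1e10)
    params <- s$params
    params[free] <- th
    ll <- tryCatch(scenario_loglik(obs, s, sample_sizes, n_loci_sim,
                                   sim_seed, params),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  best <- NULL
  if (length(free) == 1L) {
    ## deterministic objective + one dimension: golden-section (Brent)
    opt <- stats::optim(log(s$params[free]), objective, method = "Brent",
                        lower = log(lower[free]), upper = log(upper[free]),
                        control = list(maxit = maxit))
    best <- opt
  } else {
    for (r in seq_len(n_restarts)) {
      set.seed(seed + 1000L * r)
      start <- log(s$params[free]) +
        if (r == 1L) 0 else stats::runif(length(free), -0.7, 0.7)
      opt <- stats::optim(start, objective, method = "Nelder-Mead",
                          control = list(maxit = maxit))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  }
  params <- s$params
  params[free] <- exp(best$par)
  list(logL = -best$value, params = params, k = length(free),
       n_eval = n_eval, label = s$label)
}

#' Compare demographic scenarios by AIC
#'
#' Fits each scenario to the same observed joint SFS and ranks them by
#' `AIC = 2k - 2 logL`, `k` being the number of free parameters.
#'
#' @param obs Observed joint SFS (array or pairwise list).
#' @param scenarios List of [demographic_scenario()] objects.
#' @param sample_sizes Named allele-copy counts per population.
#' @param ... Passed to [fit_scenario()].
#' @return A `model_comparison` data frame sorted by AIC: `model`, `logL`,
#'   `k`, `AIC`, `dAIC`, with the fitted parameter vectors in attribute
#'   `"fits"`.
#' @export
compare_models <- function(obs, scenarios, sample_sizes, ...) {
  if (!length(scenarios)) stop("empty scenario list")
  fits <- lapply(scenarios, function(s)
    fit_scenario(obs, s, sample_sizes, ...))
  tab <- data.frame(
    model = vapply(fits, `[[`, "", "label"),
    logL = vapply(fits, `[[`, 0, "logL"),
    k = vapply(fits, `[[`, 0L, "k"))
  tab$AIC <- 2 * tab$k - 2 * tab$logL
  tab$dAIC <- tab$AIC - min(tab$AIC)
  tab <- tab[order(tab$AIC), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' Built-in scenario templates
#'
#' Desk-scale scenario set for a four-gene-pool crop dispersal history:
#' three 3-population topologies for the Mainland-Southeast-Asia (MSEA),
#' Indian-Peninsula (InP) and
#' Pacific (Pac) gene pools, each with and without InP-Pac migration, and
#' the three Africa-origin models on the winning backbone (Pacific splits
#' first, then MSEA/InP): A - Africa from InP; B - Africa from Pac; C -
#' Africa from InP with Afr-Pac gene flow. Migration rates are fixed at
#' 0.005 per generation per lineage; the Africa divergence time `TDIV1` is
#' the free parameter of models A-C. Sizes and times are desk-scale
#' defaults (N = 100 diploids, TDIV1/2/3 = 100/200/400 generations).
#'
#' @param which `"africa"` (models A-C, default) or `"topologies"` (the
#'   3-population templates).
#' @return Named list of [demographic_scenario()] objects.
#' @export
scenario_templates <- function(which = c("africa", "topologies")) {
  which <- match.arg(which)
  base_params <- c(N_MSEA = 100, N_InP = 100, N_Pac = 100, N_Afr = 100,
                   N_ANC = 100, TDIV1 = 100, TDIV2 = 200, TDIV3 = 400,
                   GF_InP_Pac = 0.005, GF_Afr_Pac = 0.005)
  if (which == "topologies") {
    pops3 <- c("MSEA", "InP", "Pac")
    topo <- list(
      `MSEA-InP` = list(list(time = "TDIV2", derived = "MSEA", into = "InP"),
                        list(time = "TDIV3", derived = "Pac", into = "InP",
                             size_after = "N_ANC")),
      `MSEA-Pac` = list(list(time = "TDIV2", derived = "MSEA", into = "Pac"),
                        list(time = "TDIV3", derived = "InP", into = "Pac",
                             size_after = "N_ANC")),
      `InP-Pac` = list(list(time = "TDIV2", derived = "InP", into = "Pac"),
                       list(time = "TDIV3", derived = "MSEA", into = "Pac",
                            size_after = "N_ANC")))
    out <- list()
    for (nm in names(topo)) {
      for (mig in c(FALSE, TRUE)) {
        lab <- paste0("topo_", nm, if (mig) "_mig" else "")
        out[[lab]] <- demographic_scenario(
          pops3, base_params, topo[[nm]],
          migration = if (mig)
            list(list(between = c("InP", "Pac"), rate = "GF_InP_Pac"))
          else list(),
          free = "TDIV2", label = lab)
      }
    }
    return(out)
  }
  pops4 <- c("MSEA", "InP", "Pac", "Afr")
  backbone <- list(list(time = "TDIV2", derived = "MSEA", into = "InP"),
                   list(time = "TDIV3", derived = "Pac", into = "InP",
                        size_after = "N_ANC"))
  mig_base <- list(list(between = c("InP", "Pac"), rate = "GF_InP_Pac"))
  splits_a <- c(list(list(time = "TDIV1", derived = "Afr", into = "InP")),
                backbone)
  splits_b <- c(list(list(time = "TDIV1", derived = "Afr", into = "Pac")),
                backbone)
  list(
    A_africa_from_inp = demographic_scenario(
      pops4, base_params, splits_a, migration = mig_base,
      free = "TDIV1", label = "A_africa_from_inp"),
    B_africa_from_pac = demographic_scenario(
      pops4, base_params, splits_b, migration = mig_base,
      free = "TDIV1", label = "B_africa_from_pac"),
    C_africa_from_inp_geneflow = demographic_scenario(
      pops4, base_params, splits_a,
      migration = c(mig_base,
                    list(list(between = c("Afr", "Pac"),
                              rate = "GF_Afr_Pac"))),
      free = "TDIV1", label = "C_africa_from_inp_geneflow"))
}
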