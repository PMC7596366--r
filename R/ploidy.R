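# Ploidy inference from the distribution of alternate-allele read fractions
# at heterozygous sites: histogram, polynomial fit, local-maxima count.
# Expected modes: diploid {1/2}; triploid {1/3, 2/3}; tetraploid
# {1/4, 1/2, 3/4}; 0 or more than 3 maxima -> unknown.

#' Parameters of the ploidy-inference stage
#'
#' @param min_site_depth Minimum per-cell depth for a heterozygous site to
#'   contribute a read fraction (trained default 30).
#' @param n_classes Number of equal-width histogram classes on (0, 1); 100,
#'   250 or 500 by convention.
#' @param poly_degree Even degree of the least-squares polynomial fitted to
#'   the class heights. Degree 10 is the smallest even degree that resolves
#'   the three tetraploid humps reliably at realistic depth.
#' @param maxima_window Open interval of allele fraction in which local
#'   maxima are accepted; edges are prone to sequencing-error artefacts.
#' @param merge_tol Maxima closer than this are merged (the higher kept).
#' @param min_peak_frac Local maxima whose fitted height falls below this
#'   fraction of the tallest fitted value are discarded; suppresses
#'   low-amplitude polynomial ringing over the empty histogram tails.
#' @param min_het_sites Minimum usable heterozygous sites; below it the
#'   call is `unknown`.
#' @return A `ploidy_params` list.
#' @export
ploidy_params <- function(min_site_depth = 30L, n_classes = 250L,
                          poly_degree = 10L, maxima_window = c(0.1, 0.9),
                          merge_tol = 0.08, min_peak_frac = 0.1,
                          min_het_sites = 100L) {
  if (poly_degree < 4L || poly_degree %% 2L != 0L)
    stop("poly_degree must be even and >= 4")
  stopifnot(length(maxima_window) == 2L,
            maxima_window[1] < maxima_window[2],
            maxima_window[1] >= 0, maxima_window[2] <= 1)
  structure(list(min_site_depth = as.integer(min_site_depth),
                 n_classes = as.integer(n_classes),
                 poly_degree = as.integer(poly_degree),
                 maxima_window = as.numeric(maxima_window),
                 merge_tol = merge_tol, min_peak_frac = min_peak_frac,
                 min_het_sites = as.integer(min_het_sites)),
            class = "ploidy_params")
}

#' Alternate-allele read fractions at heterozygous sites
#'
#' For one sample, returns `alt / (ref + alt)` at sites where the genotype
#' call is heterozygous and the cell depth reaches `min_site_depth`.
#'
#' @param rct An `rc_table` with AD counts.
#' @param sample Sample id.
#' @param params A [ploidy_params()].
#' @return Numeric vector of read fractions (possibly shorter than
#'   `min_het_sites`; the caller decides what to do then).
#' @export
het_site_fractions <- function(rct, sample, params = ploidy_params()) {
  stopifnot(inherits(rct, "rc_table"))
  j <- match(sample, rct$samples)
  if (is.na(j)) stop("unknown sample: ", sample)
  tot <- rct$ref_reads[, j] + rct$alt_reads[, j]
  use <- !is.na(rct$gt[, j]) & rct$gt[, j] == 1L &
    rct$depth[, j] >= params$min_site_depth & tot > 0L
  unname(rct$alt_reads[use, j] / tot[use])
}

## Least-squares polynomial through (midpoint, height) pairs; local maxima
## located on a fine grid by derivative sign change, restricted to the
## window, then merged by proximity.
fit_polynomial_modes <- function(midpoints, heights, params) {
  fit <- tryCatch(
    stats::lm(heights ~ stats::poly(midpoints, params$poly_degree)),
    error = function(e) NULL)
  if (is.null(fit) || anyNA(stats::coef(fit)))
    return(list(maxima = numeric(0), grid = NULL, residual = NA_real_,
                singular = TRUE))
  grid <- seq(1e-3, 1 - 1e-3, length.out = 2001L)
  y <- stats::predict(fit, newdata = data.frame(midpoints = grid))
  dy <- diff(y)
  turn <- which(dy[-length(dy)] > 0 & dy[-1L] <= 0) + 1L
  mx <- grid[turn]
  mh <- y[turn]
  inside <- mx > params$maxima_window[1] & mx < params$maxima_window[2]
  mx <- mx[inside]; mh <- mh[inside]
  ## drop ringing artefacts: peaks far below the tallest fitted value
  if (length(mx) && params$min_peak_frac > 0) {
    keep <- mh >= params$min_peak_frac * max(c(mh, y))
    mx <- mx[keep]; mh <- mh[keep]
  }
  ## merge maxima closer than merge_tol, keeping the higher
  if (length(mx) > 1L) {
    o <- order(mx)
    mx <- mx[o]; mh <- mh[o]
    repeat {
      gaps <- diff(mx)
      k <- which(gaps < params$merge_tol)
      if (!length(k)) break
      k <- k[1L]
      drop <- if (mh[k] >= mh[k + 1L]) k + 1L else k
      mx <- mx[-drop]; mh <- mh[-drop]
    }
  }
  list(maxima = mx, heights_at_maxima = mh,
       residual = sum(stats::residuals(fit)^2),
       fit = fit, grid_x = grid, grid_y = y, singular = FALSE)
}

#' Fit the read-fraction distribution and locate its modes
#'
#' Bins the fractions into `n_classes` equal-width classes on (0, 1), fits
#' a least-squares polynomial of degree `poly_degree` through the class
#' midpoints and heights, and reports the interior local maxima of the
#' fitted curve (derivative sign change + to -) inside `maxima_window`,
#' after merging maxima closer than `merge_tol`.
#'
#' @param fractions Vector of alternate-allele read fractions.
#' @param params A [ploidy_params()].
#' @return A `histogram_fit`: `class_midpoints`, `class_heights`, `maxima`
#'   (ordered allele fractions), `n_maxima`, `residual`, `n_fractions`.
#' @export
fit_distribution <- function(fractions, params = ploidy_params()) {
  breaks <- seq(0, 1, length.out = params$n_classes + 1L)
  h <- graphics::hist(fractions, breaks = breaks, plot = FALSE)
  modes <- fit_polynomial_modes(h$mids, h$counts, params)
  structure(list(class_midpoints = h$mids, class_heights = h$counts,
                 maxima = modes$maxima, n_maxima = length(modes$maxima),
                 residual = modes$residual, singular = modes$singular,
                 n_fractions = length(fractions),
                 grid_x = modes$grid_x, grid_y = modes$grid_y),
            class = "histogram_fit")
}

#' Map the number of detected modes to a ploidy level
#'
#' One mode is read as diploid (fractions around 1/2), two as triploid
#' (1/3, 2/3), three as tetraploid (1/4, 1/2, 3/4); zero or more than
#' three modes, a singular fit, or too few heterozygous sites give
#' `"unknown"`.
#'
#' @param fit A `histogram_fit`.
#' @param sample_id Optional id carried into the call.
#' @param params A [ploidy_params()] (supplies `min_het_sites`).
#' @return A `ploidy_call` list: `sample_id`, `ploidy` (`"2"`, `"3"`,
#'   `"4"` or `"unknown"`), `n_maxima`, `maxima`, `n_het_sites_used`.
#' @export
classify_ploidy <- function(fit, sample_id = NA_character_,
                            params = ploidy_params()) {
  stopifnot(inherits(fit, "histogram_fit"))
  pl <- if (isTRUE(fit$singular) || fit$n_fractions < params$min_het_sites) {
    "unknown"
  } else {
    switch(as.character(fit$n_maxima),
           "1" = "2", "2" = "3", "3" = "4", "unknown")
  }
  structure(list(sample_id = sample_id, ploidy = pl,
                 n_maxima = fit$n_maxima, maxima = fit$maxima,
                 n_het_sites_used = fit$n_fractions),
            class = "ploidy_call")
}

#' Call ploidy for every sample of a read-count table
#'
#' @param rct An `rc_table` with AD counts.
#' @param params A [ploidy_params()].
#' @return Data frame with one row per sample: `sample_id`, `ploidy`,
#'   `n_maxima`, `maxima` (comma-separated), `n_het_sites`.
#' @export
call_ploidy <- function(rct, params = ploidy_params()) {
  rows <- lapply(rct$samples, function(s) {
    fr <- het_site_fractions(rct, s, params)
    cl <- classify_ploidy(fit_distribution(fr, params), s, params)
    data.frame(sample_id = s, ploidy = cl$ploidy, n_maxima = cl$n_maxima,
               maxima = paste(sprintf("%.3f", cl$maxima), collapse = ","),
               n_het_sites = cl$n_het_sites_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Train ploidy-inference parameters on labelled accessions
#'
#' Evaluates every combination of the supplied parameter values on samples
#' of known ploidy and returns the combination with the highest accuracy
#' (`unknown` counts as incorrect). Ties are broken in favour of the higher
#' `min_site_depth`, then the smaller number of classes.
#'
#' @param rct An `rc_table` containing the labelled samples.
#' @param labels Named character/integer vector: sample id -> true ploidy.
#' @param grid Named list of candidate values for any of `min_site_depth`,
#'   `n_classes`, `poly_degree`, `min_het_sites`.
#' @return List: `best` ([ploidy_params()]), `accuracy`, `confusion`
#'   (table), `results` (per-combination accuracy data frame).
#' @export
train_parameters <- function(rct, labels,
                             grid = list(min_site_depth = c(8L, 30L),
                                         n_classes = c(100L, 250L, 500L))) {
  if (length(unique(labels)) < 2L)
    stop("training labels must span at least two ploidy levels")
  base <- ploidy_params()
  known <- setdiff(names(grid),
                   c("min_site_depth", "n_classes", "poly_degree",
                     "min_het_sites"))
  if (length(known)) stop("unknown grid dimensions: ",
                          paste(known, collapse = ", "))
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  if (nrow(combos) == 0L) stop("empty parameter grid")
  truth <- as.character(labels)
  ids <- names(labels)
  res <- combos
  res$accuracy <- NA_real_
  fits <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    p <- base
    for (nm in names(combos)) p[[nm]] <- combos[i, nm]
    calls <- vapply(ids, function(s) {
      fr <- het_site_fractions(rct, s, p)
      classify_ploidy(fit_distribution(fr, p), s, p)$ploidy
    }, character(1))
    res$accuracy[i] <- mean(calls == truth)
    fits[[i]] <- calls
  }
  ord <- order(-res$accuracy,
               -if (!is.null(res$min_site_depth)) res$min_site_depth else 0,
               if (!is.null(res$n_classes)) res$n_classes else 0)
  best_i <- ord[1L]
  best <- base
  for (nm in names(combos)) best[[nm]] <- combos[best_i, nm]
  list(best = best, accuracy = res$accuracy[best_i],
       confusion = table(truth = truth, called = fits[[best_i]]),
       results = res)
}
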