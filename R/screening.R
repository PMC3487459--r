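#' Deterministic T_fix screen over topographies and a parameter grid
#'
#' Computes `T_fix` (ratio of fixation times with and without recombination in
#' the infinite-population model) for every combination of fitness topography
#' and parameter set, in a deterministic order. Already-computed rows can be
#' skipped by passing their ids in `done`, which makes long screens resumable.
#'
#' @param topographies list of [fitness_topography()] objects sharing `L`.
#' @param param_grid data.frame with columns `s`, `eps`, `mu`, `r` (one row
#'   per parameter set); defaults to the single standard parameter set.
#' @param weights optional integer vector, one per topography: the number of
#'   equivalent landscapes each topography represents (see
#'   [orbit_representatives()]); stored in the `weight` column.
#' @param fixation_threshold fixation cutoff (default 0.99).
#' @param t_max integration horizon per arm.
#' @param done character vector of `topo_id` values to skip.
#' @param quiet suppress per-row progress output (default TRUE).
#' @return data.frame with one row per (topography, parameter set): `topo_id`,
#'   `lfg_count`, `weight`, `s`, `eps`, `mu`, `r`, `t_fix`, `time_with_r`,
#'   `time_without_r`, `censored`.
#' @export
screen_deterministic <- function(topographies,
                                 param_grid = standard_param_grid(),
                                 weights = NULL,
                                 fixation_threshold = 0.99, t_max = 1e6,
                                 done = character(0), quiet = TRUE) {
  stopifnot(all(c("s", "eps", "mu", "r") %in% names(param_grid)),
            nrow(param_grid) >= 1)
  if (is.null(weights)) weights <- rep(1L, length(topographies))
  stopifnot(length(weights) == length(topographies))
  L <- topographies[[1]]$L
  space <- genotype_space(L)
  rows <- list()
  for (ti in seq_along(topographies)) {
    topo <- topographies[[ti]]
    if (topo$id %in% done) next
    for (pi in seq_len(nrow(param_grid))) {
      p <- param_grid[pi, ]
      landscape <- build_landscape(space, s = p$s, eps = p$eps, topography = topo)
      params <- dynamics_params(mu = p$mu, r = p$r,
                                fixation_threshold = fixation_threshold,
                                t_max = t_max)
      res <- t_fix_ratio(landscape, params)
      rows[[length(rows) + 1L]] <- data.frame(
        topo_id = topo$id, lfg_count = length(topo$lfgs),
        weight = weights[ti],
        s = p$s, eps = p$eps, mu = p$mu, r = p$r,
        t_fix = res$t_fix,
        time_with_r = res$time_with_r, time_without_r = res$time_without_r,
        censored = !(res$fixed_with_r && res$fixed_without_r),
        stringsAsFactors = FALSE)
      if (!quiet)
        message(sprintf("%s  s=%g eps=%g mu=%g r=%g  T_fix=%.5g",
                        topo$id, p$s, p$eps, p$mu, p$r, res$t_fix))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standard parameter set of the four-locus screens
#'
#' Inferred defaults (midpoints of the published parameter sweeps):
#' `s = 0.05`, `eps = 1`, `mu = 1e-5`, `r = 0.05`.
#'
#' @param s,eps,mu,r overrides (each may be a vector; the full factorial grid
#'   is returned).
#' @return data.frame with columns `s`, `eps`, `mu`, `r`.
#' @export
standard_param_grid <- function(s = 0.05, eps = 1, mu = 1e-5, r = 0.05) {
  expand.grid(s = s, eps = eps, mu = mu, r = r, KEEP.OUT.ATTRS = FALSE)
}

weighted_rep <- function(x, w) rep(x, times = as.integer(w))

#' Box-plot statistics of T_fix by LFG count
#'
#' Per LFG count: quartiles (inclusive linear-interpolation convention,
#' `quantile type 7`), whiskers at the farthest points within 1.5 IQR of the
#' box ends, and outliers beyond them. Rows carrying a `weight > 1` (orbit
#' class sizes) are expanded so that the statistics refer to the full set of
#' equivalent topographies.
#'
#' @param results a [screen_deterministic()] table (one parameter set).
#' @param value column to summarize (default `"t_fix"`).
#' @return data.frame with one row per LFG count: `lfg_count`, `n`, `q1`,
#'   `median`, `q3`, `whisker_lo`, `whisker_hi`, `n_outliers`.
#' @export
summarize_by_lfg_count <- function(results, value = "t_fix") {
  if (length(unique(paste(results$s, results$eps, results$mu, results$r))) > 1)
    stop("results mix parameter sets; summarize one set at a time", call. = FALSE)
  keep <- !is.na(results[[value]])
  dropped <- unique(results$lfg_count[!keep])
  results <- results[keep, ]
  if (length(dropped))
    warning("censored/empty groups omitted for LFG counts: ",
            paste(dropped, collapse = ", "))
  w <- if ("weight" %in% names(results)) results$weight else rep(1L, nrow(results))
  groups <- split(seq_len(nrow(results)), results$lfg_count)
  out <- lapply(groups, function(ix) {
    v <- weighted_rep(results[[value]][ix], w[ix])
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- v[v >= lo_fence & v <= hi_fence]
    data.frame(lfg_count = results$lfg_count[ix[1]], n = length(v),
               q1 = q[1], median = q[2], q3 = q[3],
               whisker_lo = min(inside), whisker_hi = max(inside),
               n_outliers = sum(v < lo_fence | v > hi_fence))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$lfg_count), ]
  rownames(out) <- NULL
  out
}

#' Concordance of T_fix across two parameter sets
#'
#' Pairs the `t_fix` values of two screens over the same topographies and
#' reports the least-squares R-squared, slope, and Spearman rank correlation:
#' a measure of how robust the recombination effect of a topography is to a
#' parameter change.
#'
#' @param results_A,results_B [screen_deterministic()] tables sharing
#'   topographies.
#' @return list: `pairs` (data.frame `topo_id`, `t_fix_A`, `t_fix_B`),
#'   `r_squared`, `slope`, `rank_correlation`, `n`.
#' @export
rank_concordance <- function(results_A, results_B) {
  shared <- intersect(results_A$topo_id, results_B$topo_id)
  if (!length(shared)) stop("no shared topographies", call. = FALSE)
  a <- results_A$t_fix[match(shared, results_A$topo_id)]
  b <- results_B$t_fix[match(shared, results_B$topo_id)]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]; shared <- shared[ok]
  list(pairs = data.frame(topo_id = shared, t_fix_A = a, t_fix_B = b,
                          stringsAsFactors = FALSE),
       r_squared = stats::cor(a, b)^2,   # simple least squares: R^2 = cor^2
       slope = stats::cov(a, b) / stats::var(a),
       rank_correlation = stats::cor(a, b, method = "spearman"),
       n = length(a))
}

#' Physiological epistasis of a fitness landscape
#'
#' Regresses genotype fitness against the number of deleterious mutations `k`
#' using the one-dimensional family `m(k) = 1 - b * k^eps_hat` over all `2^L`
#' genotypes (LFGs enter at fitness 0). `eps_hat > 1` indicates
#' intermediates lower than the additive expectation (positive epistasis in
#' the deleterious-mutation convention). The exponent is found by multi-start
#' nonlinear least squares.
#'
#' By default the scale is anchored at the landscape's per-allele selection
#' coefficient (`b = s`), so `eps_hat` measures pure curvature: the deficit of
#' each LFG relative to the baseline fitness of its mutation class is
#' attributed to the exponent. With `fix_b = FALSE` both `b` and `eps_hat` are
#' free; note that the unconstrained fit can flatten (`eps_hat` below 1 or
#' near 0) on topographies whose LFGs sit close to the peak, because a large
#' `b` with a small exponent then fits the high deficits at small `k`.
#'
#' @param landscape a [build_landscape()] object with at least 3 distinct `k`
#'   values.
#' @param fix_b fix `b` at the landscape's `s` (default) instead of fitting
#'   it.
#' @param starts multi-start values for `eps_hat`.
#' @return list of class `epistasis_estimate`: `eps_hat`, `b`, `rss`
#'   (residual sum of squares), `converged`, `topo_id`.
#' @export
estimate_physiological_epistasis <- function(landscape, fix_b = TRUE,
                                             starts = c(0.25, 0.5, 1, 2, 4)) {
  k <- landscape$space$k
  m <- landscape$m
  if (length(unique(k)) < 3) stop("need >= 3 distinct k values", call. = FALSE)
  y <- 1 - m                 # residual fitness deficit; model: y = b * k^eps
  profiled <- function(log_eps) {
    ke <- k^exp(log_eps)
    b <- if (fix_b) landscape$s else sum(ke * y) / sum(ke * ke)
    sum((y - b * ke)^2)
  }
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::nlminb(log(st), profiled, lower = log(1e-3), upper = log(1e3)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(eps_hat = NA_real_, b = NA_real_, rss = NA_real_,
                          converged = FALSE, topo_id = landscape$topography$id),
                     class = "epistasis_estimate"))
  }
  eps_hat <- exp(best$par)
  ke <- k^eps_hat
  b <- if (fix_b) landscape$s else sum(ke * y) / sum(ke * ke)
  structure(list(eps_hat = eps_hat, b = b, rss = best$objective,
                 converged = best$convergence == 0 || best$objective < 1e-12,
                 topo_id = landscape$topography$id),
            class = "epistasis_estimate")
}

#' @export
print.epistasis_estimate <- function(x, ...) {
  cat(sprintf("Physiological epistasis: eps_hat = %.4g, b = %.4g (rss %.3g)\n",
              x$eps_hat, x$b, x$rss))
  invisible(x)
}

#' Stochastic T_fix screen with a deterministic reference
#'
#' For each sampled topography, computes the deterministic `T_fix` and one
#' stochastic `T_fix` estimate per population size in `N0_list`. Rows are
#' ordered by the deterministic value, the natural axis for comparing the
#' finite- and infinite-population recombination effects.
#'
#' @param topographies list of [fitness_topography()] objects.
#' @param params a [stoch_params()] object (its `N0` is overridden per run).
#' @param N0_list numeric vector of population sizes.
#' @param det_params [dynamics_params()] for the deterministic reference;
#'   defaults to matching `mu` and `r`.
#' @param s,eps baseline landscape parameters shared by both models.
#' @param seed master seed; per-(topography, N0) child seeds are derived
#'   deterministically.
#' @param quiet suppress progress messages.
#' @return data.frame: `topo_id`, `lfg_count`, `N0` (NA on the deterministic
#'   reference rows), `t_fix`, `mean_time_with_r`, `mean_time_without_r`,
#'   `sd_with_r`, `sd_without_r`, `n_censored`, sorted by deterministic
#'   `t_fix`.
#' @export
screen_stochastic <- function(topographies, params = stoch_params(),
                              N0_list = c(1e4, 1e5), det_params = NULL,
                              s = 0.05, eps = 1, seed = 1, quiet = TRUE) {
  if (is.null(det_params))
    det_params <- dynamics_params(mu = params$mu, r = params$r)
  L <- topographies[[1]]$L
  space <- genotype_space(L)
  seeds <- derive_seeds(seed, length(topographies) * length(N0_list))
  si <- 0L
  rows <- list()
  for (ti in seq_along(topographies)) {
    topo <- topographies[[ti]]
    landscape <- build_landscape(space, s = s, eps = eps, topography = topo)
    det <- t_fix_ratio(landscape, det_params)
    rows[[length(rows) + 1L]] <- data.frame(
      topo_id = topo$id, lfg_count = length(topo$lfgs), N0 = NA_real_,
      t_fix = det$t_fix,
      mean_time_with_r = det$time_with_r,
      mean_time_without_r = det$time_without_r,
      sd_with_r = NA_real_, sd_without_r = NA_real_, n_censored = 0L,
      stringsAsFactors = FALSE)
    for (N0 in N0_list) {
      si <- si + 1L
      p <- params
      p$N0 <- N0
      st <- stochastic_t_fix(landscape, p, seed = seeds[si])
      rows[[length(rows) + 1L]] <- data.frame(
        topo_id = topo$id, lfg_count = length(topo$lfgs), N0 = N0,
        t_fix = st$t_fix,
        mean_time_with_r = st$with_r$mean,
        mean_time_without_r = st$without_r$mean,
        sd_with_r = st$with_r$sd, sd_without_r = st$without_r$sd,
        n_censored = st$with_r$n_censored + st$without_r$n_censored,
        stringsAsFactors = FALSE)
      if (!quiet)
        message(sprintf("%s N0=%g stochastic T_fix=%.4g (det %.4g)",
                        topo$id, N0, st$t_fix, det$t_fix))
    }
  }
  out <- do.call(rbind, rows)
  det_rank <- out$t_fix[is.na(out$N0)][match(out$topo_id, out$topo_id[is.na(out$N0)])]
  out <- out[order(det_rank, out$topo_id, out$N0, na.last = FALSE), ]
  rownames(out) <- NULL
  out
}
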