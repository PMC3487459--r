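#' Parameters of the finite-population stochastic model
#'
#' The stochastic model is a continuous-time Moran-type birth-death process
#' over genotype compartments. A genotype-`i` cell is born at rate
#' `B * f_i * n_i` (with `f = exp(m)` the Fisherean fitness), dies at rate
#' `B * (N / N0) * n_i` (density-dependent regulation around the carrying
#' capacity), mutates to each Hamming-1 neighbour at rate `mu * n_i`, and is
#' transformed at locus `l` at rate `(r/L) * n_i * A_l / N`, where `A_l`
#' counts the individuals carrying the opposite allele at `l` (the free-DNA
#' pool mirrors the population's allele frequencies).
#'
#' @param B birth/death rate scale (per capita per unit time).
#' @param N0 target (carrying-capacity) population size.
#' @param mu mutation rate per locus.
#' @param r total per-genome recombination rate (each locus at `r/L`).
#' @param fixation_threshold peak-genotype frequency defining fixation
#'   (default 0.95).
#' @param n_reps number of replicate simulations (default 50).
#' @param t_max censoring horizon. `NULL` (default) uses 50 times the
#'   fixation time of the matching mean-field ODE when that is available.
#' @param tau_leap_threshold compartment size above which tau-leaping applies;
#'   `Inf` gives the pure (exact) Gillespie algorithm.
#' @param tau_eps tau-selection control (bound on the relative change of any
#'   compartment per leap); default 0.03.
#' @return list of class `stoch_params`.
#' @export
stoch_params <- function(B = 1, N0 = 1e4, mu = 1e-5, r = 0.05,
                         fixation_threshold = 0.95, n_reps = 50,
                         t_max = NULL, tau_leap_threshold = 100,
                         tau_eps = 0.03) {
  if (B <= 0) stop("B must be positive", call. = FALSE)
  if (N0 < 2) stop("N0 must be at least 2", call. = FALSE)
  if (mu < 0 || r < 0) stop("rates must be >= 0", call. = FALSE)
  if (fixation_threshold <= 0 || fixation_threshold >= 1)
    stop("fixation_threshold must lie in (0, 1)", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  structure(list(B = B, N0 = N0, mu = mu, r = r,
                 fixation_threshold = fixation_threshold, n_reps = n_reps,
                 t_max = t_max, tau_leap_threshold = tau_leap_threshold,
                 tau_eps = tau_eps),
            class = "stoch_params")
}

#' Malthusian to Fisherean fitness conversion
#'
#' `f = exp(m)`: the per-capita birth-rate factor corresponding to a
#' continuous-time (Malthusian) fitness `m`. Strictly increasing, with
#' `f(0) = 1` (so an LFG is born at the baseline rate `B`).
#'
#' @param m Malthusian fitness (vectorized).
#' @return Fisherean fitness `exp(m)`.
#' @export
fisher_fitness <- function(m) exp(m)

#' Event rate table of the stochastic model
#'
#' Enumerates every reaction channel and its current rate for a given
#' population state; mainly for inspection and testing (the simulator computes
#' the same rates internally).
#'
#' @param n integer vector of compartment counts (length `2^L`).
#' @param landscape a [build_landscape()] object.
#' @param params a [stoch_params()] object.
#' @return data.frame with columns `kind` (birth/death/mutation/
#'   recombination), `genotype` (0-based source index), `locus` (0-based, NA
#'   for birth/death), `product` (0-based, NA for birth/death) and `rate`.
#' @export
event_rates <- function(n, landscape, params) {
  space <- landscape$space
  L <- space$L
  if (length(n) != space$n) stop("n has the wrong length", call. = FALSE)
  if (any(n < 0)) stop("counts must be non-negative", call. = FALSE)
  N <- sum(n)
  f <- fisher_fitness(landscape$m)
  idx <- 0:(space$n - 1L)
  rows <- list(
    data.frame(kind = "birth", genotype = idx, locus = NA_integer_,
               product = NA_integer_, rate = params$B * f * n),
    data.frame(kind = "death", genotype = idx, locus = NA_integer_,
               product = NA_integer_, rate = params$B * (N / params$N0) * n)
  )
  rho <- params$r / L
  for (l in 0:(L - 1L)) {
    prod_idx <- bitwXor(idx, bitwShiftL(1L, l))
    rows[[length(rows) + 1L]] <-
      data.frame(kind = "mutation", genotype = idx, locus = l,
                 product = prod_idx, rate = params$mu * n)
    a1 <- sum(n[space$alleles[, l + 1L] == 1])
    a_opp <- ifelse(space$alleles[, l + 1L] == 1, N - a1, a1)
    rec_rate <- if (N > 0) rho * n * a_opp / N else rep(0, space$n)
    rows[[length(rows) + 1L]] <-
      data.frame(kind = "recombination", genotype = idx, locus = l,
                 product = prod_idx, rate = rec_rate)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

default_t_max <- function(landscape, params, r_arm) {
  det <- fixation_time(landscape,
                       dynamics_params(mu = params$mu, r = r_arm,
                                       fitness_scale = "fisherean",
                                       B = params$B, t_max = 1e7))
  if (det$fixed) 50 * det$time else 1e6
}

#' Simulate one replicate of the finite-population model
#'
#' Runs the continuous-time simulator (exact Gillespie algorithm, with
#' tau-leaping for compartments larger than `params$tau_leap_threshold`)
#' until the peak genotype's frequency exceeds `params$fixation_threshold`,
#' the population goes extinct, or `t_max` is reached.
#'
#' @param landscape a [build_landscape()] object.
#' @param params a [stoch_params()] object.
#' @param n0 integer vector of initial counts; default: `N0` individuals of
#'   the all-0 genotype.
#' @param snapshot_times optional sorted numeric vector; the compartment
#'   counts in effect at each time are recorded (rows of `snapshots`).
#' @param seed optional integer seed, applied locally.
#' @param stop_at_fixation set `FALSE` to run to `t_max` regardless of the
#'   peak frequency (useful when recording trajectories).
#' @param stop_at_peak_loss stop as soon as the peak genotype's count drops to
#'   zero. Only meaningful when the loss is absorbing (`mu = 0`), e.g. in
#'   fixation-probability experiments.
#' @return list of class `stoch_replicate`: `fixed`, `extinct`, `t_fix`
#'   (NA when censored), `t_end`, `n_final`, `snapshots` (matrix, one column
#'   per genotype) and `n_steps`.
#' @export
simulate_population <- function(landscape, params = stoch_params(), n0 = NULL,
                                snapshot_times = numeric(0), seed = NULL,
                                stop_at_fixation = TRUE,
                                stop_at_peak_loss = FALSE) {
  space <- landscape$space
  if (is.null(n0)) {
    n0 <- numeric(space$n)
    n0[space$origin] <- params$N0
  }
  if (length(n0) != space$n) stop("n0 has the wrong length", call. = FALSE)
  t_max <- params$t_max
  if (is.null(t_max)) t_max <- default_t_max(landscape, params, params$r)
  thr <- if (stop_at_fixation) params$fixation_threshold else 2  # unreachable
  run <- function() {
    sim_population_cpp(
      f = fisher_fitness(landscape$m), L = space$L, B = params$B,
      N0 = params$N0, mu = params$mu, r = params$r, fix_threshold = thr,
      t_max = t_max, n_init = as.numeric(n0), peak = space$peak - 1L,
      tau_threshold = params$tau_leap_threshold, tau_eps = params$tau_eps,
      snapshot_times = as.numeric(snapshot_times),
      stop_peak_loss = stop_at_peak_loss)
  }
  res <- if (is.null(seed)) run() else with_local_seed(seed, run())
  res$t_max <- t_max
  colnames(res$snapshots) <- space$genotypes
  class(res) <- "stoch_replicate"
  res
}

#' @export
print.stoch_replicate <- function(x, ...) {
  if (x$fixed) cat(sprintf("Fixation at t = %.6g", x$t_fix))
  else if (x$extinct) cat(sprintf("Extinction at t = %.6g", x$t_end))
  else cat(sprintf("Censored at t_max = %.6g", x$t_max))
  cat(sprintf("  (%g events)\n", x$n_steps))
  invisible(x)
}

# deterministic child-seed derivation from one master seed
derive_seeds <- function(seed, k) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

#' Mean fixation time over replicate simulations
#'
#' Runs `params$n_reps` independent replicates (child seeds derived
#' deterministically from `seed`) and averages the fixation times of the
#' uncensored ones. Censored or extinct replicates are reported separately and
#' never silently averaged.
#'
#' @inheritParams simulate_population
#' @param seed integer master seed.
#' @return list of class `mean_fixation_result`: `mean`, `sd` (NA for a single
#'   replicate), `times` (uncensored fixation times), `n_censored`,
#'   `n_extinct`, `n_reps`, `seeds`.
#' @export
mean_fixation_time <- function(landscape, params = stoch_params(), seed = 1,
                               n0 = NULL) {
  seeds <- derive_seeds(seed, params$n_reps)
  if (is.null(params$t_max))
    params$t_max <- default_t_max(landscape, params, params$r)
  times <- rep(NA_real_, params$n_reps)
  extinct <- logical(params$n_reps)
  for (i in seq_len(params$n_reps)) {
    rep_i <- simulate_population(landscape, params, n0 = n0, seed = seeds[i])
    if (rep_i$fixed) times[i] <- rep_i$t_fix
    extinct[i] <- isTRUE(rep_i$extinct)
  }
  ok <- !is.na(times)
  structure(list(
    mean = if (any(ok)) mean(times[ok]) else NA_real_,
    sd = if (sum(ok) > 1) stats::sd(times[ok]) else NA_real_,
    times = times[ok],
    n_censored = sum(!ok & !extinct),
    n_extinct = sum(extinct),
    n_reps = params$n_reps,
    seeds = seeds
  ), class = "mean_fixation_result")
}

#' Stochastic estimate of T_fix
#'
#' Ratio of the mean fixation time over replicates with recombination
#' (`r = params$r`) to that without (`r = 0`). The two arms use independent
#' child seeds derived from `seed`.
#'
#' @inheritParams mean_fixation_time
#' @return list of class `stoch_t_fix_result`: `t_fix`, `with_r` and
#'   `without_r` ([mean_fixation_time()] results), `r`.
#' @export
stochastic_t_fix <- function(landscape, params = stoch_params(), seed = 1,
                             n0 = NULL) {
  arm_seeds <- derive_seeds(seed, 2)
  params0 <- params
  params0$r <- 0
  with_r <- mean_fixation_time(landscape, params, seed = arm_seeds[1], n0 = n0)
  without_r <- mean_fixation_time(landscape, params0, seed = arm_seeds[2], n0 = n0)
  t_fix <- if (!is.na(with_r$mean) && !is.na(without_r$mean))
    with_r$mean / without_r$mean else NA_real_
  structure(list(t_fix = t_fix, with_r = with_r, without_r = without_r,
                 r = params$r),
            class = "stoch_t_fix_result")
}

#' @export
print.stoch_t_fix_result <- function(x, ...) {
  cat(sprintf("stochastic T_fix = %.4g (mean t[r=%g] = %.6g over %d, mean t[r=0] = %.6g over %d)\n",
              x$t_fix, x$r, x$with_r$mean, length(x$with_r$times),
              x$without_r$mean, length(x$without_r$times)))
  invisible(x)
}
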