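#' Parameters of the infinite-population dynamics
#'
#' Collects the rates and numerical controls of the mutation-selection-
#' recombination ODE model. Mutation occurs at rate `mu` per locus (forward
#' and backward rates equal). Recombination models bacterial transformation:
#' free single-allele DNA fragments, with pool allele frequencies equal to the
#' population's, are taken up and replace the homologous allele. Under the
#' default `"total"` rate convention `r` is the total per-genome uptake rate
#' and each locus is replaced at rate `r/L`; under `"per_locus"` each locus
#' is replaced at rate `r`.
#'
#' @param mu mutation rate per locus per unit time.
#' @param r recombination (DNA uptake) rate per unit time; see
#'   `rate_convention`.
#' @param fixation_threshold frequency of the fittest genotype that defines
#'   (near) fixation; default 0.99.
#' @param t_max integration horizon; reaching it without fixation is reported
#'   as a censored (non-fixed) result, not an error.
#' @param rate_convention `"total"` (default) or `"per_locus"`, see above.
#' @param fitness_scale `"malthusian"` (default): selection term
#'   `(m_i - mbar) x_i`, the model's own dynamics. `"fisherean"`: selection
#'   term `B (f_i - fbar) x_i` with `f = exp(m)`, the infinite-population
#'   mean-field limit of the stochastic simulator; used to check convergence
#'   of the finite-population model.
#' @param B birth/death rate scale; only used when
#'   `fitness_scale = "fisherean"`.
#' @param rtol,atol relative and absolute integrator tolerances.
#' @return list of class `dynamics_params`.
#' @export
dynamics_params <- function(mu = 1e-5, r = 0.05,
                            fixation_threshold = 0.99, t_max = 1e6,
                            rate_convention = c("total", "per_locus"),
                            fitness_scale = c("malthusian", "fisherean"),
                            B = 1, rtol = 1e-8, atol = 1e-12) {
  rate_convention <- match.arg(rate_convention)
  fitness_scale <- match.arg(fitness_scale)
  if (mu < 0) stop("mu must be >= 0", call. = FALSE)
  if (r < 0) stop("r must be >= 0", call. = FALSE)
  if (fixation_threshold <= 0 || fixation_threshold >= 1)
    stop("fixation_threshold must lie in (0, 1)", call. = FALSE)
  if (t_max <= 0) stop("t_max must be positive", call. = FALSE)
  structure(list(mu = mu, r = r, fixation_threshold = fixation_threshold,
                 t_max = t_max, rate_convention = rate_convention,
                 fitness_scale = fitness_scale, B = B,
                 rtol = rtol, atol = atol),
            class = "dynamics_params")
}

# per-locus replacement rate implied by the convention
per_locus_rate <- function(params, L) {
  if (params$rate_convention == "total") params$r / L else params$r
}

# selection weights on the chosen fitness scale
selection_weights <- function(landscape, params) {
  if (params$fitness_scale == "fisherean") params$B * exp(landscape$m)
  else landscape$m
}

#' Per-locus frequencies of the 1-allele
#'
#' The transformation model assumes allele frequencies in the free-DNA pool
#' equal those in the population, so these marginals drive the recombination
#' flux.
#'
#' @param x genotype frequency vector (length `2^L`).
#' @param space a [genotype_space()].
#' @return numeric vector `p` of length `L`; `p[l]` is the frequency of the
#'   1-allele at locus `l - 1` (bit `l - 1`).
#' @export
allele_frequencies <- function(x, space) {
  drop(crossprod(space$alleles, x))
}

#' Single-allele-replacement recombination indicator
#'
#' Equals 1 when replacing the allele of acceptor `i` at locus `l` by the
#' donor `d`'s allele at that locus yields recombinant `j` with `j != i`
#' (replacement by an identical allele is a no-op and is excluded); else 0.
#'
#' @param i,d,j 0-based genotype indices (acceptor, donor, product).
#' @param l 0-based locus (bit position).
#' @param L number of loci.
#' @return 0 or 1.
#' @export
recombination_indicator <- function(i, d, l, j, L) {
  if (l < 0 || l >= L) stop("locus out of range", call. = FALSE)
  mask <- bitwShiftL(1L, l)
  donor_allele <- bitwAnd(d, mask)
  product <- bitwOr(bitwAnd(i, bitwNot(mask)), donor_allele)
  as.integer(product == j && j != i)
}

# Closure computing the ODE right-hand side for a fixed landscape/params.
# dx_i/dt = mu * sum_{j in N(i)} x_j  -  mu * L * x_i
#         + (w_i - wbar) * x_i
#         + rho * sum_l [ x_flip(i,l) * p_l(a_il) - x_i * p_l(1 - a_il) ]
# with rho the per-locus uptake rate and p_l the pool allele frequencies.
make_rhs <- function(landscape, params) {
  space <- landscape$space
  L <- space$L
  n <- space$n
  nbr <- space$neighbors
  A <- space$alleles
  oneA <- 1 - A
  w <- selection_weights(landscape, params)
  mu <- params$mu
  rho <- per_locus_rate(params, L)
  function(t, x, parms) {
    xn <- matrix(x[nbr], n, L)
    dx <- mu * (rowSums(xn) - L * x) + (w - sum(w * x)) * x
    if (rho > 0) {
      p1 <- drop(crossprod(A, x))
      pm <- matrix(p1, n, L, byrow = TRUE)
      pmatch <- A * pm + oneA * (1 - pm)   # freq of i's own allele at each locus
      dx <- dx + rho * (rowSums(xn * pmatch) - x * rowSums(1 - pmatch))
    }
    list(dx)
  }
}

#' ODE right-hand side of the genotype-frequency dynamics
#'
#' Reference evaluation of the time derivative of the genotype frequency
#' vector under mutation, selection and transformation. The sum of the
#' returned vector is analytically zero (frequencies stay on the simplex).
#'
#' @param x genotype frequency vector (length `2^L`, summing to 1).
#' @param landscape a [build_landscape()] object.
#' @param params a [dynamics_params()] object.
#' @return numeric vector `dx/dt`.
#' @export
ode_rhs <- function(x, landscape, params = dynamics_params()) {
  if (length(x) != landscape$space$n)
    stop("x has the wrong length", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite frequencies", call. = FALSE)
  make_rhs(landscape, params)(0, x, NULL)[[1]]
}

default_x0 <- function(space) {
  x0 <- numeric(space$n)
  x0[space$origin] <- 1   # population starts monomorphic for the least fit genotype
  x0
}

#' Integrate the deterministic dynamics
#'
#' Solves the genotype-frequency ODE with a stiff-capable adaptive integrator
#' (`deSolve::lsoda`). States are defensively clipped at 0 and renormalized
#' only when the simplex drift exceeds `1e-8`; the number of such
#' interventions is recorded in the `renormalizations` attribute.
#'
#' @param landscape a [build_landscape()] object.
#' @param params a [dynamics_params()] object.
#' @param x0 initial frequency vector; default: all mass on the all-0
#'   genotype.
#' @param times output time grid; default 201 points over `[0, t_max]`.
#' @return data.frame with columns `time`, one frequency column per genotype
#'   (named by genotype string) and `mbar` (population mean Malthusian
#'   fitness).
#' @export
integrate_dynamics <- function(landscape, params = dynamics_params(),
                               x0 = NULL, times = NULL) {
  space <- landscape$space
  if (is.null(x0)) x0 <- default_x0(space)
  check_simplex(x0)
  if (is.null(times)) times <- seq(0, params$t_max, length.out = 201)
  sol <- deSolve::ode(y = x0, times = times, func = make_rhs(landscape, params),
                      parms = NULL, method = "lsoda",
                      rtol = params$rtol, atol = params$atol)
  xs <- unname(sol[, -1, drop = FALSE])
  renorm <- 0L
  for (i in seq_len(nrow(xs))) {
    row <- xs[i, ]
    if (any(row < 0)) row <- pmax(row, 0)
    if (abs(sum(row) - 1) > 1e-8) {
      row <- row / sum(row)
      renorm <- renorm + 1L
    }
    xs[i, ] <- row
  }
  out <- data.frame(time = sol[, 1], xs)
  names(out) <- c("time", space$genotypes)
  out$mbar <- as.numeric(xs %*% landscape$m)
  attr(out, "renormalizations") <- renorm
  out
}

check_simplex <- function(x0, tol = 1e-8) {
  if (any(x0 < -tol) || abs(sum(x0) - 1) > tol)
    stop("x0 must be a frequency vector on the simplex", call. = FALSE)
  invisible(TRUE)
}

# Integrate until g(x) = 0 (rootfun) or t_max; returns first-crossing time or
# NA. Root location uses lsodar's built-in event detection.
integrate_to_root <- function(landscape, params, x0, rootfun) {
  sol <- deSolve::lsodar(y = x0, times = c(0, params$t_max),
                         func = make_rhs(landscape, params), parms = NULL,
                         rootfunc = rootfun,
                         rtol = params$rtol, atol = params$atol)
  troot <- attr(sol, "troot")
  if (is.null(troot) || !length(troot)) NA_real_ else troot[1]
}

#' Time to (near) fixation of the fittest genotype
#'
#' First time at which the frequency of the all-1 genotype exceeds
#' `params$fixation_threshold`, located by the integrator's event detection.
#' A sufficiently high recombination rate can prevent fixation altogether (the
#' fittest genotype is broken down faster than selection assembles it), so
#' non-fixation by `t_max` is a first-class, flagged result.
#'
#' @inheritParams integrate_dynamics
#' @return list of class `fixation_result`: `time` (NA when censored),
#'   `fixed` (logical), `threshold`, `t_max`.
#' @export
fixation_time <- function(landscape, params = dynamics_params(), x0 = NULL) {
  space <- landscape$space
  if (is.null(x0)) x0 <- default_x0(space)
  check_simplex(x0)
  thr <- params$fixation_threshold
  peak <- space$peak
  if (x0[peak] > thr)
    return(structure(list(time = 0, fixed = TRUE, threshold = thr,
                          t_max = params$t_max), class = "fixation_result"))
  tr <- integrate_to_root(landscape, params, x0,
                          function(t, x, parms) x[peak] - thr)
  structure(list(time = tr, fixed = !is.na(tr), threshold = thr,
                 t_max = params$t_max),
            class = "fixation_result")
}

#' @export
print.fixation_result <- function(x, ...) {
  if (x$fixed)
    cat(sprintf("Fixation (threshold %.3g) at t = %.6g\n", x$threshold, x$time))
  else
    cat(sprintf("Not fixed by t_max = %.3g (threshold %.3g)\n", x$t_max, x$threshold))
  invisible(x)
}

#' Relative rate of adaptation with recombination, T_fix
#'
#' `T_fix` is the ratio of the fixation time of the fittest genotype in the
#' population with recombination (`r = params$r`) to that in the population
#' without recombination (`r = 0`). `T_fix > 1` means recombination
#' decelerates adaptation, `T_fix < 1` that it accelerates it.
#'
#' @inheritParams integrate_dynamics
#' @return list of class `t_fix_result`: `t_fix` (NA if either arm is
#'   censored), `time_with_r`, `time_without_r`, `fixed_with_r`,
#'   `fixed_without_r`, `r`.
#' @export
t_fix_ratio <- function(landscape, params = dynamics_params(), x0 = NULL) {
  params0 <- params
  params0$r <- 0
  with_r <- fixation_time(landscape, params, x0)
  without_r <- fixation_time(landscape, params0, x0)
  t_fix <- if (with_r$fixed && without_r$fixed) with_r$time / without_r$time else NA_real_
  structure(list(t_fix = t_fix,
                 time_with_r = with_r$time, time_without_r = without_r$time,
                 fixed_with_r = with_r$fixed, fixed_without_r = without_r$fixed,
                 r = params$r),
            class = "t_fix_result")
}

#' @export
print.t_fix_result <- function(x, ...) {
  cat(sprintf("T_fix = %.6g  (t[r=%g] = %.6g, t[r=0] = %.6g)\n",
              x$t_fix, x$r, x$time_with_r, x$time_without_r))
  invisible(x)
}

#' Pairwise linkage disequilibrium
#'
#' `D = f_11 - p_a * p_b`, where `f_11` is the joint frequency of 1-alleles at
#' loci `a` and `b` (marginalized over all other loci) and `p_a`, `p_b` the
#' marginal 1-allele frequencies. For `L = 2` this equals
#' `x_11 x_00 - x_10 x_01`.
#'
#' @param x genotype frequency vector.
#' @param space a [genotype_space()].
#' @param locus_a,locus_b distinct 0-based loci (bit positions).
#' @return numeric scalar `D`.
#' @export
pairwise_LD <- function(x, space, locus_a = 0, locus_b = 1) {
  if (locus_a == locus_b) stop("loci must differ", call. = FALSE)
  if (min(locus_a, locus_b) < 0 || max(locus_a, locus_b) >= space$L)
    stop("locus out of range", call. = FALSE)
  a <- space$alleles[, locus_a + 1L]
  b <- space$alleles[, locus_b + 1L]
  f11 <- sum(x[a == 1 & b == 1])
  f11 - sum(x[a == 1]) * sum(x[b == 1])
}

# mutation-free dynamics reduced to (x01, x10, x11); x00 = 1 - sum(y)
reduced_valley_rhs <- function(landscape, r) {
  params <- dynamics_params(mu = 0, r = r)
  rhs <- make_rhs(landscape, params)
  function(y) {
    x <- c(1 - sum(y), y)
    rhs(0, x, NULL)[[1]][-1]
  }
}

#' Critical recombination rate of a two-locus fitness valley
#'
#' For a two-locus landscape with a genuine fitness valley
#' (`m(01), m(10) < m(00) < m(11)`), there is a critical recombination rate
#' above which the fittest genotype can no longer invade a population fixed
#' for `00`: recombination with the resident breaks `11` down into the valley
#' genotypes faster than selection amplifies it. The rate is found from the
#' mutation-free dynamics linearized at the `00`-fixation fixed point: with
#' `method = "eigen"` by bisecting on the sign of the largest real part of the
#' numerically evaluated Jacobian's eigenvalues, with `method = "bisection"`
#' by bisecting on the long-time ODE outcome after a small `11` inoculum. On
#' the total-rate convention the result equals `m(11) - m(00)`.
#'
#' @param landscape a two-locus valley landscape.
#' @param method `"eigen"` (default) or `"bisection"`.
#' @param tol bisection tolerance on `r`.
#' @param inoculum initial `11` frequency for `method = "bisection"`.
#' @param t_assess integration horizon for `method = "bisection"`.
#' @return the critical rate `r_c` (scalar).
#' @export
critical_recombination_rate <- function(landscape,
                                        method = c("eigen", "bisection"),
                                        tol = 1e-6, inoculum = 3e-5,
                                        t_assess = NULL) {
  method <- match.arg(method)
  space <- landscape$space
  if (space$L != 2L) stop("defined for two-locus landscapes only", call. = FALSE)
  m <- landscape$m   # order: 00, 01, 10, 11
  if (!(m[2] < m[1] && m[3] < m[1] && m[1] < m[4]))
    stop("not a fitness valley: need m(01), m(10) < m(00) < m(11)", call. = FALSE)
  dm <- m[4] - m[1]
  lo <- 0
  hi <- 2 * dm + 0.1
  if (method == "eigen") {
    unstable <- function(r) {   # TRUE if 00-fixation is unstable (11 invades)
      f <- reduced_valley_rhs(landscape, r)
      J <- numeric_jacobian(f, numeric(3))
      max(Re(eigen(J, only.values = TRUE)$values)) > 0
    }
  } else {
    # The inoculum grows like exp((dm - r) t) near the fixed point, so the
    # grown-by-10x indicator misplaces the threshold by ~log(10)/t_assess;
    # the default horizon keeps that bias below 1e-5. The inoculum must be
    # small: the valley genotypes it spawns depress the mean fitness and
    # shift the invasion boundary by O(inoculum).
    if (is.null(t_assess)) t_assess <- 3e5
    unstable <- function(r) {
      params <- dynamics_params(mu = 0, r = r, t_max = t_assess)
      x0 <- c(1 - inoculum, 0, 0, inoculum)
      traj <- integrate_dynamics(landscape, params, x0 = x0,
                                 times = c(0, t_assess))
      traj[nrow(traj), "11"] > 10 * inoculum
    }
  }
  if (!unstable(lo)) stop("fixed point already stable at r = 0", call. = FALSE)
  if (unstable(hi)) stop("no stabilizing r found below search bound", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (unstable(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

numeric_jacobian <- function(f, y0, h = 1e-7) {
  n <- length(y0)
  f0 <- f(y0)
  J <- matrix(0, length(f0), n)
  for (j in seq_len(n)) {
    yp <- y0; yp[j] <- yp[j] + h
    ym <- y0; ym[j] <- ym[j] - h
    J[, j] <- (f(yp) - f(ym)) / (2 * h)
  }
  J
}

#' Time for the population mean fitness to reach a threshold
#'
#' First time at which the population mean Malthusian fitness exceeds
#' `threshold`; an alternative measure of the rate of adaptation that
#' correlates strongly with the fixation time.
#'
#' @inheritParams integrate_dynamics
#' @param threshold mean-fitness threshold (on the Malthusian scale).
#' @return list of class `fixation_result` (time, reached flag as `fixed`).
#' @export
time_to_mean_fitness <- function(landscape, params = dynamics_params(),
                                 threshold, x0 = NULL) {
  space <- landscape$space
  if (is.null(x0)) x0 <- default_x0(space)
  check_simplex(x0)
  m <- landscape$m
  if (sum(x0 * m) >= threshold)
    return(structure(list(time = 0, fixed = TRUE, threshold = threshold,
                          t_max = params$t_max), class = "fixation_result"))
  tr <- integrate_to_root(landscape, params, x0,
                          function(t, x, parms) sum(x * m) - threshold)
  structure(list(time = tr, fixed = !is.na(tr), threshold = threshold,
                 t_max = params$t_max),
            class = "fixation_result")
}
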