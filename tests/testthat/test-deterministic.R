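test_that("allele frequencies marginalize genotype frequencies", {
  gs <- genotype_space(2)
  x <- c(1, 0, 0, 0)                      # point mass on all-0
  expect_equal(allele_frequencies(x, gs), c(0, 0))
  x <- c(0, 0.5, 0.5, 0)                  # half on "10", half on "01"
  expect_equal(allele_frequencies(x, gs), c(0.5, 0.5))
  gs3 <- genotype_space(3)
  expect_equal(allele_frequencies(rep(1 / 8, 8), gs3), rep(0.5, 3))
})

test_that("recombination indicator encodes single-allele replacement", {
  # i=00, d=11, replacing locus 0 gives 01 (and not 10)
  expect_equal(recombination_indicator(0L, 3L, 0L, genotype_index("01"), 2), 1L)
  expect_equal(recombination_indicator(0L, 3L, 0L, genotype_index("10"), 2), 0L)
  # same-allele replacement is a no-op: indicator 0 for every j != i
  for (j in 1:3) expect_equal(recombination_indicator(0L, 0L, 0L, j, 2), 0L)
  for (j in 1:3) expect_equal(recombination_indicator(0L, 0L, 1L, j, 2), 0L)
  # most significant locus, four loci
  expect_equal(
    recombination_indicator(genotype_index("0110"), genotype_index("1111"),
                            3L, genotype_index("1110"), 4), 1L)
})

test_that("the right-hand side conserves total frequency on random states", {
  set.seed(101)
  landscapes <- list(two_locus_valley(), two_locus_single_lfg(),
                     build_landscape(3, 0.05, 1.1, fitness_topography(3, c("001", "110"))))
  params <- standard_params(r = 0.08)
  for (l in landscapes) {
    sums <- replicate(250, sum(ode_rhs(random_simplex(l$space$n), l, params)))
    expect_lt(max(abs(sums)), 1e-12)
  }
})

test_that("rhs terms isolate correctly", {
  l <- two_locus_valley()
  # point mass on the peak with mu = 0 is a fixed point for any r
  x_peak <- c(0, 0, 0, 1)
  expect_equal(ode_rhs(x_peak, l, dynamics_params(mu = 0, r = 0.3)),
               rep(0, 4))
  # mu = 0, r = 0: pure replicator dynamics
  set.seed(7)
  x <- random_simplex(4)
  dx <- ode_rhs(x, l, dynamics_params(mu = 0, r = 0))
  mbar <- sum(x * l$m)
  expect_equal(dx, (l$m - mbar) * x)
  # non-finite states are rejected
  expect_error(ode_rhs(c(NaN, 0, 0, 1), l, dynamics_params()), "non-finite")
})

test_that("rhs is equivariant under locus permutation", {
  set.seed(11)
  # swap the two loci of an asymmetric 3-locus topography: permuting the
  # state and topography together permutes the rhs identically
  perm_genotype <- function(g) {  # swap bits 0 and 2 of a 3-bit genotype
    b0 <- bitwAnd(g, 1L); b1 <- bitwAnd(bitwShiftR(g, 1L), 1L)
    b2 <- bitwAnd(bitwShiftR(g, 2L), 1L)
    b0 * 4L + b1 * 2L + b2
  }
  pg <- vapply(0:7, perm_genotype, integer(1))
  topo <- fitness_topography(3, c("001", "011"))
  topo_p <- fitness_topography(3, pg[topo$lfgs + 1L])
  l <- build_landscape(3, 0.05, 1, topo)
  lp <- build_landscape(3, 0.05, 1, topo_p)
  params <- standard_params(mu = 1e-4, r = 0.06)
  for (i in 1:20) {
    x <- random_simplex(8)
    dx <- ode_rhs(x, l, params)
    dxp <- ode_rhs(x[pg + 1L], lp, params)
    expect_equal(dxp, dx[pg + 1L], tolerance = 1e-12)
  }
})

test_that("rate conventions agree after rescaling", {
  l <- two_locus_single_lfg()
  set.seed(3)
  x <- random_simplex(4)
  dx_total <- ode_rhs(x, l, dynamics_params(mu = 1e-5, r = 0.1,
                                            rate_convention = "total"))
  dx_perloc <- ode_rhs(x, l, dynamics_params(mu = 1e-5, r = 0.05,
                                             rate_convention = "per_locus"))
  expect_equal(dx_total, dx_perloc, tolerance = 1e-14)
})

test_that("integration conserves frequencies and matches an Euler oracle", {
  l <- two_locus_smooth()
  params <- standard_params(r = 0)
  times <- seq(0, 300, by = 25)
  traj <- integrate_dynamics(l, params, times = times)
  sums <- rowSums(traj[, l$space$genotypes])
  expect_lt(max(abs(sums - 1)), 1e-8)

  # fine-grained explicit Euler cross-check of the peak frequency
  x <- c(1, 0, 0, 0)
  dt <- 0.005
  euler_peak <- numeric(length(times))
  rhs <- function(x) ode_rhs(x, l, params)
  ti <- 1
  for (step in 0:(300 / dt)) {
    t_now <- step * dt
    while (ti <= length(times) && times[ti] <= t_now + 1e-9) {
      euler_peak[ti] <- x[4]
      ti <- ti + 1
    }
    x <- x + dt * rhs(x)
  }
  expect_lt(max(abs(euler_peak - traj[["11"]])), 1e-3)
  # peak frequency is monotone increasing
  expect_true(all(diff(traj[["11"]]) > 0))
})

test_that("absorbing state without mutation stays constant", {
  l <- two_locus_valley()
  params <- dynamics_params(mu = 0, r = 0)
  traj <- integrate_dynamics(l, params, times = seq(0, 1000, 100))
  expect_true(all(abs(traj[["00"]] - 1) < 1e-10))
})

test_that("mutation-only dynamics approach the uniform distribution", {
  for (L in 2:3) {
    l <- build_landscape(L, 1e-9, 1)   # selection negligible
    params <- dynamics_params(mu = 0.01, r = 0, t_max = 1e4)
    traj <- integrate_dynamics(l, params, times = c(0, 5000))
    final <- unlist(traj[2, l$space$genotypes])
    expect_lt(max(abs(final - 1 / 2^L)), 1e-4)
  }
})

test_that("fixation time is deterministic and decreases with s", {
  l <- four_locus_smooth()
  params <- standard_params()
  t1 <- fixation_time(l, params)
  t2 <- fixation_time(l, params)
  expect_identical(t1$time, t2$time)
  expect_true(t1$fixed)

  times <- vapply(c(0.03, 0.05, 0.08, 0.12),
                  function(s) fixation_time(build_landscape(4, s, 1),
                                            standard_params(r = 0))$time,
                  numeric(1))
  expect_true(all(diff(times) < 0))
})

test_that("supercritical recombination prevents fixation in the valley", {
  l <- two_locus_valley()          # m(11) - m(00) = 0.1
  params <- standard_params(r = 0.12, t_max = 2e4)
  res <- fixation_time(l, params)
  expect_false(res$fixed)
  expect_true(is.na(res$time))
  # flagged, not an error, and T_fix propagates the censoring
  tf <- t_fix_ratio(l, params)
  expect_true(is.na(tf$t_fix))
  expect_false(tf$fixed_with_r)
  expect_true(tf$fixed_without_r)
})

test_that("T_fix reflects epistasis sign and LFG deceleration", {
  # no LFG, additive: recombination has no effect
  tf0 <- t_fix_ratio(four_locus_smooth(), standard_params())
  expect_equal(tf0$t_fix, 1, tolerance = 1e-3)
  # a single LFG decelerates
  tf1 <- t_fix_ratio(two_locus_single_lfg(), standard_params())
  expect_gt(tf1$t_fix, 1)
  # eps < 1 (positive epistasis: fitness declines sub-linearly in k, a
  # synergistic action of beneficial mutations): recombination decelerates
  tf_pos <- t_fix_ratio(four_locus_smooth(eps = 0.95), standard_params())
  expect_gt(tf_pos$t_fix, 1)
  # eps > 1 (negative epistasis, antagonistic beneficial mutations):
  # recombination accelerates
  tf_neg <- t_fix_ratio(four_locus_smooth(eps = 1.05), standard_params())
  expect_lt(tf_neg$t_fix, 1)
})

test_that("pairwise LD matches closed forms", {
  gs <- genotype_space(2)
  expect_equal(pairwise_LD(c(0.25, 0.25, 0.25, 0.25), gs), 0)
  expect_equal(pairwise_LD(c(0.5, 0, 0, 0.5), gs), 0.25)
  expect_equal(pairwise_LD(c(0, 0.5, 0.5, 0), gs), -0.25)
  # product state at L = 3 has zero LD for every locus pair
  gs3 <- genotype_space(3)
  p <- c(0.3, 0.6, 0.8)
  x <- apply(gs3$alleles, 1, function(a) prod(ifelse(a == 1, p, 1 - p)))
  for (a in 0:1) for (b in (a + 1):2)
    expect_equal(pairwise_LD(x, gs3, a, b), 0, tolerance = 1e-12)
  expect_error(pairwise_LD(c(0.5, 0, 0, 0.5), gs, 1, 1), "differ")
})

test_that("critical recombination rate equals the extreme fitness difference", {
  l <- two_locus_valley(s = 0.05)
  rc <- critical_recombination_rate(l)
  expect_equal(rc, 0.1, tolerance = 1e-4)
  # the contract r_c = m(11) - m(00) holds for eps != 1 too (at L = 2 the
  # exponent moves the all-0 extreme, k = 2, not the LFG-overridden middle)
  l2 <- two_locus_valley(s = 0.05, eps = 1.4)
  expect_equal(critical_recombination_rate(l2), l2$m[4] - l2$m[1],
               tolerance = 1e-4)
  expect_error(critical_recombination_rate(two_locus_smooth()), "valley")
  expect_error(critical_recombination_rate(four_locus_smooth()), "two-locus")
})

test_that("mean-fitness threshold time behaves like a fixation clock", {
  l <- two_locus_single_lfg()
  params <- standard_params()
  # threshold at or below the initial mean fitness is reached immediately
  res0 <- time_to_mean_fitness(l, params, threshold = 0.5)
  expect_equal(res0$time, 0)
  # monotone in the threshold
  ts <- vapply(c(0.95, 0.97, 0.99),
               function(th) time_to_mean_fitness(l, params, th)$time, numeric(1))
  expect_true(all(diff(ts) > 0))
})

test_that("mean-fitness time rank-correlates with fixation time over topographies", {
  set.seed(5)
  topos <- sample_topographies(4, 4, 12, seed = 21)
  params <- standard_params()
  space <- genotype_space(4)
  tfix <- numeric(length(topos))
  tmean <- numeric(length(topos))
  for (i in seq_along(topos)) {
    l <- build_landscape(space, 0.05, 1, topos[[i]])
    tfix[i] <- fixation_time(l, params)$time
    tmean[i] <- time_to_mean_fitness(l, params, threshold = 0.99)$time
  }
  expect_gt(cor(tfix, tmean, method = "spearman"), 0.9)
})
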