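test_that("Fisherean conversion is the exponential map", {
  expect_equal(fisher_fitness(0), 1)    # an LFG is born at the baseline rate
  expect_equal(fisher_fitness(1), exp(1))
  m <- c(0, 0.3, 0.85, 1)
  expect_equal(order(fisher_fitness(m)), order(m))
})

test_that("event rates match the model's closed forms", {
  l <- two_locus_valley()
  params <- stoch_params(N0 = 1000, mu = 1e-4, r = 0.05)

  # monomorphic all-0 population
  n <- c(1000, 0, 0, 0)
  er <- event_rates(n, l, params)
  mut <- er[er$kind == "mutation" & er$genotype == 0, ]
  expect_equal(mut$rate, rep(1e-4 * 1000, 2))
  expect_equal(sum(er$rate[er$kind == "recombination"]), 0)

  # N = N0, monomorphic at an LFG (m = 0): births balance deaths at B * N
  n <- c(0, 1000, 0, 0)
  er <- event_rates(n, l, params)
  expect_equal(sum(er$rate[er$kind == "birth"]), params$B * 1000)
  expect_equal(sum(er$rate[er$kind == "death"]), params$B * 1000)

  # recombination to flip(i, l) is zero when locus l is monomorphic
  n <- c(500, 0, 0, 500)   # both genotypes share no allele, all loci polymorphic
  er <- event_rates(n, l, params)
  rec <- er[er$kind == "recombination" & er$rate > 0, ]
  expect_equal(nrow(rec), 4)           # every (resident genotype, locus) pair
  n <- c(0, 500, 0, 500)               # locus 0 monomorphic for allele 1
  er <- event_rates(n, l, params)
  rec0 <- er[er$kind == "recombination" & er$locus == 0, ]
  expect_equal(sum(rec0$rate), 0)
})

test_that("monomorphic populations without mutation or recombination are closed", {
  l <- two_locus_valley()
  params <- stoch_params(N0 = 400, mu = 0, r = 0, t_max = 30,
                         tau_leap_threshold = Inf)
  res <- simulate_population(l, params, seed = 5)
  expect_false(res$fixed)
  expect_equal(sum(res$n_final[2:4]), 0)
})

test_that("identical seeds reproduce identical event sequences", {
  l <- two_locus_single_lfg()
  params <- stoch_params(N0 = 300, mu = 1e-3, r = 0.05, t_max = 500,
                         tau_leap_threshold = Inf)
  a <- simulate_population(l, params, seed = 42,
                           snapshot_times = seq(0, 100, 5))
  b <- simulate_population(l, params, seed = 42,
                           snapshot_times = seq(0, 100, 5))
  expect_identical(a$t_fix, b$t_fix)
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$n_steps, b$n_steps)
})

test_that("a neutral population is regulated around N0", {
  # monomorphic at an LFG (f = 1): quasi-equilibrium population size is N0
  l <- two_locus_valley()
  params <- stoch_params(N0 = 1000, mu = 0, r = 0, t_max = 100,
                         tau_leap_threshold = Inf)
  n0 <- c(0, 1000, 0, 0)
  res <- simulate_population(l, params, n0 = n0, seed = 8,
                             snapshot_times = seq(1, 100, 1),
                             stop_at_fixation = FALSE)
  Ns <- rowSums(res$snapshots)
  expect_lt(abs(mean(Ns) - 1000), 100)   # within 10% of N0
  expect_true(all(Ns > 700 & Ns < 1300))
})

test_that("scaling all rates together only rescales the clock", {
  l <- two_locus_single_lfg()
  base <- stoch_params(N0 = 200, B = 1, mu = 1e-3, r = 0.05, t_max = 1e4,
                       tau_leap_threshold = Inf)
  fast <- stoch_params(N0 = 200, B = 2, mu = 2e-3, r = 0.10, t_max = 1e4,
                       tau_leap_threshold = Inf)
  a <- simulate_population(l, base, seed = 31)
  b <- simulate_population(l, fast, seed = 31)
  expect_true(a$fixed && b$fixed)
  # same seed, uniformly doubled rates: the same event sequence, twice as fast
  expect_equal(b$t_fix, a$t_fix / 2, tolerance = 1e-9)
  expect_identical(a$n_steps, b$n_steps)
})

test_that("tau-leaping reproduces the SSA fixation-time distribution", {
  l <- two_locus_single_lfg()
  n_rep <- 40
  run_arm <- function(tau_threshold, seed0) {
    params <- stoch_params(N0 = 500, mu = 1e-3, r = 0.05, t_max = 5e3,
                           tau_leap_threshold = tau_threshold)
    vapply(seq_len(n_rep), function(i)
      simulate_population(l, params, seed = seed0 + i)$t_fix, numeric(1))
  }
  exact <- run_arm(Inf, 7000)
  leap <- run_arm(50, 8000)
  expect_false(any(is.na(exact)) || any(is.na(leap)))
  ks <- suppressWarnings(stats::ks.test(exact, leap))
  expect_gt(ks$p.value, 0.01)
})

test_that("mean fixation time reports censoring and degenerate cases honestly", {
  l <- two_locus_single_lfg()
  params <- stoch_params(N0 = 200, mu = 1e-3, r = 0.05, n_reps = 1, t_max = 5e3,
                         tau_leap_threshold = Inf)
  one <- mean_fixation_time(l, params, seed = 3)
  expect_length(one$times, 1)
  expect_equal(one$mean, one$times[1])
  expect_true(is.na(one$sd))

  # an impossible horizon censors every replicate, flagged not averaged
  params$t_max <- 1e-3
  params$n_reps <- 4
  cens <- mean_fixation_time(l, params, seed = 3)
  expect_true(is.na(cens$mean))
  expect_equal(cens$n_censored, 4)
})

test_that("block means are consistent with the 1/sqrt(n) error law", {
  l <- two_locus_single_lfg()
  params <- stoch_params(N0 = 200, mu = 1e-3, r = 0, n_reps = 160, t_max = 5e3,
                         tau_leap_threshold = 50)
  res <- mean_fixation_time(l, params, seed = 17)
  expect_length(res$times, 160)
  blocks <- matrix(res$times, nrow = 10)     # 16 blocks of 10 replicates
  sem_blocks <- stats::sd(colMeans(blocks))
  sem_pred <- res$sd / sqrt(10)
  expect_gt(sem_blocks / sem_pred, 0.5)
  expect_lt(sem_blocks / sem_pred, 2)
})

test_that("identical arms give a T_fix ratio near one", {
  l <- two_locus_single_lfg()
  params <- stoch_params(N0 = 500, mu = 1e-3, r = 0, n_reps = 20, t_max = 5e3,
                         tau_leap_threshold = 50)
  res <- stochastic_t_fix(l, params, seed = 4)
  expect_lt(abs(res$t_fix - 1), 0.15)
})

test_that("extinction is an explicit outcome", {
  # a tiny neutral population (f = 1) is a critical branching process: it
  # dies out almost surely
  l <- two_locus_valley()
  params <- stoch_params(N0 = 3, mu = 0, r = 0, t_max = 1e5,
                         tau_leap_threshold = Inf)
  n0 <- c(0, 3, 0, 0)
  res <- simulate_population(l, params, n0 = n0, seed = 12)
  expect_true(res$extinct)
  expect_false(res$fixed)
})
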