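test_that("fixation probability: limits, printed values, monotonicity", {
  # neutral limit 1/(2 Ne)
  expect_equal(fixation_probability(1, 1, 1e5), 1 / (2e5))
  expect_equal(fixation_probability(0.3, 0.3 + 1e-14, 7), 1 / 14)
  # direct evaluation: s = 0.01, Ne = 1e5 -> 1 - exp(-0.02) (denominator ~ 1)
  expect_equal(fixation_probability(1, 1.01, 1e5), -expm1(-0.02),
               tolerance = 1e-12)
  expect_equal(fixation_probability(1, 1.01, 1e5), 0.019801, tolerance = 1e-4)
  # strongly deleterious: underflows to 0 rather than overflowing
  expect_identical(fixation_probability(1, 0.99, 1e5), 0)
  expect_lt(fixation_probability(1, 0.999, 1e4), 1e-15)

  # monotone increasing in s over a wide grid; bounded in (0, 1)
  s_grid <- c(-0.5, -0.1, -0.01, -1e-4, -1e-8, 0, 1e-8, 1e-4, 0.01, 0.1, 0.5)
  p <- vapply(s_grid, function(s) fixation_probability(1, 1 + s, 1e5), 1.0)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p >= 0 & p < 1))
  # continuity at s = 0
  eps <- 1e-9
  expect_equal(fixation_probability(1, 1 + eps, 1e5), 1 / 2e5,
               tolerance = 1e-3)
  expect_equal(fixation_probability(1, 1 - eps, 1e5), 1 / 2e5,
               tolerance = 1e-3)
  expect_error(fixation_probability(1, 1, 0.5), "Ne")
})

test_that("random walk with zero rates or constant fitness behaves as theory", {
  g <- two_protein_genome()
  zero <- mutation_rates(0, 0, 0, 0, 0, 0, 0, 0)
  const_fit <- function(gn) list(fitness = 0.5)
  traj <- random_walk_evolve(g, const_fit, zero,
                             cfg = random_walk_config(max_attempts = 50,
                                                      target_fitness = 1),
                             seed = 1)
  expect_identical(nrow(traj$log), 50L)
  expect_true(all(traj$log$w_mut == 0.5))
  expect_identical(traj$genome$bits, g$bits)   # accepted children unchanged

  # constant fitness: acceptance probability alpha/(2 Ne) per attempt
  rates <- mutation_rates(point_rate = 0.01)
  cfg <- random_walk_config(Ne = 1e3, alpha = 100, target_fitness = 1,
                            max_attempts = 2000)
  traj <- random_walk_evolve(g, const_fit, rates, cfg = cfg, seed = 7)
  k <- sum(traj$log$accepted)
  p <- 100 / 2e3
  bounds <- qbinom(c(0.005, 0.995), 2000, p)   # 99% binomial interval
  expect_gte(k, bounds[1])
  expect_lte(k, bounds[2])
})

test_that("random walk is deterministic given a seed and escapes w = 0", {
  g <- two_protein_genome()
  rates <- mutation_rates(point_rate = 0.02)
  # fitness = fraction of ones: any positive mutant is accepted from w = 0
  frac_fit <- function(gn) list(fitness = mean(gn$bits == 1))
  zero_then <- function(gn) list(fitness = 0)
  cfg <- random_walk_config(Ne = 1e5, alpha = 1e4, target_fitness = 2,
                            max_attempts = 60)
  # huge relative fitness gains make alpha * P_fix exceed 1: the driver
  # clips the acceptance probability and warns once
  expect_warning(
    t1 <- random_walk_evolve(g, frac_fit, rates, cfg = cfg, seed = 3),
    "clipping")
  t2 <- suppressWarnings(
    random_walk_evolve(g, frac_fit, rates, cfg = cfg, seed = 3))
  expect_identical(t1$log, t2$log)
  expect_identical(t1$genome$bits, t2$genome$bits)

  empty <- genome(rep(0L, 200))
  t3 <- suppressWarnings(
    random_walk_evolve(empty, frac_fit, rates, cfg = cfg, seed = 4))
  first_nonzero <- which(t3$log$w_mut > 0)[1]
  expect_true(t3$log$accepted[first_nonzero])   # w = 0 resident accepts it
})

test_that("target fitness stops the walk early", {
  g <- two_protein_genome()
  rates <- mutation_rates(point_rate = 0.01)
  fit <- function(gn) list(fitness = mean(gn$bits == 1))
  cfg <- random_walk_config(target_fitness = mean(g$bits == 1) - 0.01,
                            max_attempts = 100)
  traj <- random_walk_evolve(g, fit, rates, cfg = cfg, seed = 1)
  expect_identical(nrow(traj$log), 0L)   # already above target
})

test_that("roulette selection reproduces Wright-Fisher expected frequencies", {
  # p = (0.5, 0.5), w = (1, 3): expected next-generation share (0.25, 0.75)
  g <- list(genome(rep(0L, 8)), genome(rep(1L, 8)))
  set.seed(11)
  idx <- roulette_select(g, c(1, 3), N = 10000)
  obs <- mean(idx == 2)
  se99 <- qnorm(0.995) * sqrt(0.75 * 0.25 / 10000)
  expect_gt(obs, 0.75 - se99)
  expect_lt(obs, 0.75 + se99)

  # equal fitness: frequencies unchanged in expectation
  idx <- roulette_select(g, c(2, 2), N = 10000)
  expect_equal(mean(idx == 1), 0.5, tolerance = 0.02)

  # single positive-fitness genotype sweeps immediately
  idx <- roulette_select(list(g[[1]], g[[2]], g[[1]]), c(0, 0.7, 0), N = 50)
  expect_true(all(idx == 2L))

  expect_warning(roulette_select(g, c(0, 0), N = 10), "uniform")
})

test_that("population evolution fixes the fitter genotype at Eq.-2 rates", {
  # two-genotype toy: fitness keyed on a marker bit; no mutation, selection
  # only, so frequencies follow the Wright-Fisher update exactly
  g0 <- genome(rep(0L, 10)); g1 <- genome(rep(1L, 10))
  fit <- function(gn) list(fitness = if (gn$bits[1] == 1) 0.9 else 0.3)

  # independent one-generation oracle: p' = p w1 / (p w1 + (1-p) w0)
  wf_expected <- function(p) p * 0.9 / (p * 0.9 + (1 - p) * 0.3)

  set.seed(21)
  N <- 400
  pop <- c(replicate(N / 2, g1, simplify = FALSE),
           replicate(N / 2, g0, simplify = FALSE))
  fits <- vapply(pop, function(gn) fit(gn)$fitness, 1.0)
  p_obs <- numeric(6); p_exp <- numeric(6); p <- 0.5
  for (gen in 1:6) {
    idx <- roulette_select(pop, fits)
    pop <- pop[idx]; fits <- fits[idx]
    p_exp[gen] <- wf_expected(p)
    p_obs[gen] <- mean(vapply(pop, function(gn) gn$bits[1] == 1L, TRUE))
    p <- p_obs[gen]
  }
  # each generation's observed share lies within 4 binomial SDs of Eq. 2
  for (gen in 1:6) {
    sd <- sqrt(p_exp[gen] * (1 - p_exp[gen]) / N)
    expect_lt(abs(p_obs[gen] - p_exp[gen]), 4 * sd + 1e-9)
  }
  expect_gt(p_obs[6], 0.95)   # strong selection: near fixation in 6 gens

  # full driver: G = 0 returns the homogeneous initial population
  traj <- population_evolve(g1, fit, mutation_rates(0, 0, 0, 0, 0, 0, 0, 0),
                            cfg = population_config(N = 10, generations = 0),
                            seed = 2)
  expect_length(traj$population, 10)
  expect_identical(traj$log$generation, 0L)
  expect_identical(traj$fitness, 0.9)

  # determinism of the full driver
  rates <- mutation_rates(point_rate = 0.01)
  t1 <- population_evolve(g1, fit, rates,
                          cfg = population_config(N = 12, generations = 5,
                                                  mutation_prob = 0.5),
                          seed = 9)
  t2 <- population_evolve(g1, fit, rates,
                          cfg = population_config(N = 12, generations = 5,
                                                  mutation_prob = 0.5),
                          seed = 9)
  expect_identical(t1$log, t2$log)
  expect_identical(lapply(t1$population, function(x) x$bits),
                   lapply(t2$population, function(x) x$bits))
})
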