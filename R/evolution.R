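#' Kimura fixation probability
#'
#' Probability that a new mutant with fitness `w_mut`, arising in a
#' population of effective size `Ne` whose resident has fitness `w_res`,
#' eventually fixes:
#' `P_fix = (1 - exp(-2 s)) / (1 - exp(-4 Ne s))` with selection coefficient
#' `s = (w_mut - w_res) / w_res`. The neutral limit `s -> 0` is the analytic
#' `1 / (2 Ne)`; strongly deleterious mutants are evaluated in log space to
#' avoid overflow (the result underflows to 0).
#'
#' @param w_res Resident fitness (> 0; the zero-fitness resident is handled
#'   by the random-walk driver, not here).
#' @param w_mut Mutant fitness (>= 0).
#' @param Ne Effective population size (>= 1).
#' @return Fixation probability in \[0, 1); strictly increasing in `s`.
#' @export
fixation_probability <- function(w_res, w_mut, Ne) {
  if (Ne < 1) stop("Ne must be >= 1")
  if (w_res <= 0) stop("resident fitness must be positive")
  s <- (w_mut - w_res) / w_res
  if (abs(s) < 1e-12) return(1 / (2 * Ne))
  if (s > 0) {
    # denominator 1 - exp(-4 Ne s) -> 1 rapidly
    num <- -expm1(-2 * s)
    den <- -expm1(-4 * Ne * s)
    return(num / den)
  }
  # s < 0: P = expm1(2|s|) / expm1(4 Ne |s|), computed in log space
  a <- 2 * abs(s)
  b <- 4 * Ne * abs(s)
  log_num <- if (a > 700) a else log(expm1(a))
  log_den <- if (b > 700) b else log(expm1(b))
  exp(log_num - log_den)
}

#' Random-walk configuration
#'
#' Settings for evolution as a biased random walk in genotype space: a
#' single resident genotype generates one mutant at a time, which fixes with
#' probability `alpha * P_fix` ([fixation_probability()]). `alpha` speeds up
#' the simulation and must keep `alpha * P_fix < 1`; values that exceed 1
#' are clipped with a warning.
#'
#' @param Ne Effective population size (default 1e5; prokaryote-scale values
#'   run from 1e5 to 1e8).
#' @param alpha Acceptance speed-up coefficient.
#' @param target_fitness Stop once the resident reaches this fitness.
#' @param max_attempts Stop after this many attempted mutations.
#' @export
random_walk_config <- function(Ne = 1e5, alpha = 1e4, target_fitness = 0.8,
                               max_attempts = 1000L) {
  stopifnot(Ne >= 1, alpha > 0, max_attempts >= 0)
  structure(list(Ne = Ne, alpha = alpha, target_fitness = target_fitness,
                 max_attempts = as.integer(max_attempts)),
            class = "random_walk_config")
}

#' Evolve a genome by a fixation-probability random walk
#'
#' Repeatedly mutates the resident genome ([mutate_genome()]), scores the
#' mutant with `fitness_fn`, and accepts it with probability
#' `alpha * P_fix(w, w', Ne)`. Two special cases: a zero-fitness resident
#' accepts any mutant with positive fitness outright (the selection
#' coefficient is undefined at w = 0), and two zero-fitness genotypes are
#' treated as neutral (`s = 0`). The walk stops at the target fitness or
#' when the attempt budget is exhausted.
#'
#' @param seed_genome Starting [genome()].
#' @param fitness_fn Function `genome -> fitness_report` (or any list with a
#'   `$fitness` element); must be total (score failures as 0).
#' @param rates A [mutation_rates()].
#' @param mask A [protection_mask()]; re-anchored to the accepted child
#'   after every fixation.
#' @param cfg A [random_walk_config()].
#' @param seed Optional integer seed for the whole run.
#' @return An `evolution_trajectory`: a `log` data.frame (one row per
#'   attempt: fitness of the mutant, acceptance, resident fitness after the
#'   attempt), the final `genome`, final `mask`, and the accepted genomes.
#' @export
random_walk_evolve <- function(seed_genome, fitness_fn,
                               rates = mutation_rates(),
                               mask = protection_mask(),
                               cfg = random_walk_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  resident <- seed_genome
  rep0 <- fitness_fn(resident)
  w <- rep0$fitness
  log_rows <- list()
  accepted <- list()
  alpha_clipped <- FALSE
  attempt <- 0L
  while (attempt < cfg$max_attempts && w < cfg$target_fitness) {
    attempt <- attempt + 1L
    mut <- mutate_genome(resident, rates, mask)
    rep1 <- fitness_fn(mut$genome)
    w1 <- rep1$fitness
    p_acc <- if (w <= 0) {
      if (w1 > 0) 1 else cfg$alpha / (2 * cfg$Ne)     # s = 0 when both 0
    } else {
      cfg$alpha * fixation_probability(w, w1, cfg$Ne)
    }
    if (p_acc >= 1 && !(w <= 0 && w1 > 0)) {
      if (!alpha_clipped) {
        warning("alpha * P_fix >= 1; clipping acceptance probability to 1")
        alpha_clipped <- TRUE
      }
      p_acc <- 1
    }
    acc <- stats::runif(1) < p_acc
    if (acc) {
      resident <- mut$genome
      mask <- mut$mask
      w <- w1
      accepted[[length(accepted) + 1L]] <- list(attempt = attempt,
                                                genome = resident,
                                                report = rep1)
    }
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      attempt = attempt, w_mut = w1, accepted = acc, w_resident = w,
      S_amp = rep1$S_amp %||% NA_real_, S_ult = rep1$S_ult %||% NA_real_,
      S_com = rep1$S_com %||% NA_real_)
  }
  structure(list(
    log = if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(attempt = integer(0), w_mut = numeric(0),
                 accepted = logical(0), w_resident = numeric(0),
                 S_amp = numeric(0), S_ult = numeric(0), S_com = numeric(0)),
    genome = resident, fitness = w, initial_fitness = rep0$fitness,
    accepted = accepted, mask = mask, config = cfg
  ), class = "evolution_trajectory")
}

#' @export
print.evolution_trajectory <- function(x, ...) {
  cat("<evolution_trajectory> ", nrow(x$log), " attempts, ",
      sum(x$log$accepted), " accepted, fitness ",
      format(x$initial_fitness, digits = 4), " -> ",
      format(x$fitness, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Population configuration
#'
#' @param N Population size (>= 2).
#' @param generations Number of discrete generations.
#' @param mutation_prob Per-individual probability of undergoing a
#'   [mutate_genome()] step at reproduction.
#' @param hgt_rate Per-individual horizontal gene transfer probability
#'   (donor drawn uniformly from the rest of the population).
#' @export
population_config <- function(N = 50L, generations = 20L, mutation_prob = 0.5,
                              hgt_rate = 0) {
  stopifnot(N >= 2, generations >= 0, mutation_prob >= 0, mutation_prob <= 1)
  structure(list(N = as.integer(N), generations = as.integer(generations),
                 mutation_prob = mutation_prob, hgt_rate = hgt_rate),
            class = "population_config")
}

#' Fitness-proportional (roulette) selection of the next generation
#'
#' Samples `N` individuals with replacement with probabilities
#' `p_i w_i / sum(p_j w_j)` -- the expected next-generation frequencies of a
#' Wright-Fisher population -- by drawing uniforms against the cumulative
#' weight vector. If every fitness is 0, sampling is uniform (with a
#' warning).
#'
#' @param genomes List of [genome()] objects.
#' @param fitnesses Numeric vector of the same length (>= 0).
#' @param N Number of individuals to draw (default: `length(genomes)`).
#' @return Integer vector of selected indices.
#' @export
roulette_select <- function(genomes, fitnesses, N = length(genomes)) {
  stopifnot(length(genomes) == length(fitnesses), all(fitnesses >= 0))
  if (sum(fitnesses) <= 0) {
    warning("all fitnesses are zero; sampling uniformly")
    fitnesses <- rep(1, length(fitnesses))
  }
  cum <- cumsum(fitnesses)
  r <- stats::runif(N, 0, cum[length(cum)])
  findInterval(r, cum) + 1L
}

#' Evolve a fixed-size population (Wright-Fisher with mutation and HGT)
#'
#' Starts from a homogeneous population of `N` copies of the seed. Each
#' generation: every individual reproduces and, with probability
#' `mutation_prob`, its offspring is mutated (plus optional HGT from a
#' random donor); mutants are rescored; then `N` survivors are drawn by
#' [roulette_select()].
#'
#' @inheritParams random_walk_evolve
#' @param cfg A [population_config()].
#' @return An `evolution_trajectory` with per-generation best/mean fitness,
#'   the final population and its fitnesses.
#' @export
population_evolve <- function(seed_genome, fitness_fn,
                              rates = mutation_rates(),
                              mask = protection_mask(),
                              cfg = population_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- replicate(cfg$N, seed_genome, simplify = FALSE)
  w0 <- fitness_fn(seed_genome)$fitness
  fit <- rep(w0, cfg$N)
  gen_log <- list(data.frame(generation = 0L, best = max(fit),
                             mean = mean(fit)))
  for (gen in seq_len(cfg$generations)) {
    # reproduction with mutation
    for (i in seq_len(cfg$N)) {
      if (stats::runif(1) < cfg$mutation_prob) {
        child <- mutate_genome(pop[[i]], rates, mask)$genome
        if (cfg$hgt_rate > 0 && cfg$N > 1) {
          donor <- sample(setdiff(seq_len(cfg$N), i), 1)
          child <- horizontal_transfer(pop[[donor]], child,
                                       cfg$hgt_rate, mask)$genome
        }
        pop[[i]] <- child
        fit[i] <- fitness_fn(child)$fitness
      }
    }
    # selection
    idx <- roulette_select(pop, fit)
    pop <- pop[idx]
    fit <- fit[idx]
    gen_log[[length(gen_log) + 1L]] <- data.frame(
      generation = gen, best = max(fit), mean = mean(fit))
  }
  structure(list(
    log = do.call(rbind, gen_log), population = pop, fitnesses = fit,
    genome = pop[[which.max(fit)]], fitness = max(fit),
    initial_fitness = w0, config = cfg
  ), class = "evolution_trajectory")
}

#' Write a trajectory log as CSV
#' @param traj An `evolution_trajectory`.
#' @param path Output path.
#' @export
write_trajectory_log <- function(traj, path) {
  utils::write.csv(traj$log, path, row.names = FALSE)
  invisible(path)
}
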