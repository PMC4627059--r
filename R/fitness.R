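#' Fitness weights
#'
#' Nonnegative exponents weighting the amplitude, ultrasensitivity and
#' complexity sub-scores in the combined fitness (their sum must be
#' positive).
#'
#' @param w_amp,w_ult,w_com Nonnegative weights.
#' @export
fitness_weights <- function(w_amp = 1, w_ult = 1, w_com = 0.1) {
  if (w_amp < 0 || w_ult < 0 || w_com < 0 || w_amp + w_ult + w_com <= 0) {
    stop("weights must be nonnegative with a positive sum")
  }
  list(w_amp = w_amp, w_ult = w_ult, w_com = w_com)
}

#' Amplitude and ultrasensitivity scores from a staircase response
#'
#' The staircase gives three up and three down transitions in the output
#' steady states; per direction, with transition magnitudes
#' `D1, D2, D3` (`D2` the middle step):
#' * amplitude `A = D2 / y_max` -- how much of the available output range
#'   the middle step moves;
#' * ultrasensitivity `U' = max(0, (3 U - 1) / 2)` with
#'   `U = D2 / (D1 + D2 + D3)` -- the middle step's share of the total
#'   response, rescaled so a linear response (equal steps) scores 0 and a
#'   pure middle-step switch scores 1. A flat direction (zero total) scores
#'   0.
#'
#' `S_amp` and `S_ult` are the means over the up and down directions,
#' clipped to \[0, 1\]. Non-converged phases score 0.
#'
#' @param result A `sim_result` from a staircase [run_protocol()].
#' @param y_max Output scale (> 0); typically the total concentration of the
#'   output protein.
#' @return List with `S_amp`, `S_ult` and the per-transition `delta_y`.
#' @export
score_ultrasensitivity <- function(result, y_max) {
  stopifnot(y_max > 0)
  ph <- result$phases
  k <- (nrow(ph) + 1) / 2
  if (result$protocol$kind != "staircase" || k != 4) {
    stop("score_ultrasensitivity needs a 4-level staircase result")
  }
  if (!all(ph$converged)) {
    return(list(S_amp = 0, S_ult = 0, delta_y = rep(NA_real_, 6)))
  }
  dy <- abs(diff(ph$y))
  clip01 <- function(x) min(max(x, 0), 1)
  dir_scores <- function(d) {
    A <- d[2] / y_max
    tot <- sum(d)
    U <- if (tot > 0) d[2] / tot else 0
    c(A = clip01(A), U = clip01(max(0, (3 * U - 1) / 2)))
  }
  up <- dir_scores(dy[1:3])
  down <- dir_scores(dy[4:6])
  list(S_amp = mean(c(up["A"], down["A"])),
       S_ult = mean(c(up["U"], down["U"])),
       delta_y = dy)
}

#' Network complexity score
#'
#' Counts the structural elements of a network -- proteins, domains,
#' reactive sites and interaction rules -- and maps the total C onto (0, 1\]
#' as `S_com = exp(-C / C0)`, strictly decreasing in C.
#'
#' @param net A `reaction_network`.
#' @param C0 Complexity scale (> 0).
#' @return List with `S_com` and the raw count `C`.
#' @export
score_complexity <- function(net, C0 = 100) {
  stopifnot(C0 > 0)
  C <- with(net$counts, n_proteins + n_domains + n_sites + n_rules)
  list(S_com = exp(-C / C0), C = C)
}

#' Combined fitness: weighted geometric mean of sub-scores
#'
#' `F = (S_amp^w_a * S_ult^w_u * S_com^w_c)^(1 / (w_a + w_u + w_c))`.
#' F lies between the smallest and largest positively weighted sub-score,
#' and is 0 whenever any positively weighted sub-score is 0.
#'
#' @param S_amp,S_ult,S_com Sub-scores (>= 0).
#' @param weights A [fitness_weights()] list.
#' @return Fitness in \[0, 1\] for sub-scores in \[0, 1\].
#' @export
combine_fitness <- function(S_amp, S_ult, S_com, weights = fitness_weights()) {
  w <- c(weights$w_amp, weights$w_ult, weights$w_com)
  s <- c(S_amp, S_ult, S_com)
  if (any(s < 0)) stop("sub-scores must be nonnegative")
  if (any(s == 0 & w > 0)) return(0)
  exp(sum(w * log(pmax(s, .Machine$double.xmin))) / sum(w))
}

#' Adaptation scores from a step response
#'
#' For each step direction (up and down), with `O_pre` the steady output
#' just before the step:
#' * peak deviation `dO_max = max_t |O(t) - O_pre|` over the phase;
#' * residual deviation `dO_ss = |O_final - O_pre|`;
#' * sensitivity `= dO_max / (O_pre + dO_max)` in \[0, 1);
#' * precision `= 1 - dO_ss / dO_max` (0 if there is no response).
#'
#' The adaptation fitness is the geometric mean of
#' `sensitivity * precision` over the two directions: it rewards networks
#' that respond strongly to a persistent input change and then return to
#' their pre-stimulus output. Non-converged phases score 0.
#'
#' @param result A `sim_result` from a step [run_protocol()].
#' @return List with per-direction terms and `F_adapt`.
#' @export
score_adaptation <- function(result) {
  if (result$protocol$kind != "step") {
    stop("score_adaptation needs a step-protocol result")
  }
  ph <- result$phases
  if (!all(ph$converged)) {
    return(list(F_adapt = 0, up = NULL, down = NULL))
  }
  dir_term <- function(phase_idx, O_pre) {
    out <- result$output[[phase_idx]]
    dO_max <- max(abs(out$y - O_pre))
    dO_ss <- abs(out$y[nrow(out)] - O_pre)
    sens <- dO_max / (O_pre + dO_max)
    prec <- if (dO_max > 0) 1 - dO_ss / dO_max else 0
    list(dO_max = dO_max, dO_ss = dO_ss, sensitivity = sens,
         precision = prec, term = sens * prec)
  }
  up <- dir_term(2, ph$y[1])
  down <- dir_term(3, ph$y[2])
  list(F_adapt = sqrt(up$term * down$term), up = up, down = down)
}

# total concentration of a protein in the initial state (output scale)
protein_total <- function(net, protein) {
  sum(net$conservation[protein, ] * net$x0)
}

#' Score a genome end to end
#'
#' The full genotype-to-fitness map: parse and decode the genome, compile
#' the reaction network, run the stimulus protocol and score it. Any
#' failure along the way (no proteins, state-space blow-up, missing output
#' msite, solver failure, non-convergence) yields fitness 0 -- broken
#' mutants are non-viable, never an error.
#'
#' @param g A [genome()].
#' @param config An `evosig_config`; `protocol`, `scoring`, `simulation`,
#'   `compiler` and `scaling` sections are used.
#' @param objective `"ultrasensitivity"` (staircase protocol, combined
#'   amplitude/ultrasensitivity/complexity fitness) or `"adaptation"` (step
#'   protocol, sensitivity-precision fitness; the complexity weight is
#'   applied the same way, with S_amp and S_ult replaced by the adaptation
#'   term per direction).
#' @return A `fitness_report` list: `fitness` plus sub-scores and
#'   diagnostics; `fitness` is 0 with a `reason` when the genome is not
#'   viable.
#' @export
score_genome <- function(g, config = default_config(),
                         objective = c("ultrasensitivity", "adaptation")) {
  objective <- match.arg(objective)
  fail <- function(reason) {
    structure(list(fitness = 0, S_amp = 0, S_ult = 0, S_com = NA_real_,
                   viable = FALSE, reason = reason, objective = objective),
              class = "fitness_report")
  }
  out <- tryCatch({
    parsed <- parse_genome(g)
    proteins <- decode_proteins(parsed, config)
    ip <- config$protocol$input_protein
    op <- config$protocol$output_protein
    if (length(proteins) < max(ip, op)) return(fail("missing input/output protein"))
    net <- compile_network(proteins, config)
    if (is.na(first_msite(net, op))) return(fail("output protein has no msite"))
    solver <- config_solver(config)
    levels <- config$protocol$levels
    w <- fitness_weights(config$scoring$w_amp, config$scoring$w_ult,
                         config$scoring$w_com)
    com <- score_complexity(net, config$scoring$complexity_scale)
    if (objective == "ultrasensitivity") {
      prot <- stimulus_protocol(ip, "staircase", levels)
      res <- run_protocol(net, prot, solver, output_protein = op)
      y_max <- config$scoring$y_max
      if (is.na(y_max)) y_max <- protein_total(net, op)
      if (y_max <= 0) return(fail("output protein absent from initial state"))
      us <- score_ultrasensitivity(res, y_max)
      fitness <- combine_fitness(us$S_amp, us$S_ult, com$S_com, w)
      structure(list(fitness = fitness, S_amp = us$S_amp, S_ult = us$S_ult,
                     S_com = com$S_com, C = com$C, delta_y = us$delta_y,
                     phases = res$phases, viable = TRUE, reason = "ok",
                     objective = objective),
                class = "fitness_report")
    } else {
      step <- config$protocol$step_levels %||% levels[c(1, length(levels))]
      prot <- stimulus_protocol(ip, "step", step)
      res <- run_protocol(net, prot, solver, output_protein = op)
      ad <- score_adaptation(res)
      # complexity enters as in the combined fitness, with the two
      # direction terms in place of amplitude/ultrasensitivity
      up_t <- if (is.null(ad$up)) 0 else ad$up$term
      down_t <- if (is.null(ad$down)) 0 else ad$down$term
      fitness <- combine_fitness(up_t, down_t, com$S_com, w)
      structure(list(fitness = fitness, F_adapt = ad$F_adapt,
                     up = ad$up, down = ad$down,
                     S_com = com$S_com, C = com$C, phases = res$phases,
                     viable = TRUE, reason = "ok", objective = objective),
                class = "fitness_report")
    }
  }, error = function(e) fail(conditionMessage(e)))
  out
}

#' @export
print.fitness_report <- function(x, ...) {
  cat("<fitness_report> objective=", x$objective,
      " fitness=", format(x$fitness, digits = 4), sep = "")
  if (!x$viable) cat("  [non-viable: ", x$reason, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Write a fitness report to JSON
#' @param report A `fitness_report`.
#' @param path Output path.
#' @export
write_fitness_report <- function(report, path) {
  r <- unclass(report)
  r$phases <- if (!is.null(r$phases)) as.list(r$phases)
  jsonlite::write_json(r, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
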