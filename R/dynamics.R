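#' Mass-action ODE right-hand side for a reaction network
#'
#' Builds `dx/dt = S v(x)`: the stoichiometry matrix (dense for small
#' systems, sparse beyond a size cutoff) times the
#' mass-action flux vector, where each reaction's flux is its rate constant
#' times the product of its reactant concentrations (so a symmetric
#' `2 X -> X2` binding carries flux `k [X]^2`). Evaluation is deterministic
#' and side-effect free.
#'
#' @param net A `reaction_network`.
#' @return A list with `rhs(t, x, parms)` (in the form deSolve expects),
#'   the stoichiometry matrix `S` and the rate vector `k`.
#' @export
build_odes <- function(net) {
  rx <- net$reactions
  n <- length(net$species)
  m <- nrow(rx)
  if (m == 0) {
    return(list(rhs = function(t, x, parms) list(rep(0, length(x))),
                S = Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                         x = numeric(0), dims = c(n, 0)),
                k = numeric(0)))
  }
  ii <- c(rx$r1, rx$r2[!is.na(rx$r2)], rx$p1, rx$p2[!is.na(rx$p2)])
  jj <- c(seq_len(m), which(!is.na(rx$r2)), seq_len(m), which(!is.na(rx$p2)))
  vv <- c(rep(-1, m), rep(-1, sum(!is.na(rx$r2))),
          rep(1, m), rep(1, sum(!is.na(rx$p2))))
  # a plain dense matrix is much faster per evaluation for the small systems
  # the compiler produces; switch to a sparse form above a size cutoff
  S <- if (as.numeric(n) * m <= 250000) {
    dd <- matrix(0, n, m)
    for (t in seq_along(ii)) dd[ii[t], jj[t]] <- dd[ii[t], jj[t]] + vv[t]
    dd
  } else {
    Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, m))
  }
  i1 <- rx$r1
  i2 <- rx$r2
  has2 <- !is.na(i2)
  k <- rx$rate
  rhs <- function(t, x, parms) {
    v <- k * x[i1]
    v[has2] <- v[has2] * x[i2[has2]]
    list(as.vector(S %*% v))
  }
  list(rhs = rhs, S = S, k = k,
       staging = list(r1 = as.integer(i1),
                      r2 = as.integer(ifelse(is.na(i2), 0L, i2)),
                      rate = as.numeric(k),
                      si = as.integer(ii), sj = as.integer(jj),
                      sv = as.numeric(vv), n_sp = as.integer(n)))
}

#' Solver configuration
#'
#' @param rtol,atol Relative/absolute integration tolerances (atol in uM).
#' @param ss_tol Steady-state criterion: converged when
#'   `max_i |dx_i/dt| / (atol + |x_i|) < ss_tol`.
#' @param t_max Maximum integration time per phase (s).
#' @param max_steps Solver step budget per output interval; a phase that
#'   exhausts it is reported as non-converged (an explicit simulation
#'   effort cap, so one pathologically stiff mutant cannot stall an
#'   evolution run).
#' @return A `solver_config` list.
#' @export
solver_config <- function(rtol = 1e-6, atol = 1e-9, ss_tol = 1e-6,
                          t_max = 1e5, max_steps = 5000) {
  stopifnot(rtol > 0, atol > 0, ss_tol > 0, t_max >= 0, max_steps >= 1)
  structure(list(rtol = rtol, atol = atol, ss_tol = ss_tol, t_max = t_max,
                 max_steps = max_steps),
            class = "solver_config")
}

config_solver <- function(config) {
  s <- config$simulation
  solver_config(s$rtol, s$atol, s$ss_tol, s$t_max,
                s$max_steps %||% 5000)
}

#' Integrate a network to steady state
#'
#' Integrates the mass-action ODEs with a stiff solver (lsoda) in doubling
#' time chunks until the normalized derivative criterion of
#' [solver_config()] is met or `t_max` is exhausted. Solver failures are
#' reported through the convergence flag, not as errors, so that broken
#' mutant networks can be scored as non-viable.
#'
#' @param net A `reaction_network` (or a prebuilt [build_odes()] list via
#'   `odes`).
#' @param x0 Initial state (defaults to the network's initial
#'   concentrations).
#' @param solver A [solver_config()].
#' @param odes Optional prebuilt ODE system.
#' @return List: final `state`, `converged` flag, elapsed `time`, and a
#'   `trajectory` data.frame with columns `time` and the species.
#' @export
simulate_to_steady_state <- function(net, x0 = net$x0,
                                     solver = solver_config(),
                                     odes = NULL) {
  if (is.null(odes)) odes <- build_odes(net)
  x <- as.numeric(x0)
  deriv_crit <- function(x) {
    dx <- odes$rhs(0, x, NULL)[[1]]
    max(abs(dx) / (solver$atol + abs(x)))
  }
  mk_traj <- function(times, states) {
    out <- data.frame(times, states)
    names(out) <- c("time", names(x0) %||% paste0("x", seq_along(x)))
    out
  }
  if (length(odes$k) == 0 || deriv_crit(x) < solver$ss_tol ||
      solver$t_max <= 0) {
    converged <- length(odes$k) == 0 || deriv_crit(x) < solver$ss_tol
    names(x) <- names(x0)
    return(list(state = x, converged = converged, time = 0,
                trajectory = mk_traj(0, t(x))))
  }
  # one solver call per phase: integrate on a log-spaced time grid and stop
  # at the root of the normalized-derivative criterion
  times <- unique(c(0, 10^seq(-1, log10(solver$t_max), length.out = 40)))
  out <- if (!is.null(odes$staging) && is.loaded("evosig_derivs")) {
    # compiled mass-action kernel: stage the network, then integrate with
    # the C derivative and steady-state root functions
    st <- odes$staging
    .Call("evosig_set_network", st$r1, st$r2, st$rate, st$si, st$sj, st$sv,
          st$n_sp, as.numeric(solver$atol), as.numeric(solver$ss_tol),
          PACKAGE = "evosig")
    tryCatch(
      deSolve::lsodar(y = x, times = times, func = "evosig_derivs",
                      rootfunc = "evosig_root", nroot = 1,
                      dllname = "evosig", initfunc = NULL, parms = NULL,
                      rtol = solver$rtol, atol = solver$atol,
                      maxsteps = solver$max_steps),
      error = function(e) NULL, warning = function(w) NULL)
  } else {
    rootfun <- function(t, x, parms) deriv_crit(x) - solver$ss_tol
    tryCatch(
      deSolve::lsodar(y = x, times = times, func = odes$rhs,
                      rootfunc = rootfun, rtol = solver$rtol,
                      atol = solver$atol, maxsteps = solver$max_steps),
      error = function(e) NULL, warning = function(w) NULL)
  }
  if (is.null(out) || nrow(out) < 1 || anyNA(out[nrow(out), ])) {
    names(x) <- names(x0)
    return(list(state = x, converged = FALSE, time = 0,
                trajectory = mk_traj(0, t(x))))
  }
  x <- as.numeric(out[nrow(out), -1])
  t_acc <- out[nrow(out), 1]
  names(x) <- names(x0)
  root_found <- length(attr(out, "troot")) > 0
  list(state = x, converged = root_found || deriv_crit(x) < solver$ss_tol,
       time = t_acc,
       trajectory = mk_traj(out[, 1], out[, -1, drop = FALSE]))
}

#' Stimulus protocols
#'
#' A protocol drives the total concentration of one input protein (the
#' ligand) through an ordered series of levels, letting the system relax to
#' steady state at each level.
#' * `"staircase"`: the levels are traversed up and then mirrored back down
#'   (`l1, l2, ..., lk, l(k-1), ..., l1`), giving three up and three down
#'   transitions for the default four levels; used for ultrasensitivity
#'   scoring.
#' * `"step"`: baseline, up-step, back to baseline (`l1, l2, l1`); used for
#'   adaptation scoring.
#'
#' @param target Input protein index.
#' @param kind `"staircase"` or `"step"`.
#' @param levels Increasing positive total input concentrations (uM);
#'   a staircase needs >= 4 distinct levels, a step exactly 2.
#' @return A `stimulus_protocol`.
#' @export
stimulus_protocol <- function(target, kind = c("staircase", "step"), levels) {
  kind <- match.arg(kind)
  if (any(levels <= 0)) stop("levels must be positive")
  if (kind == "staircase" && length(unique(levels)) < 4) {
    stop("a staircase needs at least 4 distinct levels")
  }
  if (kind == "step" && length(levels) != 2) {
    stop("a step protocol takes exactly 2 levels (baseline, step)")
  }
  phases <- if (kind == "staircase") {
    c(levels, rev(levels)[-1])
  } else {
    c(levels[1], levels[2], levels[1])
  }
  structure(list(target = target, kind = kind, levels = levels,
                 phases = phases), class = "stimulus_protocol")
}

# Set the input protein's conservation total to `level` by rescaling its
# free (monomeric) forms. If the target lies below the currently bound
# amount, free forms drop to 0, bound complexes are scaled down
# proportionally and their partner content is released back to monomers in
# the state they held inside the complex, so other proteins stay conserved.
clamp_input <- function(net, x, protein, level) {
  cons <- net$conservation[protein, ]
  is_free <- vapply(net$complexes, function(cx)
    length(cx$insts) == 1L && cx$insts[[1]]$p == protein, TRUE)
  free_tot <- sum(x[is_free])
  bound_tot <- sum(cons * x) - free_tot
  if (level >= bound_tot) {
    want <- level - bound_tot
    if (free_tot > 0) {
      x[is_free] <- x[is_free] * want / free_tot
    } else {
      ref <- which(is_free & cons == 1 &
                     vapply(net$complexes, function(cx)
                       length(cx$insts) == 1L &&
                         all(cx$insts[[1]]$conf == 0L) &&
                         all(cx$insts[[1]]$mod == 0L), TRUE))
      if (length(ref) == 0) ref <- which(is_free)[1]
      x[ref[1]] <- want
    }
  } else {
    x[is_free] <- 0
    f <- level / bound_tot
    for (k in which(cons > 0 & !is_free)) {
      removed <- x[k] * (1 - f)
      if (removed <= 0) next
      x[k] <- x[k] * f
      for (inst in net$complexes[[k]]$insts) {
        if (inst$p == protein) next
        mono <- canon_complex(list(insts = list(inst), bonds = list()))$key
        idx <- match(mono, net$species)
        if (!is.na(idx)) x[idx] <- x[idx] + removed
      }
    }
  }
  x
}

#' Run a stimulus protocol
#'
#' At each phase boundary the input protein's total is clamped to the new
#' level (see the package vignette for the clamping contract), then the
#' system is integrated to steady state. The output observable `y` is the
#' total concentration of output-protein copies whose first modification
#' site is modified ([output_weights()]).
#'
#' @param net A `reaction_network`.
#' @param protocol A [stimulus_protocol()].
#' @param solver A [solver_config()].
#' @param output_protein Output protein index (default from the network's
#'   configuration).
#' @return A `sim_result`: per-phase steady states, convergence flags,
#'   output values, output time courses and conservation drift.
#' @export
run_protocol <- function(net, protocol, solver = solver_config(),
                         output_protein = net$config$protocol$output_protein) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  if (protocol$target > length(net$proteins)) {
    stop("input protein index outside the network")
  }
  odes <- build_odes(net)
  w <- output_weights(net, output_protein)
  x <- net$x0
  phases <- protocol$phases
  res <- vector("list", length(phases))
  for (ph in seq_along(phases)) {
    x <- clamp_input(net, x, protocol$target, phases[ph])
    x_start <- x
    sim <- simulate_to_steady_state(net, x, solver, odes = odes)
    x <- sim$state
    totals_start <- as.vector(net$conservation %*% x_start)
    totals_end <- as.vector(net$conservation %*% x)
    drift <- max(abs(totals_end - totals_start) /
                   pmax(abs(totals_start), solver$atol))
    y_traj <- as.numeric(as.matrix(sim$trajectory[, -1, drop = FALSE]) %*% w)
    res[[ph]] <- list(
      level = phases[ph], converged = sim$converged, state = x,
      y = sum(w * x), drift = drift,
      output = data.frame(time = sim$trajectory$time, y = y_traj))
  }
  structure(list(
    phases = data.frame(
      level = phases,
      converged = vapply(res, function(r) r$converged, TRUE),
      y = vapply(res, function(r) r$y, 1.0),
      drift = vapply(res, function(r) r$drift, 1.0)),
    states = do.call(rbind, lapply(res, function(r) r$state)),
    output = lapply(res, function(r) r$output),
    protocol = protocol, output_protein = output_protein,
    output_weights = w
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat("<sim_result> ", nrow(x$phases), " phases (",
      x$protocol$kind, ")\n", sep = "")
  print(x$phases)
  invisible(x)
}

#' Write a simulated trajectory to CSV
#'
#' Concatenates the per-phase output time courses with a phase column.
#' @param result A `sim_result`.
#' @param path CSV path.
#' @export
write_trajectory <- function(result, path) {
  rows <- do.call(rbind, lapply(seq_along(result$output), function(i) {
    cbind(phase = i, result$output[[i]])
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
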