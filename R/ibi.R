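#' Configuration for the iterative Boltzmann inversion loop
#'
#' @param temperature Temperature in K (default 300, the simulation
#'   temperature the potentials are meant for).
#' @param max_iterations Maximum number of inversion iterations.
#' @param tol Convergence threshold on the Hellinger distance between the
#'   sampled and target distributions.
#' @param floor Probability floor for the potential-of-mean-force
#'   difference; see `floor_mode`.  With a histogram sampler, set it near the
#'   histogram's statistical resolution (a few expected counts per bin).
#' @param lambda Update damping in (0, 1\]; 1 applies the full fitted
#'   increment each iteration.
#' @param floor_mode Floor handling for [delta_v_surface()]: `"mask"`
#'   (default) or `"clamp"` (recommended with stochastic samplers and
#'   sharply concentrated targets).
#' @param max_step Trust cap (kJ/mol) on the largest per-term coefficient
#'   increment applied in one iteration; larger fitted increments are scaled
#'   down proportionally.  Guards against occasional ill-conditioned fits of
#'   pure sampling noise near convergence.  The cap never activates in the
#'   noise-free in-span setting, where one-step increments stay within a few
#'   kJ/mol.
#' @param weighting Loss weights for the Fourier fit: `"uniform"` (default),
#'   `"sampled"` (the sampled probabilities -- inverse-variance weighting for
#'   log-histogram noise) or `"both"` (sampled plus target, which keeps the
#'   target's support in the loss and is the stable choice together with
#'   `floor_mode = "clamp"` for concentrated out-of-span targets).
#' @param n_phi_terms,n_psi_terms Fourier terms per angle (default 5).
#' @param phases `"fixed"` (cosine-only terms) or `"free"` (cosine and sine,
#'   required for targets without phi -> -phi symmetry).
#' @param grid Working [angle_grid()].
#' @param seed Base seed; iteration i samples with seed `seed + i`.
#' @return Object of class `ibi_config`.
#' @export
ibi_config <- function(temperature = 300, max_iterations = 20, tol = 0.01,
                       floor = 1e-8, lambda = 1,
                       floor_mode = c("mask", "clamp"),
                       max_step = 20,
                       weighting = c("uniform", "sampled", "both"),
                       n_phi_terms = 5, n_psi_terms = 5,
                       phases = c("fixed", "free"),
                       grid = angle_grid(), seed = 1) {
  phases <- match.arg(phases)
  floor_mode <- match.arg(floor_mode)
  weighting <- match.arg(weighting)
  stopifnot(temperature > 0, max_iterations >= 0, tol > 0, floor > 0)
  if (!is.numeric(lambda) || lambda <= 0 || lambda > 1) {
    stop("'lambda' must lie in (0, 1]")
  }
  structure(list(temperature = temperature, max_iterations = max_iterations,
                 tol = tol, floor = floor, lambda = lambda,
                 floor_mode = floor_mode, max_step = max_step,
                 weighting = weighting,
                 n_phi_terms = n_phi_terms, n_psi_terms = n_psi_terms,
                 phases = phases, grid = grid, seed = seed),
            class = "ibi_config")
}

#' Potential-of-mean-force difference between two distributions
#'
#' Delta V(phi, psi) = kB T log( P_sampled / P_target ) per bin: positive
#' where the sampler over-populates relative to the target, so adding the
#' surface to the potential suppresses exactly those regions.  Bins where
#' either probability falls below `floor` are masked (NA).
#'
#' @param P_target,P_sampled [rama_distribution()]s on the same grid.
#' @param temperature Temperature in K.
#' @param floor Probability floor.
#' @param floor_mode `"mask"` drops every bin where either probability falls
#'   below the floor (the unbiased default).  `"clamp"` substitutes the
#'   floor for sub-floor probabilities and keeps a bin whenever *either*
#'   distribution is above it, masking only bins empty in both; this keeps a
#'   bounded repulsive signal on regions a stochastic sampler populates but
#'   the target excludes, which stabilizes inversion against concentrated
#'   targets.
#' @return List with `delta_v` (matrix, kJ/mol, NA where masked) and `mask`
#'   (logical matrix of valid bins).
#' @export
delta_v_surface <- function(P_target, P_sampled, temperature = 300,
                            floor = 1e-8, floor_mode = c("mask", "clamp")) {
  floor_mode <- match.arg(floor_mode)
  stopifnot(inherits(P_target, "rama_distribution"),
            inherits(P_sampled, "rama_distribution"))
  if (!grids_identical(P_target$grid, P_sampled$grid)) {
    stop("target and sampled distributions are on different grids")
  }
  kT <- KB_KJ_MOL_K * temperature
  if (floor_mode == "mask") {
    mask <- P_target$p >= floor & P_sampled$p >= floor
    if (!any(mask)) stop("all bins fall below the probability floor")
    dv <- matrix(NA_real_, nrow(P_target$p), ncol(P_target$p))
    dv[mask] <- kT * log(P_sampled$p[mask] / P_target$p[mask])
  } else {
    mask <- P_target$p >= floor | P_sampled$p >= floor
    if (!any(mask)) stop("all bins fall below the probability floor")
    dv <- matrix(NA_real_, nrow(P_target$p), ncol(P_target$p))
    dv[mask] <- kT * log(pmax(P_sampled$p[mask], floor) /
                           pmax(P_target$p[mask], floor))
  }
  list(delta_v = dv, mask = mask)
}

#' Exact Boltzmann sampler (noise-free surrogate)
#'
#' Satisfies the sampler contract `function(pot, temperature, seed)` by
#' returning the exact Boltzmann distribution of the potential on the grid;
#' the seed is ignored.  Useful as a deterministic stand-in for molecular
#' dynamics when the modeled system is a single (phi, psi) pair.
#'
#' @param pot A [fourier_potential()].
#' @param temperature Temperature in K.
#' @param seed Ignored (kept for contract compatibility).
#' @param grid An [angle_grid()].
#' @return A [rama_distribution()].
#' @export
exact_boltzmann_sampler <- function(pot, temperature = 300, seed = NULL,
                                    grid = angle_grid()) {
  boltzmann_distribution(pot, temperature, grid)
}

#' Metropolis Monte Carlo sampler on a dihedral potential
#'
#' Random walk on (phi, psi) with uniform step proposals of half-width
#' `step_size` degrees per axis, periodic wrapping, and Metropolis acceptance
#' min(1, exp(-dV / kB T)).  The histogram of visited states (including
#' rejection repeats) is returned.  Deterministic for a given seed.
#'
#' @param pot A [fourier_potential()].
#' @param temperature Temperature in K.
#' @param n_steps Number of Monte Carlo steps, >= 1.
#' @param step_size Proposal half-width in degrees (default 60, which keeps
#'   acceptance near 0.3-0.6 for potentials of a few kB T).
#' @param seed Integer random seed.
#' @param grid An [angle_grid()].
#' @return A [rama_distribution()] with `meta = "histogram"`.
#' @export
metropolis_sampler <- function(pot, temperature = 300, n_steps = 1e6,
                               step_size = 60, seed = 1,
                               grid = angle_grid()) {
  stopifnot(inherits(pot, "fourier_potential"))
  if (!is.numeric(n_steps) || n_steps < 1) stop("'n_steps' must be >= 1")
  n_steps <- as.integer(n_steps)
  set.seed(seed)
  kT <- KB_KJ_MOL_K * temperature
  np <- seq_along(pot$k_phi); ns <- seq_along(pot$k_psi)
  kp <- pot$k_phi; ks <- pot$k_psi
  gp <- pot$gamma_phi * pi / 180; gs <- pot$gamma_psi * pi / 180
  step <- step_size * pi / 180
  vphi <- function(t) sum(kp * (1 + cos(np * t - gp)))
  vpsi <- function(t) sum(ks * (1 + cos(ns * t - gs)))
  u <- stats::runif(n_steps)
  dphi <- stats::runif(n_steps, -step, step)
  dpsi <- stats::runif(n_steps, -step, step)
  phi <- 0; psi <- 0
  v_phi <- vphi(phi); v_psi <- vpsi(psi)
  nb <- grid$n_phi
  bw <- grid$bin_width * pi / 180
  counts <- integer(grid$n_phi * grid$n_psi)
  rejects <- 0L
  for (i in seq_len(n_steps)) {
    p2 <- phi + dphi[i]
    if (p2 > pi) p2 <- p2 - 2 * pi else if (p2 <= -pi) p2 <- p2 + 2 * pi
    s2 <- psi + dpsi[i]
    if (s2 > pi) s2 <- s2 - 2 * pi else if (s2 <= -pi) s2 <- s2 + 2 * pi
    v_p2 <- vphi(p2); v_s2 <- vpsi(s2)
    dv <- (v_p2 + v_s2) - (v_phi + v_psi)
    if (dv <= 0 || u[i] < exp(-dv / kT)) {
      phi <- p2; psi <- s2; v_phi <- v_p2; v_psi <- v_s2
      rejects <- 0L
    } else {
      rejects <- rejects + 1L
      if (rejects >= 10000L) {
        stop("10000 consecutive Metropolis rejections; try a smaller step_size")
      }
    }
    ip <- floor((phi + pi) / bw); is <- floor((psi + pi) / bw)
    if (ip >= nb) ip <- 0L
    if (is >= nb) is <- 0L
    counts[is * nb + ip + 1L] <- counts[is * nb + ip + 1L] + 1L
  }
  rama_distribution(matrix(counts, nb, nb), grid, meta = "histogram")
}

#' Build a Metropolis sampler satisfying the sampler contract
#'
#' @param n_steps,step_size,grid Passed through to [metropolis_sampler()].
#' @return A `function(pot, temperature, seed)` returning a
#'   [rama_distribution()].
#' @export
make_metropolis_sampler <- function(n_steps = 1e6, step_size = 60,
                                    grid = angle_grid()) {
  function(pot, temperature, seed) {
    metropolis_sampler(pot, temperature, n_steps, step_size, seed, grid)
  }
}

## scale an increment so no per-term coefficient exceeds the trust cap
trust_scale <- function(fit_pot, max_step) {
  biggest <- max(abs(c(fit_pot$k_phi, fit_pot$k_psi)), 0)
  if (is.finite(max_step) && biggest > max_step) max_step / biggest else 1
}

ibi_fit_weights <- function(cfg, sampled, target) {
  switch(cfg$weighting,
         uniform = NULL,
         sampled = sampled$p,
         both = sampled$p + target$p)
}

new_ibi_state <- function(iteration, potential, sampled, hellinger,
                          fit_residual = NA_real_) {
  structure(list(iteration = iteration, potential = potential,
                 sampled = sampled, hellinger = hellinger,
                 fit_residual = fit_residual),
            class = "ibi_state")
}

#' One iteration of iterative Boltzmann inversion
#'
#' Runs the sampler with the current potential, forms the
#' potential-of-mean-force difference to the target, fits the Fourier
#' increment on the unmasked bins, and applies the damped update
#' k(i+1) = k(i) + lambda * dk.
#'
#' @param state An `ibi_state` (as from [run_ibi()] history) holding the
#'   current potential, or a [fourier_potential()] for iteration 0.
#' @param target Target [rama_distribution()].
#' @param sampler A sampler contract `function(pot, temperature, seed)`.
#' @param cfg An [ibi_config()].
#' @return A new `ibi_state` with the updated potential, the distribution
#'   sampled from the *current* potential, its Hellinger distance to the
#'   target and the fit residual RMS.
#' @export
ibi_step <- function(state, target, sampler, cfg = ibi_config()) {
  if (inherits(state, "fourier_potential")) {
    state <- new_ibi_state(-1L, state, NULL, NA_real_)
  }
  stopifnot(inherits(state, "ibi_state"))
  i <- state$iteration + 1L
  pot <- state$potential
  sampled <- tryCatch(
    sampler(pot, cfg$temperature, cfg$seed + i),
    error = function(e) {
      stop(sprintf("sampler failed at iteration %d: %s", i, conditionMessage(e)))
    })
  h <- hellinger_distance(sampled, target)
  dv <- delta_v_surface(target, sampled, cfg$temperature, cfg$floor,
                        cfg$floor_mode)
  fit <- fit_fourier_to_surface(dv$delta_v, cfg$grid,
                                cfg$n_phi_terms, cfg$n_psi_terms,
                                cfg$phases, dv$mask,
                                ibi_fit_weights(cfg, sampled, target))
  newpot <- add_potentials(pot, fit$potential,
                           cfg$lambda * trust_scale(fit$potential, cfg$max_step))
  new_ibi_state(i, newpot, sampled, h, fit$residual_rms)
}

#' Run the iterative Boltzmann inversion loop
#'
#' Starting from `initial` (the zero potential by default), repeatedly
#' samples with the current potential, inverts the probability ratio to the
#' target, fits the separable Fourier increment and updates the parameters,
#' until the sampled distribution is within `cfg$tol` Hellinger distance of
#' the target or `cfg$max_iterations` is reached.  Non-convergence is
#' reported in the returned object, not raised as an error.
#'
#' @param target Target [rama_distribution()].
#' @param sampler Sampler contract `function(pot, temperature, seed)`;
#'   see [exact_boltzmann_sampler()] and [make_metropolis_sampler()].
#' @param cfg An [ibi_config()].
#' @param initial Starting [fourier_potential()]; zero potential if NULL.
#' @param start_iteration First iteration index (used to resume an
#'   interrupted run: iteration seeds are `cfg$seed + i`, so a resumed run
#'   reproduces the uninterrupted one).
#' @param on_iteration Optional `function(state)` called after each
#'   iteration is recorded (e.g. to checkpoint files).
#' @return Object of class `ibi_result`: list with `converged`, `iterations`,
#'   `potential` (from the best-scoring iteration), `best_hellinger`,
#'   `best_iteration`, `hellinger` (per-iteration trace), `fit_residual`
#'   (trace), `history` (list of `ibi_state`s) and `config`.
#' @export
run_ibi <- function(target, sampler, cfg = ibi_config(), initial = NULL,
                    start_iteration = 0L, on_iteration = NULL) {
  stopifnot(inherits(target, "rama_distribution"))
  if (is.null(initial)) {
    initial <- fourier_potential(numeric(cfg$n_phi_terms),
                                 numeric(cfg$n_psi_terms))
  }
  pot <- initial
  history <- list()
  best_h <- Inf; best_pot <- pot; best_iter <- start_iteration
  converged <- FALSE
  k <- 0L
  for (i in start_iteration:cfg$max_iterations) {
    sampled <- sampler(pot, cfg$temperature, cfg$seed + i)
    h <- hellinger_distance(sampled, target)
    if (h < best_h) { best_h <- h; best_pot <- pot; best_iter <- i }
    k <- k + 1L
    if (h <= cfg$tol || i == cfg$max_iterations) {
      history[[k]] <- new_ibi_state(i, pot, sampled, h)
      converged <- h <= cfg$tol
      if (!is.null(on_iteration)) on_iteration(history[[k]])
      break
    }
    ## trust heuristic against noise-driven divergence: when an update made
    ## things clearly worse, restart the next fit from the best potential
    ## (sampling noise differs through the iteration seed)
    if (h > 1.5 * best_h + 0.02) {
      pot <- best_pot
      sampled_fit <- sampler(pot, cfg$temperature, cfg$seed + i)
      dv <- delta_v_surface(target, sampled_fit, cfg$temperature, cfg$floor,
                            cfg$floor_mode)
      weights <- ibi_fit_weights(cfg, sampled_fit, target)
    } else {
      dv <- delta_v_surface(target, sampled, cfg$temperature, cfg$floor,
                            cfg$floor_mode)
      weights <- ibi_fit_weights(cfg, sampled, target)
    }
    fit <- fit_fourier_to_surface(dv$delta_v, cfg$grid,
                                  cfg$n_phi_terms, cfg$n_psi_terms,
                                  cfg$phases, dv$mask, weights)
    pot <- add_potentials(pot, fit$potential,
                          cfg$lambda * trust_scale(fit$potential, cfg$max_step))
    history[[k]] <- new_ibi_state(i, pot, sampled, h, fit$residual_rms)
    if (!is.null(on_iteration)) on_iteration(history[[k]])
  }
  structure(list(converged = converged,
                 iterations = history[[k]]$iteration,
                 potential = best_pot,
                 best_hellinger = best_h,
                 best_iteration = best_iter,
                 hellinger = vapply(history, `[[`, numeric(1), "hellinger"),
                 fit_residual = vapply(history, `[[`, numeric(1), "fit_residual"),
                 history = history,
                 config = cfg),
            class = "ibi_result")
}

#' @export
print.ibi_result <- function(x, ...) {
  cat(sprintf("ibi_result: %s after %d iteration(s); best Hellinger %.3g at iteration %d\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$best_hellinger, x$best_iteration))
  invisible(x)
}
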