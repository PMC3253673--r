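# Time evolution: overdamped Brownian dynamics for monomers, kinetic Monte
# Carlo for motors, Metropolis Monte Carlo for the wall, and the scheduler.

#' Create a live simulation from a state
#'
#' Wraps the compiled simulator. The returned handle owns mutable state;
#' stepping functions advance it in place and [sim_snapshot()] extracts an
#' immutable `gel_state`. Three independent random streams (thermal noise,
#' motor kinetics, wall moves) are derived from the single seed, so the draw
#' sequence of one subsystem is unaffected by activity in the others.
#'
#' @param state A `gel_state` (e.g. from [init_configuration()]).
#' @param params A `gel_params` object.
#' @param seed Integer seed (defaults to `params$seed`).
#' @param fixed_radius Imposed wall radius when `params$volume_mode` is
#'   `"fixed"`; defaults to `params$R0`.
#' @return A `gel_sim` handle.
#' @export
gel_sim <- function(state, params, seed = params$seed,
                    fixed_radius = params$R0) {
  stopifnot(inherits(state, "gel_state"), inherits(params, "gel_params"))
  fixed <- identical(params$volume_mode, "fixed")
  wall <- if (fixed) matrix(numeric(0), 0, 2) else state$wall
  par <- as_cpp_par(params, overrides = list(N = state$N, M = state$M),
                    fixed_radius = if (fixed) fixed_radius else -1,
                    wall_l0 = state$wall_l0, wall_kappa0 = state$wall_kappa0)
  ptr <- sim_create_cpp(par, state$positions, motors0(state), wall, seed)
  structure(list(ptr = ptr, params = params, N = state$N, M = state$M,
                 wall_l0 = state$wall_l0, wall_kappa0 = state$wall_kappa0,
                 fixed = fixed),
            class = "gel_sim")
}

#' @export
print.gel_sim <- function(x, ...) {
  st <- sim_state_cpp(x$ptr)
  cat(sprintf("<gel_sim> %d x %d monomers, %d motors, t = %g\n",
              x$N, x$M, nrow(st$motors), st$time))
  invisible(x)
}

#' Extract the current state of a live simulation
#'
#' @param sim A `gel_sim` handle.
#' @return A `gel_state`.
#' @export
sim_snapshot <- function(sim) {
  st <- sim_state_cpp(sim$ptr)
  motors <- st$motors
  if (nrow(motors) > 0) motors <- motors + 1L
  colnames(motors) <- c("fil_a", "mon_a", "fil_b", "mon_b")
  gel_state(st$positions, sim$N, sim$M, motors = motors, wall = st$wall,
            wall_l0 = sim$wall_l0, wall_kappa0 = sim$wall_kappa0,
            time = st$time)
}

#' Energy breakdown of a live simulation
#'
#' @param sim A `gel_sim` handle.
#' @return A tibble with columns `term`, `energy` (ending in the total).
#' @export
sim_energy <- function(sim) {
  e <- sim_energy_cpp(sim$ptr)
  tibble::tibble(term = c(names(e), "total"),
                 energy = c(unlist(e), sum(unlist(e))))
}

#' Advance Brownian dynamics only
#'
#' Integrates the overdamped Langevin equation
#' \eqn{r_i \leftarrow r_i + M_i F_i \, dt + \xi_i} with the anisotropic
#' mobility of [mobility_apply()] and Gaussian noise of covariance
#' \eqn{2 k_B T M_i dt} (fluctuation-dissipation), leaving motors and wall
#' untouched.
#'
#' @param sim A `gel_sim` handle.
#' @param n Number of BD steps.
#' @return The handle, invisibly.
#' @export
sim_bd_steps <- function(sim, n = 1) {
  sim_advance_cpp(sim$ptr, n, FALSE, FALSE)
  invisible(sim)
}

#' Run the full update scheme
#'
#' Interleaves a BD step every `dt`, a motor kinetics sweep every
#' `kinetics_interval` steps and (in pressure mode) a wall Metropolis sweep
#' every `wall_interval` steps.
#'
#' @param sim A `gel_sim` handle.
#' @param n Number of BD steps.
#' @param kinetics,wall Enable the respective sweeps.
#' @return A one-row tibble of aggregate sweep counts and the mean wall
#'   acceptance fraction.
#' @export
sim_advance <- function(sim, n, kinetics = TRUE, wall = TRUE) {
  rep <- sim_advance_cpp(sim$ptr, n, kinetics, wall)
  tibble::as_tibble(rep)
}

#' One motor kinetic Monte Carlo sweep
#'
#' Runs, over the kinetics interval \eqn{\Delta t_k =} `kinetics_interval *
#' dt`, the three stochastic motor processes:
#' * **attachment**: every monomer pair on different filaments closer than
#'   `attach_range` spawns a new motor with probability
#'   \eqn{1 - e^{-k_A \Delta t_k}} (several motors may share a monomer);
#' * **movement**: each head not at the \eqn{[+]}-end steps one monomer
#'   towards it with probability
#'   \eqn{\min(1, k_M \Delta t_k \, e^{-\Delta E / k_B T})}, where
#'   \eqn{\Delta E} is the motor spring energy change of the trial move;
#'   heads are visited in random order;
#' * **detachment**: each head fires with probability
#'   \eqn{1 - e^{-k \Delta t_k}}, using `k_E` at the \eqn{[+]}-end and `k_D`
#'   elsewhere; either head firing removes the whole motor.
#'
#' @param sim A `gel_sim` handle.
#' @param attach,move,detach Enable individual processes (all on by
#'   default), so each can be exercised in isolation.
#' @return A one-row tibble: `n_attached`, `n_moved`, `n_detached`,
#'   `n_end_detached`, `n_mot`, `n_mot_plus`.
#' @export
kinetics_sweep <- function(sim, attach = TRUE, move = TRUE, detach = TRUE) {
  tibble::as_tibble(sim_kinetics_cpp(sim$ptr, attach, move, detach))
}

#' @rdname kinetics_sweep
#' @export
attempt_attachments <- function(sim) kinetics_sweep(sim, TRUE, FALSE, FALSE)

#' @rdname kinetics_sweep
#' @export
attempt_moves <- function(sim) kinetics_sweep(sim, FALSE, TRUE, FALSE)

#' @rdname kinetics_sweep
#' @export
attempt_detachments <- function(sim) kinetics_sweep(sim, FALSE, FALSE, TRUE)

#' One wall Metropolis Monte Carlo sweep
#'
#' Attempts one uniform trial displacement in
#' `[-delta_wall, delta_wall]^2` per node, in random order, accepting with
#' the Metropolis probability \eqn{\min(1, e^{-\Delta E / k_B T})} where
#' \eqn{\Delta E} sums the wall elastic energy, the wall-monomer WCA
#' repulsion and the pressure-volume term \eqn{P V}.
#'
#' @param sim A `gel_sim` handle (pressure mode).
#' @param movable Optional integer vector of node indices allowed to move
#'   (1-based); by default all nodes. Restricting the set is useful for
#'   low-dimensional equilibrium checks.
#' @return Acceptance fraction of the sweep.
#' @export
wall_mc_sweep <- function(sim, movable = NULL) {
  if (sim$fixed) {
    stop("wall_mc_sweep requires pressure volume mode", call. = FALSE)
  }
  mv <- if (is.null(movable)) integer(0) else as.integer(movable - 1L)
  sim_wall_sweep_cpp(sim$ptr, mv)
}

#' Anisotropic slender-body mobility
#'
#' Applies the per-monomer mobility tensor
#' \eqn{M_i = \gamma^{-1} \hat t_i \hat t_i + (2\gamma)^{-1} (I - \hat t_i \hat t_i)}
#' to a set of forces, where \eqn{\hat t_i} is the normalised average of the
#' bond directions adjacent to monomer `i`. Drag is twice as large
#' perpendicular to the local filament axis as along it (2:1), so a force
#' along the tangent produces speed \eqn{F/\gamma} and a perpendicular force
#' \eqn{F/2\gamma}. Monomers with a degenerate tangent fall back to the
#' isotropic perpendicular mobility \eqn{1/(2\gamma)} with a warning.
#'
#' @param positions `M x 3` coordinates of one filament.
#' @param forces `M x 3` forces.
#' @param gamma Parallel friction coefficient.
#' @return `M x 3` matrix of velocities `M_i F_i`.
#' @export
mobility_apply <- function(positions, forces, gamma = 1) {
  positions <- as.matrix(positions)
  forces <- as.matrix(forces)
  stopifnot(nrow(positions) == nrow(forces), ncol(positions) == 3)
  if (any(!is.finite(forces))) stop("forces must be finite", call. = FALSE)
  m <- nrow(positions)
  bonds <- diff(positions)
  lens <- sqrt(rowSums(bonds^2))
  bhat <- bonds / pmax(lens, 1e-300)
  out <- matrix(0, m, 3)
  warned <- FALSE
  for (i in seq_len(m)) {
    tv <- numeric(3)
    if (i > 1 && lens[i - 1] > 1e-10) tv <- tv + bhat[i - 1, ]
    if (i < m && lens[i] > 1e-10) tv <- tv + bhat[i, ]
    tl <- sqrt(sum(tv^2))
    if (tl < 1e-10) {
      if (!warned) {
        warning("degenerate tangent; using isotropic mobility 1/(2 gamma)")
        warned <- TRUE
      }
      out[i, ] <- forces[i, ] / (2 * gamma)
    } else {
      th <- tv / tl
      fpar <- sum(forces[i, ] * th)
      out[i, ] <- fpar * th / gamma + (forces[i, ] - fpar * th) / (2 * gamma)
    }
  }
  out
}

#' Run a complete simulation
#'
#' Builds the initial aster configuration, evolves it with the interleaved
#' BD / motor-kinetics / wall-MC scheme, and records frames and per-frame
#' observables. In fixed-volume mode the wall is a rigid circle whose radius
#' follows `radius_schedule` (a data frame with columns `time` and `radius`;
#' the radius switches to each value at the given time), and wall Monte
#' Carlo is skipped.
#'
#' @param params A `gel_params` object (supplies the schedule fields `dt`,
#'   `kinetics_interval`, `wall_interval`, `frame_interval`, `t_end`,
#'   `seed`).
#' @param seed Integer seed overriding `params$seed`.
#' @param radius_schedule Optional data frame (`time`, `radius`) for
#'   fixed-volume runs.
#' @param n_bins Angular bins used for the per-frame mode amplitudes.
#' @param keep_frames Keep full snapshots (`TRUE`) or only observables.
#' @param state Optional starting `gel_state` (defaults to
#'   [init_configuration()]).
#' @return A `gel_trajectory`: list with `params`, `frames` (list of
#'   `gel_state`), and `observables`, a tibble with one row per frame:
#'   `time`, `radius`, `n_mot`, `f_plus`, `Q0`..`Q3`, `state`,
#'   `wall_acceptance`.
#' @export
#' @examples
#' \donttest{
#' p <- gel_params(N = 6, M = 5, R0 = 12, n_wall = 30, t_end = 1)
#' tr <- run_simulation(p)
#' tr$observables
#' }
run_simulation <- function(params, seed = params$seed,
                           radius_schedule = NULL, n_bins = 40,
                           keep_frames = TRUE, state = NULL) {
  stopifnot(inherits(params, "gel_params"))
  fixed <- identical(params$volume_mode, "fixed")
  if (!fixed && !is.null(radius_schedule)) {
    stop("radius_schedule applies to fixed volume mode only", call. = FALSE)
  }
  if (fixed && is.null(radius_schedule)) {
    radius_schedule <- data.frame(time = 0, radius = params$R0)
  }
  if (fixed) {
    radius_schedule <- radius_schedule[order(radius_schedule$time), ,
                                       drop = FALSE]
  }
  if (is.null(state)) state <- init_configuration(params, seed = seed)
  r0 <- if (fixed) radius_schedule$radius[1] else params$R0
  sim <- gel_sim(state, params, seed = seed, fixed_radius = r0)

  steps_total <- ceiling(params$t_end / params$dt)
  spf <- as.integer(params$frame_interval)
  n_frames <- ceiling(steps_total / spf)

  frames <- vector("list", n_frames + 1)
  obs <- vector("list", n_frames + 1)
  next_sched <- if (fixed) 1L else NA_integer_
  cur_radius <- r0

  record <- function(k, st, acc) {
    centre <- frame_centre(st, fixed, cur_radius)
    radius <- if (fixed) cur_radius else wall_radius(st)
    pol <- state_polarity(st)
    modes <- mode_amplitudes(pol, n_bins = n_bins, centre = centre)
    ms <- motor_statistics(st)
    obs[[k]] <<- tibble::tibble(
      time = st$time, radius = radius, n_mot = nrow(st$motors),
      f_plus = ms$f_plus,
      Q0 = modes$Q[1], Q1 = modes$Q[2], Q2 = modes$Q[3], Q3 = modes$Q[4],
      state = classify_state(modes$Q), wall_acceptance = acc
    )
    if (keep_frames) frames[[k]] <<- st
  }

  record(1L, sim_snapshot(sim), NA_real_)
  done <- 0
  k <- 1L
  while (done < steps_total) {
    if (fixed) {
      tnow <- done * params$dt
      while (!is.na(next_sched) && next_sched <= nrow(radius_schedule) &&
             radius_schedule$time[next_sched] <= tnow + 1e-12) {
        cur_radius <- radius_schedule$radius[next_sched]
        sim_set_radius_cpp(sim$ptr, cur_radius)
        next_sched <- next_sched + 1L
      }
    }
    n <- min(spf, steps_total - done)
    rep <- sim_advance(sim, n, kinetics = TRUE, wall = TRUE)
    done <- done + n
    k <- k + 1L
    record(k, sim_snapshot(sim), rep$wall_acceptance)
  }

  structure(
    list(params = params, seed = seed,
         frames = if (keep_frames) frames[seq_len(k)] else list(),
         observables = dplyr::bind_rows(obs[seq_len(k)])),
    class = "gel_trajectory"
  )
}

frame_centre <- function(state, fixed = FALSE, radius = NA) {
  if (!fixed && nrow(state$wall) > 0) colMeans(state$wall) else c(0, 0)
}

#' Mean wall radius of a state
#'
#' Mean distance of the wall nodes from their centroid; the system-size
#' observable used for contraction fits.
#'
#' @param state A `gel_state`.
#' @return Scalar radius.
#' @export
wall_radius <- function(state) {
  if (nrow(state$wall) == 0) return(NA_real_)
  ctr <- colMeans(state$wall)
  mean(sqrt((state$wall[, 1] - ctr[1])^2 + (state$wall[, 2] - ctr[2])^2))
}

#' @export
print.gel_trajectory <- function(x, ...) {
  cat(sprintf("<gel_trajectory> %d frames, t in [%g, %g], %d filaments\n",
              nrow(x$observables), min(x$observables$time),
              max(x$observables$time), x$params$N))
  invisible(x)
}

#' Tidy a trajectory into a per-frame, per-filament table
#'
#' Produces the centre-of-mass track and projected polarity of every
#' filament in every stored frame, the common input for
#' [transverse_velocity()] and [msad()].
#'
#' @param x A `gel_trajectory` with stored frames.
#' @param ... Unused.
#' @return A tibble with columns `time`, `filament`, `x`, `y`, `px`, `py`.
#' @export
tidy.gel_trajectory <- function(x, ...) {
  if (length(x$frames) == 0) {
    stop("trajectory was run with keep_frames = FALSE", call. = FALSE)
  }
  purrr::map_dfr(x$frames, function(st) {
    pol <- state_polarity(st)
    dplyr::mutate(pol, time = st$time, .before = 1)
  })
}

#' @export
glance.gel_trajectory <- function(x, ...) {
  ob <- x$observables
  last <- ob[nrow(ob), ]
  tibble::tibble(
    n_frames = nrow(ob), t_end = last$time, final_state = last$state,
    final_radius = last$radius, final_n_mot = last$n_mot,
    mean_n_mot = mean(ob$n_mot)
  )
}
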