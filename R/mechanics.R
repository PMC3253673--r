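# Energies and analytic forces. The heavy lifting lives in compiled code;
# these wrappers select terms and present results as tibbles.

# Build the flat parameter list consumed by the compiled core.
as_cpp_par <- function(params, overrides = list(), fixed_radius = -1,
                       wall_l0 = NA_real_, wall_kappa0 = NA_real_) {
  p <- list(
    N = params$N, M = params$M, b = params$b, sigma = params$sigma,
    eps = params$eps, k_bond = params$k_bond, kappa = params$kappa,
    k_motor = params$k_motor, attach_range = params$attach_range,
    k_A = params$k_A, k_D = params$k_D, k_M = params$k_M, k_E = params$k_E,
    gamma = params$gamma, P = params$P, Z = params$Z, kT = params$kT,
    c_stretch = params$c_stretch, c_bend = params$c_bend, dt = params$dt,
    max_disp = params$max_disp,
    kinetics_interval = as.integer(params$kinetics_interval),
    wall_interval = as.integer(params$wall_interval),
    delta_wall = params$delta_wall,
    fixed_volume = identical(params$volume_mode, "fixed"),
    fixed_radius = fixed_radius,
    wall_l0 = if (is.na(wall_l0)) 1 else wall_l0,
    wall_kappa0 = if (is.na(wall_kappa0)) 0 else wall_kappa0
  )
  utils::modifyList(p, overrides)
}

motors0 <- function(state) {
  m <- state$motors
  if (nrow(m) == 0) return(matrix(integer(0), 0, 4))
  mm <- m
  mm[] <- as.integer(m - 1L)
  mm
}

#' Repulsive Lennard-Jones (WCA) pair interaction
#'
#' Truncated-and-shifted repulsive Lennard-Jones potential
#' \eqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6] + \epsilon} for
#' \eqn{r < 2^{1/6}\sigma} and zero beyond, used for filament self-avoidance
#' and for all wall-monomer repulsions. The force column holds
#' \eqn{-dU/dr} (positive = repulsive).
#'
#' @param r Separation distance(s); must be positive.
#' @param sigma Interaction diameter.
#' @param eps Energy parameter in \eqn{k_B T}.
#' @return A tibble with columns `r`, `energy`, `force`.
#' @export
#' @examples
#' pair_repulsion(c(1, 2^(1 / 6)))
pair_repulsion <- function(r, sigma = 1, eps = 5) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("pair_repulsion: separation r must be positive and finite",
         call. = FALSE)
  }
  rc <- 2^(1 / 6) * sigma
  sr6 <- (sigma / r)^6
  inside <- r < rc
  energy <- ifelse(inside, 4 * eps * (sr6^2 - sr6) + eps, 0)
  force <- ifelse(inside, 24 * eps * (2 * sr6^2 - sr6) / r, 0)
  tibble::tibble(r = r, energy = energy, force = force)
}

#' Internal elasticity of a single filament
#'
#' Hookean bond stretching \eqn{\frac{1}{2} k_{bond} \sum_i (|r_{i+1} - r_i| - b)^2}
#' plus discrete curvature elasticity
#' \eqn{(\kappa/b) \sum_i (1 - \hat t_i \cdot \hat t_{i+1})} over interior
#' joints, with exact analytic forces (the negative gradient). This bending
#' discretisation gives a worm-like chain with persistence length
#' \eqn{\ell_p = \kappa / k_B T} in three dimensions.
#'
#' @param positions `M x 3` matrix of monomer coordinates along one filament
#'   (row 1 = \eqn{[-]}-end).
#' @param params A `gel_params` object supplying `k_bond`, `kappa` and `b`.
#' @return A list with `energy` (named: `bond`, `bend`, `total`) and
#'   `forces` (`M x 3`).
#' @export
filament_internal <- function(positions, params = gel_params(N = 1, M = nrow(positions))) {
  positions <- as.matrix(positions)
  if (nrow(positions) < 2 || ncol(positions) != 3) {
    stop("filament_internal needs an M x 3 matrix with M >= 2", call. = FALSE)
  }
  par <- as_cpp_par(params, overrides = list(
    N = 1L, M = nrow(positions), eps = 0, Z = Inf, k_motor = 0
  ))
  res <- energy_forces_cpp(par, positions, matrix(integer(0), 0, 4),
                           matrix(numeric(0), 0, 2), FALSE)
  list(
    energy = c(bond = res$bond, bend = res$bend,
               total = res$bond + res$bend),
    forces = res$forces
  )
}

#' Non-bonded energies and forces of a full state
#'
#' Applies the WCA repulsion of [pair_repulsion()] to (i) all monomer pairs
#' except directly bonded neighbours, (ii) the distance of every monomer to
#' the planar walls at `z = 0` and `z = Z`, and (iii) the distance of every
#' monomer to the nearest point of the side-wall polygon (or rigid circle in
#' fixed-volume mode) in the x-y plane.
#'
#' @param state A `gel_state`.
#' @param params A `gel_params` object.
#' @param neighbour_list Use the cell-list accelerated path (`TRUE`) or the
#'   brute-force all-pairs reference (`FALSE`, used as an oracle in tests).
#' @param fixed_radius Radius of the rigid circular wall in fixed-volume
#'   mode.
#' @return A list with `energy` (named: `excluded_volume`, `z_walls`,
#'   `side_wall`, `total`) and `forces` (`(N*M) x 3`).
#' @export
nonbonded_forces <- function(state, params, neighbour_list = FALSE,
                             fixed_radius = -1) {
  stopifnot(inherits(state, "gel_state"))
  par <- as_cpp_par(params,
                    overrides = list(N = state$N, M = state$M,
                                     k_bond = 0, kappa = 0, k_motor = 0),
                    fixed_radius = fixed_radius)
  res <- energy_forces_cpp(par, state$positions, matrix(integer(0), 0, 4),
                           state$wall, neighbour_list)
  list(
    energy = c(excluded_volume = res$excluded_volume, z_walls = res$z_walls,
               side_wall = res$side_wall,
               total = res$excluded_volume + res$z_walls + res$side_wall),
    forces = res$forces
  )
}

#' Motor spring energies and forces
#'
#' Each motor is a zero-rest-length Hookean spring of stiffness `k_motor`
#' between its two head monomers: \eqn{U = \frac{1}{2} k_{motor} d^2} with
#' `d` the three-dimensional head separation, pulling the heads together
#' with equal and opposite forces.
#'
#' @inheritParams nonbonded_forces
#' @return A list with `energy` (total motor spring energy) and `forces`.
#' @export
motor_spring <- function(state, params) {
  stopifnot(inherits(state, "gel_state"))
  par <- as_cpp_par(params, overrides = list(
    N = state$N, M = state$M, k_bond = 0, kappa = 0, eps = 0, Z = Inf
  ))
  res <- energy_forces_cpp(par, state$positions, motors0(state),
                           matrix(numeric(0), 0, 2), FALSE)
  list(energy = res$motor_springs, forces = res$forces)
}

#' Elastic energy of the confining wall
#'
#' Deviations of the node spacing from its reference `l0` cost
#' `c_stretch * kT * Z * dl^2 / l0^3` per adjacent node pair; deviations of
#' the discrete curvature (turning angle divided by `l0`) from its reference
#' `kappa0` cost `c_bend * kT * l0 * Z * dkappa^2` per node triplet. A
#' regular polygon at construction geometry has zero energy.
#'
#' @param wall `n x 2` node matrix (n >= 3).
#' @param l0 Reference node spacing.
#' @param kappa0 Reference discrete curvature (signed).
#' @param params A `gel_params` object supplying `c_stretch`, `c_bend`, `Z`
#'   and `kT`.
#' @return Named numeric: `stretch`, `bend`, `total`.
#' @export
wall_elastic <- function(wall, l0, kappa0, params = gel_params()) {
  wall <- as.matrix(wall)
  if (nrow(wall) < 3) stop("wall polygon needs at least 3 nodes", call. = FALSE)
  e <- wall_energy_cpp(wall, l0, kappa0, params$c_stretch, params$c_bend,
                       params$Z, params$kT)
  c(stretch = e$stretch, bend = e$bend, total = e$stretch + e$bend)
}

# O(n^2) simple-polygon test: no two non-adjacent edges intersect.
polygon_is_simple <- function(wall) {
  n <- nrow(wall)
  if (n < 3) return(FALSE)
  seg <- function(k) rbind(wall[k, ], wall[k %% n + 1, ])
  ccw <- function(a, b, c) {
    (c[2] - a[2]) * (b[1] - a[1]) > (b[2] - a[2]) * (c[1] - a[1])
  }
  intersects <- function(p1, p2, p3, p4) {
    ccw(p1, p3, p4) != ccw(p2, p3, p4) && ccw(p1, p2, p3) != ccw(p1, p2, p4)
  }
  for (i in seq_len(n - 2)) {
    si <- seg(i)
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      sj <- seg(j)
      if (intersects(si[1, ], si[2, ], sj[1, ], sj[2, ])) return(FALSE)
    }
  }
  TRUE
}

#' Volume enclosed by the wall
#'
#' Shoelace area of the node polygon times the gap height `Z`. The result is
#' independent of node ordering direction.
#'
#' @param wall `n x 2` node matrix describing a simple polygon.
#' @param Z Wall gap height.
#' @return Enclosed volume (scalar).
#' @export
#' @examples
#' w <- make_wall(40, 80)
#' enclosed_volume(w$wall, Z = 5) # ~ pi * 40^2 * 5
enclosed_volume <- function(wall, Z) {
  wall <- as.matrix(wall)
  if (!polygon_is_simple(wall)) {
    stop("geometry error: wall polygon is self-intersecting", call. = FALSE)
  }
  abs(polygon_area_cpp(wall)) * Z
}

#' Full energy breakdown of a state
#'
#' Evaluates every energy term of the model for one snapshot: filament bond
#' and bending elasticity, excluded volume, planar z-wall and side-wall
#' repulsion, motor springs, wall stretch and bending elasticity, and the
#' pressure-volume work term `P * V`.
#'
#' @inheritParams nonbonded_forces
#' @return A tibble with columns `term` and `energy` (in \eqn{k_B T}),
#'   ending with the total.
#' @export
energy_breakdown <- function(state, params, fixed_radius = -1) {
  stopifnot(inherits(state, "gel_state"))
  par <- as_cpp_par(params, overrides = list(N = state$N, M = state$M),
                    fixed_radius = fixed_radius,
                    wall_l0 = state$wall_l0, wall_kappa0 = state$wall_kappa0)
  res <- energy_forces_cpp(par, state$positions, motors0(state), state$wall,
                           FALSE)
  stretch <- bend_w <- pv <- 0
  if (nrow(state$wall) >= 3 && !identical(params$volume_mode, "fixed")) {
    e <- wall_energy_cpp(state$wall, state$wall_l0, state$wall_kappa0,
                         params$c_stretch, params$c_bend, params$Z, params$kT)
    stretch <- e$stretch
    bend_w <- e$bend
    pv <- params$P * enclosed_volume(state$wall, params$Z)
  }
  terms <- c(
    bond = res$bond, bend = res$bend, excluded_volume = res$excluded_volume,
    z_walls = res$z_walls, side_wall = res$side_wall,
    motor_springs = res$motor_springs, wall_stretch = stretch,
    wall_bend = bend_w, pressure_volume = pv
  )
  tibble::tibble(
    term = c(names(terms), "total"),
    energy = c(unname(terms), sum(terms))
  )
}
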