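#' Model parameters for a filament-motor simulation
#'
#' Assembles and validates the full parameter set of one run: filament
#' geometry and elasticity, motor rates, confinement, wall elasticity and the
#' numerical schedule. All energies are measured in units of \eqn{k_B T}, all
#' lengths in units of the bond length `b`, and time in units of
#' \eqn{\gamma b^2 / k_B T}.
#'
#' Derived quantities are computed once and attached:
#' * `L = M b`, the filament contour length,
#' * `tau_b = L b \gamma / (4 k_B T)`, the time for a filament to freely
#'   diffuse over one monomer distance (the natural time unit for motor
#'   rates),
#' * `P0 = eps / b^3`, the natural pressure unit set by the excluded-volume
#'   energy scale,
#' * `l_p = kappa / k_B T`, the worm-like-chain persistence length.
#'
#' @param N Number of filaments.
#' @param M Monomers per filament (at least 2). The monomer with index 1 is
#'   the \eqn{[-]}-end, index `M` the \eqn{[+]}-end towards which motors step.
#' @param b Bond rest length (simulation length unit).
#' @param sigma Excluded-volume diameter of the WCA repulsion.
#' @param eps WCA repulsion energy in \eqn{k_B T}.
#' @param k_bond Bond spring constant, \eqn{k_B T / b^2}.
#' @param kappa Bending rigidity, \eqn{b\, k_B T}; the persistence length is
#'   `kappa / kT` in units of `b`.
#' @param k_motor Motor spring constant, \eqn{k_B T / b^2} (zero rest length).
#' @param attach_range Capture radius within which a motor can bridge two
#'   monomers; defaults to the WCA cutoff \eqn{2^{1/6}\sigma}.
#' @param k_A,k_D,k_M,k_E Motor attachment, detachment, stepping and
#'   plus-end detachment rates (inverse time units). `k_E` replaces `k_D`
#'   for heads sitting at a \eqn{[+]}-end.
#' @param gamma Parallel monomer friction coefficient; perpendicular drag is
#'   `2 * gamma`.
#' @param P External pressure acting on the elastic side wall.
#' @param Z Gap between the two planar confining walls; `Inf` disables them.
#' @param R0 Initial side-wall radius; `Inf` disables the side wall.
#' @param n_wall Number of wall nodes.
#' @param c_stretch,c_bend Wall elastic coefficients: adjacent node pairs pay
#'   `c_stretch * kT * Z * dl^2 / l0^3` for spacing changes `dl`, node
#'   triplets pay `c_bend * kT * l0 * Z * dkappa^2` for discrete-curvature
#'   changes `dkappa`.
#' @param delta_wall Half-width of the uniform wall-node Monte Carlo trial
#'   displacement.
#' @param kT Thermal energy (simulation energy unit; lower it to probe
#'   deterministic limits).
#' @param dt Brownian-dynamics time step.
#' @param max_disp Per-step displacement cap (length units). Steeply
#'   overlapping excluded-volume contacts relax over several steps instead
#'   of overshooting; ordinary thermal steps (~`sqrt(2 kT dt / gamma)`) are
#'   far below the cap. Set to 0 to disable.
#' @param kinetics_interval BD steps between motor kinetic Monte Carlo
#'   sweeps (also the neighbour-list refresh stride).
#' @param wall_interval BD steps between wall Metropolis sweeps.
#' @param frame_interval BD steps between recorded trajectory frames.
#' @param t_end Run length in simulation time units.
#' @param seed Integer seed; all subsystem random streams derive from it.
#' @param volume_mode `"pressure"` for the elastic pressurised wall,
#'   `"fixed"` for a rigid circular wall of externally imposed radius.
#'
#' @return An object of class `gel_params`: a named list of all parameters
#'   plus the derived quantities `L`, `tau_b`, `P0` and `l_p`.
#' @seealso [make_params()] to build parameters from a flat key-value
#'   configuration, [physical_units()] for conversion to laboratory units.
#' @export
#' @examples
#' p <- gel_params(N = 40, M = 10, k_A = 0.03)
#' p$tau_b # = M / 4 in units of gamma b^2 / kT
gel_params <- function(N = 175, M = 30, b = 1, sigma = b, eps = 5,
                       k_bond = 100, kappa = 200, k_motor = 1,
                       attach_range = 2^(1 / 6) * sigma,
                       k_A = 0.035, k_D = 0.001, k_M = 0.001, k_E = k_D,
                       gamma = 1, P = 0.12, Z = 5 * b, R0 = 40 * b,
                       n_wall = 80, c_stretch = 0.5, c_bend = 1000,
                       delta_wall = 0.1 * b, kT = 1,
                       dt = 5e-4, max_disp = 0.25 * b,
                       kinetics_interval = 10, wall_interval = 10,
                       frame_interval = 1000, t_end = 100,
                       seed = 1, volume_mode = c("pressure", "fixed")) {
  volume_mode <- match.arg(volume_mode)
  p <- list(
    N = N, M = M, b = b, sigma = sigma, eps = eps, k_bond = k_bond,
    kappa = kappa, k_motor = k_motor, attach_range = attach_range,
    k_A = k_A, k_D = k_D, k_M = k_M, k_E = k_E, gamma = gamma, P = P,
    Z = Z, R0 = R0, n_wall = n_wall, c_stretch = c_stretch,
    c_bend = c_bend, delta_wall = delta_wall, kT = kT, dt = dt,
    max_disp = max_disp,
    kinetics_interval = kinetics_interval, wall_interval = wall_interval,
    frame_interval = frame_interval, t_end = t_end, seed = seed,
    volume_mode = volume_mode
  )
  validate_params(p)
  p$L <- p$M * p$b
  p$tau_b <- p$L * p$b * p$gamma / (4 * p$kT)
  p$P0 <- p$eps / p$b^3
  p$l_p <- p$kappa / p$kT
  structure(p, class = "gel_params")
}

validate_params <- function(p) {
  cfg_stop <- function(key, why) {
    stop(sprintf("configuration error: parameter '%s' %s", key, why),
         call. = FALSE)
  }
  num_keys <- setdiff(names(p), "volume_mode")
  for (key in num_keys) {
    v <- p[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      cfg_stop(key, "must be a single numeric value")
    }
  }
  for (key in c("k_A", "k_D", "k_M", "k_E", "P", "eps", "k_bond", "kappa",
                "k_motor", "c_stretch", "c_bend", "delta_wall", "kT",
                "max_disp")) {
    if (p[[key]] < 0) cfg_stop(key, "must be non-negative")
  }
  for (key in c("b", "sigma", "attach_range", "gamma", "Z", "R0")) {
    if (p[[key]] <= 0) cfg_stop(key, "must be positive")
  }
  if (p$M < 2) cfg_stop("M", "must be at least 2")
  if (p$N < 1) cfg_stop("N", "must be at least 1")
  if (p$n_wall < 3) cfg_stop("n_wall", "must be at least 3")
  if (p$dt <= 0) cfg_stop("dt", "must be positive")
  if (p$t_end <= 0) cfg_stop("t_end", "must be positive")
  for (key in c("kinetics_interval", "wall_interval", "frame_interval")) {
    if (p[[key]] < 1 || p[[key]] != round(p[[key]])) {
      cfg_stop(key, "must be a positive integer")
    }
  }
  invisible(p)
}

#' Build model parameters from a flat key-value configuration
#'
#' Thin constructor over [gel_params()] for configurations read from files or
#' assembled programmatically. Every key must name a [gel_params()] argument;
#' unknown keys are rejected so that typos never pass silently. Omitted keys
#' take the documented defaults.
#'
#' @param config Named list (or named vector) of parameter values.
#' @return A `gel_params` object.
#' @export
#' @examples
#' make_params(list(N = 40, M = 10, k_A = 0.01))
make_params <- function(config = list()) {
  config <- as.list(config)
  if (length(config) > 0 && (is.null(names(config)) || any(names(config) == ""))) {
    stop("configuration error: all entries must be named", call. = FALSE)
  }
  known <- names(formals(gel_params))
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop(sprintf("configuration error: unknown key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  do.call(gel_params, config)
}

#' @export
print.gel_params <- function(x, ...) {
  cat("<gel_params>\n")
  cat(sprintf("  %d filaments x %d monomers (L = %g b, l_p = %g b)\n",
              x$N, x$M, x$L, x$l_p))
  cat(sprintf("  rates: k_A/k_D = %g, k_M tau_b = %g, k_E/k_D = %g\n",
              if (x$k_D > 0) x$k_A / x$k_D else NA,
              x$k_M * x$tau_b,
              if (x$k_D > 0) x$k_E / x$k_D else NA))
  cat(sprintf("  pressure: P/P0 = %g (%s volume mode)\n",
              x$P / x$P0, x$volume_mode))
  cat(sprintf("  schedule: dt = %g, t_end = %g (tau_b = %g)\n",
              x$dt, x$t_end, x$tau_b))
  invisible(x)
}

#' Map simulation units onto laboratory units
#'
#' The model is defined in reduced units (lengths in `b`, energies in
#' \eqn{k_B T}). Choosing a physical bond length pins down the remaining
#' scales: with `b = 10` nm (between the actin and microtubule diameters) the
#' motor force scale \eqn{k_B T / b} is about 0.4 pN and the default filament
#' is 0.3 um long.
#'
#' @param params A `gel_params` object.
#' @param b_nm Physical bond length in nanometres.
#' @param kT_pN_nm Thermal energy in pN nm (4.114 at 298 K).
#' @return A tibble with one row per mapped quantity: `quantity`,
#'   `simulation` (reduced value), `physical`, `unit`.
#' @export
#' @examples
#' physical_units(gel_params())
physical_units <- function(params, b_nm = 10, kT_pN_nm = 4.114) {
  stopifnot(inherits(params, "gel_params"))
  tibble::tibble(
    quantity = c("bond length b", "filament length L", "persistence length l_p",
                 "force unit kT/b", "motor spring k_motor",
                 "pressure unit P0"),
    simulation = c(params$b, params$L, params$l_p, 1, params$k_motor,
                   params$P0),
    physical = c(
      b_nm,
      params$L / params$b * b_nm / 1000,
      params$l_p / params$b * b_nm / 1000,
      kT_pN_nm / b_nm,
      params$k_motor * kT_pN_nm / b_nm^2,
      # 1 pN/nm^2 = 1e6 Pa, so eps * kT / b^3 in kPa:
      params$eps * kT_pN_nm / b_nm^3 * 1000
    ),
    unit = c("nm", "um", "um", "pN", "pN/nm", "kPa")
  )
}
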