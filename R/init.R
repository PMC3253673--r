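#' System state container
#'
#' Bundles monomer coordinates, the motor roster and the wall geometry at one
#' instant. Positions are stored as an `(N*M) x 3` matrix in filament-major
#' order: row `(f - 1) * M + m` holds monomer `m` of filament `f`, with
#' monomer 1 the \eqn{[-]}-end and monomer `M` the \eqn{[+]}-end.
#'
#' @param positions `(N*M) x 3` numeric matrix of monomer coordinates.
#' @param N,M Filament count and monomers per filament.
#' @param motors Integer matrix with columns `fil_a`, `mon_a`, `fil_b`,
#'   `mon_b` (1-based); the two heads of a motor must sit on different
#'   filaments.
#' @param wall `n x 2` matrix of wall-node `(x, y)` coordinates (0 rows for a
#'   rigid circular wall or an unconfined system).
#' @param wall_l0 Reference wall-node spacing.
#' @param wall_kappa0 Reference discrete curvature (signed; positive for a
#'   counter-clockwise polygon).
#' @param time Simulation time of the snapshot.
#' @return An object of class `gel_state`.
#' @export
gel_state <- function(positions, N, M, motors = empty_motors(), wall = NULL,
                      wall_l0 = NA_real_, wall_kappa0 = NA_real_, time = 0) {
  positions <- as.matrix(positions)
  if (nrow(positions) != N * M || ncol(positions) != 3) {
    stop("positions must be an (N*M) x 3 matrix", call. = FALSE)
  }
  if (is.null(wall)) wall <- matrix(numeric(0), 0, 2)
  motors <- as.matrix(motors)
  if (ncol(motors) != 4) stop("motors must have 4 columns", call. = FALSE)
  if (nrow(motors) == 0) {
    motors <- empty_motors()
  } else {
    storage.mode(motors) <- "integer"
  }
  if (nrow(motors) > 0) {
    if (any(motors[, 1] == motors[, 3])) {
      stop("motor heads must sit on different filaments", call. = FALSE)
    }
    if (any(motors[, c(1, 3)] < 1 | motors[, c(1, 3)] > N) ||
        any(motors[, c(2, 4)] < 1 | motors[, c(2, 4)] > M)) {
      stop("motor head indices out of range", call. = FALSE)
    }
  }
  structure(
    list(positions = positions, N = N, M = M, motors = motors, wall = wall,
         wall_l0 = wall_l0, wall_kappa0 = wall_kappa0, time = time),
    class = "gel_state"
  )
}

#' @rdname gel_state
#' @export
empty_motors <- function() {
  m <- matrix(integer(0), 0, 4)
  colnames(m) <- c("fil_a", "mon_a", "fil_b", "mon_b")
  m
}

#' @export
print.gel_state <- function(x, ...) {
  cat(sprintf("<gel_state> %d filaments x %d monomers, %d motors, %d wall nodes, t = %g\n",
              x$N, x$M, nrow(x$motors), nrow(x$wall), x$time))
  invisible(x)
}

#' Tidy a system state into a monomer table
#'
#' @param x A `gel_state`.
#' @param ... Unused.
#' @return A tibble with columns `filament`, `monomer`, `x`, `y`, `z`.
#' @export
tidy.gel_state <- function(x, ...) {
  pos <- x$positions
  tibble::tibble(
    filament = rep(seq_len(x$N), each = x$M),
    monomer = rep(seq_len(x$M), times = x$N),
    x = pos[, 1], y = pos[, 2], z = pos[, 3]
  )
}

#' Build a regular polygonal wall
#'
#' @param R Radius of the circumscribed circle.
#' @param n_wall Number of nodes.
#' @return A list with `wall` (`n x 2` node matrix, counter-clockwise),
#'   `l0` (node spacing) and `kappa0` (discrete curvature `2 pi / (n l0)`).
#' @export
make_wall <- function(R, n_wall = 80) {
  ang <- 2 * pi * (seq_len(n_wall) - 1) / n_wall
  wall <- cbind(R * cos(ang), R * sin(ang))
  l0 <- 2 * R * sin(pi / n_wall)
  list(wall = wall, l0 = l0, kappa0 = 2 * pi / (n_wall * l0))
}

#' Initial radial aster configuration
#'
#' Places all filaments straight and radial with their \eqn{[+]}-ends
#' pointing towards the centre, distributed as evenly as possible over three
#' parallel layers at heights `b`, `Z/2` and `Z - b`. Within each layer the
#' azimuthal positions are equally spaced with a random per-filament jitter
#' and a random global phase, so repeated runs from different seeds start
#' from statistically equivalent but distinct configurations. The radial span
#' of each filament is `[R0 - L - 2b + b, R0 - 2b]` (the \eqn{[-]}-end
#' outermost), which keeps every monomer clear of the side wall. The wall is
#' a regular `n_wall`-gon of radius `R0`; the motor roster starts empty.
#'
#' @param params A `gel_params` object.
#' @param seed Integer seed (defaults to `params$seed`).
#' @return A `gel_state`.
#' @export
#' @examples
#' st <- init_configuration(gel_params(N = 6, M = 5, R0 = 12))
#' st
init_configuration <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "gel_params"))
  clearance <- 2 * params$b
  if (!is.finite(params$R0) || params$R0 <= params$L + 3 * params$b) {
    stop("initialisation error: R0 must exceed L + 3b so that radial filaments fit inside the wall",
         call. = FALSE)
  }
  if (!is.finite(params$Z)) {
    stop("initialisation error: the layered aster initial condition needs a finite wall gap Z",
         call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  n_layers <- 3L
  base <- params$N %/% n_layers
  counts <- base + as.integer(seq_len(n_layers) <= params$N %% n_layers)
  zs <- c(params$b, params$Z / 2, params$Z - params$b)

  radii <- params$R0 - clearance - (seq_len(params$M) - 1) * params$b
  pos <- matrix(NA_real_, params$N * params$M, 3)
  f <- 0L
  for (l in seq_len(n_layers)) {
    nl <- counts[l]
    if (nl == 0L) next
    spacing <- 2 * pi / nl
    phase <- runif(1, 0, 2 * pi)
    ang <- phase + spacing * (seq_len(nl) - 1) +
      runif(nl, -0.25, 0.25) * spacing
    for (j in seq_len(nl)) {
      f <- f + 1L
      rows <- (f - 1L) * params$M + seq_len(params$M)
      pos[rows, 1] <- radii * cos(ang[j])
      pos[rows, 2] <- radii * sin(ang[j])
      pos[rows, 3] <- zs[l]
    }
  }
  w <- make_wall(params$R0, params$n_wall)
  gel_state(pos, params$N, params$M, wall = w$wall, wall_l0 = w$l0,
            wall_kappa0 = w$kappa0, time = 0)
}
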