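# Synthetic-data generators: ideal polarity fields, rotating/diffusing
# rings, tanh-shaped radius series and lifetime samples. They make every
# analysis operation testable without running the simulator.

with_local_seed <- function(seed, expr) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Ideal polarity fields on a ring
#'
#' Generates `n` points uniformly spaced in angle on a ring, carrying the
#' ideal polarity field of the requested state (see
#' [ideal_state_targets()]) plus optional Gaussian angular noise. Regions
#' where the ideal field vanishes (the nematic everywhere, the spindle and
#' semi-aster outside their polar arcs) are realised as antiparallel pairs
#' of unit vectors at the same angle — individual filaments always carry
#' unit polarity, and opposing pairs give the required zero *mean*
#' orientation exactly as a real apolar arrangement does.
#'
#' @param state One of `"aster"`, `"semi-aster"`, `"spindle"`, `"nematic"`.
#' @param n Number of ring points (antiparallel pairs count as one point).
#' @param noise Standard deviation (radians) of the angular noise applied
#'   to each polarity vector.
#' @param radius Ring radius.
#' @param seed Integer seed (only used when `noise > 0`).
#' @return A tibble with columns `filament`, `x`, `y`, `px`, `py`, directly
#'   consumable by [mode_amplitudes()].
#' @export
#' @examples
#' mode_amplitudes(gen_ideal_field("aster", n = 2000))$Q
gen_ideal_field <- function(state = c("aster", "semi-aster", "spindle", "nematic"),
                            n = 1000, noise = 0, radius = 10, seed = 1) {
  state <- match.arg(state)
  stopifnot(n >= 1, noise >= 0)
  theta <- 2 * pi * (seq_len(n) - 0.5) / n - pi
  pol <- switch(state,
    "aster" = cbind(-cos(theta), -sin(theta)),
    "semi-aster" = {
      p <- cbind(-cos(theta / 3), -sin(theta / 3))
      p[abs(theta) >= 3 * pi / 4, ] <- NA
      p
    },
    "spindle" = {
      p <- cbind(-cos(theta), sin(theta))
      arc <- abs(theta) < pi / 4 | abs(theta) > 3 * pi / 4
      p[!arc, ] <- NA
      p
    },
    "nematic" = matrix(NA_real_, n, 2)
  )
  polar <- is.finite(pol[, 1])
  # polar points: one filament with the ideal field direction
  out1 <- tibble::tibble(
    theta = theta[polar], px = pol[polar, 1], py = pol[polar, 2]
  )
  # apolar points: antiparallel pair along the local tangent
  th0 <- theta[!polar]
  out0 <- tibble::tibble(
    theta = rep(th0, each = 2),
    px = as.vector(rbind(-sin(th0), sin(th0))),
    py = as.vector(rbind(cos(th0), -cos(th0)))
  )
  out <- dplyr::arrange(dplyr::bind_rows(out1, out0), .data$theta)
  if (noise > 0) {
    out <- with_local_seed(seed, {
      eps <- rnorm(nrow(out), 0, noise)
      dplyr::mutate(out,
        px2 = cos(eps) * .data$px - sin(eps) * .data$py,
        py = sin(eps) * .data$px + cos(eps) * .data$py,
        px = .data$px2, px2 = NULL
      )
    })
  }
  tibble::tibble(
    filament = seq_len(nrow(out)),
    x = radius * cos(out$theta), y = radius * sin(out$theta),
    px = out$px, py = out$py
  )
}

#' Rigidly rotating, angularly diffusing ring trajectory
#'
#' `n` aster-oriented particles on a ring advance by `omega * dt` per frame
#' plus independent Gaussian angular noise of variance `2 * D_theta * dt` —
#' the minimal kinematics interpolating between ballistic collective
#' rotation (MSAD slope 2) and angular diffusion (slope 1).
#'
#' @param omega Angular velocity (positive = counter-clockwise).
#' @param D_theta Angular diffusion coefficient.
#' @param n Particles.
#' @param frames Number of frames (>= 2).
#' @param dt Frame time spacing.
#' @param radius Ring radius.
#' @param seed Integer seed.
#' @return A tibble with columns `time`, `filament`, `x`, `y`, `px`, `py`.
#' @export
#' @examples
#' glance(msad(gen_rotating_ring(omega = 0.01, D_theta = 0)))$slope # ~ 2
gen_rotating_ring <- function(omega = 0, D_theta = 0, n = 50, frames = 100,
                              dt = 1, radius = 10, seed = 1) {
  stopifnot(frames >= 2, n >= 1, D_theta >= 0)
  theta0 <- 2 * pi * (seq_len(n) - 0.5) / n
  th <- with_local_seed(seed, {
    incr <- matrix(omega * dt, frames - 1, n)
    if (D_theta > 0) {
      incr <- incr + matrix(rnorm((frames - 1) * n, 0,
                                  sqrt(2 * D_theta * dt)), frames - 1, n)
    }
    apply(rbind(theta0, incr), 2, cumsum)
  })
  tibble::tibble(
    time = rep((seq_len(frames) - 1) * dt, times = n),
    filament = rep(seq_len(n), each = frames),
    theta = as.vector(th)
  ) |>
    dplyr::mutate(
      x = radius * cos(.data$theta), y = radius * sin(.data$theta),
      px = -cos(.data$theta), py = -sin(.data$theta), theta = NULL
    )
}

#' Noisy hyperbolic-tangent radius series
#'
#' Exact four-parameter tanh contraction curve
#' `R(t) = R_min + dR * tanh((t - t_cont) / dt_width)` plus i.i.d. Gaussian
#' noise, for exercising [fit_contraction()].
#'
#' @param R_min,dR,t_cont,dt_width Curve parameters. Note that with this
#'   parameterisation the radius *decreases* through `t_cont` when `dR < 0`
#'   and increases when `dR > 0`; a contraction from `R_min + |dR|` down to
#'   `R_min - |dR|` corresponds to `dR < 0`.
#' @param t_end Series length; samples are equally spaced on `[0, t_end]`.
#' @param n Number of samples.
#' @param noise Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return A tibble with columns `time`, `radius`.
#' @export
gen_tanh_radius <- function(R_min = 30, dR = -10, t_cont = 5000,
                            dt_width = 500, t_end = 10000, n = 200,
                            noise = 0, seed = 1) {
  stopifnot(n >= 2, noise >= 0)
  tt <- seq(0, t_end, length.out = n)
  r <- R_min + dR * tanh((tt - t_cont) / dt_width)
  if (noise > 0) {
    r <- with_local_seed(seed, r + rnorm(n, 0, noise))
  }
  tibble::tibble(time = tt, radius = r)
}

#' Lifetime samples from candidate distributions
#'
#' I.i.d. waiting-time samples from the two hypotheses that
#' [lifetime_tests()] discriminates: exponential (contraction at a fixed
#' rate) or normal (contraction at a fixed time).
#'
#' @param dist `"exponential"` or `"normal"`.
#' @param mean Distribution mean (> 0).
#' @param n Sample size (>= 1).
#' @param sd Standard deviation for the normal case.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
gen_lifetime_sample <- function(dist = c("exponential", "normal"),
                                mean = 1.7e4, n = 20, sd = mean / 4,
                                seed = 1) {
  dist <- match.arg(dist)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (mean <= 0) stop("mean must be positive", call. = FALSE)
  with_local_seed(seed, {
    switch(dist,
      exponential = rexp(n, rate = 1 / mean),
      normal = rnorm(n, mean, sd)
    )
  })
}
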