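# Independent oracles used across the test files.

# Analytic ideal polarity fields as functions of theta (NA outside support).
ideal_field_fun <- function(state) {
  switch(state,
    "aster" = function(th) cbind(-cos(th), -sin(th)),
    "semi-aster" = function(th) {
      p <- cbind(-cos(th / 3), -sin(th / 3))
      p[abs(th) >= 3 * pi / 4, ] <- 0
      p
    },
    "spindle" = function(th) {
      p <- cbind(-cos(th), sin(th))
      arc <- abs(th) < pi / 4 | abs(th) > 3 * pi / 4
      p[!arc, ] <- 0
      p
    },
    "nematic" = function(th) cbind(0 * th, 0 * th)
  )
}

# Quadrature oracle for the angular mode amplitudes Q_0..Q_3 of a smooth
# field: direct Riemann sums of the coefficient integrals, independent of
# the binning estimator under test.
quadrature_modes <- function(field_fun, n_quad = 2e6) {
  th <- seq(-pi, pi, length.out = n_quad + 1)[-(n_quad + 1)]
  dth <- 2 * pi / n_quad
  p <- field_fun(th)
  vapply(0:3, function(m) {
    ax <- sum(p[, 1] * cos(m * th)) * dth
    ay <- sum(p[, 2] * cos(m * th)) * dth
    bx <- if (m == 0) 0 else sum(p[, 1] * sin(m * th)) * dth
    by <- if (m == 0) 0 else sum(p[, 2] * sin(m * th)) * dth
    (ax^2 + ay^2 + bx^2 + by^2) / (2 * pi^2)
  }, numeric(1))
}

# A frozen two-filament "ladder": parallel straight filaments a distance d
# apart, rung pairs within motor capture range. Returns a gel_state.
make_ladder <- function(M = 5, d = 1, Z = 5) {
  pos <- rbind(
    cbind(seq_len(M), 0, Z / 2),
    cbind(seq_len(M), d, Z / 2)
  )
  gel_state(pos, N = 2, M = M)
}

# Single eligible monomer pair on two far-apart filaments (only monomers
# 1a and 1b are within capture range of each other).
make_frozen_pair <- function(Z = 5) {
  # two 2-monomer filaments, first monomers 0.5 apart, second monomers far
  pos <- rbind(
    c(0, 0, Z / 2), c(0, 40, Z / 2),
    c(0.5, 0, Z / 2), c(0.5, -40, Z / 2)
  )
  gel_state(pos, N = 2, M = 2)
}

# Free-space params (no confining walls) for passive-filament checks.
free_params <- function(...) {
  gel_params(Z = Inf, R0 = 1e6, k_A = 0, k_D = 0, k_M = 0, k_E = 0, P = 0, ...)
}

# A state holding one straight filament along +x, centred at the origin.
straight_filament_state <- function(M = 10, b = 1) {
  pos <- cbind(b * (seq_len(M) - (M + 1) / 2), 0, 0)
  gel_state(pos, N = 1, M = M)
}
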