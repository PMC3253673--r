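test_that("filament internal elasticity matches hand-evaluated cases", {
  p <- gel_params(N = 1, M = 3)
  # straight chain at rest length: zero energy, zero force
  straight <- cbind(0:2, 0, 0)
  r <- filament_internal(straight, p)
  expect_equal(unname(r$energy["total"]), 0, tolerance = 1e-14)
  expect_equal(max(abs(r$forces)), 0, tolerance = 1e-12)

  # one bond stretched to 1.1 b: E = 0.5 * 100 * 0.1^2 = 0.5 kBT
  stretched <- cbind(c(0, 1, 2.1), 0, 0)
  r <- filament_internal(stretched, p)
  expect_equal(unname(r$energy["bond"]), 0.5, tolerance = 1e-12)

  # right-angle joint at rest bond length: E = (kappa/b)(1 - cos 90) = 200
  bent <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  r <- filament_internal(bent, p)
  expect_equal(unname(r$energy["bend"]), 200, tolerance = 1e-12)

  # coincident consecutive monomers are rejected
  expect_error(filament_internal(rbind(c(0, 0, 0), c(0, 0, 0)), p),
               "degenerate")
})

test_that("WCA pair repulsion has the right values, cutoff and monotonicity", {
  expect_equal(pair_repulsion(2^(1 / 6))$energy, 0)
  expect_equal(pair_repulsion(1)$energy, 5) # 4 eps (1 - 1) + eps at r = sigma
  expect_equal(pair_repulsion(0.9)$energy, 38.18059, tolerance = 1e-6)
  expect_error(pair_repulsion(0), "positive")
  expect_error(pair_repulsion(-1), "positive")

  r <- seq(0.7, 2^(1 / 6) - 1e-9, length.out = 200)
  e <- pair_repulsion(r)$energy
  expect_true(all(diff(e) < 0)) # monotonically decreasing inside the cutoff
  expect_true(all(pair_repulsion(r)$force > 0))
  # continuity at the cutoff
  expect_lt(pair_repulsion(2^(1 / 6) - 1e-8)$energy, 1e-5)
})

test_that("non-bonded terms vanish beyond cutoffs and respect both plates", {
  p <- gel_params(N = 2, M = 2)
  # two dimers 2b apart in mid-gap, far from the side wall
  pos <- rbind(c(0, 0, 2.5), c(1, 0, 2.5), c(0, 2, 2.5), c(1, 2, 2.5))
  w <- make_wall(40, 80)
  st <- gel_state(pos, 2, 2, wall = w$wall, wall_l0 = w$l0,
                  wall_kappa0 = w$kappa0)
  r <- nonbonded_forces(st, p)
  expect_equal(unname(r$energy["total"]), 0)
  expect_equal(max(abs(r$forces)), 0)

  # monomer close to the bottom plate feels only that plate (Z = 5b)
  st2 <- gel_state(rbind(c(0, 0, 1), c(1, 0, 1)), 1, 2, wall = w$wall,
                   wall_l0 = w$l0, wall_kappa0 = w$kappa0)
  r2 <- nonbonded_forces(st2, p)
  expect_equal(unname(r2$energy["z_walls"]), 2 * pair_repulsion(1)$energy)
  expect_true(all(r2$forces[, 3] > 0)) # pushed up, away from z = 0
})

test_that("neighbour-list forces equal the brute-force oracle", {
  # 5 crowded filaments in a small box so EV, walls and motors all engage
  set.seed(42)
  p <- gel_params(N = 5, M = 6, R0 = 8, n_wall = 30)
  w <- make_wall(8, 30)
  ang <- runif(5, 0, 2 * pi)
  pos <- do.call(rbind, lapply(seq_len(5), function(f) {
    r0 <- 6 - (0:5) * 0.9
    cbind(r0 * cos(ang[f]), r0 * sin(ang[f]), runif(1, 1, 4))
  }))
  pos <- pos + matrix(rnorm(90, sd = 0.05), ncol = 3)
  mo <- rbind(c(1L, 3L, 2L, 4L), c(4L, 1L, 5L, 2L))
  st <- gel_state(pos, 5, 6, motors = mo, wall = w$wall, wall_l0 = w$l0,
                  wall_kappa0 = w$kappa0)
  a <- nonbonded_forces(st, p, neighbour_list = TRUE)
  b <- nonbonded_forces(st, p, neighbour_list = FALSE)
  expect_equal(a$energy, b$energy, tolerance = 1e-12)
  expect_equal(a$forces, b$forces, tolerance = 1e-12)
})

test_that("motor springs store (1/2) k d^2 and add per motor", {
  p <- gel_params(N = 2, M = 2)
  # coincident heads: zero energy
  pos0 <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 0), c(-1, 0, 0))
  st0 <- gel_state(pos0, 2, 2, motors = matrix(c(1L, 1L, 2L, 1L), 1))
  expect_equal(motor_spring(st0, p)$energy, 0)

  # separation sqrt(2) b: E = 0.5 * 1 * 2 = 1 kBT
  pos1 <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0))
  st1 <- gel_state(pos1, 2, 2, motors = matrix(c(1L, 1L, 2L, 1L), 1))
  expect_equal(motor_spring(st1, p)$energy, 1, tolerance = 1e-12)

  # two motors on the same pair double the energy
  st2 <- gel_state(pos1, 2, 2,
                   motors = rbind(c(1L, 1L, 2L, 1L), c(1L, 1L, 2L, 1L)))
  expect_equal(motor_spring(st2, p)$energy, 2, tolerance = 1e-12)
})

test_that("wall elasticity is zero at construction and matches direct sums", {
  p <- gel_params()
  w <- make_wall(40, 80)
  e0 <- wall_elastic(w$wall, w$l0, w$kappa0, p)
  expect_equal(unname(e0["total"]), 0, tolerance = 1e-18)

  # uniform 1% dilation: curvature term stays 0 only if kappa scaled; with
  # the turning-angle convention the angles are unchanged but l0 in the
  # denominator is the reference, so stretch = sum 1/2 Z (0.01 l0)^2 / l0^3
  w1 <- make_wall(40 * 1.01, 80)
  e1 <- wall_elastic(w1$wall, w$l0, w$kappa0, p)
  dl <- w1$l0 - w$l0
  expect_equal(unname(e1["stretch"]),
               80 * p$c_stretch * p$Z * dl^2 / w$l0^3, tolerance = 1e-10)
  # curvature changes because the turning angle is fixed but kappa = phi/l0
  # is referenced to the original l0; direct formula check
  phi <- 2 * pi / 80
  dk <- phi / w$l0 - w$kappa0 # zero: same l0 reference used on both sides
  expect_equal(dk, 0)
  expect_equal(unname(e1["bend"]), 0, tolerance = 1e-18)

  # single displaced node: energy matches an independent R evaluation
  w2 <- w$wall
  w2[5, ] <- w2[5, ] * 1.0025 # 0.1b outward at R = 40
  e2 <- wall_elastic(w2, w$l0, w$kappa0, p)
  direct <- local({
    n <- nrow(w2)
    stretch <- 0
    bend <- 0
    for (k in seq_len(n)) {
      k2 <- k %% n + 1
      km <- (k - 2) %% n + 1
      dl <- sqrt(sum((w2[k2, ] - w2[k, ])^2)) - w$l0
      stretch <- stretch + p$c_stretch * p$Z * dl^2 / w$l0^3
      u <- w2[k, ] - w2[km, ]
      v <- w2[k2, ] - w2[k, ]
      phi <- atan2(u[1] * v[2] - u[2] * v[1], sum(u * v))
      bend <- bend + p$c_bend * w$l0 * p$Z * (phi / w$l0 - w$kappa0)^2
    }
    c(stretch = stretch, bend = bend)
  })
  expect_equal(unname(e2["stretch"]), unname(direct["stretch"]),
               tolerance = 1e-12)
  expect_equal(unname(e2["bend"]), unname(direct["bend"]), tolerance = 1e-12)
  expect_gt(unname(e2["total"]), 0)

  expect_error(wall_elastic(w$wall[1:2, ], w$l0, w$kappa0, p), "3 nodes")
})

test_that("enclosed volume is the shoelace area times the gap", {
  w <- make_wall(40, 80)
  expect_equal(enclosed_volume(w$wall, Z = 5),
               0.5 * 80 * 40^2 * sin(2 * pi / 80) * 5, tolerance = 1e-10)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(enclosed_volume(sq, Z = 5), 5)
  expect_equal(enclosed_volume(sq[4:1, ], Z = 5), 5) # orientation-free
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(enclosed_volume(bow, Z = 5), "self-intersecting")
})

test_that("every analytic force is the negative gradient of the energy", {
  set.seed(99)
  p <- gel_params(N = 3, M = 4, R0 = 7, n_wall = 24)
  w <- make_wall(7, 24)
  for (rep in 1:3) {
    base <- do.call(rbind, lapply(1:3, function(f) {
      a <- runif(1, 0, 2 * pi)
      r0 <- 5 - (0:3)
      cbind(r0 * cos(a), r0 * sin(a), runif(1, 0.8, 4.2))
    }))
    pos <- base + matrix(rnorm(36, sd = 0.08), ncol = 3)
    mo <- matrix(c(1L, 2L, 2L, 3L), 1)
    par <- activegel:::as_cpp_par(p, overrides = list(N = 3L, M = 4L))
    mo0 <- matrix(as.integer(mo - 1L), 1)
    ref <- activegel:::energy_forces_cpp(par, pos, mo0, w$wall, FALSE)
    etot <- function(pp) {
      r <- activegel:::energy_forces_cpp(par, pp, mo0, w$wall, FALSE)
      r$bond + r$bend + r$excluded_volume + r$z_walls + r$side_wall +
        r$motor_springs
    }
    h <- 1e-6
    for (i in sample(12, 5)) {
      for (cc in 1:3) {
        pp <- pos
        pp[i, cc] <- pos[i, cc] + h
        e1 <- etot(pp)
        pp[i, cc] <- pos[i, cc] - h
        e0 <- etot(pp)
        fd <- -(e1 - e0) / (2 * h)
        expect_equal(ref$forces[i, cc], fd,
                     tolerance = 1e-6 * max(1, abs(fd)))
      }
    }
  }
})

test_that("energies are invariant under rigid rotation and x-y translation", {
  set.seed(5)
  p <- gel_params(N = 2, M = 5, R0 = 9, n_wall = 20)
  w <- make_wall(9, 20)
  pos <- rbind(cbind(seq(2, 6), 0.3, 2.5), cbind(0.4, seq(2, 6), 2.1)) +
    matrix(rnorm(30, sd = 0.05), ncol = 3)
  mo <- matrix(c(1L, 4L, 2L, 2L), 1)
  st <- gel_state(pos, 2, 5, motors = mo, wall = w$wall, wall_l0 = w$l0,
                  wall_kappa0 = w$kappa0)
  e_ref <- energy_breakdown(st, p)$energy

  rot <- function(xy, a) {
    cbind(cos(a) * xy[, 1] - sin(a) * xy[, 2],
          sin(a) * xy[, 1] + cos(a) * xy[, 2])
  }
  a <- 0.73
  st_rot <- gel_state(cbind(rot(pos[, 1:2], a), pos[, 3]), 2, 5, motors = mo,
                      wall = rot(w$wall, a), wall_l0 = w$l0,
                      wall_kappa0 = w$kappa0)
  expect_equal(energy_breakdown(st_rot, p)$energy, e_ref, tolerance = 1e-9)

  shift <- c(1.3, -0.7)
  st_tr <- gel_state(cbind(pos[, 1] + shift[1], pos[, 2] + shift[2],
                           pos[, 3]), 2, 5, motors = mo,
                     wall = cbind(w$wall[, 1] + shift[1],
                                  w$wall[, 2] + shift[2]),
                     wall_l0 = w$l0, wall_kappa0 = w$kappa0)
  expect_equal(energy_breakdown(st_tr, p)$energy, e_ref, tolerance = 1e-9)
})
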