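test_that("filament polarity is the normalised projected end-to-end vector", {
  expect_equal(unname(filament_polarity(cbind(0:4, 0, 0))), c(1, 0))
  expect_equal(unname(filament_polarity(cbind(0, seq(4, 0), 1:5))), c(0, -1))
  # bent filament: same as the projected end-to-end vector by construction
  bent <- rbind(c(0, 0, 0), c(1, 0.5, 0), c(2, -0.2, 1), c(3, 1, 0))
  v <- c(3, 1) / sqrt(10)
  expect_equal(unname(filament_polarity(bent)), v)
  # vertical filament has no projection
  expect_true(all(is.na(filament_polarity(cbind(0, 0, 0:3)))))
})

test_that("mode amplitudes reproduce the quadrature oracle for ideal fields", {
  for (state in c("aster", "semi-aster", "spindle", "nematic")) {
    oracle <- quadrature_modes(ideal_field_fun(state))
    field <- gen_ideal_field(state, n = 1e5)
    got <- mode_amplitudes(field, n_bins = 400)$Q
    expect_equal(got, oracle, tolerance = 1e-3,
                 label = sprintf("Q (binned, %s)", state))
  }
  # aster hits the closed form exactly
  expect_equal(quadrature_modes(ideal_field_fun("aster")), c(0, 1, 0, 0),
               tolerance = 1e-8)
  # (fields with jumps carry O(1/n) Riemann error, hence the 1e-5 tolerances)
  # semi-aster closed forms; Q2 by quadrature is 333/(1225 pi^2), not the
  # commonly printed 333/(1715 pi^2)
  semi <- quadrature_modes(ideal_field_fun("semi-aster"))
  expect_equal(semi[c(1, 2, 4)],
               c(9 / pi^2, 9 / (4 * pi^2), 9 / (100 * pi^2)),
               tolerance = 1e-5)
  expect_equal(semi[3], 333 / (1225 * pi^2), tolerance = 1e-5)
  expect_gt(abs(semi[3] - 333 / (1715 * pi^2)), 5e-3)
  # spindle by quadrature is exactly half the printed (Q1, Q3)
  spin <- quadrature_modes(ideal_field_fun("spindle"))
  expect_equal(spin, c(0, 1 / 4 + 1 / pi^2, 0, 1 / pi^2), tolerance = 1e-5)
})

test_that("mode amplitudes are invariant under global rotation", {
  rotate <- function(field, a) {
    dplyr::mutate(field,
      x2 = cos(a) * x - sin(a) * y, y2 = sin(a) * x + cos(a) * y,
      px2 = cos(a) * px - sin(a) * py, py2 = sin(a) * px + cos(a) * py,
      x = x2, y = y2, px = px2, py = py2
    )[, c("x", "y", "px", "py")]
  }
  # rotations by whole bins leave the binned estimate exactly invariant
  field <- gen_ideal_field("semi-aster", n = 2e4)
  q0 <- mode_amplitudes(field, n_bins = 40)$Q
  for (kbin in c(3, 11, -7)) {
    qr <- mode_amplitudes(rotate(field, kbin * 2 * pi / 40), n_bins = 40)$Q
    expect_equal(qr, q0, tolerance = 1e-6)
  }
  # arbitrary angles: invariant up to the binning resolution
  aster <- gen_ideal_field("aster", n = 4e4)
  qa <- mode_amplitudes(aster, n_bins = 40)$Q
  for (a in c(0.377, 1.7, -2.21)) {
    qr <- mode_amplitudes(rotate(aster, a), n_bins = 40)$Q
    expect_equal(qr, qa, tolerance = 1e-3)
  }
})

test_that("classification is a fixed point on its own targets and uses distance", {
  for (src in c("printed", "derived")) {
    tg <- ideal_state_targets(src)
    for (i in seq_len(nrow(tg))) {
      expect_identical(
        classify_state(as.numeric(tg[i, c("Q0", "Q1", "Q2", "Q3")]), tg),
        tg$state[i]
      )
    }
  }
  expect_identical(classify_state(c(0, 1, 0, 0)), "aster")
  expect_identical(classify_state(c(0, 0, 0, 0)), "nematic")
  # explicit distance comparison oracle for a mixed vector
  q <- c(0.9, 0.2, 0.02, 0.01)
  tg <- ideal_state_targets("printed")
  d <- apply(as.matrix(tg[, -1]), 1, function(t) sqrt(sum((t - q)^2)))
  expect_identical(tg$state[which.min(d)], "semi-aster")
  expect_identical(classify_state(q), "semi-aster")
  expect_error(classify_state(c(1, 0)), "4 components")
})

test_that("transverse velocity detects rigid rotation and ignores radial flow", {
  # counter-clockwise rigid ring: <(v x p)_z> = omega * r
  tr <- gen_rotating_ring(omega = 0.02, D_theta = 0, n = 40, frames = 60,
                          dt = 1, radius = 8)
  v <- transverse_velocity(tr)
  expect_equal(mean(v$v_trans), 0.02 * 8, tolerance = 1e-3)
  # clockwise: opposite sign
  trc <- gen_rotating_ring(omega = -0.02, D_theta = 0, n = 40, frames = 60,
                           dt = 1, radius = 8)
  expect_equal(mean(transverse_velocity(trc)$v_trans), -0.16, tolerance = 1e-3)

  # static configuration: exactly zero
  trs <- gen_rotating_ring(omega = 0, D_theta = 0, n = 20, frames = 10)
  expect_equal(max(abs(transverse_velocity(trs)$v_trans)), 0)

  # purely radial contraction of an aster: velocity parallel to polarity
  frames <- purrr::map_dfr(0:10, function(k) {
    r <- 10 - 0.2 * k
    th <- 2 * pi * (1:30) / 30
    tibble::tibble(time = k, filament = 1:30, x = r * cos(th),
                   y = r * sin(th), px = -cos(th), py = -sin(th))
  })
  expect_equal(max(abs(transverse_velocity(frames)$v_trans)), 0,
               tolerance = 1e-12)

  expect_error(transverse_velocity(frames[frames$time == 0, ]), "2 frames")
})

test_that("vorticity statistics implement |mu|/sigma with degenerate guard", {
  x <- c(-1, 3) # mean 1, sd sqrt(8)
  vs <- vorticity_stats(x)
  expect_equal(vs$V, 1 / sqrt(8))

  set.seed(2)
  big <- rnorm(4e4, mean = 1, sd = 2)
  expect_equal(vorticity_stats(big)$V, 0.5, tolerance = 0.02)

  expect_warning(vsc <- vorticity_stats(rep(2, 10)), "Inf")
  expect_true(is.infinite(vsc$V))

  set.seed(3)
  noise <- rnorm(1000)
  expect_lt(vorticity_stats(noise)$V, 0.2) # ~ n^-1/2, far below 0.7

  # series restricted to t <= t_cont: only the rotating segment enters,
  # and a constant segment is flagged as degenerate
  df <- tibble::tibble(time = 1:100, v_trans = c(rep(1, 50), rep(0, 50)))
  expect_warning(vs2 <- vorticity_stats(df, t_cont = 50), "Inf")
  expect_equal(vs2$mu, 1)
  vs3 <- vorticity_stats(df, t_cont = 100)
  expect_equal(vs3$mu, 0.5)
})

test_that("tanh contraction fit recovers parameters and flags flat series", {
  clean <- gen_tanh_radius(R_min = 30, dR = 10, t_cont = 5000,
                           dt_width = 500, t_end = 10000, n = 300, noise = 0)
  g <- glance(fit_contraction(clean))
  expect_equal(g$R_min, 30, tolerance = 1e-6)
  expect_equal(g$dR, 10, tolerance = 1e-6)
  expect_equal(g$t_cont, 5000, tolerance = 1e-6)
  expect_equal(g$dt_width, 500, tolerance = 1e-6)
  expect_true(g$contracted)

  # noisy recovery study: t_cont within +-100 across replicates
  errs <- vapply(1:25, function(k) {
    noisy <- gen_tanh_radius(R_min = 20, dR = -10, t_cont = 5000,
                             dt_width = 500, t_end = 10000, n = 200,
                             noise = 0.5, seed = k)
    glance(fit_contraction(noisy))$t_cont - 5000
  }, numeric(1))
  expect_lt(max(abs(errs)), 100)

  # monotone flat noise: no contraction, maximum-time assignment
  flat <- gen_tanh_radius(R_min = 30, dR = 0, t_cont = 5000, dt_width = 500,
                          t_end = 8000, n = 100, noise = 0.3, seed = 9)
  gf <- glance(fit_contraction(flat, t_max = 16000))
  expect_false(gf$contracted)
  expect_equal(gf$t_cont, 16000)

  expect_error(fit_contraction(clean[1:5, ]), "8 points")
})

test_that("MSAD separates ballistic rotation from angular diffusion", {
  # rigid rotation: msad = (omega dt)^2, slope 2; omega = 0.01, dt = 100 -> 1
  rot <- gen_rotating_ring(omega = 0.01, D_theta = 0, n = 30, frames = 101,
                           dt = 10)
  m <- msad(rot)
  expect_equal(m$slope, 2, tolerance = 0.01)
  row <- m$curve[abs(m$curve$dt - 100) < 1e-9, ]
  expect_equal(row$msad, 1, tolerance = 1e-9)

  # diffusion: msad = 2 D dt, slope 1
  dif <- gen_rotating_ring(omega = 0, D_theta = 5e-4, n = 400, frames = 80,
                           dt = 1, seed = 3)
  md <- msad(dif)
  expect_equal(md$slope, 1, tolerance = 0.1)
  mid <- md$curve[md$curve$dt == 20, ]
  expect_equal(mid$msad, 2 * 5e-4 * 20, tolerance = 0.15)

  # static frames: identically zero
  sta <- gen_rotating_ring(omega = 0, D_theta = 0, n = 10, frames = 10)
  expect_equal(max(msad(sta)$curve$msad), 0)

  # slope crosses from ~1 to ~2 as omega tau exceeds the diffusive scale
  slopes <- vapply(c(0, 2e-3, 0.05), function(om) {
    msad(gen_rotating_ring(omega = om, D_theta = 5e-4, n = 150, frames = 60,
                           dt = 1, seed = 4))$slope
  }, numeric(1))
  expect_true(all(diff(slopes) > 0))
  expect_lt(slopes[1], 1.2)
  expect_gt(slopes[3], 1.8)

  expect_error(msad(rot[rot$time == 0, ]), "2 frames")
})

test_that("angle unwrapping is continuous through the branch cut", {
  th <- unwrap_angle_oracle <- NULL
  tr <- gen_rotating_ring(omega = 0.5, D_theta = 0, n = 3, frames = 50, dt = 1)
  m <- msad(tr) # 0.5 rad/frame crosses +-pi repeatedly
  expect_equal(m$curve$msad[1], 0.25, tolerance = 1e-10)
  expect_equal(m$curve$msad[40], (0.5 * 40)^2, tolerance = 1e-6)
})

test_that("motor statistics count plus-end occupancy", {
  pos <- rbind(cbind(1:4, 0, 2), cbind(1:4, 1, 2))
  mo <- rbind(c(1L, 4L, 2L, 2L), # one head at the [+]-end (monomer M)
              c(1L, 2L, 2L, 2L),
              c(1L, 3L, 2L, 1L))
  st <- gel_state(pos, 2, 4, motors = mo)
  ms <- motor_statistics(st)
  expect_equal(ms$n_mot_per_filament, 1.5)
  expect_equal(ms$f_plus, 1 / 3)

  empty <- gel_state(pos, 2, 4)
  ms0 <- motor_statistics(empty)
  expect_equal(ms0$n_mot_per_filament, 0)
  expect_true(is.na(ms0$f_plus))
})

test_that("direction binomial test matches exact tail sums", {
  expect_equal(direction_binomial_test(10, 10)$p_value, 1)
  expect_equal(direction_binomial_test(12, 8)$p_value, 0.5034447,
               tolerance = 1e-6)
  expect_equal(direction_binomial_test(20, 0)$p_value, 2 * 0.5^20,
               tolerance = 1e-9)
})

test_that("the normal A2 statistic matches an independent implementation", {
  for (k in 1:5) {
    x <- gen_lifetime_sample("normal", mean = 10, sd = 2, n = 30, seed = k)
    ours <- tidy(lifetime_tests(x, n_boot = 10, seed = 1))
    theirs <- nortest::ad.test(x)$statistic
    expect_equal(ours$A2[ours$distribution == "normal"], unname(theirs),
                 tolerance = 1e-10)
  }
})

test_that("lifetime tests favour the generating distribution", {
  # exponential samples: exponential A2 below normal A2 in most replicates
  wins <- vapply(1:20, function(k) {
    x <- gen_lifetime_sample("exponential", mean = 1.7e4, n = 30, seed = k)
    tt <- tidy(lifetime_tests(x, n_boot = 50, seed = k))
    tt$A2[tt$distribution == "exponential"] < tt$A2[tt$distribution == "normal"]
  }, logical(1))
  expect_gt(mean(wins), 0.7)

  # and a normal sample is recognised as such
  x <- gen_lifetime_sample("normal", mean = 100, sd = 10, n = 40, seed = 5)
  tt <- tidy(lifetime_tests(x, n_boot = 400, seed = 2))
  expect_gt(tt$p_value[tt$distribution == "normal"], 0.05)

  expect_error(lifetime_tests(c(1, 2, 3)), "n >= 5")
})

test_that("bootstrap p-values are calibrated under the null", {
  # samples drawn from an exponential: p-values approximately uniform
  ps <- vapply(1:150, function(k) {
    x <- gen_lifetime_sample("exponential", mean = 50, n = 20, seed = 1000 + k)
    lifetime_tests(x, n_boot = 99, seed = k)$exponential$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("switching times are recovered from signed series", {
  # square wave of period 200: all intervals 100
  sq <- rep(rep(c(1, -1), each = 100), 5)
  sw <- switching_times(sq, window = 5)
  expect_true(all(abs(sw$intervals - 100) < 1e-9))

  # noisy telegraph: switch points recovered within half the window
  set.seed(6)
  true_switch <- c(300, 520, 940)
  sig <- rep(1, 1200)
  state <- 1
  last <- 1
  for (s in true_switch) {
    sig[last:(s - 1)] <- state
    state <- -state
    last <- s
  }
  sig[last:1200] <- state
  noisy <- sig + rnorm(1200, sd = 0.3)
  sw2 <- switching_times(noisy, window = 21)
  found <- sw2$switch_times
  expect_equal(length(found), 3)
  expect_true(all(abs(found - true_switch) < 21))

  # constant-sign series: no switches
  expect_equal(length(switching_times(rep(1, 100), window = 5)$intervals), 0)
  expect_error(switching_times(c(1, -1), window = 5), "longer")
})
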