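test_that("coom_series evaluates the offset model exactly and reproducibly", {
  # phi(s) = 2 * 0.5 * cos(s) = cos(s); amplitude 2, offset pi, t = 0 -> -2
  spec <- coom_spec(n = 2, offsets = c(pi, 0), amplitudes = c(2, 1),
                    duration = 200, dt = 0.5)
  rec <- coom_series(spec)
  expect_equal(unname(rec$values[1, 1]), 2 * cos(-pi))
  expect_equal(unname(rec$values[2, 1]), cos(0))
  # quarter-period delayed copy: channel 1 leads, a_12 > 0
  spec2 <- coom_spec(offsets = c(0, pi / 2), duration = 400)
  A <- lead_matrix(normalize(coom_series(spec2)))
  expect_gt(A[1, 2], 0)
  # seeded determinism
  sn <- coom_spec(offsets = c(0, 1), duration = 200, noise_sd = 0.3)
  expect_identical(coom_series(sn, seed = 9)$values, coom_series(sn, seed = 9)$values)
  expect_false(identical(coom_series(sn, seed = 9)$values,
                         coom_series(sn, seed = 10)$values))
  # snr definition: noise variance matches signal RMS^2 / snr
  clean <- coom_series(coom_spec(offsets = c(0, 1), duration = 864))$values
  noisy <- coom_series(coom_spec(offsets = c(0, 1), duration = 864, snr = 10),
                       seed = 3)$values
  expect_equal(stats::sd(noisy - clean), sqrt(mean(clean^2) / 10),
               tolerance = 0.05)
  expect_error(coom_spec(offsets = c(0, 1), duration = 50, omega = 2 * pi / 100),
               class = "cyclicity_error_bad_spec")
})

test_that("wave fields reduce to the chain of offsets", {
  # flat wave on collinear sensors: recovered order equals spatial order
  ws <- wave_spec(positions = c(0, 1, 2, 3, 4), delay = function(xi) 0.5 * xi,
                  omega = 2 * pi / 100)
  rec <- wave_series(ws, duration = 400)
  fit <- cyclicity(rec, keep_top = 5)
  expect_equal(fit$ordering$channel, paste0("s", 1:5))
  # constant delay: proportional channels, identically zero lead matrix
  wc <- wave_spec(positions = 1:4, delay = function(xi) 1.3)
  raw <- wave_series(wc, duration = 300)
  expect_identical(max(abs(lead_matrix(raw$values))), 0)
  # spherical wave: order follows distance from the excitation center
  pos <- rbind(c(0, 0.5), c(1.5, 0), c(0, 2.5), c(3.5, 0))
  wsph <- wave_spec(positions = pos, delay = function(xi) 0.6 * sqrt(sum(xi^2)))
  fit2 <- cyclicity(wave_series(wsph, duration = 400), keep_top = 4)
  expect_equal(fit2$ordering$channel, paste0("s", 1:4))
})

test_that("wave offsets match an equivalent coom_series", {
  delays <- c(0, 0.4, 0.9)
  ws <- wave_spec(positions = 1:3, delay = delays, omega = 2 * pi / 80)
  eq <- coom_spec(offsets = delays, omega = 2 * pi / 80, duration = 320,
                  dt = 0.72)
  expect_equal(unname(wave_series(ws, duration = 320)$values),
               unname(coom_series(eq)$values))
})

test_that("ripple trains recover order and ignore the length of calm intervals", {
  spec <- coom_spec(n = 4, offsets = c(0, 0.8, 1.6, 2.4),
                    seed_function = pulse_seed(0.5),
                    omega = 2 * pi / 50, duration = 720, dt = 0.72)
  # grid-aligned events so stretching rests preserves the sampling phase
  ev1 <- c(72, 216, 360)
  rec1 <- ripple_train(spec, ev1)
  fit <- cyclicity(rec1, keep_top = 4)
  expect_equal(fit$ordering$channel, paste0("ch", 1:4))
  # doubling the rest intervals leaves the lead matrix unchanged
  rec2 <- ripple_train(spec, c(72, 360, 648))
  A1 <- lead_matrix(rec1$values)
  A2 <- lead_matrix(rec2$values)
  expect_lt(max(abs(A1 - A2)), 1e-9)
  expect_error(ripple_train(spec, c(100, 101)),
               class = "cyclicity_error_overlapping_events")
  # no events: constant recording, degenerate downstream
  quiet <- ripple_train(spec, numeric(0))
  expect_true(all(quiet$values == 0))
  expect_error(normalize(quiet), class = "cyclicity_error_degenerate_channel")
})

test_that("block pairs encode the designed lead-lag sign structure", {
  alt <- block_design(rep(40, 8), rep_len(c(1L, -1L), 8), lag = 1.44)
  steady <- block_design(rep(40, 8), rep(1L, 8), lag = 1.44)
  b_alt <- pair_dynamics(block_pair(alt, snr = 10, seed = 2))$burstiness
  b_steady <- pair_dynamics(block_pair(steady, snr = 10, seed = 2))$burstiness
  expect_gt(b_alt, 5 * b_steady)
  # steady design: overall monotone accumulation
  tr <- pair_dynamics(block_pair(steady, seed = 2))$trajectory$values
  expect_gt(tr[length(tr)], 0.9 * max(tr))
  expect_error(block_pair(block_design(40, 1L, lag = 6), pulse_rate = 0.2),
               class = "cyclicity_error_bad_spec")
})

test_that("analytic lead matrix matches quadrature up to one calibrated constant", {
  offsets <- c(0, 0.7, 1.5, 2.2, 3.4)
  spec <- coom_spec(offsets = offsets, amplitudes = c(1, 2, 0.5, 1.5, 1),
                    omega = 2 * pi / 100, duration = 200)
  A <- analytic_lead_matrix(spec)
  oracle <- oracle_coom_lead(spec$amplitudes, offsets, spec$omega,
                             0, 100) # one period
  expect_lt(norm(unclass(A) - oracle, "F") / norm(oracle, "F"), 1e-4)
  # uncalibrated closed form agrees with the calibrated one
  A0 <- analytic_lead_matrix(spec, calibrate = FALSE)
  expect_lt(norm(unclass(A) - unclass(A0), "F") / norm(unclass(A0), "F"), 1e-4)
  # equal offsets: proportional signals, zero matrix
  z <- analytic_lead_matrix(coom_spec(n = 3, offsets = rep(1, 3), duration = 200))
  expect_equal(max(abs(z)), 0)
  # two harmonics: a sum of two rank-2 terms, numerical rank <= 4
  spec2 <- coom_spec(offsets = offsets,
                     seed_function = fourier_seed(c(0.5, 0.25)),
                     duration = 200)
  sv <- svd(unclass(analytic_lead_matrix(spec2)))$d
  expect_lt(sv[5] / sv[1], 1e-9)
  rec2 <- coom_series(spec2)
  svn <- svd(unclass(lead_matrix(rec2$values)))$d
  expect_lt(svn[5] / svn[1], 1e-3) # sampled series: rank 4 up to discretization
  expect_error(analytic_lead_matrix(
    coom_spec(n = 2, offsets = c(0, 1), seed_function = pulse_seed(1),
              duration = 100)),
    class = "cyclicity_error_pulse_seed")
})

test_that("monotone time warps change areas within the discretization bound", {
  spec <- coom_spec(offsets = c(0, pi / 2), omega = 2 * pi / 100,
                    duration = 400, dt = 0.1) # dense sampling
  rec <- coom_series(spec)
  dur <- max(frame_times(rec))
  warp <- function(t) dur * (t / dur + 0.15 * sin(pi * t / dur)^2)
  wrec <- warp_time(rec, warp)
  a0 <- oriented_area(rec$values[1, ], rec$values[2, ])
  a1 <- oriented_area(wrec$values[1, ], wrec$values[2, ])
  # conservative C1 bounds for the sampling perturbations of each channel
  Ck <- max(abs(rec$values[1, ])) + spec$omega * max(abs(rec$values[1, ]))
  Cl <- max(abs(rec$values[2, ])) + spec$omega * max(abs(rec$values[2, ]))
  expect_lt(abs(a1 - a0),
            discretization_error_bound(Ck, Cl, 0.1 * (1 + 0.15 * pi)))
  # cubic warp leaves the recovered ordering unchanged
  spec10 <- coom_spec(offsets = seq(0, by = pi / 10, length.out = 10L),
                      duration = 864)
  rec10 <- coom_series(spec10)
  dur10 <- max(frame_times(rec10))
  w10 <- warp_time(rec10, function(t) dur10 * (0.4 * (t / dur10)^3 +
                                               0.6 * (t / dur10)))
  expect_equal(cyclicity(w10, keep_top = 10)$ordering$channel,
               paste0("ch", 1:10))
})
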