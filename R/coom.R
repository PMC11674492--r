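#' Seed waveforms for the chain-of-offsets model
#'
#' The chain-of-offsets model (COOM) drives every channel with the same seed
#' waveform, offset by a channel-specific phase -- the signature of a
#' traveling wave read at fixed sensors. Two seed families are supported:
#' `fourier_seed(coefficients)` defines the periodic waveform
#' `phi(s) = sum_m 2 Re(c_m exp(i m s))` from complex Fourier coefficients
#' `c_m`, `m = 1..M`; `pulse_seed(width)` defines the solitary Gaussian bump
#' `phi(s) = exp(-(s / width)^2)` on the phase axis, used for ripple trains.
#'
#' @param coefficients complex (or numeric) vector of Fourier coefficients
#'   `c_1..c_M`.
#' @param width positive bump width in phase units.
#' @return a `"seed_function"` object.
#' @export
fourier_seed <- function(coefficients) {
  coefficients <- as.complex(coefficients)
  if (!length(coefficients) || !all(is.finite(Mod(coefficients))))
    stop_ca("cyclicity_error_bad_seed_function", "invalid Fourier coefficients")
  structure(list(type = "fourier", coefficients = coefficients),
            class = "seed_function")
}

#' @rdname fourier_seed
#' @export
pulse_seed <- function(width = 1) {
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0)
    stop_ca("cyclicity_error_bad_seed_function", "pulse width must be positive")
  structure(list(type = "pulse", width = width), class = "seed_function")
}

# evaluate the seed waveform at phase s
phi_eval <- function(sf, s) {
  switch(sf$type,
         fourier = {
           out <- numeric(length(s))
           for (m in seq_along(sf$coefficients))
             out <- out + 2 * Re(sf$coefficients[m] * exp(1i * m * s))
           out
         },
         pulse = exp(-(s / sf$width)^2),
         stop_ca("cyclicity_error_bad_seed_function", "unknown seed type"))
}

#' Chain-of-offsets model specification
#'
#' Describes the ground-truth generative model
#' `x_k(t) = a_k * phi(omega * t - alpha_k) + noise`: `n` channels share the
#' seed waveform `phi`, each delayed by its phase offset `alpha_k` (radians)
#' and scaled by its amplitude `a_k`. The offsets are the quantity the
#' analysis pipeline is supposed to recover (up to cyclic rotation), which is
#' what makes the simulator an oracle for every downstream stage.
#'
#' @param n number of channels (>= 2).
#' @param offsets phase offsets `alpha_k` in radians (length n).
#' @param amplitudes positive amplitudes `a_k` (recycled to length n).
#' @param seed_function a [fourier_seed()] or [pulse_seed()]; default a pure
#'   first harmonic.
#' @param omega angular frequency in rad/s; the default `2 * pi / 100`
#'   corresponds to a 0.01 Hz infraslow wave.
#' @param duration recording length in seconds (must cover at least one
#'   period for periodic seeds).
#' @param dt sampling interval in seconds (default the HCP repetition time
#'   0.72 s).
#' @param noise_sd additive white-noise standard deviation per frame.
#' @param snr if non-`NULL`, overrides `noise_sd` so that
#'   `(signal RMS / noise sd)^2 = snr`.
#' @param seed default RNG seed used by [coom_series()].
#' @return a `"coom_spec"` object.
#' @export
coom_spec <- function(n = length(offsets), offsets,
                      amplitudes = 1,
                      seed_function = fourier_seed(0.5),
                      omega = 2 * pi / 100,
                      duration = 864, dt = 0.72,
                      noise_sd = 0, snr = NULL, seed = 1L) {
  n <- as.integer(n)
  if (n < 2L) stop_ca("cyclicity_error_too_few_channels", "COOM needs n >= 2")
  offsets <- as.numeric(offsets)
  if (length(offsets) != n || !all(is.finite(offsets)))
    stop_ca("cyclicity_error_bad_spec", "need %d finite offsets", n)
  amplitudes <- rep_len(as.numeric(amplitudes), n)
  if (any(!is.finite(amplitudes)) || any(amplitudes <= 0))
    stop_ca("cyclicity_error_bad_spec", "amplitudes must be positive")
  if (!inherits(seed_function, "seed_function"))
    stop_ca("cyclicity_error_bad_seed_function",
            "`seed_function` must be a fourier_seed() or pulse_seed()")
  if (!is.finite(omega) || omega <= 0 || !is.finite(duration) || duration <= 0 ||
      !is.finite(dt) || dt <= 0)
    stop_ca("cyclicity_error_bad_spec", "omega, duration and dt must be positive")
  if (seed_function$type == "fourier" && duration < 2 * pi / omega)
    stop_ca("cyclicity_error_bad_spec",
            "duration %.3g s is shorter than one period (%.3g s)",
            duration, 2 * pi / omega)
  if (!is.null(snr) && (!is.finite(snr) || snr <= 0))
    stop_ca("cyclicity_error_bad_spec", "snr must be positive")
  structure(list(n = n, offsets = offsets, amplitudes = amplitudes,
                 seed_function = seed_function, omega = omega,
                 duration = duration, dt = dt,
                 noise_sd = as.numeric(noise_sd), snr = snr,
                 seed = seed),
            class = "coom_spec")
}

#' @export
print.coom_spec <- function(x, ...) {
  cat(sprintf("<coom_spec> n = %d, %s seed, omega = %.4g rad/s, %.4g s at dt = %.3g s\n",
              x$n, x$seed_function$type, x$omega, x$duration, x$dt))
  cat("  offsets:", format(x$offsets, digits = 3), "\n")
  invisible(x)
}

# add seeded white noise; sd chosen from snr if given
.with_noise <- function(clean, noise_sd, snr, seed) {
  if (!is.null(snr)) noise_sd <- sqrt(mean(clean^2)) / sqrt(snr)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed %||% 1L)
    clean <- clean + matrix(stats::rnorm(length(clean), sd = noise_sd),
                            nrow(clean), ncol(clean))
  }
  clean
}

#' Simulate a chain-of-offsets recording
#'
#' Samples `x_k(t_i) = a_k * phi(omega * t_i - alpha_k)` on the frame grid
#' `t_i = i * dt` and adds seeded white Gaussian noise. Identical spec and
#' seed give bit-identical output.
#'
#' @param spec a [coom_spec()].
#' @param seed RNG seed (defaults to the spec's own).
#' @param id recording identifier.
#' @return a [recording()] with channels `ch1..chn`.
#' @export
coom_series <- function(spec, seed = spec$seed, id = NULL) {
  if (!inherits(spec, "coom_spec"))
    stop_ca("cyclicity_error_bad_spec", "`spec` must be a coom_spec()")
  tt <- seq(0, by = spec$dt, length.out = floor(spec$duration / spec$dt + 1e-9))
  clean <- t(vapply(seq_len(spec$n), function(k) {
    spec$amplitudes[k] * phi_eval(spec$seed_function, spec$omega * tt - spec$offsets[k])
  }, numeric(length(tt))))
  vals <- .with_noise(clean, spec$noise_sd, spec$snr, seed)
  recording(vals, paste0("ch", seq_len(spec$n)), dt = spec$dt,
            id = id %||% sprintf("coom-n%d-seed%s", spec$n, format(seed)))
}

#' @export
simulate.coom_spec <- function(object, nsim = 1, seed = object$seed, ...) {
  lapply(seq_len(nsim), function(i)
    coom_series(object, seed = seed + i - 1L,
                id = sprintf("coom-n%d-seed%d", object$n, seed + i - 1L)))
}

#' Traveling-wave field specification
#'
#' A traveling wave `U(xi, t) = a(xi) * u(omega * t - h(xi))` read at a
#' finite set of sensor positions reduces exactly to a chain-of-offsets
#' model with offsets `alpha_k = h(xi_k)` (phase units of the waveform
#' argument): for a flat wave `h` is linear in position, for a spherical
#' wave it is the distance from the excitation center.
#'
#' @param positions sensor positions `xi_k` (numeric vector or matrix with
#'   one row per sensor).
#' @param amplitude site amplitude: function of position or numeric vector.
#' @param delay spatial delay function `h`: function of position or numeric
#'   vector, in phase units.
#' @param waveform waveform `u` as a function of phase; default cosine.
#' @param omega angular frequency (rad/s).
#' @return a `"wave_spec"` object.
#' @export
wave_spec <- function(positions, amplitude = 1, delay, waveform = cos,
                      omega = 2 * pi / 100) {
  pos <- if (is.matrix(positions)) positions else matrix(positions, ncol = 1L)
  n <- nrow(pos)
  if (n < 2L) stop_ca("cyclicity_error_too_few_channels", "need >= 2 sensors")
  evalsite <- function(f) {
    if (is.function(f)) apply(pos, 1L, f) else rep_len(as.numeric(f), n)
  }
  a <- evalsite(amplitude)
  h <- evalsite(delay)
  if (!all(is.finite(a)) || any(a <= 0))
    stop_ca("cyclicity_error_bad_spec", "site amplitudes must be positive")
  if (!all(is.finite(h)))
    stop_ca("cyclicity_error_bad_spec", "delays must be finite")
  if (!is.function(waveform))
    stop_ca("cyclicity_error_bad_spec", "`waveform` must be a function")
  structure(list(positions = pos, amplitudes = a, delays = h,
                 waveform = waveform, omega = omega),
            class = "wave_spec")
}

#' Simulate a traveling-wave recording
#'
#' @param spec a [wave_spec()].
#' @param duration,dt recording length and sampling interval in seconds.
#' @param noise_sd additive white-noise standard deviation.
#' @param seed RNG seed.
#' @return a [recording()]; sensor k is channel `s<k>`.
#' @export
wave_series <- function(spec, duration = 864, dt = 0.72, noise_sd = 0,
                        seed = 1L) {
  if (!inherits(spec, "wave_spec"))
    stop_ca("cyclicity_error_bad_spec", "`spec` must be a wave_spec()")
  tt <- seq(0, by = dt, length.out = floor(duration / dt + 1e-9))
  n <- nrow(spec$positions)
  clean <- t(vapply(seq_len(n), function(k) {
    spec$amplitudes[k] * spec$waveform(spec$omega * tt - spec$delays[k])
  }, numeric(length(tt))))
  vals <- .with_noise(clean, noise_sd, NULL, seed)
  recording(vals, paste0("s", seq_len(n)), dt = dt, id = "wave")
}

#' Simulate a solitary ripple train
#'
#' Emits the spec's pulse at each event time, lagged per channel by
#' `alpha_k / omega` seconds, with the network at rest between events. The
#' whole lead-lag formalism is insensitive to the length of the calm
#' intervals: stretching the rests leaves the lead matrix unchanged (exactly,
#' when event times stay on the frame grid).
#'
#' @param spec a [coom_spec()] with a [pulse_seed()].
#' @param event_times ripple onset times in seconds; events must not overlap
#'   after the per-channel lags. An empty list yields a constant resting
#'   recording (which [normalize()] rejects as degenerate).
#' @param rest_value baseline value between events (default 0).
#' @param seed RNG seed.
#' @return a [recording()].
#' @export
ripple_train <- function(spec, event_times, rest_value = 0, seed = spec$seed) {
  if (!inherits(spec, "coom_spec"))
    stop_ca("cyclicity_error_bad_spec", "`spec` must be a coom_spec()")
  if (spec$seed_function$type != "pulse")
    stop_ca("cyclicity_error_bad_seed_function",
            "ripple trains need a pulse-type seed function")
  event_times <- sort(as.numeric(event_times))
  w <- spec$seed_function$width
  support <- 2 * 4 * w / spec$omega +
    (max(spec$offsets) - min(spec$offsets)) / spec$omega
  if (length(event_times) > 1L && min(diff(event_times)) <= support)
    stop_ca("cyclicity_error_overlapping_events",
            "events closer than the pulse support (%.3g s)", support)
  tt <- seq(0, by = spec$dt, length.out = floor(spec$duration / spec$dt + 1e-9))
  clean <- matrix(rest_value, spec$n, length(tt))
  for (k in seq_len(spec$n)) {
    for (e in event_times) {
      s <- spec$omega * (tt - e) - spec$offsets[k]
      clean[k, ] <- clean[k, ] + spec$amplitudes[k] * phi_eval(spec$seed_function, s)
    }
  }
  vals <- .with_noise(clean, spec$noise_sd, spec$snr, seed)
  recording(vals, paste0("ch", seq_len(spec$n)), dt = spec$dt, id = "ripples")
}

#' Task block designs
#'
#' A block design partitions the session into contiguous blocks, each with a
#' lead-lag sign: `+1` means channel 1 leads during the block, `-1` means it
#' follows, `0` means rest (no events). [block_pair()] turns a design into a
#' two-channel recording whose oriented-area trajectory rises in `+1` blocks
#' and falls in `-1` blocks, so the persistent extrema sit at block
#' boundaries -- the synthetic analogue of task-locked lead-lag reversals.
#'
#' `social_task_design()` alternates the sign at the 38-s interval between
#' social-task segments over a full 1200-frame session;
#' `motor_task_design()` emulates the motor run's 13 blocks (10 movement
#' blocks of 12 s, each preceded by a 3-s cue, plus three 15-s fixations) as
#' 13 contiguous 15-s blocks of alternating sign; `rest_design()` is a
#' single steady block with no reversals.
#'
#' @param durations block lengths in seconds.
#' @param signs per-block lead-lag signs in `{-1, 0, 1}`.
#' @param lag lag magnitude delta in seconds by which channel 2 trails or
#'   precedes channel 1 (default two 0.72-s frames).
#' @param name design label.
#' @return a `"block_design"` object with `boundaries` (start times plus the
#'   end time), `signs`, `lag`, `name`.
#' @export
block_design <- function(durations, signs, lag = 2 * 0.72, name = "blocks") {
  durations <- as.numeric(durations)
  if (!length(durations) || any(!is.finite(durations)) || any(durations <= 0))
    stop_ca("cyclicity_error_bad_spec", "block durations must be positive")
  signs <- as.integer(signs)
  if (length(signs) != length(durations) || !all(signs %in% c(-1L, 0L, 1L)))
    stop_ca("cyclicity_error_bad_spec",
            "need one sign in {-1, 0, 1} per block")
  if (!is.finite(lag) || lag <= 0)
    stop_ca("cyclicity_error_bad_spec", "lag must be positive")
  structure(list(boundaries = c(0, cumsum(durations)), signs = signs,
                 lag = lag, name = name),
            class = "block_design")
}

#' @rdname block_design
#' @param duration total session length in seconds.
#' @param segment interval between task segments in seconds.
#' @export
social_task_design <- function(duration = 1200 * 0.72, segment = 38,
                               lag = 2 * 0.72) {
  nb <- ceiling(duration / segment)
  durations <- rep(segment, nb)
  durations[nb] <- duration - (nb - 1) * segment
  block_design(durations, rep_len(c(1L, -1L), nb), lag = lag, name = "social")
}

#' @rdname block_design
#' @export
motor_task_design <- function(lag = 2 * 0.72) {
  block_design(rep(15, 13), rep_len(c(1L, -1L), 13), lag = lag, name = "motor")
}

#' @rdname block_design
#' @export
rest_design <- function(duration = 1200 * 0.72, lag = 2 * 0.72) {
  block_design(duration, 1L, lag = lag, name = "rest")
}

#' @export
print.block_design <- function(x, ...) {
  cat(sprintf("<block_design> '%s': %d blocks over %.4g s, lag %.3g s, signs %s\n",
              x$name, length(x$signs), max(x$boundaries), x$lag,
              paste(x$signs, collapse = " ")))
  invisible(x)
}

#' Simulate a two-channel recording from a block design
#'
#' Channel 1 is a train of solitary Gaussian activity pulses; channel 2 is
#' the same train with each pulse shifted by `+lag` seconds in `+1` blocks
#' (channel 1 leads) and `-lag` in `-1` blocks (channel 2 leads); blocks with
#' sign 0 emit no pulses. The resulting oriented-area trajectory `a_12(t)`
#' increases during `+1` blocks and decreases during `-1` blocks, producing
#' persistent extrema at the block boundaries. Pulse times are a jittered
#' grid, seeded per recording: spontaneous activity events are not
#' phase-locked to the block schedule across recordings, and without the
#' jitter any common divisor of pulse spacing and block length would imprint
#' a spurious beat shared by every simulated pair. The task emulation
#' deliberately uses this lagged-pulse pair rather than a hemodynamic
#' forward model: the claims tested downstream (reversal timing, burstiness
#' contrast) depend only on the lead-lag sign structure.
#'
#' @param design a [block_design()].
#' @param pulse_rate pulses per second (default 0.2: one solitary activity
#'   pulse every 5 s on average).
#' @param dt sampling interval in seconds.
#' @param pulse_width Gaussian pulse width in seconds (default 1.5, so
#'   successive pulses are well separated and each block is a train of
#'   solitary ripples).
#' @param jitter uniform jitter half-width in seconds applied to each pulse
#'   time (default 1; set 0 for a strict grid).
#' @param noise_sd additive white-noise standard deviation.
#' @param snr if non-`NULL`, sets the noise so `(signal RMS / sd)^2 = snr`.
#' @param seed RNG seed (drives both the pulse jitter and the noise).
#' @return a two-channel [recording()] with labels `"lead"`, `"lag"`.
#' @export
block_pair <- function(design, pulse_rate = 0.2, dt = 0.72, pulse_width = 1.5,
                       jitter = 1, noise_sd = 0, snr = NULL, seed = 1L) {
  if (!inherits(design, "block_design"))
    stop_ca("cyclicity_error_bad_spec", "`design` must be a block_design()")
  spacing <- 1 / pulse_rate
  if (design$lag >= spacing)
    stop_ca("cyclicity_error_bad_spec",
            "lag (%.3g s) must be smaller than the pulse spacing (%.3g s)",
            design$lag, spacing)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed %||% 1L)
  total <- max(design$boundaries)
  tt <- seq(0, by = dt, length.out = floor(total / dt + 1e-9))
  centers <- seq(spacing / 2, total - spacing / 2, by = spacing)
  if (jitter > 0)
    centers <- centers + stats::runif(length(centers), -jitter, jitter)
  # sign of the block each pulse falls in
  blk <- findInterval(centers, design$boundaries, rightmost.closed = TRUE)
  s <- design$signs[blk]
  keep <- s != 0L
  centers <- centers[keep]; s <- s[keep]
  g <- function(u) exp(-(u / pulse_width)^2)
  x1 <- numeric(length(tt)); x2 <- numeric(length(tt))
  for (i in seq_along(centers)) {
    x1 <- x1 + g(tt - centers[i])
    x2 <- x2 + g(tt - centers[i] - s[i] * design$lag)
  }
  clean <- rbind(x1, x2)
  if (!is.null(snr)) noise_sd <- sqrt(mean(clean^2)) / sqrt(snr)
  vals <- clean
  if (noise_sd > 0)
    vals <- vals + matrix(stats::rnorm(length(clean), sd = noise_sd),
                          nrow(clean), ncol(clean))
  recording(vals, c("lead", "lag"), dt = dt,
            id = sprintf("%s-seed%s", design$name, format(seed)))
}

#' Analytic COOM lead matrix
#'
#' For a Fourier-seeded noiseless chain of offsets the lead matrix has the
#' closed form: entries proportional to
#' `a_k a_l sum_m m |c_m|^2 sin(m (alpha_l - alpha_k))`, a sum of rank-2
#' skew-symmetric matrices (one per harmonic). The overall positive constant
#' and sign convention are, by default, calibrated against direct quadrature
#' of the oriented-area integral on one densely sampled period, making this
#' an independent oracle for [lead_matrix()]. With `calibrate = FALSE` the
#' closed-form per-period constant `4 * pi` (for the convention
#' `phi(s) = sum_m 2 Re(c_m e^{i m s})`) is used.
#'
#' @param spec a [coom_spec()] with a [fourier_seed()] and no noise.
#' @param calibrate calibrate the scalar constant by quadrature (default
#'   `TRUE`).
#' @param n_quad samples per period used for the calibration quadrature.
#' @return a `"lead_matrix"`; areas are per period of the raw (unnormalized)
#'   signals.
#' @export
analytic_lead_matrix <- function(spec, calibrate = TRUE, n_quad = 4096L) {
  if (!inherits(spec, "coom_spec"))
    stop_ca("cyclicity_error_bad_spec", "`spec` must be a coom_spec()")
  if (spec$seed_function$type != "fourier")
    stop_ca("cyclicity_error_pulse_seed",
            "analytic lead matrix requires a Fourier-type seed function")
  cm <- spec$seed_function$coefficients
  a <- spec$amplitudes; al <- spec$offsets; n <- spec$n
  S <- matrix(0, n, n)
  for (m in seq_along(cm)) {
    dphase <- outer(al, al, function(x, y) sin(m * (y - x)))
    S <- S + m * Mod(cm[m])^2 * dphase
  }
  S <- S * outer(a, a)
  if (calibrate) {
    period <- 2 * pi / spec$omega
    tt <- seq(0, period, length.out = n_quad + 1L)
    X <- t(vapply(seq_len(n), function(k)
      a[k] * phi_eval(spec$seed_function, spec$omega * tt - al[k]),
      numeric(length(tt))))
    rownames(X) <- paste0("ch", seq_len(n))
    Anum <- lead_matrix(X)
    denom <- sum(S * S)
    kappa <- if (denom > 0) sum(unclass(Anum) * S) / denom else 0
    if (denom > 0 && kappa <= 0)
      stop_ca("cyclicity_error_bad_spec",
              "calibration produced a non-positive constant; sign convention violated")
    A <- kappa * S
  } else {
    A <- 4 * pi * S
  }
  dimnames(A) <- list(paste0("ch", seq_len(n)), paste0("ch", seq_len(n)))
  class(A) <- c("lead_matrix", "matrix", "array")
  A
}
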