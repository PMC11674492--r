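#' Fit a cyclicity analysis to a multichannel recording
#'
#' The full reparametrization-invariant lead-lag analysis in one call: the
#' recording is centered and energy-normalized, all pairwise oriented areas
#' are assembled into the skew-symmetric lead matrix, the constellation of a
#' leading eigenvector is extracted and oriented, an origin-centered ellipse
#' is fitted to it, channels are ranked by their elliptic norm (rank 1 = most
#' strongly swept by the dominant ripple), and the top-ranked channels are
#' ordered by phase -- the imputed order in which the traveling wave excites
#' them.
#'
#' @param x a [recording()], or a numeric matrix / data frame with channels
#'   in rows (a plain matrix is passed through [recording()]).
#' @param dt,id sampling interval and identifier, used when `x` is not
#'   already a recording.
#' @param pair_index which conjugate eigenvalue pair to analyze (1 = largest
#'   magnitude; 2 corresponds to the third eigenvalue in the
#'   all-eigenvalues convention).
#' @param keep_top how many top-ranked channels enter the phase ordering
#'   (default 20, capped at n; 24 is the common alternative cutoff).
#' @param normalize center and energy-normalize first (default `TRUE`; the
#'   standard pipeline).
#' @return An object of class `"cyclicity"`: a list with components
#'   `recording` (the normalized recording), `lead` ([lead_matrix()]),
#'   `spectrum` ([lead_eigen()]), `constellation`, `ellipse`, `ranking`,
#'   `ordering` ([phase_order()] of the kept channels), `dominance`
#'   (`|lambda_1|/|lambda_3|`, `NA` for n < 4), `pair_index`, `keep_top`,
#'   `call`.
#' @examples
#' spec <- coom_spec(offsets = seq(0, 0.9 * pi, length.out = 6),
#'                   duration = 300, snr = 20)
#' fit <- cyclicity(coom_series(spec))
#' fit
#' coef(fit)
#' @seealso [pair_dynamics()] for the time-resolved view of a single pair.
#' @export
cyclicity <- function(x, dt = 1, id = "recording", pair_index = 1L,
                      keep_top = 20L, normalize = TRUE) {
  rec <- if (inherits(x, "recording")) x else recording(x, dt = dt, id = id)
  nrec <- if (normalize && !inherits(rec, "normalized_recording"))
    normalize(rec) else rec
  A <- lead_matrix(nrec)
  spec <- lead_eigen(A)
  con <- leading_constellation(A, pair_index = pair_index)
  q <- fit_ellipse(con)
  ranking <- elliptic_rank(con, q)
  k <- min(as.integer(keep_top), n_channels(rec))
  kept <- ranking$channel[ranking$rank <= k]
  ordering <- phase_order(con, keep = kept)
  dom <- if (n_channels(rec) >= 4L) dominance_ratio(spec) else NA_real_
  structure(list(recording = nrec, lead = A, spectrum = spec,
                 constellation = con, ellipse = q, ranking = ranking,
                 ordering = ordering, dominance = dom,
                 pair_index = as.integer(pair_index), keep_top = k,
                 call = match.call()),
            class = "cyclicity")
}

#' @export
print.cyclicity <- function(x, ...) {
  cat(sprintf("Cyclicity analysis of '%s' (%d channels x %d frames)\n",
              x$recording$id, n_channels(x$recording), n_frames(x$recording)))
  cat(sprintf("  leading |lambda| = %.4g (pair %d); dominance |l1|/|l3| = %s\n",
              x$constellation$eigenvalue_magnitude, x$pair_index,
              if (is.na(x$dominance)) "NA" else format(x$dominance, digits = 4)))
  cat(sprintf("  imputed sweep order (top %d): %s\n", x$keep_top,
              paste(x$ordering$channel, collapse = " -> ")))
  invisible(x)
}

#' @export
summary.cyclicity <- function(object, ...) {
  structure(list(id = object$recording$id,
                 n = n_channels(object$recording),
                 T = n_frames(object$recording),
                 dt = object$recording$dt,
                 magnitudes = object$spectrum$magnitudes,
                 dominance = object$dominance,
                 degenerate_ellipse = object$ellipse$degenerate,
                 ranking = object$ranking[order(object$ranking$rank), ],
                 ordering = object$ordering,
                 keep_top = object$keep_top,
                 pair_index = object$pair_index),
            class = "summary.cyclicity")
}

#' @export
print.summary.cyclicity <- function(x, ...) {
  cat(sprintf("Cyclicity analysis of '%s': %d channels, %d frames (dt = %g s)\n",
              x$id, x$n, x$T, x$dt))
  cat("Eigenvalue magnitudes (per conjugate pair):\n  ")
  cat(format(utils::head(x$magnitudes, 6L), digits = 4), "\n")
  cat(sprintf("Dominance |lambda_1|/|lambda_3|: %s\n",
              if (is.na(x$dominance)) "NA (n < 4)" else format(x$dominance, digits = 4)))
  if (x$degenerate_ellipse)
    cat("Constellation ellipse fit was degenerate (eigenvalues clipped)\n")
  cat(sprintf("Top channels by elliptic rank (of %d kept):\n", x$keep_top))
  print(utils::head(x$ranking, min(10L, x$keep_top)), row.names = FALSE)
  cat("Imputed sweep order (ascending phase):\n  ")
  cat(paste(x$ordering$channel, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
coef.cyclicity <- function(object, ...) {
  stats::setNames(object$ordering$phase, object$ordering$channel)
}

#' @export
plot.cyclicity <- function(x, ...) {
  plot(x$constellation, q = x$ellipse, ...)
  invisible(x)
}

#' Time-resolved dynamics of one channel pair
#'
#' Computes the oriented-area trajectory of a channel pair of a (normalized)
#' recording, its persistent reversal events, and its burstiness. This is
#' the single-pair microscope behind the carpet and burstiness summaries:
#' steady trajectories mean a constant leader, near-zero fluctuation means a
#' synchronized (or independent) pair, and persistent direction changes mean
#' task-locked role reversals.
#'
#' @param x a [cyclicity()] fit or a [recording()].
#' @param pair two channel labels (or indices).
#' @param p number of longest-lived features kept for events.
#' @param n_bars bars summed by [burstiness()].
#' @param signed_mode `"both"` or `"f"` (see [reversal_events()]).
#' @return an object of class `"pair_dynamics"`: list with `trajectory`,
#'   `events`, `burstiness`, `pair`, `dt`.
#' @export
pair_dynamics <- function(x, pair = 1:2, p = 10L, n_bars = 10L,
                          signed_mode = c("both", "f")) {
  signed_mode <- match.arg(signed_mode)
  rec <- if (inherits(x, "cyclicity")) x$recording else x
  if (!inherits(rec, "normalized_recording")) rec <- normalize(rec)
  labels <- rec$channel_labels
  if (is.numeric(pair)) pair <- labels[pair]
  if (length(pair) != 2L || !all(pair %in% labels))
    stop_ca("cyclicity_error_bad_subset", "`pair` must name two channels")
  traj <- area_trajectory(rec$values[pair[1L], ], rec$values[pair[2L], ],
                          pair = pair)
  ev <- reversal_events(traj, p = p, signed_mode = signed_mode)
  structure(list(trajectory = traj, events = ev,
                 burstiness = burstiness(traj, n_bars = n_bars,
                                         signed_mode = signed_mode),
                 pair = pair, dt = rec$dt),
            class = "pair_dynamics")
}

#' @export
print.pair_dynamics <- function(x, ...) {
  v <- x$trajectory$values
  cat(sprintf("<pair_dynamics> %s vs %s: increment %.4g, burstiness %.4g, %d reversal features\n",
              x$pair[1L], x$pair[2L], v[length(v)], x$burstiness,
              nrow(x$events$features)))
  invisible(x)
}

#' @export
plot.pair_dynamics <- function(x, ...) {
  plot(x$trajectory, ...)
  fr <- reversal_frames(x$events, "min")
  if (length(fr))
    graphics::points(fr - 1L, x$trajectory$values[fr], col = "red", pch = 19)
  fr <- reversal_frames(x$events, "max")
  if (length(fr))
    graphics::points(fr - 1L, x$trajectory$values[fr], col = "blue", pch = 17)
  invisible(x)
}
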