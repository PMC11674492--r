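#' Multichannel recording
#'
#' A `recording` holds an n-channel real-valued time series (channels in rows,
#' frames in columns) together with channel labels, the sampling interval
#' `dt` (seconds), and an identifier. It is the container fed to
#' [lead_matrix()] and [cyclicity()]. The lead-lag machinery itself is
#' invariant under reparametrizations of the time axis, so `dt` is metadata
#' only: it is used to report reversal spacings and session durations in
#' seconds, never inside an oriented-area computation.
#'
#' @param values numeric matrix, n channels x T frames (n >= 2, T >= 3,
#'   all values finite).
#' @param channel_labels character vector of n unique labels; defaults to the
#'   rownames of `values` or `ch1..chn`.
#' @param dt sampling interval in seconds (> 0).
#' @param id recording identifier string.
#' @return An object of class `"recording"`: a list with elements `values`,
#'   `channel_labels`, `dt`, `id`.
#' @seealso [read_recording()], [normalize()], [lead_matrix()]
#' @examples
#' rec <- recording(rbind(sin(1:100 / 5), cos(1:100 / 5)), c("a", "b"), dt = 0.72)
#' rec
#' @export
recording <- function(values, channel_labels = NULL, dt = 1, id = "recording") {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop_ca("cyclicity_error_bad_values", "`values` must be a numeric matrix")
  n <- nrow(values)
  T <- ncol(values)
  if (n < 2L)
    stop_ca("cyclicity_error_too_few_channels", "need at least 2 channels, got %d", n)
  if (T < 3L)
    stop_ca("cyclicity_error_too_few_frames", "need at least 3 frames, got %d", T)
  if (!all(is.finite(values)))
    stop_ca("cyclicity_error_non_finite", "recording contains non-finite values")
  if (is.null(channel_labels)) channel_labels <- rownames(values)
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(n))
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != n)
    stop_ca("cyclicity_error_label_length",
            "got %d labels for %d channels", length(channel_labels), n)
  if (anyNA(channel_labels) || any(!nzchar(channel_labels)))
    stop_ca("cyclicity_error_missing_labels", "channel labels must be non-empty")
  if (anyDuplicated(channel_labels))
    stop_ca("cyclicity_error_duplicate_labels", "duplicate channel labels: %s",
            paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop_ca("cyclicity_error_bad_dt", "`dt` must be a single positive number")
  dimnames(values) <- list(channel_labels, NULL)
  structure(list(values = values, channel_labels = channel_labels,
                 dt = as.numeric(dt), id = as.character(id)),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<%s> '%s': %d channels x %d frames, dt = %g s (%.2f s total)\n",
              paste(class(x), collapse = "/"), x$id,
              n_channels(x), n_frames(x), x$dt, duration(x)))
  invisible(x)
}

#' Recording accessors
#'
#' `n_channels()` and `n_frames()` return the dimensions, `duration()` the
#' total session span `T * dt` in seconds (so a 1200-frame recording at
#' TR = 0.72 s spans 864 s; the interval between the first and last sample is
#' `(T - 1) * dt`), and `frame_times()` the sample times `(0:(T-1)) * dt`.
#'
#' @param rec a [recording()].
#' @return scalar or numeric vector.
#' @export
n_channels <- function(rec) nrow(rec$values)

#' @rdname n_channels
#' @export
n_frames <- function(rec) ncol(rec$values)

#' @rdname n_channels
#' @export
duration <- function(rec) n_frames(rec) * rec$dt

#' @rdname n_channels
#' @export
frame_times <- function(rec) (seq_len(n_frames(rec)) - 1) * rec$dt

#' Read a recording from delimited text
#'
#' The expected dialect is one header row of channel labels followed by one
#' row per frame (frames in rows, channels in columns, as parcellated fMRI
#' tables are usually exported); the matrix is transposed to channels x frames
#' internally. The delimiter (comma or tab) is auto-detected from the header
#' row. Validation is strict: missing or duplicate labels, ragged rows,
#' non-numeric cells and too-short series each raise a distinct classed error
#' rather than being silently repaired, because a silently imputed cell would
#' corrupt every oriented area downstream.
#'
#' @param path path to a UTF-8 CSV/TSV file.
#' @param dt sampling interval in seconds.
#' @param id recording identifier; defaults to the file name.
#' @return a validated [recording()].
#' @export
read_recording <- function(path, dt = 1, id = NULL) {
  if (!file.exists(path))
    stop_ca("cyclicity_error_missing_file", "no such file: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")] # provenance/comment lines
  if (length(lines) < 2L)
    stop_ca("cyclicity_error_too_few_frames", "file has no data rows: %s", path)
  sep <- if (lengths(strsplit(lines[1L], "\t", fixed = TRUE)) >=
             lengths(strsplit(lines[1L], ",", fixed = TRUE))) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  labels <- trimws(fields[[1L]])
  n <- length(labels)
  if (any(!nzchar(labels)))
    stop_ca("cyclicity_error_missing_labels", "empty channel label in header of %s", path)
  if (anyDuplicated(labels))
    stop_ca("cyclicity_error_duplicate_labels", "duplicate channel labels: %s",
            paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (!anyNA(suppressWarnings(as.numeric(labels))))
    stop_ca("cyclicity_error_missing_labels",
            "header row of %s looks numeric; expected channel labels", path)
  body <- fields[-1L]
  bad <- which(lengths(body) != n)
  if (length(bad))
    stop_ca("cyclicity_error_ragged_rows",
            "row %d has %d cells, expected %d", bad[1L] + 1L, lengths(body)[bad[1L]], n)
  vals <- suppressWarnings(as.numeric(unlist(body, use.names = FALSE)))
  if (anyNA(vals)) {
    flat <- unlist(body, use.names = FALSE)
    first <- which(is.na(suppressWarnings(as.numeric(flat))))[1L]
    stop_ca("cyclicity_error_non_numeric",
            "non-numeric cell '%s' at row %d, column %d",
            flat[first], (first - 1L) %/% n + 2L, (first - 1L) %% n + 1L)
  }
  m <- matrix(vals, nrow = n, ncol = length(body)) # frames in columns
  recording(m, labels, dt = dt, id = id %||% basename(path))
}

#' Center and energy-normalize a recording
#'
#' Each channel is centered (time average set to zero) and divided by the
#' square root of its quadratic variation, the sum of squared successive
#' differences, so every channel leaves with unit quadratic variation.
#' This energy normalization puts channels of different amplitude on a common
#' scale before oriented areas are compared across pairs; it maps
#' `c * x + b` to `sign(c) * normalize(x)` and is idempotent. Dividing by the
#' quadratic variation itself (not its square root) is available via
#' `divisor = "qv"` for callers that prefer that reading.
#'
#' @param x a [recording()].
#' @param divisor `"sqrt_qv"` (default; output has unit quadratic variation)
#'   or `"qv"`.
#' @param ... unused.
#' @return an object of class `c("normalized_recording", "recording")`.
#' @export
normalize <- function(x, ...) UseMethod("normalize")

#' @rdname normalize
#' @export
normalize.recording <- function(x, divisor = c("sqrt_qv", "qv"), ...) {
  divisor <- match.arg(divisor)
  v <- x$values - rowMeans(x$values)
  qv <- rowSums(t(diff(t(v)))^2)
  if (any(qv <= 0)) {
    bad <- x$channel_labels[which(qv <= 0)[1L]]
    stop_ca("cyclicity_error_degenerate_channel",
            "channel '%s' is constant (zero quadratic variation)", bad)
  }
  v <- v / if (divisor == "sqrt_qv") sqrt(qv) else qv
  out <- recording(v, x$channel_labels, dt = x$dt, id = x$id)
  class(out) <- c("normalized_recording", "recording")
  out
}

#' Resample a recording along a warped time axis
#'
#' Applies a strictly increasing, endpoint-fixing map of `[0, duration]` to
#' the sample times and re-reads the linear interpolation of each channel at
#' the warped times (same number of frames). Oriented areas are invariants of
#' the underlying curve, so a warp changes them only through the
#' discretization error bounded by [discretization_error_bound()]; this
#' function exists to exercise that invariance.
#'
#' @param rec a [recording()].
#' @param warp vectorized monotone function mapping `[0, duration - dt]`
#'   onto itself (frame times run from 0 to `(T-1) * dt`).
#' @return a [recording()] with the same dimensions.
#' @export
warp_time <- function(rec, warp) {
  tt <- frame_times(rec)
  wt <- warp(tt)
  if (!is.numeric(wt) || length(wt) != length(tt) || !all(is.finite(wt)))
    stop_ca("cyclicity_error_bad_warp", "warp must return finite times for every frame")
  if (any(diff(wt) <= 0))
    stop_ca("cyclicity_error_bad_warp", "warp must be strictly increasing")
  tol <- 1e-8 * max(tt[length(tt)], 1)
  if (abs(wt[1L] - tt[1L]) > tol || abs(wt[length(wt)] - tt[length(tt)]) > tol)
    stop_ca("cyclicity_error_bad_warp", "warp must fix the endpoints of the recording")
  v <- t(apply(rec$values, 1L, function(ch) stats::approx(tt, ch, xout = wt)$y))
  recording(v, rec$channel_labels, dt = rec$dt, id = paste0(rec$id, "+warped"))
}
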