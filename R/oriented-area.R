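#' Oriented area of a pair of time series
#'
#' The oriented (algebraic) area is the level-2 iterated path integral
#' \deqn{a_{kl} = \tfrac12 \oint (x\,dy - y\,dx),}
#' the signed area encircled by the parametric plot of the two series. For
#' the linearly interpolated discrete curve this is computed exactly by the
#' left-endpoint shoelace sum
#' \deqn{\tfrac12 \sum_i \big(x_i\,\Delta y_i - y_i\,\Delta x_i\big),}
#' so no quadrature choice remains open. A positive value is the heuristic
#' signature of `x` leading `y` (a delayed copy of `x` traces the loop
#' counterclockwise); proportional signals and signals with non-overlapping
#' time supports give exactly zero. The formula involves no time stamps,
#' which is what makes the quantifier invariant under monotone
#' reparametrizations of the time axis.
#'
#' @param x,y numeric vectors of equal length (>= 2), finite.
#' @return scalar oriented area.
#' @examples
#' t <- seq(0, 2 * pi, length.out = 1001)
#' oriented_area(cos(t), sin(t)) # ~ pi: counterclockwise unit circle
#' @export
oriented_area <- function(x, y) {
  sum(.oa_terms(x, y))
}

# shared increment terms; validates both series
.oa_terms <- function(x, y) {
  if (length(x) != length(y))
    stop_ca("cyclicity_error_length_mismatch",
            "series have lengths %d and %d", length(x), length(y))
  if (length(x) < 2L)
    stop_ca("cyclicity_error_too_few_frames", "need at least 2 samples")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_ca("cyclicity_error_non_finite", "series contain non-finite values")
  T <- length(x)
  0.5 * (x[-T] * diff(y) - y[-T] * diff(x))
}

#' Oriented-area trajectory
#'
#' Evaluates the oriented area on the expanding windows `[frame 1, frame t]`,
#' turning the single-number quantifier into a function of time: the running
#' balance of the leader-follower relationship. Its overall increment is the
#' lead-matrix entry; how that increment is reached (steadily, near zero, or
#' punctuated by direction reversals) is the raw material for
#' [reversal_events()] and [burstiness()].
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @param pair character pair of labels, stored for reporting.
#' @return an object of class `"area_trajectory"`: list with `values`
#'   (length `T`, starting at 0, ending at [oriented_area()]) and `pair`.
#' @export
area_trajectory <- function(x, y, pair = c("x", "y")) {
  structure(list(values = c(0, cumsum(.oa_terms(x, y))),
                 pair = as.character(pair)),
            class = "area_trajectory")
}

#' @export
print.area_trajectory <- function(x, ...) {
  v <- x$values
  cat(sprintf("<area_trajectory> %s vs %s: %d frames, increment %.4g, range [%.4g, %.4g]\n",
              x$pair[1L], x$pair[2L], length(v), v[length(v)], min(v), max(v)))
  invisible(x)
}

#' @export
plot.area_trajectory <- function(x, ...) {
  graphics::plot(seq_along(x$values) - 1L, x$values, type = "l",
                 xlab = "frame", ylab = expression(a[kl](t)),
                 main = sprintf("%s vs %s", x$pair[1L], x$pair[2L]), ...)
  invisible(x)
}

#' Lead matrix of a recording
#'
#' Arranges all pairwise oriented areas into the skew-symmetric n x n lead
#' matrix `A = (a_kl)`, the collective summary of the leader-follower
#' structure whose spectral decomposition drives the rest of the pipeline.
#' The full analysis pipeline computes it on a centered, energy-normalized
#' recording (see [normalize()]); the function accepts any recording or plain
#' channels-by-frames matrix since the oracle checks in the package compare
#' raw-signal areas against closed forms.
#'
#' @param rec a [recording()] (normalized or not) or a numeric matrix with
#'   channels in rows.
#' @return an object of class `"lead_matrix"`: the skew-symmetric numeric
#'   matrix with channel labels as dimnames.
#' @export
lead_matrix <- function(rec) {
  if (inherits(rec, "recording")) {
    X <- rec$values
  } else if (is.matrix(rec) && is.numeric(rec)) {
    X <- rec
  } else {
    stop_ca("cyclicity_error_bad_values", "`rec` must be a recording or numeric matrix")
  }
  if (!all(is.finite(X)))
    stop_ca("cyclicity_error_non_finite", "recording contains non-finite values")
  T <- ncol(X)
  if (T < 2L) stop_ca("cyclicity_error_too_few_frames", "need at least 2 frames")
  P <- X[, -T, drop = FALSE]
  D <- X[, -1L, drop = FALSE] - P
  C <- tcrossprod(P, D)        # C[k,l] = sum_i x_k[i] * dx_l[i]
  A <- 0.5 * (C - t(C))        # exactly skew-symmetric, zero diagonal
  labels <- rownames(X) %||% paste0("ch", seq_len(nrow(X)))
  dimnames(A) <- list(labels, labels)
  class(A) <- c("lead_matrix", "matrix", "array")
  A
}

#' @export
print.lead_matrix <- function(x, ...) {
  cat(sprintf("<lead_matrix> %d x %d, max |a_kl| = %.4g\n", nrow(x), ncol(x),
              max(abs(x))))
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))], ...)
  if (nrow(x) > 6L) cat(sprintf("... (%d more channels)\n", nrow(x) - 6L))
  invisible(x)
}

#' Discretization error bound for oriented areas
#'
#' If the continuous signals are perturbed by terms whose C^1 norms are
#' bounded by `C_k` and `C_l` and which vanish at the sampling points spaced
#' `delta` apart, the oriented area moves by at most `2 * C_k * C_l * delta`.
#' The bound is linear in the step, which is what justifies replacing the
#' integrals by shoelace sums on densely sampled data.
#'
#' @param C_k,C_l positive bounds on the C^1 norms of the perturbations of
#'   the two channels (signal units).
#' @param delta positive discretization step (time units).
#' @return the scalar bound.
#' @export
discretization_error_bound <- function(C_k, C_l, delta) {
  vals <- c(C_k = C_k, C_l = C_l, delta = delta)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop_ca("cyclicity_error_bad_bound_inputs",
            "C_k, C_l and delta must all be strictly positive")
  2 * C_k * C_l * delta
}
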