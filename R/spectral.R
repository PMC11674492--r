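#' Spectral decomposition of a lead matrix
#'
#' A real skew-symmetric matrix has purely imaginary eigenvalues in conjugate
#' pairs `+/- i lambda_s` with complex-conjugate eigenvectors. The
#' decomposition is computed through the Hermitian matrix `i A` (so the
#' spectrum is exactly real by construction and the work is done by the
#' symmetric eigensolver), and one representative eigenvector is kept per
#' conjugate pair. How fast the magnitudes `|lambda_1| >= |lambda_2| >= ...`
#' decay measures how well the recording is explained by a small number of
#' propagating ripples: a single noiseless chain-of-offsets wave gives a
#' rank-2 matrix with one nonzero pair.
#'
#' @param A a [lead_matrix()] or skew-symmetric numeric matrix.
#' @param tol relative tolerance for the skew-symmetry check.
#' @return an object of class `"lead_spectrum"`: list with
#'   `magnitudes` (one `|lambda|` per conjugate pair, non-increasing;
#'   `ceiling(n/2)` entries, the last one 0 for odd n),
#'   `vectors` (complex n x npair matrix, column s an eigenvector for
#'   eigenvalue `-i * magnitudes[s]`), `labels`, `n`.
#' @export
lead_eigen <- function(A, tol = 1e-9) {
  A <- .check_skew(A, tol)
  n <- nrow(A)
  e <- eigen(1i * A, symmetric = TRUE) # values mu (real, decreasing); A v = -i mu v
  npair <- ceiling(n / 2)
  structure(list(magnitudes = pmax(e$values[seq_len(npair)], 0),
                 vectors = e$vectors[, seq_len(npair), drop = FALSE],
                 labels = rownames(A) %||% paste0("ch", seq_len(n)),
                 n = n),
            class = "lead_spectrum")
}

.check_skew <- function(A, tol = 1e-9) {
  if (!is.matrix(A) || !is.numeric(unclass(A)) || nrow(A) != ncol(A))
    stop_ca("cyclicity_error_bad_values", "`A` must be a square numeric matrix")
  A <- unclass(A)
  scale <- max(abs(A))
  if (scale > 0 && max(abs(A + t(A))) > tol * scale)
    stop_ca("cyclicity_error_not_skew",
            "matrix is not skew-symmetric within relative tolerance %g", tol)
  0.5 * (A - t(A))
}

#' @export
print.lead_spectrum <- function(x, ...) {
  cat(sprintf("<lead_spectrum> n = %d, %d conjugate pairs\n", x$n,
              length(x$magnitudes)))
  cat("  |lambda|:", format(utils::head(x$magnitudes, 5L), digits = 4), "\n")
  invisible(x)
}

#' Spectral dominance ratio |lambda_1| / |lambda_3|
#'
#' Conjugate pairs are counted once, so the second distinct magnitude is the
#' third eigenvalue in the all-eigenvalues convention (`lambda_2` being the
#' conjugate partner of `lambda_1`); the ratio measures the dominance of the
#' rank-2 approximation of the lead matrix. A ratio much greater than 1 says
#' a single traveling ripple explains most of the temporal ordering.
#'
#' @param d a [lead_eigen()] decomposition, [lead_matrix()], or skew matrix.
#' @return `|lambda_1| / |lambda_3|`; `Inf` when `|lambda_3|` vanishes
#'   relative to `|lambda_1|` (exact rank-2 input).
#' @export
dominance_ratio <- function(d) {
  if (!inherits(d, "lead_spectrum")) d <- lead_eigen(d)
  if (d$n < 4L)
    stop_ca("cyclicity_error_too_few_channels",
            "dominance ratio needs at least 4 channels, got %d", d$n)
  m <- d$magnitudes
  if (m[2L] <= 1e-12 * m[1L]) Inf else m[1L] / m[2L]
}

#' Constellation of a leading eigenvector
#'
#' The components of an eigenvector of the chosen `+/- i |lambda|` pair,
#' viewed as labeled points in the complex plane. Under the chain-of-offsets
#' model the cyclic order of their arguments reproduces the order in which
#' the channels are swept by the traveling wave. The conjugate-pair ambiguity
#' (which of the two mirror-image constellations to report) is resolved with
#' the most confident leader-follower pair: for the reference pair
#' `(k*, l*) = argmax |a_kl|`, the signed angle from point `k*` to point `l*`
#' must have the same sign as `a_{k*l*}`, i.e. leaders precede followers
#' counterclockwise. The operation is deterministic: ties in `|a_kl|` are
#' broken lexicographically and reference pairs with an ill-defined angle
#' (a component at the origin, or an angle of exactly 0 or pi) are skipped
#' in favor of the next largest entry.
#'
#' @param A a [lead_matrix()].
#' @param pair_index which conjugate pair to use (1 = largest magnitude).
#' @param tol relative tolerance for the skew-symmetry check.
#' @return an object of class `"constellation"`: list with `points` (named
#'   complex vector, unit Euclidean norm), `eigenvalue_magnitude`,
#'   `pair_index`, `orientation_reference` (the label pair used).
#' @export
leading_constellation <- function(A, pair_index = 1L, tol = 1e-9) {
  spec <- if (inherits(A, "lead_spectrum")) A else lead_eigen(A, tol = tol)
  if (inherits(A, "lead_spectrum"))
    stop_ca("cyclicity_error_bad_values",
            "pass the lead matrix itself: the orientation rule needs its entries")
  A <- .check_skew(A, tol)
  m <- spec$magnitudes
  nonzero <- sum(m > 1e-12 * max(m, 0))
  if (nonzero == 0L)
    stop_ca("cyclicity_error_zero_matrix",
            "lead matrix has no nonzero eigenvalue pair")
  if (pair_index < 1L || pair_index > nonzero)
    stop_ca("cyclicity_error_bad_pair_index",
            "pair_index %d exceeds the %d nonzero pairs", pair_index, nonzero)
  v <- spec$vectors[, pair_index]
  names(v) <- spec$labels
  v <- v / sqrt(sum(Mod(v)^2))

  # candidate reference pairs (k < l), strongest |a_kl| first, lexicographic ties
  ut <- which(upper.tri(A), arr.ind = TRUE)
  ord <- order(-abs(A[ut]), ut[, 1L], ut[, 2L])
  ref <- NULL
  for (i in ord) {
    k <- ut[i, 1L]; l <- ut[i, 2L]
    if (abs(A[k, l]) <= 0) break
    if (Mod(v[k]) < 1e-12 || Mod(v[l]) < 1e-12) next
    ang <- Arg(v[l] / v[k])
    if (abs(ang) < 1e-12 || abs(abs(ang) - pi) < 1e-12) next
    ref <- c(k, l)
    if (sign(ang) != sign(A[k, l])) v <- Conj(v)
    break
  }
  if (is.null(ref))
    stop_ca("cyclicity_error_zero_matrix",
            "no reference pair with a well-defined phase shift")
  structure(list(points = v,
                 eigenvalue_magnitude = m[pair_index],
                 pair_index = as.integer(pair_index),
                 orientation_reference = spec$labels[ref]),
            class = "constellation")
}

#' @export
print.constellation <- function(x, ...) {
  cat(sprintf(
    "<constellation> pair %d, |lambda| = %.4g, %d points, oriented by (%s, %s)\n",
    x$pair_index, x$eigenvalue_magnitude, length(x$points),
    x$orientation_reference[1L], x$orientation_reference[2L]))
  invisible(x)
}

#' @export
plot.constellation <- function(x, q = NULL, labels = TRUE, ...) {
  p <- x$points
  lim <- max(Mod(p)) * 1.15
  graphics::plot(Re(p), Im(p), xlim = c(-lim, lim), ylim = c(-lim, lim),
                 xlab = "Re", ylab = "Im", asp = 1,
                 main = sprintf("constellation (pair %d)", x$pair_index), ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  if (labels)
    graphics::text(Re(p), Im(p), names(p), pos = 3, cex = 0.7, col = "grey40")
  if (!is.null(q)) {
    th <- seq(0, 2 * pi, length.out = 361)
    # unit level set of q: radial scaling of the unit circle
    r <- 1 / sqrt(q$a * cos(th)^2 + 2 * q$b * cos(th) * sin(th) + q$c * sin(th)^2)
    graphics::lines(r * cos(th), r * sin(th), col = "red")
  }
  invisible(x)
}

#' Fit the constellation ellipse
#'
#' Fits an origin-centered positive-definite quadratic form
#' `q(z) = a x^2 + 2 b x y + c y^2` whose unit level set is the constellation
#' ellipse, by linear least squares on `q(z_i) = 1` with design columns
#' `(x_i^2, 2 x_i y_i, y_i^2)` (deterministic, no iteration). If the
#' minimizer is not positive definite (points collinear with the origin),
#' the eigenvalues of the 2x2 form matrix are clipped at
#' `1e-6 * max(eigenvalue)` (or at `1e-6` when both are non-positive) and
#' the result is flagged degenerate.
#'
#' @param points complex vector of constellation points, or a
#'   [leading_constellation()] object.
#' @return an object of class `"quadratic_form"`: list with `a`, `b`, `c`,
#'   `degenerate` (logical).
#' @export
fit_ellipse <- function(points) {
  if (inherits(points, "constellation")) points <- points$points
  if (!is.complex(points)) points <- as.complex(points)
  if (length(points) < 3L)
    stop_ca("cyclicity_error_too_few_points",
            "ellipse fit needs at least 3 points, got %d", length(points))
  if (all(Mod(points) < 1e-300))
    stop_ca("cyclicity_error_degenerate_points", "all points are at the origin")
  X <- Re(points); Y <- Im(points)
  M <- cbind(X^2, 2 * X * Y, Y^2)
  beta <- qr.coef(qr(M), rep(1, length(points)))
  beta[is.na(beta)] <- 0
  FM <- matrix(c(beta[1L], beta[2L], beta[2L], beta[3L]), 2L)
  ev <- eigen(FM, symmetric = TRUE)
  degenerate <- FALSE
  if (min(ev$values) <= 0) {
    degenerate <- TRUE
    eps <- 1e-6 * if (max(ev$values) > 0) max(ev$values) else 1
    FM <- ev$vectors %*% diag(pmax(ev$values, eps)) %*% t(ev$vectors)
  }
  structure(list(a = FM[1L, 1L], b = FM[1L, 2L], c = FM[2L, 2L],
                 degenerate = degenerate),
            class = "quadratic_form")
}

#' @export
print.quadratic_form <- function(x, ...) {
  cat(sprintf("<quadratic_form> q(z) = %.4g x^2 + 2(%.4g) xy + %.4g y^2%s\n",
              x$a, x$b, x$c, if (x$degenerate) " [degenerate, clipped]" else ""))
  invisible(x)
}

#' Elliptic norm of complex points
#'
#' @param z complex vector.
#' @param q a [fit_ellipse()] quadratic form.
#' @return `sqrt(q(z))` per point: the distance in the metric whose unit ball
#'   is the constellation ellipse.
#' @export
elliptic_norm <- function(z, q) {
  x <- Re(z); y <- Im(z)
  val <- q$a * x^2 + 2 * q$b * x * y + q$c * y^2
  sqrt(pmax(val, 0))
}

#' Rank channels by elliptic norm
#'
#' Orders the constellation points by their distance from the origin in the
#' metric of the fitted constellation ellipse: rank 1 is the point with the
#' largest norm, i.e. the channel most strongly driven by the ripple the
#' chosen eigenvector captures. Channels whose components cluster near the
#' origin (not reached by the wave) receive high ranks. Ties are broken by
#' channel label order.
#'
#' @param points named complex vector or a [leading_constellation()].
#' @param q a positive-definite [fit_ellipse()] quadratic form.
#' @return an object of class `"elliptic_ranking"`: data frame with columns
#'   `channel`, `norm`, `rank`, in channel order.
#' @export
elliptic_rank <- function(points, q) {
  if (inherits(points, "constellation")) points <- points$points
  if (q$a <= 0 || q$a * q$c - q$b^2 <= 0)
    stop_ca("cyclicity_error_not_positive_definite",
            "quadratic form is not positive definite")
  labels <- names(points) %||% paste0("ch", seq_along(points))
  norms <- elliptic_norm(points, q)
  ord <- order(-norms, labels)
  rank <- integer(length(points))
  rank[ord] <- seq_along(points)
  structure(data.frame(channel = labels, norm = norms, rank = rank,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("elliptic_ranking", "data.frame"))
}

#' Average elliptic ranking over recordings
#'
#' The per-recording metric differs from recording to recording; the stable
#' quantity is the average of the integer ranks. Channels of low mean rank
#' are the ones consistently exposed to the dominant ripple.
#'
#' @param rankings list of [elliptic_rank()] results (or of [cyclicity()]
#'   fits, whose rankings are extracted) over a common channel set.
#' @return data frame with `channel`, `mean_rank`, sorted ascending by
#'   `mean_rank` (ties by label).
#' @export
average_rank <- function(rankings) {
  rankings <- lapply(rankings, function(r) {
    if (inherits(r, "cyclicity")) r$ranking else r
  })
  if (!length(rankings))
    stop_ca("cyclicity_error_bad_values", "no rankings supplied")
  chans <- sort(rankings[[1L]]$channel)
  for (r in rankings)
    if (!identical(sort(r$channel), chans))
      stop_ca("cyclicity_error_channel_mismatch",
              "rankings do not share a common channel set")
  ranks <- vapply(rankings,
                  function(r) r$rank[match(chans, r$channel)],
                  numeric(length(chans)))
  mr <- rowMeans(as.matrix(ranks))
  out <- data.frame(channel = chans, mean_rank = mr,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$mean_rank, out$channel), , drop = FALSE]
}

#' Phase ordering of dominant channels
#'
#' Rotates the kept constellation points so that their center of mass lands
#' on the positive real axis (the zero-phase axis then points away from the
#' cluster), reports each point's argument in `(-pi, pi]`, and orders the
#' channels by ascending phase -- counterclockwise starting from the negative
#' real axis. For a chain-of-offsets wave this recovers the order in which
#' the wave sweeps the channels. The rule is equivariant: rotating all input
#' points by a fixed angle leaves the ordering unchanged.
#'
#' @param con a [leading_constellation()] (or named complex vector).
#' @param keep channels to order: a character vector of labels, or a single
#'   integer k meaning the k channels of largest Euclidean modulus; defaults
#'   to all channels. The pipeline passes the top-k of [elliptic_rank()].
#' @return an object of class `"phase_ordering"`: data frame with `channel`,
#'   `phase` (radians, non-decreasing), in sweep order.
#' @export
phase_order <- function(con, keep = NULL) {
  points <- if (inherits(con, "constellation")) con$points else con
  labels <- names(points) %||% paste0("ch", seq_along(points))
  names(points) <- labels
  if (is.null(keep)) keep <- labels
  if (is.numeric(keep) && length(keep) == 1L) {
    k <- as.integer(keep)
    if (k < 1L || k > length(points))
      stop_ca("cyclicity_error_bad_subset", "keep = %d out of range", k)
    keep <- labels[order(-Mod(points), labels)][seq_len(k)]
  }
  if (!length(keep))
    stop_ca("cyclicity_error_bad_subset", "empty channel subset")
  if (!all(keep %in% labels))
    stop_ca("cyclicity_error_bad_subset", "unknown channels: %s",
            paste(setdiff(keep, labels), collapse = ", "))
  p <- points[keep]
  centroid <- mean(p)
  if (Mod(centroid) < 1e-12 * max(Mod(p), 1e-300))
    stop_ca("cyclicity_error_degenerate_points",
            "centroid at the origin: rotation is ill-defined")
  phases <- Arg(p * exp(-1i * Arg(centroid)))
  ord <- order(phases, names(p))
  structure(data.frame(channel = names(p)[ord], phase = phases[ord],
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("phase_ordering", "data.frame"))
}

#' Channel-by-position frequency matrix of orderings
#'
#' Across recordings the imputed sweep order fluctuates with noise and
#' subject variability; the histogram of the positions each channel occupies
#' is the stable summary. Returns a row-stochastic matrix (channels x
#' positions); channels are sorted by their mean position.
#'
#' @param orderings list of [phase_order()] results over a common channel
#'   subset.
#' @return matrix of class `"ordering_histogram"` with attribute
#'   `"mean_position"`.
#' @export
ordering_histogram <- function(orderings) {
  if (!length(orderings))
    stop_ca("cyclicity_error_bad_values", "no orderings supplied")
  chans <- sort(orderings[[1L]]$channel)
  k <- length(chans)
  counts <- matrix(0, k, k, dimnames = list(chans, seq_len(k)))
  pos_sum <- stats::setNames(numeric(k), chans)
  for (o in orderings) {
    if (!identical(sort(o$channel), chans))
      stop_ca("cyclicity_error_channel_mismatch",
              "orderings do not share a common channel subset")
    idx <- cbind(match(o$channel, chans), seq_len(k))
    counts[idx] <- counts[idx] + 1
    pos_sum[o$channel] <- pos_sum[o$channel] + seq_len(k)
  }
  freq <- counts / length(orderings)
  mean_pos <- pos_sum / length(orderings)
  ord <- order(mean_pos, chans)
  freq <- freq[ord, , drop = FALSE]
  structure(freq, mean_position = mean_pos[ord],
            class = c("ordering_histogram", "matrix", "array"))
}

#' Do two orderings agree up to rotation?
#'
#' Cyclic orders have no distinguished starting point: a traveling wave
#' reported as `b, c, a` is the same sweep as `a, b, c`. This helper checks
#' whether `a` is a rotation (not a reflection) of `b`.
#'
#' @param a,b vectors containing the same elements.
#' @return logical.
#' @export
same_cyclic_order <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b) || !setequal(a, b)) return(FALSE)
  n <- length(a)
  start <- match(b[1L], a)
  identical(a[((start - 1L + seq_len(n) - 1L) %% n) + 1L], b)
}
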