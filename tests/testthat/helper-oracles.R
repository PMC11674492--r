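# Independent oracles used to cross-check the package's implementations.
# They deliberately share no code with the package internals.

# Brute-force 0-dim sublevel persistence by threshold sweep: points are
# activated in ascending (value, index) order; runs of activated points are
# the components. A point whose two neighbors both belong to existing runs
# merges them; the run whose minimum is higher (or later, on ties) dies.
oracle_persistence <- function(f) {
  n <- length(f)
  ord <- order(f, seq_len(n))
  added <- logical(n)
  pairs <- list()
  run_min <- function(lo, hi) {
    seg <- f[lo:hi]
    j <- which.min(seg) # first index on ties = earliest = older
    c(val = seg[j], idx = lo + j - 1L)
  }
  for (i in ord) {
    L <- i > 1L && added[i - 1L]
    R <- i < n && added[i + 1L]
    if (L && R) {
      lo <- if (any(!added[1:(i - 1L)])) max(which(!added[1:(i - 1L)])) + 1L else 1L
      hi <- if (any(!added[(i + 1L):n])) i + min(which(!added[(i + 1L):n])) - 1L else n
      ml <- run_min(lo, i - 1L)
      mr <- run_min(i + 1L, hi)
      left_older <- (ml["val"] < mr["val"]) ||
        (ml["val"] == mr["val"] && ml["idx"] < mr["idx"])
      young <- if (left_older) mr else ml
      pairs[[length(pairs) + 1L]] <-
        c(birth = unname(young["val"]), death = f[i],
          birth_index = unname(young["idx"]), death_index = i)
    }
    added[i] <- TRUE
  }
  g <- ord[1L]
  out <- if (length(pairs)) as.data.frame(do.call(rbind, pairs))
         else data.frame(birth = numeric(0), death = numeric(0),
                         birth_index = numeric(0), death_index = numeric(0))
  list(pairs = out, essential = list(value = f[g], index = g))
}

# canonical form of a finite-pair table for exact comparison
canon_pairs <- function(p) {
  p <- as.data.frame(lapply(p, as.numeric))
  p[order(p$birth_index), c("birth", "death", "birth_index", "death_index"),
    drop = FALSE]
}

# Quadrature oracle for the oriented area of two continuously defined
# signals: trapezoidal integration of (x * dy/dt - y * dx/dt) / 2 using the
# analytic derivatives, on a grid of n_grid points. This is a different
# route than the package's shoelace sum (which never sees derivatives).
oracle_area_quadrature <- function(xf, yf, dxf, dyf, t0, t1, n_grid = 20000L) {
  tt <- seq(t0, t1, length.out = n_grid)
  integrand <- 0.5 * (xf(tt) * dyf(tt) - yf(tt) * dxf(tt))
  h <- tt[2L] - tt[1L]
  sum((integrand[-1L] + integrand[-n_grid]) / 2) * h
}

# Quadrature oracle for the lead matrix of a single-harmonic chain of
# offsets x_k(t) = a_k cos(omega t - alpha_k) over [t0, t1].
oracle_coom_lead <- function(amps, offsets, omega, t0, t1, n_grid = 20000L) {
  n <- length(offsets)
  A <- matrix(0, n, n)
  for (k in seq_len(n - 1L)) {
    for (l in (k + 1L):n) {
      A[k, l] <- oracle_area_quadrature(
        function(t) amps[k] * cos(omega * t - offsets[k]),
        function(t) amps[l] * cos(omega * t - offsets[l]),
        function(t) -amps[k] * omega * sin(omega * t - offsets[k]),
        function(t) -amps[l] * omega * sin(omega * t - offsets[l]),
        t0, t1, n_grid)
      A[l, k] <- -A[k, l]
    }
  }
  A
}

# temporary CSV helper for read_recording tests
write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
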