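#' Sublevel-set persistence of a 1D series
#'
#' Standard 0-dimensional persistent homology of the sublevel filtration
#' `{f <= v}`, computed with a union-find sweep in ascending value order and
#' the elder rule: a component is born at each local minimum; when two
#' components merge at a value, the one with the higher (younger) birth dies,
#' producing the finite pair `(birth, death)`. The global minimum never dies
#' and is reported as the single essential class. The span `death - birth` of
#' a pair measures how robust the corresponding dip of `f` is to small-scale
#' jitter, which is what lets persistent features filter noisy extrema.
#' Endpoints count as local extrema when their single neighbor is
#' respectively larger/smaller; ties in value are broken by the smaller time
#' index being older.
#'
#' @param f numeric vector (length >= 2, finite).
#' @return an object of class `"persistence_diagram"`: list with
#'   `pairs` (data frame `birth`, `death`, `birth_index`, `death_index`;
#'   1-based frame indices; `death > birth` for series with distinct values),
#'   `essential` (list `value`, `index`), and `n`.
#' @examples
#' sublevel_persistence(c(0, 3, 1, 4, 2, 5))
#' @export
sublevel_persistence <- function(f) {
  if (!is.numeric(f) || length(f) < 2L)
    stop_ca("cyclicity_error_too_few_frames",
            "persistence needs a numeric series of length >= 2")
  if (!all(is.finite(f)))
    stop_ca("cyclicity_error_non_finite", "series contains non-finite values")
  n <- length(f)
  ord <- order(f, seq_len(n))
  parent <- integer(n)               # 0 = not yet added; else union-find parent
  min_val <- numeric(n); min_idx <- integer(n)
  added <- logical(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]] # path halving
      i <- parent[i]
    }
    i
  }
  births <- numeric(0); deaths <- numeric(0)
  b_idx <- integer(0); d_idx <- integer(0)
  for (i in ord) {
    added[i] <- TRUE
    parent[i] <- i; min_val[i] <- f[i]; min_idx[i] <- i
    left  <- if (i > 1L && added[i - 1L]) find(i - 1L) else 0L
    right <- if (i < n && added[i + 1L]) find(i + 1L) else 0L
    if (left && right && left != right) {
      # elder rule: component with the higher (or later, on ties) birth dies
      l_old <- (min_val[left] < min_val[right]) ||
        (min_val[left] == min_val[right] && min_idx[left] < min_idx[right])
      older <- if (l_old) left else right
      younger <- if (l_old) right else left
      births <- c(births, min_val[younger]); deaths <- c(deaths, f[i])
      b_idx <- c(b_idx, min_idx[younger]); d_idx <- c(d_idx, i)
      parent[younger] <- older
      parent[i] <- older
    } else if (left || right) {
      r <- if (left) left else right
      if (left && right) parent[right] <- left # same root; keep tree shallow
      parent[i] <- r
    }
  }
  g <- ord[1L]
  structure(list(pairs = data.frame(birth = births, death = deaths,
                                    birth_index = b_idx, death_index = d_idx),
                 essential = list(value = f[g], index = g),
                 n = n),
            class = "persistence_diagram")
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("<persistence_diagram> %d finite pairs, essential (%.4g, Inf) at frame %d\n",
              nrow(x$pairs), x$essential$value, x$essential$index))
  if (nrow(x$pairs)) print(utils::head(x$pairs, 10L), ...)
  invisible(x)
}

# Finite features of f and -f in one table. Births/deaths are reported in each
# sign's own scale (span is invariant); min_frame marks the feature's born
# extremum in f (a minimum for sign +1, a maximum for sign -1), max_frame the
# paired merge extremum.
merged_features <- function(f, signed_mode = c("both", "f")) {
  signed_mode <- match.arg(signed_mode)
  one <- function(g, s) {
    d <- sublevel_persistence(g)$pairs
    if (!nrow(d)) return(NULL)
    data.frame(sign = rep.int(s, nrow(d)), birth = d$birth, death = d$death,
               span = d$death - d$birth,
               min_frame = d$birth_index, max_frame = d$death_index)
  }
  out <- rbind(one(f, 1L),
               if (signed_mode == "both") one(-f, -1L))
  if (is.null(out))
    out <- data.frame(sign = integer(0), birth = numeric(0), death = numeric(0),
                      span = numeric(0), min_frame = integer(0),
                      max_frame = integer(0))
  out
}

#' Longest-lived persistence features
#'
#' Selects the `<= p` finite pairs of largest span `death - birth`; ties are
#' broken by earlier birth index. The essential class is never included.
#'
#' @param d a [sublevel_persistence()] diagram, or a feature table as
#'   produced internally for both signs (any data frame with columns `birth`,
#'   `death` and a birth-index column).
#' @param p maximum number of features to keep (>= 1).
#' @return data frame of kept features sorted by decreasing span.
#' @export
top_features <- function(d, p) {
  if (!is.numeric(p) || length(p) != 1L || p < 1)
    stop_ca("cyclicity_error_bad_values", "`p` must be a positive integer")
  tab <- if (inherits(d, "persistence_diagram")) d$pairs else d
  if (!nrow(tab)) return(tab)
  span <- tab$death - tab$birth
  bidx <- if ("birth_index" %in% names(tab)) tab$birth_index else tab$min_frame
  ord <- order(-span, bidx)
  tab[ord[seq_len(min(as.integer(p), nrow(tab)))], , drop = FALSE]
}

#' Persistent lead-lag reversals of an oriented-area trajectory
#'
#' A reversal is a persistent change of direction of the cumulative
#' oriented-area trajectory: the leader-follower role of the pair flips.
#' Downward-then-up episodes are minima of the trajectory; upward-then-down
#' episodes are minima of its negation, so sublevel persistence is run on
#' both `f` and `-f`, the finite feature lists are merged, and the `p`
#' longest-lived features overall are kept (the same merge that
#' [burstiness()] sums over). The reported events are the time stamps of the
#' born extrema and of their paired merge extrema -- births and deaths -- of
#' those kept features. `signed_mode = "f"` restricts to features of `f`
#' alone for comparison.
#'
#' @param traj an [area_trajectory()] or numeric vector.
#' @param p number of longest-lived features to keep (default 10).
#' @param signed_mode `"both"` (default) or `"f"`.
#' @return an object of class `"reversal_events"`: list with `features`
#'   (kept-feature table with `sign`, `birth`, `death`, `span`, `min_frame`,
#'   `max_frame`), `pair`, `p`, `signed_mode`, `n` (frames).
#' @export
reversal_events <- function(traj, p = 10L, signed_mode = c("both", "f")) {
  signed_mode <- match.arg(signed_mode)
  pair <- c("x", "y")
  if (inherits(traj, "area_trajectory")) {
    pair <- traj$pair
    f <- traj$values
  } else {
    f <- as.numeric(traj)
  }
  feats <- top_features(merged_features(f, signed_mode), p)
  structure(list(features = feats, pair = pair, p = as.integer(p),
                 signed_mode = signed_mode, n = length(f)),
            class = "reversal_events")
}

#' @export
print.reversal_events <- function(x, ...) {
  cat(sprintf("<reversal_events> %s vs %s: %d kept features (p = %d, mode '%s'), %d frames\n",
              x$pair[1L], x$pair[2L], nrow(x$features), x$p, x$signed_mode, x$n))
  if (nrow(x$features)) print(x$features, row.names = FALSE, ...)
  invisible(x)
}

#' Event frames of detected reversals
#'
#' @param ev a [reversal_events()] object.
#' @param kind `"both"` (births and deaths), `"min"` (born extrema only) or
#'   `"max"` (merge extrema only).
#' @return sorted vector of unique 1-based frame indices.
#' @export
reversal_frames <- function(ev, kind = c("both", "min", "max")) {
  kind <- match.arg(kind)
  fr <- switch(kind,
               both = c(ev$features$min_frame, ev$features$max_frame),
               min = ev$features$min_frame,
               max = ev$features$max_frame)
  sort(unique(fr))
}

#' Cluster reversal time stamps into epochs
#'
#' Groups a set of event frames into distinct reversal epochs: maximal runs
#' of events in which consecutive stamps are separated by at most `min_gap`
#' frames. Pooling the stamps of many pairs and clustering them recovers the
#' task-block boundaries at which the lead-lag direction flips.
#'
#' @param frames numeric vector of event frames (pooled over pairs if
#'   desired).
#' @param min_gap events further apart than this many frames start a new
#'   epoch (default 5).
#' @return data frame with one row per epoch: `center` (median frame),
#'   `n_events`, `first`, `last`.
#' @export
reversal_epochs <- function(frames, min_gap = 5) {
  frames <- sort(as.numeric(frames))
  if (!length(frames))
    return(data.frame(center = numeric(0), n_events = integer(0),
                      first = numeric(0), last = numeric(0)))
  grp <- cumsum(c(1, diff(frames) > min_gap))
  agg <- function(f) vapply(split(frames, grp), f, numeric(1))
  data.frame(center = agg(stats::median), n_events = agg(length),
             first = agg(min), last = agg(max), row.names = NULL)
}

#' Carpet summary of reversal events across pairs
#'
#' Builds the pairs-by-frames binary raster of birth/death events and the
#' per-frame count of pairs recording one, the summary in which task-locked
#' reversals appear as regularly spaced vertical stripes while resting-state
#' dynamics leave a nearly empty carpet.
#'
#' @param events a [reversal_events()] object or a list of them.
#' @param T number of frames (defaults to the events' own frame count).
#' @return an object of class `"carpet_summary"`: list with `raster`
#'   (pairs x T binary matrix) and `counts` (per-frame column sums).
#' @export
carpet <- function(events, T = NULL) {
  if (inherits(events, "reversal_events")) events <- list(events)
  if (!length(events))
    stop_ca("cyclicity_error_bad_values", "no events supplied")
  T <- as.integer(T %||% max(vapply(events, function(e) e$n, integer(1))))
  raster <- matrix(0L, length(events), T)
  rownames(raster) <- vapply(events, function(e) paste(e$pair, collapse = "|"),
                             character(1))
  for (i in seq_along(events)) {
    fr <- reversal_frames(events[[i]], "both")
    if (length(fr) && (min(fr) < 1L || max(fr) > T))
      stop_ca("cyclicity_error_index_out_of_range",
              "event frame outside [1, %d]", T)
    raster[i, fr] <- 1L
  }
  structure(list(raster = raster, counts = colSums(raster)),
            class = "carpet_summary")
}

#' @export
print.carpet_summary <- function(x, ...) {
  cat(sprintf("<carpet_summary> %d pairs x %d frames, %d events, max count %d\n",
              nrow(x$raster), ncol(x$raster), sum(x$raster), max(x$counts)))
  invisible(x)
}

#' @export
plot.carpet_summary <- function(x, ...) {
  graphics::plot(seq_along(x$counts), x$counts, type = "h",
                 xlab = "frame", ylab = "pairs with birth/death", ...)
  invisible(x)
}

#' Uniform-scatter null threshold for carpet counts
#'
#' Permutation null for the carpet's peak height: each pair's events are
#' re-scattered uniformly over the frames (preserving the per-pair event
#' count) and the maximum per-frame count of each permutation is recorded;
#' the requested quantile of those maxima is returned. An observed peak at
#' or below the 99th null percentile is the signature of resting-like
#' dynamics with no synchronized reversals; task-locked reversals push the
#' peaks far above it.
#'
#' @param cs a [carpet()] summary.
#' @param prob quantile of the null maxima (default 0.99).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return scalar threshold for the peak per-frame count.
#' @export
carpet_null_quantile <- function(cs, prob = 0.99, n_perm = 100L, seed = 1L) {
  T <- ncol(cs$raster)
  m <- rowSums(cs$raster)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  null_max <- replicate(n_perm, {
    counts <- integer(T)
    for (k in m) {
      fr <- sample.int(T, k)
      counts[fr] <- counts[fr] + 1L
    }
    max(counts)
  })
  as.numeric(stats::quantile(null_max, probs = prob, type = 1L))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Burstiness of an oriented-area trajectory
#'
#' The total span of the `n_bars` longest-lived persistence features of the
#' trajectory (features of the negated trajectory included, same merge as
#' [reversal_events()]). Pairs that accumulate their oriented area in abrupt
#' task-locked jumps score high; pairs that accumulate it gradually, or
#' fluctuate near zero, score low. With fewer than `n_bars` finite features
#' the sum runs over all of them; a strictly monotone trajectory scores 0.
#'
#' @param traj an [area_trajectory()] or numeric vector.
#' @param n_bars number of longest bars to sum (default 10; the statistic is
#'   insensitive to this choice in the 8--20 range).
#' @param signed_mode `"both"` (default) or `"f"`.
#' @return scalar burstiness.
#' @export
burstiness <- function(traj, n_bars = 10L, signed_mode = c("both", "f")) {
  signed_mode <- match.arg(signed_mode)
  f <- if (inherits(traj, "area_trajectory")) traj$values else as.numeric(traj)
  feats <- merged_features(f, signed_mode)
  if (!nrow(feats)) return(0)
  sum(top_features(feats, n_bars)$span)
}
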