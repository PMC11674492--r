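skew_from_blocks <- function(mags) {
  n <- 2 * length(mags)
  A <- matrix(0, n, n)
  for (i in seq_along(mags)) {
    j <- 2 * i - 1
    A[j, j + 1] <- mags[i]
    A[j + 1, j] <- -mags[i]
  }
  dimnames(A) <- list(paste0("ch", 1:n), paste0("ch", 1:n))
  A
}

test_that("eigendecomposition of skew matrices: imaginary pairs, sorted magnitudes", {
  # rank-2 outer-product matrix: eigenpair (+-i, (-+i, 1, 0))
  Q <- outer(c(1, 0, 0), c(0, 1, 0)) - outer(c(0, 1, 0), c(1, 0, 0))
  s <- lead_eigen(Q)
  expect_equal(s$magnitudes, c(1, 0))
  w <- s$vectors[, 1]
  expect_lt(max(Mod(Q %*% w - (-1i) * w)), 1e-9) # A w = -i|lambda| w
  expect_lt(Mod(w[3]), 1e-9)

  expect_equal(lead_eigen(matrix(0, 4, 4))$magnitudes, c(0, 0))

  set.seed(5)
  M <- matrix(rnorm(36), 6, 6)
  A <- M - t(M)
  s6 <- lead_eigen(A)
  expect_length(s6$magnitudes, 3L)
  expect_true(all(diff(s6$magnitudes) <= 0))
  # cross-check against the full eigensolver: purely imaginary values in
  # conjugate pairs whose absolute imaginary parts match the magnitudes
  ev <- eigen(A, only.values = TRUE)$values
  expect_lt(max(abs(Re(ev))) / max(Mod(ev)), 1e-9)
  expect_equal(sort(unique(round(abs(Im(ev)), 9))), sort(round(s6$magnitudes, 9)))

  expect_error(lead_eigen(M), class = "cyclicity_error_not_skew")
})

test_that("rank-2 outer products have eigenvalue sin(theta) |u| |v|", {
  set.seed(8)
  for (i in 1:25) {
    u <- rnorm(6); v <- rnorm(6)
    Q <- outer(u, v) - outer(v, u)
    theta <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
    expect_equal(lead_eigen(Q)$magnitudes[1],
                 abs(sin(theta)) * sqrt(sum(u^2)) * sqrt(sum(v^2)),
                 tolerance = 1e-9)
  }
})

test_that("dominance ratio divides first and second pair magnitudes", {
  expect_equal(dominance_ratio(skew_from_blocks(c(2, 1, 0.5))), 2.0)
  # exact rank 2: |lambda_3| = 0 -> infinity sentinel
  expect_identical(dominance_ratio(skew_from_blocks(c(3, 0))), Inf)
  expect_error(dominance_ratio(skew_from_blocks(1)),
               class = "cyclicity_error_too_few_channels")
})

test_that("constellation orientation follows the strongest lead-lag pair", {
  # three-channel chain: ch1 leads ch2 leads ch3
  spec <- coom_spec(offsets = c(0, 0.8, 1.6), duration = 400)
  A <- lead_matrix(normalize(coom_series(spec)))
  con <- leading_constellation(A)
  ref <- con$orientation_reference
  k <- ref[1]; l <- ref[2]
  ang <- Arg(con$points[l] / con$points[k])
  expect_identical(unname(sign(ang)), sign(A[k, l]))
  # the conjugate constellation violates the orientation contract
  expect_identical(unname(sign(Arg(Conj(con$points[l]) / Conj(con$points[k])))),
                   -sign(A[k, l]))
  # deterministic: identical on recomputation
  expect_identical(con, leading_constellation(A))
  expect_error(leading_constellation(matrix(0, 3, 3)),
               class = "cyclicity_error_zero_matrix")
  expect_error(leading_constellation(A, pair_index = 5),
               class = "cyclicity_error_bad_pair_index")
})

test_that("constellation argument order equals the planted offset order", {
  spec <- coom_spec(offsets = seq(0, by = pi / 10, length.out = 10L),
                    duration = 864)
  A <- lead_matrix(normalize(coom_series(spec)))
  con <- leading_constellation(A)
  args_order <- names(sort(Arg(con$points * exp(-1i * Arg(mean(con$points))))))
  expect_true(same_cyclic_order(args_order, paste0("ch", 1:10)))
})

test_that("ellipse fit recovers exact ellipses and flags degeneracies", {
  th <- seq(0, 2 * pi, length.out = 13)[-13]
  circ <- 2 * exp(1i * th)
  q <- fit_ellipse(circ)
  expect_equal(c(q$a, q$b, q$c), c(0.25, 0, 0.25), tolerance = 1e-9)
  expect_false(q$degenerate)
  # x^2/4 + y^2 = 1
  ell <- complex(real = 2 * cos(th), imaginary = sin(th))
  q2 <- fit_ellipse(ell)
  expect_equal(c(q2$a, q2$b, q2$c), c(0.25, 0, 1), tolerance = 1e-9)
  # arbitrary positive-definite form, exact recovery from on-curve points
  set.seed(2)
  for (i in 1:10) {
    F <- crossprod(matrix(rnorm(4), 2)) + diag(0.1, 2)
    Fi <- solve(chol(F))   # maps the unit circle onto {q = 1}
    pts <- Fi %*% rbind(cos(th), sin(th))
    qf <- fit_ellipse(complex(real = pts[1, ], imaginary = pts[2, ]))
    expect_equal(c(qf$a, qf$b, qf$c), c(F[1, 1], F[1, 2], F[2, 2]),
                 tolerance = 1e-9)
  }
  # collinear through the origin: clipped but positive definite
  line <- complex(real = c(1, 2, -1.5), imaginary = c(0.5, 1, -0.75))
  qd <- fit_ellipse(line)
  expect_true(qd$degenerate)
  expect_gt(qd$a, 0)
  expect_gt(qd$a * qd$c - qd$b^2, 0)
  expect_error(fit_ellipse(complex(real = 1:2, imaginary = 1:2)),
               class = "cyclicity_error_too_few_points")
  expect_error(fit_ellipse(complex(real = numeric(3), imaginary = numeric(3))),
               class = "cyclicity_error_degenerate_points")
})

test_that("elliptic ranking orders by q-norm with label tie-breaks", {
  qid <- structure(list(a = 1, b = 0, c = 1, degenerate = FALSE),
                   class = "quadratic_form")
  pts <- stats::setNames(complex(modulus = c(3, 2, 1),
                                 argument = c(0.1, 2, -1)), c("u", "v", "w"))
  r <- elliptic_rank(pts, qid)
  expect_equal(r$rank, c(1L, 2L, 3L))
  expect_equal(r$norm, c(3, 2, 1), tolerance = 1e-12)
  # anisotropic norm: (1, 0) beats (0, 1.5) under q = 4x^2 + y^2
  q4 <- structure(list(a = 4, b = 0, c = 1, degenerate = FALSE),
                  class = "quadratic_form")
  pts2 <- stats::setNames(c(1 + 0i, 0 + 1.5i), c("p", "q"))
  r2 <- elliptic_rank(pts2, q4)
  expect_equal(r2$norm, c(2, 1.5))
  expect_equal(r2$rank, c(1L, 2L))
  # exact ties resolved by label order
  r3 <- elliptic_rank(stats::setNames(rep(1 + 1i, 3), c("c", "a", "b")), qid)
  expect_equal(r3$rank[order(r3$channel)], 1:3)
  bad <- structure(list(a = 1, b = 2, c = 1, degenerate = FALSE),
                   class = "quadratic_form")
  expect_error(elliptic_rank(pts, bad),
               class = "cyclicity_error_not_positive_definite")
})

test_that("average rank aggregates recordings and breaks ties by label", {
  mk <- function(chs, ranks) {
    structure(data.frame(channel = chs, norm = rev(ranks), rank = ranks,
                         stringsAsFactors = FALSE),
              class = c("elliptic_ranking", "data.frame"))
  }
  avg <- average_rank(list(mk(c("a", "b"), c(1L, 2L)), mk(c("a", "b"), c(3L, 4L))))
  expect_equal(avg$mean_rank[avg$channel == "a"], 2.0)
  # reversed rankings of two channels: equal means, label breaks the tie
  avg2 <- average_rank(list(mk(c("a", "b"), 1:2), mk(c("a", "b"), 2:1)))
  expect_equal(avg2$channel, c("a", "b"))
  expect_equal(avg2$mean_rank, c(1.5, 1.5))
  # identical rankings reproduce the common order
  avg3 <- average_rank(list(mk(c("a", "b", "c"), c(2L, 1L, 3L)),
                            mk(c("a", "b", "c"), c(2L, 1L, 3L))))
  expect_equal(avg3$channel, c("b", "a", "c"))
  expect_error(average_rank(list(mk(c("a", "b"), 1:2), mk(c("a", "x"), 1:2))),
               class = "cyclicity_error_channel_mismatch")
})

test_that("phase ordering is centroid-anchored and rotation-equivariant", {
  pts <- stats::setNames(complex(modulus = c(1, 1, 1),
                                 argument = c(-0.4, 0.1, 0.5)),
                         c("a", "b", "c"))
  po <- phase_order(pts)
  expect_equal(po$channel, c("a", "b", "c"))
  expect_true(all(diff(po$phase) >= 0))
  # rotating every point leaves the ordering unchanged
  for (rot in c(0.7, 2.9, -2)) {
    po_rot <- phase_order(pts * exp(1i * rot))
    expect_equal(po_rot$channel, po$channel)
    expect_equal(po_rot$phase, po$phase, tolerance = 1e-12)
  }
  expect_error(phase_order(pts, keep = character(0)),
               class = "cyclicity_error_bad_subset")
  sym <- stats::setNames(c(1 + 0i, -1 + 0i), c("a", "b"))
  expect_error(phase_order(sym), class = "cyclicity_error_degenerate_points")
})

test_that("planted chain order is recovered through the full spectral path", {
  spec <- coom_spec(offsets = seq(0, by = pi / 10, length.out = 10L),
                    duration = 864)
  con <- leading_constellation(lead_matrix(normalize(coom_series(spec))))
  po <- phase_order(con)
  expect_equal(po$channel, paste0("ch", 1:10))
})

test_that("ordering histogram is row-stochastic with truth as the mode", {
  mk_po <- function(chs) {
    structure(data.frame(channel = chs, phase = seq(-1, 1, length.out = length(chs)),
                         stringsAsFactors = FALSE),
              class = c("phase_ordering", "data.frame"))
  }
  # identical orderings: a permutation matrix
  h <- ordering_histogram(list(mk_po(c("b", "a", "c")), mk_po(c("b", "a", "c"))))
  expect_true(all(rowSums(h) == 1))
  expect_equal(sort(as.vector(unclass(h))), c(rep(0, 6), rep(1, 3)))
  expect_equal(rownames(h), c("b", "a", "c"))
  # repeated noisy chain draws: modal position equals the planted position
  spec <- coom_spec(offsets = seq(0, by = pi / 8, length.out = 8L),
                    duration = 864, snr = 10)
  po_list <- lapply(1:20, function(i) {
    con <- leading_constellation(lead_matrix(normalize(coom_series(spec, seed = i))))
    phase_order(con)
  })
  hh <- ordering_histogram(po_list)
  modal <- apply(unclass(hh), 1, which.max)
  expect_equal(modal[paste0("ch", 1:8)], stats::setNames(1:8, paste0("ch", 1:8)))
  expect_equal(unname(rowSums(hh)), rep(1, 8))
  expect_error(ordering_histogram(list(mk_po(c("a", "b")), mk_po(c("a", "x")))),
               class = "cyclicity_error_channel_mismatch")
})

test_that("cyclic-order comparison accepts rotations and rejects reflections", {
  expect_true(same_cyclic_order(c("a", "b", "c"), c("b", "c", "a")))
  expect_false(same_cyclic_order(c("a", "b", "c"), c("c", "b", "a")))
  expect_false(same_cyclic_order(c("a", "b"), c("a", "x")))
})
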