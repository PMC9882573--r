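test_that("knot assignment reproduces hand-derived maps", {
  m <- phase_map(3, 5)
  expect_equal(m$assign, c(1L, 1L, 2L, 2L, 3L))
  expect_equal(m$g, c(2L, 2L, 1L))

  # equal lengths: the map is the identity
  m <- phase_map(7, 7)
  expect_equal(m$assign, 1:7)
  expect_equal(m$g, rep(1L, 7))

  expect_error(phase_map(5, 4), "singular")
  expect_error(phase_map(1, 5), "at least 2")
})

test_that("maps agree with the dense knot-inequality oracle", {
  for (n in c(2, 3, 5, 8, 13, 21, 30)) {
    for (tt in unique(c(n, n + 1, 2 * n, 3 * n + 1, 120))) {
      if (tt < n || tt > 120) next
      dense <- dense_theta_oracle(n, tt)
      expect_equal(theta_matrix(phase_map(n, tt)), dense,
                   info = sprintf("N=%d T=%d", n, tt))
      # matrix-free forward/backward equal dense matrix algebra
      x <- rnorm(n)
      m <- phase_map(n, tt)
      expect_equal(phase_forward(m, x), as.vector(dense %*% x))
      xi <- rnorm(tt)
      g <- colSums(dense)
      expect_equal(phase_backward(m, xi),
                   as.vector((t(dense) %*% xi) / g), tolerance = 1e-12)
    }
  }
})

test_that("gramian is diagonal and the phase diagonal is constant", {
  set.seed(1)
  for (i in 1:25) {
    n <- sample(2:40, 1)
    tt <- n + sample(0:80, 1)
    th <- theta_matrix(phase_map(n, tt))
    gram <- crossprod(th)
    expect_true(all(gram[row(gram) != col(gram)] == 0))
    expect_true(all(diag(gram) >= 1))
    expect_equal(unique(diag(tcrossprod(th))), 1)
    # surjective, non-decreasing assignment
    m <- phase_map(n, tt)
    expect_true(all(diff(m$assign) >= 0))
    expect_setequal(unique(m$assign), seq_len(n))
  }
})

test_that("R-aligned maps pin the R peak to a fixed phase", {
  m <- phase_map_r_aligned(2, 3, 7, 3)
  expect_equal(m$assign, c(1L, 2L, 3L, 3L, 4L, 4L, 5L))
  expect_equal(m$r_phase, 3L)
  expect_equal(m$assign[m$r_phase], 3L)  # time index of the R peak
  expect_equal(sum(m$g), 7L)

  # the two-segment build reduces to the plain map over the shared pre-R part
  ms <- phase_map_r_aligned(5, 6, 21, 11)
  mp <- phase_map(6, 11)
  expect_equal(ms$assign[1:11], mp$assign)
  expect_true(all(ms$g >= 1))

  expect_error(phase_map_r_aligned(4, 3, 10, 3), "r_phase too small")
  expect_error(phase_map_r_aligned(2, 8, 9, 3), "post-R segment")
})

test_that("forward warps by replication and backward inverts it exactly", {
  m <- phase_map(3, 5)
  expect_equal(phase_forward(m, c(2.5, -1, 7)), c(2.5, 2.5, -1, -1, 7))
  expect_equal(phase_forward(m, c(0, 1, 0)), c(0, 0, 1, 1, 0))
  expect_equal(phase_forward(m, rep(4, 3)), rep(4, 5))
  expect_equal(phase_backward(m, c(1, 3, 2, 4, 5)), c(2, 3, 5))
  expect_equal(phase_backward(m, rep(3, 5)), rep(3, 3))
  expect_error(phase_forward(m, 1:4), "n_time")
  expect_error(phase_backward(m, 1:4), "n_phase")
})

test_that("time-phase-time round trips are exact", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(2:60, 1)
    tt <- n + sample(0:150, 1)
    m <- if (i %% 2 == 0) phase_map(n, tt) else {
      r <- sample(seq_len(n), 1)
      rp <- min(max(r, round(tt * r / n)), tt - (n - r))
      phase_map_r_aligned(r - 1, n - r + 1, tt, rp)
    }
    xi <- sample.int(1000, n)  # integer-valued: bit-exact round trip
    expect_identical(phase_backward(m, phase_forward(m, as.numeric(xi))),
                     as.numeric(xi))
    x <- rnorm(n)
    expect_equal(phase_backward(m, phase_forward(m, x)), x, tolerance = 1e-13)
  }
})
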