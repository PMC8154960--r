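test_that("BP normalization matches the hand-computed 5-term window", {
  # constant series: every ratio is 1
  expect_equal(bp_normalize(rep(3.7, 20)), rep(0, 20))
  # single bump: centre value is log(2 / mean(1,1,2,1,1))
  s <- c(1, 1, 1, 1, 2, 1, 1, 1, 1)
  expect_equal(bp_normalize(s)[5], log(2 / 1.2))
  # scaling invariance: ratios cancel any global factor
  x <- as.numeric(generate_ring_series(40, 1.5, 0.3, seed = 3))
  expect_equal(bp_normalize(x), bp_normalize(17.3 * x))
  expect_error(bp_normalize(c(1, 2, 3, 4)), "at least 5")
  expect_error(bp_normalize(c(1, 2, -1, 4, 5)), "positive")
})

test_that("TBP follows t = r sqrt(n-2)/sqrt(1-r^2) and caps at 100", {
  x <- as.numeric(generate_ring_series(27, 1.5, 0.3, seed = 11))
  y <- as.numeric(generate_ring_series(27, 1.2, 0.4, seed = 12))
  r <- cor(bp_normalize(x), bp_normalize(y))
  expect_equal(tbp(x, y), r * sqrt(25) / sqrt(1 - r^2))
  # frozen closed-form value: r = 0.5 at n = 27 gives 2.8867513
  expect_equal(0.5 * sqrt(25) / sqrt(1 - 0.25), 2.8867513, tolerance = 1e-7)
  # identical series: r = 1, capped
  expect_identical(tbp(x, x), 100)
  # symmetry and scale invariance
  expect_equal(tbp(x, y), tbp(y, x))
  expect_equal(tbp(x, y), tbp(2.5 * x, y))
  expect_error(tbp(rep(1, 10), x[1:10]), "degenerate")
  expect_error(tbp(x, y[1:10]), "aligned")
})

test_that("TBP = 100 and Gl = 100 for identical series of any length", {
  for (n in c(5, 12, 50, 200, 500)) {
    s <- as.numeric(generate_ring_series(n, 2, 0.3, seed = n))
    expect_identical(tbp(s, s), 100)
    expect_equal(gleichlaufigkeit(s, s)$gl, 100)
  }
})

test_that("Gleichlaeufigkeit scores signs, ties, and opposition correctly", {
  up <- c(1, 2, 3, 4, 5)
  expect_equal(gleichlaufigkeit(up, rev(up))$gl, 0)    # strictly opposite
  # exactly one zero difference scores 1/2
  x <- c(1, 2, 2, 3)
  y <- c(1, 2, 3, 4)
  expect_equal(gleichlaufigkeit(x, y)$gl, 100 * (1 + 0.5 + 1) / 3)
  # both zero scores 1
  expect_equal(gleichlaufigkeit(c(1, 1, 2), c(3, 3, 4))$gl, 100)
  # z and p for a perfect match over n rings
  g <- gleichlaufigkeit(up, up)
  expect_equal(g$z, 0.5 * 2 * sqrt(4))
  expect_equal(g$p, pnorm(g$z, lower.tail = FALSE))
  expect_error(gleichlaufigkeit(1, 1), "at least 2")
})

test_that("Gl is invariant under strictly monotone transforms", {
  x <- as.numeric(generate_ring_series(60, 1.5, 0.3, seed = 5))
  y <- as.numeric(generate_ring_series(60, 1.5, 0.3, seed = 6))
  g0 <- gleichlaufigkeit(x, y)$gl
  expect_equal(gleichlaufigkeit(exp(x), exp(y))$gl, g0)
  expect_equal(gleichlaufigkeit(x^3, y^3)$gl, g0)
})

test_that("Gl of independent random walks averages 50% (Monte-Carlo null)", {
  set.seed(99)
  nrep <- 10000L; n <- 101L
  gl <- replicate(nrep, {
    dx <- sign(rnorm(n - 1)); dy <- sign(rnorm(n - 1))
    100 * mean(dx == dy)        # continuous: ties have probability 0
  })
  expect_lt(abs(mean(gl) - 50), 0.5)
})

test_that("rbar averages pairwise correlations of BP-normalized series", {
  x <- as.numeric(generate_ring_series(50, 1.5, 0.3, seed = 21))
  expect_equal(rbar(list(x, x)), 1.0)
  expect_equal(rbar(list(x, x, x, x)), 1.0)
  y <- as.numeric(generate_ring_series(50, 1.5, 0.3, seed = 22))
  z <- as.numeric(generate_ring_series(50, 1.5, 0.3, seed = 23))
  bx <- bp_normalize(x); by <- bp_normalize(y); bz <- bp_normalize(z)
  manual <- mean(c(cor(bx, by), cor(bx, bz), cor(by, bz)))
  expect_equal(rbar(list(x, y, z)), manual, tolerance = 1e-12)
})

test_that("sliding crossdating finds an embedded sub-series at the true lag", {
  ref <- generate_ring_series(100, 1.6, 0.3, seed = 31)
  smp <- ring_series(as.numeric(ref)[31:70])
  tab <- crossdate_sliding(smp, ref, min_overlap = 30)
  expect_s3_class(tab, "crossdate_result")
  expect_equal(tab$offset[1], 30)        # sample ring 1 = reference ring 31
  expect_equal(tab$gl[1], 100)
  expect_identical(tab$tbp[1], 100)
  expect_equal(tab$marker[1], "###")
})

test_that("noisy re-measurement still crossdates at the true lag", {
  ref <- generate_ring_series(100, 1.6, 0.3, seed = 41)
  set.seed(42)
  noisy <- as.numeric(ref)[31:70] * exp(rnorm(40, 0, 0.05))
  tab <- crossdate_sliding(ring_series(noisy), ref, min_overlap = 30)
  expect_equal(tab$offset[1], 30)
  expect_gt(tab$tbp[1], 10)
  expect_gt(tab$gl[1], 75)
})

test_that("sliding table matches a brute-force per-lag recomputation", {
  smp <- generate_ring_series(50, 1.4, 0.35, seed = 51)
  ref <- generate_ring_series(50, 1.4, 0.35, seed = 52)
  mo <- 20L
  tab <- crossdate_sliding(smp, ref, min_overlap = mo)
  s <- as.numeric(smp); r <- as.numeric(ref)
  for (o in seq(-(length(s) - mo), length(r) - mo)) {
    i1 <- max(1L, 1L - o); i2 <- min(length(s), length(r) - o)
    n <- i2 - i1 + 1L
    if (n < mo) next
    xs <- s[i1:i2]; ys <- r[(i1 + o):(i2 + o)]
    row <- tab[tab$offset == o, ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$n_overlap, n)
    expect_equal(row$tbp, tbp(xs, ys))
    expect_equal(row$gl, gleichlaufigkeit(xs, ys)$gl)
  }
})
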