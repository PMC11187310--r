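# Shrake-Rupley SASA against analytic sphere oracles, and Eq.-style
# buried interface areas.

test_that("an isolated atom matches the closed-form sphere area", {
  a <- atomSet("C", matrix(0, 1, 3))
  r <- sasa(a, probeRadius = 1.4, nPoints = 960L)
  exact <- 4 * pi * (1.87 + 1.4)^2
  expect_lt(abs(r$total - exact) / exact, 0.01)

  # two atoms out of contact: exactly additive
  b <- atomSet(c("C", "C"), rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_lt(abs(sasa(b)$total - 2 * exact) / (2 * exact), 0.01)
})

test_that("two overlapping spheres match the analytic cap formula", {
  d <- 3.0
  ats <- atomSet(c("C", "C"), rbind(c(0, 0, 0), c(d, 0, 0)))
  r <- sasa(ats, probeRadius = 1.4, nPoints = 960L)
  R <- 1.87 + 1.4
  h <- R - d / 2                       # buried cap height per sphere
  exact <- 2 * (4 * pi * R^2 - 2 * pi * R * h)
  expect_lt(abs(r$total - exact) / exact, 0.02)
})

test_that("buried area follows SASA1 + SASA2 - SASA12 with its symmetries", {
  a <- atomSet("C", matrix(c(0, 0, 0), 1))
  b <- atomSet("C", matrix(c(3, 0, 0), 1))
  res <- interfaceB(a, b)
  expect_equal(res@buriedB, res@sasa1 + res@sasa2 - res@sasa12)
  R <- 3.27; h <- R - 1.5
  analytic <- 2 * 2 * pi * R * h
  expect_lt(abs(buriedArea(res) - analytic) / analytic, 0.02)

  # swap symmetry is exact
  swapped <- interfaceB(b, a)
  expect_identical(buriedArea(swapped), buriedArea(res))

  # partners far apart bury nothing
  far <- atomSet("C", matrix(c(100, 0, 0), 1))
  expect_lte(abs(buriedArea(interfaceB(a, far))), 0.5)
})

test_that("areas are invariant under rigid motions within 0.1%", {
  set.seed(33)
  n <- 50
  xyz <- matrix(rnorm(n * 3, 0, 4), ncol = 3)
  el <- sample(c("C", "N", "O", "S"), n, replace = TRUE)
  ats <- atomSet(el, xyz)
  ref <- sasa(ats)$total
  for (k in 1:3) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    moved <- atomSet(el, xyz %*% q + rep(rnorm(3, 0, 20), each = n))
    expect_lt(abs(sasa(moved)$total - ref) / ref, 0.001)
  }
})

test_that("doubling the sample points changes totals by < 0.5%", {
  set.seed(34)
  xyz <- matrix(rnorm(50 * 3, 0, 4), ncol = 3)
  ats <- atomSet(rep("C", 50), xyz)
  a1 <- sasa(ats, nPoints = 960L)$total
  a2 <- sasa(ats, nPoints = 1920L)$total
  expect_lt(abs(a2 - a1) / a1, 0.005)
})

test_that("identical overlapping atoms warn but still compute", {
  ats <- atomSet(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_warning(r <- sasa(ats), "overlapping")
  expect_gt(r$total, 0)
})
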