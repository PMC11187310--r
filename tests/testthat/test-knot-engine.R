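# KMT reduction, closure, Alexander invariants and knot typing.

test_that("KMT reduction collapses trivial geometry and never grows", {
  line <- polyline3D(cbind(2 * seq_len(50), 0.001 * seq_len(50), 0))
  red <- kmtReduce(line)
  expect_equal(nrow(coords(red)), 2L)

  set.seed(42)
  th <- seq(0, 2 * pi, length.out = 201)[-201]
  circ <- polyline3D(15 * cbind(cos(th), sin(th), 0 * th) +
                       matrix(rnorm(600, 0, 0.1), ncol = 3))
  redc <- kmtReduce(circ, closed = TRUE)
  expect_lte(nrow(coords(redc)), 10L)
  expect_equal(unname(alexanderInvariants(redc)), c(1L, 1L))
})

test_that("KMT reduction preserves closed-curve invariants", {
  for (cv in list(trefoilCurve(), figure8Curve(), grannyCurve())) {
    pre <- alexanderInvariants(cv, reduce = FALSE)
    post <- alexanderInvariants(cv, reduce = TRUE)
    expect_identical(pre, post)
    expect_lte(nrow(coords(kmtReduce(cv, closed = TRUE))), nrow(coords(cv)))
  }
})

test_that("Alexander invariants match closed-form values on parametric curves", {
  expect_equal(unname(alexanderInvariants(circleCurve())), c(1L, 1L))
  expect_equal(unname(alexanderInvariants(trefoilCurve())), c(3L, 7L))
  expect_equal(unname(alexanderInvariants(figure8Curve())), c(5L, 11L))
  expect_equal(unname(alexanderInvariants(cinquefoilCurve())), c(5L, 31L))
  expect_equal(unname(alexanderInvariants(fiveTwoCurve())), c(7L, 16L))
  expect_equal(unname(alexanderInvariants(sixOneCurve())), c(9L, 20L))
})

test_that("determinants are multiplicative under connected sum", {
  # braid-closure connected sums sharing one strand, 3_1 x 3_1 built
  # geometrically as well
  expect_equal(unname(alexanderInvariants(grannyCurve())), c(9L, 49L))
  cs34 <- closedCurve("braid", word = c(1, 1, 1, 2, -3, 2, -3))
  expect_equal(unname(alexanderInvariants(cs34)), c(3L * 5L, 7L * 11L))
  cs44 <- closedCurve("braid", word = c(1, -2, 1, -2, 3, -4, 3, -4))
  expect_equal(unname(alexanderInvariants(cs44)), c(5L * 5L, 11L * 11L))
})

test_that("invariants are unchanged by rigid motions and mirroring", {
  base <- list(trefoilCurve(), figure8Curve(), grannyCurve())
  set.seed(7)
  for (cv in base) {
    ref <- alexanderInvariants(cv)
    for (k in 1:4) {
      q <- qr.Q(qr(matrix(rnorm(9), 3)))
      if (det(q) < 0) q[, 1] <- -q[, 1]
      moved <- polyline3D(coords(cv) %*% q +
                            rep(rnorm(3, 0, 30), each = nrow(coords(cv))))
      expect_identical(alexanderInvariants(moved), ref)
    }
    mirrored <- polyline3D(coords(cv) %*% diag(c(1, 1, -1)))
    expect_identical(alexanderInvariants(mirrored), ref)
  }
})

test_that("knot labels come from the invariant-pair lookup", {
  expect_equal(classifyKnot(c(1, 1)), "0_1")
  expect_equal(classifyKnot(c(3, 7)), "3_1")
  expect_equal(classifyKnot(c(5, 11)), "4_1")
  expect_equal(classifyKnot(c(7, 16)), "5_2")
  # the pair disambiguates what the determinant alone cannot
  expect_equal(classifyKnot(c(9, 20)), "6_1")
  expect_equal(classifyKnot(c(9, 49)), "3_1#3_1")
  expect_equal(classifyKnot(c(17, 100)), "unresolved(17,100)")
})

test_that("chain closure is deterministic and respects its strategy", {
  cv <- makeCurve(curveSpec("torus", q = 3, tailN = 15, tailC = 15,
                            seed = 3))$polyline
  cfgA <- closureConfig("sphere_random", nClosures = 100L, seed = 7L)
  a <- closeChain(cv, cfgA)
  b <- closeChain(cv, cfgA)
  expect_identical(lapply(a, coords), lapply(b, coords))
  expect_length(a, 100L)

  d <- closeChain(cv, closureConfig("direct"))
  expect_length(d, 1L)
  expect_equal(nrow(coords(d[[1]])), nrow(coords(cv)))  # one implied segment

  expect_error(closureConfig("direct", nClosures = 5L), NA)
  expect_equal(closureConfig("direct", nClosures = 5L)@nClosures, 1L)
})

test_that("knotType calls deep open knots with high support", {
  cfg <- closureConfig(seed = 1)
  tre <- makeCurve(curveSpec("torus", q = 3, tailN = 20, tailC = 20,
                             seed = 3))$polyline
  kc <- knotType(tre, cfg)
  expect_equal(knotLabel(kc), "3_1")
  expect_gte(supportOf(kc), 0.9)

  comp <- makeCurve(curveSpec("connected_sum", tailN = 20, tailC = 20,
                              seed = 4))$polyline
  kc2 <- knotType(comp, cfg)
  expect_equal(knotLabel(kc2), "3_1#3_1")
  expect_gte(supportOf(kc2), 0.9)

  coil <- makeCurve(curveSpec("random_coil", nPoints = 30, seed = 5))$polyline
  expect_equal(knotLabel(knotType(coil, cfg)), "0_1")

  # determinism of the whole call
  kc3 <- knotType(tre, cfg)
  expect_identical(invariantPair(kc3), invariantPair(kc))
  expect_identical(supportOf(kc3), supportOf(kc))
})

test_that("closed trefoil typed directly has full support", {
  kc <- knotType(trefoilCurve(), closureConfig("direct"))
  expect_equal(knotLabel(kc), "3_1")
  expect_equal(supportOf(kc), 1)
})
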