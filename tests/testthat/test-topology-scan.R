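# Fingerprinting, core localization, composite and slipknot calls.

cfg1 <- closureConfig(seed = 1)

test_that("fingerprint of an unknotted coil has no knotted entries", {
  coil <- makeCurve(curveSpec("random_coil", nPoints = 45, seed = 6))$polyline
  fp <- knotFingerprint(coil, cfg1)
  expect_true(all(fp@entries$label == "0_1"))
  expect_true(any(fp@entries$start == 0 & fp@entries$end == 45))
  expect_error(knotFingerprint(coil, cfg1, stride = 20L), "stride")
})

test_that("a single planted trefoil core is localized within 5 residues", {
  cv <- makeCurve(curveSpec("torus", q = 3, nPoints = 71, tailN = 40,
                            tailC = 89, seed = 21))
  rep <- analyzeTopology(cv$polyline, closureConfig(seed = 21))
  expect_equal(knotLabel(rep), "3_1")
  expect_false(isComposite(rep))
  expect_false(isSlipknotted(rep))
  co <- cores(rep)
  expect_equal(nrow(co), 1L)
  iv <- cv$truth$core_intervals[[1]]
  expect_lte(abs(co$start - iv[1]), 5)
  expect_lte(abs(co$end - iv[2]), 5)
  expect_equal(co$depth_n, co$start - 1L)
  expect_equal(co$depth_c, nrow(coords(cv$polyline)) - co$end)
})

test_that("two planted trefoils give two disjoint cores and composite = TRUE", {
  cv <- makeCurve(curveSpec("connected_sum", tailN = 18, tailC = 18,
                            seed = 22))
  rep <- analyzeTopology(cv$polyline, closureConfig(seed = 22))
  expect_equal(knotLabel(rep), "3_1#3_1")
  expect_true(isComposite(rep))
  co <- cores(rep)
  expect_equal(nrow(co), 2L)
  expect_true(all(co$label == "3_1"))
  expect_lt(co$end[1], co$start[2])            # disjoint
  expect_equal(prod(co$det1), globalCall(rep)@det1)
  expect_equal(prod(co$det2), globalCall(rep)@det2)
  for (i in 1:2) {
    iv <- cv$truth$core_intervals[[i]]
    expect_lte(abs(co$start[i] - iv[1]), 5)
    expect_lte(abs(co$end[i] - iv[2]), 5)
  }
})

test_that("a slipknot is flagged: global unknot with a knotted subchain", {
  cv <- makeCurve(curveSpec("slipknot", seed = 23))
  rep <- analyzeTopology(cv$polyline, closureConfig(seed = 23))
  expect_equal(knotLabel(rep), "0_1")
  expect_true(isSlipknotted(rep))
  expect_false(isComposite(rep))
})

test_that("reported cores are minimal: one more trimmed residue loses the knot", {
  cv <- makeCurve(curveSpec("torus", q = 3, nPoints = 71, tailN = 30,
                            tailC = 30, seed = 24))
  cfg <- closureConfig(seed = 24)
  rep <- analyzeTopology(cv$polyline, cfg)
  co <- cores(rep)
  expect_equal(nrow(co), 1L)
  p <- coords(cv$polyline)
  # trimming 1 + tolerance (2) residues from either end loses the trefoil
  left <- knotType(polyline3D(p[(co$start + 2):co$end, ]), cfg)
  right <- knotType(polyline3D(p[co$start:(co$end - 2), ]), cfg)
  expect_false(knotLabel(left) == "3_1" && knotLabel(right) == "3_1")
})

test_that("minCoreLength and entanglement classification are pure bookkeeping", {
  r1 <- fakeReport("3_1", coreLengths = c(62L, 70L))
  r2 <- fakeReport("3_1", coreLengths = 58L)
  r3 <- fakeReport("0_1", coreLengths = 45L, slip = TRUE, det = c(1L, 1L))
  r4 <- fakeReport("0_1", det = c(1L, 1L))

  expect_equal(minCoreLength(list(r1, r2)), 58L)
  expect_equal(minCoreLength(list(r2)), 58L)
  expect_error(minCoreLength(list(r4)), "not entangled")

  expect_equal(classifyDomainEntanglement(list(r1, r2)), "knot")
  expect_equal(classifyDomainEntanglement(list(r3)), "slipknot")
  expect_equal(classifyDomainEntanglement(list(r1, r3)), "both")
  expect_equal(classifyDomainEntanglement(list(r4)), "none")
})
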