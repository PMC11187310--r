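# Generators: determinism, self-consistent planted truth, and agreement
# between generator and engine.

test_that("generators are deterministic under their seed", {
  for (kind in c("torus", "connected_sum", "slipknot", "random_coil")) {
    a <- makeCurve(curveSpec(kind, seed = 9L))
    b <- makeCurve(curveSpec(kind, seed = 9L))
    expect_identical(coords(a$polyline), coords(b$polyline))
    expect_identical(a$truth, b$truth)
    c <- makeCurve(curveSpec(kind, seed = 10L))
    expect_false(identical(coords(a$polyline), coords(c$polyline)))
  }
  fx1 <- makeAnnotationFixture(nDecoys = 40, seed = 3)
  fx2 <- makeAnnotationFixture(nDecoys = 40, seed = 3)
  expect_identical(fx1, fx2)
})

test_that("planted truth is self-consistent", {
  for (s in 1:5) {
    cs <- makeCurve(curveSpec("connected_sum", seed = s))
    n <- nrow(coords(cs$polyline))
    iv <- cs$truth$core_intervals
    expect_length(iv, 2L)
    for (v in iv) {
      expect_gte(v[1], 1L); expect_lte(v[2], n); expect_lt(v[1], v[2])
    }
    expect_lt(iv[[1]][2], iv[[2]][1])    # disjoint
  }
})

test_that("generator and engine agree on planted labels across kinds", {
  kinds <- list(
    list(spec = curveSpec("unknot", closed = TRUE, noise = 0.2, seed = 1),
         label = "0_1"),
    list(spec = curveSpec("torus", q = 3, tailN = 16, tailC = 16, seed = 2),
         label = "3_1"),
    list(spec = curveSpec("torus", q = 3, closed = TRUE, seed = 3),
         label = "3_1"),
    list(spec = curveSpec("figure8", closed = TRUE, seed = 4),
         label = "4_1"),
    list(spec = curveSpec("connected_sum", tailN = 16, tailC = 16, seed = 5),
         label = "3_1#3_1"),
    list(spec = curveSpec("slipknot", seed = 6), label = "0_1"))
  for (k in kinds) {
    cv <- makeCurve(k$spec)
    kc <- knotType(cv$polyline, closureConfig(seed = 17))
    expect_equal(knotLabel(kc), k$label)
    expect_gte(supportOf(kc), 0.9)
  }
})

test_that("invalid curve specs are refused", {
  expect_error(curveSpec("torus", q = 4), "odd")
  expect_error(curveSpec("braid"), "word")
  expect_error(curveSpec("torus", nPoints = 10), "nPoints")
  expect_error(curveSpec("unknot", noise = -1), "noise")
  # braid closure of a two-component link is refused
  expect_error(makeCurve(curveSpec("braid", word = c(1, 1), nStrands = 2,
                                   closed = TRUE)), "component")
})

test_that("annotation fixture plants pass and decoys fail by construction", {
  fx <- makeAnnotationFixture(nDecoys = 60, seed = 8)
  expect_length(fx$truth, 5L)
  out <- screenArchitectures(fx$records, defaultRegistry())
  expect_setequal(out$protein_id[out$verdict == "candidate"], fx$truth)
  # every planted protein has a qualifying homology hit
  ph <- fx$hits[fx$hits$query_id %in% fx$truth, ]
  expect_equal(nrow(ph), 5L)
  expect_true(all(ph$evalue < 1e-3 & ph$subject_knotted))

  empty <- makeAnnotationFixture(nDecoys = 0, planted = character(0), seed = 1)
  expect_equal(length(empty$truth), 0L)
})

test_that("planted families must exist in the registry", {
  expect_error(makeAnnotationFixture(planted = "PF99999-PF99999", seed = 1),
               "absent")
})
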