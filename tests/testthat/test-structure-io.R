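# PDB / mmCIF parsing, the confidence gate, and the pseudo-PDB writer.

test_that("pseudo-PDB round trip preserves points and coordinates", {
  cv <- makeCurve(curveSpec("torus", q = 3, seed = 1))$polyline
  f <- withr::local_tempfile(fileext = ".pdb")
  writePseudoPdb(cv, f, bfactor = 88)
  model <- readStructure(f)
  expect_length(model@chains, 1L)
  tr <- model@chains[[1]]
  expect_equal(nrow(tr@coords), nrow(coords(cv)))
  expect_lte(max(abs(tr@coords - coords(cv))), 1e-3)
  expect_equal(tr@residueIds, seq_len(nrow(coords(cv))))
  expect_equal(mean(tr@confidence), 88)

  # parsing is deterministic
  model2 <- readStructure(f)
  expect_identical(model2@chains[[1]]@coords, tr@coords)

  expect_error(writePseudoPdb(polyline3D(cbind(0:1, 0, 0)), f), "3 points")
})

test_that("multi-chain files give one trace per chain; CA gaps are logged", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTwoChainPdb(f)
  model <- readStructure(f)
  expect_length(model@chains, 2L)
  expect_setequal(vapply(model@chains, function(ch) ch@chainId, ""),
                  c("A", "B"))
  expect_equal(nrow(model@chains[[1]]@coords), 8L)

  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeTwoChainPdb(f2, gapResidue = 5)
  expect_message(m2 <- readStructure(f2), "gap")
  chA <- m2@chains[[which(vapply(m2@chains, function(ch) ch@chainId, "") == "A")]]
  expect_equal(nrow(chA@coords), 7L)
  expect_false(5L %in% chA@residueIds)
})

test_that("mmCIF input is parsed with per-chain confidence", {
  f <- withr::local_tempfile(fileext = ".cif")
  file.copy(test_path("fixtures", "mini.cif"), f)
  model <- readStructure(f)
  expect_equal(model@sourceFormat, "mmcif")
  expect_length(model@chains, 2L)
  ids <- vapply(model@chains, function(ch) ch@chainId, "")
  a <- model@chains[[match("A", ids)]]
  expect_equal(nrow(a@coords), 3L)
  expect_equal(mean(a@confidence), 90)
})

test_that("the mean-pLDDT gate refuses low-confidence chains unless forced", {
  cv <- makeCurve(curveSpec("unknot", seed = 2))$polyline
  hi <- withr::local_tempfile(fileext = ".pdb")
  lo <- withr::local_tempfile(fileext = ".pdb")
  writePseudoPdb(cv, hi, bfactor = 90)
  writePseudoPdb(cv, lo, bfactor = 50)

  chHi <- readStructure(hi)@chains[[1]]
  chLo <- readStructure(lo)@chains[[1]]
  expect_s4_class(chainToPolyline(chHi, minConfidence = 70), "Polyline3D")
  expect_error(chainToPolyline(chLo, minConfidence = 70), "mean confidence 50")
  expect_s4_class(chainToPolyline(chLo, minConfidence = 70, force = TRUE),
                  "Polyline3D")

  # absent confidence: accepted with a warning
  noConf <- new("ChainTrace", chainId = "X", residueIds = chLo@residueIds,
                coords = chLo@coords, confidence = numeric(0))
  expect_warning(chainToPolyline(noConf, minConfidence = 70), "no confidence")
})

test_that("unreadable or empty inputs error cleanly", {
  expect_error(readStructure(tempfile()), "not found")
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", bad)
  expect_error(readStructure(bad))
})
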