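# The candidate screen, homology gate, gene arrangements and registry.

test_that("screen applies the two-knot and length rules", {
  reg <- data.frame(family_id = c("PF00194", "PF01699"),
                    entanglement_class = "knot",
                    min_core_length = c(200L, 120L),
                    knots_per_domain = c(1, 0.5),
                    stringsAsFactors = FALSE)
  rec <- data.frame(
    protein_id = c("ok", "ok", "single", "short", "short", "caca", "caca",
                   "caca", "caca"),
    length = c(500L, 500L, 400L, 350L, 350L, 300L, 300L, 300L, 300L),
    family_id = c("PF00194", "PF00194", "PF00194", "PF00194", "PF00194",
                  "PF01699", "PF01699", "PF01699", "PF01699"),
    start = c(5L, 260L, 10L, 1L, 160L, 1L, 70L, 140L, 210L),
    end = c(240L, 495L, 300L, 150L, 340L, 60L, 130L, 200L, 280L),
    stringsAsFactors = FALSE)
  out <- screenArchitectures(rec, reg)

  ok <- out[out$protein_id == "ok", ]
  expect_equal(ok$verdict, "candidate")
  expect_equal(ok$architecture, "PF00194-PF00194")
  expect_equal(ok$required_length, 400)

  expect_equal(out$reason[out$protein_id == "single"], "n_entangled<2")
  expect_equal(out$reason[out$protein_id == "short"], "too_short")

  # four half-knot domains = two expected knots, required length 2 x 120
  caca <- out[out$protein_id == "caca", ]
  expect_equal(caca$verdict, "candidate")
  expect_equal(caca$expected_knots, 2)
  expect_equal(caca$required_length, 240)
  expect_equal(caca$architecture, "PF01699-PF01699-PF01699-PF01699")

  # report completeness: every protein exactly once
  expect_setequal(out$protein_id, unique(rec$protein_id))
  expect_equal(nrow(out), length(unique(rec$protein_id)))
})

test_that("a domain range outside the chain rejects that record only", {
  reg <- defaultRegistry()
  rec <- data.frame(protein_id = c("bad", "bad", "good", "good"),
                    length = c(200L, 200L, 400L, 400L),
                    family_id = "PF01746",
                    start = c(1L, 150L, 1L, 200L),
                    end = c(100L, 250L, 120L, 320L),
                    stringsAsFactors = FALSE)
  out <- screenArchitectures(rec, reg)
  expect_equal(out$reason[out$protein_id == "bad"], "invalid_range")
  expect_equal(out$verdict[out$protein_id == "good"], "candidate")
})

test_that("homology gate uses a strict e-value inequality and flags no-hit", {
  reg <- defaultRegistry()
  rec <- do.call(rbind, lapply(c("p1", "p2", "p3", "p4"), function(id)
    data.frame(protein_id = id, length = 400L, family_id = "PF01746",
               start = c(1L, 200L), end = c(120L, 320L),
               stringsAsFactors = FALSE)))
  hits <- data.frame(
    query_id = c("p1", "p2", "p3"),
    subject_id = "S",
    evalue = c(1e-7, 1e-2, 1e-3),
    subject_knotted = c(TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  out <- homologyGate(screenArchitectures(rec, reg), hits)
  expect_equal(out$verdict[out$protein_id == "p1"], "candidate")
  expect_equal(out$reason[out$protein_id == "p2"], "homology")
  # boundary: exactly 1e-3 is rejected (strict <)
  expect_equal(out$reason[out$protein_id == "p3"], "homology")
  # no hits: flagged, not dropped
  p4 <- out[out$protein_id == "p4", ]
  expect_equal(p4$verdict, "candidate")
  expect_true(is.na(p4$passed_homology))
})

test_that("screen recovers exactly the planted architectures among decoys", {
  fx <- makeAnnotationFixture(nDecoys = 200, seed = 11)
  out <- homologyGate(screenArchitectures(fx$records, defaultRegistry()),
                      fx$hits)
  found <- out$protein_id[out$verdict == "candidate"]
  expect_setequal(found, fx$truth)
  summ <- summarizeArchitectures(out)
  expect_equal(nrow(summ), 5L)
  expect_setequal(summ$architecture, tableOneArchitectures())
})

test_that("screen is monotone in core lengths and e-value threshold", {
  fx <- makeAnnotationFixture(nDecoys = 120, seed = 12)
  reg <- defaultRegistry()
  base <- homologyGate(screenArchitectures(fx$records, reg), fx$hits)
  baseSet <- base$protein_id[base$verdict == "candidate"]

  regUp <- reg; regUp$min_core_length <- regUp$min_core_length * 2L
  up <- homologyGate(screenArchitectures(fx$records, regUp), fx$hits)
  expect_true(all(up$protein_id[up$verdict == "candidate"] %in% baseSet))

  tight <- homologyGate(screenArchitectures(fx$records, reg), fx$hits,
                        threshold = 1e-40)
  expect_true(all(tight$protein_id[tight$verdict == "candidate"] %in% baseSet))
})

test_that("gene arrangements classify the four genomic layouts", {
  fx <- makeGeneFixture()
  for (nm in names(fx))
    expect_equal(classifyGeneArrangement(fx[[nm]]$a, fx[[nm]]$b),
                 fx[[nm]]$expected)
  # the adjacency cutoff is configurable
  expect_equal(classifyGeneArrangement(fx$adjacent$a, fx$adjacent$b,
                                       adjacencyMaxGap = 5L), "separated")
  bad <- list(gene_id = "x", start = 10L, end = 5L)
  expect_error(classifyGeneArrangement(bad, fx$adjacent$b), "malformed")
})

test_that("buildRegistry composes classification and minimal length", {
  reps <- list(
    famA = list(fakeReport("3_1", coreLengths = c(60L, 58L))),
    famB = list(fakeReport("0_1", coreLengths = 45L, slip = TRUE,
                           det = c(1L, 1L))),
    famC = list(fakeReport("0_1", det = c(1L, 1L))))
  reg <- buildRegistry(reps)
  expect_setequal(reg$family_id, c("famA", "famB"))
  expect_equal(reg$min_core_length[reg$family_id == "famA"], 58L)
  expect_equal(reg$entanglement_class[reg$family_id == "famB"], "slipknot")
  expect_error(buildRegistry(list()), "no domain")
})
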