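# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

closedCurve <- function(kind, q = 3, word = NULL, n = NULL) {
  makeCurve(curveSpec(kind, q = q, word = word, nPoints = n,
                      closed = TRUE, noise = 0))$polyline
}

# canonical noiseless closed curves
circleCurve <- function() fixture("circle", function() closedCurve("unknot"))
trefoilCurve <- function() fixture("trefoil", function() closedCurve("torus", q = 3))
figure8Curve <- function() fixture("fig8", function() closedCurve("figure8"))
cinquefoilCurve <- function() fixture("t25", function() closedCurve("torus", q = 5))
fiveTwoCurve <- function() fixture("k52", function()
  closedCurve("braid", word = c(1, 1, 1, 2, -1, 2)))
sixOneCurve <- function() fixture("k61", function()
  closedCurve("braid", word = c(1, 1, 2, -1, -3, 2, -3)))
grannyCurve <- function() fixture("granny", function()
  closedCurve("connected_sum"))

# a small PDB text fixture with two chains and one residue lacking a CA
writeTwoChainPdb <- function(path, gapResidue = NULL) {
  rec <- function(serial, name, resno, chain, x, y, z) {
    pad <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
    sprintf("ATOM  %5d %4s GLY %s%4d    %8.3f%8.3f%8.3f  1.00 20.00           %s",
            serial, pad, chain, resno, x, y, z, substr(name, 1, 1))
  }
  lines <- character(0); serial <- 0
  for (ch in c("A", "B")) {
    for (r in 1:8) {
      serial <- serial + 1
      lines <- c(lines, rec(serial, "N", r, ch, 3.8 * r - 1, 0.5, 0))
      if (!(ch == "A" && !is.null(gapResidue) && r == gapResidue)) {
        serial <- serial + 1
        lines <- c(lines, rec(serial, "CA", r, ch,
                              3.8 * r, if (ch == "A") 0 else 10, 0.3 * r))
      }
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# fabricate a TopologyReport without running the engine (for the pure
# bookkeeping operations)
fakeReport <- function(label = "3_1", coreLengths = integer(0),
                       slip = FALSE, det = c(3L, 7L)) {
  cores <- if (length(coreLengths)) {
    data.frame(start = 10L, end = 10L + coreLengths - 1L,
               length = coreLengths, label = "3_1", support = 1,
               det1 = 3L, det2 = 7L, depth_n = 9L, depth_c = 20L,
               stringsAsFactors = FALSE)
  } else {
    data.frame(start = integer(0), end = integer(0), length = integer(0),
               label = character(0), support = numeric(0), det1 = integer(0),
               det2 = integer(0), depth_n = integer(0), depth_c = integer(0),
               stringsAsFactors = FALSE)
  }
  fp <- new("KnotFingerprint",
            entries = data.frame(start = 0L, end = 100L, label = label,
                                 support = 1, det1 = det[1], det2 = det[2],
                                 stringsAsFactors = FALSE),
            stride = 5L, chainLength = 100L)
  new("TopologyReport", chainLabel = "fake",
      globalCall = new("KnotCall", label = label, support = 1,
                       det1 = det[1], det2 = det[2], nClosures = 100L),
      fingerprint = fp, cores = cores, slipknotted = slip,
      composite = FALSE)
}
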