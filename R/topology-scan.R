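## Localization of knotted cores along a chain: subchain fingerprint,
## bisection refinement to the minimal knotted interval, composite and
## slipknot calls.

#' Knot fingerprint over a grid of subchains
#'
#' Computes a [KnotCall-class] for every subchain on a grid of start/end
#' positions at the given stride (0-based half-open residue intervals),
#' plus the full chain.  Entries use a reduced number of closures per
#' subchain; the result is deterministic under the config seed.
#'
#' @param polyline a [Polyline3D-class] of at least `3 * stride` residues.
#' @param config a [ClosureConfig-class]; its seed drives every entry.
#' @param stride grid step in residues (default 5).
#' @param nClosures closures per grid entry (default 20; the final calls of
#'   [locateCores()] re-evaluate candidate intervals at the full
#'   `config@nClosures`).
#' @param callThreshold majority fraction below which an entry is
#'   unresolved.
#' @return a [KnotFingerprint-class].
#' @export
knotFingerprint <- function(polyline, config = closureConfig(), stride = 5L,
                            nClosures = 20L, callThreshold = 0.5) {
  stopifnot(is(polyline, "Polyline3D"))
  n <- nrow(polyline@points)
  stride <- as.integer(stride)
  if (n < 3L * stride) stop("stride too large for chain length")
  minLen <- max(3L * stride, 15L)
  starts <- seq(0L, n - minLen, by = stride)
  ends <- seq(minLen, n, by = stride)
  if (ends[length(ends)] != n) ends <- c(ends, n)
  grid <- expand.grid(start = starts, end = ends)
  grid <- grid[grid$end - grid$start >= minLen, ]
  if (!any(grid$start == 0L & grid$end == n))
    grid <- rbind(grid, data.frame(start = 0L, end = n))
  cfg <- closureConfig(config@strategy,
                       nClosures = if (config@strategy == "direct") 1L else nClosures,
                       seed = config@seed,
                       sphereRadiusFactor = config@sphereRadiusFactor)
  p <- polyline@points
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$start[i]; e <- grid$end[i]
    kc <- knotType(polyline3D(p[(s + 1):e, , drop = FALSE]), cfg, callThreshold)
    data.frame(start = s, end = e, label = kc@label, support = kc@support,
               det1 = kc@det1, det2 = kc@det2, stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, rows)
  entries <- entries[order(entries$start, entries$end), ]
  rownames(entries) <- NULL
  new("KnotFingerprint", entries = entries, stride = stride,
      chainLength = as.integer(n))
}

## is a fingerprint label a definite knot?
isKnottedLabel <- function(label) {
  !is.na(label) & label != "0_1" & !startsWith(label, "unresolved")
}

#' Locate minimal knotted cores
#'
#' Takes the maximal knotted regions of a fingerprint grid, and refines
#' each by bisection trimming -- re-evaluating the knot call at the full
#' closure count -- until the minimal interval still carrying the knot is
#' found at single-residue resolution.  Cores closer than 3 residues are
#' merged and re-called; cores are reported 1-based inclusive and sorted
#' by start.
#'
#' @param fingerprint a [KnotFingerprint-class].
#' @param polyline the chain the fingerprint was computed on.
#' @param config a [ClosureConfig-class] used for refinement calls.
#' @param callThreshold majority fraction for a definite call.
#' @return data.frame of cores: `start`, `end`, `length`, `label`,
#'   `support`, `det1`, `det2`, `depth_n`, `depth_c` (possibly 0 rows).
#' @export
locateCores <- function(fingerprint, polyline, config = closureConfig(),
                        callThreshold = 0.5) {
  stopifnot(is(fingerprint, "KnotFingerprint"), is(polyline, "Polyline3D"))
  e <- fingerprint@entries
  n <- fingerprint@chainLength
  p <- polyline@points
  kn <- e[isKnottedLabel(e$label), , drop = FALSE]
  empty <- data.frame(start = integer(0), end = integer(0), length = integer(0),
                      label = character(0), support = numeric(0),
                      det1 = integer(0), det2 = integer(0),
                      depth_n = integer(0), depth_c = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(kn) == 0) return(empty)

  callIv <- function(s, ei) {    # 0-based half-open interval
    knotType(polyline3D(p[(s + 1):ei, , drop = FALSE]), config, callThreshold)
  }
  ## during refinement the interval must keep carrying the *same* knot:
  ## closures of an over-trimmed interval can re-thread into a different
  ## (spurious) knot type, which must stop the trim, not feed it
  refLabel <- NA_character_
  knottedIv <- function(s, ei) {
    if (ei - s < 3) return(FALSE)
    lab <- callIv(s, ei)@label
    if (is.na(refLabel)) isKnottedLabel(lab) else identical(lab, refLabel)
  }

  ## minimal knotted grid entries: no other knotted entry strictly inside
  len <- kn$end - kn$start
  ord <- order(len)
  kn <- kn[ord, ]
  ## (refinement helper defined below uses refLabel set per candidate)

  ## trim the two ends alternately, one residue at a time, stopping each
  ## side at its first loss of the knot: robust against re-threading
  ## artifacts far inside the core, where a binary search could be fooled
  ## by non-monotone closure statistics
  maxTrim <- 4L * fingerprint@stride
  refineOne <- function(s0, e0) {
    s1 <- s0; e1 <- e0
    k <- 0L
    repeat {
      moved <- FALSE
      if (k < maxTrim && e1 - s1 > 6L) {
        if (knottedIv(s1 + 1L, e1)) { s1 <- s1 + 1L; moved <- TRUE }
        else if (knottedIv(s1 + 2L, e1)) { s1 <- s1 + 2L; moved <- TRUE }
        if (moved) k <- k + 1L
      }
      if (k < maxTrim && e1 - s1 > 6L) {
        if (knottedIv(s1, e1 - 1L)) { e1 <- e1 - 1L; k <- k + 1L; moved <- TRUE }
        else if (knottedIv(s1, e1 - 2L)) { e1 <- e1 - 2L; k <- k + 1L; moved <- TRUE }
      }
      if (!moved) break
    }
    c(s1, e1)
  }

  ## iterative peeling: refine the shortest knotted entry to its minimal
  ## core, then drop every entry overlapping that core (grid entries that
  ## straddle two knots disappear once the first core is claimed), and
  ## repeat on what is left -- disjoint cores by construction
  cores <- NULL
  remaining <- kn
  while (nrow(remaining) > 0 && (is.null(cores) || nrow(cores) < 8)) {
    best <- remaining[which.min(remaining$end - remaining$start), ]
    refLabel <<- best$label[1]
    ## expand by one stride so trimming approaches the boundary from
    ## outside the fuzzy zone rather than from a lucky inside call
    s0 <- max(0L, best$start[1] - fingerprint@stride)
    e0 <- min(n, best$end[1] + fingerprint@stride)
    iv <- refineOne(s0, e0)
    kc <- callIv(iv[1], iv[2])
    if (isKnottedLabel(kc@label)) {
      cores <- rbind(cores, data.frame(
        start = iv[1], end = iv[2], label = kc@label, support = kc@support,
        det1 = kc@det1, det2 = kc@det2, stringsAsFactors = FALSE))
      remaining <- remaining[remaining$end <= iv[1] | remaining$start >= iv[2], ,
                             drop = FALSE]
    } else {
      remaining <- remaining[!(remaining$start == best$start[1] &
                                 remaining$end == best$end[1]), , drop = FALSE]
    }
  }
  if (is.null(cores) || nrow(cores) == 0) return(empty)
  cores <- cores[order(cores$start), , drop = FALSE]
  ## merge cores separated by fewer than 3 residues and re-call
  i <- 1L
  while (i < nrow(cores)) {
    if (cores$start[i + 1] - cores$end[i] < 3) {
      kc <- callIv(cores$start[i], cores$end[i + 1])
      cores[i, c("start", "end", "label", "support", "det1", "det2")] <-
        list(cores$start[i], cores$end[i + 1], kc@label, kc@support,
             kc@det1, kc@det2)
      cores <- cores[-(i + 1), , drop = FALSE]
    } else i <- i + 1L
  }
  cores <- cores[isKnottedLabel(cores$label), , drop = FALSE]
  if (nrow(cores) == 0) return(empty)
  data.frame(start = cores$start + 1L, end = cores$end,
             length = cores$end - cores$start,
             label = cores$label, support = cores$support,
             det1 = cores$det1, det2 = cores$det2,
             depth_n = cores$start, depth_c = n - cores$end,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full topology analysis of one chain
#'
#' Global knot call, subchain fingerprint, core localization, and the
#' composite / slipknot flags: `composite` is TRUE when at least two
#' disjoint cores exist whose invariants multiply to the global invariant
#' pair (the Alexander determinant is multiplicative under connected sum);
#' `slipknotted` is TRUE when the global call is unknotted but some
#' subchain carries a definite knot.
#'
#' @param polyline a [Polyline3D-class].
#' @param config a [ClosureConfig-class].
#' @param stride fingerprint grid step (default 5 residues).
#' @param fpClosures closures per fingerprint entry (default 20).
#' @param callThreshold majority fraction for a definite call.
#' @param chainLabel identifier recorded in the report.
#' @return a [TopologyReport-class].
#' @examples
#' \donttest{
#' cs <- makeCurve(curveSpec("connected_sum", tailN = 20, tailC = 20, seed = 1))
#' rep <- analyzeTopology(cs$polyline, closureConfig(seed = 1))
#' isComposite(rep)  # TRUE
#' }
#' @export
analyzeTopology <- function(polyline, config = closureConfig(), stride = 5L,
                            fpClosures = 20L, callThreshold = 0.5,
                            chainLabel = "chain") {
  stopifnot(is(polyline, "Polyline3D"))
  global <- knotType(polyline, config, callThreshold)
  fp <- knotFingerprint(polyline, config, stride = stride,
                        nClosures = fpClosures, callThreshold = callThreshold)
  cores <- locateCores(fp, polyline, config, callThreshold)
  composite <- FALSE
  if (nrow(cores) >= 2 && !is.na(global@det1)) {
    composite <- prod(cores$det1) == global@det1 &&
      prod(cores$det2) == global@det2
  }
  slip <- global@label == "0_1" && any(isKnottedLabel(fp@entries$label))
  new("TopologyReport", chainLabel = chainLabel, globalCall = global,
      fingerprint = fp, cores = cores, slipknotted = slip,
      composite = composite)
}

#' Minimal knotted-core length over structures
#'
#' The minimum, over all cores of all reports, of the core length in
#' residues -- the "minimal length" a domain needs to carry its knot.
#'
#' @param instances list of [TopologyReport-class] objects.
#' @return integer, the shortest core length.
#' @export
minCoreLength <- function(instances) {
  if (is(instances, "TopologyReport")) instances <- list(instances)
  lens <- unlist(lapply(instances, function(r) r@cores$length))
  if (!length(lens)) stop("domain not entangled: no knotted cores in any report")
  as.integer(min(lens))
}

#' Classify a domain's entanglement
#'
#' A domain family is classified from the topology reports of its
#' structures: `"knot"` when knotted structures occur and none is
#' slipknotted, `"slipknot"` when only slipknotted structures occur,
#' `"both"` when both kinds occur, `"none"` otherwise.
#'
#' @param instances list of [TopologyReport-class] objects.
#' @return one of `"knot"`, `"slipknot"`, `"both"`, `"none"`.
#' @export
classifyDomainEntanglement <- function(instances) {
  if (is(instances, "TopologyReport")) instances <- list(instances)
  if (!length(instances)) stop("need at least one report")
  isSlip <- vapply(instances, function(r) r@slipknotted, logical(1))
  isKnot <- vapply(instances, function(r)
    nrow(r@cores) > 0 && !r@slipknotted &&
      isKnottedLabel(r@globalCall@label), logical(1))
  if (any(isKnot) && any(isSlip)) "both"
  else if (any(isKnot)) "knot"
  else if (any(isSlip)) "slipknot"
  else "none"
}
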