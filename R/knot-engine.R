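## Knot typing of open and closed polygonal curves: KMT reduction,
## stochastic closure, exact Alexander-determinant invariants, label lookup.

#' Construct a Polyline3D
#'
#' @param points numeric matrix (n x 3) of coordinates in angstroms, or a
#'   three-column object coercible to one.
#' @param labels optional integer residue indices parallel to the rows.
#' @return a [Polyline3D-class] object.
#' @examples
#' pl <- polyline3D(cbind(1:5, 0, 0))
#' @export
polyline3D <- function(points, labels = integer(0)) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  new("Polyline3D", points = points, labels = as.integer(labels))
}

#' Construct a ClosureConfig
#'
#' Defaults follow common practice for deep protein knots: 100 random
#' sphere closures with the closure sphere at twice the chain's radius, and
#' a mandatory seed so every call is reproducible.
#'
#' @param strategy `"sphere_random"` (default), `"two_ray"` or `"direct"`.
#' @param nClosures closures to evaluate (forced to 1 for `direct`).
#' @param seed integer seed; required for stochastic strategies.
#' @param sphereRadiusFactor closure-sphere radius relative to the chain's
#'   maximal centroid distance.
#' @return a [ClosureConfig-class] object.
#' @export
closureConfig <- function(strategy = c("sphere_random", "direct", "two_ray"),
                          nClosures = 100L, seed = 1L,
                          sphereRadiusFactor = 2.0) {
  strategy <- match.arg(strategy)
  if (strategy == "direct") nClosures <- 1L
  new("ClosureConfig", strategy = strategy, nClosures = as.integer(nClosures),
      seed = as.integer(seed), sphereRadiusFactor = sphereRadiusFactor)
}

## run expr with a locally seeded RNG, restoring the caller's stream
withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## Deterministic sequence of projection rotations: Fibonacci-sphere view
## directions, each completed to an orthonormal frame.  Independent of the
## RNG so invariant computation never consumes random numbers.
projectionRotations <- function(n = 25L) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  w <- cbind(r * cos(phi), r * sin(phi), z)   # projection (z) axis
  rots <- matrix(0, n, 9)
  for (k in seq_len(n)) {
    wz <- w[k, ]
    a <- if (abs(wz[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- a - sum(a * wz) * wz
    u <- u / sqrt(sum(u^2))
    v <- c(wz[2] * u[3] - wz[3] * u[2],
           wz[3] * u[1] - wz[1] * u[3],
           wz[1] * u[2] - wz[2] * u[1])
    rots[k, ] <- c(u, v, wz)
  }
  rots
}

.ROTS <- NULL
getRotations <- function() {
  if (is.null(.ROTS)) utils::assignInMyNamespace(".ROTS", projectionRotations(25L))
  .ROTS
}

#' KMT chain reduction
#'
#' Iteratively removes every vertex whose triangle with its two neighbours
#' is pierced by no other segment of the chain, until a full sweep removes
#' nothing.  Endpoints of open chains are never removed; for closed curves
#' the knot invariants are preserved.
#'
#' @param polyline a [Polyline3D-class].
#' @param closed treat the curve as closed (last vertex joins the first).
#' @return a [ReducedPolyline-class].
#' @examples
#' line <- polyline3D(cbind(seq_len(10), 0, 0))
#' kmtReduce(line)  # collapses to its endpoints
#' @export
kmtReduce <- function(polyline, closed = FALSE) {
  stopifnot(is(polyline, "Polyline3D"))
  p <- polyline@points
  if (nrow(p) < 3) stop("kmtReduce needs at least 3 points")
  keep <- kmt_indices_cpp(p, closed)
  lab <- if (length(polyline@labels)) polyline@labels[keep] else integer(0)
  new("ReducedPolyline", points = p[keep, , drop = FALSE], labels = lab,
      originalCount = nrow(p), keptIndices = as.integer(keep))
}

## closure arcs: list of matrices of extra vertices appended after the last
## chain point; the closed polygon then wraps back to the first point.
## Consumes RNG draws for sphere_random (seeding is the caller's job).
closureArcs <- function(points, config) {
  n <- nrow(points)
  if (config@strategy == "direct")
    return(list(matrix(numeric(0), ncol = 3)))
  ctr <- colMeans(points)
  rad <- sqrt(max(rowSums((points - rep(ctr, each = n))^2)))
  if (rad < 1e-6) rad <- 1
  R <- config@sphereRadiusFactor * rad
  far <- 100 * R
  nc <- config@nClosures
  if (config@strategy == "two_ray") {
    dN <- points[1, ] - points[2, ]
    dC <- points[n, ] - points[n - 1, ]
    dN <- dN / sqrt(sum(dN^2)); dC <- dC / sqrt(sum(dC^2))
    ## push each terminus along its own direction to the sphere, then far out
    sC <- raySphere(points[n, ], dC, ctr, R)
    sN <- raySphere(points[1, ], dN, ctr, R)
    arc <- rbind(sC, ctr + far * (sC - ctr) / sqrt(sum((sC - ctr)^2)),
                 ctr + far * (sN - ctr) / sqrt(sum((sN - ctr)^2)), sN)
    return(rep(list(arc), nc))
  }
  ## sphere_random: one independent sphere point per terminus per closure
  u <- matrix(stats::rnorm(nc * 6), ncol = 6)
  lapply(seq_len(nc), function(i) {
    vC <- u[i, 1:3] / sqrt(sum(u[i, 1:3]^2))
    vN <- u[i, 4:6] / sqrt(sum(u[i, 4:6]^2))
    rbind(ctr + R * vC, ctr + far * vC, ctr + far * vN, ctr + R * vN)
  })
}

raySphere <- function(p, d, ctr, R) {
  ## first intersection of ray p + t d (t > 0) with sphere (ctr, R)
  pc <- p - ctr
  b <- sum(pc * d); c0 <- sum(pc^2) - R^2
  disc <- b^2 - c0
  t <- if (disc <= 0) 2 * R else -b + sqrt(disc)
  if (t <= 0) t <- 2 * R
  p + t * d
}

#' Close an open chain
#'
#' Produces explicitly closed curves for the configured closure strategy:
#' `direct` joins the termini with one segment, `sphere_random` extends
#' both termini to random points on a sphere around the chain and joins
#' them far outside it, `two_ray` extends the termini along their terminal
#' directions.  The same seed always produces identical closures.
#'
#' @param polyline an open [Polyline3D-class].
#' @param config a [ClosureConfig-class].
#' @return a list of closed [Polyline3D-class] curves (closure implied
#'   between last and first vertex).
#' @export
closeChain <- function(polyline, config = closureConfig()) {
  stopifnot(is(polyline, "Polyline3D"))
  p <- polyline@points
  if (nrow(p) < 3) stop("need at least 3 points")
  arcs <- withLocalSeed(config@seed, closureArcs(p, config))
  lapply(arcs, function(a) polyline3D(rbind(p, a)))
}

#' Alexander-determinant invariants of a closed curve
#'
#' Projects the closed curve along a deterministic sequence of generic
#' directions, builds the Alexander matrix of the resulting diagram, and
#' evaluates the (normalized) Alexander polynomial at t = -1 and t = -2
#' over exact integer arithmetic.  A zero-crossing diagram returns (1, 1).
#'
#' @param polyline a closed [Polyline3D-class] (closure implied between the
#'   last and first vertex), at least 3 points.
#' @param reduce run KMT reduction first (default TRUE; the invariants are
#'   unchanged, the diagram gets much smaller).
#' @return named integer vector `c(det1, det2)` with
#'   `det1 = |Delta(-1)|`, `det2 = |Delta(-2)|`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 61)[-61]
#' circle <- polyline3D(10 * cbind(cos(th), sin(th), 0 * th))
#' alexanderInvariants(circle)  # (1, 1): unknot
#' @export
alexanderInvariants <- function(polyline, reduce = TRUE) {
  stopifnot(is(polyline, "Polyline3D"))
  p <- polyline@points
  if (nrow(p) < 3) stop("need at least 3 points")
  if (reduce && nrow(p) > 3) p <- kmtReduce(polyline, closed = TRUE)@points
  res <- alex_batch_cpp(p, list(matrix(numeric(0), ncol = 3)), getRotations())
  if (is.na(res[1, 1]))
    stop("no generic projection found after maximum retries")
  c(det1 = as.integer(res[1, 1]), det2 = as.integer(res[1, 2]))
}

## label lookup: |Delta(-1)|, |Delta(-2)| pairs of the knots this package
## can name, including the composite double trefoil
.KNOT_TABLE <- c(
  "1/1"   = "0_1",
  "3/7"   = "3_1",
  "5/11"  = "4_1",
  "5/31"  = "5_1",
  "7/16"  = "5_2",
  "9/20"  = "6_1",
  "11/59" = "6_2",
  "13/67" = "6_3",
  "9/49"  = "3_1#3_1"
)

#' Label a knot from its invariant pair
#'
#' Looks the pair (`|Delta(-1)|`, `|Delta(-2)|`) up in the table of knots
#' through six crossings plus the composite double trefoil.  The pair
#' disambiguates what the determinant alone cannot: 6_1 and 3_1#3_1 share
#' det1 = 9 but differ at t = -2 (20 vs 49).  Unknown pairs map to
#' `"unresolved(det1,det2)"`.
#'
#' @param inv integer vector `c(det1, det2)` as returned by
#'   [alexanderInvariants()].
#' @return a single character label.
#' @examples
#' classifyKnot(c(3, 7))   # "3_1"
#' classifyKnot(c(9, 49))  # "3_1#3_1"
#' @export
classifyKnot <- function(inv) {
  if (any(is.na(inv))) return("unresolved(NA,NA)")
  key <- paste0(inv[1], "/", inv[2])
  if (key %in% names(.KNOT_TABLE)) unname(.KNOT_TABLE[[key]])
  else sprintf("unresolved(%d,%d)", as.integer(inv[1]), as.integer(inv[2]))
}

#' Knot type of a chain by reduction, closure and majority vote
#'
#' The full engine: KMT-reduce the open chain, close it `nClosures` times
#' according to `config`, compute the Alexander invariant pair for every
#' closure, and call the majority label.  The call is demoted to
#' `"unresolved"` when the majority support falls below `callThreshold`.
#' Fixed seed and config give an identical result.
#'
#' @param polyline a [Polyline3D-class] (open chain; pass a closed curve
#'   with `strategy = "direct"` to type it as-is).
#' @param config a [ClosureConfig-class].
#' @param callThreshold minimal majority fraction for a definite label
#'   (default 0.5, strict majority).
#' @return a [KnotCall-class].
#' @examples
#' tre <- makeCurve(curveSpec("torus", q = 3, closed = TRUE, noise = 0))$polyline
#' knotType(tre, closureConfig("direct"))  # 3_1, support 1
#' @export
knotType <- function(polyline, config = closureConfig(), callThreshold = 0.5) {
  stopifnot(is(polyline, "Polyline3D"))
  p <- polyline@points
  if (nrow(p) < 3) stop("need at least 3 points")
  red <- if (nrow(p) > 3) kmtReduce(polyline, closed = FALSE)@points else p
  arcs <- withLocalSeed(config@seed, closureArcs(red, config))
  res <- alex_batch_cpp(red, arcs, getRotations())
  votes <- ifelse(is.na(res[, 1]), "NA/NA", paste0(res[, 1], "/", res[, 2]))
  tab <- sort(table(votes), decreasing = TRUE)
  top <- names(tab)[1]
  n <- nrow(res)
  if (top == "NA/NA") {
    return(new("KnotCall", label = "unresolved(NA,NA)", support = 0,
               det1 = NA_integer_, det2 = NA_integer_, nClosures = as.integer(n)))
  }
  support <- as.numeric(tab[1]) / n
  pair <- as.integer(strsplit(top, "/", fixed = TRUE)[[1]])
  label <- classifyKnot(pair)
  if (support < callThreshold && !startsWith(label, "unresolved"))
    label <- sprintf("unresolved(%d,%d)", pair[1], pair[2])
  new("KnotCall", label = label, support = support,
      det1 = pair[1], det2 = pair[2], nClosures = as.integer(n))
}
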