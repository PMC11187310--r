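## Solvent-accessible surface areas by Shrake-Rupley sphere sampling and
## the buried interface area B = SASA1 + SASA2 - SASA12 of a two-partner
## complex.

## NACCESS-style van der Waals radii (angstrom)
.VDW_RADII <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.80, H = 1.00)
.VDW_DEFAULT <- 1.80

#' Construct an atom set
#'
#' @param elements character vector of element symbols.
#' @param coords numeric matrix (n x 3) of coordinates in angstroms.
#' @param radii optional per-atom van der Waals radii; defaults to a
#'   NACCESS-style element table (C 1.87, N 1.65, O 1.40, S 1.85, P 1.80,
#'   H 1.00, otherwise 1.80 A).
#' @return list of class `"AtomSet"` with `elements`, `coords`, `radii`.
#' @export
atomSet <- function(elements, coords, radii = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3) stop("coords must have 3 columns")
  if (length(elements) != nrow(coords)) stop("one element per atom")
  if (nrow(coords) < 1) stop("at least one atom required")
  if (is.null(radii)) {
    radii <- unname(.VDW_RADII[toupper(elements)])
    radii[is.na(radii)] <- .VDW_DEFAULT
  }
  if (any(radii <= 0)) stop("radii must be positive")
  structure(list(elements = as.character(elements), coords = unname(coords),
                 radii = as.numeric(radii)), class = "AtomSet")
}

#' Atom set from a structure file
#'
#' Reads all non-hydrogen, non-water ATOM records of the selected chains.
#'
#' @param path PDB/mmCIF file.
#' @param chains optional chain ids to keep (default: all).
#' @return an `"AtomSet"`.
#' @export
atomSetFromStructure <- function(path, chains = NULL) {
  parsed <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE)
  at <- parsed$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT")), , drop = FALSE]
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms selected")
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(el == ""))
    el <- substr(trimws(at$elety), 1, 1)
  atomSet(el, as.matrix(at[, c("x", "y", "z")]))
}

## deterministic Fibonacci sphere point set (n x 3 unit vectors)
fibonacciSphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

## Orientation frame from the atom coordinates: principal axes with signs
## fixed by third moments, right-handed.  The sampling sphere is expressed
## in this molecule-attached frame, which makes the computed areas
## invariant under rigid motions up to numerical eigen precision.
molecularFrame <- function(coords) {
  n <- nrow(coords)
  if (n < 3) return(diag(3))
  cc <- sweep(coords, 2, colMeans(coords))
  cv <- crossprod(cc) / n
  ev <- eigen(cv, symmetric = TRUE)
  if (min(abs(diff(ev$values))) < 1e-6 * max(abs(ev$values), 1e-9)) {
    ## (near-)degenerate principal values: fall back to the lab frame
    ## rather than pick an arbitrary rotation
    return(diag(3))
  }
  V <- ev$vectors
  for (k in 1:3) {
    s <- sum((cc %*% V[, k])^3)
    if (abs(s) > 1e-9 && s < 0) V[, k] <- -V[, k]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom accessible areas by deterministic sphere sampling: `nPoints`
#' Fibonacci-lattice points on each atom's expanded sphere (radius =
#' vdW + probe); a point is accessible when it lies inside no other
#' atom's expanded sphere.  The point set is oriented in a
#' molecule-attached principal-axes frame, so areas are invariant under
#' rigid motions; no randomness is involved.
#'
#' @param atoms an `"AtomSet"`.
#' @param probeRadius solvent probe radius in angstroms (default 1.4, a
#'   water molecule).
#' @param nPoints sample points per atom (default 960).
#' @return list with `total` (A^2) and `perAtom` (numeric vector).
#' @examples
#' a <- atomSet("C", matrix(0, 1, 3))
#' sasa(a)$total           # isolated sphere: 4*pi*(1.87+1.4)^2
#' @export
sasa <- function(atoms, probeRadius = 1.4, nPoints = 960L) {
  stopifnot(inherits(atoms, "AtomSet"), probeRadius >= 0, nPoints >= 100)
  xyz <- atoms$coords
  n <- nrow(xyz)
  R <- atoms$radii + probeRadius
  S <- fibonacciSphere(as.integer(nPoints)) %*% t(molecularFrame(xyz))
  if (n > 1) {
    d2 <- as.matrix(stats::dist(xyz))^2
    if (any(d2[upper.tri(d2)] < 1e-12))
      warning("overlapping identical atoms; areas computed as-is")
  }
  per <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(S * R[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, nPoints)
    if (n > 1) {
      nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
      for (j in nb) {
        if (!any(acc)) break
        dj <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        acc <- acc & dj > R[j]^2
      }
    }
    per[i] <- 4 * pi * R[i]^2 * sum(acc) / nPoints
  }
  list(total = sum(per), perAtom = per)
}

#' Buried interface area of a binary complex
#'
#' Computes SASA of each partner in isolation and of their union, and
#' the buried area `B = SASA1 + SASA2 - SASA12`.  Swapping the partners
#' leaves B unchanged; partners out of contact give B = 0 up to the
#' sampling tolerance.
#'
#' @param set1,set2 `"AtomSet"` partners.
#' @param probeRadius solvent probe radius (default 1.4 A).
#' @param nPoints sample points per atom (default 960).
#' @return an [InterfaceResult-class].
#' @examples
#' a <- atomSet("C", matrix(c(0, 0, 0), 1))
#' b <- atomSet("C", matrix(c(3, 0, 0), 1))
#' buriedArea(interfaceB(a, b))   # twice the analytic buried cap area
#' @export
interfaceB <- function(set1, set2, probeRadius = 1.4, nPoints = 960L) {
  stopifnot(inherits(set1, "AtomSet"), inherits(set2, "AtomSet"))
  s1 <- sasa(set1, probeRadius, nPoints)$total
  s2 <- sasa(set2, probeRadius, nPoints)$total
  both <- atomSet(c(set1$elements, set2$elements),
                  rbind(set1$coords, set2$coords),
                  c(set1$radii, set2$radii))
  s12 <- sasa(both, probeRadius, nPoints)$total
  new("InterfaceResult", sasa1 = s1, sasa2 = s2, sasa12 = s12,
      buriedB = s1 + s2 - s12, probeRadius = probeRadius,
      nPoints = as.integer(nPoints))
}
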