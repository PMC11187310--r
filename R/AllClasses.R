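#' @import methods
NULL

#' Polyline3D: an ordered 3D backbone curve
#'
#' The carrier object for every topology operation: an ordered set of 3D
#' points (typically one C-alpha per residue, in angstroms) with optional
#' parallel residue labels.  Open chains are stored as-is; closing is done
#' explicitly by [closeChain()] or implicitly by the closure machinery of
#' [knotType()].
#'
#' @slot points numeric matrix with 3 columns (x, y, z in angstroms).
#' @slot labels integer vector of residue indices parallel to the rows of
#'   `points`, or length zero when unlabelled.
#'
#' @seealso [polyline3D()], [knotType()], [kmtReduce()]
#' @export
setClass("Polyline3D",
  representation(points = "matrix", labels = "integer"),
  prototype(points = matrix(numeric(0), ncol = 3), labels = integer(0))
)

setValidity("Polyline3D", function(object) {
  p <- object@points
  if (!is.numeric(p) || ncol(p) != 3) return("points must be a numeric matrix with 3 columns")
  if (nrow(p) < 1) return("at least one point required")
  if (!all(is.finite(p))) return("coordinates must be finite")
  if (length(object@labels) && length(object@labels) != nrow(p))
    return("labels must be empty or parallel to points")
  if (nrow(p) > 1) {
    d <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
    if (any(d < 1e-9)) return("consecutive points must be distinct")
  }
  TRUE
})

#' ReducedPolyline: a KMT-reduced curve
#'
#' Result of [kmtReduce()]: a [Polyline3D-class] whose vertex count is no
#' larger than the input's, carrying the original point count and the
#' indices of the surviving vertices.  For closed inputs the reduction
#' preserves the knot invariants.
#'
#' @slot originalCount integer, number of vertices before reduction.
#' @slot keptIndices integer, 1-based indices of surviving input vertices.
#' @export
setClass("ReducedPolyline",
  contains = "Polyline3D",
  representation(originalCount = "integer", keptIndices = "integer")
)

setValidity("ReducedPolyline", function(object) {
  if (nrow(object@points) > object@originalCount)
    return("reduction must not increase the point count")
  TRUE
})

#' ChainTrace: one chain's C-alpha trace
#'
#' @slot chainId single character chain identifier.
#' @slot residueIds strictly increasing integer author residue numbers.
#' @slot coords numeric matrix (n x 3) of C-alpha coordinates in angstroms.
#' @slot confidence per-residue confidence score in \[0, 100\] (pLDDT read
#'   from the B-factor column), or length zero when absent.
#' @export
setClass("ChainTrace",
  representation(chainId = "character", residueIds = "integer",
                 coords = "matrix", confidence = "numeric")
)

setValidity("ChainTrace", function(object) {
  n <- nrow(object@coords)
  if (length(object@residueIds) != n) return("one residue id per coordinate row")
  if (n > 1 && any(diff(object@residueIds) <= 0))
    return("residue ids must be strictly increasing")
  if (length(object@confidence) && length(object@confidence) != n)
    return("confidence must be empty or per-residue")
  if (n > 1) {
    d <- sqrt(rowSums((object@coords[-1, , drop = FALSE] -
                       object@coords[-n, , drop = FALSE])^2))
    if (any(d < 1e-9)) return("consecutive points must be distinct")
  }
  TRUE
})

#' StructureModel: a parsed structure file
#'
#' One model with one [ChainTrace-class] per polymer chain, as returned by
#' [readStructure()].
#'
#' @slot modelId single character identifier (derived from the file name).
#' @slot chains list of [ChainTrace-class] objects.
#' @slot sourceFormat one of `"pdb"`, `"mmcif"`, `"synthetic"`.
#' @export
setClass("StructureModel",
  representation(modelId = "character", chains = "list", sourceFormat = "character")
)

setValidity("StructureModel", function(object) {
  if (length(object@chains) < 1) return("model contains no polymer chains")
  if (!all(vapply(object@chains, is, logical(1), "ChainTrace")))
    return("chains must be ChainTrace objects")
  ids <- vapply(object@chains, function(ch) ch@chainId, character(1))
  if (anyDuplicated(ids)) return("chain ids must be unique within a model")
  if (!object@sourceFormat %in% c("pdb", "mmcif", "synthetic"))
    return("sourceFormat must be pdb, mmcif or synthetic")
  TRUE
})

#' ClosureConfig: how open chains are closed
#'
#' Settings for the stochastic (or deterministic) closure used to assign a
#' knot type to an open chain.  `sphere_random` extends both termini to
#' random points on a sphere around the chain and joins them far outside it;
#' `two_ray` extends the termini along their terminal directions; `direct`
#' joins the termini with a single segment.
#'
#' @slot strategy one of `"direct"`, `"sphere_random"`, `"two_ray"`.
#' @slot nClosures number of closures (1 for `direct`).
#' @slot seed integer seed driving closure directions.
#' @slot sphereRadiusFactor sphere radius as a multiple of the chain's
#'   maximal distance from its centroid.
#' @seealso [closureConfig()], [knotType()]
#' @export
setClass("ClosureConfig",
  representation(strategy = "character", nClosures = "integer",
                 seed = "integer", sphereRadiusFactor = "numeric")
)

setValidity("ClosureConfig", function(object) {
  if (!object@strategy %in% c("direct", "sphere_random", "two_ray"))
    return("strategy must be direct, sphere_random or two_ray")
  if (object@nClosures < 1L) return("nClosures must be >= 1")
  if (object@strategy == "direct" && object@nClosures != 1L)
    return("direct closure forces nClosures = 1")
  if (object@sphereRadiusFactor <= 0) return("sphereRadiusFactor must be positive")
  TRUE
})

#' KnotCall: a knot-type decision with its support
#'
#' @slot label knot label (`"0_1"`, `"3_1"`, ..., `"3_1#3_1"`, or
#'   `"unresolved(d1,d2)"`).
#' @slot support fraction of closures voting for the majority invariant pair.
#' @slot det1 majority `|Delta(-1)|` (the knot determinant).
#' @slot det2 majority `|Delta(-2)|`.
#' @slot nClosures number of closures evaluated.
#' @export
setClass("KnotCall",
  representation(label = "character", support = "numeric",
                 det1 = "integer", det2 = "integer", nClosures = "integer")
)

setValidity("KnotCall", function(object) {
  if (length(object@label) != 1) return("label must be a single string")
  if (object@support < 0 || object@support > 1) return("support must be in [0, 1]")
  TRUE
})

#' KnotFingerprint: knot calls over a grid of subchains
#'
#' @slot entries data.frame with columns `start`, `end` (0-based half-open
#'   residue interval), `label`, `support`, `det1`, `det2`.
#' @slot stride grid step in residues.
#' @slot chainLength number of residues in the scanned chain.
#' @export
setClass("KnotFingerprint",
  representation(entries = "data.frame", stride = "integer", chainLength = "integer")
)

setValidity("KnotFingerprint", function(object) {
  e <- object@entries
  need <- c("start", "end", "label", "support", "det1", "det2")
  if (!all(need %in% names(e))) return("entries missing required columns")
  if (nrow(e)) {
    if (any(e$start < 0 | e$end > object@chainLength | e$start >= e$end))
      return("intervals must satisfy 0 <= start < end <= chainLength")
    if (!any(e$start == 0 & e$end == object@chainLength))
      return("full-chain interval must be present")
  }
  TRUE
})

#' TopologyReport: full topology analysis of one chain
#'
#' @slot chainLabel identifier of the analysed chain.
#' @slot globalCall [KnotCall-class] for the whole chain.
#' @slot fingerprint [KnotFingerprint-class] used for localization.
#' @slot cores data.frame of knotted cores: `start`, `end` (1-based
#'   inclusive), `length`, `label`, `support`, `det1`, `det2`, `depth_n`,
#'   `depth_c`.
#' @slot slipknotted TRUE when the global call is unknotted but some
#'   subchain carries a knot.
#' @slot composite TRUE when two or more disjoint cores multiply to the
#'   global invariants (a composite knot such as 3_1#3_1).
#' @export
setClass("TopologyReport",
  representation(chainLabel = "character", globalCall = "KnotCall",
                 fingerprint = "KnotFingerprint", cores = "data.frame",
                 slipknotted = "logical", composite = "logical")
)

#' InterfaceResult: SASA terms and buried interface area
#'
#' Holds the three solvent-accessible surface areas of a two-partner
#' complex and the buried area B = SASA1 + SASA2 - SASA12.
#'
#' @slot sasa1,sasa2 SASA of each partner in isolation (A^2).
#' @slot sasa12 SASA of the binary complex (A^2).
#' @slot buriedB buried interface area (A^2).
#' @slot probeRadius probe radius used (A).
#' @slot nPoints sphere sample points per atom.
#' @export
setClass("InterfaceResult",
  representation(sasa1 = "numeric", sasa2 = "numeric", sasa12 = "numeric",
                 buriedB = "numeric", probeRadius = "numeric", nPoints = "integer")
)

setValidity("InterfaceResult", function(object) {
  if (abs(object@buriedB - (object@sasa1 + object@sasa2 - object@sasa12)) > 1e-6)
    return("buriedB must equal sasa1 + sasa2 - sasa12")
  TRUE
})
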