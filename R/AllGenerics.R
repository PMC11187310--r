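#' Accessors for knotscan classes
#'
#' Small accessor generics so that slots never need to be touched directly:
#' `coords()` returns the coordinate matrix of a curve or trace,
#' `residueLabels()` its residue indices, `knotLabel()` / `supportOf()` /
#' `invariantPair()` the content of a [KnotCall-class], `cores()` /
#' `globalCall()` / `isComposite()` / `isSlipknotted()` the content of a
#' [TopologyReport-class], `fpEntries()` the grid of a
#' [KnotFingerprint-class], and `buriedArea()` the buried interface area of
#' an [InterfaceResult-class].
#'
#' @param x an object of the documented class.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname accessors
#' @export
setGeneric("residueLabels", function(x) standardGeneric("residueLabels"))
#' @rdname accessors
#' @export
setGeneric("knotLabel", function(x) standardGeneric("knotLabel"))
#' @rdname accessors
#' @export
setGeneric("supportOf", function(x) standardGeneric("supportOf"))
#' @rdname accessors
#' @export
setGeneric("invariantPair", function(x) standardGeneric("invariantPair"))
#' @rdname accessors
#' @export
setGeneric("cores", function(x) standardGeneric("cores"))
#' @rdname accessors
#' @export
setGeneric("globalCall", function(x) standardGeneric("globalCall"))
#' @rdname accessors
#' @export
setGeneric("isComposite", function(x) standardGeneric("isComposite"))
#' @rdname accessors
#' @export
setGeneric("isSlipknotted", function(x) standardGeneric("isSlipknotted"))
#' @rdname accessors
#' @export
setGeneric("fpEntries", function(x) standardGeneric("fpEntries"))
#' @rdname accessors
#' @export
setGeneric("buriedArea", function(x) standardGeneric("buriedArea"))

#' @rdname accessors
#' @export
setMethod("coords", "Polyline3D", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("coords", "ChainTrace", function(x) x@coords)
#' @rdname accessors
#' @export
setMethod("residueLabels", "Polyline3D", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("residueLabels", "ChainTrace", function(x) x@residueIds)
#' @rdname accessors
#' @export
setMethod("knotLabel", "KnotCall", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("knotLabel", "TopologyReport", function(x) x@globalCall@label)
#' @rdname accessors
#' @export
setMethod("supportOf", "KnotCall", function(x) x@support)
#' @rdname accessors
#' @export
setMethod("invariantPair", "KnotCall", function(x) c(det1 = x@det1, det2 = x@det2))
#' @rdname accessors
#' @export
setMethod("cores", "TopologyReport", function(x) x@cores)
#' @rdname accessors
#' @export
setMethod("globalCall", "TopologyReport", function(x) x@globalCall)
#' @rdname accessors
#' @export
setMethod("isComposite", "TopologyReport", function(x) x@composite)
#' @rdname accessors
#' @export
setMethod("isSlipknotted", "TopologyReport", function(x) x@slipknotted)
#' @rdname accessors
#' @export
setMethod("fpEntries", "KnotFingerprint", function(x) x@entries)
#' @rdname accessors
#' @export
setMethod("buriedArea", "InterfaceResult", function(x) x@buriedB)

setMethod("show", "Polyline3D", function(object) {
  cat(sprintf("Polyline3D with %d points", nrow(object@points)))
  if (length(object@labels)) cat(sprintf(" (residues %d..%d)",
                                         min(object@labels), max(object@labels)))
  cat("\n")
})

setMethod("show", "ReducedPolyline", function(object) {
  cat(sprintf("ReducedPolyline: %d -> %d points\n",
              object@originalCount, nrow(object@points)))
})

setMethod("show", "StructureModel", function(object) {
  cat(sprintf("StructureModel '%s' (%s), %d chain(s):\n",
              object@modelId, object@sourceFormat, length(object@chains)))
  for (ch in object@chains)
    cat(sprintf("  chain %s: %d residues%s\n", ch@chainId, nrow(ch@coords),
                if (length(ch@confidence))
                  sprintf(", mean confidence %.1f", mean(ch@confidence)) else ""))
})

setMethod("show", "KnotCall", function(object) {
  cat(sprintf("KnotCall: %s (support %.2f over %d closures; |Delta(-1)|=%d, |Delta(-2)|=%d)\n",
              object@label, object@support, object@nClosures,
              object@det1, object@det2))
})

setMethod("show", "KnotFingerprint", function(object) {
  kn <- sum(!object@entries$label %in% "0_1")
  cat(sprintf("KnotFingerprint: %d subchain entries (stride %d, chain length %d), %d knotted\n",
              nrow(object@entries), object@stride, object@chainLength, kn))
})

setMethod("show", "TopologyReport", function(object) {
  cat(sprintf("TopologyReport for '%s': global %s", object@chainLabel,
              object@globalCall@label))
  if (object@composite) cat(" [composite]")
  if (object@slipknotted) cat(" [slipknot]")
  cat(sprintf("; %d core(s)\n", nrow(object@cores)))
  if (nrow(object@cores)) {
    for (i in seq_len(nrow(object@cores)))
      cat(sprintf("  core %d: %s at residues %d-%d (depth N %d, C %d)\n", i,
                  object@cores$label[i], object@cores$start[i], object@cores$end[i],
                  object@cores$depth_n[i], object@cores$depth_c[i]))
  }
})

setMethod("show", "InterfaceResult", function(object) {
  cat(sprintf("InterfaceResult: SASA1 = %.1f, SASA2 = %.1f, SASA12 = %.1f, B = %.1f A^2\n",
              object@sasa1, object@sasa2, object@sasa12, object@buriedB))
})
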