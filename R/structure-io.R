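## Reading protein structures into C-alpha chain traces, the confidence
## gate for predicted models, and the pseudo-PDB writer used for synthetic
## curves.

#' Read a protein structure into per-chain C-alpha traces
#'
#' Parses a PDB or mmCIF file (via bio3d) and extracts one
#' [ChainTrace-class] per polymer chain: C-alpha coordinates in file
#' order, author residue numbers, and per-residue confidence taken from
#' the B-factor column when every B-factor in the model lies in
#' \[0, 100\] (the convention predicted models use for pLDDT).  Residues
#' lacking a C-alpha are skipped with a message; only altloc '' or 'A'
#' atoms are kept; for multi-model files only the first model is read.
#'
#' @param path path to a `.pdb` or `.cif` file.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return a [StructureModel-class].
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)) "mmcif"
              else "pdb"
  }
  parsed <- tryCatch(
    if (format == "mmcif") suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE),
    error = function(e) stop("unreadable structure file: ", path, " (",
                             conditionMessage(e), ")", call. = FALSE))
  at <- parsed$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no polymer chains in ", path)
  plddtLike <- all(is.finite(at$b)) && all(at$b >= 0 & at$b <= 100) &&
    any(at$b != 0)
  chains <- list()
  for (ch in unique(at$chain)) {
    chAt <- at[at$chain == ch, , drop = FALSE]
    nRes <- length(unique(chAt$resno))
    ca <- chAt[chAt$elety == "CA" & (is.na(chAt$alt) | chAt$alt %in% c("", "A")), ,
               drop = FALSE]
    ca <- ca[!duplicated(ca$resno), , drop = FALSE]
    if (nrow(ca) < nRes)
      message("chain ", ch, ": ", nRes - nrow(ca),
              " residue(s) without a C-alpha skipped (gap logged)")
    if (nrow(ca) == 0) next
    ## keep file order; enforce strictly increasing author numbering
    keep <- c(TRUE, diff(ca$resno) > 0)
    if (!all(keep)) {
      message("chain ", ch, ": ", sum(!keep),
              " residue(s) out of numbering order dropped")
      ca <- ca[keep, , drop = FALSE]
    }
    chains[[length(chains) + 1]] <- new(
      "ChainTrace", chainId = as.character(ch),
      residueIds = as.integer(ca$resno),
      coords = unname(as.matrix(ca[, c("x", "y", "z")])),
      confidence = if (plddtLike) as.numeric(ca$b) else numeric(0))
  }
  if (!length(chains)) stop("no polymer chains in ", path)
  new("StructureModel",
      modelId = sub("\\.(pdb|cif)(\\.gz)?$", "", basename(path),
                    ignore.case = TRUE),
      chains = chains,
      sourceFormat = if (format == "mmcif") "mmcif" else "pdb")
}

#' Chain trace to polyline, with a confidence gate
#'
#' Converts a [ChainTrace-class] to the [Polyline3D-class] the topology
#' machinery works on.  When `minConfidence` is given and the chain's
#' mean confidence (pLDDT) falls below it, the conversion refuses --
#' low-confidence models produce topological artifacts.  The refusal can
#' be overridden with `force = TRUE`; chains without confidence values
#' are accepted with a warning (there is no basis to filter them).
#'
#' @param chain a [ChainTrace-class].
#' @param minConfidence optional minimal mean pLDDT (commonly 70).
#' @param force accept the chain even if the gate fails.
#' @return a [Polyline3D-class] with residue labels.
#' @export
chainToPolyline <- function(chain, minConfidence = NULL, force = FALSE) {
  stopifnot(is(chain, "ChainTrace"))
  if (!is.null(minConfidence)) {
    if (!length(chain@confidence)) {
      warning("chain ", chain@chainId,
              " has no confidence values; gate not applied")
    } else {
      m <- mean(chain@confidence)
      if (m < minConfidence && !force)
        stop(sprintf(
          "chain %s rejected: mean confidence %.1f below threshold %.1f",
          chain@chainId, m, minConfidence))
    }
  }
  polyline3D(chain@coords, labels = chain@residueIds)
}

#' Write a polyline as a pseudo-PDB file
#'
#' Serializes a curve as legal fixed-width PDB ATOM records: one CA atom
#' per residue (GLY), chain A, residues numbered from 1.  Reading the
#' file back reproduces the coordinates to 0.001 A (the PDB column
#' precision).
#'
#' @param polyline a [Polyline3D-class] with at least 3 points.
#' @param path output file path.
#' @param bfactor optional per-residue value for the B-factor column
#'   (e.g. a confidence score), recycled.
#' @return `path`, invisibly.
#' @export
writePseudoPdb <- function(polyline, path, bfactor = 0) {
  stopifnot(is(polyline, "Polyline3D"))
  p <- polyline@points
  if (nrow(p) < 3) stop("refusing to write fewer than 3 points")
  if (any(abs(p) >= 10000)) stop("coordinates exceed PDB fixed-width columns")
  b <- rep_len(bfactor, nrow(p))
  con <- file(path, "w")
  on.exit(close(con))
  lines <- sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00%6.2f           C",
    seq_len(nrow(p)), seq_len(nrow(p)), p[, 1], p[, 2], p[, 3], b)
  writeLines(c(lines, "END"), con)
  invisible(path)
}
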