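## The candidate pipeline for doubly knotted proteins: screen annotation
## tables for architectures able to carry two knots, gate candidates on
## homology to known knotted structures, classify gene arrangements, and
## build the entangled-domain registry from topology reports.

#' Validate / construct an entangled-domain registry
#'
#' The registry maps domain family ids to their entanglement class and
#' minimal knotted-core length.  `knots_per_domain` expresses how much of
#' a knot one domain contributes: 1 for families whose single domain
#' carries a knot, 0.5 for families where two consecutive domains
#' together form one knot (e.g. the CaCA transporter repeat), so four
#' such domains are needed for a double knot.
#'
#' @param registry data.frame with columns `family_id`,
#'   `entanglement_class` (knot/slipknot/both), `min_core_length`,
#'   and optionally `knots_per_domain` (default 1).
#' @return the validated registry data.frame.
#' @export
entangledRegistry <- function(registry) {
  need <- c("family_id", "entanglement_class", "min_core_length")
  if (!all(need %in% names(registry)))
    stop("registry needs columns: ", paste(need, collapse = ", "))
  if (!"knots_per_domain" %in% names(registry)) registry$knots_per_domain <- 1
  if (anyDuplicated(registry$family_id)) stop("family ids must be unique")
  if (any(registry$min_core_length < 1)) stop("min_core_length must be >= 1")
  if (!all(registry$entanglement_class %in% c("knot", "slipknot", "both")))
    stop("entanglement_class must be knot, slipknot or both")
  registry
}

#' Screen protein architectures for double-knot candidates
#'
#' A protein passes when (a) its domains contribute an expected knot
#' count of at least 2 (sum of `knots_per_domain` over domains whose
#' family is registered with class `knot` or `both`), and (b) the chain
#' is long enough to hold those knots: protein length >=
#' sum(min_core_length * knots_per_domain) over the qualifying domains.
#' Every protein appears exactly once in the output, candidates and
#' rejections alike, with the reason for any rejection.
#'
#' @param records domain annotation table: one row per domain instance
#'   with columns `protein_id`, `length`, `family_id`, `start`, `end`
#'   (1-based inclusive residue ranges).
#' @param registry an entangled-domain registry (see
#'   [entangledRegistry()]).
#' @return data.frame with one row per protein: `protein_id`,
#'   `architecture`, `n_entangled_domains`, `expected_knots`,
#'   `required_length`, `length`, `passed_length`, `verdict`, `reason`.
#' @examples
#' fx <- makeAnnotationFixture(nDecoys = 20, seed = 1)
#' out <- screenArchitectures(fx$records, defaultRegistry())
#' table(out$verdict)
#' @export
screenArchitectures <- function(records, registry) {
  registry <- entangledRegistry(registry)
  need <- c("protein_id", "length", "family_id", "start", "end")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  if (nrow(registry) == 0) stop("registry is empty")
  out <- lapply(split(records, records$protein_id), function(r) {
    r <- r[order(r$start), , drop = FALSE]
    arch <- paste(r$family_id, collapse = "-")
    len <- r$length[1]
    row <- data.frame(protein_id = r$protein_id[1], architecture = arch,
                      n_entangled_domains = 0L, expected_knots = 0,
                      required_length = 0, length = len,
                      passed_length = NA, verdict = "rejected",
                      reason = "", stringsAsFactors = FALSE)
    if (any(r$start < 1 | r$end > len | r$start > r$end)) {
      row$reason <- "invalid_range"
      return(row)
    }
    m <- match(r$family_id, registry$family_id)
    qual <- !is.na(m) & registry$entanglement_class[m] %in% c("knot", "both")
    kpd <- ifelse(qual, registry$knots_per_domain[m], 0)
    row$n_entangled_domains <- sum(qual)
    row$expected_knots <- sum(kpd)
    row$required_length <- sum(ifelse(qual,
                                      registry$min_core_length[m] * kpd, 0))
    row$passed_length <- len >= row$required_length
    if (row$expected_knots < 2) {
      row$reason <- "n_entangled<2"
    } else if (!row$passed_length) {
      row$reason <- "too_short"
    } else {
      row$verdict <- "candidate"
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Gate candidates on homology to knotted structures
#'
#' A candidate is kept when its best homology hit (lowest e-value) is
#' significant -- e-value strictly below the threshold -- AND the subject
#' is knotted.  Candidates without any hit are flagged
#' (`passed_homology = NA`) but not rejected: a missing search result is
#' not evidence of an unknotted protein.
#'
#' @param report output of [screenArchitectures()].
#' @param hits homology table: `query_id`, `subject_id`, `evalue`,
#'   `subject_knotted` (logical or 0/1).
#' @param threshold e-value threshold, strict inequality (default 1e-3).
#' @return `report` with columns `best_evalue`, `passed_homology` added
#'   and verdicts updated (`rejected` / reason `homology` where the gate
#'   fails).
#' @export
homologyGate <- function(report, hits, threshold = 1e-3) {
  stopifnot(threshold > 0)
  need <- c("query_id", "subject_id", "evalue", "subject_knotted")
  if (!all(need %in% names(hits)))
    stop("hits need columns: ", paste(need, collapse = ", "))
  hits$subject_knotted <- as.logical(hits$subject_knotted)
  report$best_evalue <- NA_real_
  report$passed_homology <- NA
  for (i in seq_len(nrow(report))) {
    h <- hits[hits$query_id == report$protein_id[i], , drop = FALSE]
    if (nrow(h) == 0) next
    best <- h[which.min(h$evalue), ]
    report$best_evalue[i] <- best$evalue
    report$passed_homology[i] <- best$evalue < threshold && best$subject_knotted
    if (report$verdict[i] == "candidate" && !report$passed_homology[i]) {
      report$verdict[i] <- "rejected"
      report$reason[i] <- "homology"
    }
  }
  report
}

#' Classify the genomic arrangement of two gene loci
#'
#' The four ways two genes co-locate on a genome: `fused` (one ORF),
#' `overlapping` (intervals intersect), `adjacent` (gap between nearest
#' ends no larger than `adjacencyMaxGap` nucleotides), `separated`
#' (anything farther).
#'
#' @param a,b gene loci: lists (or one-row data.frames) with `gene_id`,
#'   `start`, `end` (1-based genomic coordinates), `strand`, and
#'   optionally `fused`.
#' @param adjacencyMaxGap adjacency cutoff in nucleotides (default 50; a
#'   labelled choice, exemplars in bacterial genomes range from ~10 nt to
#'   thousands).
#' @return one of `"separated"`, `"adjacent"`, `"overlapping"`, `"fused"`.
#' @examples
#' fx <- makeGeneFixture()
#' classifyGeneArrangement(fx$adjacent$a, fx$adjacent$b)  # "adjacent"
#' @export
classifyGeneArrangement <- function(a, b, adjacencyMaxGap = 50L) {
  chk <- function(x) {
    if (is.null(x$gene_id) || is.null(x$start) || is.null(x$end))
      stop("locus needs gene_id, start, end")
    if (x$start > x$end) stop("malformed locus: start > end")
    x
  }
  a <- chk(a); b <- chk(b)
  if (identical(a$gene_id, b$gene_id) || isTRUE(a$fused) || isTRUE(b$fused))
    return("fused")
  if (max(a$start, b$start) <= min(a$end, b$end)) return("overlapping")
  gap <- max(a$start, b$start) - min(a$end, b$end) - 1L
  if (gap <= adjacencyMaxGap) "adjacent" else "separated"
}

#' Build an entangled-domain registry from topology reports
#'
#' For each domain family, classifies its entanglement from the topology
#' reports of its structures ([classifyDomainEntanglement()]) and records
#' the minimal knotted-core length ([minCoreLength()]).  Families with no
#' entanglement are omitted.
#'
#' @param domainInstances named list: family id -> list of
#'   [TopologyReport-class] objects.
#' @param knotsPerDomain optional named numeric: knots contributed per
#'   domain for specific families (default 1).
#' @return a registry data.frame (see [entangledRegistry()]).
#' @export
buildRegistry <- function(domainInstances, knotsPerDomain = NULL) {
  if (!length(domainInstances)) stop("no domain instances supplied")
  rows <- lapply(names(domainInstances), function(fam) {
    reps <- domainInstances[[fam]]
    cls <- classifyDomainEntanglement(reps)
    if (cls == "none") return(NULL)
    data.frame(family_id = fam, entanglement_class = cls,
               min_core_length = minCoreLength(reps),
               knots_per_domain = if (!is.null(knotsPerDomain) &&
                                        fam %in% names(knotsPerDomain))
                 knotsPerDomain[[fam]] else 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(family_id = character(0),
                                      entanglement_class = character(0),
                                      min_core_length = integer(0),
                                      knots_per_domain = numeric(0),
                                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a domain annotation table
#'
#' Tab-separated with header: `protein_id`, `length`, `family_id`,
#' `start`, `end` (one row per domain instance).
#'
#' @param path TSV file path.
#' @return data.frame suitable for [screenArchitectures()].
#' @export
readArchitectureTable <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a homology hit table
#'
#' Tab-separated with header: `query_id`, `subject_id`, `evalue`,
#' `subject_knotted` (0/1).
#'
#' @param path TSV file path.
#' @return data.frame suitable for [homologyGate()].
#' @export
readHomologyTable <- function(path) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE)
  h$subject_knotted <- as.logical(h$subject_knotted)
  h
}

#' Summarize candidates per architecture
#'
#' Groups candidate proteins by architecture string and reports, per
#' architecture, the protein count, an example protein id, and the knot
#' type established for that architecture (when per-protein knot labels
#' are supplied).
#'
#' @param report gated output of [homologyGate()] (or
#'   [screenArchitectures()]).
#' @param knotTypes optional named character: protein id -> knot label
#'   from structure analysis.
#' @return data.frame: `architecture`, `n_proteins`, `example_protein`,
#'   `knot_type`.
#' @export
summarizeArchitectures <- function(report, knotTypes = NULL) {
  cand <- report[report$verdict == "candidate", , drop = FALSE]
  if (nrow(cand) == 0)
    return(data.frame(architecture = character(0), n_proteins = integer(0),
                      example_protein = character(0), knot_type = character(0),
                      stringsAsFactors = FALSE))
  out <- lapply(split(cand, cand$architecture), function(g) {
    kt <- NA_character_
    if (!is.null(knotTypes)) {
      hit <- intersect(g$protein_id, names(knotTypes))
      if (length(hit)) kt <- unname(knotTypes[[hit[1]]])
    }
    data.frame(architecture = g$architecture[1], n_proteins = nrow(g),
               example_protein = g$protein_id[1], knot_type = kt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$n_proteins, out$architecture), , drop = FALSE]
  rownames(out) <- NULL
  out
}
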