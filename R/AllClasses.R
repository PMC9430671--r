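#' @import methods
NULL

#' Cohort of phage lytic-enzyme genes
#'
#' A \code{LysinCohort} holds, for each gene, its coding sequence (CDS,
#' including the stop codon), the encoded protein, the host genus of the
#' phage, and a family label separating the family under study (e.g.
#' endolysins) from a control family. The container enforces the coupling
#' between CDS and protein: the CDS length is \code{3 * (nchar(protein) + 1)}
#' and its translation under the bacterial genetic code (table 11), with the
#' initiator codon read as Met whether it is ATG, GTG or TTG, equals the
#' protein.
#'
#' Records violating these invariants are rejected at construction;
#' \code{\link{readCohort}} collects them into a validation report instead of
#' failing, so large cohorts surface all problems at once.
#'
#' @slot cds A \code{\link[Biostrings]{DNAStringSet}} of coding sequences,
#'   named by gene id.
#' @slot protein An \code{\link[Biostrings]{AAStringSet}} of protein
#'   sequences, named by gene id.
#' @slot info A \code{\link[S4Vectors]{DataFrame}} with columns
#'   \code{gene_id}, \code{host_genus}, \code{family} (one of
#'   \code{"endolysin"}, \code{"control"}) and \code{source}.
#'
#' @seealso \code{\link{readCohort}}, \code{\link{writeCohort}},
#'   \code{\link{runScreen}}
#' @importClassesFrom Biostrings DNAStringSet AAStringSet
#' @importClassesFrom S4Vectors DataFrame
#' @exportClass LysinCohort
setClass("LysinCohort",
  slots = c(cds = "DNAStringSet", protein = "AAStringSet", info = "DFrame"))

setValidity("LysinCohort", function(object) {
  msgs <- character(0)
  n <- nrow(object@info)
  need <- c("gene_id", "host_genus", "family", "source")
  if (!all(need %in% colnames(object@info)))
    return(paste("info must have columns:", paste(need, collapse = ", ")))
  if (length(object@cds) != n || length(object@protein) != n)
    msgs <- c(msgs, "cds, protein and info must describe the same genes")
  ids <- object@info$gene_id
  if (anyDuplicated(ids))
    msgs <- c(msgs, "duplicated gene_id")
  if (n > 0) {
    if (!identical(names(object@cds), ids) ||
        !identical(names(object@protein), ids))
      msgs <- c(msgs, "cds/protein names must equal info$gene_id")
    if (any(is.na(object@info$host_genus) | object@info$host_genus == ""))
      msgs <- c(msgs, "host_genus must be non-empty")
    if (!all(object@info$family %in% c("endolysin", "control")))
      msgs <- c(msgs, "family must be 'endolysin' or 'control'")
    bad <- which(!.cdsProteinConsistent(object@cds, object@protein))
    if (length(bad))
      msgs <- c(msgs, paste0("CDS/protein inconsistent for: ",
                             paste(head(ids[bad], 5), collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of the four-step iTSS screen
#'
#' One row per gene of the screened cohort, giving the top-scoring in-frame
#' internal start candidate (if any), the four filter flags (background
#' outlier, gene extremities, conserved-domain overlap, phage tail domains)
#' and the resulting status. A gene is \code{retained} iff it has a candidate
#' and all four flags are \code{TRUE}.
#'
#' @slot calls A \code{data.frame} with columns \code{gene_id},
#'   \code{codon_index}, \code{start_codon}, \code{tir},
#'   \code{outlier_pass}, \code{edge_pass}, \code{domain_pass},
#'   \code{tail_pass}, \code{status}, \code{no_domain_info}, \code{note}.
#' @slot summary Named list with \code{n_total}, \code{n_with_candidate},
#'   \code{n_retained}, \code{fraction_retained}.
#' @slot config The \code{\link{filterConfig}} used.
#'
#' @seealso \code{\link{runScreen}}, \code{\link{retainedCalls}},
#'   \code{\link{screenFraction}}
#' @exportClass ScreenResult
setClass("ScreenResult",
  slots = c(calls = "data.frame", summary = "list", config = "list"))

setValidity("ScreenResult", function(object) {
  cl <- object@calls
  need <- c("gene_id", "codon_index", "start_codon", "tir", "outlier_pass",
            "edge_pass", "domain_pass", "tail_pass", "status")
  if (!all(need %in% colnames(cl)))
    return(paste("calls must have columns:", paste(need, collapse = ", ")))
  ok <- !is.na(cl$codon_index) & cl$outlier_pass & cl$edge_pass &
    cl$domain_pass & cl$tail_pass
  ok[is.na(ok)] <- FALSE
  if (!identical(cl$status == "retained", unname(ok)))
    return("status 'retained' must equal candidate & all four flags")
  TRUE
})

#' Identity-threshold clustering of a cohort
#'
#' Single-linkage components of the graph whose edges connect protein pairs
#' with percent identity strictly above the threshold. The representative of
#' each cluster is its longest member (ties broken by gene id).
#'
#' @slot threshold Percent-identity threshold in (0, 100].
#' @slot members Named list, cluster id to character vector of gene ids.
#' @slot representative Named character vector, cluster id to gene id.
#'
#' @seealso \code{\link{clusterByIdentity}}, \code{\link{itssPositionConsensus}}
#' @exportClass ClusterSet
setClass("ClusterSet",
  slots = c(threshold = "numeric", members = "list",
            representative = "character"))

setValidity("ClusterSet", function(object) {
  if (length(object@threshold) != 1 || object@threshold <= 0 ||
      object@threshold > 100)
    return("threshold must be a single value in (0, 100]")
  if (length(object@members) != length(object@representative))
    return("one representative per cluster required")
  if (length(object@members)) {
    if (any(lengths(object@members) == 0))
      return("clusters must be non-empty")
    ok <- mapply(function(m, r) r %in% m,
                 object@members, object@representative)
    if (!all(ok)) return("representative must be a cluster member")
  }
  TRUE
})

#' Gel-filtration calibration curve
#'
#' Linearised least-squares calibration of a size-exclusion column from
#' protein standards: \code{log10(mass)} is fitted as a linear function of
#' the partition coefficient Kav, and \code{sqrt(-ln Kav)} as a linear
#' function of the Stokes radius (Laurent-Killander form).
#'
#' @slot v0 Void volume (mL).
#' @slot vt Total column volume (mL).
#' @slot mass_fit Numeric \code{c(slope, intercept)} of
#'   \code{log10(mass_kda) ~ Kav}.
#' @slot rs_fit Numeric \code{c(slope, intercept)} of
#'   \code{sqrt(-ln Kav) ~ Rs_nm}.
#' @slot r2_mass,r2_rs R-squared of the two fits.
#' @slot n_standards Number of standards used.
#'
#' @seealso \code{\link{gfCalibrate}}, \code{\link{estimateMass}},
#'   \code{\link{estimateRs}}, \code{\link{kav}}
#' @exportClass CalibrationCurve
setClass("CalibrationCurve",
  slots = c(v0 = "numeric", vt = "numeric", mass_fit = "numeric",
            rs_fit = "numeric", r2_mass = "numeric", r2_rs = "numeric",
            n_standards = "integer"))

setValidity("CalibrationCurve", function(object) {
  if (object@v0 >= object@vt) return("v0 must be < vt")
  if (object@n_standards < 3L) return("at least 3 standards required")
  TRUE
})

#' Best integer stoichiometry of an FLP/CTP complex
#'
#' Exhaustive enumeration of compositions (a FLP, b CTP) within bounds,
#' minimising the absolute deviation between the predicted complex mass
#' \code{a * m_flp + b * m_ctp} and an observed (native-MS) mass. Ties break
#' by smaller a, then smaller b. The full ranked table is kept.
#'
#' @slot m_flp,m_ctp Subunit masses (kDa).
#' @slot observed Observed complex mass (kDa).
#' @slot a_max,b_max Enumeration bounds (inclusive, from 0).
#' @slot best Integer \code{c(a, b)} of the best composition.
#' @slot predicted Predicted mass of the best composition (kDa).
#' @slot residual Signed residual, predicted minus observed (kDa).
#' @slot table The full enumeration, ranked by absolute residual.
#'
#' @seealso \code{\link{bestStoichiometry}}, \code{\link{complexMass}}
#' @exportClass StoichiometryFit
setClass("StoichiometryFit",
  slots = c(m_flp = "numeric", m_ctp = "numeric", observed = "numeric",
            a_max = "integer", b_max = "integer", best = "integer",
            predicted = "numeric", residual = "numeric",
            table = "data.frame"))

setValidity("StoichiometryFit", function(object) {
  if (length(object@best) != 2 || any(object@best < 0))
    return("best must be two non-negative counts")
  if (all(object@best == 0)) return("best composition cannot be (0, 0)")
  TRUE
})
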