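#' @rdname LysinCohort-class
#' @param x A \code{LysinCohort}.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname LysinCohort-class
#' @export
setGeneric("cdsSeqs", function(x) standardGeneric("cdsSeqs"))

#' @rdname LysinCohort-class
#' @export
setGeneric("proteinSeqs", function(x) standardGeneric("proteinSeqs"))

#' @rdname LysinCohort-class
#' @export
setGeneric("hostGenus", function(x) standardGeneric("hostGenus"))

#' @rdname LysinCohort-class
#' @export
setGeneric("familyLabel", function(x) standardGeneric("familyLabel"))

#' Extract the retained calls of a screen, ranked by TIR
#'
#' Retained calls are ranked by descending TIR; ties break by gene id so the
#' ranking is reproducible.
#'
#' @param x A \code{\link{ScreenResult}}.
#' @return A \code{data.frame} of retained calls.
#' @export
setGeneric("retainedCalls", function(x) standardGeneric("retainedCalls"))

#' Fraction of genes retained by the screen, as a printed percentage
#'
#' Computes \code{100 * n_retained / n_total} rounded half-up to one decimal,
#' the convention used for reported screen percentages. Dispatches either on
#' a \code{\link{ScreenResult}} or on a pair of counts.
#'
#' @param x A \code{ScreenResult}, or the number of retained genes.
#' @param n_total Total number of genes (counts signature only).
#' @return A single numeric percentage with one decimal, or \code{NA} when
#'   the cohort is empty.
#' @examples
#' screenFraction(312, 635)   # 49.1
#' screenFraction(1946, 3780) # 51.5
#' @export
setGeneric("screenFraction",
  function(x, n_total) standardGeneric("screenFraction"))

#' @rdname ClusterSet-class
#' @param x A \code{ClusterSet}.
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname ClusterSet-class
#' @export
setGeneric("clusterRepresentatives",
  function(x) standardGeneric("clusterRepresentatives"))
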