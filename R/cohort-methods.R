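#' Construct a LysinCohort from parallel vectors
#'
#' Low-level constructor; fails on the first invalid record. Use
#' \code{\link{readCohort}} for collect-and-report validation of files.
#'
#' @param gene_id Character vector of unique gene ids.
#' @param cds Character vector (or \code{DNAStringSet}) of coding sequences
#'   including the stop codon.
#' @param protein Character vector (or \code{AAStringSet}) of protein
#'   sequences without a stop symbol.
#' @param host_genus Character vector of host genera (non-empty).
#' @param family \code{"endolysin"} or \code{"control"}, recycled.
#' @param source Free-text provenance, recycled.
#' @return A \code{\link{LysinCohort}}.
#' @examples
#' LysinCohort("g1", "ATGGCTTAA", "MA", "Streptococcus")
#' @importFrom Biostrings DNAStringSet AAStringSet
#' @export
LysinCohort <- function(gene_id, cds, protein, host_genus,
                        family = "endolysin", source = "") {
  n <- length(gene_id)
  info <- S4Vectors::DataFrame(
    gene_id = as.character(gene_id),
    host_genus = rep_len(as.character(host_genus), n),
    family = rep_len(as.character(family), n),
    source = rep_len(as.character(source), n))
  cds <- Biostrings::DNAStringSet(cds)
  protein <- Biostrings::AAStringSet(protein)
  names(cds) <- names(protein) <- info$gene_id
  new("LysinCohort", cds = cds, protein = protein, info = info)
}

# Per-record CDS/protein consistency: length 3*(L+1), one terminal stop,
# translation (code table 11) with initiator forced to Met.
#' @importFrom Biostrings getGeneticCode translate
.cdsProteinConsistent <- function(cds, protein) {
  vapply(seq_along(cds), function(i) {
    d <- as.character(cds[[i]])
    p <- as.character(protein[[i]])
    if (!grepl("^[ACGT]+$", d)) return(FALSE)
    if (nchar(d) %% 3 != 0) return(FALSE)
    if (nchar(d) != 3 * (nchar(p) + 1)) return(FALSE)
    tr <- as.character(Biostrings::translate(
      Biostrings::DNAString(d),
      genetic.code = Biostrings::getGeneticCode("11")))
    if (substr(tr, nchar(tr), nchar(tr)) != "*") return(FALSE)
    body <- substr(tr, 1, nchar(tr) - 1)
    if (grepl("\\*", body)) return(FALSE)
    first <- substr(d, 1, 3)
    if (!first %in% c("ATG", "GTG", "TTG")) return(FALSE)
    substr(body, 1, 1) <- "M"  # initiator read as Met regardless of codon
    identical(body, p)
  }, logical(1))
}

#' @describeIn LysinCohort-class Number of genes.
#' @export
setMethod("length", "LysinCohort", function(x) nrow(x@info))

#' @describeIn LysinCohort-class Gene ids.
#' @export
setMethod("geneIds", "LysinCohort", function(x) x@info$gene_id)

#' @describeIn LysinCohort-class Coding sequences as a \code{DNAStringSet}.
#' @export
setMethod("cdsSeqs", "LysinCohort", function(x) x@cds)

#' @describeIn LysinCohort-class Protein sequences as an \code{AAStringSet}.
#' @export
setMethod("proteinSeqs", "LysinCohort", function(x) x@protein)

#' @describeIn LysinCohort-class Host genus per gene, named by gene id.
#' @export
setMethod("hostGenus", "LysinCohort", function(x)
  stats::setNames(x@info$host_genus, x@info$gene_id))

#' @describeIn LysinCohort-class Family label per gene, named by gene id.
#' @export
setMethod("familyLabel", "LysinCohort", function(x)
  stats::setNames(x@info$family, x@info$gene_id))

#' @describeIn LysinCohort-class Subset by index, gene id or logical.
#' @param i Index vector.
#' @param j,drop Ignored.
#' @param ... Ignored.
#' @export
setMethod("[", "LysinCohort", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@info$gene_id)
  new("LysinCohort", cds = x@cds[i], protein = x@protein[i],
      info = x@info[i, , drop = FALSE])
})

setMethod("show", "LysinCohort", function(object) {
  cat("LysinCohort with", length(object), "genes\n")
  if (length(object)) {
    fam <- table(object@info$family)
    cat("  family:", paste(names(fam), fam, sep = "=", collapse = ", "), "\n")
    gen <- sort(table(object@info$host_genus), decreasing = TRUE)
    cat("  genera:", paste(utils::head(names(gen), 5), utils::head(gen, 5),
                           sep = "=", collapse = ", "),
        if (length(gen) > 5) "..." else "", "\n")
    cat("  protein lengths:", min(Biostrings::width(object@protein)), "-",
        max(Biostrings::width(object@protein)), "aa\n")
  }
})

setMethod("show", "ScreenResult", function(object) {
  s <- object@summary
  cat("ScreenResult:", s$n_total, "genes;", s$n_with_candidate,
      "with candidate;", s$n_retained, "retained")
  if (!is.na(s$fraction_retained))
    cat(sprintf(" (%.1f%%)", 100 * s$fraction_retained))
  cat("\n")
})

#' @describeIn ScreenResult-class All per-gene calls.
#' @param x A \code{ScreenResult}.
#' @export
screenCalls <- function(x) x@calls

#' @describeIn ScreenResult-class Summary counts list.
#' @export
screenSummary <- function(x) x@summary

setMethod("retainedCalls", "ScreenResult", function(x) {
  cl <- x@calls[x@calls$status == "retained", , drop = FALSE]
  cl <- cl[order(-cl$tir, cl$gene_id), , drop = FALSE]
  rownames(cl) <- NULL
  cl
})

setMethod("show", "ClusterSet", function(object) {
  cat("ClusterSet at >", object@threshold, "% identity:",
      length(object@members), "clusters,", sum(lengths(object@members)),
      "sequences\n")
  sz <- sort(lengths(object@members), decreasing = TRUE)
  cat("  sizes:", paste(utils::head(sz, 8), collapse = ", "),
      if (length(sz) > 8) "..." else "", "\n")
})

#' @describeIn ClusterSet-class Number of clusters.
#' @export
setMethod("length", "ClusterSet", function(x) length(x@members))

setMethod("clusterMembers", "ClusterSet", function(x) x@members)

setMethod("clusterRepresentatives", "ClusterSet",
          function(x) x@representative)

setMethod("show", "CalibrationCurve", function(object) {
  cat("CalibrationCurve:", object@n_standards, "standards, V0 =",
      object@v0, "mL, Vt =", object@vt, "mL\n")
  cat(sprintf("  log10(mass) = %.4f * Kav + %.4f  (R2 = %.4f)\n",
              object@mass_fit[1], object@mass_fit[2], object@r2_mass))
  cat(sprintf("  sqrt(-ln Kav) = %.4f * Rs + %.4f  (R2 = %.4f)\n",
              object@rs_fit[1], object@rs_fit[2], object@r2_rs))
})

setMethod("show", "StoichiometryFit", function(object) {
  cat(sprintf(
    "StoichiometryFit: observed %.3f kDa vs %d FLP (%.1f kDa) + %d CTP (%.1f kDa)\n",
    object@observed, object@best[1], object@m_flp, object@best[2],
    object@m_ctp))
  cat(sprintf("  predicted %.3f kDa, residual %+.3f kDa\n",
              object@predicted, object@residual))
  cat("  next best:\n")
  print(utils::head(object@table[-1, c("a", "b", "predicted", "residual")],
                    3), row.names = FALSE)
})

#' @describeIn StoichiometryFit-class Best composition as \code{c(a, b)}.
#' @param x A \code{StoichiometryFit}.
#' @export
bestComposition <- function(x) stats::setNames(x@best, c("flp", "ctp"))

#' @describeIn StoichiometryFit-class Full ranked enumeration table.
#' @export
stoichiometryTable <- function(x) x@table
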