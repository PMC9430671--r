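#' Derive the FLP and CTP products of a gene with an iTSS
#'
#' The full-length product (FLP) is the whole protein; the C-terminal
#' product (CTP) is the suffix beginning at the iTSS codon, with its first
#' residue read as Met regardless of the native residue. An optional
#' C-terminal tag (e.g. the His6-containing \code{"PGGGSHHHHHH"}) is
#' appended to both products and included in the reported masses. Masses are
#' average isotopic masses (the SDS-PAGE-facing convention); use
#' \code{\link{sequenceMass}} directly for monoisotopic values.
#'
#' @param gene A single-gene \code{\link{LysinCohort}} or a protein string.
#' @param itss_codon 1-based codon index of the internal start (2..L).
#' @param tag C-terminal tag appended to both products (default none).
#' @return List with \code{flp_seq}, \code{ctp_seq}, \code{tag_seq},
#'   \code{flp_mass_da}, \code{ctp_mass_da}.
#' @examples
#' pp <- deriveProducts(strrep("A", 310), 209, tag = "PGGGSHHHHHH")
#' nchar(pp$ctp_seq) - nchar(pp$tag_seq)  # 102
#' @export
deriveProducts <- function(gene, itss_codon, tag = "") {
  prot <- if (is(gene, "LysinCohort")) {
    stopifnot(length(gene) == 1L)
    as.character(proteinSeqs(gene)[[1L]])
  } else toupper(as.character(gene))
  L <- nchar(prot)
  itss_codon <- as.integer(itss_codon)
  if (itss_codon < 2L || itss_codon > L)
    stop("itss_codon out of range: ", itss_codon)
  ctp <- substr(prot, itss_codon, L)
  substr(ctp, 1L, 1L) <- "M"
  flp_seq <- paste0(prot, tag)
  ctp_seq <- paste0(ctp, tag)
  list(flp_seq = flp_seq, ctp_seq = ctp_seq, tag_seq = tag,
       flp_mass_da = sequenceMass(flp_seq, "average"),
       ctp_mass_da = sequenceMass(ctp_seq, "average"))
}

#' Classify the domain architecture of a gene around its iTSS
#'
#' Two architecture groups recur among lytic enzymes with in-frame internal
#' starts: group 1 has two catalytic domains (CDs) with the iTSS strictly
#' between consecutive CDs (the CTP keeps the second CD plus the
#' cell-wall-binding domain); group 2 has exactly one CD, entirely upstream
#' of the iTSS (the CTP carries only C-terminal, often unannotated,
#' sequence). Anything else is unclassified.
#'
#' @param domains \code{data.frame} of categorised domain hits of one gene
#'   (columns \code{accession}, \code{name}, \code{start_aa}, \code{end_aa},
#'   \code{category}).
#' @param itss_codon 1-based codon index of the iTSS.
#' @return List with \code{group} (\code{"group1_two_CDs"},
#'   \code{"group2_one_CD"} or \code{"unclassified"}), \code{flp_domains}
#'   (all hits, sorted), and \code{ctp_domains} (hits fully downstream of
#'   the iTSS, coordinates shifted to the CTP frame where the iTSS codon is
#'   residue 1).
#' @export
classifyArchitecture <- function(domains, itss_codon) {
  itss_codon <- as.integer(itss_codon)
  if (is.null(domains))
    domains <- data.frame(accession = character(0), name = character(0),
                          start_aa = integer(0), end_aa = integer(0),
                          category = character(0))
  domains <- domains[order(domains$start_aa), , drop = FALSE]
  rownames(domains) <- NULL
  ctp <- domains[domains$start_aa >= itss_codon, , drop = FALSE]
  if (nrow(ctp)) {
    ctp$start_aa <- ctp$start_aa - itss_codon + 1L
    ctp$end_aa <- ctp$end_aa - itss_codon + 1L
  }
  cds_hits <- domains[domains$category == "catalytic", , drop = FALSE]
  group <- "unclassified"
  if (nrow(cds_hits) >= 2L) {
    between <- vapply(seq_len(nrow(cds_hits) - 1L), function(i)
      cds_hits$end_aa[i] < itss_codon &&
        itss_codon < cds_hits$start_aa[i + 1L], logical(1))
    if (any(between)) group <- "group1_two_CDs"
  } else if (nrow(cds_hits) == 1L && cds_hits$end_aa < itss_codon) {
    group <- "group2_one_CD"
  }
  list(group = group, flp_domains = domains, ctp_domains = ctp)
}
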