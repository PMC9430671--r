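#' Read a gene cohort from FASTA + metadata files
#'
#' Reads CDS and protein FASTA files plus a tab-separated metadata table and
#' assembles a validated \code{\link{LysinCohort}}. Validation is
#' collect-and-report: records failing the CDS/protein consistency invariant
#' (length divisible by 3, one terminal stop codon, translation under genetic
#' code table 11 with the initiator read as Met matching the protein) are
#' excluded from the cohort and listed in the \code{problems} report, never
#' silently dropped.
#'
#' @param fasta_cds Path to a FASTA of coding sequences (stop codon included).
#' @param fasta_protein Path to a FASTA of protein sequences.
#' @param metadata_tsv Path to a TSV with header columns \code{gene_id},
#'   \code{host_genus}, \code{family} (optional \code{source}).
#' @return A list with elements \code{cohort} (\code{LysinCohort} of the
#'   valid records) and \code{problems} (\code{data.frame} with columns
#'   \code{gene_id}, \code{problem}).
#' @examples
#' dir <- system.file("extdata", "toy_cohort", package = "lysinITSS")
#' cc <- readCohort(file.path(dir, "cds.fasta"),
#'                  file.path(dir, "protein.fasta"),
#'                  file.path(dir, "metadata.tsv"))
#' cc$cohort
#' @importFrom Biostrings readDNAStringSet readAAStringSet
#' @export
readCohort <- function(fasta_cds, fasta_protein, metadata_tsv) {
  for (f in c(fasta_cds, fasta_protein, metadata_tsv))
    if (!file.exists(f)) stop("file not found: ", f)
  meta <- utils::read.delim(metadata_tsv, stringsAsFactors = FALSE,
                            colClasses = "character")
  need <- c("gene_id", "host_genus", "family")
  if (!all(need %in% colnames(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (!"source" %in% colnames(meta))
    meta$source <- rep("", nrow(meta))
  if (nrow(meta) == 0) {
    warning("empty metadata: returning empty cohort")
    return(list(cohort = .emptyCohort(),
                problems = data.frame(gene_id = character(0),
                                      problem = character(0))))
  }
  cds <- Biostrings::readDNAStringSet(fasta_cds)
  prot <- Biostrings::readAAStringSet(fasta_protein)
  names(cds) <- sub("\\s.*$", "", names(cds))
  names(prot) <- sub("\\s.*$", "", names(prot))

  probs <- list()
  keep <- logical(nrow(meta))
  for (i in seq_len(nrow(meta))) {
    id <- meta$gene_id[i]
    p <- character(0)
    if (!id %in% names(cds)) p <- c(p, "missing CDS")
    if (!id %in% names(prot)) p <- c(p, "missing protein")
    if (is.na(meta$host_genus[i]) || meta$host_genus[i] == "")
      p <- c(p, "empty host_genus")
    if (!meta$family[i] %in% c("endolysin", "control"))
      p <- c(p, "family not endolysin/control")
    if (!length(p)) {
      d <- as.character(cds[[id]])
      if (nchar(d) %% 3 != 0) {
        p <- "CDS length not divisible by 3"
      } else if (!.cdsProteinConsistent(cds[id], prot[id])) {
        p <- "CDS/protein inconsistent (stop codon, length or translation)"
      }
    }
    if (length(p)) {
      probs[[length(probs) + 1L]] <-
        data.frame(gene_id = id, problem = paste(p, collapse = "; "))
    } else keep[i] <- TRUE
  }
  meta <- meta[keep, , drop = FALSE]
  cohort <- if (nrow(meta)) {
    LysinCohort(meta$gene_id, cds[meta$gene_id], prot[meta$gene_id],
                meta$host_genus, meta$family, meta$source)
  } else .emptyCohort()
  problems <- if (length(probs)) do.call(rbind, probs) else
    data.frame(gene_id = character(0), problem = character(0))
  list(cohort = cohort, problems = problems)
}

.emptyCohort <- function() {
  new("LysinCohort", cds = Biostrings::DNAStringSet(),
      protein = Biostrings::AAStringSet(),
      info = S4Vectors::DataFrame(gene_id = character(0),
                                  host_genus = character(0),
                                  family = character(0),
                                  source = character(0)))
}

#' Write a cohort back to FASTA + metadata files
#'
#' Inverse of \code{\link{readCohort}}: emits \code{cds.fasta},
#' \code{protein.fasta} and \code{metadata.tsv} into a directory such that
#' re-reading reproduces every field.
#'
#' @param cohort A \code{\link{LysinCohort}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @importFrom Biostrings writeXStringSet
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "LysinCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fc <- file.path(dir, "cds.fasta")
  fp <- file.path(dir, "protein.fasta")
  fm <- file.path(dir, "metadata.tsv")
  Biostrings::writeXStringSet(cohort@cds, fc)
  Biostrings::writeXStringSet(cohort@protein, fp)
  utils::write.table(as.data.frame(cohort@info), fm, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(cds = fc, protein = fp, metadata = fm))
}

#' Default Pfam accession to functional category map
#'
#' Starter map covering the domain families that recur in phage lytic
#' enzymes: catalytic domains (amidases, CHAP, lysozyme-like glycoside
#' hydrolases, M23 peptidase), cell-wall-binding domains (SH3_5, LysM,
#' Cpl-7), and virion/tail-diagnostic families. Accessions absent from the
#' map are categorised \code{"other"}. Extend or replace via a JSON file and
#' \code{\link{readCategoryMap}}.
#'
#' @return Named character vector, accession to category (one of
#'   \code{"catalytic"}, \code{"cwbd"}, \code{"tail"}, \code{"other"}).
#' @export
defaultCategoryMap <- function() {
  c(PF01510 = "catalytic",  # Amidase_2
    PF01520 = "catalytic",  # Amidase_3
    PF05382 = "catalytic",  # Amidase_5
    PF05257 = "catalytic",  # CHAP
    PF01183 = "catalytic",  # Glyco_hydro_25
    PF00959 = "catalytic",  # Phage_lysozyme
    PF01832 = "catalytic",  # Glucosaminidase
    PF01551 = "catalytic",  # Peptidase_M23
    PF08460 = "cwbd",       # SH3_5
    PF01476 = "cwbd",       # LysM
    PF08230 = "cwbd",       # CW_7 repeat
    PF01473 = "cwbd",       # Choline-binding repeat
    defaultTailAccessions(),
    PF04860 = "other")      # portal: control family marker, not a tail domain
}

#' Starter list of tail-domain Pfam accessions
#'
#' Domains diagnostic of virion structural (tail) proteins; their presence
#' flags a likely misannotated virion-associated lysin and fails filter (iv)
#' of the screen. Intended as a configurable starting point, not an
#' exhaustive census.
#'
#' @return Named character vector, accession to \code{"tail"}.
#' @export
defaultTailAccessions <- function() {
  c(PF03906 = "tail",  # Phage_tail_3
    PF04865 = "tail",  # Baseplate_J
    PF05100 = "tail",  # Phage_tail_fiber
    PF05939 = "tail",  # Phage_min_tail
    PF06605 = "tail")  # tape measure-like
}

#' Read an accession to category map from JSON
#'
#' @param path JSON file mapping accession strings to one of
#'   \code{"catalytic"}, \code{"cwbd"}, \code{"tail"}, \code{"other"}.
#' @return Named character vector.
#' @export
readCategoryMap <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- unlist(m)
  bad <- setdiff(unique(m), c("catalytic", "cwbd", "tail", "other"))
  if (length(bad)) stop("unknown categories in map: ",
                        paste(bad, collapse = ", "))
  m
}

#' Read conserved-domain hits for a cohort
#'
#' Parses a whitespace-delimited domain-hit table ('#' lines are comments)
#' with columns \code{gene_id accession name start_aa end_aa evalue}, assigns
#' functional categories from an accession map (default category
#' \code{"other"}), and validates coordinates against protein lengths when a
#' cohort is supplied. Validation is collect-and-report.
#'
#' @param path Path to the domain-hit table.
#' @param category_map Named character vector (see
#'   \code{\link{defaultCategoryMap}}) or path to a JSON map.
#' @param cohort Optional \code{\link{LysinCohort}} for coordinate checks.
#' @return A list with \code{hits} (\code{data.frame} with columns
#'   \code{gene_id}, \code{accession}, \code{name}, \code{start_aa},
#'   \code{end_aa}, \code{evalue}, \code{category}, sorted by gene then
#'   \code{start_aa}) and \code{problems}.
#' @export
readDomainHits <- function(path, category_map = defaultCategoryMap(),
                           cohort = NULL) {
  if (is.character(category_map) && length(category_map) == 1 &&
      file.exists(category_map))
    category_map <- readCategoryMap(category_map)
  cols <- c("gene_id", "accession", "name", "start_aa", "end_aa", "evalue")
  raw <- utils::read.table(path, comment.char = "#",
                           stringsAsFactors = FALSE, col.names = cols,
                           colClasses = c("character", "character",
                                          "character", "integer", "integer",
                                          "numeric"))
  domainHits(raw, category_map = category_map, cohort = cohort)
}

#' Build a validated domain-hit table from a data.frame
#'
#' @param hits \code{data.frame} with columns \code{gene_id},
#'   \code{accession}, \code{name}, \code{start_aa}, \code{end_aa},
#'   \code{evalue}.
#' @inheritParams readDomainHits
#' @return Same shape as \code{\link{readDomainHits}}.
#' @export
domainHits <- function(hits, category_map = defaultCategoryMap(),
                       cohort = NULL) {
  probs <- list()
  bad <- hits$end_aa < hits$start_aa | hits$start_aa < 1L |
    !is.finite(hits$evalue) | hits$evalue < 0
  if (!is.null(cohort) && length(cohort)) {
    plen <- stats::setNames(Biostrings::width(proteinSeqs(cohort)),
                            geneIds(cohort))
    known <- hits$gene_id %in% names(plen)
    over <- known & hits$end_aa > plen[hits$gene_id]
    bad <- bad | over | !known
  }
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    probs <- data.frame(
      gene_id = hits$gene_id[bad],
      problem = "invalid domain coordinates or evalue")
  } else {
    probs <- data.frame(gene_id = character(0), problem = character(0))
  }
  hits <- hits[!bad, , drop = FALSE]
  hits$category <- unname(category_map[hits$accession])
  hits$category[is.na(hits$category)] <- "other"
  hits <- hits[order(hits$gene_id, hits$start_aa), , drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, problems = probs)
}

#' Write a domain-hit table in the format readDomainHits parses
#'
#' @param hits \code{data.frame} of hits (category column dropped on write).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeDomainHits <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# gene_id accession name start_aa end_aa evalue", con)
  if (nrow(hits))
    writeLines(sprintf("%s %s %s %d %d %g", hits$gene_id, hits$accession,
                       hits$name, hits$start_aa, hits$end_aa, hits$evalue),
               con)
  invisible(path)
}

#' Read a precomputed TIR table
#'
#' A TIR table carries externally predicted translation-initiation rates
#' (e.g. genuine RBS-calculator output) keyed by gene and 1-based codon
#' index; when supplied to \code{\link{scoreGene}} or \code{\link{runScreen}}
#' it overrides the built-in scorer entirely.
#'
#' @param tsv Path to a TSV with header columns \code{gene_id},
#'   \code{codon_index}, \code{tir}.
#' @return A \code{data.frame} of class \code{c("tir_table", "data.frame")}.
#' @export
readTirTable <- function(tsv) {
  tab <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  need <- c("gene_id", "codon_index", "tir")
  if (!all(need %in% colnames(tab)))
    stop("TIR table must have columns: ", paste(need, collapse = ", "))
  tab <- tab[, need]
  if (!is.numeric(tab$tir)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$tir))))
    stop("non-numeric tir at line(s): ",
         paste(bad + 1L, collapse = ", "))  # +1 for header
  }
  tirTable(tab)
}

#' Build a TIR table from a data.frame
#'
#' @param tab \code{data.frame} with columns \code{gene_id},
#'   \code{codon_index}, \code{tir}.
#' @return Validated table of class \code{c("tir_table", "data.frame")}.
#' @export
tirTable <- function(tab) {
  tab$codon_index <- as.integer(tab$codon_index)
  tab$tir <- as.numeric(tab$tir)
  if (any(!is.finite(tab$tir) | tab$tir <= 0))
    stop("all tir values must be positive")
  if (any(tab$codon_index < 2L))
    stop("codon_index must be >= 2 (internal starts only)")
  key <- paste(tab$gene_id, tab$codon_index)
  if (anyDuplicated(key))
    stop("duplicate TIR table key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  class(tab) <- c("tir_table", "data.frame")
  tab
}
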