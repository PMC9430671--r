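#' Configuration of the four-step iTSS filter cascade
#'
#' The cascade excludes a gene when its top-scoring internal start candidate
#' (i) is not a statistical outlier against the gene's own candidate TIR
#' background, (ii) lies within the first or last \code{edge_window_aa}
#' codons, (iii) falls inside a conserved domain (inclusive endpoints), or
#' (iv) when the protein carries a phage tail domain.
#'
#' @param edge_window_aa Width of the excluded gene extremities in codons
#'   (default 20; indices 1..20 and (L-19)..L fail).
#' @param outlier_rule \code{"tukey"} (default): candidate TIR must exceed
#'   Q3 + \code{fence_multiplier} * IQR of all scored candidates of the gene
#'   (quartiles by linear interpolation); or \code{"zscore"}: standardised
#'   TIR must exceed \code{zscore_threshold}.
#' @param fence_multiplier Tukey fence multiplier (default 1.5).
#' @param zscore_threshold Threshold for the z-score rule (default 2).
#' @param tail_accessions Accessions treated as tail domains in addition to
#'   hits already categorised \code{"tail"}.
#' @return An object of class \code{"filter_config"}.
#' @export
filterConfig <- function(edge_window_aa = 20L,
                         outlier_rule = c("tukey", "zscore"),
                         fence_multiplier = 1.5, zscore_threshold = 2,
                         tail_accessions = names(defaultTailAccessions())) {
  outlier_rule <- match.arg(outlier_rule)
  edge_window_aa <- as.integer(edge_window_aa)
  if (edge_window_aa < 1L) stop("edge_window_aa must be >= 1")
  structure(list(edge_window_aa = edge_window_aa,
                 outlier_rule = outlier_rule,
                 fence_multiplier = fence_multiplier,
                 zscore_threshold = zscore_threshold,
                 tail_accessions = tail_accessions),
            class = "filter_config")
}

#' Select the top-scoring candidate of one gene
#'
#' The candidate with maximum TIR; ties break by smallest codon index.
#'
#' @param scored \code{data.frame} of scored candidates of a single gene
#'   (as returned by \code{\link{scoreGene}}).
#' @return One-row \code{data.frame}, or \code{NULL} when no candidates.
#' @export
selectTopCandidate <- function(scored) {
  if (is.null(scored) || nrow(scored) == 0) return(NULL)
  if ("gene_id" %in% colnames(scored) &&
      length(unique(scored$gene_id)) > 1L)
    stop("candidates belong to more than one gene")
  o <- order(-scored$tir, scored$codon_index)
  scored[o[1L], , drop = FALSE]
}

#' Filter (i): TIR clearly above the gene's own background
#'
#' Under the Tukey rule the candidate passes iff its TIR strictly exceeds
#' Q3 + fence * IQR of all scored in-frame candidates of the gene; a gene
#' with a single candidate (its own background) or with all-equal TIRs can
#' therefore never pass. Under the z-score rule the candidate passes iff
#' (tir - mean)/sd exceeds the threshold.
#'
#' @param candidate_tir TIR of the candidate under test.
#' @param all_tirs Numeric TIRs of every scored candidate of the gene
#'   (including the candidate).
#' @param cfg A \code{\link{filterConfig}}.
#' @return Logical.
#' @export
filterOutlier <- function(candidate_tir, all_tirs, cfg = filterConfig()) {
  stopifnot(length(all_tirs) >= 1L)
  if (cfg$outlier_rule == "tukey") {
    q <- stats::quantile(all_tirs, c(0.25, 0.75), names = FALSE, type = 7)
    fence <- q[2] + cfg$fence_multiplier * (q[2] - q[1])
    candidate_tir > fence
  } else {
    s <- stats::sd(all_tirs)
    if (!is.finite(s) || s == 0) return(FALSE)
    (candidate_tir - mean(all_tirs)) / s > cfg$zscore_threshold
  }
}

#' Filter (ii): iTSS away from the gene extremities
#'
#' Passes iff the candidate codon index lies strictly after the first
#' \code{edge_window_aa} codons and at least \code{edge_window_aa} codons
#' before the protein end (both windows inclusive of their boundary). A
#' protein no longer than twice the window fails automatically.
#'
#' @param codon_index 1-based codon index of the candidate.
#' @param protein_len Protein length in residues.
#' @param cfg A \code{\link{filterConfig}}.
#' @return Logical.
#' @export
filterEdges <- function(codon_index, protein_len, cfg = filterConfig()) {
  w <- cfg$edge_window_aa
  if (protein_len <= 2L * w) return(FALSE)
  codon_index > w && codon_index <= protein_len - w
}

#' Filter (iii): iTSS not inside a conserved domain
#'
#' Passes iff no domain hit contains the candidate codon, with inclusive
#' interval endpoints: an iTSS at a domain's first or last residue still
#' truncates the domain.
#'
#' @param codon_index 1-based codon index of the candidate.
#' @param domains \code{data.frame} of domain hits of this gene (columns
#'   \code{start_aa}, \code{end_aa}); zero rows pass.
#' @return Logical.
#' @export
filterDomainOverlap <- function(codon_index, domains) {
  if (is.null(domains) || nrow(domains) == 0) return(TRUE)
  !any(domains$start_aa <= codon_index & codon_index <= domains$end_aa)
}

#' Filter (iv): absence of phage tail domains
#'
#' Passes iff no hit of the gene is categorised \code{"tail"} or carries an
#' accession from the configured tail list. A gene with no hits at all
#' passes (literal absence of tail domains).
#'
#' @param domains \code{data.frame} of domain hits of this gene (columns
#'   \code{accession}, optionally \code{category}).
#' @param cfg A \code{\link{filterConfig}}.
#' @return Logical.
#' @export
filterTailDomains <- function(domains, cfg = filterConfig()) {
  if (is.null(domains) || nrow(domains) == 0) return(TRUE)
  tail_cat <- if ("category" %in% colnames(domains))
    domains$category == "tail" else FALSE
  !any(tail_cat | domains$accession %in% cfg$tail_accessions)
}

#' Run the full iTSS screen over a cohort
#'
#' For each gene: enumerate and score in-frame internal start candidates
#' (built-in model or precomputed table), register the candidate with the
#' highest TIR, and evaluate the four filters independently. A gene is
#' retained iff it has a candidate and passes all four. Genes lacking any
#' domain annotation pass filters (iii) and (iv) by default and are flagged
#' (\code{no_domain_info}).
#'
#' @param cohort A \code{\link{LysinCohort}}.
#' @param domains Domain hits \code{data.frame} (the \code{hits} element of
#'   \code{\link{readDomainHits}}), or \code{NULL}.
#' @param model An \code{\link{sdModel}} for the built-in scorer.
#' @param tir_table Optional precomputed \code{\link{tirTable}}; overrides
#'   the model.
#' @param cfg A \code{\link{filterConfig}}.
#' @return A \code{\link{ScreenResult}}.
#' @examples
#' cc <- generateCohort(generatorConfig(n_genes = 8, seed = 1))
#' res <- runScreen(cc$cohort, cc$domains)
#' screenSummary(res)
#' @export
runScreen <- function(cohort, domains = NULL, model = sdModel(),
                      tir_table = NULL, cfg = filterConfig()) {
  ids <- geneIds(cohort)
  plens <- Biostrings::width(proteinSeqs(cohort))
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    scored <- scoreGene(cohort[i], model = model, tir_table = tir_table)
    top <- selectTopCandidate(scored)
    dom <- if (!is.null(domains))
      domains[domains$gene_id == id, , drop = FALSE] else NULL
    no_dom <- is.null(dom) || nrow(dom) == 0
    if (is.null(top)) {
      rows[[i]] <- data.frame(
        gene_id = id, codon_index = NA_integer_,
        start_codon = NA_character_, tir = NA_real_,
        outlier_pass = FALSE, edge_pass = FALSE, domain_pass = FALSE,
        tail_pass = FALSE, status = "no_candidate",
        no_domain_info = no_dom, note = "")
      next
    }
    flags <- c(
      outlier_pass = filterOutlier(top$tir, scored$tir, cfg),
      edge_pass = filterEdges(top$codon_index, plens[i], cfg),
      domain_pass = filterDomainOverlap(top$codon_index, dom),
      tail_pass = filterTailDomains(dom, cfg))
    rows[[i]] <- data.frame(
      gene_id = id, codon_index = top$codon_index,
      start_codon = top$start_codon, tir = top$tir,
      outlier_pass = flags[["outlier_pass"]],
      edge_pass = flags[["edge_pass"]],
      domain_pass = flags[["domain_pass"]],
      tail_pass = flags[["tail_pass"]],
      status = if (all(flags)) "retained" else "excluded",
      no_domain_info = no_dom,
      note = if (no_dom) "no domain annotations: filters iii/iv passed"
             else "")
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), codon_index = integer(0),
               start_codon = character(0), tir = numeric(0),
               outlier_pass = logical(0), edge_pass = logical(0),
               domain_pass = logical(0), tail_pass = logical(0),
               status = character(0), no_domain_info = logical(0),
               note = character(0))
  rownames(calls) <- NULL
  n_total <- nrow(calls)
  n_cand <- sum(calls$status != "no_candidate")
  n_ret <- sum(calls$status == "retained")
  new("ScreenResult", calls = calls,
      summary = list(n_total = n_total, n_with_candidate = n_cand,
                     n_retained = n_ret,
                     fraction_retained =
                       if (n_total > 0) n_ret / n_total else NA_real_),
      config = unclass(cfg))
}

#' Write screen calls as TSV
#'
#' @param screen A \code{\link{ScreenResult}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeScreen <- function(screen, path) {
  utils::write.table(screen@calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Compare screen outcomes of a target and a control family
#'
#' Reports the retained fraction of each family and their ratio
#' (target / control). No significance test is attached. The ratio is
#' \code{NA} when either cohort is empty or the control fraction is zero.
#'
#' @param target,control \code{\link{ScreenResult}}s computed under the same
#'   filter configuration.
#' @return One-row \code{data.frame} with columns \code{n_target},
#'   \code{n_control}, \code{target_fraction}, \code{control_fraction},
#'   \code{ratio}.
#' @export
compareFamilies <- function(target, control) {
  if (!identical(target@config, control@config))
    warning("target and control were screened under different configs")
  tf <- target@summary$fraction_retained
  cf <- control@summary$fraction_retained
  ratio <- if (is.na(tf) || is.na(cf) || cf == 0) NA_real_ else tf / cf
  data.frame(n_target = target@summary$n_total,
             n_control = control@summary$n_total,
             target_fraction = tf, control_fraction = cf, ratio = ratio)
}
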