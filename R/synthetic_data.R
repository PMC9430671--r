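#' Configuration of the synthetic cohort generator
#'
#' The generator emulates a phage lytic-enzyme cohort with known ground
#' truth: genes with or without a planted in-frame internal start of
#' controllable Shine-Dalgarno strength, domain layouts drawn from the two
#' recurring architecture groups (two CDs with the iTSS between them; one CD
#' with the iTSS downstream), host-genus labels, and optional planted filter
#' violations so each screen filter can be exercised on purpose.
#'
#' @param n_genes Number of genes in the study family.
#' @param itss_fraction Probability a gene carries a planted iTSS
#'   (default 0.5, the prevalence regime the screen is designed around).
#' @param genus_weights Named sampling weights for host genera.
#' @param architecture_mix Named weights for \code{group1}, \code{group2},
#'   \code{none} domain layouts.
#' @param planted_strength \code{"strong"} (canonical AGGAGG at spacing
#'   5-10 nt), \code{"weak"} (no planted SD, so the site is not an outlier),
#'   or \code{"mixed"} (50/50).
#' @param edge_violation_rate,domain_violation_rate,tail_rate Probabilities
#'   that a planted iTSS is deliberately placed in the gene extremities,
#'   inside a conserved domain, or that the gene receives a tail-domain hit
#'   (defaults 0).
#' @param tag C-terminal tag recorded in the truth table for product
#'   derivation (default none).
#' @param n_control Size of an additional control family (family label
#'   \code{"control"}) in which no iTSS is ever planted.
#' @param seed Integer RNG seed; the whole cohort is a deterministic
#'   function of the config.
#' @return An object of class \code{"generator_config"}.
#' @export
generatorConfig <- function(n_genes, itss_fraction = 0.5,
                            genus_weights = c(Streptococcus = 0.30,
                                              Staphylococcus = 0.25,
                                              Enterococcus = 0.15,
                                              Lactobacillus = 0.10,
                                              Listeria = 0.10,
                                              Mycobacterium = 0.10),
                            architecture_mix = c(group1 = 0.45,
                                                 group2 = 0.45,
                                                 none = 0.10),
                            planted_strength = c("strong", "weak", "mixed"),
                            edge_violation_rate = 0,
                            domain_violation_rate = 0, tail_rate = 0,
                            tag = "", n_control = 0L, seed = 1L) {
  planted_strength <- match.arg(planted_strength)
  rates <- c(edge_violation_rate, domain_violation_rate, tail_rate)
  if (any(rates < 0 | rates > 1) || sum(rates) > 1)
    stop("violation rates must be in [0,1] and sum to at most 1")
  if (itss_fraction < 0 || itss_fraction > 1)
    stop("itss_fraction must be in [0, 1]")
  if (sum(genus_weights) <= 0 || sum(architecture_mix) <= 0)
    stop("weights must have positive sum")
  if (itss_fraction > 0 && architecture_mix[["group1"]] +
      architecture_mix[["group2"]] + architecture_mix[["none"]] <= 0)
    stop("contradictory config: iTSSs requested but no architecture weight")
  structure(list(n_genes = as.integer(n_genes),
                 itss_fraction = itss_fraction,
                 genus_weights = genus_weights / sum(genus_weights),
                 architecture_mix =
                   architecture_mix / sum(architecture_mix),
                 planted_strength = planted_strength,
                 edge_violation_rate = edge_violation_rate,
                 domain_violation_rate = domain_violation_rate,
                 tail_rate = tail_rate, tag = tag,
                 n_control = as.integer(n_control),
                 seed = as.integer(seed)),
            class = "generator_config")
}

.SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}
.START_CODONS <- c("ATG", "GTG", "TTG")
.NONSTART_SENSE <- setdiff(.SENSE_CODONS, .START_CODONS)

# positions (nt, 1-based) of hexamers within Hamming distance 1 of AGGAGG
.sdLikePositions <- function(nt) {
  chars <- strsplit(nt, "")[[1L]]
  n <- length(chars)
  if (n < 6L) return(integer(0))
  tgt <- c("A", "G", "G", "A", "G", "G")
  mism <- matrix(0L, nrow = n - 5L, ncol = 6L)
  for (k in 1:6)
    mism[, k] <- as.integer(chars[k:(n - 6L + k)] != tgt[k])
  which(rowSums(mism) <= 1L)
}

# Generate one synthetic gene. Internal; driven by generateCohort.
.generateGene <- function(cfg, gene_id, family) {
  genus <- sample(names(cfg$genus_weights), 1L,
                  prob = cfg$genus_weights)
  arch <- sample(names(cfg$architecture_mix), 1L,
                 prob = cfg$architecture_mix)
  has_itss <- family == "endolysin" && stats::runif(1) < cfg$itss_fraction
  L <- switch(arch,
              group1 = sample(340:400, 1L),
              group2 = sample(280:330, 1L),
              none = sample(250:330, 1L))
  dom <- switch(arch,
    group1 = data.frame(
      accession = c("PF01510", "PF05257", "PF08460"),
      name = c("Amidase_2", "CHAP", "SH3_5"),
      start_aa = c(10L, round(0.52 * L), round(0.80 * L)),
      end_aa = c(round(0.33 * L), round(0.72 * L), L - 5L)),
    group2 = data.frame(
      accession = c("PF01183", "PF08460"),
      name = c("Glyco_hydro_25", "SH3_5"),
      start_aa = c(6L, round(0.74 * L)),
      end_aa = c(round(0.58 * L), L - 10L)),
    none = data.frame(
      accession = "PF08460", name = "SH3_5",
      start_aa = 10L, end_aa = 60L))

  outcome <- "none"
  strength <- NA_character_
  p <- NA_integer_
  if (has_itss) {
    u <- stats::runif(1)
    r <- c(cfg$edge_violation_rate, cfg$domain_violation_rate,
           cfg$tail_rate)
    outcome <- if (u < r[1]) "fail_edge"
      else if (u < r[1] + r[2]) "fail_domain"
      else if (u < sum(r)) "fail_tail"
      else "planted"
    strength <- switch(cfg$planted_strength,
                       strong = "strong", weak = "weak",
                       mixed = sample(c("strong", "weak"), 1L))
    if (outcome == "planted")
      outcome <- if (strength == "strong") "retain" else "fail_outlier"
    safe <- switch(arch,
      group1 = seq(dom$end_aa[1] + 2L, dom$start_aa[2] - 2L),
      group2 = seq(dom$end_aa[1] + 2L, dom$start_aa[2] - 2L),
      none = seq(dom$end_aa[1] + 2L, L - 21L))
    safe <- intersect(safe, 21:(L - 20L))
    p <- switch(outcome,
      fail_edge = {
        covered <- unlist(mapply(seq, dom$start_aa, dom$end_aa,
                                 SIMPLIFY = FALSE))
        cand <- setdiff(c(8:20, (L - 19L):(L - 1L)), covered)
        cand[sample.int(length(cand), 1L)]
      },
      fail_domain = {
        inside <- intersect(seq(dom$start_aa[1] + 1L, dom$end_aa[1] - 1L),
                            21:(L - 20L))
        inside[sample.int(length(inside), 1L)]
      },
      safe[sample.int(length(safe), 1L)])
    if (outcome == "fail_tail") {
      tail_row <- data.frame(accession = "PF04865", name = "Baseplate_J",
                             start_aa = dom$start_aa[nrow(dom)],
                             end_aa = dom$end_aa[nrow(dom)])
      dom <- rbind(dom, tail_row)
    }
  }

  codons <- c("ATG", sample(.SENSE_CODONS, L - 1L, replace = TRUE))
  if (has_itss) {
    codons[p] <- "ATG"
    # neighbours of the planted start must not be competing start codons
    for (q in c(p - 1L, p - 2L))
      if (q >= 2L && codons[q] %in% .START_CODONS)
        codons[q] <- sample(.NONSTART_SENSE, 1L)
  }
  codons <- c(codons, "TAA")
  nt <- paste(codons, collapse = "")
  sd_range <- integer(0)
  if (has_itss && strength == "strong") {
    start_nt <- 3L * (p - 1L) + 1L
    sd_range <- (start_nt - 13L):(start_nt - 8L)  # aligned spacing 7 nt
    substr(nt, sd_range[1], sd_range[6]) <- "AGGAGG"
    # planting may have created an in-frame stop in a boundary codon
    for (ci in unique((sd_range - 1L) %/% 3L + 1L)) {
      cd <- substr(nt, 3L * (ci - 1L) + 1L, 3L * ci)
      if (cd %in% c("TAA", "TAG", "TGA")) {
        free <- setdiff(seq(3L * (ci - 1L) + 1L, 3L * ci), sd_range)
        for (fp in free) substr(nt, fp, fp) <- "C"
      }
    }
  }
  # reject SD-like hexamers outside the planted site so planted sites
  # dominate the score background
  protect_codon <- c(1L, if (has_itss) p, L + 1L)
  protect_nt <- sd_range
  for (iter in 1:200) {
    occ <- .sdLikePositions(nt)
    occ <- occ[!vapply(occ, function(o)
      any((o:(o + 5L)) %in% protect_nt), logical(1))]
    if (!length(occ)) break
    o <- occ[1L]
    cods <- unique((seq(o, o + 5L) - 1L) %/% 3L + 1L)
    cods <- setdiff(cods, protect_codon)
    cods <- cods[vapply(cods, function(ci)
      !any(seq(3L * (ci - 1L) + 1L, 3L * ci) %in% protect_nt),
      logical(1))]
    if (!length(cods)) break  # cannot touch: overlaps only protected codons
    for (ci in cods) {
      repl <- sample(if (ci %in% c(p - 1L, p - 2L)) .NONSTART_SENSE
                     else .SENSE_CODONS, 1L)
      substr(nt, 3L * (ci - 1L) + 1L, 3L * ci) <- repl
    }
  }
  tr <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = Biostrings::getGeneticCode("11")))
  prot <- substr(tr, 1L, nchar(tr) - 1L)
  substr(prot, 1L, 1L) <- "M"
  dom$gene_id <- gene_id
  dom$evalue <- signif(stats::runif(nrow(dom), 1e-30, 1e-5), 3)
  dom <- dom[, c("gene_id", "accession", "name", "start_aa", "end_aa",
                 "evalue")]
  list(record = data.frame(gene_id = gene_id, cds = nt, protein = prot,
                           host_genus = genus, family = family,
                           source = "synthetic"),
       domains = dom,
       truth = data.frame(gene_id = gene_id, has_itss = has_itss,
                          itss_codon = p,
                          planted_class = if (has_itss)
                            paste(arch, strength, sep = "_") else arch,
                          intended_filter_outcome = outcome))
}

#' Generate a synthetic cohort with ground truth
#'
#' Builds \code{n_genes} study-family genes (plus an optional control
#' family) per the configuration, assembles them into a validated
#' \code{\link{LysinCohort}} with categorised domain hits and a truth table,
#' and (by default) verifies each gene by running the actual screen: the
#' truth table then carries the realized status and a \code{collision} flag
#' for genes whose screen outcome differs from the intended one (e.g. a
#' spurious backbone site out-scoring a planted one, or a background site of
#' an unplanted gene passing all filters). Byte-identical output for a given
#' config.
#'
#' @param cfg A \code{\link{generatorConfig}}.
#' @param out_dir Optional directory; when given, writes \code{cds.fasta},
#'   \code{protein.fasta}, \code{metadata.tsv}, \code{domains.txt} and
#'   \code{truth.tsv} in the exact formats the readers parse.
#' @param verify Run the screen for collision logging (default \code{TRUE}).
#' @param model,filter_cfg Scorer and filter configuration used for
#'   verification (defaults match \code{\link{runScreen}}).
#' @return List with \code{cohort} (\code{LysinCohort}), \code{domains}
#'   (categorised hits \code{data.frame}), \code{truth} (\code{data.frame}),
#'   and, when verified, \code{screen} (\code{\link{ScreenResult}}).
#' @examples
#' cc <- generateCohort(generatorConfig(n_genes = 5, seed = 42))
#' cc$truth
#' @export
generateCohort <- function(cfg, out_dir = NULL, verify = TRUE,
                           model = sdModel(), filter_cfg = filterConfig()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  ids <- c(if (cfg$n_genes > 0) sprintf("G%04d", seq_len(cfg$n_genes)),
           if (cfg$n_control > 0) sprintf("CTRL%04d",
                                          seq_len(cfg$n_control)))
  fam <- c(rep("endolysin", cfg$n_genes), rep("control", cfg$n_control))
  genes <- mapply(function(id, f) .generateGene(cfg, id, f), ids, fam,
                  SIMPLIFY = FALSE)
  if (length(genes)) {
    rec <- do.call(rbind, lapply(genes, `[[`, "record"))
    cohort <- LysinCohort(rec$gene_id, rec$cds, rec$protein,
                          rec$host_genus, rec$family, rec$source)
    domains <- domainHits(do.call(rbind, lapply(genes, `[[`, "domains")),
                          cohort = cohort)$hits
    truth <- do.call(rbind, lapply(genes, `[[`, "truth"))
    rownames(truth) <- NULL
  } else {
    cohort <- .emptyCohort()
    domains <- data.frame(gene_id = character(0), accession = character(0),
                          name = character(0), start_aa = integer(0),
                          end_aa = integer(0), evalue = numeric(0),
                          category = character(0))
    truth <- data.frame(gene_id = character(0), has_itss = logical(0),
                        itss_codon = integer(0),
                        planted_class = character(0),
                        intended_filter_outcome = character(0))
  }
  out <- list(cohort = cohort, domains = domains, truth = truth)
  if (verify && length(genes)) {
    scr <- runScreen(cohort, domains, model = model, cfg = filter_cfg)
    calls <- screenCalls(scr)
    m <- match(truth$gene_id, calls$gene_id)
    truth$realized_status <- calls$status[m]
    truth$realized_codon <- calls$codon_index[m]
    intended_ret <- truth$intended_filter_outcome == "retain"
    truth$collision <- (intended_ret &
                          (truth$realized_status != "retained" |
                             truth$realized_codon != truth$itss_codon)) |
      (!intended_ret & truth$realized_status == "retained")
    out$truth <- truth
    out$screen <- scr
  }
  if (!is.null(out_dir)) {
    writeCohort(cohort, out_dir)
    writeDomainHits(domains, file.path(out_dir, "domains.txt"))
    utils::write.table(out$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
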