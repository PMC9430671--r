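#' Simplified Shine-Dalgarno translation-initiation model
#'
#' Parameters of the built-in translation-initiation-rate (TIR) scorer. The
#' score of an internal start candidate is
#' \deqn{TIR = k \exp(-\beta \, \Delta G_{total})}
#' where \eqn{\Delta G_{total}} is the best (lowest) sum, over upstream SD
#' placements, of the SD:anti-SD hybridisation energy of the longest
#' contiguous complementary run (per-pair energies G:C \eqn{-3.0}, A:U
#' \eqn{-2.0}, G:U wobble \eqn{-1.0} kcal/mol, duplex initiation penalty
#' \eqn{+4.1}), a quadratic spacing penalty outside the optimal aligned
#' spacing, and a start-codon bonus ordering ATG < GTG < TTG. This is a
#' deliberately small surrogate for full thermodynamic RBS models: it ranks
#' start sites by SD strength, spacing and start codon, and makes no claim
#' of numerical agreement with published TIR predictions. Precomputed TIR
#' tables (\code{\link{readTirTable}}) can replace it entirely.
#'
#' With the defaults, a canonical AGGAGG at aligned spacing 7 nt upstream of
#' an ATG scores about 10,000 relative units, placing planted strong sites in
#' the regime of experimentally notable TIRs.
#'
#' @param anti_sd Anti-Shine-Dalgarno core, 5'-3' RNA (default
#'   \code{"CCUCCU"}, whose reverse complement is the SD consensus AGGAGG).
#' @param beta Energy-to-rate slope (1/(kcal/mol), default 0.45).
#' @param k Rate scale (relative units, default 47.2).
#' @param spacing_window Integer range of aligned SD-start spacings searched
#'   (nt between the SD 3' end and the start codon; default 4 to 16).
#' @param spacing_opt Optimal spacing range (default 5 to 10); no penalty
#'   inside it.
#' @param spacing_penalty Quadratic penalty coefficient (kcal/mol per nt^2)
#'   outside the optimum (default 0.3).
#' @param start_bonus Named energies (kcal/mol) added per start codon
#'   (default \code{c(ATG = 0, GTG = 1, TTG = 2)}).
#' @param genus_params Named list of per-genus overrides, each a list with
#'   any of the above fields; the host genus selects the override, unknown
#'   genera fall back to the defaults (mirroring the choice of the closest
#'   available relative).
#' @return An object of class \code{"sd_model"}.
#' @examples
#' m <- sdModel()
#' @export
sdModel <- function(anti_sd = "CCUCCU", beta = 0.45, k = 47.2,
                    spacing_window = c(4L, 16L), spacing_opt = c(5L, 10L),
                    spacing_penalty = 0.3,
                    start_bonus = c(ATG = 0, GTG = 1, TTG = 2),
                    genus_params = list()) {
  anti_sd <- toupper(anti_sd)
  if (nchar(anti_sd) < 4) stop("anti_sd must be at least 4 nt")
  if (!grepl("^[ACGU]+$", anti_sd)) stop("anti_sd must be RNA (ACGU)")
  if (beta <= 0 || k <= 0) stop("beta and k must be positive")
  structure(list(anti_sd = anti_sd, beta = beta, k = k,
                 spacing_window = as.integer(spacing_window),
                 spacing_opt = as.integer(spacing_opt),
                 spacing_penalty = spacing_penalty,
                 start_bonus = start_bonus,
                 genus_params = genus_params),
            class = "sd_model")
}

#' Read an SD model configuration from JSON
#'
#' @param path JSON file with any of the \code{\link{sdModel}} fields,
#'   optionally a \code{genus_params} object keyed by genus.
#' @return An \code{"sd_model"} object.
#' @export
readSdModel <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sdModel, cfg)
}

# Resolve per-genus overrides against the defaults.
.modelForGenus <- function(model, genus) {
  ov <- model$genus_params[[genus]]
  if (is.null(ov)) return(model)
  for (f in names(ov)) model[[f]] <- ov[[f]]
  model
}

#' Enumerate in-frame internal start candidates of a gene
#'
#' Scans the CDS codon-by-codon and returns every internal codon (index
#' \eqn{\ge 2} on the 1-based protein coordinate system, the stop codon
#' excluded) that is ATG, GTG or TTG, in ascending order. These are the
#' candidate internal translation start sites before scoring.
#'
#' @param gene A single-gene \code{\link{LysinCohort}}, or a CDS character
#'   string.
#' @return \code{data.frame} with columns \code{codon_index},
#'   \code{start_codon}.
#' @examples
#' findInframeStarts("ATGAAAATGTAA")  # one candidate: ATG at codon 3
#' @export
findInframeStarts <- function(gene) {
  cds <- .geneCds(gene)
  n_codon <- nchar(cds) %/% 3L
  if (n_codon < 3L)
    return(data.frame(codon_index = integer(0), start_codon = character(0)))
  idx <- 2:(n_codon - 1L)  # exclude initiator and stop codon
  codons <- substring(cds, 3L * (idx - 1L) + 1L, 3L * idx)
  sel <- codons %in% c("ATG", "GTG", "TTG")
  data.frame(codon_index = idx[sel], start_codon = codons[sel])
}

.geneCds <- function(gene) {
  if (is(gene, "LysinCohort")) {
    stopifnot(length(gene) == 1L)
    as.character(cdsSeqs(gene)[[1L]])
  } else toupper(as.character(gene))
}

# Pairing energy of an upstream hexamer-sized window against the anti-SD.
# window and anti_sd both 5'->3'; position i of the window faces position
# L+1-i of the anti-SD. Returns the summed per-pair energy of the longest
# contiguous paired run (0 if the run is shorter than 2 pairs).
.pairEnergies <- c("A:U" = -2, "U:A" = -2, "G:C" = -3, "C:G" = -3,
                   "G:U" = -1, "U:G" = -1)

.hybridizationEnergy <- function(window, anti_sd) {
  L <- nchar(anti_sd)
  w <- strsplit(chartr("T", "U", window), "")[[1L]]
  a <- rev(strsplit(anti_sd, "")[[1L]])  # face positions 3'->5'
  e <- .pairEnergies[paste(w, a, sep = ":")]
  e[is.na(e)] <- 0
  paired <- e < 0
  if (!any(paired)) return(0)
  r <- rle(paired)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- 0
  for (j in which(r$values & r$lengths >= 2L))
    best <- min(best, sum(e[starts[j]:ends[j]]))
  best
}

#' Score one internal start candidate with the built-in SD model
#'
#' Searches aligned spacings within the model's spacing window for the best
#' SD:anti-SD hybridisation upstream of the candidate start codon (using
#' only sequence inside the CDS), adds the spacing penalty and start-codon
#' bonus, and converts the total free energy to a TIR. Deterministic;
#' strengthening the SD match at fixed spacing never lowers the score.
#'
#' @param gene A single-gene \code{\link{LysinCohort}} or CDS string.
#' @param codon_index 1-based codon index of an internal ATG/GTG/TTG.
#' @param model An \code{\link{sdModel}}.
#' @param genus Optional host genus used to resolve per-genus model
#'   parameters.
#' @return One-row \code{data.frame}: \code{codon_index},
#'   \code{start_codon}, \code{tir}, \code{sd_energy} (kcal/mol, the
#'   SD+spacing term), \code{spacing_nt} (NA when no SD pairing found).
#' @export
scoreTir <- function(gene, codon_index, model = sdModel(), genus = NULL) {
  cds <- .geneCds(gene)
  if (!is.null(genus)) model <- .modelForGenus(model, genus)
  n_codon <- nchar(cds) %/% 3L
  codon_index <- as.integer(codon_index)
  if (codon_index < 2L || codon_index >= n_codon)
    stop("codon_index out of range: ", codon_index)
  start_nt <- 3L * (codon_index - 1L) + 1L
  start_codon <- substr(cds, start_nt, start_nt + 2L)
  if (!start_codon %in% c("ATG", "GTG", "TTG"))
    stop("codon at index ", codon_index, " is not ATG/GTG/TTG")
  L <- nchar(model$anti_sd)
  best <- 0
  best_sp <- NA_integer_
  for (sp in model$spacing_window[1]:model$spacing_window[2]) {
    from <- start_nt - sp - L
    if (from < 1L) next
    win <- substr(cds, from, from + L - 1L)
    dg <- .hybridizationEnergy(win, model$anti_sd)
    if (dg < 0) {
      dg <- dg + 4.1  # duplex initiation
      d <- max(model$spacing_opt[1] - sp, sp - model$spacing_opt[2], 0)
      dg <- dg + model$spacing_penalty * d^2
    } else dg <- 0
    dg <- min(dg, 0)  # an unfavourable duplex is simply not formed
    if (dg < best) { best <- dg; best_sp <- sp }
  }
  dg_total <- best + unname(model$start_bonus[start_codon])
  data.frame(codon_index = codon_index, start_codon = start_codon,
             tir = model$k * exp(-model$beta * dg_total),
             sd_energy = best, spacing_nt = best_sp)
}

#' Score all internal start candidates of a gene
#'
#' Enumerates candidates with \code{\link{findInframeStarts}} and scores
#' them, either with the built-in model or, when a precomputed TIR table is
#' supplied, by table lookup. Table values take absolute precedence: the
#' built-in model is never consulted, and candidates absent from the table
#' are excluded (unscored). A gene entirely absent from a supplied table
#' raises a warning and yields zero scored candidates.
#'
#' @param gene A single-gene \code{\link{LysinCohort}} or CDS string.
#' @param model An \code{\link{sdModel}} (ignored when \code{tir_table} is
#'   given).
#' @param tir_table Optional \code{\link{tirTable}}.
#' @param gene_id Gene id used for table lookup (taken from the cohort when
#'   available).
#' @param genus Optional host genus for per-genus model parameters.
#' @return \code{data.frame} with columns \code{gene_id}, \code{codon_index},
#'   \code{start_codon}, \code{tir}, \code{sd_energy}, \code{spacing_nt}.
#' @export
scoreGene <- function(gene, model = sdModel(), tir_table = NULL,
                      gene_id = NULL, genus = NULL) {
  if (is(gene, "LysinCohort")) {
    stopifnot(length(gene) == 1L)
    if (is.null(gene_id)) gene_id <- geneIds(gene)
    if (is.null(genus)) genus <- unname(hostGenus(gene))
  }
  if (is.null(gene_id)) gene_id <- "gene"
  cand <- findInframeStarts(gene)
  empty <- data.frame(gene_id = character(0), codon_index = integer(0),
                      start_codon = character(0), tir = numeric(0),
                      sd_energy = numeric(0), spacing_nt = integer(0))
  if (nrow(cand) == 0) return(empty)
  if (!is.null(tir_table)) {
    sub <- tir_table[tir_table$gene_id == gene_id, , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("gene '", gene_id, "' absent from TIR table: left unscored")
      return(empty)
    }
    m <- match(cand$codon_index, sub$codon_index)
    keep <- !is.na(m)
    if (!any(keep)) return(empty)
    return(data.frame(gene_id = gene_id,
                      codon_index = cand$codon_index[keep],
                      start_codon = cand$start_codon[keep],
                      tir = sub$tir[m[keep]],
                      sd_energy = NA_real_, spacing_nt = NA_integer_))
  }
  rows <- lapply(cand$codon_index, function(i)
    scoreTir(gene, i, model = model, genus = genus))
  out <- do.call(rbind, rows)
  cbind(gene_id = gene_id, out)
}
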