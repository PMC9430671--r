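# Independent oracles, coded without reference to the package internals.

# Residue masses rebuilt from elemental composition and atomic masses, as a
# cross-check of the package's residue table.
oracle_peptide_mass <- function(protein) {
  atoms <- c(H = 1.0078250319, C = 12, N = 14.0030740052,
             O = 15.9949146221, S = 31.97207069)
  comp <- list(  # residue formulas (amino acid minus water): C, H, N, O, S
    G = c(2, 3, 1, 1, 0), A = c(3, 5, 1, 1, 0), S = c(3, 5, 1, 2, 0),
    P = c(5, 7, 1, 1, 0), V = c(5, 9, 1, 1, 0), T = c(4, 7, 1, 2, 0),
    C = c(3, 5, 1, 1, 1), L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
    N = c(4, 6, 2, 2, 0), D = c(4, 5, 1, 3, 0), Q = c(5, 8, 2, 2, 0),
    K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0), M = c(5, 9, 1, 1, 1),
    H = c(6, 7, 3, 1, 0), F = c(9, 9, 1, 1, 0), R = c(6, 12, 4, 1, 0),
    Y = c(9, 9, 1, 2, 0), W = c(11, 10, 2, 1, 0))
  res_mass <- function(aa) {
    f <- comp[[aa]]
    f[1] * atoms["C"] + f[2] * atoms["H"] + f[3] * atoms["N"] +
      f[4] * atoms["O"] + f[5] * atoms["S"]
  }
  chars <- strsplit(protein, "")[[1]]
  sum(vapply(chars, res_mass, numeric(1))) +
    2 * atoms["H"] + atoms["O"]  # one water
}

# Independent stoichiometry search: plain double loop, first-better-kept,
# explicit tie-breaks.
oracle_stoichiometry <- function(observed, m_flp, m_ctp, a_max, b_max) {
  best <- NULL
  best_err <- Inf
  for (a in 0:a_max) for (b in 0:b_max) {
    if (a == 0 && b == 0) next
    err <- abs(a * m_flp + b * m_ctp - observed)
    if (err < best_err - 1e-12) {
      best_err <- err
      best <- c(a, b)
    }
    # equal error: keep the earlier (smaller a, then smaller b) -- the loop
    # order already visits in that order, so do nothing
  }
  best
}

# Type-7 quantile by hand (linear interpolation of order statistics).
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# Brute-force re-evaluation of the four screen filters from raw inputs
# (TIR table, protein lengths, domain hits); independent of the package's
# filter functions.
oracle_screen <- function(cohort, domains, tir_table,
                          edge_w = 20, fence = 1.5,
                          tail_acc = names(defaultTailAccessions())) {
  ids <- geneIds(cohort)
  plen <- Biostrings::width(proteinSeqs(cohort))
  out <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    cand <- tir_table[tir_table$gene_id == id, , drop = FALSE]
    if (nrow(cand) == 0)
      return(data.frame(gene_id = id, status = "no_candidate",
                        failing = ""))
    cand <- cand[order(cand$codon_index), ]
    top <- cand[cand$tir == max(cand$tir), ][1, ]
    q1 <- oracle_quantile(cand$tir, 0.25)
    q3 <- oracle_quantile(cand$tir, 0.75)
    f <- character(0)
    if (!(top$tir > q3 + fence * (q3 - q1))) f <- c(f, "outlier")
    if (!(top$codon_index > edge_w &&
          top$codon_index <= plen[i] - edge_w)) f <- c(f, "edge")
    dom <- domains[domains$gene_id == id, , drop = FALSE]
    if (nrow(dom) &&
        any(dom$start_aa <= top$codon_index &
            top$codon_index <= dom$end_aa)) f <- c(f, "domain")
    if (nrow(dom) && any(dom$accession %in% tail_acc)) f <- c(f, "tail")
    data.frame(gene_id = id,
               status = if (length(f)) "excluded" else "retained",
               failing = paste(f, collapse = ","))
  })
  do.call(rbind, out)
}
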