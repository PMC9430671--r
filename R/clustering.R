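# Identity-objective substitution matrix over the AA alphabet.
.identityScoringMatrix <- function() {
  letters <- c(Biostrings::AA_STANDARD, "X", "B", "Z", "J", "U", "O", "*")
  m <- matrix(0, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1
  m
}

#' Global percent identity of two protein sequences
#'
#' Needleman-Wunsch global alignment under an identity objective (match +1,
#' mismatch 0, affine gaps: opening 2, extension 0.5). Identity is
#' 100 * matches / alignment length, with internal and terminal gap columns
#' counted in the denominator (the conservative choice; set
#' \code{denominator = "shorter"} to divide by the shorter sequence length
#' instead). Arguments are ordered canonically before aligning so the result
#' is exactly symmetric even when co-optimal alignments exist.
#'
#' @param a,b Protein sequences (character or \code{AAString}).
#' @param denominator \code{"alignment"} (default) or \code{"shorter"}.
#' @return Percent identity in [0, 100].
#' @examples
#' pairwiseIdentity("ACDEFG", "ACDEFG")  # 100
#' pairwiseIdentity("ACDEFG", "ACDEFA")  # 83.33
#' @importFrom Biostrings pairwiseAlignment alignedPattern alignedSubject
#' @export
pairwiseIdentity <- function(a, b, denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  if (a > b) { tmp <- a; a <- b; b <- tmp }  # canonical order for symmetry
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = .identityScoringMatrix(),
    gapOpening = 2, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  matches <- sum(pa == pb & pa != "-")
  den <- if (denominator == "alignment") length(pa)
         else min(nchar(a), nchar(b))
  100 * matches / den
}

#' Full pairwise percent-identity matrix
#'
#' @param proteins An \code{AAStringSet} or named character vector.
#' @inheritParams pairwiseIdentity
#' @return Symmetric numeric matrix with 100 on the diagonal.
#' @export
identityMatrix <- function(proteins,
                           denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  ids <- names(proteins)
  seqs <- as.character(proteins)  # strips names on plain vectors
  n <- length(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  names(seqs) <- ids
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <-
        pairwiseIdentity(seqs[i], seqs[j], denominator)
    }
  }
  m
}

#' Cluster sequences by a percent-identity threshold
#'
#' Single-linkage connected components of the graph whose edges connect
#' pairs with identity strictly above \code{threshold_pct} ("over X\%
#' identity" is read as a graph threshold, not a centroid method). The
#' representative of each cluster is its longest member, ties broken by gene
#' id; cluster ids are assigned in order of the smallest member gene id, so
#' the result is invariant to input order.
#'
#' @param x A \code{\link{LysinCohort}}, an \code{AAStringSet}, or a named
#'   character vector of proteins; alternatively a precomputed identity
#'   matrix via \code{id_matrix}.
#' @param threshold_pct Identity threshold in (0, 100].
#' @param id_matrix Optional precomputed symmetric identity matrix (skips
#'   the alignments).
#' @inheritParams pairwiseIdentity
#' @return A \code{\link{ClusterSet}}.
#' @importFrom igraph graph_from_adjacency_matrix components
#' @export
clusterByIdentity <- function(x, threshold_pct,
                              denominator = c("alignment", "shorter"),
                              id_matrix = NULL) {
  if (threshold_pct <= 0 || threshold_pct > 100)
    stop("threshold_pct must be in (0, 100]")
  seqs <- if (is(x, "LysinCohort"))
    stats::setNames(as.character(proteinSeqs(x)), geneIds(x))
  else stats::setNames(as.character(x), names(x))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (is.null(id_matrix)) id_matrix <- identityMatrix(seqs, denominator)
  id_matrix <- id_matrix[names(seqs), names(seqs), drop = FALSE]
  adj <- id_matrix > threshold_pct
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(names(seqs), comp)
  # order clusters by smallest member id for input-order invariance
  groups <- groups[order(vapply(groups, function(g) min(g), character(1)))]
  names(groups) <- sprintf("C%03d", seq_along(groups))
  groups <- lapply(groups, sort)
  reps <- vapply(groups, function(g) {
    w <- nchar(seqs[g])
    g[order(-w, g)][1L]
  }, character(1))
  new("ClusterSet", threshold = threshold_pct, members = groups,
      representative = reps)
}

#' Does one partition refine another?
#'
#' TRUE iff every cluster of \code{fine} is contained in a single cluster of
#' \code{coarse}; clustering at a higher identity threshold must refine the
#' partition at a lower one.
#'
#' @param fine,coarse \code{\link{ClusterSet}}s over the same sequences.
#' @return Logical.
#' @export
refinesPartition <- function(fine, coarse) {
  assign_of <- function(cs) {
    mem <- clusterMembers(cs)
    stats::setNames(rep(names(mem), lengths(mem)), unlist(mem))
  }
  co <- assign_of(coarse)
  all(vapply(clusterMembers(fine), function(m)
    length(unique(co[m])) == 1L, logical(1)))
}

# Center-star progressive multiple alignment. Aligns every sequence to the
# longest (the center) with the identity-objective pairwise aligner and
# merges the pairwise gap patterns into common columns (member insertions
# are left-aligned within their gap block). Adequate at cluster scale; not
# a general-purpose MSA.
.centerStarMSA <- function(seqs) {
  ids <- names(seqs)
  seqs <- stats::setNames(as.character(seqs), ids)
  n <- length(seqs)
  if (n == 1L) {
    m <- matrix(strsplit(seqs, "")[[1L]], nrow = 1)
    rownames(m) <- ids
    return(m)
  }
  center_i <- order(-nchar(seqs), ids)[1L]
  center <- seqs[center_i]
  Lc <- nchar(center)
  others <- setdiff(seq_len(n), center_i)
  # pairwise alignments center vs member
  pa <- lapply(others, function(j) {
    aln <- Biostrings::pairwiseAlignment(
      center, seqs[j], type = "global",
      substitutionMatrix = .identityScoringMatrix(),
      gapOpening = 2, gapExtension = 0.5)
    list(c = strsplit(as.character(Biostrings::alignedPattern(aln)),
                      "")[[1L]],
         m = strsplit(as.character(Biostrings::alignedSubject(aln)),
                      "")[[1L]])
  })
  # gaps inserted into the center before residue i (slot Lc+1 = trailing)
  gaps_before <- function(cvec) {
    gb <- integer(Lc + 1L)
    slot <- 1L
    run <- 0L
    for (ch in cvec) {
      if (ch == "-") run <- run + 1L
      else { gb[slot] <- run; run <- 0L; slot <- slot + 1L }
    }
    gb[Lc + 1L] <- run
    gb
  }
  gb_list <- lapply(pa, function(p) gaps_before(p$c))
  master <- Reduce(pmax, gb_list)
  expand_member <- function(p, gb) {
    out <- character(0)
    pos <- 1L
    for (i in seq_len(Lc + 1L)) {
      block <- if (gb[i] > 0) p$m[pos:(pos + gb[i] - 1L)] else character(0)
      pos <- pos + gb[i]
      piece <- c(block, rep("-", master[i] - gb[i]))
      if (i <= Lc) {
        piece <- c(piece, p$m[pos])
        pos <- pos + 1L
      }
      out <- c(out, piece)
    }
    out
  }
  center_chars <- strsplit(center, "")[[1L]]
  center_row <- character(0)
  for (i in seq_len(Lc + 1L))
    center_row <- c(center_row, rep("-", master[i]),
                    if (i <= Lc) center_chars[i])
  rows <- vector("list", n)
  rows[[center_i]] <- center_row
  for (k in seq_along(others))
    rows[[others[k]]] <- expand_member(pa[[k]], gb_list[[k]])
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  m
}

#' iTSS positional consensus within clusters
#'
#' For each cluster, aligns the member proteins (built-in center-star
#' progressive alignment), maps each member's iTSS codon to its alignment
#' column, and reports the modal column: the column value maximising the
#' number of members whose iTSS lies within \code{tolerance} columns of it.
#' The consensus column is declared when that count exceeds half of the
#' members having a call; \code{support} is the count divided by the cluster
#' size. Predictions recurring at the same relative position across related
#' sequences are considered better supported.
#'
#' @param clusters A \code{\link{ClusterSet}}.
#' @param cohort The \code{\link{LysinCohort}} the clusters were built from.
#' @param screen A \code{\link{ScreenResult}} (its calls supply the iTSS
#'   codon per gene), or a \code{data.frame} with columns \code{gene_id},
#'   \code{codon_index}.
#' @param tolerance Column tolerance for "same relative position"
#'   (default 2).
#' @return \code{data.frame} with one row per cluster: \code{cluster_id},
#'   \code{n_members}, \code{n_with_call}, \code{consensus_column}
#'   (\code{NA} when no consensus), \code{support}.
#' @export
itssPositionConsensus <- function(clusters, cohort, screen, tolerance = 2L) {
  calls <- if (is(screen, "ScreenResult")) screen@calls else screen
  seqs <- stats::setNames(as.character(proteinSeqs(cohort)),
                          geneIds(cohort))
  mem <- clusterMembers(clusters)
  out <- vector("list", length(mem))
  for (ci in seq_along(mem)) {
    members <- mem[[ci]]
    missing <- setdiff(members, names(seqs))
    if (length(missing))
      stop("cluster member(s) absent from cohort: ",
           paste(missing, collapse = ", "))
    msa <- .centerStarMSA(seqs[members])
    idx <- calls$codon_index[match(members, calls$gene_id)]
    with_call <- which(!is.na(idx))
    cols <- vapply(with_call, function(k) {
      row <- msa[members[k], ]
      which(cumsum(row != "-") == idx[k] & row != "-")[1L]
    }, integer(1))
    n_with <- length(with_call)
    if (n_with == 0L) {
      out[[ci]] <- data.frame(cluster_id = names(mem)[ci],
                              n_members = length(members),
                              n_with_call = 0L,
                              consensus_column = NA_integer_, support = 0)
      next
    }
    counts <- vapply(cols, function(c0)
      sum(abs(cols - c0) <= tolerance), integer(1))
    best <- order(-counts, cols)[1L]
    n_share <- counts[best]
    consensus <- if (n_share > n_with / 2) cols[best] else NA_integer_
    out[[ci]] <- data.frame(cluster_id = names(mem)[ci],
                            n_members = length(members),
                            n_with_call = n_with,
                            consensus_column = consensus,
                            support = n_share / length(members))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
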