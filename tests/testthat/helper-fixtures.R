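# Fixture builders shared across test files. Everything is constructed in
# code; no binary data.

# Fixed reverse-translation map. Deliberately avoids GTG and TTG so the only
# in-frame start candidates of a hand-built gene are its Met positions.
.codon_of <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
               G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
               M = "ATG", N = "AAT", P = "CCG", Q = "CAA", R = "CGT",
               S = "AGC", T = "ACG", V = "GTT", W = "TGG", Y = "TAT")

reverse_translate <- function(protein) {
  paste0(paste(.codon_of[strsplit(protein, "")[[1]]], collapse = ""), "TAA")
}

# protein of length n with M at `met_at` (position 1 always M) and no other
# Met; letters cycle over a fixed non-M alphabet
make_protein <- function(n, met_at = integer(0)) {
  alpha <- strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1]]
  p <- paste(rep_len(alpha, n), collapse = "")
  substr(p, 1, 1) <- "M"
  for (i in met_at) substr(p, i, i) <- "M"
  p
}

# The 20-gene screen fixture: 8 genes pass all four filters, 12 violate
# exactly one each (3 per filter). TIRs come from a hand-built table so
# every flag is forced by construction.
make_screen_fixture <- function() {
  genes <- list()
  tir_rows <- list()
  dom_rows <- list()
  expected <- list()
  add_gene <- function(id, cand, dom, outcome) {
    met_at <- cand$codon_index
    prot <- make_protein(100, met_at)
    genes[[id]] <<- data.frame(gene_id = id,
                               cds = reverse_translate(prot),
                               protein = prot)
    tir_rows[[id]] <<- data.frame(gene_id = id,
                                  codon_index = cand$codon_index,
                                  tir = cand$tir)
    dom$gene_id <- id
    dom$evalue <- 1e-12
    dom_rows[[id]] <<- dom
    expected[[id]] <<- data.frame(gene_id = id, outcome = outcome)
  }
  dom_std <- data.frame(accession = c("PF05257", "PF08460"),
                        name = c("CHAP", "SH3_5"),
                        start_aa = c(5L, 85L), end_aa = c(18L, 95L))
  dom_mid <- data.frame(accession = c("PF05257", "PF08460"),
                        name = c("CHAP", "SH3_5"),
                        start_aa = c(30L, 85L), end_aa = c(60L, 95L))
  dom_tail <- rbind(dom_std,
                    data.frame(accession = "PF04865", name = "Baseplate_J",
                               start_aa = 85L, end_aa = 95L))
  for (i in 1:8)
    add_gene(sprintf("r%02d", i),
             data.frame(codon_index = c(30L, 45L, 50L, 60L, 75L),
                        tir = c(30, 31, 5000, 32, 33)),
             dom_std, "retain")
  for (i in 1:3)
    add_gene(sprintf("o%02d", i),
             data.frame(codon_index = c(30L, 45L, 50L, 60L, 75L),
                        tir = c(30, 32, 34, 36, 40)),
             dom_std, "fail_outlier")
  for (i in 1:3)
    add_gene(sprintf("e%02d", i),
             data.frame(codon_index = c(10L, 65L, 70L, 75L, 80L),
                        tir = c(5000, 30, 31, 32, 33)),
             dom_mid, "fail_edge")
  for (i in 1:3)
    add_gene(sprintf("d%02d", i),
             data.frame(codon_index = c(45L, 65L, 70L, 75L, 80L),
                        tir = c(5000, 30, 31, 32, 33)),
             dom_mid, "fail_domain")
  for (i in 1:3)
    add_gene(sprintf("t%02d", i),
             data.frame(codon_index = c(50L, 65L, 70L, 75L, 80L),
                        tir = c(5000, 30, 31, 32, 33)),
             dom_tail, "fail_tail")
  rec <- do.call(rbind, genes)
  genera <- rep_len(c("Streptococcus", "Enterococcus", "Listeria"),
                    nrow(rec))
  cohort <- LysinCohort(rec$gene_id, rec$cds, rec$protein, genera)
  domains <- domainHits(do.call(rbind, dom_rows), cohort = cohort)$hits
  list(cohort = cohort, domains = domains,
       tir_table = tirTable(do.call(rbind, tir_rows)),
       expected = do.call(rbind, expected))
}

# Minimal consistent ScreenResult with given retained/total counts, for
# functions that only consume the summary.
make_dummy_screen <- function(n_retained, n_total) {
  stopifnot(n_retained <= n_total)
  status <- rep("no_candidate", n_total)
  status[seq_len(n_retained)] <- "retained"
  ret <- status == "retained"
  calls <- data.frame(
    gene_id = sprintf("g%04d", seq_len(n_total)),
    codon_index = ifelse(ret, 50L, NA_integer_),
    start_codon = ifelse(ret, "ATG", NA_character_),
    tir = ifelse(ret, 1000, NA_real_),
    outlier_pass = ret, edge_pass = ret, domain_pass = ret,
    tail_pass = ret, status = status,
    no_domain_info = rep(FALSE, n_total), note = rep("", n_total))
  methods::new("ScreenResult", calls = calls,
               summary = list(n_total = n_total,
                              n_with_candidate = n_retained,
                              n_retained = n_retained,
                              fraction_retained =
                                if (n_total > 0) n_retained / n_total
                                else NA_real_),
               config = unclass(filterConfig()))
}
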