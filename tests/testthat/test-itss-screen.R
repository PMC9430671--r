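test_that("top-candidate selection takes the max TIR, ties to 5' side", {
  sc <- data.frame(gene_id = "g", codon_index = c(50L, 209L, 280L),
                   start_codon = "ATG", tir = c(10, 5000, 12))
  expect_equal(selectTopCandidate(sc)$codon_index, 209L)
  tie <- data.frame(gene_id = "g", codon_index = c(200L, 100L),
                    start_codon = "ATG", tir = c(7, 7))
  expect_equal(selectTopCandidate(tie)$codon_index, 100L)
  expect_null(selectTopCandidate(sc[0, ]))
  mixed <- data.frame(gene_id = c("a", "b"), codon_index = c(5L, 6L),
                      start_codon = "ATG", tir = c(1, 2))
  expect_error(selectTopCandidate(mixed), "more than one gene")
})

test_that("outlier filter implements the Tukey fence", {
  tirs <- c(10, 12, 9, 11, 5000)
  q1 <- oracle_quantile(tirs, 0.25)
  q3 <- oracle_quantile(tirs, 0.75)
  expect_gt(5000, q3 + 1.5 * (q3 - q1))
  expect_true(filterOutlier(5000, tirs))
  expect_false(filterOutlier(12, tirs))
  expect_false(filterOutlier(7, rep(7, 5)))   # degenerate: IQR 0
  expect_false(filterOutlier(100, 100))       # single candidate
  # z-score alternative
  zcfg <- filterConfig(outlier_rule = "zscore", zscore_threshold = 1.5)
  expect_true(filterOutlier(5000, tirs, zcfg))
  expect_false(filterOutlier(100, 100, zcfg))
})

test_that("edge filter boundaries are inclusive 20-AA windows", {
  expect_false(filterEdges(20, 100))
  expect_true(filterEdges(21, 100))
  expect_true(filterEdges(80, 100))
  expect_false(filterEdges(81, 100))
  expect_true(filterEdges(209, 310))
  expect_false(filterEdges(20, 40))  # protein too short for any pass
})

test_that("domain overlap uses inclusive interval membership", {
  dom <- data.frame(start_aa = 10L, end_aa = 60L)
  expect_false(filterDomainOverlap(35, dom))
  expect_false(filterDomainOverlap(10, dom))
  expect_false(filterDomainOverlap(60, dom))
  expect_true(filterDomainOverlap(61, dom))
  expect_true(filterDomainOverlap(35, dom[0, ]))
})

test_that("tail filter checks categories and the accession list", {
  ok <- data.frame(accession = c("PF05257", "PF08460"),
                   category = c("catalytic", "cwbd"))
  expect_true(filterTailDomains(ok))
  bad <- rbind(ok, data.frame(accession = "PF04865", category = "tail"))
  expect_false(filterTailDomains(bad))
  # accession list matters even without a category column
  expect_false(filterTailDomains(data.frame(accession = "PF04865")))
  expect_true(filterTailDomains(ok[0, ]))
})

test_that("the 20-gene fixture screens exactly as constructed", {
  fx <- make_screen_fixture()
  res <- runScreen(fx$cohort, fx$domains, tir_table = fx$tir_table)
  calls <- screenCalls(res)
  expect_equal(screenSummary(res)$n_retained, 8L)
  merged <- merge(calls, fx$expected, by = "gene_id")
  for (i in seq_len(nrow(merged))) {
    row <- merged[i, ]
    expect_equal(row$status == "retained", row$outcome == "retain")
    if (row$outcome != "retain") {
      flag <- c(fail_outlier = "outlier_pass", fail_edge = "edge_pass",
                fail_domain = "domain_pass",
                fail_tail = "tail_pass")[[row$outcome]]
      expect_false(row[[flag]])
      others <- setdiff(c("outlier_pass", "edge_pass", "domain_pass",
                          "tail_pass"), flag)
      expect_true(all(unlist(row[others])))
    }
  }
})

test_that("screen agrees with the brute-force oracle on small cohorts", {
  fx <- make_screen_fixture()
  res <- runScreen(fx$cohort, fx$domains, tir_table = fx$tir_table)
  orc <- oracle_screen(fx$cohort, fx$domains, fx$tir_table)
  calls <- screenCalls(res)
  m <- match(orc$gene_id, calls$gene_id)
  expect_identical(calls$status[m], orc$status)

  # also against the built-in scorer: feed its scores to the oracle as a
  # raw TIR table and compare flag-by-flag
  cc <- generateCohort(generatorConfig(n_genes = 15, seed = 23,
                                       edge_violation_rate = 0.2,
                                       domain_violation_rate = 0.2,
                                       tail_rate = 0.2), verify = FALSE)
  scored <- do.call(rbind, lapply(seq_len(length(cc$cohort)), function(i)
    scoreGene(cc$cohort[i])))
  tab <- tirTable(scored[, c("gene_id", "codon_index", "tir")])
  res2 <- runScreen(cc$cohort, cc$domains, tir_table = tab)
  orc2 <- oracle_screen(cc$cohort, cc$domains, tab)
  calls2 <- screenCalls(res2)
  m2 <- match(orc2$gene_id, calls2$gene_id)
  expect_identical(calls2$status[m2], orc2$status)
})

test_that("the four flags are independent and status a pure conjunction", {
  fx <- make_screen_fixture()
  res <- runScreen(fx$cohort, fx$domains, tir_table = fx$tir_table)
  calls <- screenCalls(res)
  plen <- stats::setNames(Biostrings::width(proteinSeqs(fx$cohort)),
                          geneIds(fx$cohort))
  for (perm in list(1:4, 4:1, c(2, 4, 1, 3))) {
    for (i in seq_len(nrow(calls))) {
      row <- calls[i, ]
      if (is.na(row$codon_index)) next
      gene_tirs <- fx$tir_table$tir[fx$tir_table$gene_id == row$gene_id]
      dom <- fx$domains[fx$domains$gene_id == row$gene_id, ]
      evals <- list(
        function() filterOutlier(row$tir, gene_tirs),
        function() filterEdges(row$codon_index, plen[[row$gene_id]]),
        function() filterDomainOverlap(row$codon_index, dom),
        function() filterTailDomains(dom))
      flags <- vapply(evals[perm], function(f) f(), logical(1))
      expect_equal(all(flags), row$status == "retained")
    }
  }
})

test_that("genes without domain annotations pass filters iii/iv, flagged", {
  prot <- make_protein(100, 50L)
  cds <- reverse_translate(prot)
  start_nt <- 3 * (50 - 1) + 1
  substr(cds, start_nt - 13, start_nt - 8) <- "AGGAGG"
  cohort <- LysinCohort("g1", cds, {
    tr <- Biostrings::translate(Biostrings::DNAString(cds),
                                genetic.code =
                                  Biostrings::getGeneticCode("11"))
    p <- sub("\\*$", "", as.character(tr)); substr(p, 1, 1) <- "M"; p
  }, "Listeria")
  res <- runScreen(cohort, domains = NULL)
  calls <- screenCalls(res)
  expect_true(calls$domain_pass && calls$tail_pass)
  expect_true(calls$no_domain_info)
  expect_match(calls$note, "no domain annotations")
})

test_that("family comparison reports fractions and their ratio", {
  target <- make_dummy_screen(515, 1000)
  control <- make_dummy_screen(152, 1000)
  cmp <- compareFamilies(target, control)
  expect_equal(cmp$target_fraction, 0.515)
  expect_equal(cmp$control_fraction, 0.152)
  expect_equal(cmp$ratio, 0.515 / 0.152, tolerance = 1e-12)
  same <- compareFamilies(target, target)
  expect_equal(same$ratio, 1)
  empty <- make_dummy_screen(0, 0)
  expect_true(is.na(compareFamilies(target, empty)$ratio))
})

test_that("an empty cohort screens to all-zero counts", {
  cc <- generateCohort(generatorConfig(n_genes = 0, seed = 1),
                       verify = FALSE)
  res <- runScreen(cc$cohort, cc$domains)
  s <- screenSummary(res)
  expect_equal(s$n_total, 0L)
  expect_equal(s$n_retained, 0L)
  expect_true(is.na(s$fraction_retained))
})
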