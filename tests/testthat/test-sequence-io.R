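test_that("packaged toy cohort reads cleanly", {
  dir <- system.file("extdata", "toy_cohort", package = "lysinITSS")
  cc <- readCohort(file.path(dir, "cds.fasta"),
                   file.path(dir, "protein.fasta"),
                   file.path(dir, "metadata.tsv"))
  expect_equal(length(cc$cohort), 3L)
  expect_equal(nrow(cc$problems), 0L)
  expect_setequal(geneIds(cc$cohort), c("G0001", "G0002", "G0003"))
})

test_that("inconsistent records are reported, not silently dropped", {
  dir <- withr::local_tempdir()
  good <- make_protein(40, 25L)
  bad <- make_protein(40)
  cds_good <- reverse_translate(good)
  cds_bad <- sub("TAA$", "GCT", reverse_translate(bad))  # stop removed
  writeLines(c(">g1", cds_good, ">g2", cds_bad),
             file.path(dir, "cds.fasta"))
  writeLines(c(">g1", good, ">g2", bad), file.path(dir, "prot.fasta"))
  writeLines(c("gene_id\thost_genus\tfamily",
               "g1\tListeria\tendolysin", "g2\tListeria\tendolysin"),
             file.path(dir, "meta.tsv"))
  cc <- readCohort(file.path(dir, "cds.fasta"),
                   file.path(dir, "prot.fasta"),
                   file.path(dir, "meta.tsv"))
  expect_equal(geneIds(cc$cohort), "g1")
  expect_equal(cc$problems$gene_id, "g2")
  expect_match(cc$problems$problem, "inconsistent")
})

test_that("empty metadata yields an empty cohort with a warning", {
  dir <- withr::local_tempdir()
  writeLines(">x\nATGTAA", file.path(dir, "c.fasta"))
  writeLines(">x\nM", file.path(dir, "p.fasta"))
  writeLines("gene_id\thost_genus\tfamily", file.path(dir, "m.tsv"))
  expect_warning(
    cc <- readCohort(file.path(dir, "c.fasta"), file.path(dir, "p.fasta"),
                     file.path(dir, "m.tsv")),
    "empty")
  expect_equal(length(cc$cohort), 0L)
})

test_that("missing metadata column is a configuration error", {
  dir <- withr::local_tempdir()
  writeLines(">x\nATGTAA", file.path(dir, "c.fasta"))
  writeLines(">x\nM", file.path(dir, "p.fasta"))
  writeLines(c("gene_id\thost_genus", "x\tListeria"),
             file.path(dir, "m.tsv"))
  expect_error(readCohort(file.path(dir, "c.fasta"),
                          file.path(dir, "p.fasta"),
                          file.path(dir, "m.tsv")),
               "family")
})

test_that("write/read round-trip reproduces every field", {
  cc <- generateCohort(generatorConfig(n_genes = 4, n_control = 2,
                                       seed = 3), verify = FALSE)
  dir <- withr::local_tempdir()
  writeCohort(cc$cohort, dir)
  back <- readCohort(file.path(dir, "cds.fasta"),
                     file.path(dir, "protein.fasta"),
                     file.path(dir, "metadata.tsv"))
  expect_equal(nrow(back$problems), 0L)
  expect_identical(geneIds(back$cohort), geneIds(cc$cohort))
  expect_identical(as.character(cdsSeqs(back$cohort)),
                   as.character(cdsSeqs(cc$cohort)))
  expect_identical(as.character(proteinSeqs(back$cohort)),
                   as.character(proteinSeqs(cc$cohort)))
  expect_identical(hostGenus(back$cohort), hostGenus(cc$cohort))
  expect_identical(familyLabel(back$cohort), familyLabel(cc$cohort))
})

test_that("admitted records always satisfy CDS/protein consistency", {
  # property: every generated record accepted by the container translates
  # back to its protein under code table 11 with the initiator read as Met
  cc <- generateCohort(generatorConfig(n_genes = 10, seed = 9),
                       verify = FALSE)
  cds <- as.character(cdsSeqs(cc$cohort))
  prot <- as.character(proteinSeqs(cc$cohort))
  for (i in seq_along(cds)) {
    expect_equal(nchar(cds[i]), 3 * (nchar(prot[i]) + 1))
    tr <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds[i]),
      genetic.code = Biostrings::getGeneticCode("11")))
    body <- substr(tr, 1, nchar(tr) - 1)
    substr(body, 1, 1) <- "M"
    expect_identical(body, unname(prot[i]))
  }
})

test_that("domain hits get categories from the map, default other", {
  hits <- data.frame(gene_id = "g1", accession = c("PF05257", "PF99999"),
                     name = c("CHAP", "mystery"),
                     start_aa = c(10L, 130L), end_aa = c(120L, 150L),
                     evalue = c(1e-20, 1e-3))
  dd <- domainHits(hits, category_map = c(PF05257 = "catalytic"))
  expect_equal(dd$hits$category, c("catalytic", "other"))
  expect_equal(nrow(dd$problems), 0L)
})

test_that("bad domain coordinates become record-level problems", {
  hits <- data.frame(gene_id = c("g1", "g1"),
                     accession = c("PF05257", "PF08460"),
                     name = c("CHAP", "SH3_5"),
                     start_aa = c(10L, 60L), end_aa = c(40L, 50L),
                     evalue = c(1e-20, 1e-8))
  dd <- domainHits(hits)
  expect_equal(nrow(dd$hits), 1L)
  expect_equal(nrow(dd$problems), 1L)
  # coordinates beyond the protein are caught when a cohort is supplied
  prot <- make_protein(30)
  cohort <- LysinCohort("g1", reverse_translate(prot), prot, "Listeria")
  dd2 <- domainHits(data.frame(gene_id = "g1", accession = "PF05257",
                               name = "CHAP", start_aa = 5L, end_aa = 50L,
                               evalue = 1e-10), cohort = cohort)
  expect_equal(nrow(dd2$hits), 0L)
  expect_equal(nrow(dd2$problems), 1L)
})

test_that("domain table file round-trips through the parser", {
  cc <- generateCohort(generatorConfig(n_genes = 3, seed = 5),
                       verify = FALSE)
  path <- withr::local_tempfile(fileext = ".txt")
  writeDomainHits(cc$domains, path)
  back <- readDomainHits(path, cohort = cc$cohort)
  expect_equal(nrow(back$problems), 0L)
  expect_equal(back$hits[, names(cc$domains)], cc$domains)
})

test_that("TIR tables validate keys and values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tcodon_index\ttir", "g1\t209\t12000"), path)
  tt <- readTirTable(path)
  expect_equal(tt$tir[tt$gene_id == "g1" & tt$codon_index == 209], 12000)

  expect_error(tirTable(data.frame(gene_id = c("g1", "g1"),
                                   codon_index = c(209L, 209L),
                                   tir = c(1, 2))),
               "duplicate.*g1 209")
  expect_error(tirTable(data.frame(gene_id = "g1", codon_index = 209L,
                                   tir = -5)),
               "positive")
  writeLines(c("gene_id\tcodon_index\ttir", "g1\t209\toops"), path)
  expect_error(readTirTable(path), "non-numeric")
})
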