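test_that("minimal annotation round-trips through the standard formats", {
  asm <- data.frame(name = "Chr01", length_bp = 100000L)
  genes <- data.frame(gene_id = "g1", chromosome = "Chr01",
                      start = 100L, end = 2100L)
  dom <- data.frame(gene_id = "g1", domain = "NBARC")
  g <- RGAGenome(asm, genes, domains = dom)
  expect_equal(geneIds(g), "g1")
  expect_equal(domainCalls(g)$domain, "NBARC")

  d <- withr::local_tempdir()
  writeAnnotation(g, file.path(d, "g.gff3"), file.path(d, "dom.tsv"))
  g2 <- readAnnotation(file.path(d, "g.gff3"), file.path(d, "dom.tsv"))
  expect_identical(as.data.frame(assemblyInfo(g2)),
                   as.data.frame(assemblyInfo(g)))
  expect_identical(names(geneRanges(g2)), "g1")
  expect_equal(start(geneRanges(g2)), 100L)
  expect_equal(end(geneRanges(g2)), 2100L)
  expect_identical(as.data.frame(domainCalls(g2)),
                   as.data.frame(domainCalls(g)))
})

test_that("full synthetic genome survives write/read unchanged", {
  g <- generateGenome(speciesProfile(n_rga = 30, n_non_rga = 10, seed = 3))
  d <- withr::local_tempdir()
  writeAnnotation(g, file.path(d, "g.gff3"), file.path(d, "dom.tsv"),
                  file.path(d, "p.fa"))
  g2 <- readAnnotation(file.path(d, "g.gff3"), file.path(d, "dom.tsv"),
                       file.path(d, "p.fa"))
  expect_identical(as.data.frame(assemblyInfo(g2)),
                   as.data.frame(assemblyInfo(g)))
  expect_identical(names(geneRanges(g2)), names(geneRanges(g)))
  expect_equal(start(geneRanges(g2)), start(geneRanges(g)))
  expect_identical(as.data.frame(domainCalls(g2)),
                   as.data.frame(domainCalls(g)))
  expect_identical(as.character(proteinSeqs(g2)),
                   as.character(proteinSeqs(g)))
})

test_that("reader output does not depend on input record order", {
  g <- generateGenome(speciesProfile(n_rga = 20, n_non_rga = 5, seed = 8))
  d <- withr::local_tempdir()
  writeAnnotation(g, file.path(d, "g.gff3"), file.path(d, "dom.tsv"))
  # shuffle the domain table rows
  dom <- read.delim(file.path(d, "dom.tsv"))
  set.seed(1)
  dom <- dom[sample.int(nrow(dom)), ]
  write.table(dom, file.path(d, "dom_shuf.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  g2 <- readAnnotation(file.path(d, "g.gff3"), file.path(d, "dom_shuf.tsv"))
  a <- as.data.frame(domainCalls(g))
  b <- as.data.frame(domainCalls(g2))
  key <- function(x) sort(paste(x$gene_id, x$domain, sep = "|"))
  expect_identical(key(b), key(a))
  # classification is identical either way
  expect_identical(classifyGenome(g2), classifyGenome(g))
})

test_that("referential integrity and label errors are hard and named", {
  asm <- data.frame(name = "Chr01", length_bp = 10000L)
  genes <- data.frame(gene_id = "g1", chromosome = "Chr01",
                      start = 1L, end = 100L)
  expect_error(
    RGAGenome(asm, genes,
              domains = data.frame(gene_id = "g9", domain = "LRR")),
    "g9")
  expect_error(
    RGAGenome(asm, rbind(genes, genes)), "g1")
  expect_error(normaliseDomainLabels("FRILLY_DOMAIN"), "FRILLY_DOMAIN")
})

test_that("domain synonyms are normalised to the canonical vocabulary", {
  expect_identical(normaliseDomainLabels(c("NB-ARC", "NBS", "Pkinase",
                                           "Coiled-coil", "LysM")),
                   c("NBARC", "NBARC", "KINASE", "CC", "LYSM"))
  # already-canonical labels pass through
  expect_identical(normaliseDomainLabels(domainVocabulary()),
                   domainVocabulary())
  d <- withr::local_tempdir()
  asm <- data.frame(name = "Chr01", length_bp = 10000L)
  genes <- data.frame(gene_id = "g1", chromosome = "Chr01",
                      start = 1L, end = 100L)
  writeAnnotation(RGAGenome(asm, genes),
                  file.path(d, "g.gff3"), file.path(d, "unused.tsv"))
  writeLines(c("gene_id\tdomain", "g1\tNB-ARC"), file.path(d, "dom.tsv"))
  g <- readAnnotation(file.path(d, "g.gff3"), file.path(d, "dom.tsv"))
  expect_identical(domainCalls(g)$domain, "NBARC")
})

test_that("hit tables parse, preserve order and reject invalid rows", {
  d <- withr::local_tempdir()
  f <- file.path(d, "hits.tsv")
  writeLines(c("RgeneA\tg1\t1e-60\t72.5\t300",
               "RgeneB\tg2\t0\t61\t200"), f)
  h <- readHits(f)
  expect_equal(h$query_id, c("RgeneA", "RgeneB"))
  expect_equal(h$evalue, c(1e-60, 0))
  expect_equal(h$similarity_pct[1], 72.5)
  expect_equal(h$aln_length_aa[1], 300L)

  writeLines(character(), f)
  expect_equal(nrow(readHits(f)), 0)

  writeLines("RgeneA\tg1\t1e-60\t101\t300", f)
  expect_error(readHits(f), "row 1")
  writeLines("RgeneA\tg1\t-1\t50\t300", f)
  expect_error(readHits(f), "row 1")
})

test_that("packaged QTL and R-gene fixtures are complete and valid", {
  qtl <- readQtlTable()
  expect_equal(nrow(qtl), 57)
  expect_true(all(qtl$disease %in% c("BL", "BR", "CR", "HR", "SSR", "WR")))
  expect_true(all(qtl$start <= qtl$end))
  # the largest blackleg interval spans a whole chromosome arm
  expect_true("LMJR2" %in% qtl$qtl_name)

  cat <- readRGeneCatalog()
  expect_equal(nrow(cat), 49)
  expect_true(all(lengths(cat$diseases) >= 1))
})
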