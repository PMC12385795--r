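test_that("the decision table assigns the canonical architectures", {
  cases <- list(
    list(c("TIR", "NBARC", "LRR"), "NLR", "TNL", "typical"),
    list(c("CC", "NBARC", "LRR"), "NLR", "CNL", "typical"),
    list(c("NBARC", "LRR", "RPW8"), "NLR", "RNL", "typical"),
    list(c("NBARC", "RPW8"), "NLR", "RN", "atypical"),
    list(c("TIR", "NBARC", "LRR", "RPW8"), "NLR", "OTHER", "atypical"),
    list(c("CC", "NBARC", "RPW8"), "NLR", "OTHER", "atypical"),
    list(c("TIR", "NBARC"), "NLR", "TN", "atypical"),
    list(c("NBARC", "LRR"), "NLR", "NL", "atypical"),
    list(c("NBARC"), "NLR", "NBS", "atypical"),
    list(c("TIR"), "NLR", "TX", "atypical"),
    list(c("TIR", "RPW8"), "NLR", "OTHER", "atypical"))
  for (cs in cases) {
    ann <- classifyDomains(cs[[1]])
    expect_equal(ann$rga_class, cs[[2]], label = paste(cs[[1]], collapse = "+"))
    expect_equal(ann$nlr_subtype, cs[[3]], label = paste(cs[[1]], collapse = "+"))
    expect_equal(ann$typical, cs[[4]], label = paste(cs[[1]], collapse = "+"))
  }
})

test_that("receptor classes subclass by ectodomain and need a membrane", {
  rlk <- classifyDomains(c("TM", "KINASE", "LRR"))
  expect_equal(rlk$rga_class, "RLK")
  expect_equal(rlk$receptor_subclass, "LRR")
  expect_equal(rlk$superfamily, "TM-LRR")
  expect_equal(classifyDomains(c("TM", "KINASE", "LYSM"))$receptor_subclass,
               "LYSM")
  expect_equal(classifyDomains(c("TM", "KINASE"))$receptor_subclass,
               "OTHER_RECEPTOR")
  rlp <- classifyDomains(c("TM", "LRR"))
  expect_equal(rlp$rga_class, "RLP")
  expect_equal(rlp$receptor_subclass, "LRR")
  # orphan signatures are not receptors
  expect_equal(classifyDomains(c("KINASE", "LRR"))$rga_class, "NONE")
  expect_equal(classifyDomains(c("TM", "CC"))$rga_class, "TMCC")
  expect_equal(classifyDomains("RPW8")$rga_class, "RPW8")
  expect_equal(classifyDomains(character())$rga_class, "NONE")
})

test_that("typical flag partitions the NLR-side subtypes", {
  expect_equal(typicalFlag("TNL"), "typical")
  expect_equal(typicalFlag("RNL"), "typical")
  expect_equal(typicalFlag("TX"), "atypical")
  expect_equal(typicalFlag("NBS"), "atypical")
  expect_error(typicalFlag("RLK"), "subtype")
})

test_that("classification is total and deterministic over all 512 subsets", {
  voc <- domainVocabulary()
  fields <- c("rga_class", "nlr_subtype", "receptor_subclass",
              "typical", "superfamily")
  for (mask in 0:(2^length(voc) - 1)) {
    doms <- voc[bitwAnd(mask, 2^(seq_along(voc) - 1)) > 0]
    ann <- classifyDomains(doms)
    ann2 <- classifyDomains(rev(doms))
    expect_identical(ann, ann2)
    expect_true(all(vapply(ann[fields], length, 0L) == 1))
    # structural invariants of the annotation
    expect_equal(ann$nlr_subtype != "none", ann$rga_class == "NLR")
    expect_equal(ann$receptor_subclass != "none",
                 ann$rga_class %in% c("RLK", "RLP"))
    expect_equal(ann$superfamily == "TM-LRR",
                 ann$rga_class %in% c("RLK", "RLP"))
    expect_equal(ann$typical %in% c("typical", "atypical"),
                 ann$nlr_subtype != "none")
    # the RPW8 reclassification acts inside the NLR side: an NBARC or
    # TIR gene keeps class NLR whether or not RPW8 is present
    if (any(c("NBARC", "TIR") %in% doms))
      expect_equal(ann$rga_class, "NLR")
  }
  expect_error(classifyDomains("WRKY"), "WRKY")
})

test_that("count table mirrors the published layout and sums consistently", {
  asm <- data.frame(name = c("Chr01", "Contig 001"),
                    length_bp = c(2e6L, 5e4L))
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"),
    chromosome = c("Chr01", "Chr01", "Chr01", "Contig 001"),
    start = c(1000L, 5000L, 9000L, 100L),
    end = c(2000L, 6000L, 10000L, 900L))
  dom <- data.frame(
    gene_id = c("g1", "g1", "g1", "g2", "g2", "g2", "g4"),
    domain = c("TIR", "NBARC", "LRR", "TM", "KINASE", "LRR", "NBARC"))
  g <- RGAGenome(asm, genes, domains = dom)
  ann <- classifyGenome(g)
  tab <- rgaCountTable(ann, g)
  expect_equal(tab$chromosome, c("Chr01", "Contig 001", "Total"))
  tot <- tab[tab$chromosome == "Total", ]
  expect_equal(tot$total, 3)   # g3 has no domains
  expect_equal(tot$tnl, 1)
  expect_equal(tot$rlk, 1)
  expect_equal(tot$lrr_rlk, 1)
  expect_equal(tot$other, 1)   # bare NBS is tabulated under OTHER
  # per-row class columns sum to the row total
  sub_cols <- c("rlk", "rlp", "tm_cc", "tnl", "cnl", "rnl", "tx", "tn",
                "nl", "rn", "cn", "other", "rpw8")
  expect_equal(rowSums(tab[sub_cols]), tab$total, ignore_attr = TRUE)

  # permuting gene order leaves the table unchanged
  perm <- c(3, 1, 4, 2)
  g2 <- RGAGenome(asm, genes[perm, ], domains = dom)
  expect_identical(rgaCountTable(classifyGenome(g2), g2), tab)
})

test_that("planted class labels are recovered from generated genomes", {
  g <- generateGenome(speciesProfile(n_rga = 300, n_non_rga = 60,
                                     seed = 21))
  ann <- classifyGenome(g)
  truth <- groundTruth(g)$classes[ann$gene_id]
  expected <- plantedExpectation(truth)
  expect_identical(ann$rga_class, expected$rga_class)
  expect_identical(ann$nlr_subtype, expected$nlr_subtype)
  expect_identical(ann$receptor_subclass, expected$receptor_subclass)
  expect_identical(ann$superfamily, expected$superfamily)
  # subtype counts aggregate to the NLR-side total
  tab <- rgaCountTable(ann, g)
  tot <- tab[tab$chromosome == "Total", ]
  nlr_total <- sum(ann$rga_class == "NLR")
  expect_equal(sum(tot[c("tnl", "cnl", "rnl", "tx", "tn", "nl", "rn",
                         "cn", "other")]), nlr_total)
  expect_equal(sum(ann$typical == "typical") +
                 sum(ann$typical == "atypical"), nlr_total)
})
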