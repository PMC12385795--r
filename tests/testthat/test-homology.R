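hit_row <- function(e, s, l, q = "R1", subj = "g1") {
  data.frame(query_id = q, subject_id = subj, evalue = e,
             similarity_pct = s, aln_length_aa = l)
}

test_that("the three filter rules and their boundaries", {
  expect_equal(nrow(filterHits(hit_row(0, 80, 300))), 1)       # E0 end
  expect_equal(nrow(filterHits(hit_row(1e-45, 80, 300))), 1)   # inclusive
  expect_equal(nrow(filterHits(hit_row(1e-30, 90, 300))), 0)   # too weak
  expect_equal(nrow(filterHits(hit_row(1e-60, 59.9, 300))), 0)
  expect_equal(nrow(filterHits(hit_row(1e-60, 60, 300))), 1)
  expect_equal(nrow(filterHits(hit_row(1e-60, 90, 147))), 0)
  expect_equal(nrow(filterHits(hit_row(1e-60, 90, 148))), 1)
})

test_that("filtering is monotone in its thresholds and order-stable", {
  set.seed(23)
  hits <- data.frame(
    query_id = sample(paste0("R", 1:5), 200, TRUE),
    subject_id = sample(paste0("g", 1:50), 200, TRUE),
    evalue = 10^-runif(200, 0, 120),
    similarity_pct = runif(200, 0, 100),
    aln_length_aa = sample(50:400, 200, TRUE))
  kept <- filterHits(hits)
  relaxed <- filterHits(hits, e_max = 1e-30, sim_min = 40, len_min_aa = 100)
  tightened <- filterHits(hits, e_max = 1e-60, sim_min = 80,
                          len_min_aa = 200)
  key <- function(h) paste(h$query_id, h$subject_id, h$evalue)
  expect_true(all(key(kept) %in% key(relaxed)))
  expect_true(all(key(tightened) %in% key(kept)))
  # kept set independent of row order
  perm <- hits[sample.int(nrow(hits)), ]
  expect_setequal(key(filterHits(perm)), key(kept))
  # order preserved within the kept subset
  expect_identical(kept, hits[rownames(kept), ])
})

test_that("on synthetic tables the filter keeps exactly the planted pairs", {
  g <- generateGenome(speciesProfile(n_rga = 100, n_non_rga = 20,
                                     seed = 31))
  sim <- simulateHits(g, n_decoys = 12, seed = 4)
  kept <- filterHits(sim$hits)
  key <- function(q, s) paste(q, s)
  expect_setequal(key(kept$query_id, kept$subject_id),
                  key(sim$manifest$query_id,
                      sim$manifest$subject_id)[sim$manifest$planted])
  # every decoy violates exactly the one rule recorded for it
  decoys <- sim$hits[!sim$manifest$planted, ]
  rules <- sim$manifest$violated_rule[!sim$manifest$planted]
  fails <- cbind(evalue = decoys$evalue > 1e-45,
                 similarity = decoys$similarity_pct < 60,
                 length = decoys$aln_length_aa < 148)
  expect_true(all(rowSums(fails) == 1))
  expect_identical(colnames(fails)[apply(fails, 1, which)], rules)
  # without decoys everything survives
  expect_equal(nrow(filterHits(simulateHits(g, 0, 1)$hits)),
               nrow(groundTruth(g)$homologues))
})

test_that("CDRH aggregation counts many-to-many relations correctly", {
  ann <- data.frame(gene_id = c("g1", "g2", "g3"),
                    rga_class = c("NLR", "RLK", "NONE"),
                    nlr_subtype = c("TNL", "none", "none"),
                    receptor_subclass = c("none", "LRR", "none"),
                    typical = c("typical", "n/a", "n/a"),
                    superfamily = c("NLR", "TM-LRR", "none"))
  catalog <- data.frame(r_gene_id = c("RA", "RB"),
                        diseases = I(list(c("WR", "BL"), "WR")))
  hits <- rbind(hit_row(1e-60, 80, 300, "RA", "g1"),
                hit_row(1e-60, 80, 300, "RB", "g1"),
                hit_row(1e-60, 80, 300, "RA", "g3"))
  kept <- filterHits(hits)
  cdrh <- cdrhMap(kept, ann, catalog)
  expect_equal(cdrh$summary$n_cdrh, 1)
  expect_equal(cdrh$summary$n_multi_match_cdrh, 1)
  expect_equal(cdrh$records$matched_r_genes[[1]], c("RA", "RB"))
  expect_equal(cdrh$records$diseases[[1]], c("BL", "WR"))
  expect_equal(unname(cdrh$summary$class_composition[["TNL"]]), 1)
  # the non-RGA side picks up g3 and the two sides partition subjects
  non <- nonRgaHomologues(kept, ann, catalog)
  expect_equal(non$records$gene_id, "g3")
  expect_length(intersect(cdrh$records$gene_id, non$records$gene_id), 0)
  expect_setequal(c(cdrh$records$gene_id, non$records$gene_id),
                  unique(kept$subject_id))
  # unknown subject is a hard error
  expect_error(cdrhMap(hit_row(1e-60, 80, 300, "RA", "gX"), ann, catalog),
               "gX")
  # empty input gives empty summaries
  empty <- cdrhMap(kept[0, ], ann, catalog)
  expect_equal(empty$summary$n_cdrh, 0)
  expect_equal(empty$summary$n_r_genes_with_homologue, 0)
})

test_that("a run mirroring the reported shape counts 10 homologues", {
  ann <- data.frame(gene_id = paste0("g", 1:10),
                    rga_class = "NLR", nlr_subtype = "TNL",
                    receptor_subclass = "none", typical = "typical",
                    superfamily = "NLR")
  catalog <- data.frame(r_gene_id = "At_WRR9", diseases = I(list("WR")))
  hits <- do.call(rbind, lapply(paste0("g", 1:10), function(s)
    hit_row(1e-60, 85, 250, "At_WRR9", s)))
  cdrh <- cdrhMap(filterHits(hits), ann, catalog)
  expect_equal(unname(cdrh$summary$per_r_gene_counts[["At_WRR9"]]), 10)
  expect_equal(cdrh$summary$n_r_genes_multiple, 1)
})

test_that("disease rollup deduplicates within and unions across diseases", {
  catalog <- data.frame(r_gene_id = c("RA", "RB", "RC"),
                        diseases = I(list("WR", "WR", c("BL", "WR"))))
  ann <- data.frame(gene_id = c("g1", "g2"), rga_class = "RLK",
                    nlr_subtype = "none", receptor_subclass = "LRR",
                    typical = "n/a", superfamily = "TM-LRR")
  hits <- rbind(hit_row(1e-60, 80, 300, "RA", "g1"),
                hit_row(1e-60, 80, 300, "RB", "g1"),
                hit_row(1e-60, 80, 300, "RC", "g2"))
  cdrh <- cdrhMap(filterHits(hits), ann, catalog)
  roll <- diseaseRollup(cdrh$records, catalog)
  expect_equal(unname(roll[["WR"]]), 2)  # g1 counted once despite RA+RB
  expect_equal(unname(roll[["BL"]]), 1)
  bad <- cdrh$records
  bad$matched_r_genes[[1]] <- "RZ"
  expect_error(diseaseRollup(bad, catalog), "RZ")
})
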