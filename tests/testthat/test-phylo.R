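test_that("p-distance uses pairwise deletion of gapped columns", {
  expect_equal(pDistance("AAAA", "AAAA"), 0)
  expect_equal(pDistance("AR-ND", "AKCND"), 0.25)
  expect_equal(pDistance("AAAA", "RRRR"), 1)
  expect_error(pDistance("AA", "AAA"), "equal length")
  expect_error(pDistance("--A", "A--"), "comparable")
})

test_that("Jukes-Cantor protein correction matches its closed form", {
  expect_equal(jcProtein(0), 0)
  expect_equal(jcProtein(0.5), -(19 / 20) * log(1 - (20 / 19) * 0.5))
  expect_equal(jcProtein(0.5), 0.70985, tolerance = 1e-4)
  expect_error(jcProtein(0.95), "saturated")
  expect_error(jcProtein(-0.1), "non-negative")
  p <- seq(0, 0.9, by = 0.05)
  d <- vapply(p, jcProtein, 0)
  expect_true(all(d >= p))            # correction inflates
  expect_true(all(diff(d) > 0))       # strictly increasing
  # numeric inversion recovers p to machine-level accuracy
  for (p0 in c(0.05, 0.3, 0.7)) {
    p_hat <- stats::uniroot(function(x) jcProtein(x) - jcProtein(p0),
                            c(0, 0.94), tol = 1e-14)$root
    expect_lt(abs(p_hat - p0), 1e-12)
  }
})

test_that("UPGMA on hand-worked cases", {
  d2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"),
                                                 c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(toNewick(t2), "(A:0.5,B:0.5);")
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(d3)
  expect_equal(unname(t3$heights), c(1, 2))
  cop <- ape::cophenetic.phylo(t3$phylo)
  expect_equal(cop["A", "B"], 2)
  expect_equal(cop["A", "C"], 4)
  expect_error(upgma(matrix(c(0, 1, 2, 0), 2,
                            dimnames = list(c("A", "B"), c("A", "B")))),
               "symmetric")
})

test_that("UPGMA equals the independent average-linkage reference", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(3:6, 1)
    m <- matrix(runif(n * n), n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    labs <- paste0("t", seq_len(n))
    dimnames(m) <- list(labs, labs)
    tr <- upgma(m)
    hc <- hclust(as.dist(m), method = "average")
    cop_tree <- ape::cophenetic.phylo(tr$phylo)[labs, labs]
    cop_ref <- as.matrix(cophenetic(hc))[labs, labs]
    expect_equal(cop_tree, cop_ref, tolerance = 1e-8)
    # ultrametricity: merge heights non-decreasing root-wards
    expect_true(all(diff(sort(tr$heights)) >= 0))
    expect_true(ape::is.ultrametric(tr$phylo, tol = 1e-8))
  }
})

test_that("UPGMA reconstructs ultrametric input exactly", {
  # distances generated from a known ultrametric tree
  set.seed(5)
  base <- upgma(local({
    n <- 6
    m <- matrix(runif(36), 6); m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(letters[1:6], letters[1:6])
    m
  }))
  d_ultra <- ape::cophenetic.phylo(base$phylo)[letters[1:6], letters[1:6]]
  rebuilt <- upgma(d_ultra)
  expect_equal(ape::cophenetic.phylo(rebuilt$phylo)[letters[1:6],
                                                    letters[1:6]],
               d_ultra, tolerance = 1e-10)
})

test_that("bootstrap supports are deterministic and signal-responsive", {
  base <- strrep("A", 10)
  aln <- c(a1 = paste0(base, "CCCCCCCCCC"), a2 = paste0(base, "CCCCCCCCCG"),
           a3 = paste0(base, "CCCCCCCCGG"), b1 = paste0(base, "WWWWWWWWWW"),
           b2 = paste0(base, "WWWWWWWWWR"), b3 = paste0(base, "WWWWWWWWRR"))
  bt <- bootstrapSupports(aln, n_reps = 100, seed = 5)
  expect_gte(bt$supports[["a1;a2;a3"]], 95)
  expect_gte(bt$supports[["b1;b2;b3"]], 95)
  expect_true(all(bt$supports >= 0 & bt$supports <= 100))
  bt2 <- bootstrapSupports(aln, n_reps = 100, seed = 5)
  expect_identical(bt$supports, bt2$supports)
  # two taxa: the single clade is trivially always present
  two <- bootstrapSupports(c(x = "AACC", y = "AAGG"), n_reps = 10, seed = 1)
  expect_equal(unname(two$supports), 100)
})

test_that("Newick export round-trips topology, lengths and labels", {
  set.seed(55)
  for (rep in 1:10) {
    n <- sample(3:7, 1)
    m <- matrix(runif(n * n), n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    labs <- paste0("leaf", seq_len(n))
    dimnames(m) <- list(labs, labs)
    tr <- upgma(m)
    back <- ape::read.tree(text = toNewick(tr))
    expect_setequal(back$tip.label, labs)
    expect_equal(ape::cophenetic.phylo(back)[labs, labs],
                 ape::cophenetic.phylo(tr$phylo)[labs, labs],
                 tolerance = 1e-8)
  }
  # labels with spaces are written under the underscore convention and
  # survive the round trip; the original labels stay on the tree object
  d <- matrix(c(0, 1, 1, 0), 2,
              dimnames = list(c("gene one", "gene two"),
                              c("gene one", "gene two")))
  tr <- upgma(d)
  nw <- toNewick(tr)
  expect_match(nw, "gene_one", fixed = TRUE)
  back <- ape::read.tree(text = nw)
  expect_setequal(back$tip.label, c("gene_one", "gene_two"))
  expect_setequal(tr$leaf_labels, c("gene one", "gene two"))
})
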