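#' Physical clustering of genes within a genomic distance threshold
#'
#' Per chromosome, genes are sorted by start; the gap between neighbours
#' is `start(next) - end(previous)` (1-based closed intervals, so
#' abutting genes have gap 1 and overlapping genes a non-positive gap).
#' Maximal runs in which every consecutive gap is `<= threshold_bp` and
#' holding at least two genes form clusters; singletons are not clusters.
#' The boundary is inclusive: a gap exactly equal to the threshold still
#' clusters.
#'
#' @param x an [RGAGenome-class], or a named `GRanges` of genes
#' @param threshold_bp maximum intergenic distance within a cluster
#'   (default 10 kb)
#' @param gene_ids optional subset of gene ids (e.g. one RGA family)
#' @param annotations optional [classifyGenome()] output used to report
#'   clustered-gene counts per class/subtype
#' @return List with `clusters` (a `data.frame` with `chromosome`,
#'   `span_start`, `span_end`, `n_members` and a list-column `members`
#'   of gene ids sorted by start), `clustered_genes` (character vector)
#'   and, when annotations are given, `class_counts` (table of clustered
#'   genes per reporting category).
#' @export
#' @examples
#' asm <- data.frame(name = "Chr01", length_bp = 1e5)
#' g <- data.frame(gene_id = c("a", "b", "c"), chromosome = "Chr01",
#'                 start = c(1000, 5000, 25000), end = c(2000, 6000, 26000))
#' physicalClusters(RGAGenome(asm, g))$clusters$n_members  # one cluster of 2
physicalClusters <- function(x, threshold_bp = 10000, gene_ids = NULL,
                             annotations = NULL) {
  if (threshold_bp < 0) stop("threshold_bp must be non-negative")
  gr <- if (is(x, "RGAGenome")) geneRanges(x) else x
  if (!is.null(gene_ids)) gr <- gr[intersect(names(gr), gene_ids)]
  rows <- list()
  for (ch in unique(as.character(seqnames(gr)))) {
    g <- gr[as.character(seqnames(gr)) == ch]
    ord <- order(start(g), end(g), names(g))
    g <- g[ord]
    if (length(g) < 2) next
    gaps <- start(g)[-1] - end(g)[-length(g)]
    run <- cumsum(c(0L, as.integer(gaps > threshold_bp)))
    for (r in split(seq_along(g), run)) {
      if (length(r) < 2) next
      rows[[length(rows) + 1]] <- data.frame(
        chromosome = ch,
        span_start = min(start(g)[r]),
        span_end = max(end(g)[r]),
        n_members = length(r),
        members = I(list(names(g)[r])))
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chromosome = character(), span_start = integer(),
               span_end = integer(), n_members = integer(),
               members = I(list()))
  clustered <- unlist(clusters$members, use.names = FALSE)
  out <- list(clusters = clusters,
              clustered_genes = if (is.null(clustered)) character()
                                else clustered)
  if (!is.null(annotations) && length(out$clustered_genes)) {
    ann <- annotations[match(out$clustered_genes, annotations$gene_id), ]
    cat <- ifelse(ann$rga_class == "NLR", ann$nlr_subtype, ann$rga_class)
    out$class_counts <- table(cat)
  }
  out
}

#' Default RGA family partition
#'
#' Partition gene ids into the family units used for per-family physical
#' clustering: NLR (all subtypes pooled, TX and OTHER included), RLK,
#' RLP, TM-CC and RPW8.
#'
#' @param annotations output of [classifyGenome()]
#' @return Named list of gene-id vectors.
#' @export
rgaFamilies <- function(annotations) {
  keep <- annotations$rga_class != "NONE"
  split(annotations$gene_id[keep], annotations$rga_class[keep])
}

#' Pairwise global-alignment similarity matrix
#'
#' Global (Needleman-Wunsch) alignment of each protein pair with a stated
#' toy scoring scheme (match +1, mismatch -1, linear gap -2 by default);
#' similarity is the fraction of alignment columns that match. The
#' scoring is deliberately simple and configurable; it is a device for
#' recovering relative similarity structure, not a substitution model.
#'
#' @param sequences a named [Biostrings::AAStringSet] (>= 2 sequences,
#'   none empty)
#' @param match,mismatch,gap alignment scores (gap is the linear
#'   per-residue gap penalty)
#' @return Symmetric numeric matrix in `[0, 1]` with unit diagonal,
#'   dimnames from the sequence names.
#' @export
pairwiseSimilarity <- function(sequences, match = 1, mismatch = -1,
                               gap = -2) {
  n <- length(sequences)
  if (n < 2) stop("need at least 2 sequences")
  if (any(width(sequences) == 0)) stop("empty sequence")
  alphabet <- unique(unlist(strsplit(as.character(sequences), "")))
  sub <- matrix(mismatch, length(alphabet), length(alphabet),
                dimnames = list(alphabet, alphabet))
  diag(sub) <- match
  sim <- diag(1, n)
  dimnames(sim) <- list(names(sequences), names(sequences))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      aln <- Biostrings::pairwiseAlignment(
        sequences[[i]], sequences[[j]], type = "global",
        substitutionMatrix = sub, gapOpening = 0, gapExtension = -gap)
      cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
      sim[i, j] <- sim[j, i] <- Biostrings::nmatch(aln) / cols
    }
  }
  sim
}

#' Cut an average-linkage dendrogram into k similarity clusters
#'
#' Agglomerative average-linkage clustering on distance
#' `1 - similarity`, cut into exactly `k` groups, with an optional
#' composition table by superfamily (TM-LRR, NLR, TM-CC, RPW8).
#'
#' @param similarity symmetric similarity matrix as from
#'   [pairwiseSimilarity()]
#' @param k number of clusters, `1 <= k <= n`
#' @param annotations optional [classifyGenome()] output for the
#'   composition table
#' @return List with `assignment` (named integer vector), `tree` (the
#'   `hclust` object) and optionally `composition` (cluster x
#'   superfamily table).
#' @export
dendrogramClusters <- function(similarity, k, annotations = NULL) {
  n <- nrow(similarity)
  if (k < 1 || k > n) stop("k must be in [1, n]")
  if (!isTRUE(all.equal(similarity, t(similarity))))
    stop("similarity matrix must be symmetric")
  tree <- hclust(as.dist(1 - similarity), method = "average")
  assignment <- cutree(tree, k = k)
  out <- list(assignment = assignment, tree = tree)
  if (!is.null(annotations)) {
    sf <- annotations$superfamily[
      match(names(assignment), annotations$gene_id)]
    out$composition <- table(cluster = assignment, superfamily = sf)
  }
  out
}
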