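#' Observed proportion of differing sites (p-distance)
#'
#' Pairwise deletion: columns where either sequence has a gap (`-` or
#' `.`) are dropped; `p` is the mismatch fraction over the remaining
#' columns. Case-insensitive.
#'
#' @param seq_a,seq_b aligned amino-acid strings of equal length
#' @return `p` in `[0, 1]`.
#' @export
#' @examples
#' pDistance("AR-ND", "AKCND")  # 1 mismatch over 4 comparable columns
pDistance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop("aligned sequences must be equal length")
  ok <- !(a %in% c("-", ".")) & !(b %in% c("-", "."))
  if (!any(ok)) stop("no comparable (both non-gap) columns")
  mean(a[ok] != b[ok])
}

#' Jukes-Cantor protein distance
#'
#' Multiple-hit correction for a 20-state alphabet:
#' `d = -(19/20) * log(1 - (20/19) * p)`. Undefined at saturation
#' (`p >= 19/20`).
#'
#' @param p observed mismatch proportion, `0 <= p < 19/20`
#' @return Corrected distance `d >= p`.
#' @export
#' @examples
#' jcProtein(0.5)  # ~0.70985
jcProtein <- function(p) {
  if (any(p < 0)) stop("p must be non-negative")
  if (any(p >= 19 / 20)) stop("p >= 19/20: distance saturated")
  -(19 / 20) * log(1 - (20 / 19) * p)
}

#' Jukes-Cantor distance matrix from an alignment
#'
#' Applies [pDistance()] with pairwise deletion to every sequence pair
#' and corrects with [jcProtein()].
#'
#' @param alignment named character vector or `AAStringSet` of aligned
#'   sequences (equal lengths)
#' @return Symmetric distance matrix with zero diagonal.
#' @export
jcDistanceMatrix <- function(alignment) {
  if (is(alignment, "XStringSet"))
    alignment <- setNames(as.character(alignment), names(alignment))
  n <- length(alignment)
  if (n < 2) stop("need at least 2 sequences")
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <-
        jcProtein(pDistance(alignment[[i]], alignment[[j]]))
    }
  }
  d
}

#' UPGMA tree from a distance matrix
#'
#' Size-weighted average-linkage agglomeration: at each step the two
#' clusters at minimal average distance are merged at height
#' `distance / 2`; ties are broken by the lexicographically smallest
#' pair of cluster labels (a cluster is labelled by its smallest leaf),
#' making the result platform-independent. The tree is rooted,
#' ultrametric and returned as an [ape] `phylo` with a `node_heights`
#' attribute.
#'
#' @param d symmetric distance matrix with labelled dimnames
#' @return Object of class `upgmaTree`: list with `phylo`, `heights`
#'   (named by internal node), and `leaf_labels`.
#' @export
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgma(d)$heights  # A,B join at 1; C at 2
upgma <- function(d) {
  if (!isTRUE(all.equal(d, t(d))))
    stop("distance matrix must be symmetric")
  labels <- rownames(d)
  n <- length(labels)
  if (n < 2) stop("need at least 2 taxa")
  # Newick-safe tip labels: whitespace and structural characters become
  # underscores (the convention ape's Newick dialect uses)
  safe <- make.unique(gsub("[^-A-Za-z0-9_.|]", "_", labels), sep = "_")
  # active clusters: label = smallest member, with newick fragment,
  # height and size
  cl <- lapply(seq_len(n), function(i)
    list(key = labels[i], newick = safe[i],
         height = 0, size = 1L))
  names(cl) <- labels
  dd <- d
  heights <- numeric(0)
  merge_id <- 0L
  while (length(cl) > 1) {
    keys <- names(cl)
    m <- dd[keys, keys, drop = FALSE]
    diag(m) <- Inf
    best <- min(m)
    # candidate pairs at the minimum; lexicographically smallest pair wins
    idx <- which(m <= best + 0, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    pair_lab <- t(apply(idx, 1, function(r) sort(keys[r])))
    ord <- order(pair_lab[, 1], pair_lab[, 2])
    a <- pair_lab[ord[1], 1]; b <- pair_lab[ord[1], 2]
    h <- best / 2
    merge_id <- merge_id + 1L
    node <- paste0("node", merge_id)
    heights[node] <- h
    ca <- cl[[a]]; cb <- cl[[b]]
    newick <- sprintf("(%s:%s,%s:%s)",
                      ca$newick, format(h - ca$height, digits = 15),
                      cb$newick, format(h - cb$height, digits = 15))
    # size-weighted average distance to every other cluster
    others <- setdiff(keys, c(a, b))
    new_key <- min(a, b)
    if (length(others)) {
      newd <- setNames(
        (ca$size * dd[a, others] + cb$size * dd[b, others]) /
          (ca$size + cb$size), others)
      dd <- dd[others, others, drop = FALSE]
      dd <- rbind(cbind(dd, newd[others]), c(newd[others], 0))
      rownames(dd)[nrow(dd)] <- colnames(dd)[ncol(dd)] <- new_key
    } else {
      dd <- matrix(0, 1, 1, dimnames = list(new_key, new_key))
    }
    cl[[a]] <- NULL; cl[[b]] <- NULL
    cl[[new_key]] <- list(key = new_key, newick = newick, height = h,
                          size = ca$size + cb$size)
  }
  tree_str <- paste0(cl[[1]]$newick, ";")
  phy <- ape::read.tree(text = tree_str)
  structure(list(phylo = phy, heights = heights, leaf_labels = labels),
            class = "upgmaTree")
}

#' @export
print.upgmaTree <- function(x, ...) {
  cat("UPGMA tree with", length(x$leaf_labels), "leaves; root height",
      format(max(x$heights), digits = 4), "\n")
  if (!is.null(x$supports))
    cat("  bootstrap supports on", length(x$supports), "clades\n")
  invisible(x)
}

# rooted clade leaf sets of a phylo, as sorted ";"-joined strings keyed
# by internal node number
clade_keys <- function(phy) {
  n_tip <- length(phy$tip.label)
  nodes <- seq(n_tip + 1, n_tip + phy$Nnode)
  tips <- lapply(nodes, function(nd)
    sort(ape::extract.clade(phy, nd)$tip.label))
  setNames(vapply(tips, paste, "", collapse = ";"), nodes)
}

#' Bootstrap supports for a UPGMA tree
#'
#' Builds the tree on the full alignment, then resamples alignment
#' columns with replacement `n_reps` times; each replicate is run
#' through the same distance + UPGMA path and a clade's support is the
#' percentage of usable replicates containing a clade with the same
#' leaf set. Replicates in which some pair has no comparable column (or
#' is saturated) are skipped with a warning and the denominator
#' adjusted. Deterministic given `seed`.
#'
#' @param alignment named character vector or `AAStringSet` of aligned
#'   sequences
#' @param n_reps number of bootstrap replicates (default 1000)
#' @param seed integer seed
#' @return An `upgmaTree` with a `supports` element (percent, named by
#'   clade leaf-set key) and node labels on the `phylo` set to supports.
#' @export
bootstrapSupports <- function(alignment, n_reps = 1000, seed = 1) {
  if (is(alignment, "XStringSet"))
    alignment <- setNames(as.character(alignment), names(alignment))
  if (length(alignment) < 2) stop("need at least 2 sequences")
  if (n_reps < 1) stop("n_reps must be >= 1")
  tree <- upgma(jcDistanceMatrix(alignment))
  keys <- clade_keys(tree$phylo)
  counts <- setNames(numeric(length(keys)), keys)
  L <- nchar(alignment[[1]])
  mat <- do.call(rbind, strsplit(toupper(unlist(alignment)), ""))
  rownames(mat) <- names(alignment)
  set.seed(seed)
  used <- 0L
  skipped <- 0L
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_aln <- apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
    rep_tree <- tryCatch(upgma(jcDistanceMatrix(rep_aln)),
                         error = function(e) NULL)
    if (is.null(rep_tree)) { skipped <- skipped + 1L; next }
    used <- used + 1L
    rep_keys <- clade_keys(rep_tree$phylo)
    hit <- names(counts) %in% rep_keys
    counts[hit] <- counts[hit] + 1
  }
  if (skipped > 0)
    warning(skipped, " replicate(s) skipped (no comparable columns or ",
            "saturated pair); support denominator is ", used)
  if (used == 0) stop("no usable bootstrap replicates")
  supports <- 100 * counts / used
  tree$supports <- supports
  tree$n_replicates_used <- used
  # attach supports as internal node labels in node-number order
  n_tip <- length(tree$phylo$tip.label)
  node_keys <- clade_keys(tree$phylo)
  tree$phylo$node.label <- format(round(supports[node_keys], 1),
                                  trim = TRUE)
  tree
}

#' Export a tree as Newick
#'
#' Branch lengths always written; bootstrap supports (when present) as
#' internal node labels. Leaf labels follow the Newick convention of
#' [ape]: whitespace and structural characters are replaced with
#' underscores when the tree is built. The string parses back (via
#' [ape::read.tree()]) to a tree with identical topology, heights and
#' labels.
#'
#' @param tree an `upgmaTree`
#' @param file optional path; when given the string is also written out
#' @return The Newick string, invisibly when `file` is given.
#' @export
toNewick <- function(tree, file = NULL) {
  str <- ape::write.tree(tree$phylo)
  if (!is.null(file)) {
    writeLines(str, file)
    return(invisible(str))
  }
  str
}
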