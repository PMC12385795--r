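# small builders shared across test files

tiny_genome <- function(genes, assembly = NULL, domains = NULL) {
  if (is.null(assembly))
    assembly <- data.frame(
      name = unique(genes$chromosome),
      length_bp = max(genes$end) + 1e5)
  RGAGenome(assembly, genes, domains = domains)
}

# brute-force physical clustering oracle: transitive closure of the
# "within threshold" relation over all gene pairs on a chromosome
brute_force_clusters <- function(df, threshold) {
  out <- list()
  for (ch in unique(df$chromosome)) {
    g <- df[df$chromosome == ch, ]
    n <- nrow(g)
    if (n < 2) next
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        gap <- max(g$start[i], g$start[j]) - min(g$end[i], g$end[j])
        adj[i, j] <- gap <= threshold
      }
    }
    # connected components by repeated expansion
    seen <- rep(FALSE, n)
    for (i in seq_len(n)) {
      if (seen[i]) next
      comp <- i
      repeat {
        grow <- which(apply(adj[comp, , drop = FALSE], 2, any) & !seen)
        grow <- setdiff(grow, comp)
        if (!length(grow)) break
        comp <- c(comp, grow)
        seen[comp] <- TRUE
      }
      seen[comp] <- TRUE
      if (length(comp) >= 2) {
        ord <- comp[order(g$start[comp])]
        out[[length(out) + 1]] <- g$gene_id[ord]
      }
    }
  }
  out
}

# plain Rand index between two partitions
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
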