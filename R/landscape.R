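#' RGA density per chromosome
#'
#' Count per megabase, reported with round-half-even at `digits`
#' decimals (set `digits = NULL` for the raw ratio).
#'
#' @param count integer RGA count
#' @param length_mbp chromosome length in Mbp (> 0)
#' @param digits decimals for reporting (default 2)
#' @return Numeric vector of densities (RGA/Mbp).
#' @export
#' @examples
#' rgaDensity(131, 54.73)  # 2.39
rgaDensity <- function(count, length_mbp, digits = 2) {
  if (any(length_mbp <= 0)) stop("chromosome length must be positive")
  d <- count / length_mbp
  if (is.null(digits)) d else round(d, digits)
}

strip_total_row <- function(count_table) {
  count_table[count_table$chromosome != "Total", , drop = FALSE]
}

#' Species-level landscape summary
#'
#' Headline statistics from a per-chromosome count table: the species RGA
#' total, its percentage of the genome's genes, per-class percentages of
#' the RGA total, per-row shares, and the mean RGA count per chromosome
#' computed over chromosome rows only (contigs excluded). Percentages are
#' rounded half-even at 2 decimals for reporting.
#'
#' @param count_table per-chromosome table as produced by
#'   [rgaCountTable()] or [readPublishedCounts()] (a `Total` row, if
#'   present, is ignored)
#' @param genome_gene_total total number of genes in the genome (> 0)
#' @return List with `total_rgas`, `pct_of_genes`, `class_pct` (named
#'   over the count columns), `mean_per_chromosome`,
#'   `typical_nlr`/`atypical_nlr` aggregates, and `per_row`
#'   (`chromosome`, `rga_count`, `share_pct`, `density` for
#'   non-contig rows).
#' @export
summariseLandscape <- function(count_table, genome_gene_total) {
  if (genome_gene_total <= 0) stop("genome_gene_total must be positive")
  tab <- strip_total_row(count_table)
  total <- sum(tab$total)
  cls_cols <- setdiff(intersect(COUNT_TABLE_COLUMNS, colnames(tab)), "total")
  class_pct <- round(100 * colSums(tab[cls_cols]) / total, 2)
  chrom <- tab[!tab$is_contig, , drop = FALSE]
  per_row <- data.frame(
    chromosome = chrom$chromosome,
    rga_count = chrom$total,
    share_pct = round(100 * chrom$total / total, 2),
    density = rgaDensity(chrom$total, chrom$position_mbp))
  typical <- sum(tab$tnl, tab$cnl, tab$rnl)
  atypical <- sum(tab$tx, tab$tn, tab$nl, tab$rn, tab$cn, tab$other)
  list(total_rgas = total,
       pct_of_genes = round(100 * total / genome_gene_total, 2),
       class_pct = class_pct,
       mean_per_chromosome = round(sum(chrom$total) / nrow(chrom), 2),
       typical_nlr = typical,
       atypical_nlr = atypical,
       per_row = per_row)
}

#' Chromosome size versus RGA count regression
#'
#' Ordinary least squares of count on size across chromosomes.
#'
#' @param sizes chromosome sizes (Mbp), at least 3, not all equal
#' @param counts RGA counts, same length
#' @return List with `slope`, `intercept`, `pearson_r`.
#' @export
sizeCountRegression <- function(sizes, counts) {
  stopifnot(length(sizes) == length(counts))
  if (length(sizes) < 3) stop("need at least 3 chromosomes")
  if (length(unique(sizes)) == 1)
    stop("constant chromosome sizes: slope undefined")
  fit <- lm(counts ~ sizes)
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       pearson_r = if (length(unique(counts)) == 1) 0
                   else unname(cor(sizes, counts)))
}

#' Larger-chromosome-but-not-more-RGAs pairwise count
#'
#' Number of unordered chromosome pairs in which the larger chromosome
#' carries no more RGAs than the smaller one (equal counts are counted:
#' the larger chromosome then still has "not more").
#'
#' @param sizes chromosome sizes, all distinct
#' @param counts RGA counts, same length
#' @return Integer pair count.
#' @export
#' @examples
#' largerButNotMorePairs(c(3, 2, 1), c(1, 2, 3))  # every pair: 3
largerButNotMorePairs <- function(sizes, counts) {
  stopifnot(length(sizes) == length(counts))
  if (length(sizes) < 2) stop("need at least 2 chromosomes")
  if (anyDuplicated(sizes))
    stop("tied chromosome sizes: larger/smaller undefined")
  ord <- order(sizes)
  sizes <- sizes[ord]; counts <- counts[ord]
  n <- 0L
  for (j in seq_along(sizes)[-1])
    n <- n + sum(counts[j] <= counts[seq_len(j - 1)])
  n
}

#' Positional RGA profile along chromosomes
#'
#' Tiles each chromosome with fixed windows (the last window may be
#' short), assigns each gene to the window containing its start, and
#' counts genes per window, optionally split by RGA class. Also reports
#' the end-bias fraction: the share of genes whose start lies in the two
#' distal 25% segments of its chromosome.
#'
#' @param x an [RGAGenome-class]
#' @param annotations optional [classifyGenome()] output; when given,
#'   only genes with `rga_class != "NONE"` are profiled and window counts
#'   are split by class
#' @param window_bp window size in bp (default 1e6)
#' @return List with `windows` (`chromosome`, `window_start`,
#'   `window_end`, `class`, `count`) and `end_bias_fraction`.
#' @export
positionalProfile <- function(x, annotations = NULL, window_bp = 1e6) {
  if (window_bp <= 0) stop("window_bp must be positive")
  gr <- geneRanges(x)
  cls <- rep("all", length(gr))
  if (!is.null(annotations)) {
    cls <- annotations$rga_class[match(names(gr), annotations$gene_id)]
    keep <- !is.na(cls) & cls != "NONE"
    gr <- gr[keep]; cls <- cls[keep]
  }
  asm <- as.data.frame(assemblyInfo(x))
  rows <- list()
  for (i in seq_len(nrow(asm))) {
    ch <- asm$name[i]
    len <- asm$length_bp[i]
    starts <- seq(1L, len, by = window_bp)
    ends <- pmin(starts + window_bp - 1, len)
    sel <- as.character(seqnames(gr)) == ch
    if (!any(sel) && length(starts) == 0) next
    win <- findInterval(start(gr)[sel], starts)
    for (k in unique(cls[sel])) {
      cnt <- tabulate(win[cls[sel] == k], nbins = length(starts))
      rows[[length(rows) + 1]] <- data.frame(
        chromosome = ch, window_start = starts, window_end = ends,
        class = k, count = cnt)
    }
  }
  windows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chromosome = character(), window_start = integer(),
               window_end = integer(), class = character(),
               count = integer())
  list(windows = windows,
       end_bias_fraction = endBiasFraction(x,
         gene_ids = names(gr)))
}

#' Fraction of genes in the distal chromosome quarters
#'
#' Share of genes whose start coordinate falls in the first or last 25%
#' of its chromosome. Uniform placement gives 0.5 in expectation; the
#' end-biased placement seen for RGAs gives more.
#'
#' @param x an [RGAGenome-class]
#' @param gene_ids optional subset of gene ids
#' @return Fraction in `[0, 1]`.
#' @export
endBiasFraction <- function(x, gene_ids = NULL) {
  gr <- geneRanges(x)
  if (!is.null(gene_ids)) gr <- gr[gene_ids]
  if (!length(gr)) return(NA_real_)
  asm <- as.data.frame(assemblyInfo(x))
  len <- asm$length_bp[match(as.character(seqnames(gr)), asm$name)]
  rel <- start(gr) / len
  mean(rel <= 0.25 | rel > 0.75)
}
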