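#' Is a gene fully contained in a QTL interval?
#'
#' Vectorised containment predicate on 1-based fully closed coordinates:
#' a gene is `"within"` iff `qtl_start <= gene_start` and
#' `gene_end <= qtl_end` and the chromosome labels match. Partial overlap
#' is `"outside"`.
#'
#' @param gene_chrom,gene_start,gene_end gene coordinates
#' @param qtl_chrom,qtl_start,qtl_end QTL coordinates
#' @return Character vector of `"within"`/`"outside"`.
#' @export
#' @examples
#' withinQtl("A1", 100, 200, "A1", 50, 500)   # within
#' withinQtl("A1", 400, 600, "A1", 50, 500)   # outside
withinQtl <- function(gene_chrom, gene_start, gene_end,
                      qtl_chrom, qtl_start, qtl_end) {
  ok <- gene_chrom == qtl_chrom & qtl_start <= gene_start &
    gene_end <= qtl_end
  ifelse(ok, "within", "outside")
}

#' Co-localise receptor genes with QTL intervals
#'
#' For every gene of the requested classes (RLK and RLP by default, the
#' receptor classes the co-localisation analysis targets) and every QTL,
#' decides containment via [GenomicRanges::findOverlaps] with
#' `type = "within"` (or any-overlap when `mode = "overlap"`). Genes and
#' QTL must share one coordinate system; `chrom_map` renames QTL
#' chromosome labels onto assembly names, and QTL on chromosomes absent
#' from the assembly are skipped with a warning.
#'
#' @param x an [RGAGenome-class]
#' @param annotations [classifyGenome()] output
#' @param qtls QTL table ([readQtlTable()])
#' @param classes RGA classes to test (default RLK and RLP)
#' @param chrom_map optional named character vector mapping QTL
#'   chromosome labels to assembly sequence names
#' @param mode `"within"` (full containment, default) or `"overlap"`
#' @return List with `pairs` (`gene_id`, `qtl_name`, `rga_class`; one
#'   row per within relation), `per_qtl` (gene counts per QTL split by
#'   class), `per_gene` (number of QTL per gene, zero rows omitted),
#'   `in_any_qtl` (named counts per class of genes inside >= 1 QTL, with
#'   `tested` totals), `max_qtl_gene` and `max_gene_qtl`.
#' @export
colocaliseGenes <- function(x, annotations, qtls,
                            classes = c("RLK", "RLP"), chrom_map = NULL,
                            mode = c("within", "overlap")) {
  mode <- match.arg(mode)
  keep <- annotations$rga_class %in% classes
  ids <- annotations$gene_id[keep]
  gr <- geneRanges(x)[ids]
  qchrom <- as.character(qtls$chromosome)
  if (!is.null(chrom_map)) {
    hit <- qchrom %in% names(chrom_map)
    qchrom[hit] <- chrom_map[qchrom[hit]]
  }
  known <- qchrom %in% assemblyInfo(x)$name
  if (any(!known)) {
    warning("skipping ", sum(!known),
            " QTL on chromosomes absent from the assembly: ",
            paste(unique(qtls$qtl_name[!known]), collapse = ", "))
    qtls <- qtls[known, , drop = FALSE]
    qchrom <- qchrom[known]
  }
  lev <- unique(c(seqlevels(gr), qchrom))
  qgr <- GRanges(factor(qchrom, levels = lev),
                 IRanges(qtls$start, qtls$end))
  GenomeInfoDb::seqlevels(gr) <- lev
  ov <- findOverlaps(gr, qgr,
                     type = if (mode == "within") "within" else "any")
  pairs <- data.frame(
    gene_id = ids[S4Vectors::queryHits(ov)],
    qtl_name = qtls$qtl_name[S4Vectors::subjectHits(ov)],
    rga_class = annotations$rga_class[
      match(ids[S4Vectors::queryHits(ov)], annotations$gene_id)])
  cls_tested <- annotations$rga_class[keep]
  per_qtl <- as.data.frame.matrix(
    table(factor(pairs$qtl_name, levels = unique(qtls$qtl_name)),
          factor(pairs$rga_class, levels = classes)))
  per_qtl <- data.frame(qtl_name = rownames(per_qtl), per_qtl,
                        row.names = NULL, check.names = FALSE)
  per_qtl$total <- rowSums(per_qtl[, classes, drop = FALSE])
  per_gene <- as.data.frame(table(gene_id = pairs$gene_id),
                            stringsAsFactors = FALSE)
  names(per_gene)[2] <- "n_qtl"
  in_any <- vapply(classes, function(cl)
    length(unique(pairs$gene_id[pairs$rga_class == cl])), 0L)
  tested <- vapply(classes, function(cl) sum(cls_tested == cl), 0L)
  list(pairs = pairs,
       per_qtl = per_qtl,
       per_gene = per_gene,
       in_any_qtl = in_any,
       tested = tested,
       max_qtl_gene = if (nrow(per_gene))
         per_gene$gene_id[which.max(per_gene$n_qtl)] else NA_character_,
       max_gene_qtl = if (nrow(per_qtl))
         per_qtl$qtl_name[which.max(per_qtl$total)] else NA_character_)
}
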