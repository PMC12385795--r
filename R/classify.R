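#' Classify one domain set into an RGA annotation
#'
#' Deterministic, total decision table mapping a gene's set of canonical
#' domains to its RGA class, NLR-side subtype, receptor subclass,
#' typical/atypical flag and superfamily. Precedence (top-down):
#'
#' 1. `NBARC` present: base subtype from TIR/CC/LRR
#'    (TIR+LRR = TNL, TIR = TN, CC+LRR = CNL, CC = CN, LRR = NL,
#'    none = NBS, TIR winning over CC when both occur); then RPW8
#'    reclassification: NBS+RPW8 = RN, NL+RPW8 = RNL, any of
#'    TNL/CNL/CN/TN plus RPW8 = OTHER.
#' 2. `TIR` without `NBARC`: TX (TX+RPW8 = OTHER).
#' 3. `KINASE` + `TM`: RLK, subclassed by ectodomain (LRR, LYSM, else
#'    other receptor).
#' 4. `TM` + an ectodomain (LRR/LYSM/OTHER_ECTO) without `KINASE`: RLP,
#'    same subclassing.
#' 5. `RPW8` alone (no NBARC, none of the above): standalone RPW8 class.
#' 6. `TM` + `CC`: TM-CC.
#' 7. otherwise: NONE.
#'
#' TX and OTHER are tabulated among the NLR-side subtypes (class `NLR`)
#' even though TX genes lack NBARC, matching how the field groups them;
#' bare-NBS keeps the distinct subtype mark `NBS` in the annotation and is
#' tabulated under OTHER in the count table.
#'
#' @param domains character vector of canonical domain labels (a set;
#'   duplicates are ignored)
#' @return Named list with `rga_class` (`RLK`, `RLP`, `NLR`, `TMCC`,
#'   `RPW8`, `NONE`), `nlr_subtype` (`TNL`, `CNL`, `RNL`, `TN`, `CN`,
#'   `RN`, `NL`, `TX`, `NBS`, `OTHER` or `none`), `receptor_subclass`
#'   (`LRR`, `LYSM`, `OTHER_RECEPTOR` or `none`), `typical` (`typical`,
#'   `atypical` or `n/a`) and `superfamily` (`TM-LRR`, `NLR`, `TM-CC`,
#'   `RPW8` or `none`).
#' @export
#' @examples
#' classifyDomains(c("TIR", "NBARC", "LRR"))   # TNL, typical
#' classifyDomains(c("NBARC", "RPW8"))          # RN
#' classifyDomains(c("TM", "KINASE", "LRR"))    # LRR-RLK
classifyDomains <- function(domains) {
  domains <- unique(as.character(domains))
  bad <- setdiff(domains, DOMAIN_VOCABULARY)
  if (length(bad))
    stop("unknown domain label(s): ", paste(bad, collapse = ", "))
  has <- function(d) d %in% domains
  ann <- list(rga_class = "NONE", nlr_subtype = "none",
              receptor_subclass = "none", typical = "n/a",
              superfamily = "none")
  subclass <- function() {
    if (has("LRR")) "LRR" else if (has("LYSM")) "LYSM" else "OTHER_RECEPTOR"
  }
  if (has("NBARC")) {
    base <- if (has("TIR")) {
      if (has("LRR")) "TNL" else "TN"
    } else if (has("CC")) {
      if (has("LRR")) "CNL" else "CN"
    } else if (has("LRR")) "NL" else "NBS"
    sub <- if (has("RPW8")) {
      switch(base, NBS = "RN", NL = "RNL", "OTHER")
    } else base
    ann$rga_class <- "NLR"
    ann$nlr_subtype <- sub
    ann$superfamily <- "NLR"
  } else if (has("TIR")) {
    ann$rga_class <- "NLR"
    ann$nlr_subtype <- if (has("RPW8")) "OTHER" else "TX"
    ann$superfamily <- "NLR"
  } else if (has("KINASE") && has("TM")) {
    ann$rga_class <- "RLK"
    ann$receptor_subclass <- subclass()
    ann$superfamily <- "TM-LRR"
  } else if (has("TM") && (has("LRR") || has("LYSM") || has("OTHER_ECTO"))) {
    ann$rga_class <- "RLP"
    ann$receptor_subclass <- subclass()
    ann$superfamily <- "TM-LRR"
  } else if (has("RPW8")) {
    ann$rga_class <- "RPW8"
    ann$superfamily <- "RPW8"
  } else if (has("TM") && has("CC")) {
    ann$rga_class <- "TMCC"
    ann$superfamily <- "TM-CC"
  }
  if (ann$nlr_subtype != "none")
    ann$typical <- typicalFlag(ann$nlr_subtype)
  ann
}

#' Typical/atypical flag for an NLR-side subtype
#'
#' Full three-domain architectures (TNL, CNL, RNL) are typical; the
#' partial or disordered complements (CN, RN, NL, TN, TX, NBS, OTHER)
#' are atypical.
#'
#' @param nlr_subtype one of the NLR-side subtype labels
#' @return `"typical"` or `"atypical"`.
#' @export
typicalFlag <- function(nlr_subtype) {
  stopifnot(length(nlr_subtype) == 1)
  if (nlr_subtype %in% c("TNL", "CNL", "RNL")) return("typical")
  if (nlr_subtype %in% c("CN", "RN", "NL", "TN", "TX", "NBS", "OTHER"))
    return("atypical")
  stop("not an NLR-side subtype: ", nlr_subtype)
}

#' Classify every gene of a genome
#'
#' Applies [classifyDomains()] to each gene's domain set.
#'
#' @param x an [RGAGenome-class]
#' @return `data.frame` with one row per gene (gene order preserved):
#'   `gene_id`, `rga_class`, `nlr_subtype`, `receptor_subclass`,
#'   `typical`, `superfamily`.
#' @seealso [rgaCountTable()] for the per-chromosome count table.
#' @export
classifyGenome <- function(x) {
  sets <- domainSets(x)
  rows <- lapply(sets, classifyDomains)
  out <- data.frame(
    gene_id = names(sets),
    rga_class = vapply(rows, `[[`, "", "rga_class"),
    nlr_subtype = vapply(rows, `[[`, "", "nlr_subtype"),
    receptor_subclass = vapply(rows, `[[`, "", "receptor_subclass"),
    typical = vapply(rows, `[[`, "", "typical"),
    superfamily = vapply(rows, `[[`, "", "superfamily"),
    row.names = NULL)
  out
}

# column order of the published-style count table
COUNT_TABLE_COLUMNS <- c("rlk", "lrr_rlk", "lysm_rlk", "other_rlk",
                         "rlp", "lrr_rlp", "lysm_rlp", "other_rlp",
                         "tm_cc", "tnl", "cnl", "rnl", "tx", "tn", "nl",
                         "rn", "cn", "other", "rpw8", "total")

#' Per-chromosome RGA count table
#'
#' Tabulates a classification into the standard per-chromosome layout:
#' one row per chromosome, then contigs, then a `Total` row; columns
#' RLK (with LRR/LysM/other-receptor subclasses), RLP (same), TM-CC,
#' the NLR-side subtypes, RPW8 and the per-row RGA total. Bare-NBS genes
#' are counted in the `other` column (the layout has no NBS column).
#'
#' @param annotations output of [classifyGenome()]
#' @param x the [RGAGenome-class] the annotations came from
#' @return `data.frame` with columns `chromosome`, `is_contig`,
#'   `position_mbp` and the count columns.
#' @export
rgaCountTable <- function(annotations, x) {
  asm <- as.data.frame(assemblyInfo(x))
  asm <- asm[order(asm$is_contig), , drop = FALSE]
  chrom <- as.character(seqnames(geneRanges(x)))[
    match(annotations$gene_id, geneIds(x))]
  one_row <- function(ann) {
    cls <- ann$rga_class
    sub <- ann$nlr_subtype
    rec <- ann$receptor_subclass
    n <- function(v) sum(v)
    c(rlk = n(cls == "RLK"),
      lrr_rlk = n(cls == "RLK" & rec == "LRR"),
      lysm_rlk = n(cls == "RLK" & rec == "LYSM"),
      other_rlk = n(cls == "RLK" & rec == "OTHER_RECEPTOR"),
      rlp = n(cls == "RLP"),
      lrr_rlp = n(cls == "RLP" & rec == "LRR"),
      lysm_rlp = n(cls == "RLP" & rec == "LYSM"),
      other_rlp = n(cls == "RLP" & rec == "OTHER_RECEPTOR"),
      tm_cc = n(cls == "TMCC"),
      tnl = n(sub == "TNL"), cnl = n(sub == "CNL"), rnl = n(sub == "RNL"),
      tx = n(sub == "TX"), tn = n(sub == "TN"), nl = n(sub == "NL"),
      rn = n(sub == "RN"), cn = n(sub == "CN"),
      other = n(sub %in% c("OTHER", "NBS")),
      rpw8 = n(cls == "RPW8"),
      total = n(cls != "NONE"))
  }
  mat <- t(vapply(asm$name, function(ch) {
    one_row(annotations[!is.na(chrom) & chrom == ch, , drop = FALSE])
  }, numeric(length(COUNT_TABLE_COLUMNS))))
  colnames(mat) <- COUNT_TABLE_COLUMNS
  out <- data.frame(chromosome = asm$name,
                    is_contig = asm$is_contig,
                    position_mbp = ifelse(asm$is_contig, NA_real_,
                                          asm$length_bp / 1e6),
                    mat, row.names = NULL)
  total <- out[1, , drop = FALSE]
  total$chromosome <- "Total"
  total$is_contig <- NA
  total$position_mbp <- NA_real_
  total[COUNT_TABLE_COLUMNS] <- as.list(colSums(mat))
  rbind(out, total)
}
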