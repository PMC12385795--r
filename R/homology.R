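#' Filter alignment hits with the CDRH criteria
#'
#' Keeps a hit iff all three hold: E-value `<= e_max` (i.e. in the range
#' E0 to `e_max`; E0 denotes a reported E-value of zero), percent
#' similarity `>= sim_min`, and alignment length `>= len_min_aa`.
#' The length rule reflects the smallest reference protein in the cloned
#' R-gene set (148 aa); it is applied to the alignment length by default.
#' Row order is preserved.
#'
#' @param hits hit `data.frame` as from [readHits()] or [simulateHits()]
#' @param e_max maximum E-value (default 1e-45)
#' @param sim_min minimum percent similarity (default 60)
#' @param len_min_aa minimum alignment length in aa (default 148)
#' @return The kept subset of `hits`.
#' @export
#' @examples
#' h <- data.frame(query_id = "R1", subject_id = "g1",
#'                 evalue = c(0, 1e-30), similarity_pct = 80,
#'                 aln_length_aa = 300)
#' filterHits(h)$evalue  # only the E0 hit survives
filterHits <- function(hits, e_max = 1e-45, sim_min = 60,
                       len_min_aa = 148) {
  keep <- hits$evalue <= e_max &
    hits$similarity_pct >= sim_min &
    hits$aln_length_aa >= len_min_aa
  hits[keep, , drop = FALSE]
}

#' Cloned disease resistance gene homologue (CDRH) map
#'
#' A CDRH is a genome gene classified as an RGA (class not `NONE`) with
#' at least one kept hit against a cloned R gene. Relationships are
#' many-to-many: no best-hit selection is applied. Each CDRH inherits
#' the union of the disease codes of its matched R genes.
#'
#' @param kept_hits filtered hits ([filterHits()])
#' @param annotations [classifyGenome()] output covering every subject
#' @param r_catalog cloned R-gene catalogue ([readRGeneCatalog()])
#' @return List with `records` (`data.frame`: `gene_id`, `rga_class`,
#'   `nlr_subtype`, list-columns `matched_r_genes` and `diseases`,
#'   `n_r_genes`) and `summary` (list: `n_r_genes_with_homologue`,
#'   `n_r_genes_multiple`, `per_r_gene_counts`, `n_cdrh`,
#'   `n_multi_match_cdrh`, `class_composition`).
#' @export
cdrhMap <- function(kept_hits, annotations, r_catalog) {
  homologue_map(kept_hits, annotations, r_catalog, rga = TRUE)
}

#' Non-RGA homologues of cloned R genes
#'
#' Same construction as [cdrhMap()], restricted to subject genes
#' classified `NONE`. Together the two record sets partition all kept
#' subjects.
#'
#' @inheritParams cdrhMap
#' @return Same shape as [cdrhMap()] (class composition omitted).
#' @export
nonRgaHomologues <- function(kept_hits, annotations, r_catalog) {
  homologue_map(kept_hits, annotations, r_catalog, rga = FALSE)
}

homologue_map <- function(kept_hits, annotations, r_catalog, rga) {
  missing <- setdiff(kept_hits$subject_id, annotations$gene_id)
  if (length(missing))
    stop("subject gene(s) absent from annotations: ",
         paste(head(missing, 5), collapse = ", "))
  cls <- annotations$rga_class[
    match(kept_hits$subject_id, annotations$gene_id)]
  hits <- kept_hits[if (rga) cls != "NONE" else cls == "NONE", ,
                    drop = FALSE]
  subjects <- unique(hits$subject_id)
  matched <- lapply(subjects, function(s)
    sort(unique(hits$query_id[hits$subject_id == s])))
  dis_of <- function(rg) {
    i <- match(rg, r_catalog$r_gene_id)
    if (anyNA(i)) stop("R gene(s) not in catalogue: ",
                       paste(rg[is.na(i)], collapse = ", "))
    sort(unique(unlist(r_catalog$diseases[i])))
  }
  idx <- match(subjects, annotations$gene_id)
  records <- data.frame(
    gene_id = subjects,
    rga_class = annotations$rga_class[idx],
    nlr_subtype = annotations$nlr_subtype[idx],
    n_r_genes = lengths(matched),
    row.names = NULL)
  records$matched_r_genes <- I(matched)
  records$diseases <- I(lapply(matched, dis_of))
  per_r_gene <- table(unlist(matched))
  summary <- list(
    n_r_genes_with_homologue = length(per_r_gene),
    n_r_genes_multiple = sum(per_r_gene > 1),
    per_r_gene_counts = per_r_gene,
    n_cdrh = nrow(records),
    n_multi_match_cdrh = sum(records$n_r_genes > 1))
  if (rga && nrow(records)) {
    cat <- ifelse(records$rga_class == "NLR",
                  ifelse(records$nlr_subtype == "NBS", "OTHER",
                         records$nlr_subtype),
                  records$rga_class)
    lev <- c("RLK", "RLP", "CNL", "TNL", "RNL", "TN", "CN", "RN", "NL",
             "TX", "OTHER", "RPW8", "TMCC")
    summary$class_composition <- table(factor(cat, levels = lev))
  }
  list(records = records, summary = summary)
}

#' Per-disease CDRH counts
#'
#' Rolls CDRH records up by disease: a CDRH contributes once to each
#' disease in its inherited disease set, deduplicated within a disease
#' even when several matched R genes confer it.
#'
#' @param records the `records` element of a [cdrhMap()] result
#' @param r_catalog cloned R-gene catalogue (used to validate codes)
#' @return Named integer vector of CDRH counts per disease code.
#' @export
diseaseRollup <- function(records, r_catalog) {
  unknown <- setdiff(unlist(records$matched_r_genes), r_catalog$r_gene_id)
  if (length(unknown))
    stop("R gene(s) not in catalogue: ", paste(unknown, collapse = ", "))
  pairs <- unique(data.frame(
    gene = rep(records$gene_id, lengths(records$diseases)),
    disease = unlist(records$diseases)))
  tab <- table(pairs$disease)
  setNames(as.integer(tab), names(tab))
}
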