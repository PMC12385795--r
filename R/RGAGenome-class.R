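#' RGAGenome: an annotated assembly for RGA analysis
#'
#' Container holding everything the characterisation stages need: the
#' assembly (chromosome/contig names and lengths), gene models as a
#' [GenomicRanges::GRanges] (1-based, fully closed intervals), optional
#' protein sequences as a [Biostrings::AAStringSet], and per-gene domain
#' calls restricted to the controlled vocabulary.
#'
#' @slot assembly `DataFrame` with columns `name`, `length_bp`, `is_contig`.
#' @slot genes `GRanges` named by gene id, with a `protein_length`
#'   metadata column (`NA` when unknown).
#' @slot proteins `AAStringSet` named by gene id (may be empty or partial).
#' @slot domains `DataFrame` with columns `gene_id`, `domain`,
#'   `aa_start`, `aa_end` (coordinates optional, `NA` when absent).
#'
#' @seealso [readAnnotation()], [generateGenome()], [classifyGenome()]
#' @export
setClass("RGAGenome",
  representation(
    assembly = "DataFrame",
    genes = "GRanges",
    proteins = "AAStringSet",
    domains = "DataFrame"
  )
)

setValidity("RGAGenome", function(object) {
  msg <- character()
  asm <- object@assembly
  need <- c("name", "length_bp", "is_contig")
  if (!all(need %in% colnames(asm)))
    return(paste("assembly must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(asm$name))
    msg <- c(msg, "duplicated sequence names in assembly")
  if (any(asm$length_bp <= 0))
    msg <- c(msg, "assembly lengths must be positive")
  gr <- object@genes
  ids <- names(gr)
  if (length(gr)) {
    if (is.null(ids) || anyDuplicated(ids))
      msg <- c(msg, "gene ids must be present and unique")
    bad_chrom <- setdiff(as.character(unique(seqnames(gr))), asm$name)
    if (length(bad_chrom))
      msg <- c(msg, paste("gene chromosomes not in assembly:",
                          paste(bad_chrom, collapse = ", ")))
    len <- asm$length_bp[match(as.character(seqnames(gr)), asm$name)]
    if (any(start(gr) < 1, na.rm = TRUE))
      msg <- c(msg, "gene start coordinates must be >= 1")
    over <- !is.na(len) & end(gr) > len
    if (any(over))
      msg <- c(msg, paste("genes extend past chromosome end:",
                          paste(head(ids[over], 5), collapse = ", ")))
  }
  if (length(object@proteins)) {
    orphan <- setdiff(names(object@proteins), ids)
    if (length(orphan))
      msg <- c(msg, paste("protein sequences for unknown genes:",
                          paste(head(orphan, 5), collapse = ", ")))
    pl <- mcols(gr)$protein_length
    if (!is.null(pl)) {
      hit <- match(names(object@proteins), ids)
      both <- !is.na(pl[hit])
      if (any(both & pl[hit] != width(object@proteins)))
        msg <- c(msg, "protein_length disagrees with sequence length")
    }
  }
  dom <- object@domains
  if (nrow(dom)) {
    if (!all(c("gene_id", "domain") %in% colnames(dom)))
      return("domains must have gene_id and domain columns")
    unknown_gene <- setdiff(dom$gene_id, ids)
    if (length(unknown_gene))
      msg <- c(msg, paste("domain calls for unknown genes:",
                          paste(head(unknown_gene, 5), collapse = ", ")))
    bad_dom <- setdiff(dom$domain, DOMAIN_VOCABULARY)
    if (length(bad_dom))
      msg <- c(msg, paste("domain labels outside the vocabulary:",
                          paste(unique(bad_dom), collapse = ", ")))
    if (all(c("aa_start", "aa_end") %in% colnames(dom))) {
      both <- !is.na(dom$aa_start) & !is.na(dom$aa_end)
      if (any(dom$aa_start[both] > dom$aa_end[both]))
        msg <- c(msg, "aa_start > aa_end in domain calls")
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct an RGAGenome
#'
#' @param assembly `data.frame`/`DataFrame` with columns `name`, `length_bp`
#'   and optionally `is_contig` (default derived from `contig_pattern`).
#' @param genes `GRanges` named by gene id, or a `data.frame` with columns
#'   `gene_id`, `chromosome`, `start`, `end` and optional `strand`,
#'   `protein_length`.
#' @param proteins optional `AAStringSet` named by gene id.
#' @param domains optional `data.frame` with columns `gene_id`, `domain`
#'   and optional `aa_start`, `aa_end`. Labels must already be canonical;
#'   use [normaliseDomainLabels()] for raw tables.
#' @param contig_pattern regular expression identifying chromosome (i.e.
#'   non-contig) names when `assembly$is_contig` is missing.
#'
#' @return An [RGAGenome-class] object.
#' @export
#' @examples
#' asm <- data.frame(name = "Chr01", length_bp = 1e6)
#' genes <- data.frame(gene_id = "g1", chromosome = "Chr01",
#'                     start = 100, end = 2100)
#' dom <- data.frame(gene_id = "g1", domain = c("TM", "KINASE", "LRR"))
#' RGAGenome(asm, genes, domains = dom)
RGAGenome <- function(assembly, genes, proteins = AAStringSet(),
                      domains = NULL, contig_pattern = "^Chr") {
  assembly <- as.data.frame(assembly)
  if (is.null(assembly$is_contig))
    assembly$is_contig <- !grepl(contig_pattern, assembly$name)
  asm <- DataFrame(name = as.character(assembly$name),
                   length_bp = as.integer(assembly$length_bp),
                   is_contig = as.logical(assembly$is_contig))
  if (is.data.frame(genes)) {
    if (anyDuplicated(genes$gene_id))
      stop("duplicated gene ids: ",
           paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
                 collapse = ", "))
    strand <- if (is.null(genes$strand)) "*" else {
      s <- as.character(genes$strand)
      s[!s %in% c("+", "-")] <- "*"
      s
    }
    gr <- GRanges(seqnames = as.character(genes$chromosome),
                  ranges = IRanges(as.integer(genes$start),
                                   as.integer(genes$end)),
                  strand = strand)
    names(gr) <- as.character(genes$gene_id)
    mcols(gr)$protein_length <-
      if (is.null(genes$protein_length)) NA_integer_
      else as.integer(genes$protein_length)
  } else {
    gr <- genes
    if (is.null(mcols(gr)$protein_length))
      mcols(gr)$protein_length <- NA_integer_
  }
  if (is.null(domains))
    domains <- data.frame(gene_id = character(), domain = character(),
                          aa_start = integer(), aa_end = integer())
  domains <- as.data.frame(domains)
  if (is.null(domains$aa_start)) domains$aa_start <- NA_integer_
  if (is.null(domains$aa_end)) domains$aa_end <- NA_integer_
  dom <- DataFrame(gene_id = as.character(domains$gene_id),
                   domain = as.character(domains$domain),
                   aa_start = as.integer(domains$aa_start),
                   aa_end = as.integer(domains$aa_end))
  new("RGAGenome", assembly = asm, genes = gr,
      proteins = proteins, domains = dom)
}

#' @describeIn RGAGenome assembly table (name, length_bp, is_contig)
#' @param x an `RGAGenome`
#' @export
assemblyInfo <- function(x) x@assembly

#' @describeIn RGAGenome gene models as a named `GRanges`
#' @export
geneRanges <- function(x) x@genes

#' @describeIn RGAGenome protein sequences as an `AAStringSet`
#' @export
proteinSeqs <- function(x) x@proteins

#' @describeIn RGAGenome domain call table
#' @export
domainCalls <- function(x) x@domains

#' @describeIn RGAGenome gene identifiers
#' @export
geneIds <- function(x) names(x@genes)

#' Domain sets per gene
#'
#' Collapse the domain-call table of an [RGAGenome] to one character vector
#' of unique canonical domain labels per gene (empty vector for genes with
#' no calls).
#'
#' @param x an `RGAGenome`
#' @return Named list, one element per gene in gene order.
#' @export
domainSets <- function(x) {
  ids <- geneIds(x)
  sets <- split(x@domains$domain, factor(x@domains$gene_id, levels = ids))
  lapply(sets, function(d) sort(unique(d)))
}

setMethod("show", "RGAGenome", function(object) {
  asm <- object@assembly
  cat("RGAGenome with", sum(!asm$is_contig), "chromosomes,",
      sum(asm$is_contig), "contigs\n")
  cat(" ", length(object@genes), "genes;",
      length(object@proteins), "protein sequences;",
      nrow(object@domains), "domain calls\n")
  gt <- metadata(object@genes)$ground_truth
  if (!is.null(gt)) cat("  synthetic genome with ground truth manifest\n")
  invisible(NULL)
})
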