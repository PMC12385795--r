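#' Normalise domain labels to the controlled vocabulary
#'
#' Domain predictors emit many aliases for the same signature
#' (e.g. `"NB-ARC"`, `"NBS"` for the nucleotide-binding domain). This maps
#' them onto the canonical nine-label vocabulary via the packaged synonym
#' table, and fails hard on anything unmappable.
#'
#' @param labels character vector of raw domain labels
#' @param synonyms named character vector mapping alias -> canonical label;
#'   defaults to the packaged map ([domainSynonyms()]).
#' @return Character vector of canonical labels, same length as `labels`.
#' @export
#' @examples
#' normaliseDomainLabels(c("NB-ARC", "Pkinase", "LRR"))
normaliseDomainLabels <- function(labels, synonyms = domainSynonyms()) {
  key <- toupper(gsub("[ .-]", "_", trimws(labels)))
  out <- ifelse(key %in% DOMAIN_VOCABULARY, key, unname(synonyms[key]))
  if (anyNA(out)) {
    bad <- unique(labels[is.na(out)])
    stop("unmappable domain label(s): ", paste(bad, collapse = ", "))
  }
  out
}

#' Packaged domain synonym map
#'
#' @return Named character vector alias -> canonical label.
#' @export
domainSynonyms <- function() {
  path <- system.file("extdata", "domain_synonyms.tsv", package = "rgascape")
  tab <- read.delim(path, stringsAsFactors = FALSE)
  setNames(tab$canonical, toupper(gsub("[ .-]", "_", tab$alias)))
}

#' Read an annotated assembly from standard files
#'
#' Reads gene models from GFF3 (via rtracklayer), optional protein
#' sequences from FASTA and domain calls from a tab-separated table with
#' columns `gene_id`, `domain` and optional `aa_start`, `aa_end`. Domain
#' labels are normalised through the synonym map. Assembly lengths come
#' from the GFF3 `##sequence-region` pragmas; where absent, the maximal
#' gene end per sequence is used.
#'
#' @param gff3_file path to GFF3 with `gene` features carrying `ID`s
#' @param domain_file path to the domain-call TSV
#' @param fasta_file optional path to a protein FASTA; headers must match
#'   gene ids (first whitespace-separated token)
#' @param contig_pattern regular expression identifying chromosome names;
#'   sequences not matching it are flagged as contigs
#' @return An [RGAGenome-class].
#' @export
readAnnotation <- function(gff3_file, domain_file, fasta_file = NULL,
                           contig_pattern = "^Chr") {
  gr <- rtracklayer::import(gff3_file, format = "gff3")
  gr <- gr[gr$type == "gene"]
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(ids == ""))
    stop("GFF3 gene records must carry stable IDs")
  if (anyDuplicated(ids))
    stop("duplicated gene IDs in GFF3: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lens <- seqlengths(gr)
  # sequence-region pragmas carry the assembly lengths; rtracklayer
  # drops them on import, so recover them from the header
  prag <- grep("^##sequence-region", readLines(gff3_file), value = TRUE)
  if (length(prag)) {
    parts <- strsplit(trimws(prag), "[[:space:]]+")
    pnames <- vapply(parts, `[[`, "", 2)
    plens <- as.numeric(vapply(parts, `[[`, "", 4))
    lens[intersect(names(lens), pnames)] <-
      plens[match(intersect(names(lens), pnames), pnames)]
    extra <- setdiff(pnames, names(lens))
    lens <- c(lens, setNames(plens[match(extra, pnames)], extra))
  }
  if (anyNA(lens)) {
    obs <- vapply(split(end(gr), as.character(seqnames(gr))), max, 0)
    lens[is.na(lens)] <- obs[names(lens)[is.na(lens)]]
  }
  assembly <- data.frame(name = names(lens), length_bp = as.integer(lens))
  genes <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)), strand(gr))
  names(genes) <- ids
  mcols(genes)$protein_length <- NA_integer_

  proteins <- AAStringSet()
  if (!is.null(fasta_file)) {
    proteins <- readAAStringSet(fasta_file)
    names(proteins) <- sub("\\s.*", "", names(proteins))
    orphan <- setdiff(names(proteins), ids)
    if (length(orphan))
      stop("protein sequences for unknown genes: ",
           paste(head(orphan, 5), collapse = ", "))
    mcols(genes)$protein_length[match(names(proteins), ids)] <-
      width(proteins)
  }

  dom <- read.delim(domain_file, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "domain") %in% colnames(dom)))
    stop("domain table must have gene_id and domain columns")
  unknown <- setdiff(dom$gene_id, ids)
  if (length(unknown))
    stop("domain calls reference unknown gene(s): ",
         paste(unique(unknown), collapse = ", "))
  dom$domain <- normaliseDomainLabels(dom$domain)

  RGAGenome(assembly, genes, proteins = proteins, domains = dom,
            contig_pattern = contig_pattern)
}

#' Write an RGAGenome back to GFF3/FASTA/TSV
#'
#' Inverse of [readAnnotation()]: the three files written here re-read to
#' an identical record set.
#'
#' @param x an `RGAGenome`
#' @param gff3_file,domain_file,fasta_file output paths (`fasta_file`
#'   skipped when the object holds no protein sequences)
#' @return Invisibly, the paths written.
#' @export
writeAnnotation <- function(x, gff3_file, domain_file, fasta_file = NULL) {
  asm <- assemblyInfo(x)
  gr <- geneRanges(x)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", asm$name, asm$length_bp))
  if (length(gr)) {
    strand <- as.character(strand(gr))
    strand[strand == "*"] <- "."
    lines <- c(lines, sprintf("%s\trgascape\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              as.character(seqnames(gr)), start(gr), end(gr),
                              strand, names(gr)))
  }
  writeLines(lines, gff3_file)
  dom <- as.data.frame(domainCalls(x))
  write.table(dom, domain_file, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(gff3_file, domain_file)
  if (!is.null(fasta_file) && length(proteinSeqs(x))) {
    writeXStringSet(proteinSeqs(x), fasta_file)
    paths <- c(paths, fasta_file)
  }
  invisible(paths)
}

#' Read a protein alignment hit table
#'
#' Parses a BLAST-outfmt-6-like tab-separated table into a validated hit
#' data frame (`query_id`, `subject_id`, `evalue`, `similarity_pct`,
#' `aln_length_aa`). Column positions are configurable for other dialects.
#'
#' @param file path to the tab-separated table (no header by default)
#' @param col_map named integer vector giving the column position of
#'   `query`, `subject`, `evalue`, `similarity` and `length`
#' @param header does the file carry a header line?
#' @return `data.frame` of hits, input row order preserved.
#' @export
readHits <- function(file,
                     col_map = c(query = 1L, subject = 2L, evalue = 3L,
                                 similarity = 4L, length = 5L),
                     header = FALSE) {
  empty <- data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), similarity_pct = numeric(),
                      aln_length_aa = integer())
  first <- tryCatch(readLines(file, n = 1), error = function(e) character())
  if (!length(first)) return(empty)
  raw <- read.delim(file, header = header, stringsAsFactors = FALSE)
  if (nrow(raw) == 0)
    return(data.frame(query_id = character(), subject_id = character(),
                      evalue = numeric(), similarity_pct = numeric(),
                      aln_length_aa = integer()))
  hits <- data.frame(
    query_id = as.character(raw[[col_map[["query"]]]]),
    subject_id = as.character(raw[[col_map[["subject"]]]]),
    evalue = as.numeric(raw[[col_map[["evalue"]]]]),
    similarity_pct = as.numeric(raw[[col_map[["similarity"]]]]),
    aln_length_aa = as.integer(raw[[col_map[["length"]]]]))
  bad <- which(is.na(hits$evalue) | hits$evalue < 0)
  if (length(bad))
    stop("invalid E-value at row ", bad[1])
  bad <- which(is.na(hits$similarity_pct) | hits$similarity_pct < 0 |
                 hits$similarity_pct > 100)
  if (length(bad))
    stop("similarity outside [0, 100] at row ", bad[1])
  bad <- which(is.na(hits$aln_length_aa) | hits$aln_length_aa < 1)
  if (length(bad))
    stop("alignment length < 1 aa at row ", bad[1])
  hits
}

#' Read a QTL interval table
#'
#' CSV with columns `qtl_name`, `species`, `disease`, `chromosome`,
#' `start`, `end`; 1-based fully closed coordinates. Disease codes are
#' validated against the six QTL disease codes (BL, BR, CR, HR, SSR, WR).
#'
#' @param file path to the CSV; default is the packaged table of 57
#'   published Brassica disease-resistance QTL.
#' @return `data.frame` of QTL records.
#' @export
readQtlTable <- function(file = system.file("extdata",
                                            "brassica_qtl_intervals.csv",
                                            package = "rgascape")) {
  qtl <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("qtl_name", "species", "disease", "chromosome", "start", "end")
  if (!all(need %in% colnames(qtl)))
    stop("QTL table must have columns ", paste(need, collapse = ", "))
  qtl$start <- as.integer(qtl$start)
  qtl$end <- as.integer(qtl$end)
  bad <- setdiff(qtl$disease, QTL_DISEASE_CODES)
  if (length(bad))
    stop("unknown disease code(s): ", paste(bad, collapse = ", "))
  if (any(qtl$start > qtl$end))
    stop("QTL with start > end")
  qtl[need]
}

#' Read a cloned R-gene catalogue
#'
#' CSV with columns `r_gene_id` and `diseases` (semicolon-separated
#' disease codes). The packaged default is a synthetic stand-in for the
#' published 49-gene catalogue: entries named in the source literature
#' carry their reported disease associations, the remainder are
#' synthetic placeholders (see the file header).
#'
#' @param file path to the catalogue CSV
#' @return `data.frame` with columns `r_gene_id` (character) and
#'   `diseases` (list of character vectors).
#' @export
readRGeneCatalog <- function(file = system.file("extdata",
                                                "cloned_r_genes_synthetic.csv",
                                                package = "rgascape")) {
  cat <- read.csv(file, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("r_gene_id", "diseases") %in% colnames(cat)))
    stop("catalogue must have r_gene_id and diseases columns")
  dis <- strsplit(cat$diseases, ";", fixed = TRUE)
  dis <- lapply(dis, trimws)
  if (any(lengths(dis) == 0))
    stop("every R gene needs at least one disease code")
  bad <- setdiff(unlist(dis), R_GENE_DISEASE_CODES)
  if (length(bad))
    stop("unknown disease code(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(cat$r_gene_id))
    stop("duplicated R-gene ids in catalogue")
  data.frame(r_gene_id = cat$r_gene_id,
             diseases = I(dis))
}

#' Published per-chromosome RGA count tables
#'
#' The per-chromosome, per-class RGA counts reported for the three
#' Brassicaceae study genomes (B. nigra, S. arvensis, S. alba), packaged
#' as a fixture for the landscape statistics. `position_mbp` is the
#' chromosome size in Mbp (`NA` for contigs).
#'
#' @param species optional species name to subset to
#' @return `data.frame` with one row per chromosome/contig.
#' @export
readPublishedCounts <- function(species = NULL) {
  path <- system.file("extdata", "rga_counts_published.csv",
                      package = "rgascape")
  tab <- read.csv(path, stringsAsFactors = FALSE)
  tab$is_contig <- as.logical(tab$is_contig)
  if (!is.null(species)) {
    tab <- tab[tab$species == species, , drop = FALSE]
    if (!nrow(tab)) stop("unknown species: ", species)
  }
  tab
}

#' Published genome summaries
#'
#' Genome-level figures for the three study genomes: total gene counts,
#' chromosome and contig numbers, approximate assembly size.
#'
#' @return `data.frame`, one row per species.
#' @export
readGenomeSummary <- function() {
  path <- system.file("extdata", "genome_summary_published.csv",
                      package = "rgascape")
  read.csv(path, stringsAsFactors = FALSE)
}
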