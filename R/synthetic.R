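# canonical domain set planted for each synthetic class label; by
# construction the classifier's decision table inverts this exactly
PLANTED_DOMAIN_SETS <- list(
  "LRR-RLK"   = c("TM", "KINASE", "LRR"),
  "LysM-RLK"  = c("TM", "KINASE", "LYSM"),
  "OTHER-RLK" = c("TM", "KINASE"),
  "LRR-RLP"   = c("TM", "LRR"),
  "LysM-RLP"  = c("TM", "LYSM"),
  "OTHER-RLP" = c("TM", "OTHER_ECTO"),
  "TM-CC"     = c("TM", "CC"),
  "TNL"       = c("TIR", "NBARC", "LRR"),
  "CNL"       = c("CC", "NBARC", "LRR"),
  "RNL"       = c("NBARC", "LRR", "RPW8"),
  "TX"        = c("TIR"),
  "TN"        = c("TIR", "NBARC"),
  "NL"        = c("NBARC", "LRR"),
  "RN"        = c("NBARC", "RPW8"),
  "CN"        = c("CC", "NBARC"),
  "OTHER"     = c("TIR", "NBARC", "LRR", "RPW8"),
  "RPW8"      = c("RPW8"))

PLANTED_EXPECTED <- list(
  "LRR-RLK"   = c("RLK",  "none", "LRR"),
  "LysM-RLK"  = c("RLK",  "none", "LYSM"),
  "OTHER-RLK" = c("RLK",  "none", "OTHER_RECEPTOR"),
  "LRR-RLP"   = c("RLP",  "none", "LRR"),
  "LysM-RLP"  = c("RLP",  "none", "LYSM"),
  "OTHER-RLP" = c("RLP",  "none", "OTHER_RECEPTOR"),
  "TM-CC"     = c("TMCC", "none", "none"),
  "TNL"       = c("NLR",  "TNL",  "none"),
  "CNL"       = c("NLR",  "CNL",  "none"),
  "RNL"       = c("NLR",  "RNL",  "none"),
  "TX"        = c("NLR",  "TX",   "none"),
  "TN"        = c("NLR",  "TN",   "none"),
  "NL"        = c("NLR",  "NL",   "none"),
  "RN"        = c("NLR",  "RN",   "none"),
  "CN"        = c("NLR",  "CN",   "none"),
  "OTHER"     = c("NLR",  "OTHER", "none"),
  "RPW8"      = c("RPW8", "none", "none"))

PLANTED_SUPERFAMILY <- c(
  "LRR-RLK" = "TM-LRR", "LysM-RLK" = "TM-LRR", "OTHER-RLK" = "TM-LRR",
  "LRR-RLP" = "TM-LRR", "LysM-RLP" = "TM-LRR", "OTHER-RLP" = "TM-LRR",
  "TM-CC" = "TM-CC", "TNL" = "NLR", "CNL" = "NLR", "RNL" = "NLR",
  "TX" = "NLR", "TN" = "NLR", "NL" = "NLR", "RN" = "NLR", "CN" = "NLR",
  "OTHER" = "NLR", "RPW8" = "RPW8")

# class composition of the B. nigra study genome (per-class totals of the
# published count table), used as the default planted proportions
default_class_proportions <- function() {
  counts <- c("LRR-RLK" = 325, "LysM-RLK" = 6, "OTHER-RLK" = 490,
              "LRR-RLP" = 162, "LysM-RLP" = 2, "TM-CC" = 272,
              "TNL" = 119, "CNL" = 37, "RNL" = 9, "TX" = 71, "TN" = 30,
              "NL" = 37, "RN" = 9, "CN" = 15, "OTHER" = 30, "RPW8" = 11)
  counts / sum(counts)
}

#' Synthetic species profile
#'
#' The study conditions for [generateGenome()]: chromosome sizes, the
#' class composition to plant (default: the B. nigra composition of the
#' published count table), the end-bias of RGA placement (positions are
#' drawn from a symmetric `Beta(alpha, alpha)` scaled to the chromosome,
#' `alpha = 0.5` concentrating mass at the chromosome ends), the
#' clusters to plant, and the number of non-RGA decoy genes.
#'
#' @param chromosome_lengths integer bp lengths, named or auto-named
#'   `Chr01..`; defaults to the study genome's eight chromosome sizes
#'   scaled 1:10 (5.1-7.4 Mbp) to keep simulated data small
#' @param n_rga number of RGA genes to plant (default 1000)
#' @param n_non_rga number of non-RGA genes (no domains or orphan
#'   single domains; default 200)
#' @param class_proportions named fractions over the planted class
#'   labels (must sum to 1)
#' @param end_bias_alpha Beta shape for RGA positions (> 0)
#' @param cluster_spec list of `list(chromosome, n_members, max_gap)`
#'   clusters to plant; members count towards `n_rga`
#' @param cluster_isolation_bp guard distance kept free of other genes
#'   around every planted cluster so that 10-kb ground truth stays well
#'   defined (default 25 kb)
#' @param n_rga_homologues,n_non_rga_homologues planted homologue pairs
#'   against the cloned R-gene catalogue
#' @param seed integer seed governing all randomness of the generator
#' @return A `speciesProfile` list, validated.
#' @export
speciesProfile <- function(chromosome_lengths = NULL,
                           n_rga = 1000, n_non_rga = 200,
                           class_proportions = default_class_proportions(),
                           end_bias_alpha = 0.5,
                           cluster_spec = NULL,
                           cluster_isolation_bp = 25000,
                           n_rga_homologues = 20,
                           n_non_rga_homologues = 5,
                           seed = 1) {
  if (is.null(chromosome_lengths))
    # the study genome's eight chromosome sizes, scaled 1:10 to keep
    # simulated coordinates small
    chromosome_lengths <- as.integer(round(1e5 *
      c(54.73, 73.74, 59.02, 51.41, 67.89, 61.87, 59.87, 71.98)))
  if (is.null(names(chromosome_lengths)))
    names(chromosome_lengths) <- sprintf("Chr%02d",
                                         seq_along(chromosome_lengths))
  if (is.null(cluster_spec))
    cluster_spec <- list(
      list(chromosome = names(chromosome_lengths)[1], n_members = 3L,
           max_gap = 5000L),
      list(chromosome = names(chromosome_lengths)[2], n_members = 4L,
           max_gap = 8000L),
      list(chromosome = names(chromosome_lengths)[min(3,
           length(chromosome_lengths))], n_members = 2L,
           max_gap = 10000L))
  bad <- setdiff(names(class_proportions), names(PLANTED_DOMAIN_SETS))
  if (length(bad))
    stop("unknown planted class label(s): ", paste(bad, collapse = ", "))
  if (abs(sum(class_proportions) - 1) > 1e-9)
    stop("class proportions must sum to 1")
  if (end_bias_alpha <= 0) stop("end_bias_alpha must be positive")
  for (cs in cluster_spec) {
    if (cs$max_gap < 0) stop("cluster max_gap must be non-negative")
    if (!cs$chromosome %in% names(chromosome_lengths))
      stop("cluster on unknown chromosome: ", cs$chromosome)
  }
  structure(list(chromosome_lengths = chromosome_lengths,
                 n_rga = as.integer(n_rga),
                 n_non_rga = as.integer(n_non_rga),
                 class_proportions = class_proportions,
                 end_bias_alpha = end_bias_alpha,
                 cluster_spec = cluster_spec,
                 cluster_isolation_bp = as.integer(cluster_isolation_bp),
                 n_rga_homologues = as.integer(n_rga_homologues),
                 n_non_rga_homologues = as.integer(n_non_rga_homologues),
                 seed = as.integer(seed)),
            class = "speciesProfile")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# superfamily consensus blocks drawn once per generator call, all derived
# from one ancestral block with 40% of positions resampled per
# superfamily: within-superfamily similarity stays well above
# between-superfamily, while cross-family distances remain finite (below
# the Jukes-Cantor saturation point)
superfamily_consensus <- function() {
  sfs <- c("TM-LRR", "NLR", "TM-CC", "RPW8")
  ancestor <- sample(AA20, 90, replace = TRUE)
  setNames(lapply(sfs, function(s) {
    cons <- ancestor
    flip <- sample.int(90, 36)
    cons[flip] <- sample(AA20, 36, replace = TRUE)
    cons
  }), sfs)
}

mutate_consensus <- function(cons, rate = 0.1) {
  flip <- runif(length(cons)) < rate
  cons[flip] <- sample(AA20, sum(flip), replace = TRUE)
  paste0(paste(cons, collapse = ""), random_protein(sample(10:30, 1)))
}

intersects_any <- function(s, e, zones) {
  if (!nrow(zones)) return(FALSE)
  any(s <= zones$end & e >= zones$start)
}

#' Generate a synthetic annotated genome with ground truth
#'
#' Emulates the statistical structure the characterisation assumes:
#' class composition planted from the profile's proportions (each gene
#' carrying exactly the canonical domain set of its class, so the
#' classifier's decision table inverts the planting), end-biased
#' `Beta(alpha, alpha)` gene placement, physical clusters with bounded
#' inter-gene gaps and an isolation guard zone, per-superfamily protein
#' motif blocks, planted homologue pairs against the cloned R-gene
#' catalogue, and non-RGA genes with no or orphan domains. Byte-identical
#' output for a given profile (one seed governs every draw).
#'
#' @param profile a [speciesProfile()]
#' @return An [RGAGenome-class]; the ground-truth manifest is stored in
#'   the object metadata and retrievable via [groundTruth()].
#' @export
generateGenome <- function(profile) {
  stopifnot(inherits(profile, "speciesProfile"))
  set.seed(profile$seed)
  lens <- profile$chromosome_lengths
  consensus <- superfamily_consensus()
  zones <- data.frame(chromosome = character(), start = integer(),
                      end = integer())
  gene_len <- function(n) as.integer(round(runif(n, 900, 3000)))

  rows <- list()
  labels <- character()
  clusters <- list()
  iso <- profile$cluster_isolation_bp

  # planted clusters first; members drawn from the class proportions
  draw_class <- function(n)
    sample(names(profile$class_proportions), n, replace = TRUE,
           prob = profile$class_proportions)
  gid <- 0L
  next_id <- function() {
    gid <<- gid + 1L
    sprintf("g%04d", gid)
  }
  for (ci in seq_along(profile$cluster_spec)) {
    cs <- profile$cluster_spec[[ci]]
    L <- lens[[cs$chromosome]]
    glens <- gene_len(cs$n_members)
    gaps <- as.integer(round(runif(cs$n_members - 1, 1, max(1, cs$max_gap))))
    need <- sum(glens) + sum(gaps)
    if (need + 2 * iso >= L)
      stop("cluster specification exceeds chromosome length on ",
           cs$chromosome)
    ch_zones <- zones[zones$chromosome == cs$chromosome, , drop = FALSE]
    for (try in seq_len(1000)) {
      anchor <- as.integer(round(runif(1, iso + 1, L - need - iso)))
      if (!intersects_any(anchor - iso, anchor + need + iso, ch_zones))
        break
      if (try == 1000) stop("could not place cluster ", ci)
    }
    starts <- anchor + cumsum(c(0L, glens[-cs$n_members] + gaps))
    ids <- vapply(seq_len(cs$n_members), function(i) next_id(), "")
    cls <- draw_class(cs$n_members)
    rows[[length(rows) + 1]] <- data.frame(
      gene_id = ids, chromosome = cs$chromosome,
      start = starts, end = starts + glens - 1L)
    labels[ids] <- cls
    clusters[[length(clusters) + 1]] <- ids
    zones <- rbind(zones, data.frame(
      chromosome = cs$chromosome,
      start = anchor - iso, end = anchor + need - 1L + iso))
  }
  n_clustered <- gid

  place_random <- function(n, end_biased) {
    out <- vector("list", n)
    chroms <- sample(names(lens), n, replace = TRUE, prob = lens)
    glens <- gene_len(n)
    for (i in seq_len(n)) {
      L <- lens[[chroms[i]]]
      ch_zones <- zones[zones$chromosome == chroms[i], , drop = FALSE]
      for (try in seq_len(1000)) {
        rel <- if (end_biased)
          rbeta(1, profile$end_bias_alpha, profile$end_bias_alpha)
        else runif(1)
        s <- 1L + as.integer(floor(rel * (L - glens[i])))
        e <- s + glens[i] - 1L
        if (!intersects_any(s, e, ch_zones)) break
        if (try == 1000) stop("placement rejection limit reached")
      }
      out[[i]] <- data.frame(chromosome = chroms[i], start = s, end = e)
    }
    do.call(rbind, out)
  }

  # remaining RGA genes, end-biased placement
  n_free <- profile$n_rga - n_clustered
  if (n_free < 0) stop("cluster members exceed n_rga")
  if (n_free > 0) {
    pos <- place_random(n_free, end_biased = TRUE)
    ids <- vapply(seq_len(n_free), function(i) next_id(), "")
    rows[[length(rows) + 1]] <- cbind(data.frame(gene_id = ids), pos)
    labels[ids] <- draw_class(n_free)
  }

  # non-RGA genes, uniform placement, no or orphan domains
  if (profile$n_non_rga > 0) {
    pos <- place_random(profile$n_non_rga, end_biased = FALSE)
    ids <- vapply(seq_len(profile$n_non_rga), function(i) next_id(), "")
    rows[[length(rows) + 1]] <- cbind(data.frame(gene_id = ids), pos)
    labels[ids] <- "non-RGA"
  }

  genes <- do.call(rbind, rows)

  # domain calls: canonical set per planted class; orphans for non-RGAs
  dom_rows <- list()
  orphan_pool <- list(character(), "KINASE", "LRR", "CC")
  for (i in seq_len(nrow(genes))) {
    id <- genes$gene_id[i]
    lab <- labels[[id]]
    doms <- if (lab == "non-RGA")
      orphan_pool[[sample.int(4, 1)]]
    else PLANTED_DOMAIN_SETS[[lab]]
    if (length(doms))
      dom_rows[[length(dom_rows) + 1]] <-
        data.frame(gene_id = id, domain = doms)
  }
  domains <- do.call(rbind, dom_rows)

  # proteins: superfamily motif blocks + noise; random for non-RGAs
  prot <- vapply(genes$gene_id, function(id) {
    lab <- labels[[id]]
    if (lab == "non-RGA") random_protein(sample(80:140, 1))
    else mutate_consensus(consensus[[PLANTED_SUPERFAMILY[[lab]]]])
  }, "")
  proteins <- AAStringSet(prot)
  names(proteins) <- genes$gene_id
  genes$protein_length <- nchar(prot)

  # planted homologue pairs against the packaged R-gene catalogue
  catalog <- readRGeneCatalog()
  rga_ids <- genes$gene_id[labels[genes$gene_id] != "non-RGA"]
  non_ids <- genes$gene_id[labels[genes$gene_id] == "non-RGA"]
  h_rga <- sample(rga_ids, min(profile$n_rga_homologues, length(rga_ids)))
  h_non <- sample(non_ids,
                  min(profile$n_non_rga_homologues, length(non_ids)))
  subj <- c(h_rga, h_non)
  n_h <- length(subj)
  homologues <- data.frame(
    query_id = sample(catalog$r_gene_id, n_h, replace = TRUE),
    subject_id = subj,
    evalue = c(0, 10^-runif(n_h - 1, 46, 180))[seq_len(n_h)],
    similarity_pct = round(runif(n_h, 60, 100), 1),
    aln_length_aa = sample(148:500, n_h, replace = TRUE),
    subject_is_rga = subj %in% h_rga)

  truth <- list(
    classes = labels,
    clusters = clusters,
    homologues = homologues,
    profile = profile)

  asm <- data.frame(name = names(lens), length_bp = unname(lens),
                    is_contig = FALSE)
  g <- RGAGenome(asm, genes, proteins = proteins, domains = domains)
  metadata(g@genes)$ground_truth <- truth
  g
}

#' Ground-truth manifest of a synthetic genome
#'
#' @param x an [RGAGenome-class] produced by [generateGenome()]
#' @return List with `classes` (gene -> planted class label, `"non-RGA"`
#'   for decoy genes), `clusters` (list of member-id vectors),
#'   `homologues` (planted hit rows) and the generating `profile`.
#' @export
groundTruth <- function(x) {
  gt <- metadata(x@genes)$ground_truth
  if (is.null(gt)) stop("no ground truth: not a synthetic genome")
  gt
}

#' Expected classification of planted genes
#'
#' The annotation the classifier must produce for each planted class
#' label; used for label-recovery checks.
#'
#' @param labels vector of planted class labels (as in
#'   `groundTruth(x)$classes`)
#' @return `data.frame` with `rga_class`, `nlr_subtype`,
#'   `receptor_subclass`, `superfamily` per input label (`NONE` rows for
#'   `"non-RGA"`... see Details).
#' @details Non-RGA genes may legitimately carry orphan domains; their
#'   expected class is `NONE`.
#' @export
plantedExpectation <- function(labels) {
  one <- function(lab) {
    if (lab == "non-RGA")
      return(c("NONE", "none", "none", "none"))
    c(PLANTED_EXPECTED[[lab]], PLANTED_SUPERFAMILY[[lab]])
  }
  m <- t(vapply(labels, one, character(4)))
  data.frame(rga_class = m[, 1], nlr_subtype = m[, 2],
             receptor_subclass = m[, 3], superfamily = m[, 4],
             row.names = NULL)
}

#' Simulate an alignment hit table with decoys
#'
#' Emits the planted homologue pairs of a synthetic genome (which pass
#' all three CDRH filters by construction) plus `n_decoys` decoy hits
#' that each violate exactly one named filter rule while satisfying the
#' other two.
#'
#' @param x synthetic [RGAGenome-class]
#' @param n_decoys number of decoy hits
#' @param seed integer seed
#' @return List with `hits` (planted rows first, then decoys) and
#'   `manifest` (`query_id`, `subject_id`, `planted`, `violated_rule`
#'   in `evalue`/`similarity`/`length`/`NA`).
#' @export
simulateHits <- function(x, n_decoys = 0, seed = 1) {
  gt <- groundTruth(x)
  set.seed(seed)
  planted <- gt$homologues
  catalog <- readRGeneCatalog()
  rules <- c("evalue", "similarity", "length")
  decoys <- NULL
  if (n_decoys > 0) {
    pool <- setdiff(geneIds(x), planted$subject_id)
    subj <- sample(pool, n_decoys, replace = n_decoys > length(pool))
    rule <- rules[(seq_len(n_decoys) - 1) %% 3 + 1]
    decoys <- data.frame(
      query_id = sample(catalog$r_gene_id, n_decoys, replace = TRUE),
      subject_id = subj,
      evalue = ifelse(rule == "evalue", 10^-runif(n_decoys, 1, 44),
                      10^-runif(n_decoys, 46, 180)),
      similarity_pct = round(ifelse(rule == "similarity",
                                    runif(n_decoys, 5, 59.5),
                                    runif(n_decoys, 60, 100)), 1),
      aln_length_aa = ifelse(rule == "length",
                             sample(20:147, n_decoys, replace = TRUE),
                             sample(148:400, n_decoys, replace = TRUE)),
      violated_rule = rule)
  }
  hits <- rbind(planted[, c("query_id", "subject_id", "evalue",
                            "similarity_pct", "aln_length_aa")],
                if (!is.null(decoys))
                  decoys[, c("query_id", "subject_id", "evalue",
                             "similarity_pct", "aln_length_aa")])
  manifest <- data.frame(
    query_id = hits$query_id,
    subject_id = hits$subject_id,
    planted = c(rep(TRUE, nrow(planted)),
                rep(FALSE, if (is.null(decoys)) 0 else nrow(decoys))),
    violated_rule = c(rep(NA_character_, nrow(planted)),
                      if (!is.null(decoys)) decoys$violated_rule))
  rownames(hits) <- rownames(manifest) <- NULL
  list(hits = hits, manifest = manifest)
}

#' Generate a random QTL set with containment ground truth
#'
#' Draws `n_qtl` intervals inside the assembly's chromosomes and records
#' for every (gene, QTL) pair whether the gene is fully contained, by a
#' direct brute-force coordinate check.
#'
#' @param x an [RGAGenome-class]
#' @param n_qtl number of intervals
#' @param seed integer seed
#' @return List with `qtls` (a QTL table) and `flags`
#'   (`gene_id`, `qtl_name`, `status`).
#' @export
generateQtlSet <- function(x, n_qtl = 10, seed = 1) {
  set.seed(seed)
  asm <- as.data.frame(assemblyInfo(x))
  if (!nrow(asm)) stop("empty assembly")
  ch <- sample(asm$name, n_qtl, replace = TRUE)
  len <- asm$length_bp[match(ch, asm$name)]
  width <- as.integer(round(runif(n_qtl, 0.02, 0.2) * len))
  start <- as.integer(floor(runif(n_qtl, 1, len - width)))
  qtls <- data.frame(
    qtl_name = sprintf("QTL%02d", seq_len(n_qtl)),
    species = "synthetic",
    disease = sample(QTL_DISEASE_CODES, n_qtl, replace = TRUE),
    chromosome = ch, start = start, end = start + width)
  gr <- geneRanges(x)
  gchrom <- as.character(seqnames(gr))
  flags <- do.call(rbind, lapply(seq_len(n_qtl), function(i) {
    data.frame(gene_id = names(gr), qtl_name = qtls$qtl_name[i],
               status = withinQtl(gchrom, start(gr), end(gr),
                                  qtls$chromosome[i], qtls$start[i],
                                  qtls$end[i]))
  }))
  list(qtls = qtls, flags = flags)
}
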