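#' Read a declarative run configuration
#'
#' YAML key-value configuration for [runPipeline()]. Recognised keys
#' (all optional unless noted):
#'
#' * `mode`: `"files"` (read `gff3`, `domains`, optional `fasta`) or
#'   `"synthetic"` (generate a genome; `seed`, `n_rga`, `n_non_rga`,
#'   `end_bias_alpha` feed [speciesProfile()]).
#' * `out_dir` (required): where stage outputs and `summary.json` go.
#' * thresholds: `cluster_gap_bp` (default 10000), `e_max` (1e-45),
#'   `sim_min` (60), `len_min_aa` (148), `window_bp` (1e6).
#' * `dendrogram_k` (default 4), `similarity_n_max` (default 40; the
#'   pairwise-alignment stage is quadratic, so it runs on at most this
#'   many sequences), `bootstrap_reps` (default 100), `phylo_n_max`
#'   (default 12), `seed`.
#' * `qtl_table`: CSV path (default: packaged published intervals);
#'   `chrom_map`: named map of QTL chromosome labels to assembly names.
#' * `hits`: optional hit-table path; in synthetic mode hits are
#'   simulated with `n_decoy_hits` (default 30) decoys.
#' * `contig_pattern` (default `"^Chr"`).
#'
#' @param file YAML path
#' @return A validated config list (class `rgaRunConfig`).
#' @export
readRunConfig <- function(file) {
  if (!file.exists(file)) stop("config file not found: ", file)
  cfg <- yaml::read_yaml(file)
  asRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a named list of configuration values (same keys)
#' @export
asRunConfig <- function(cfg) {
  defaults <- list(mode = "synthetic", seed = 1L,
                   n_rga = 300L, n_non_rga = 60L,
                   end_bias_alpha = 0.5,
                   cluster_gap_bp = 10000, e_max = 1e-45, sim_min = 60,
                   len_min_aa = 148, window_bp = 1e6,
                   dendrogram_k = 4L, similarity_n_max = 40L,
                   bootstrap_reps = 100L, phylo_n_max = 12L,
                   n_decoy_hits = 30L, contig_pattern = "^Chr",
                   qtl_table = NULL, chrom_map = NULL, hits = NULL,
                   gff3 = NULL, domains = NULL, fasta = NULL,
                   out_dir = NULL)
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  if (!cfg$mode %in% c("files", "synthetic"))
    stop("mode must be 'files' or 'synthetic'")
  stopifnot(cfg$cluster_gap_bp >= 0, cfg$e_max > 0,
            cfg$sim_min >= 0, cfg$sim_min <= 100, cfg$len_min_aa >= 1,
            cfg$window_bp > 0, cfg$bootstrap_reps >= 1)
  if (cfg$mode == "files") {
    for (key in c("gff3", "domains")) {
      if (is.null(cfg[[key]]))
        stop("mode 'files' requires the ", key, " path")
      if (!file.exists(cfg[[key]]))
        stop("input file not found: ", cfg[[key]])
    }
  }
  structure(cfg, class = "rgaRunConfig")
}

#' Run the full characterisation pipeline
#'
#' Executes every stage on one genome: classification and count table,
#' landscape statistics and positional profile, physical clustering
#' (all RGAs and per family), sequence-similarity dendrogram clusters,
#' CDRH and non-RGA homologue maps with disease rollup, QTL
#' co-localisation of RLKs/RLPs, and a bootstrapped UPGMA tree of a
#' sequence subset. Stage outputs are written as TSV/CSV/Newick under
#' `out_dir`, and the headline statistics are collected into
#' `summary.json` (deterministic for a given config).
#'
#' @param config an `rgaRunConfig` ([readRunConfig()]/[asRunConfig()])
#' @return The summary list, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "rgaRunConfig")) config <- asRunConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  log_lines <- character()
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " [info] ", ...)
    log_lines <<- c(log_lines, line)
  }

  say("loading inputs (mode=", config$mode, ")")
  if (config$mode == "synthetic") {
    profile <- speciesProfile(n_rga = config$n_rga,
                              n_non_rga = config$n_non_rga,
                              end_bias_alpha = config$end_bias_alpha,
                              seed = config$seed)
    genome <- generateGenome(profile)
  } else {
    genome <- readAnnotation(config$gff3, config$domains,
                             fasta_file = config$fasta,
                             contig_pattern = config$contig_pattern)
  }

  say("classifying ", length(geneRanges(genome)), " genes")
  ann <- classifyGenome(genome)
  counts <- rgaCountTable(ann, genome)
  write.table(ann, out("classification.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.csv(counts, out("count_table.csv"), row.names = FALSE)

  say("landscape statistics")
  summary_land <- summariseLandscape(counts, length(geneRanges(genome)))
  profile_pos <- positionalProfile(genome, ann,
                                   window_bp = config$window_bp)
  write.csv(profile_pos$windows, out("window_profile.csv"),
            row.names = FALSE)
  chrom_rows <- summary_land$per_row
  chrom_sizes <- counts$position_mbp[!counts$is_contig &
                                       counts$chromosome != "Total"]
  regression <- if (nrow(chrom_rows) >= 3 &&
                    length(unique(chrom_sizes)) > 1)
    sizeCountRegression(chrom_sizes, chrom_rows$rga_count)
  else NULL

  say("physical clustering at ", config$cluster_gap_bp, " bp")
  rga_ids <- ann$gene_id[ann$rga_class != "NONE"]
  phys <- physicalClusters(genome, threshold_bp = config$cluster_gap_bp,
                           gene_ids = rga_ids, annotations = ann)
  fam_phys <- lapply(rgaFamilies(ann), function(ids)
    physicalClusters(genome, threshold_bp = config$cluster_gap_bp,
                     gene_ids = ids))
  cl_tab <- phys$clusters
  cl_tab$members <- vapply(cl_tab$members, paste, "", collapse = ";")
  write.table(cl_tab, out("physical_clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  say("similarity dendrogram")
  sim_clusters <- NULL
  prot <- proteinSeqs(genome)
  prot <- prot[intersect(names(prot), rga_ids)]
  if (length(prot) >= max(2, config$dendrogram_k)) {
    if (length(prot) > config$similarity_n_max) {
      set.seed(config$seed)
      prot <- prot[sort(sample.int(length(prot),
                                   config$similarity_n_max))]
    }
    sim <- pairwiseSimilarity(prot)
    sim_clusters <- dendrogramClusters(sim, k = config$dendrogram_k,
                                       annotations = ann)
    write.csv(data.frame(gene_id = names(sim_clusters$assignment),
                         cluster = sim_clusters$assignment),
              out("similarity_clusters.csv"), row.names = FALSE)
  }

  say("homology filtering")
  catalog <- readRGeneCatalog()
  hits <- if (!is.null(config$hits)) readHits(config$hits)
  else if (config$mode == "synthetic")
    simulateHits(genome, n_decoys = config$n_decoy_hits,
                 seed = config$seed)$hits
  else NULL
  homology <- NULL
  if (!is.null(hits)) {
    kept <- filterHits(hits, e_max = config$e_max,
                       sim_min = config$sim_min,
                       len_min_aa = config$len_min_aa)
    cdrh <- cdrhMap(kept, ann, catalog)
    nonrga <- nonRgaHomologues(kept, ann, catalog)
    rollup <- diseaseRollup(cdrh$records, catalog)
    rec <- cdrh$records
    rec$matched_r_genes <- vapply(rec$matched_r_genes, paste, "",
                                  collapse = ";")
    rec$diseases <- vapply(rec$diseases, paste, "", collapse = ";")
    write.table(rec, out("cdrh.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    homology <- list(n_hits = nrow(hits), n_kept = nrow(kept),
                     cdrh = cdrh$summary[c("n_cdrh",
                                           "n_r_genes_with_homologue",
                                           "n_multi_match_cdrh")],
                     non_rga = nonrga$summary[c("n_cdrh",
                                                "n_r_genes_with_homologue")],
                     disease_rollup = as.list(rollup))
  }

  say("QTL co-localisation")
  qtls <- if (!is.null(config$qtl_table)) readQtlTable(config$qtl_table)
  else if (config$mode == "synthetic")
    generateQtlSet(genome, n_qtl = 10, seed = config$seed)$qtls
  else readQtlTable()
  coloc <- withCallingHandlers(
    colocaliseGenes(genome, ann, qtls,
                    chrom_map = unlist(config$chrom_map)),
    warning = function(w) {
      say("warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  write.csv(coloc$per_qtl, out("qtl_counts.csv"), row.names = FALSE)

  say("phylogenetics")
  tree_info <- NULL
  if (length(prot) >= 3) {
    set.seed(config$seed)
    take <- prot[sort(sample.int(length(prot),
                                 min(config$phylo_n_max, length(prot))))]
    # equal-length alignment by padding (sequences here are unaligned;
    # a real run supplies a pre-aligned FASTA)
    L <- max(width(take))
    aligned <- vapply(as.character(take), function(s)
      paste0(s, strrep("-", L - nchar(s))), "")
    names(aligned) <- names(take)
    tree <- suppressWarnings(
      bootstrapSupports(aligned, n_reps = config$bootstrap_reps,
                        seed = config$seed))
    toNewick(tree, out("tree.nwk"))
    tree_info <- list(n_leaves = length(take),
                      n_replicates_used = tree$n_replicates_used,
                      mean_support = mean(tree$supports))
  }

  summary <- list(
    seed = config$seed,
    mode = config$mode,
    n_genes = length(geneRanges(genome)),
    n_rga = summary_land$total_rgas,
    pct_of_genes = summary_land$pct_of_genes,
    mean_per_chromosome = summary_land$mean_per_chromosome,
    typical_nlr = summary_land$typical_nlr,
    atypical_nlr = summary_land$atypical_nlr,
    end_bias_fraction = profile_pos$end_bias_fraction,
    regression = regression,
    n_physical_clusters = nrow(phys$clusters),
    n_clustered_genes = length(phys$clustered_genes),
    clusters_per_family = lapply(fam_phys, function(f)
      length(f$clustered_genes)),
    similarity_k = if (is.null(sim_clusters)) NULL else
      length(unique(sim_clusters$assignment)),
    homology = homology,
    coloc_in_any_qtl = as.list(coloc$in_any_qtl),
    coloc_tested = as.list(coloc$tested),
    tree = tree_info)
  write_json(summary, out("summary.json"), auto_unbox = TRUE,
             digits = NA, pretty = TRUE, null = "null")
  writeLines(log_lines, out("run.log"))
  invisible(summary)
}
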