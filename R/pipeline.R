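## End-to-end orchestration: genome filtering -> architecture resolution
## -> Rosetta-stone screening -> MCL clustering -> classification, with
## TSV/JSON reports and a per-stage log.

#' Pipeline configuration
#'
#' All thresholds of the pipeline with their method defaults: synteny gap
#' 5 genes, identity 25%, E-value 1e-9, split and composite coverage
#' 0.60, pairwise overlap 100 aa, MCL inflation 1.2 with subclustering at
#' 1.6 below 40% inter-cluster identity, split-set frequency cutoffs
#' 0.1 (fission) / 0.9 (fusion), bacterial criteria >2 phyla or >=1000
#' genomes, KO E-value 1e-10, genome redundancy cutoff 0.10.
#'
#' @param ... overrides for any default field.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    max_gene_sep = 5, min_identity = 25, max_evalue = 1e-9,
    min_split_cov = 0.60, min_composite_cov = 0.60,
    max_pair_overlap = 100,
    inflation = 1.2, sub_inflation = 1.6, max_inter_identity = 40,
    cluster_size_threshold = 10, identity_floor = 25,
    freq_fission = 0.1, freq_fusion = 0.9,
    bact_phyla = 2, bact_genomes = 1000,
    ko_evalue = 1e-10, ko_full = 0.8, ko_half = 0.6, both_frac = 0.2,
    max_redundancy = 0.10, default_completeness = 0.7,
    max_token_overlap = 15, min_bitscore = 0,
    seed = 1)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "pipeline_config")
}

#' Load a dataset directory
#'
#' Reads the file layout written by [write_synthetic_dataset()]:
#' `proteins.faa`, `genes.tsv`, `domains.tsv`, and optionally
#' `clans.tsv`, `ko.tsv`, `genomes.tsv`, `truth.tsv`.
#'
#' @param dir dataset directory.
#' @return list with the in-memory tables.
#' @export
load_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  opt <- function(f, reader) if (file.exists(p(f))) reader(p(f)) else NULL
  aa <- Biostrings::readAAStringSet(p("proteins.faa"))
  seqs <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
  list(genes = read_gene_table(p("genes.tsv"), "flat_tsv"),
       proteins = seqs,
       domain_hits = read_domain_table(p("domains.tsv")),
       clans = opt("clans.tsv", read_clan_table),
       ko = opt("ko.tsv", read_ko_table),
       metas = opt("genomes.tsv", read_genome_meta),
       truth = opt("truth.tsv", function(f)
         utils::read.delim(f, stringsAsFactors = FALSE)))
}

#' Run the full fusion/fission screening pipeline
#'
#' Executes genome filtering, architecture resolution, composite
#' candidate detection, split-set enumeration, synteny testing, alignment
#' filtering, family assembly, MCL clustering with subclustering, and
#' classification.  When `out_dir` is given, writes `families.tsv`,
#' `members.tsv`, `clusters.tsv`, `classification.tsv`, `summary.json`
#' and `log.txt`.
#'
#' @param dataset list with `genes`, `proteins`, `domain_hits`, and
#'   optionally `clans`, `ko`, `metas` (see [load_dataset()]).
#' @param config a [pipeline_config()].
#' @param alignments optional external alignment table
#'   ([read_tabular_alignments()] output); pairs it covers take
#'   precedence over the internal aligner.
#' @param bacterial_map optional bacterial mapping data.frame (columns
#'   `cluster_id`, `genome_id`, `phylum`).
#' @param out_dir optional output directory.
#' @return list with `families`, `screen`, `clustering`,
#'   `classification`, `tables`, `summary`, `log`.
#' @export
run_screen <- function(dataset, config = pipeline_config(),
                       alignments = NULL, bacterial_map = NULL,
                       out_dir = NULL) {
  stopifnot(is.list(dataset), !is.null(dataset$genes),
            !is.null(dataset$proteins), !is.null(dataset$domain_hits))
  set.seed(config$seed)
  log_lines <- c(sprintf("fusefission run (%s)", utils::packageVersion("fusefission")),
                 "thresholds:",
                 vapply(names(unclass(config)), function(k)
                   sprintf("  %s = %s", k, format(config[[k]])), ""))
  genes <- dataset$genes

  ## stage 1: genome filtering
  if (!is.null(dataset$metas)) {
    kept <- filter_genomes(dataset$metas,
                           max_redundancy = config$max_redundancy,
                           default_completeness = config$default_completeness)
    if (!length(kept)) stop("no genomes after filtering", call. = FALSE)
    genes <- genes[genes$genome_id %in% kept, , drop = FALSE]
    log_lines <- c(log_lines,
                   sprintf("genomes retained: %d / %d", length(kept),
                           nrow(dataset$metas)))
  }
  seqs <- dataset$proteins[names(dataset$proteins) %in% genes$protein_id]
  hits <- dataset$domain_hits[
    dataset$domain_hits$protein_id %in% genes$protein_id, , drop = FALSE]

  ## stage 2: architectures
  archs <- resolve_architectures(hits, clans = dataset$clans,
                                 min_bitscore = config$min_bitscore,
                                 max_token_overlap = config$max_token_overlap)
  log_lines <- c(log_lines,
                 sprintf("proteins with architectures: %d", length(archs)))

  ## stage 3: Rosetta-stone screening
  screen <- screen_families(
    archs, genes, alignments = alignments, seqs = seqs,
    max_gene_sep = config$max_gene_sep,
    min_identity = config$min_identity, max_evalue = config$max_evalue,
    min_split_cov = config$min_split_cov,
    max_pair_overlap = config$max_pair_overlap,
    min_composite_cov = config$min_composite_cov)
  families <- screen$families
  log_lines <- c(log_lines, "screening stage counts:",
                 sprintf("  %s = %d", names(screen$stage_counts),
                         screen$stage_counts))

  ## stage 4: clustering
  ko_retained <- ko_accept_all(dataset$ko, max_evalue = config$ko_evalue)
  annotations <- if (!is.null(ko_retained))
    setNames(ko_retained$ko_id, ko_retained$protein_id) else NULL
  clustering <- cluster_composites(
    families, seqs, annotations = annotations,
    inflation = config$inflation, floor = config$identity_floor,
    size_threshold = config$cluster_size_threshold,
    sub_inflation = config$sub_inflation,
    max_inter_identity = config$max_inter_identity)
  if (!is.null(clustering$assignments)) {
    cluster_of <- setNames(
      ifelse(is.na(clustering$assignments$subcluster_id),
             clustering$assignments$cluster_id,
             clustering$assignments$subcluster_id),
      clustering$assignments$protein_id)
    for (i in seq_along(families)) {
      cl <- unique(cluster_of[families[[i]]$composite_ids])
      families[[i]]$cluster_id <- paste(sort(cl), collapse = ",")
    }
  }
  n_singletons <- if (is.null(clustering$assignments)) 0L else
    sum(vapply(clustering$clusters, length, 0L) == 1)
  log_lines <- c(log_lines,
                 sprintf("clusters: %d (%d singletons, excluded from classification)",
                         length(clustering$clusters), n_singletons))

  ## stage 5: classification
  classification <- classify_clusters(
    clustering, families, genes, metas = dataset$metas,
    bacterial_map = bacterial_map, ko_table = dataset$ko,
    thresholds = list(freq_fission = config$freq_fission,
                      freq_fusion = config$freq_fusion,
                      bact_phyla = config$bact_phyla,
                      bact_genomes = config$bact_genomes,
                      ko_full = config$ko_full, ko_half = config$ko_half,
                      both_frac = config$both_frac),
    ko_evalue = config$ko_evalue)
  label_counts <- if (is.null(classification)) integer(0) else
    table(classification$label)
  log_lines <- c(log_lines,
                 sprintf("classified clusters: %d",
                         if (is.null(classification)) 0L
                         else nrow(classification)))

  tables <- families_to_tables(families, genes)
  genome_of <- setNames(genes$genome_id, genes$protein_id)
  comp_ids <- unique(unlist(lapply(families, `[[`, "composite_ids")))
  per_genome <- table(genome_of[comp_ids])
  summary <- list(
    n_families = length(families),
    n_clusters = length(clustering$clusters),
    n_singletons = n_singletons,
    label_counts = as.list(setNames(as.integer(label_counts),
                                    names(label_counts))),
    composites_per_genome = as.list(setNames(as.integer(per_genome),
                                             names(per_genome))))

  result <- list(families = families, screen = screen,
                 clustering = clustering,
                 classification = classification, tables = tables,
                 summary = summary, log = log_lines)
  if (!is.null(out_dir)) write_report_bundle(result, out_dir)
  result
}

write_report_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) {
    if (!is.null(df))
      utils::write.table(df, file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  wt(result$tables$families, "families.tsv")
  wt(result$tables$members, "members.tsv")
  wt(result$clustering$assignments, "clusters.tsv")
  wt(result$classification, "classification.tsv")
  jsonlite::write_json(result$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(result$log, file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' Generate a synthetic dataset (pipeline wrapper)
#'
#' Thin wrapper over [generate_synthetic_dataset()] for CLI symmetry.
#'
#' @param config a [synth_config()].
#' @param out_dir dataset directory to write.
#' @return the dataset list, invisibly.
#' @export
run_simulate <- function(config = synth_config(), out_dir) {
  invisible(generate_synthetic_dataset(config, dir = out_dir))
}

#' Re-classify from an intermediate statistics table
#'
#' Applies the classification vote to a table of per-cluster statistics
#' (the stat columns of `classification.tsv`), reproducing labels from
#' intermediate tables alone.
#'
#' @param stats_table data.frame with columns `cluster_id`,
#'   `split_set_freq`, `n_bact_phyla`, `n_bact_genomes`,
#'   `complete_genomes_composite`, `complete_genomes_split_only`,
#'   `median_ko_cov_composite`, `median_ko_cov_split`,
#'   `frac_composites_also_split`.
#' @param thresholds see [classify_thresholds()].
#' @return data.frame `cluster_id`, `label`, `V1`..`V4`.
#' @export
run_classify_only <- function(stats_table,
                              thresholds = classify_thresholds()) {
  need <- c("cluster_id", "split_set_freq", "n_bact_phyla",
            "n_bact_genomes", "complete_genomes_composite",
            "complete_genomes_split_only", "median_ko_cov_composite",
            "median_ko_cov_split", "frac_composites_also_split")
  miss <- setdiff(need, names(stats_table))
  if (length(miss))
    stop("missing column: ", paste(miss, collapse = ", "), call. = FALSE)
  rows <- lapply(seq_len(nrow(stats_table)), function(i) {
    r <- stats_table[i, ]
    stats <- list(split_set_freq = r$split_set_freq,
                  n_bact_phyla_with_composite = r$n_bact_phyla,
                  n_bact_genomes_with_composite = r$n_bact_genomes,
                  n_bact_phyla_min2 = NA_integer_,
                  complete_genomes_composite = r$complete_genomes_composite,
                  complete_genomes_split_only = r$complete_genomes_split_only,
                  median_ko_cov_composite = r$median_ko_cov_composite,
                  median_ko_cov_split = r$median_ko_cov_split,
                  frac_composites_also_split = r$frac_composites_also_split)
    res <- classify(stats, thresholds)
    data.frame(cluster_id = r$cluster_id, label = res$label,
               V1 = res$votes[["V1"]], V2 = res$votes[["V2"]],
               V3 = res$votes[["V3"]], V4 = res$votes[["V4"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Map a bacterial proteome onto archaeal clusters
#'
#' Applies [map_bacterial()] to every bacterial protein and joins genome
#' and phylum metadata, producing the table [compute_stats()] consumes.
#'
#' @param bact_architectures named list of bacterial architectures (or
#'   signatures).
#' @param bact_alignments alignment table, bacterial proteins as queries
#'   against archaeal proteins.
#' @param families archaeal family list (provides composite signatures).
#' @param assignments cluster assignment data.frame from
#'   [cluster_composites()].
#' @param bact_genome_of named vector protein -> genome.
#' @param bact_phylum_of named vector genome -> phylum.
#' @return data.frame `bact_protein_id`, `outcome`, `cluster_id`,
#'   `subject_id`, `genome_id`, `phylum`.
#' @export
map_bacterial_all <- function(bact_architectures, bact_alignments,
                              families, assignments, bact_genome_of,
                              bact_phylum_of) {
  archaeal_sigs <- list()
  for (f in families)
    for (p in f$composite_ids) archaeal_sigs[[p]] <- f$signature
  cluster_of <- setNames(assignments$cluster_id, assignments$protein_id)
  sigs <- lapply(bact_architectures, function(a)
    if (is.data.frame(a)) signature(a) else a)
  by_query <- split(bact_alignments, bact_alignments$query_id)
  rows <- lapply(sort(names(sigs)), function(pid) {
    res <- map_bacterial(by_query[[pid]], sigs[[pid]], archaeal_sigs,
                         cluster_of)
    g <- unname(bact_genome_of[pid])
    data.frame(bact_protein_id = pid, outcome = res$outcome,
               cluster_id = res$cluster_id, subject_id = res$subject_id,
               genome_id = g,
               phylum = unname(bact_phylum_of[g]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
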