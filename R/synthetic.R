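## Deterministic synthetic genome sets with planted fusion, fission and
## technical-fission events, plus the matching domain/KO/metadata tables
## and a ground-truth table, so the entire pipeline is testable with no
## downloads and no external aligners.
##
## Evolution model: every domain has an ancestral block sequence; each
## genome's copy substitutes residues independently at a per-copy rate
## chosen so that the EXPECTED pairwise identity between two homologous
## copies equals target_identity (substitutions always change the
## residue; no indels by default, keeping identity arithmetic
## closed-form).  Domain hits are emitted from construction coordinates,
## KO assignments give composites full model coverage and split proteins
## half, and syntenic split genes are placed at consecutive gene ranks.

#' Synthetic dataset configuration
#'
#' Defaults are the study conditions of the package's benchmark: 30
#' genomes, 40 planted fusion families, 20 planted fission families,
#' pairwise identity 0.7, 3 promiscuous distractor domains, and one fifth
#' of genomes flagged as fragmented (contig-level) assemblies.
#'
#' Fusion events (recent gene merging) plant the composite in 2 genomes
#' and syntenic split pairs in 19, so the syntenic split-set frequency
#' 19/21 exceeds the 0.9 fusion cutoff; fission events reverse the
#' proportions (10 composites, 1 syntenic split pair, frequency 1/11).
#' Technical fissions place the split pair only in fragmented genomes.
#'
#' @param seed integer RNG seed; the generator is a pure function of the
#'   configuration.
#' @param n_genomes number of genomes.
#' @param n_contigs_per_genome contigs per genome (planted events always
#'   stay on one contig).
#' @param n_background_families single-domain families padding each
#'   genome.
#' @param n_planted_fusion_families,n_planted_fission_families planted
#'   event counts.
#' @param frac_technical_fission technical fissions as a fraction of all
#'   planted fusion+fission events.
#' @param promiscuous_domain_count distractor domains appended to
#'   unrelated background proteins (composite candidates that must not
#'   become families).
#' @param target_identity expected pairwise identity between homologous
#'   copies, in (0, 1].
#' @param domain_length_range two integers, min/max domain length in aa.
#' @param fragmented_genome_fraction fraction of genomes flagged
#'   `assembly_level = "contig"`.
#' @param fusion_composite_genomes,fusion_split_genomes,fission_composite_genomes,fission_split_genomes
#'   genomes carrying each state per planted event.
#' @param n_nonsyntenic_fusion_sets fusion families that additionally get
#'   a far-apart (non-syntenic) split pair in one extra genome.
#' @param clan_mapped_fusion_families fusion families whose split-state
#'   domains carry a different accession mapped to the same Pfam clan
#'   (exercising clan-level matching).
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1, n_genomes = 30,
                         n_contigs_per_genome = 1,
                         n_background_families = 30,
                         n_planted_fusion_families = 40,
                         n_planted_fission_families = 20,
                         frac_technical_fission = 0.1,
                         promiscuous_domain_count = 3,
                         target_identity = 0.7,
                         domain_length_range = c(60, 120),
                         fragmented_genome_fraction = 0.2,
                         fusion_composite_genomes = 2,
                         fusion_split_genomes = 19,
                         fission_composite_genomes = 10,
                         fission_split_genomes = 1,
                         n_nonsyntenic_fusion_sets = 3,
                         clan_mapped_fusion_families = 3) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genomes >= 1, cfg$target_identity > 0,
            cfg$target_identity <= 1,
            length(cfg$domain_length_range) == 2,
            cfg$domain_length_range[1] >= 5,
            cfg$domain_length_range[1] <= cfg$domain_length_range[2])
  n_events <- cfg$n_planted_fusion_families + cfg$n_planted_fission_families
  if (n_events > 0 && cfg$n_genomes <
      max(cfg$fusion_composite_genomes + cfg$fusion_split_genomes,
          cfg$fission_composite_genomes + cfg$fission_split_genomes))
    stop("not enough genomes to host the planted events", call. = FALSE)
  cfg$n_technical <- round(cfg$frac_technical_fission * n_events)
  n_frag <- round(cfg$fragmented_genome_fraction * cfg$n_genomes)
  if (cfg$n_technical > 0 && n_frag < 2)
    stop("technical fissions need at least two fragmented genomes",
         call. = FALSE)
  structure(cfg, class = "synth_config")
}

## substitution rate per copy giving expected pairwise identity t:
## identity(q) = (1-q)^2 + q^2/19  (both copies mutate independently;
## two mutated sites coincide with probability 1/19)
substitution_rate <- function(t) {
  (19 / 20) * (1 - sqrt(1 - (20 / 19) * (1 - t)))
}

rand_aa <- function(n) sample.int(20L, n, replace = TRUE)

mutate_codes <- function(codes, q) {
  hit <- which(stats::runif(length(codes)) < q)
  if (length(hit)) {
    r <- sample.int(19L, length(hit), replace = TRUE)
    codes[hit] <- r + (r >= codes[hit])  # uniform over the 19 others
  }
  codes
}

codes_to_seq <- function(codes) paste(AA_ALPHABET[codes], collapse = "")

#' Generate a synthetic dataset with planted events
#'
#' Produces gene tables, protein sequences, domain hits, a clan table, KO
#' assignments, genome metadata and a ground-truth table, all in memory;
#' optionally writes them to `dir` in exactly the formats the readers in
#' this package consume (see [write_synthetic_dataset()]).  Deterministic
#' given the configuration seed.
#'
#' @param config a [synth_config()].
#' @param dir optional output directory.
#' @return list with elements `genes`, `proteins` (named character vector
#'   of sequences), `domain_hits`, `clans`, `ko`, `metas`, `truth`,
#'   `config`.
#' @export
generate_synthetic_dataset <- function(config = synth_config(),
                                       dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  q <- substitution_rate(config$target_identity)
  genome_ids <- sprintf("G%03d", seq_len(config$n_genomes))
  n_frag <- round(config$fragmented_genome_fraction * config$n_genomes)
  fragmented <- sort(sample(genome_ids, n_frag))
  complete <- setdiff(genome_ids, fragmented)

  metas <- data.frame(
    genome_id = genome_ids,
    assembly_level = ifelse(genome_ids %in% fragmented, "contig",
                            "complete"),
    completeness = round(stats::runif(config$n_genomes, 0.9, 1.0), 3),
    redundancy = round(stats::runif(config$n_genomes, 0, 0.05), 3),
    taxon_path = paste0("Archaea;Phylum", 1 + (seq_along(genome_ids) %% 4),
                        ";Genus", seq_along(genome_ids)),
    stringsAsFactors = FALSE)

  new_domain <- local({
    counter <- 0L
    function() {
      counter <<- counter + 1L
      len <- sample(seq(config$domain_length_range[1],
                        config$domain_length_range[2]), 1)
      list(acc = sprintf("PF9%04d", counter), len = len,
           ancestral = rand_aa(len))
    }
  })

  proteins <- list()   # protein_id -> list(genome, domains=list(acc,len), codes list)
  units <- lapply(genome_ids, function(g) list())
  names(units) <- genome_ids
  tail_units <- lapply(genome_ids, function(g) list())  # far-apart placement
  names(tail_units) <- genome_ids
  clan_rows <- list()
  ko_rows <- list()
  truth_rows <- list()

  add_protein <- function(pid, genome, parts) {
    ## parts: list of list(acc, domain, variant_of) in order
    codes <- integer(0); doms <- list()
    for (p in parts) {
      block <- mutate_codes(p$domain$ancestral, q)
      doms[[length(doms) + 1L]] <- list(acc = p$acc, len = p$domain$len)
      codes <- c(codes, block)
    }
    proteins[[pid]] <<- list(genome = genome, domains = doms,
                             codes = codes)
    pid
  }

  add_ko <- function(pid, ko_id, coverage) {
    ko_rows[[length(ko_rows) + 1L]] <<- data.frame(
      protein_id = pid, ko_id = ko_id, bitscore = 500, evalue = 1e-50,
      model_threshold = 100, model_coverage = coverage,
      stringsAsFactors = FALSE)
  }

  plant_event <- function(tag, kind, comp_genomes, split_genomes,
                          clan_mapped = FALSE, nonsyn_genome = NULL) {
    dA <- new_domain(); dB <- new_domain()
    accA_split <- dA$acc; accB_split <- dB$acc
    tokA <- dA$acc; tokB <- dB$acc
    if (clan_mapped) {
      ## the split state carries sister accessions of the same clans
      accA_split <- sub("^PF9", "PF8", dA$acc)
      accB_split <- sub("^PF9", "PF8", dB$acc)
      clanA <- sub("^PF9", "CL0", dA$acc)
      clanB <- sub("^PF9", "CL0", dB$acc)
      clan_rows[[length(clan_rows) + 1L]] <<- data.frame(
        domain_acc = c(dA$acc, accA_split, dB$acc, accB_split),
        clan_acc = c(clanA, clanA, clanB, clanB),
        stringsAsFactors = FALSE)
      tokA <- clanA; tokB <- clanB
    }
    ko_id <- sprintf("K9%04d", length(truth_rows) + 1L)
    comp_ids <- character(0); split_ids <- character(0)
    for (g in comp_genomes) {
      pid <- sprintf("%s_%s_c", g, tag)
      add_protein(pid, g, list(list(acc = dA$acc, domain = dA),
                               list(acc = dB$acc, domain = dB)))
      units[[g]][[length(units[[g]]) + 1L]] <<- pid
      add_ko(pid, ko_id, 1.0)
      comp_ids <- c(comp_ids, pid)
    }
    for (g in split_genomes) {
      p1 <- sprintf("%s_%s_s1", g, tag)
      p2 <- sprintf("%s_%s_s2", g, tag)
      add_protein(p1, g, list(list(acc = accA_split, domain = dA)))
      add_protein(p2, g, list(list(acc = accB_split, domain = dB)))
      units[[g]][[length(units[[g]]) + 1L]] <<- c(p1, p2)  # adjacent genes
      add_ko(p1, ko_id, 0.5); add_ko(p2, ko_id, 0.5)
      split_ids <- c(split_ids, p1, p2)
    }
    if (!is.null(nonsyn_genome)) {
      g <- nonsyn_genome
      p1 <- sprintf("%s_%s_n1", g, tag)
      p2 <- sprintf("%s_%s_n2", g, tag)
      add_protein(p1, g, list(list(acc = accA_split, domain = dA)))
      add_protein(p2, g, list(list(acc = accB_split, domain = dB)))
      units[[g]][[length(units[[g]]) + 1L]] <<- p1
      tail_units[[g]][[length(tail_units[[g]]) + 1L]] <<- p2  # contig tail
      add_ko(p1, ko_id, 0.5); add_ko(p2, ko_id, 0.5)
    }
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      event_id = tag, kind = kind,
      signature = paste(tokA, tokB, sep = "|"),
      composite_genomes = paste(comp_genomes, collapse = ","),
      split_genomes = paste(split_genomes, collapse = ","),
      composite_ids = paste(comp_ids, collapse = ","),
      split_ids = paste(split_ids, collapse = ","),
      stringsAsFactors = FALSE)
  }

  ## planted fusions: few composites, many syntenic split pairs
  for (i in seq_len(config$n_planted_fusion_families)) {
    hosts <- sample(genome_ids,
                    config$fusion_composite_genomes +
                      config$fusion_split_genomes)
    comp_g <- hosts[seq_len(config$fusion_composite_genomes)]
    split_g <- setdiff(hosts, comp_g)
    nonsyn <- NULL
    if (i <= config$n_nonsyntenic_fusion_sets) {
      rest <- setdiff(genome_ids, hosts)
      if (length(rest)) nonsyn <- sample(rest, 1)
    }
    plant_event(sprintf("FUS%03d", i), "fusion", comp_g, split_g,
                clan_mapped = i <= config$clan_mapped_fusion_families,
                nonsyn_genome = nonsyn)
  }
  ## planted fissions: many composites, one syntenic split pair
  for (i in seq_len(config$n_planted_fission_families)) {
    hosts <- sample(genome_ids,
                    config$fission_composite_genomes +
                      config$fission_split_genomes)
    comp_g <- hosts[seq_len(config$fission_composite_genomes)]
    split_g <- setdiff(hosts, comp_g)
    plant_event(sprintf("FIS%03d", i), "fission", comp_g, split_g)
  }
  ## technical fissions: split state only in fragmented assemblies
  for (i in seq_len(config$n_technical)) {
    comp_g <- sample(complete, min(6, length(complete)))
    split_g <- sample(fragmented, 2)
    plant_event(sprintf("TEC%03d", i), "technical_fission", comp_g,
                split_g)
  }

  ## background single-domain families, some with a promiscuous domain
  ## appended (composite candidates that must never become families)
  prom <- replicate(config$promiscuous_domain_count, new_domain(),
                    simplify = FALSE)
  for (i in seq_len(config$n_background_families)) {
    dom <- new_domain()
    carriers <- genome_ids[stats::runif(config$n_genomes) < 0.8]
    prom_dom <- if (config$promiscuous_domain_count > 0 &&
                    i <= config$promiscuous_domain_count * 3) {
      prom[[1 + (i - 1) %% config$promiscuous_domain_count]]
    } else NULL
    for (g in carriers) {
      pid <- sprintf("%s_BG%03d", g, i)
      parts <- list(list(acc = dom$acc, domain = dom))
      if (!is.null(prom_dom) && stats::runif(1) < 0.5)
        parts <- c(parts, list(list(acc = prom_dom$acc,
                                    domain = prom_dom)))
      add_protein(pid, g, parts)
      units[[g]][[length(units[[g]]) + 1L]] <- pid
    }
  }

  ## lay out genes: shuffle units, keep non-syntenic partners at the
  ## opposite ends of the contig (rank gap far above the synteny cutoff)
  gene_rows <- list()
  hit_rows <- list()
  for (g in genome_ids) {
    u <- units[[g]]
    ord <- c(u[sample.int(length(u))], tail_units[[g]])
    ids <- unlist(ord, use.names = FALSE)
    n_ctg <- max(1L, config$n_contigs_per_genome)
    ## planted multi-gene units never straddle a contig boundary: contigs
    ## split at unit boundaries
    unit_ctg <- rep(seq_len(n_ctg), length.out = length(ord))
    unit_ctg <- sort(unit_ctg)
    pos <- setNames(rep(1L, n_ctg), paste0(g, "_ctg", seq_len(n_ctg)))
    for (k in seq_along(ord)) {
      ctg <- paste0(g, "_ctg", unit_ctg[k])
      for (pid in ord[[k]]) {
        len <- length(proteins[[pid]]$codes)
        span <- 3L * (len + 1L)
        start <- pos[[ctg]]
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          protein_id = pid, genome_id = g, contig_id = ctg,
          gene_index = NA_integer_,
          strand = sample(c("+", "-"), 1),
          start = start, end = start + span - 1L, length_aa = len,
          stringsAsFactors = FALSE)
        pos[[ctg]] <- start + span + 50L
        ## domain hits straight from construction coordinates
        offset <- 0L
        for (d in proteins[[pid]]$domains) {
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            protein_id = pid, domain_acc = d$acc,
            ali_start = offset + 1L, ali_end = offset + d$len,
            bitscore = round(1.5 * d$len, 1), evalue = 1e-30,
            stringsAsFactors = FALSE)
          offset <- offset + d$len
        }
      }
    }
  }

  genes <- rank_genes(do.call(rbind, gene_rows))
  validate_gene_table(genes)
  seqs <- vapply(proteins, function(p) codes_to_seq(p$codes), "")
  clans <- if (length(clan_rows)) {
    unique(do.call(rbind, clan_rows))
  } else {
    data.frame(domain_acc = character(), clan_acc = character(),
               stringsAsFactors = FALSE)
  }
  dataset <- list(
    genes = genes,
    proteins = seqs[order(names(seqs))],
    domain_hits = do.call(rbind, hit_rows),
    clans = clans,
    ko = do.call(rbind, ko_rows),
    metas = metas,
    truth = do.call(rbind, truth_rows),
    config = config)
  if (!is.null(dir)) write_synthetic_dataset(dataset, dir)
  dataset
}

#' Write a synthetic dataset to disk
#'
#' Emits `proteins.faa`, `genes.tsv`, `domains.tsv`, `clans.tsv`,
#' `ko.tsv`, `genomes.tsv` and `truth.tsv` -- exactly the formats the
#' package readers consume.
#'
#' @param dataset output of [generate_synthetic_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  aa <- Biostrings::AAStringSet(dataset$proteins)
  Biostrings::writeXStringSet(aa, file.path(dir, "proteins.faa"))
  write_gene_table(dataset$genes, file.path(dir, "genes.tsv"))
  write_domain_table(dataset$domain_hits, file.path(dir, "domains.tsv"))
  write_clan_table(dataset$clans, file.path(dir, "clans.tsv"))
  write_ko_table(dataset$ko, file.path(dir, "ko.tsv"))
  write_genome_meta(dataset$metas, file.path(dir, "genomes.tsv"))
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Score detected families against the planted truth
#'
#' A planted event is recovered iff a detected family carries the event's
#' signature, contains at least one of its planted composites, and has at
#' least one syntenic split set consisting of planted split proteins of
#' the event.  Precision is the fraction of detected families that match
#' some planted event; recall is reported per event kind.  When a
#' classification table and cluster assignments are supplied, direction
#' accuracy is the fraction of recovered fusion/fission events whose
#' cluster label points in the planted direction.
#'
#' @param families detected family list ([assemble_families()] output).
#' @param truth truth data.frame from [generate_synthetic_dataset()].
#' @param classification optional data.frame from [classify_clusters()].
#' @param assignments optional data.frame from [cluster_composites()].
#' @return list with `precision`, `recall` (named by kind),
#'   `recall_overall`, `n_detected`, `n_matched`, and
#'   `direction_accuracy` (`NA` without classification input).
#' @export
score_against_truth <- function(families, truth, classification = NULL,
                                assignments = NULL) {
  fam_keys <- vapply(families, function(f) sig_key(f$signature), "")
  matched_fam <- logical(length(families))
  recovered <- logical(nrow(truth))
  fam_of_event <- rep(NA_integer_, nrow(truth))
  for (e in seq_len(nrow(truth))) {
    comp_ids <- strsplit(truth$composite_ids[e], ",", fixed = TRUE)[[1]]
    split_ids <- strsplit(truth$split_ids[e], ",", fixed = TRUE)[[1]]
    for (i in which(fam_keys == truth$signature[e])) {
      f <- families[[i]]
      has_comp <- any(comp_ids %in% f$composite_ids)
      has_set <- any(vapply(f$split_sets, function(s) {
        s$syntenic && all(s$members %in% split_ids)
      }, TRUE))
      if (has_comp && has_set) {
        recovered[e] <- TRUE
        matched_fam[i] <- TRUE
        if (is.na(fam_of_event[e])) fam_of_event[e] <- i
      }
    }
  }
  kinds <- sort(unique(truth$kind))
  recall <- vapply(kinds, function(k) {
    sel <- truth$kind == k
    if (!any(sel)) NA_real_ else mean(recovered[sel])
  }, 0)
  direction <- NA_real_
  if (!is.null(classification) && !is.null(assignments)) {
    cluster_of <- setNames(assignments$cluster_id, assignments$protein_id)
    label_of <- setNames(classification$label, classification$cluster_id)
    dir_ok <- c(); sel <- truth$kind %in% c("fusion", "fission")
    for (e in which(sel & recovered)) {
      f <- families[[fam_of_event[e]]]
      cl <- cluster_of[f$composite_ids]
      cl <- cl[!is.na(cl)]
      if (!length(cl)) { dir_ok <- c(dir_ok, FALSE); next }
      top <- names(sort(table(cl), decreasing = TRUE))[1]
      lab <- label_of[top]
      ok <- !is.na(lab) && startsWith(lab, truth$kind[e])
      dir_ok <- c(dir_ok, ok)
    }
    if (length(dir_ok)) direction <- mean(dir_ok)
  }
  list(precision = if (length(families))
         mean(matched_fam) else NA_real_,
       recall = recall,
       recall_overall = mean(recovered),
       n_detected = length(families),
       n_matched = sum(matched_fam),
       direction_accuracy = direction)
}
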