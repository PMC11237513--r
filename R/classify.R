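## Heuristic fusion/fission classification of composite-protein clusters.
##
## Four criteria vote for a direction: (V1) the syntenic split-set
## frequency of the cluster's families, (V2) the distribution of the
## composite state across bacterial lineages/genomes, (V3) the composite
## vs split-only balance in closed (complete) genomes, and (V4) the KO
## model coverage of composites (full) vs splits (halved).  A majority of
## cast votes gives a "high confidence" label, weaker signal a "probable"
## one; clusters whose composites are themselves split partners of more
## complex composites are "fusion and fission".

CLASS_LABELS <- c("fusion_high", "fusion_probable", "fission_high",
                  "fission_probable", "fusion_and_fission", "unclassified")

#' Default classification thresholds
#'
#' The frequency cutoffs (0.1 / 0.9) and the bacterial-distribution
#' cutoffs (>2 phyla or >=1000 genomes) are fixed by the method; the KO
#' coverage operationalization (full >= 0.8, halved <= 0.6) and the
#' fusion-and-fission fraction (0.2) are configurable conventions.
#'
#' @return named list of thresholds.
#' @export
classify_thresholds <- function() {
  list(freq_fission = 0.1, freq_fusion = 0.9,
       bact_phyla = 2, bact_genomes = 1000,
       ko_full = 0.8, ko_half = 0.6,
       both_frac = 0.2)
}

#' Accept at most one KO assignment per protein
#'
#' For models with an adaptive threshold the assignment is kept iff its
#' bit score reaches the threshold (inclusive).  Models without a
#' threshold are kept only when they are the protein's best hit (highest
#' bit score over all its assignments) and the E-value is strictly below
#' `max_evalue`.  Among kept assignments the best bit score wins (ties by
#' KO id).
#'
#' @param assignments data.frame of KO assignments for one protein.
#' @param max_evalue E-value cutoff for threshold-less models, default
#'   `1e-10` (exclusive).
#' @return one-row data.frame, or `NULL` when nothing is retained.
#' @export
ko_accept <- function(assignments, max_evalue = 1e-10) {
  if (is.null(assignments) || nrow(assignments) == 0) return(NULL)
  if (length(unique(assignments$protein_id)) > 1)
    stop("ko_accept expects assignments for a single protein", call. = FALSE)
  best_bits <- max(assignments$bitscore)
  has_thr <- !is.na(assignments$model_threshold)
  keep <- (has_thr & assignments$bitscore >= assignments$model_threshold) |
    (!has_thr & assignments$bitscore == best_bits &
       assignments$evalue < max_evalue)
  kept <- assignments[keep, , drop = FALSE]
  if (nrow(kept) == 0) return(NULL)
  kept <- kept[order(-kept$bitscore, kept$ko_id), , drop = FALSE]
  kept[1, , drop = FALSE]
}

## retained KO per protein over a whole table; returns a data.frame
ko_accept_all <- function(ko_table, max_evalue = 1e-10) {
  if (is.null(ko_table) || nrow(ko_table) == 0) return(NULL)
  kept <- lapply(split(ko_table, ko_table$protein_id), ko_accept,
                 max_evalue = max_evalue)
  kept <- kept[!vapply(kept, is.null, TRUE)]
  if (!length(kept)) return(NULL)
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  out
}

#' Map one bacterial protein onto the archaeal clusters
#'
#' Takes the highest-bitscore hit of the bacterial protein against the
#' archaeal proteins.  If the best hit is a predicted archaeal composite
#' and both proteins have identical domain architectures, the bacterial
#' protein maps to that composite's cluster; a best-hit composite with a
#' differing architecture is counted separately; any other best hit maps
#' to nothing.  Among multiple equal-best hits the highest-score
#' representative per identical and per non-identical architecture is
#' kept, so an identical-architecture composite wins the tie.
#'
#' @param hits alignment data.frame, this bacterial protein (query)
#'   against archaeal proteins (subjects).
#' @param bact_sig the bacterial protein's signature (character vector).
#' @param archaeal_sigs named list of archaeal composite signatures.
#' @param cluster_of named vector mapping archaeal composite ids to
#'   cluster ids.
#' @return list with `outcome` (`"mapped"`, `"architecture_mismatch"`,
#'   `"none"`), `cluster_id` (or `NA`), `subject_id` (or `NA`).
#' @export
map_bacterial <- function(hits, bact_sig, archaeal_sigs, cluster_of) {
  if (is.null(hits) || nrow(hits) == 0)
    return(list(outcome = "none", cluster_id = NA_character_,
                subject_id = NA_character_))
  best <- hits[hits$bitscore == max(hits$bitscore), , drop = FALSE]
  best <- best[order(best$subject_id), , drop = FALSE]
  is_comp <- best$subject_id %in% names(archaeal_sigs)
  same <- vapply(seq_len(nrow(best)), function(i) {
    is_comp[i] &&
      identical(sig_key(archaeal_sigs[[best$subject_id[i]]]),
                sig_key(bact_sig))
  }, TRUE)
  if (any(same)) {
    subj <- best$subject_id[same][1]
    return(list(outcome = "mapped",
                cluster_id = unname(cluster_of[subj]), subject_id = subj))
  }
  if (any(is_comp)) {
    subj <- best$subject_id[is_comp][1]
    return(list(outcome = "architecture_mismatch",
                cluster_id = NA_character_, subject_id = subj))
  }
  list(outcome = "none", cluster_id = NA_character_,
       subject_id = NA_character_)
}

#' Per-cluster statistics feeding the classifier
#'
#' Aggregates the cluster's families: the syntenic split-set frequency
#' `sum(S_syn) / (sum(C) + sum(S_syn))` (C restricted to composites in
#' this cluster), bacterial phylum/genome counts of mapped composite
#' homologs, composite vs split-only tallies over complete genomes, the
#' median retained-KO model coverage of composite and split proteins, and
#' the fraction of the cluster's composites that are themselves members of
#' a split set for a longer-architecture composite of the same cluster.
#'
#' @param members character vector: composite ids of one cluster.
#' @param families list of `fusion_family` objects.
#' @param genes gene record data.frame.
#' @param metas genome metadata data.frame, or `NULL`.
#' @param bacterial_map data.frame of bacterial mapping results with
#'   columns `cluster_id`, `genome_id`, `phylum` (rows for mapped
#'   proteins), or `NULL` when no bacterial set was screened.
#' @param cluster_id this cluster's id (to select `bacterial_map` rows).
#' @param ko_retained retained KO assignments ([ko_accept_all()] output),
#'   or `NULL`.
#' @return named list of statistics (`NA` where the underlying data is
#'   absent).
#' @export
compute_stats <- function(members, families, genes, metas = NULL,
                          bacterial_map = NULL, cluster_id = NA,
                          ko_retained = NULL) {
  genome_of <- setNames(genes$genome_id, genes$protein_id)
  fams <- Filter(function(f) any(f$composite_ids %in% members), families)

  s_syn <- sum(vapply(fams, function(f)
    sum(vapply(f$split_sets, function(s) s$syntenic, TRUE)), 0L))
  c_n <- sum(vapply(fams, function(f)
    sum(f$composite_ids %in% members), 0L))
  split_set_freq <- if (c_n + s_syn > 0) s_syn / (c_n + s_syn) else NA_real_

  ## bacterial distribution of the composite state
  if (is.null(bacterial_map)) {
    n_phyla <- NA_integer_; n_bact_genomes <- NA_integer_
    n_phyla_min2 <- NA_integer_
  } else {
    bm <- bacterial_map[!is.na(bacterial_map$cluster_id) &
                          bacterial_map$cluster_id == cluster_id, ,
                        drop = FALSE]
    n_bact_genomes <- length(unique(bm$genome_id))
    n_phyla <- length(unique(bm$phylum))
    per_phy <- table(unique(bm[, c("phylum", "genome_id")])$phylum)
    n_phyla_min2 <- sum(per_phy >= 2)
  }

  ## complete-genome tallies
  cc <- NA_integer_; cs <- NA_integer_
  if (!is.null(metas)) {
    complete <- metas$genome_id[metas$assembly_level == "complete"]
    comp_genomes <- unique(unname(genome_of[unlist(lapply(
      fams, function(f) f$composite_ids[f$composite_ids %in% members]))]))
    split_genomes <- unique(unlist(lapply(fams, function(f)
      vapply(f$split_sets, `[[`, "", "genome_id"))))
    cc <- length(intersect(comp_genomes, complete))
    cs <- length(setdiff(intersect(split_genomes, complete),
                         comp_genomes))
  }

  ## KO coverage medians
  ko_comp <- NA_real_; ko_split <- NA_real_
  if (!is.null(ko_retained)) {
    split_ids <- unique(unlist(lapply(fams, function(f)
      unlist(lapply(f$split_sets, `[[`, "members")))))
    comp_cov <- ko_retained$model_coverage[
      ko_retained$protein_id %in% members]
    split_cov <- ko_retained$model_coverage[
      ko_retained$protein_id %in% split_ids]
    if (length(comp_cov)) ko_comp <- stats::median(comp_cov)
    if (length(split_cov)) ko_split <- stats::median(split_cov)
  }

  ## composites that are split partners of longer composites here
  split_members <- unique(unlist(lapply(fams, function(f)
    unlist(lapply(f$split_sets, `[[`, "members")))))
  frac_both <- if (length(members))
    mean(members %in% split_members) else NA_real_

  list(split_set_freq = split_set_freq,
       n_bact_phyla_with_composite = n_phyla,
       n_bact_genomes_with_composite = n_bact_genomes,
       n_bact_phyla_min2 = n_phyla_min2,
       complete_genomes_composite = cc,
       complete_genomes_split_only = cs,
       median_ko_cov_composite = ko_comp,
       median_ko_cov_split = ko_split,
       frac_composites_also_split = frac_both,
       n_composites = length(members),
       n_families = length(fams))
}

#' Classify a cluster as fusion, fission, both, or unclassified
#'
#' Applies the heuristic vote.  V1: split-set frequency below
#' `freq_fission` votes fission, above `freq_fusion` votes fusion.  V2:
#' composite state in more than `bact_phyla` bacterial phyla or at least
#' `bact_genomes` bacterial genomes votes fission; complete absence from
#' the screened bacterial set votes fusion.  V3: among complete genomes
#' carrying the family, a majority with the composite votes fission, a
#' majority with splits only votes fusion.  V4: full composite KO
#' coverage (>= `ko_full`) with halved split coverage (<= `ko_half`)
#' votes fission (the criterion has no fusion direction).  Before voting,
#' a fraction >= `both_frac` of composites that are themselves split
#' partners of longer composites forces `fusion_and_fission`.  A strict
#' majority with at least two cast votes gives a high-confidence label;
#' any weaker non-zero signal gives a probable label (ties broken by V1's
#' direction, then V2's); no signal leaves the cluster unclassified.
#'
#' @param stats statistics list from [compute_stats()]; absent data is
#'   `NA` and abstains.
#' @param thresholds threshold list, see [classify_thresholds()].
#' @param use_min2_rule if `TRUE`, the fusion direction of V2 requires
#'   that no bacterial phylum has two or more mapped assemblies, instead
#'   of requiring zero mapped genomes.
#' @return list with `label` (one of `fusion_high`, `fusion_probable`,
#'   `fission_high`, `fission_probable`, `fusion_and_fission`,
#'   `unclassified`) and `votes` (named character vector over V1..V4 with
#'   values `"fission"`, `"fusion"`, `"abstain"`).
#' @export
classify <- function(stats, thresholds = classify_thresholds(),
                     use_min2_rule = FALSE) {
  th <- thresholds
  v <- c(V1 = "abstain", V2 = "abstain", V3 = "abstain", V4 = "abstain")

  freq <- stats$split_set_freq
  if (!is.na(freq)) {
    if (freq < th$freq_fission) v["V1"] <- "fission"
    else if (freq > th$freq_fusion) v["V1"] <- "fusion"
  }

  ng <- stats$n_bact_genomes_with_composite
  np <- stats$n_bact_phyla_with_composite
  if (!is.na(ng) && !is.na(np)) {
    if (np > th$bact_phyla || ng >= th$bact_genomes) {
      v["V2"] <- "fission"
    } else {
      no_bact <- if (use_min2_rule) {
        !is.na(stats$n_bact_phyla_min2) && stats$n_bact_phyla_min2 == 0
      } else ng == 0
      if (no_bact) v["V2"] <- "fusion"
    }
  }

  cc <- stats$complete_genomes_composite
  cs <- stats$complete_genomes_split_only
  if (!is.na(cc) && !is.na(cs) && (cc + cs) > 0) {
    if (cc > cs) v["V3"] <- "fission"
    else if (cs > cc) v["V3"] <- "fusion"
  }

  kc <- stats$median_ko_cov_composite
  ks <- stats$median_ko_cov_split
  if (!is.na(kc) && !is.na(ks) && kc >= th$ko_full && ks <= th$ko_half)
    v["V4"] <- "fission"

  fb <- stats$frac_composites_also_split
  if (!is.na(fb) && fb >= th$both_frac)
    return(list(label = "fusion_and_fission", votes = v))

  nf <- sum(v == "fission"); nu <- sum(v == "fusion")
  label <- if (nf + nu == 0) {
    "unclassified"
  } else if (nf + nu >= 2 && nf != nu) {
    if (nf > nu) "fission_high" else "fusion_high"
  } else if (nf + nu == 1) {
    if (nf == 1) "fission_probable" else "fusion_probable"
  } else {
    ## tie: V1's direction wins if it voted, else V2's, else no tiebreak
    if (v["V1"] != "abstain") {
      if (v["V1"] == "fission") "fission_probable" else "fusion_probable"
    } else if (v["V2"] != "abstain") {
      if (v["V2"] == "fission") "fission_probable" else "fusion_probable"
    } else "unclassified"
  }
  list(label = label, votes = v)
}

#' Classify every non-singleton cluster
#'
#' @param clustering result of [cluster_composites()].
#' @param families list of `fusion_family` objects.
#' @param genes gene record data.frame.
#' @param metas genome metadata, or `NULL`.
#' @param bacterial_map bacterial mapping data.frame, or `NULL`.
#' @param ko_table raw KO assignment table, or `NULL`.
#' @param thresholds see [classify_thresholds()].
#' @param ko_evalue E-value cutoff for threshold-less KO models.
#' @inheritParams classify
#' @return data.frame with one row per non-singleton cluster: the label,
#'   the four votes, and every statistic.
#' @export
classify_clusters <- function(clustering, families, genes, metas = NULL,
                              bacterial_map = NULL, ko_table = NULL,
                              thresholds = classify_thresholds(),
                              ko_evalue = 1e-10, use_min2_rule = FALSE) {
  ko_retained <- ko_accept_all(ko_table, max_evalue = ko_evalue)
  rows <- list()
  for (cid in names(clustering$clusters)) {
    members <- clustering$clusters[[cid]]
    if (length(members) < 2) next
    stats <- compute_stats(members, families, genes, metas,
                           bacterial_map, cluster_id = cid,
                           ko_retained = ko_retained)
    res <- classify(stats, thresholds, use_min2_rule = use_min2_rule)
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = cid, label = res$label,
      V1 = res$votes[["V1"]], V2 = res$votes[["V2"]],
      V3 = res$votes[["V3"]], V4 = res$votes[["V4"]],
      split_set_freq = stats$split_set_freq,
      n_bact_phyla = stats$n_bact_phyla_with_composite,
      n_bact_genomes = stats$n_bact_genomes_with_composite,
      complete_genomes_composite = stats$complete_genomes_composite,
      complete_genomes_split_only = stats$complete_genomes_split_only,
      median_ko_cov_composite = stats$median_ko_cov_composite,
      median_ko_cov_split = stats$median_ko_cov_split,
      frac_composites_also_split = stats$frac_composites_also_split,
      n_composites = stats$n_composites,
      n_families = stats$n_families,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
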