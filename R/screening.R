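## Rosetta-stone screening: enumerate split protein sets matching a
## composite's domain architecture, test genomic colocalization, apply the
## alignment-based filters, and assemble fusion/fission families.
##
## A family is retained only when at least one composite protein and at
## least one split set encoded by syntenic genes pass all filters; split
## sets with the same signature that pass the filters but are not syntenic
## are then attached to the split side of the family.

#' Enumerate candidate split sets for a composite signature in one genome
#'
#' Finds every way of partitioning the composite signature into two or more
#' contiguous blocks such that each block is realized by a distinct protein
#' in the genome whose full signature equals that block.  Multidomain
#' blocks must preserve internal domain order; a protein whose signature is
#' a permutation of a block never matches.
#'
#' @param composite_sig character vector of token ids, length >= 2.
#' @param genome_signatures named list mapping each protein id of one
#'   genome to its signature (character vector of token ids).
#' @return list of character vectors (ordered member tuples, block order
#'   along the composite signature), deduplicated; empty list when nothing
#'   matches.
#' @export
enumerate_split_sets <- function(composite_sig, genome_signatures) {
  L <- length(composite_sig)
  if (L < 2) stop("composite signature must have length >= 2", call. = FALSE)
  if (!length(genome_signatures)) return(list())
  keys <- vapply(genome_signatures, sig_key, "")
  ids <- names(genome_signatures)
  out <- list()
  seen <- character(0)
  ## each bitmask selects the set of cut points after token 1 .. L-1
  for (mask in seq_len(bitwShiftL(1L, L - 1L) - 1L)) {
    cuts <- which(bitwAnd(mask, bitwShiftL(1L, 0:(L - 2L))) > 0L)
    bounds <- c(0L, cuts, L)
    blocks <- lapply(seq_len(length(bounds) - 1L), function(k) {
      composite_sig[(bounds[k] + 1L):bounds[k + 1L]]
    })
    cand <- lapply(blocks, function(b) ids[keys == sig_key(b)])
    if (any(lengths(cand) == 0L)) next
    combos <- expand.grid(cand, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(nrow(combos))) {
      tuple <- as.character(unlist(combos[r, ], use.names = FALSE))
      if (anyDuplicated(tuple)) next
      key <- paste(tuple, collapse = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- tuple
    }
  }
  out
}

#' Are genes genomically colocalized (syntenic)?
#'
#' All members must lie on a single contig and, after sorting their gene
#' ranks, every consecutive pair must be at most `max_gene_sep` ranks
#' apart (chained colocalization -- the operon-like reading for sets with
#' more than two members).  Strand is ignored.
#'
#' @param members character vector of protein ids.
#' @param genes gene record data.frame (see [read_gene_table()]).
#' @param max_gene_sep maximum rank gap between consecutive members,
#'   default 5 (inclusive).
#' @return logical.
#' @export
is_syntenic <- function(members, genes, max_gene_sep = 5) {
  idx <- match(members, genes$protein_id)
  if (anyNA(idx))
    stop("no gene record for protein: ", members[is.na(idx)][1],
         call. = FALSE)
  g <- genes[idx, , drop = FALSE]
  if (length(unique(paste(g$genome_id, g$contig_id))) > 1) return(FALSE)
  r <- sort(g$gene_index)
  all(diff(r) <= max_gene_sep)
}

#' Composite-split pairwise alignment filter
#'
#' A split candidate is retained against a composite when the pairwise
#' alignment has identity strictly greater than `min_identity`, E-value
#' strictly less than `max_evalue`, and covers at least `min_split_cov` of
#' the split protein (subject coordinates).
#'
#' @param aln one-row alignment data.frame, composite as query and split
#'   candidate as subject.
#' @param split_len length of the split protein in residues.
#' @param min_identity identity threshold in percent, default 25
#'   (exclusive).
#' @param max_evalue E-value threshold, default `1e-9` (exclusive).
#' @param min_split_cov minimum fraction of the split protein covered,
#'   default 0.60 (inclusive).
#' @return logical.
#' @export
pair_passes_filters <- function(aln, split_len, min_identity = 25,
                                max_evalue = 1e-9, min_split_cov = 0.60) {
  if (is.null(aln) || nrow(aln) == 0) return(FALSE)
  if (split_len <= 0) stop("split_len must be positive", call. = FALSE)
  cov <- (aln$s_end - aln$s_start + 1) / split_len
  aln$pct_identity > min_identity & aln$evalue < max_evalue &
    cov >= min_split_cov
}

## total length of the union of 1-based inclusive intervals
union_length <- function(starts, ends) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L; cur_s <- starts[1]; cur_e <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= cur_e + 1L) {
      cur_e <- max(cur_e, ends[i])
    } else {
      tot <- tot + (cur_e - cur_s + 1L)
      cur_s <- starts[i]; cur_e <- ends[i]
    }
  }
  tot + (cur_e - cur_s + 1L)
}

#' Split-set level alignment filter
#'
#' Given the single best alignment of every set member onto one composite,
#' the set passes when no two member alignments overlap on the composite
#' (query coordinates) by more than `max_pair_overlap` residues and the
#' union of the member alignments covers at least `min_composite_cov` of
#' the composite.  Every member must have an alignment.
#'
#' @param alns data.frame with one row per member: the best-bitscore
#'   alignment onto the composite (query = composite).
#' @param composite_len composite protein length in residues.
#' @param n_members number of members in the set (defaults to
#'   `nrow(alns)`; pass explicitly to catch unaligned members).
#' @param max_pair_overlap maximum pairwise overlap in residues, default
#'   100 (inclusive).
#' @param min_composite_cov minimum composite coverage fraction, default
#'   0.60 (inclusive).
#' @return logical.
#' @export
set_passes_filters <- function(alns, composite_len, n_members = nrow(alns),
                               max_pair_overlap = 100,
                               min_composite_cov = 0.60) {
  if (is.null(alns) || nrow(alns) == 0 || nrow(alns) < n_members)
    return(FALSE)
  n <- nrow(alns)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      ov <- interval_overlap(alns$q_start[i], alns$q_end[i],
                             alns$q_start[(i + 1):n], alns$q_end[(i + 1):n])
      if (any(ov > max_pair_overlap)) return(FALSE)
    }
  }
  union_length(alns$q_start, alns$q_end) / composite_len >= min_composite_cov
}

#' Assemble fusion/fission families from screened candidates
#'
#' Families are keyed by architecture signature.  A family is emitted iff
#' at least one composite candidate and at least one syntenic,
#' filter-passing split set with that signature exist anywhere in the
#' dataset; afterwards, filter-passing but non-syntenic split sets with
#' the same signature are attached to the split side, flagged
#' `syntenic = FALSE`.
#'
#' @param candidates data.frame of composite candidates with columns
#'   `protein_id`, `genome_id`, `sig_key`.
#' @param split_sets list of split-set records, each a list with elements
#'   `sig_key`, `genome_id`, `members` (character vector), `syntenic`
#'   (logical), `passes` (logical: all alignment filters passed against at
#'   least one composite of the signature).
#' @return list of `fusion_family` objects: `family_id`, `signature`
#'   (character vector), `composite_ids`, `split_sets` (list of records
#'   with `set_id`, `genome_id`, `members`, `syntenic`).
#' @export
assemble_families <- function(candidates, split_sets) {
  set_keys <- vapply(split_sets, function(s) s$sig_key, "")
  fam_keys <- sort(unique(candidates$sig_key))
  families <- list()
  for (key in fam_keys) {
    sets <- split_sets[set_keys == key]
    passing <- sets[vapply(sets, function(s) isTRUE(s$passes), TRUE)]
    syn <- vapply(passing, function(s) isTRUE(s$syntenic), TRUE)
    if (!any(syn)) next
    ordered <- c(passing[syn], passing[!syn])
    ordered <- lapply(seq_along(ordered), function(i) {
      s <- ordered[[i]]
      list(set_id = sprintf("S%03d", i), genome_id = s$genome_id,
           members = s$members, syntenic = isTRUE(s$syntenic))
    })
    fam <- structure(list(
      family_id = NA_character_,
      signature = sig_unkey(key),
      composite_ids = sort(unique(candidates$protein_id[
        candidates$sig_key == key])),
      split_sets = ordered,
      cluster_id = NA_character_, cluster_subindex = NA_integer_),
      class = "fusion_family")
    families[[length(families) + 1L]] <- fam
  }
  for (i in seq_along(families))
    families[[i]]$family_id <- sprintf("F%04d", i)
  families
}

#' Split-set and split-protein frequencies of a family
#'
#' `split_set_frequency` is the number of syntenic split sets over the
#' total of composite proteins and syntenic split sets,
#' `S_syn / (C + S_syn)`.  `split_protein_frequency` counts syntenic split
#' proteins instead of sets, `P_syn / (C + P_syn)`; since every set has at
#' least two members it is always at least the set version.  The set
#' version is the statistic used for fusion/fission classification.
#'
#' @param family a `fusion_family` object.
#' @return fraction in `[0, 1)`.
#' @export
split_set_frequency <- function(family) {
  syn <- vapply(family$split_sets, function(s) s$syntenic, TRUE)
  s_syn <- sum(syn)
  c_n <- length(family$composite_ids)
  s_syn / (c_n + s_syn)
}

#' @rdname split_set_frequency
#' @export
split_protein_frequency <- function(family) {
  syn <- vapply(family$split_sets, function(s) s$syntenic, TRUE)
  p_syn <- sum(vapply(family$split_sets[syn], function(s)
    length(s$members), 0L))
  c_n <- length(family$composite_ids)
  p_syn / (c_n + p_syn)
}

#' @export
print.fusion_family <- function(x, ...) {
  cat(sprintf("<fusion_family %s> signature: %s\n", x$family_id,
              paste(x$signature, collapse = "+")))
  cat(sprintf("  %d composite(s); %d split set(s) (%d syntenic)\n",
              length(x$composite_ids), length(x$split_sets),
              sum(vapply(x$split_sets, function(s) s$syntenic, TRUE))))
  invisible(x)
}

#' Screen a dataset for fusion/fission families
#'
#' Runs the Rosetta-stone core: flags composite candidates, enumerates
#' split sets per genome, tests synteny, applies the pairwise and
#' set-level alignment filters against every composite of the signature,
#' and assembles families.
#'
#' @param architectures named list of per-protein architectures
#'   ([resolve_architectures()] output).
#' @param genes gene record data.frame covering all proteins.
#' @param alignments alignment data.frame (composite vs split candidates;
#'   both orientations accepted, the best bit-score row per pair is
#'   used), or `NULL` to align with the internal aligner.
#' @param seqs named character vector of protein sequences; required when
#'   `alignments` is `NULL`.  External alignments take precedence over
#'   the internal aligner for pairs they cover.
#' @param scheme [scoring_scheme()] for the internal aligner.
#' @param max_gene_sep,min_identity,max_evalue,min_split_cov,max_pair_overlap,min_composite_cov
#'   filter thresholds, see the individual filter functions.
#' @return list with `families` (from [assemble_families()]),
#'   `candidates`, and per-stage counts in `stage_counts`.
#' @export
screen_families <- function(architectures, genes, alignments = NULL,
                            seqs = NULL, scheme = scoring_scheme(),
                            max_gene_sep = 5, min_identity = 25,
                            max_evalue = 1e-9, min_split_cov = 0.60,
                            max_pair_overlap = 100,
                            min_composite_cov = 0.60) {
  if (is.null(alignments) && is.null(seqs))
    stop("either alignments or seqs must be supplied", call. = FALSE)
  signatures <- lapply(architectures, signature)
  lens <- setNames(genes$length_aa, genes$protein_id)
  genome_of <- setNames(genes$genome_id, genes$protein_id)

  is_comp <- vapply(signatures, length, 0L) >= 2
  comp_ids <- names(signatures)[is_comp]
  candidates <- data.frame(
    protein_id = comp_ids,
    genome_id = unname(genome_of[comp_ids]),
    sig_key = vapply(signatures[comp_ids], sig_key, ""),
    stringsAsFactors = FALSE)

  best <- best_alignment_table(alignments)
  db_letters <- if (!is.null(seqs)) sum(nchar(seqs)) else 0
  aln_cache <- new.env(parent = emptyenv())
  lookup_aln <- function(comp, member) {
    key <- paste(comp, member, sep = "\r")
    i <- match(key, rownames(best))
    if (!is.na(i)) return(best[i, , drop = FALSE])
    if (is.null(seqs)) return(NULL)
    ckey <- gsub("\r", "_", key, fixed = TRUE)
    if (exists(ckey, envir = aln_cache, inherits = FALSE)) {
      v <- get(ckey, envir = aln_cache, inherits = FALSE)
      return(if (identical(v, "none")) NULL else v)
    }
    hit <- local_align(seqs[[comp]], seqs[[member]], scheme,
                       db_size_letters = db_letters,
                       query_id = comp, subject_id = member)
    assign(ckey, if (is.null(hit)) "none" else hit, envir = aln_cache)
    hit
  }

  ## enumerate split sets per candidate signature x genome
  sigs_by_genome <- split(signatures, genome_of[names(signatures)])
  split_sets <- list()
  for (key in unique(candidates$sig_key)) {
    comp_sig <- sig_unkey(key)
    comps <- candidates$protein_id[candidates$sig_key == key]
    for (gid in names(sigs_by_genome)) {
      tuples <- enumerate_split_sets(comp_sig, sigs_by_genome[[gid]])
      for (tuple in tuples) {
        passes <- any(vapply(comps, function(cp) {
          set_passes_against(cp, tuple, lens, lookup_aln,
                             min_identity, max_evalue, min_split_cov,
                             max_pair_overlap, min_composite_cov)
        }, TRUE))
        split_sets[[length(split_sets) + 1L]] <- list(
          sig_key = key, genome_id = gid, members = tuple,
          syntenic = is_syntenic(tuple, genes, max_gene_sep),
          passes = passes)
      }
    }
  }

  families <- assemble_families(candidates, split_sets)
  list(families = families, candidates = candidates,
       split_sets = split_sets,
       stage_counts = c(
         proteins = length(signatures),
         composite_candidates = nrow(candidates),
         candidate_signatures = length(unique(candidates$sig_key)),
         split_sets_enumerated = length(split_sets),
         split_sets_passing = sum(vapply(split_sets, function(s)
           isTRUE(s$passes), TRUE)),
         families = length(families)))
}

## Index the best-bitscore alignment per (query, subject) ordered pair.
## Both orientations of the input are indexed so either direction of an
## all-vs-all search can serve a lookup; a flipped row swaps query/subject
## ids and coordinate pairs.
best_alignment_table <- function(aln) {
  if (is.null(aln) || nrow(aln) == 0) return(empty_alignments())
  flipped <- aln
  flipped$query_id <- aln$subject_id
  flipped$subject_id <- aln$query_id
  flipped$q_start <- aln$s_start; flipped$q_end <- aln$s_end
  flipped$s_start <- aln$q_start; flipped$s_end <- aln$q_end
  both <- rbind(aln, flipped)
  key <- paste(both$query_id, both$subject_id, sep = "\r")
  o <- order(key, -both$bitscore)
  both <- both[o, , drop = FALSE]
  key <- key[o]
  best <- both[!duplicated(key), , drop = FALSE]
  rownames(best) <- key[!duplicated(key)]
  best
}

## evaluate all pair filters + the set filter of one tuple vs one composite
set_passes_against <- function(comp_id, members, lens, lookup_aln,
                               min_identity, max_evalue, min_split_cov,
                               max_pair_overlap, min_composite_cov) {
  alns <- vector("list", length(members))
  for (i in seq_along(members)) {
    a <- lookup_aln(comp_id, members[i])
    if (is.null(a)) return(FALSE)
    if (!pair_passes_filters(a, split_len = lens[[members[i]]],
                             min_identity = min_identity,
                             max_evalue = max_evalue,
                             min_split_cov = min_split_cov))
      return(FALSE)
    alns[[i]] <- a
  }
  set_passes_filters(do.call(rbind, alns), composite_len = lens[[comp_id]],
                     n_members = length(members),
                     max_pair_overlap = max_pair_overlap,
                     min_composite_cov = min_composite_cov)
}

#' Tabulate families for output
#'
#' Converts a family list to the two output tables: `families` (one row
#' per family with counts and frequencies) and `members` (one row per
#' protein role).
#'
#' @param families list of `fusion_family` objects.
#' @param genes gene record data.frame (for member genome ids).
#' @return list of two data.frames, `families` and `members`.
#' @export
families_to_tables <- function(families, genes) {
  genome_of <- setNames(genes$genome_id, genes$protein_id)
  fam_rows <- lapply(families, function(f) {
    syn <- vapply(f$split_sets, function(s) s$syntenic, TRUE)
    data.frame(
      family_id = f$family_id,
      signature = sig_key(f$signature),
      n_composites = length(f$composite_ids),
      n_split_sets = length(f$split_sets),
      n_syntenic_sets = sum(syn),
      split_set_freq = split_set_frequency(f),
      split_protein_freq = split_protein_frequency(f),
      cluster_id = f$cluster_id,
      stringsAsFactors = FALSE)
  })
  mem_rows <- lapply(families, function(f) {
    comp <- data.frame(family_id = f$family_id, role = "composite",
                       set_id = NA_character_, syntenic = NA,
                       protein_id = f$composite_ids,
                       genome_id = unname(genome_of[f$composite_ids]),
                       stringsAsFactors = FALSE)
    spl <- lapply(f$split_sets, function(s) {
      data.frame(family_id = f$family_id, role = "split",
                 set_id = s$set_id, syntenic = s$syntenic,
                 protein_id = s$members,
                 genome_id = unname(genome_of[s$members]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(list(comp), spl))
  })
  list(families = if (length(fam_rows)) do.call(rbind, fam_rows) else NULL,
       members = if (length(mem_rows)) do.call(rbind, mem_rows) else NULL)
}
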