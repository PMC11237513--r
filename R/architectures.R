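## Resolution of raw domain hits into non-overlapping, clan-mapped domain
## architectures, and the composite-candidate predicate.
##
## A protein's architecture is the ordered list of domain tokens it carries;
## a token is the Pfam clan accession when the domain belongs to a clan
## (expanding the search space so homologous families match) and the raw
## domain accession otherwise.

## residues shared by two 1-based inclusive intervals
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

#' Resolve domain hits into a non-overlapping architecture
#'
#' Greedy selection by descending bit score (ties broken by smaller start,
#' then lexicographic domain accession).  A hit is rejected when it overlaps
#' any already accepted hit by more than `max_token_overlap` residues.
#' Surviving hits are sorted by start and clan-mapped: the token is the clan
#' accession when the domain has one, else the domain accession.  Setting
#' `max_token_overlap = 0` reproduces strictly non-overlapping behaviour.
#'
#' @param hits data.frame of domain hits for a single protein (columns
#'   `protein_id`, `domain_acc`, `ali_start`, `ali_end`, `bitscore`).
#' @param clans clan mapping data.frame (`domain_acc`, `clan_acc`), or
#'   `NULL` for no mapping.
#' @param min_bitscore drop hits below this bit score (default 0, trusting
#'   upstream gathering thresholds).
#' @param max_token_overlap maximum tolerated residue overlap between two
#'   accepted hits, default 15 aa.
#' @return data.frame of tokens (`token_id`, `start`, `end`, `bitscore`)
#'   sorted by start, with the protein id as attribute `protein_id`.  An
#'   empty hit list yields an empty architecture, not an error.
#' @export
resolve_architecture <- function(hits, clans = NULL, min_bitscore = 0,
                                 max_token_overlap = 15) {
  empty <- data.frame(token_id = character(), start = integer(),
                      end = integer(), bitscore = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0) {
    attr(empty, "protein_id") <- NA_character_
    return(empty)
  }
  if (length(unique(hits$protein_id)) > 1)
    stop("resolve_architecture expects hits for a single protein",
         call. = FALSE)
  hits <- hits[hits$bitscore >= min_bitscore, , drop = FALSE]
  if (nrow(hits) == 0) {
    attr(empty, "protein_id") <- NA_character_
    return(empty)
  }
  ord <- order(-hits$bitscore, hits$ali_start, hits$domain_acc)
  hits <- hits[ord, , drop = FALSE]
  acc_start <- integer(0); acc_end <- integer(0); keep <- integer(0)
  for (i in seq_len(nrow(hits))) {
    ov <- interval_overlap(hits$ali_start[i], hits$ali_end[i],
                           acc_start, acc_end)
    if (!length(ov) || all(ov <= max_token_overlap)) {
      keep <- c(keep, i)
      acc_start <- c(acc_start, hits$ali_start[i])
      acc_end <- c(acc_end, hits$ali_end[i])
    }
  }
  sel <- hits[keep, , drop = FALSE]
  sel <- sel[order(sel$ali_start, sel$ali_end, sel$domain_acc), , drop = FALSE]
  arch <- data.frame(token_id = map_to_clan(sel$domain_acc, clans),
                     start = sel$ali_start, end = sel$ali_end,
                     bitscore = sel$bitscore, stringsAsFactors = FALSE)
  rownames(arch) <- NULL
  attr(arch, "protein_id") <- hits$protein_id[1]
  arch
}

## clan-map a vector of domain accessions; unmapped accessions pass through
map_to_clan <- function(domain_acc, clans) {
  if (is.null(clans) || nrow(clans) == 0) return(domain_acc)
  idx <- match(domain_acc, clans$domain_acc)
  clan <- clans$clan_acc[idx]
  ifelse(!is.na(idx) & !is.na(clan), clan, domain_acc)
}

#' Architecture signature
#'
#' Order-preserving projection of an architecture to its token ids.
#' Repeated identical tokens are preserved: self-fusion architectures like
#' `(A, A)` are legitimate signatures.
#'
#' @param arch architecture data.frame from [resolve_architecture()].
#' @return character vector of token ids (possibly empty).
#' @export
signature <- function(arch) {
  as.character(arch$token_id)
}

## signatures are keyed as strings; "|" never occurs in Pfam accessions
sig_key <- function(sig) paste(sig, collapse = "|")
sig_unkey <- function(key) strsplit(key, "|", fixed = TRUE)[[1]]

#' Is a protein a composite (fusion) candidate?
#'
#' A candidate composite carries two or more non-overlapping domain tokens.
#' Repeated identical tokens count: proteins fused with themselves are
#' candidates.
#'
#' @param arch architecture data.frame from [resolve_architecture()].
#' @return logical.
#' @export
is_composite_candidate <- function(arch) {
  length(signature(arch)) >= 2
}

#' Resolve architectures for a whole domain-hit table
#'
#' Convenience wrapper applying [resolve_architecture()] per protein.
#'
#' @param hits data.frame of domain hits for any number of proteins.
#' @inheritParams resolve_architecture
#' @return named list of architecture data.frames, one per protein that has
#'   at least one surviving hit.
#' @export
resolve_architectures <- function(hits, clans = NULL, min_bitscore = 0,
                                  max_token_overlap = 15) {
  if (is.null(hits) || nrow(hits) == 0) return(list())
  sp <- split(hits, hits$protein_id)
  out <- lapply(sp, resolve_architecture, clans = clans,
                min_bitscore = min_bitscore,
                max_token_overlap = max_token_overlap)
  out[vapply(out, nrow, 0L) > 0]
}
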