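## Internal pairwise aligner: local alignment with Karlin-Altschul
## E-values for screening, global alignment for clustering distances.
## The production path ingests external (DIAMOND/BLAST) tabular output via
## read_tabular_alignments(); this aligner exists so the whole pipeline is
## runnable and testable without external tools.  Its E-values use
## published gapped BLOSUM62 (open 11 / extend 1) Karlin-Altschul
## constants and are declared approximate.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Alignment scoring scheme
#'
#' Bundles a symmetric 20x20 substitution matrix with affine gap penalties
#' and Karlin-Altschul statistics parameters.  A gap of length L costs
#' `gap_open + gap_extend * L`.  Defaults are the published constants for
#' gapped BLOSUM62 with gap open 11 / extend 1 (lambda = 0.267,
#' K = 0.041); the matrix itself is the BLOSUM62 shipped with Biostrings.
#'
#' @param matrix 20x20 integer substitution matrix with amino-acid
#'   dimnames; default BLOSUM62.
#' @param gap_open gap opening penalty (positive), default 11.
#' @param gap_extend gap extension penalty (positive), default 1; must be
#'   `<= gap_open`.
#' @param karlin_lambda,karlin_k Karlin-Altschul parameters for the raw
#'   score scale.
#' @return list of class `"scoring_scheme"`.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = 11, gap_extend = 1,
                           karlin_lambda = 0.267, karlin_k = 0.041) {
  if (is.null(matrix)) {
    blosum62 <- get(utils::data("BLOSUM62", package = "Biostrings",
                                envir = environment()))
    matrix <- blosum62[AA_ALPHABET, AA_ALPHABET]
  }
  stopifnot(nrow(matrix) == 20, ncol(matrix) == 20,
            isTRUE(all.equal(matrix, t(matrix))),
            gap_open > 0, gap_extend > 0, gap_extend <= gap_open,
            karlin_lambda > 0, karlin_k > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, karlin_lambda = karlin_lambda,
                 karlin_k = karlin_k),
            class = "scoring_scheme")
}

encode_seq <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1 || is.na(seq) || !nzchar(seq))
    stop(what, " must be a non-empty string", call. = FALSE)
  codes <- match(strsplit(toupper(seq), "")[[1]], AA_ALPHABET)
  if (anyNA(codes))
    stop(what, " contains a non-amino-acid symbol", call. = FALSE)
  codes - 1L
}

#' Local (Smith-Waterman) alignment with affine gaps
#'
#' Returns the optimal local alignment of `query_seq` against
#' `subject_seq` as a one-row alignment-hit data.frame compatible with
#' [read_tabular_alignments()] output.  Percent identity is identical
#' aligned residue pairs over alignment columns (gap columns included),
#' the BLAST `pident` convention.  The E-value is
#' `K * |query| * db_size_letters * exp(-lambda * score)`.
#'
#' @param query_seq,subject_seq amino-acid strings (non-empty).
#' @param scheme a [scoring_scheme()].
#' @param db_size_letters effective database size in residues (defaults to
#'   the subject length for a one-to-one comparison).
#' @param query_id,subject_id labels for the output row.
#' @return one-row data.frame, or `NULL` when no positive-scoring local
#'   alignment exists.
#' @export
local_align <- function(query_seq, subject_seq, scheme = scoring_scheme(),
                        db_size_letters = nchar(subject_seq),
                        query_id = "query", subject_id = "subject") {
  qa <- encode_seq(query_seq, "query_seq")
  sa <- encode_seq(subject_seq, "subject_seq")
  res <- .align_local(qa, sa, scheme$matrix, scheme$gap_open,
                      scheme$gap_extend)
  if (isTRUE(res$empty) || res$score <= 0) return(NULL)
  evalue <- scheme$karlin_k * length(qa) * db_size_letters *
    exp(-scheme$karlin_lambda * res$score)
  data.frame(query_id = query_id, subject_id = subject_id,
             pct_identity = 100 * res$n_ident / res$n_cols,
             aln_length = as.integer(res$n_cols),
             mismatch = as.integer(res$n_cols - res$n_ident),
             gapopen = 0L,
             q_start = res$q_start, q_end = res$q_end,
             s_start = res$s_start, s_end = res$s_end,
             evalue = evalue, bitscore = res$score,
             stringsAsFactors = FALSE)
}

#' Raw local alignment score
#'
#' The optimal affine-gap Smith-Waterman score (0 when no positive-scoring
#' alignment exists).
#'
#' @inheritParams local_align
#' @return numeric score.
#' @export
local_align_score <- function(query_seq, subject_seq,
                              scheme = scoring_scheme()) {
  qa <- encode_seq(query_seq, "query_seq")
  sa <- encode_seq(subject_seq, "subject_seq")
  res <- .align_local(qa, sa, scheme$matrix, scheme$gap_open,
                      scheme$gap_extend)
  res$score
}

#' Global (Needleman-Wunsch) percent identity
#'
#' Optimal affine-gap global alignment; identity is identical aligned
#' pairs over alignment columns (end gaps included) times 100.
#'
#' @inheritParams local_align
#' @param seq_a,seq_b amino-acid strings (non-empty).
#' @return percent identity in `[0, 100]`.
#' @export
global_percent_identity <- function(seq_a, seq_b,
                                    scheme = scoring_scheme()) {
  a <- encode_seq(seq_a, "seq_a")
  b <- encode_seq(seq_b, "seq_b")
  res <- .align_global(a, b, scheme$matrix, scheme$gap_open,
                       scheme$gap_extend)
  100 * res$n_ident / res$n_cols
}

#' Raw global alignment score
#'
#' @inheritParams global_percent_identity
#' @return numeric optimal Needleman-Wunsch score.
#' @export
global_align_score <- function(seq_a, seq_b, scheme = scoring_scheme()) {
  a <- encode_seq(seq_a, "seq_a")
  b <- encode_seq(seq_b, "seq_b")
  .align_global(a, b, scheme$matrix, scheme$gap_open, scheme$gap_extend)$score
}
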