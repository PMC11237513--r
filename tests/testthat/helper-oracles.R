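## Independent brute-force oracles.  These deliberately share no code
## with the package implementations: alignment scores come from
## exhaustive enumeration over the alignment space, split sets from a
## recursive partition enumerator, and MCL from a loop-written dense
## reference with attractor-based cluster extraction.

## exhaustive optimal global alignment score (affine gaps, gap of length
## L costs gap_open + gap_extend * L); enumerates every alignment as a
## move sequence (D = aligned pair, U = gap in b, L = gap in a), with a
## sound admissible bound for pruning (never prunes an optimal path)
oracle_global_enum <- function(a, b, scheme) {
  S <- scheme$matrix
  ac <- match(strsplit(a, "")[[1]], colnames(S))
  bc <- match(strsplit(b, "")[[1]], colnames(S))
  n <- length(ac); m <- length(bc)
  ge <- scheme$gap_extend; gi <- scheme$gap_open + ge
  max_s <- max(S)
  best <- -Inf
  rec <- function(i, j, s, prev) {
    if (i == n && j == m) {
      if (s > best) best <<- s
      return(invisible())
    }
    if (s + max_s * min(n - i, m - j) - ge * abs((n - i) - (m - j)) < best)
      return(invisible())  # admissible upper bound
    if (i < n && j < m) rec(i + 1L, j + 1L, s + S[ac[i + 1L], bc[j + 1L]], 1L)
    if (i < n) rec(i + 1L, j, s - (if (prev == 2L) ge else gi), 2L)
    if (j < m) rec(i, j + 1L, s - (if (prev == 3L) ge else gi), 3L)
  }
  rec(0L, 0L, 0, 1L)
  best
}

## exhaustive optimal local alignment score: every alignment starting and
## ending on an aligned pair, floored at 0
oracle_local_enum <- function(a, b, scheme) {
  S <- scheme$matrix
  ac <- match(strsplit(a, "")[[1]], colnames(S))
  bc <- match(strsplit(b, "")[[1]], colnames(S))
  n <- length(ac); m <- length(bc)
  ge <- scheme$gap_extend; gi <- scheme$gap_open + ge
  max_s <- max(S)
  best <- 0
  rec <- function(i, j, s, prev) {
    if (prev == 1L && s > best) best <<- s
    if (s + max_s * min(n - i, m - j) <= best - 1e-9)
      return(invisible())
    if (i < n && j < m) rec(i + 1L, j + 1L, s + S[ac[i + 1L], bc[j + 1L]], 1L)
    if (i < n) rec(i + 1L, j, s - (if (prev == 2L) ge else gi), 2L)
    if (j < m) rec(i, j + 1L, s - (if (prev == 3L) ge else gi), 3L)
  }
  for (i in seq_len(n))
    for (j in seq_len(m))
      rec(i, j, S[ac[i], bc[j]], 1L)
  best
}

## brute-force split-set enumeration: recursively partition the signature
## into contiguous blocks, assigning a distinct matching protein to each
oracle_split_sets <- function(sig, genome_sigs) {
  ids <- names(genome_sigs)
  results <- list()
  rec <- function(pos, used, acc) {
    if (pos > length(sig)) {
      if (length(acc) >= 2)
        results[[length(results) + 1L]] <<- acc
      return(invisible())
    }
    for (end in pos:length(sig)) {
      block <- sig[pos:end]
      for (id in ids) {
        if (id %in% used) next
        if (identical(unname(genome_sigs[[id]]), block))
          rec(end + 1L, c(used, id), c(acc, id))
      }
    }
  }
  rec(1L, character(0), character(0))
  unique(results)
}

## brute-force optimal conflict-free domain-hit subset (max total
## bitscore subject to pairwise overlap <= max_overlap)
oracle_best_hit_subset <- function(hits, max_overlap) {
  n <- nrow(hits)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) > 1) {
      ok <- TRUE
      for (i in seq_along(sel)[-1]) {
        for (j in seq_len(i - 1)) {
          a <- sel[i]; b <- sel[j]
          ov <- min(hits$ali_end[a], hits$ali_end[b]) -
            max(hits$ali_start[a], hits$ali_start[b]) + 1
          if (ov > max_overlap) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (!ok) next
    }
    s <- sum(hits$bitscore[sel])
    if (s > best) best <- s
  }
  best
}

## dense loop-written MCL reference with attractor-based extraction:
## attractors are nodes keeping mass on their diagonal; each attractor
## claims the nodes whose columns feed it; overlapping claims merge
oracle_mcl_partition <- function(A, inflation, iters = 300) {
  n <- nrow(A)
  for (v in seq_len(n)) {
    mx <- max(A[v, ])
    A[v, v] <- if (mx > 0) mx else 1
  }
  M <- A
  for (j in seq_len(n)) M[, j] <- M[, j] / sum(M[, j])
  for (it in seq_len(iters)) {
    M2 <- matrix(0, n, n)
    for (i in seq_len(n))
      for (j in seq_len(n))
        M2[i, j] <- sum(M[i, ] * M[, j])
    M2 <- M2^inflation
    for (j in seq_len(n)) {
      cs <- sum(M2[, j])
      M2[, j] <- if (cs > 0) M2[, j] / cs else
        replace(numeric(n), j, 1)
    }
    if (max(abs(M2 - M)) < 1e-10) { M <- M2; break }
    M <- M2
  }
  thr <- 1e-5
  claims <- lapply(which(diag(M) > thr), function(a) which(M[a, ] > thr))
  groups <- list()
  for (cl in claims) {
    hit <- which(vapply(groups, function(g) any(g %in% cl), TRUE))
    merged <- sort(unique(c(cl, unlist(groups[hit]))))
    groups <- c(groups[setdiff(seq_along(groups), hit)], list(merged))
  }
  assigned <- unlist(groups)
  for (v in setdiff(seq_len(n), assigned)) groups <- c(groups, list(v))
  memb <- integer(n)
  for (k in seq_along(groups)) memb[groups[[k]]] <- k
  memb
}

## independent transcription of the classification vote rule
expected_label_from_votes <- function(votes, frac_both = 0,
                                      both_cut = 0.2) {
  if (frac_both >= both_cut) return("fusion_and_fission")
  nf <- sum(votes == "fission"); nu <- sum(votes == "fusion")
  if (nf + nu == 0) return("unclassified")
  if (nf + nu >= 2 && nf != nu)
    return(if (nf > nu) "fission_high" else "fusion_high")
  if (nf + nu == 1)
    return(if (nf == 1) "fission_probable" else "fusion_probable")
  for (v in votes[c("V1", "V2")])
    if (v != "abstain")
      return(if (v == "fission") "fission_probable" else "fusion_probable")
  "unclassified"
}

## craft a stats list that forces a given vote combination
stats_for_votes <- function(v1, v2, v3, v4, frac_both = 0) {
  freq <- switch(v1, fission = 0.05, fusion = 0.95, abstain = 0.5)
  bact <- switch(v2, fission = c(4L, 50L), fusion = c(0L, 0L),
                 abstain = c(1L, 5L))
  cg <- switch(v3, fission = c(5L, 1L), fusion = c(1L, 5L),
               abstain = c(0L, 0L))
  ko <- switch(v4, fission = c(1.0, 0.5), abstain = c(0.9, 0.9))
  list(split_set_freq = freq,
       n_bact_phyla_with_composite = bact[1],
       n_bact_genomes_with_composite = bact[2],
       n_bact_phyla_min2 = NA_integer_,
       complete_genomes_composite = cg[1],
       complete_genomes_split_only = cg[2],
       median_ko_cov_composite = ko[1],
       median_ko_cov_split = ko[2],
       frac_composites_also_split = frac_both)
}
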