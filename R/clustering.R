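## Composite-protein similarity graph and in-house Markov Clustering.
##
## Composite proteins are aligned globally; edge weight is the global
## percent identity (pairs below a floor carry no edge).  MCL runs at low
## inflation (1.2) for the primary partition; clusters with more than 10
## members are tentatively re-clustered at inflation 1.6 and the split is
## accepted only when the subclusters are clearly separated by identity
## and by functional annotation or sequence length.

#' Build a composite-protein similarity graph
#'
#' All-vs-all global alignment of the supplied sequences; an undirected
#' edge is stored for every pair whose global percent identity reaches
#' `floor`.  No self-edges are stored (self-loops are added inside
#' [mcl()]).
#'
#' @param seqs named character vector of protein sequences.
#' @param scheme a [scoring_scheme()].
#' @param floor minimum percent identity for an edge, default 25.
#' @return list with `nodes` (character vector) and `edges` (data.frame
#'   `from`, `to`, `weight`).
#' @export
similarity_graph <- function(seqs, scheme = scoring_scheme(), floor = 25) {
  nodes <- sort(names(seqs))
  from <- character(0); to <- character(0); w <- numeric(0)
  n <- length(nodes)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        pid <- global_percent_identity(seqs[[nodes[i]]], seqs[[nodes[j]]],
                                       scheme)
        if (pid >= floor) {
          from <- c(from, nodes[i]); to <- c(to, nodes[j]); w <- c(w, pid)
        }
      }
    }
  }
  list(nodes = nodes,
       edges = data.frame(from = from, to = to, weight = w,
                          stringsAsFactors = FALSE))
}

graph_matrix <- function(graph) {
  nodes <- sort(graph$nodes)
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges
  if (!is.null(e) && nrow(e)) {
    i <- match(e$from, nodes); j <- match(e$to, nodes)
    A[cbind(i, j)] <- e$weight
    A[cbind(j, i)] <- e$weight
  }
  A
}

#' Markov Clustering (MCL)
#'
#' In-house dense MCL: the weighted adjacency matrix gains self-loops
#' (loop weight = the node's maximum incident edge weight; 1 for isolated
#' nodes), is column-normalized, and then alternates expansion (matrix
#' square) with inflation (elementwise power and column renormalization),
#' pruning entries below `prune_below`, until the maximum entry change
#' falls under `tol` or `max_iter` iterations.  Clusters are the weakly
#' connected components of the converged nonzero structure.
#'
#' @param graph list with `nodes` and `edges` as from
#'   [similarity_graph()].
#' @param inflation inflation exponent, must be > 1.  Higher values give
#'   finer granularity.
#' @param prune_below entries below this value are zeroed each iteration.
#' @param tol convergence tolerance on the maximum entry change.
#' @param max_iter iteration cap.
#' @return list with `membership` (named integer vector, a partition) and
#'   `clusters` (list of character vectors, ordered by decreasing size
#'   then smallest member).
#' @export
mcl <- function(graph, inflation, prune_below = 1e-6, tol = 1e-8,
                max_iter = 200) {
  if (!length(graph$nodes)) stop("graph is empty", call. = FALSE)
  if (inflation <= 1) stop("inflation must be > 1", call. = FALSE)
  A <- graph_matrix(graph)
  loop <- apply(A, 1, max)
  loop[loop <= 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    M_new <- M %*% M                      # expansion
    M_new <- M_new^inflation              # inflation
    M_new[M_new < prune_below] <- 0
    cs <- colSums(M_new)
    dead <- cs == 0
    if (any(dead)) {                      # numerically emptied column
      M_new[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    M_new <- sweep(M_new, 2, cs, "/")
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < tol) break
  }
  structure_adj <- (M > 0) | (t(M) > 0)
  g <- igraph::graph_from_adjacency_matrix(structure_adj,
                                           mode = "undirected")
  comp <- igraph::components(g)$membership
  partition_from_membership(comp, rownames(M))
}

## normalize a raw membership vector into deterministic cluster labels:
## clusters ordered by decreasing size, ties by smallest member name
partition_from_membership <- function(memb, nodes) {
  cl <- split(nodes, memb[nodes])
  cl <- lapply(cl, sort)
  o <- order(-lengths(cl), vapply(cl, `[`, "", 1))
  cl <- cl[o]
  membership <- integer(length(nodes))
  names(membership) <- nodes
  for (k in seq_along(cl)) membership[cl[[k]]] <- k
  list(membership = membership, clusters = unname(cl))
}

#' Subcluster a large MCL cluster
#'
#' Clusters with more than `size_threshold` members (strict) are re-run
#' through [mcl()] at `sub_inflation` on the induced subgraph.  The split
#' is accepted only when (a) the maximum pairwise identity between members
#' of different subclusters stays strictly below `max_inter_identity`,
#' and (b) the subclusters are separated by annotation or length: no KO
#' label is shared across subclusters, or every pair of subclusters
#' differs in median sequence length by more than `length_sep` (relative
#' to the smaller median).  Otherwise the original cluster is returned.
#'
#' @param members character vector: one cluster from [mcl()] at the
#'   primary inflation.
#' @param graph the full similarity graph (edges provide pairwise
#'   identities).
#' @param annotations named character vector of KO labels (`NA` = none).
#' @param lengths named numeric vector of sequence lengths.
#' @param size_threshold subclustering only applies above this size,
#'   default 10 (strict).
#' @param sub_inflation inflation for the re-run, default 1.6.
#' @param max_inter_identity identity ceiling between subclusters,
#'   default 40 (exclusive).
#' @param length_sep relative median-length separation, default 0.2.
#' @return list of character vectors: the accepted subclusters, or the
#'   original cluster as a single element.
#' @export
subcluster <- function(members, graph, annotations = NULL, lengths = NULL,
                       size_threshold = 10, sub_inflation = 1.6,
                       max_inter_identity = 40, length_sep = 0.2) {
  if (length(members) <= size_threshold) return(list(members))
  e <- graph$edges
  keep <- e$from %in% members & e$to %in% members
  sub <- list(nodes = members, edges = e[keep, , drop = FALSE])
  part <- mcl(sub, inflation = sub_inflation)
  cl <- part$clusters
  if (length(cl) < 2) return(list(members))
  ## (a) identity separation between subclusters
  memb <- part$membership
  ee <- sub$edges
  inter <- memb[ee$from] != memb[ee$to]
  if (any(inter) && max(ee$weight[inter]) >= max_inter_identity)
    return(list(members))
  ## (b) separation by annotation or by length
  kos <- lapply(cl, function(m) {
    k <- if (is.null(annotations)) character(0) else annotations[m]
    unique(k[!is.na(k)])
  })
  ko_disjoint <- TRUE
  if (length(cl) > 1) {
    for (i in seq_len(length(cl) - 1))
      for (j in (i + 1):length(cl))
        if (length(intersect(kos[[i]], kos[[j]]))) ko_disjoint <- FALSE
  }
  len_sep <- FALSE
  if (!is.null(lengths)) {
    med <- vapply(cl, function(m) stats::median(lengths[m]), 0)
    len_sep <- TRUE
    for (i in seq_len(length(cl) - 1))
      for (j in (i + 1):length(cl))
        if (abs(med[i] - med[j]) / min(med[i], med[j]) <= length_sep)
          len_sep <- FALSE
  }
  if (ko_disjoint || len_sep) cl else list(members)
}

#' Assign architecture subindices within a cluster
#'
#' Clusters can contain multiple domain architectures; the distinct
#' signatures within a cluster are numbered 1..k in order of decreasing
#' member count (ties broken lexicographically by signature).
#'
#' @param members character vector of the cluster's protein ids.
#' @param signatures named list mapping protein id to signature (character
#'   vector of tokens).
#' @return named integer vector mapping signature key (tokens joined with
#'   `|`) to subindex.
#' @export
assign_subindices <- function(members, signatures) {
  keys <- vapply(signatures[members], sig_key, "")
  tab <- table(keys)
  o <- order(-as.integer(tab), names(tab))
  setNames(seq_along(o), names(tab)[o])
}

#' Cluster the composite proteins of a family set
#'
#' Builds the similarity graph over all composite proteins, runs [mcl()]
#' at `inflation`, applies [subcluster()] to clusters larger than
#' `size_threshold`, and assigns per-cluster architecture subindices.
#' Singleton clusters are flagged (they are excluded from
#' classification).
#'
#' @param families list of `fusion_family` objects.
#' @param seqs named character vector of protein sequences (must cover all
#'   composites).
#' @param annotations,lengths see [subcluster()]; lengths default to
#'   `nchar(seqs)`.
#' @param scheme a [scoring_scheme()].
#' @param inflation primary inflation, default 1.2.
#' @param floor identity floor for graph edges, default 25.
#' @inheritParams subcluster
#' @return list with `assignments` (data.frame `protein_id`, `cluster_id`,
#'   `subcluster_id`, `signature_subindex`, `singleton`), `graph`, and
#'   `clusters` (list of member vectors keyed by cluster_id).
#' @export
cluster_composites <- function(families, seqs, annotations = NULL,
                               lengths = NULL, scheme = scoring_scheme(),
                               inflation = 1.2, floor = 25,
                               size_threshold = 10, sub_inflation = 1.6,
                               max_inter_identity = 40, length_sep = 0.2) {
  comp_ids <- sort(unique(unlist(lapply(families, `[[`, "composite_ids"))))
  if (!length(comp_ids))
    return(list(assignments = NULL, graph = NULL, clusters = list()))
  missing <- setdiff(comp_ids, names(seqs))
  if (length(missing))
    stop("no sequence for composite: ", missing[1], call. = FALSE)
  if (is.null(lengths)) lengths <- nchar(seqs)
  graph <- similarity_graph(seqs[comp_ids], scheme, floor = floor)
  part <- mcl(graph, inflation = inflation)

  signatures <- list()
  for (f in families)
    for (p in f$composite_ids) signatures[[p]] <- f$signature

  rows <- list()
  clusters <- list()
  for (k in seq_along(part$clusters)) {
    members <- part$clusters[[k]]
    subs <- subcluster(members, graph, annotations, lengths,
                       size_threshold = size_threshold,
                       sub_inflation = sub_inflation,
                       max_inter_identity = max_inter_identity,
                       length_sep = length_sep)
    sub_ids <- if (length(subs) > 1) {
      paste0(k, "_", seq_along(subs))
    } else NA_character_
    for (s in seq_along(subs)) {
      mem <- subs[[s]]
      cid <- as.character(k)
      subidx <- assign_subindices(mem, signatures)
      keys <- vapply(signatures[mem], sig_key, "")
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = mem, cluster_id = cid,
        subcluster_id = if (length(subs) > 1) sub_ids[s] else NA_character_,
        signature_subindex = unname(subidx[keys]),
        singleton = length(mem) == 1,
        stringsAsFactors = FALSE)
      clusters[[if (length(subs) > 1) sub_ids[s] else cid]] <- mem
    }
  }
  list(assignments = do.call(rbind, rows), graph = graph,
       clusters = clusters)
}
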