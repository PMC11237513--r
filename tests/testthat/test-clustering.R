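test_that("disconnected components never merge and isolated nodes stay singletons", {
  g <- clique_graph(c(3, 3), weight = 80)
  g$nodes <- c(g$nodes, "lonely")
  part <- mcl(g, inflation = 1.2)
  sizes <- sort(lengths(part$clusters))
  expect_equal(sizes, c(1L, 3L, 3L))
  expect_equal(part$clusters[[which(lengths(part$clusters) == 1)]],
               "lonely")
})

test_that("a weak bridge between two dense cliques is cut", {
  g <- clique_graph(c(4, 4), weight = 80)
  g$edges <- rbind(g$edges,
                   data.frame(from = "q1_1", to = "q2_1", weight = 10,
                              stringsAsFactors = FALSE))
  part <- mcl(g, inflation = 2.0)
  expect_equal(sort(lengths(part$clusters)), c(4L, 4L))
  ## dense reference implementation agrees
  nodes <- sort(g$nodes)
  A <- matrix(0, 8, 8, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(g$edges))) {
    A[g$edges$from[r], g$edges$to[r]] <- g$edges$weight[r]
    A[g$edges$to[r], g$edges$from[r]] <- g$edges$weight[r]
  }
  ref <- oracle_mcl_partition(A, inflation = 2.0)
  got <- part$membership[nodes]
  expect_equal(length(unique(ref)), 2L)
  for (k in unique(ref))
    expect_length(unique(got[ref == k]), 1L)
})

test_that("clique unions are recovered exactly across inflations", {
  set.seed(211)
  for (rep in 1:15) {
    sizes <- sample(1:6, sample(2:4, 1), replace = TRUE)
    g <- clique_graph(sizes, weight = sample(c(40, 60, 90), 1))
    for (infl in c(1.2, 1.6, 2.0)) {
      part <- mcl(g, inflation = infl)
      expect_equal(sort(lengths(part$clusters)), sort(sizes))
      ## each clique is one cluster
      for (k in seq_along(sizes)) {
        ids <- grep(sprintf("^q%d_", k), g$nodes, value = TRUE)
        expect_length(unique(part$membership[ids]), 1L)
      }
    }
  }
})

test_that("mcl always returns a partition and is insertion-order invariant", {
  set.seed(223)
  for (rep in 1:30) {
    n <- sample(4:15, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    pairs <- t(utils::combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.3
    edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                        weight = round(runif(sum(keep), 25, 95), 1),
                        stringsAsFactors = FALSE)
    g <- list(nodes = nodes, edges = edges)
    part <- mcl(g, inflation = 1.6)
    expect_setequal(names(part$membership), nodes)
    expect_equal(sum(lengths(part$clusters)), n)   # every node exactly once
    expect_false(anyDuplicated(unlist(part$clusters)) > 0)

    perm <- sample(n)
    g2 <- list(nodes = nodes[perm],
               edges = edges[sample(nrow(edges)), , drop = FALSE])
    part2 <- mcl(g2, inflation = 1.6)
    expect_equal(part2$membership[nodes], part$membership[nodes])
  }
  expect_error(mcl(list(nodes = "a", edges = NULL), inflation = 1.0),
               "inflation")
  expect_error(mcl(list(nodes = character(0), edges = NULL), 1.5),
               "empty")
})

test_that("higher inflation never coarsens the fixed random-graph suite on average", {
  set.seed(227)
  n_low <- n_high <- numeric(20)
  for (rep in 1:20) {
    n <- sample(8:14, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    pairs <- t(utils::combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.4
    g <- list(nodes = nodes,
              edges = data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                                 weight = round(runif(sum(keep), 25, 95), 1),
                                 stringsAsFactors = FALSE))
    n_low[rep] <- length(mcl(g, 1.2)$clusters)
    n_high[rep] <- length(mcl(g, 1.6)$clusters)
  }
  expect_gte(mean(n_high), mean(n_low))
})

test_that("subclustering applies only above 10 members and respects both gates", {
  ## two tight 6-member groups (90% within) joined by one cross edge
  build <- function(cross_identity) {
    nodes <- c(sprintf("a%d", 1:6), sprintf("b%d", 1:6))
    pr <- t(utils::combn(nodes, 2))
    same <- substr(pr[, 1], 1, 1) == substr(pr[, 2], 1, 1)
    keep <- same | (pr[, 1] == "a1" & pr[, 2] == "b1")
    pr <- pr[keep, , drop = FALSE]
    w <- ifelse(substr(pr[, 1], 1, 1) == substr(pr[, 2], 1, 1), 90,
                cross_identity)
    list(nodes = nodes,
         edges = data.frame(from = pr[, 1], to = pr[, 2], weight = w,
                            stringsAsFactors = FALSE))
  }
  kos <- setNames(rep(c("K00001", "K00002"), each = 6),
                  c(sprintf("a%d", 1:6), sprintf("b%d", 1:6)))
  lens <- setNames(rep(c(100, 300), each = 6), names(kos))

  g <- build(30)
  out <- subcluster(g$nodes, g, annotations = kos, lengths = lens)
  expect_length(out, 2L)
  expect_setequal(out[[1]], sprintf(if ("a1" %in% out[[1]]) "a%d"
                                    else "b%d", 1:6))

  ## cross identity at/above 40 rejects the split
  g45 <- build(45)
  expect_length(subcluster(g45$nodes, g45, annotations = kos,
                           lengths = lens), 1L)

  ## shared KO labels and similar lengths reject the split
  same_ko <- setNames(rep("K00001", 12), names(kos))
  same_len <- setNames(rep(100, 12), names(kos))
  expect_length(subcluster(g$nodes, g, annotations = same_ko,
                           lengths = same_len), 1L)

  ## a cluster of exactly 10 is never subclustered
  g10 <- clique_graph(c(5, 5), weight = 90)
  expect_length(subcluster(g10$nodes, g10, annotations = NULL,
                           lengths = NULL), 1L)
})

test_that("architecture subindices rank signatures by abundance then name", {
  sigs <- c(lapply(1:5, function(i) c("X", "Y")),
            lapply(1:2, function(i) c("X", "Z")))
  names(sigs) <- sprintf("p%d", 1:7)
  idx <- assign_subindices(names(sigs), sigs)
  expect_equal(unname(idx["X|Y"]), 1L)
  expect_equal(unname(idx["X|Z"]), 2L)

  tied <- c(lapply(1:3, function(i) c("B")), lapply(1:3, function(i) c("A")))
  names(tied) <- sprintf("t%d", 1:6)
  idx2 <- assign_subindices(names(tied), tied)
  expect_equal(unname(idx2["A"]), 1L)  # lexicographic tie-break
  expect_equal(unname(idx2["B"]), 2L)

  one <- assign_subindices("p1", list(p1 = c("X", "Y")))
  expect_equal(unname(one["X|Y"]), 1L)
})
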