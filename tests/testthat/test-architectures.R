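test_that("disjoint hits all survive, in start order", {
  hits <- make_hit(c("p", "p"), c("PFA", "PFB"), c(1L, 120L),
                   c(100L, 200L), bitscore = c(50, 40))
  arch <- resolve_architecture(hits)
  expect_equal(arch$token_id, c("PFA", "PFB"))
  expect_equal(arch$start, c(1L, 120L))
})

test_that("overlaps beyond the tolerance drop the weaker hit", {
  hits <- make_hit(c("p", "p"), c("PFA", "PFB"), c(1L, 80L),
                   c(100L, 200L), bitscore = c(50, 40))
  arch <- resolve_architecture(hits, max_token_overlap = 15)  # overlap 21
  expect_equal(arch$token_id, "PFA")
  arch2 <- resolve_architecture(hits, max_token_overlap = 25)
  expect_equal(arch2$token_id, c("PFA", "PFB"))
})

test_that("equal-score ties resolve by start then accession", {
  hits <- make_hit(rep("p", 2), c("PFZ", "PFA"), c(1L, 1L), c(100L, 100L),
                   bitscore = c(40, 40))
  arch <- resolve_architecture(hits)
  expect_equal(arch$token_id, "PFA")
})

test_that("clan mapping replaces accessions at the token level", {
  hits <- make_hit(c("p", "p"), c("PF00001", "PF99999"), c(1L, 150L),
                   c(100L, 250L))
  clans <- data.frame(domain_acc = "PF00001", clan_acc = "CL0123",
                      stringsAsFactors = FALSE)
  arch <- resolve_architecture(hits, clans)
  expect_equal(signature(arch), c("CL0123", "PF99999"))
})

test_that("signatures preserve order, repeats, and emptiness", {
  hits <- make_hit(c("p", "p"), c("PFA", "PFA"), c(1L, 150L),
                   c(100L, 250L))
  expect_equal(signature(resolve_architecture(hits)), c("PFA", "PFA"))
  empty <- resolve_architecture(make_hit(character(0), character(0),
                                         integer(0), integer(0)))
  expect_length(signature(empty), 0L)
})

test_that("composite candidacy needs two or more tokens, self-fusions count", {
  one <- resolve_architecture(make_hit("p", "PFA", 1L, 100L))
  expect_false(is_composite_candidate(one))
  two <- resolve_architecture(make_hit(c("p", "p"), c("PFA", "PFB"),
                                       c(1L, 150L), c(100L, 250L)))
  expect_true(is_composite_candidate(two))
  selff <- resolve_architecture(make_hit(c("p", "p"), c("PFA", "PFA"),
                                         c(1L, 150L), c(100L, 250L)))
  expect_true(is_composite_candidate(selff))
})

test_that("resolved architectures never violate the overlap bound and are order-invariant", {
  set.seed(73)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    starts <- sample(1:300, n)
    hits <- make_hit(rep("p", n), sprintf("PF%05d", sample(1e4, n)),
                     starts, starts + sample(30:120, n, replace = TRUE),
                     bitscore = round(runif(n, 10, 90), 1))
    tol <- sample(c(0, 15, 40), 1)
    arch <- resolve_architecture(hits, max_token_overlap = tol)
    if (nrow(arch) > 1) {
      for (i in seq_len(nrow(arch) - 1)) {
        ov <- pmax(0L, pmin(arch$end[i], arch$end[-(1:i)]) -
                     pmax(arch$start[i], arch$start[-(1:i)]) + 1L)
        expect_true(all(ov <= tol))
      }
    }
    shuffled <- hits[sample(nrow(hits)), , drop = FALSE]
    expect_equal(resolve_architecture(shuffled, max_token_overlap = tol),
                 arch)
  }
})

test_that("greedy selection keeps at least half the brute-force optimum", {
  set.seed(74)
  for (rep in 1:30) {
    n <- sample(2:8, 1)
    starts <- sample(1:200, n)
    hits <- make_hit(rep("p", n), sprintf("PF%05d", seq_len(n)),
                     starts, starts + sample(30:100, n, replace = TRUE),
                     bitscore = round(runif(n, 5, 80), 1))
    arch <- resolve_architecture(hits, max_token_overlap = 15)
    opt <- oracle_best_hit_subset(hits, max_overlap = 15)
    expect_gte(sum(arch$bitscore), 0.5 * opt)
  }
})
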