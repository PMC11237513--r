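test_that("identical sequences align at 100% identity over their full length", {
  set.seed(101)
  s <- rand_seq(50)
  hit <- local_align(s, s)
  expect_equal(hit$pct_identity, 100)
  expect_equal(c(hit$q_start, hit$q_end), c(1L, 50L))
  expect_equal(c(hit$s_start, hit$s_end), c(1L, 50L))
  expect_equal(global_percent_identity(s, s), 100)
})

test_that("sequences with no positive-scoring pair yield no local alignment", {
  ## G vs W scores -2 under BLOSUM62: every column is negative
  expect_null(local_align("GGGGG", "WWWWW"))
  expect_equal(local_align_score("GGGGG", "WWWWW"), 0)
  expect_equal(global_percent_identity("AAAA", "TTTT"), 0)
})

test_that("invalid sequences are rejected", {
  expect_error(local_align("", "MKV"), "non-empty")
  expect_error(global_percent_identity("MKV", "MK9"), "non-amino-acid")
  expect_error(local_align("MKX", "MKV"), "non-amino-acid")
})

test_that("local and global scores match exhaustive enumeration on short pairs", {
  set.seed(103)
  scheme <- scoring_scheme()
  for (rep in 1:25) {
    a <- rand_seq(sample(2:6, 1))
    b <- rand_seq(sample(2:6, 1))
    expect_equal(global_align_score(a, b), oracle_global_enum(a, b, scheme))
    expect_equal(local_align_score(a, b), oracle_local_enum(a, b, scheme))
  }
})

test_that("global identity is symmetric", {
  set.seed(107)
  for (rep in 1:20) {
    a <- rand_seq(sample(5:40, 1))
    b <- rand_seq(sample(5:40, 1))
    expect_equal(global_percent_identity(a, b),
                 global_percent_identity(b, a))
  }
})

test_that("the E-value decreases strictly with score at fixed lengths", {
  scheme <- scoring_scheme()
  ev <- function(score) scheme$karlin_k * 100 * 1e6 *
    exp(-scheme$karlin_lambda * score)
  scores <- seq(20, 200, by = 20)
  expect_true(all(diff(vapply(scores, ev, 0)) < 0))
  ## and through the public interface: a longer perfect match scores
  ## higher and gets a smaller E-value
  set.seed(109)
  s <- rand_seq(80)
  h1 <- local_align(substr(s, 1, 30), s, db_size_letters = 1e6)
  h2 <- local_align(s, s, db_size_letters = 1e6)
  expect_gt(h2$bitscore, h1$bitscore)
  expect_lt(h2$evalue, h1$evalue)
})

test_that("local score is at least the best exact-substring score", {
  set.seed(113)
  scheme <- scoring_scheme()
  S <- scheme$matrix
  for (rep in 1:15) {
    a <- rand_seq(sample(6:14, 1))
    b <- rand_seq(sample(6:14, 1))
    ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
    best_sub <- 0
    for (i in seq_along(ac)) {
      for (j in seq_along(bc)) {
        k <- 0; s <- 0
        while (i + k <= length(ac) && j + k <= length(bc) &&
               ac[i + k] == bc[j + k]) {
          s <- s + S[ac[i + k], ac[i + k]]
          k <- k + 1
          best_sub <- max(best_sub, s)
        }
      }
    }
    expect_gte(local_align_score(a, b, scheme), best_sub)
  }
})
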