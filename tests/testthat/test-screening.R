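test_that("split-set enumeration matches the forced examples", {
  g <- list(P = "A", Q = "B")
  expect_equal(enumerate_split_sets(c("A", "B"), g), list(c("P", "Q")))

  g2 <- list(P = c("A", "B"), Q = "C", R = "A", S = "B")
  sets <- enumerate_split_sets(c("A", "B", "C"), g2)
  expect_setequal(lapply(sets, paste, collapse = "+"),
                  list("P+Q", "R+S+Q"))

  g3 <- list(P = c("B", "A"))
  expect_equal(enumerate_split_sets(c("A", "B"), g3), list())
})

test_that("split-set enumeration agrees with the brute-force partition oracle", {
  set.seed(19)
  toks <- LETTERS[1:5]
  for (rep in 1:60) {
    L <- sample(2:5, 1)
    sig <- sample(toks, L, replace = TRUE)
    np <- sample(2:12, 1)
    genome <- lapply(seq_len(np), function(i)
      sample(toks, sample(1:3, 1), replace = TRUE))
    names(genome) <- sprintf("p%02d", seq_len(np))
    got <- enumerate_split_sets(sig, genome)
    want <- oracle_split_sets(sig, genome)
    key <- function(x) sort(vapply(x, paste, "", collapse = "+"))
    expect_equal(key(got), key(want))
  }
})

test_that("synteny uses the chained five-gene rule on one contig", {
  genes <- make_genes(sprintf("p%d", 1:12))
  expect_true(is_syntenic(c("p4", "p9"), genes))    # ranks 3 and 8, gap 5
  expect_false(is_syntenic(c("p4", "p10"), genes))  # gap 6
  expect_true(is_syntenic(c("p3", "p7", "p12"), genes))  # gaps 4 and 5
  two_ctg <- rbind(make_genes("a1", contig_id = "c1"),
                   make_genes("b1", contig_id = "c2"))
  expect_false(is_syntenic(c("a1", "b1"), two_ctg))
  expect_error(is_syntenic(c("p4", "zz"), genes), "no gene record")
})

test_that("pairwise filters use strict identity/E-value and inclusive coverage", {
  base <- make_aln(pct_identity = 30, evalue = 1e-12, s_start = 1L,
                   s_end = 120L)
  expect_true(pair_passes_filters(base, split_len = 200))  # cov 0.60 exactly
  expect_false(pair_passes_filters(
    make_aln(pct_identity = 25.0, evalue = 1e-10, s_end = 160L), 200))
  expect_false(pair_passes_filters(
    make_aln(pct_identity = 30, evalue = 1e-9, s_end = 160L), 200))
  expect_false(pair_passes_filters(
    make_aln(pct_identity = 30, evalue = 1e-12, s_end = 119L), 200))
  expect_error(pair_passes_filters(base, split_len = 0), "positive")
})

test_that("set-level filter bounds pairwise overlap and composite coverage", {
  a <- rbind(make_aln(q_start = 1L, q_end = 200L),
             make_aln(q_start = 151L, q_end = 480L))
  expect_true(set_passes_filters(a, composite_len = 500))  # overlap 50, cov 0.96
  b <- rbind(make_aln(q_start = 1L, q_end = 200L),
             make_aln(q_start = 100L, q_end = 480L))
  expect_false(set_passes_filters(b, composite_len = 500))  # overlap 101
  single <- make_aln(q_start = 1L, q_end = 290L)
  expect_false(set_passes_filters(single, composite_len = 500,
                                  n_members = 2))  # member unaligned
  expect_false(set_passes_filters(single, composite_len = 500,
                                  n_members = 1))  # coverage 0.58
})

test_that("families require a syntenic passing set, then adopt non-syntenic ones", {
  cand <- data.frame(protein_id = "comp1", genome_id = "G1",
                     sig_key = "A|B", stringsAsFactors = FALSE)
  syn_set <- list(sig_key = "A|B", genome_id = "G2",
                  members = c("x1", "x2"), syntenic = TRUE, passes = TRUE)
  nonsyn <- list(sig_key = "A|B", genome_id = "G3",
                 members = c("y1", "y2"), syntenic = FALSE, passes = TRUE)

  fams <- assemble_families(cand, list(syn_set))
  expect_length(fams, 1L)
  expect_equal(fams[[1]]$composite_ids, "comp1")

  expect_length(assemble_families(cand, list(nonsyn)), 0L)

  fams3 <- assemble_families(cand, list(syn_set, nonsyn))
  expect_length(fams3, 1L)
  expect_equal(vapply(fams3[[1]]$split_sets, `[[`, TRUE, "syntenic"),
               c(TRUE, FALSE))

  failing <- list(sig_key = "A|B", genome_id = "G2",
                  members = c("x1", "x2"), syntenic = TRUE, passes = FALSE)
  expect_length(assemble_families(cand, list(failing, nonsyn)), 0L)
})

test_that("split-set and split-protein frequencies match hand arithmetic", {
  expect_equal(split_set_frequency(make_family(n_comp = 3, n_syn = 2)), 0.4)
  expect_equal(split_set_frequency(make_family(n_comp = 9, n_syn = 1)), 0.1)
  expect_equal(split_protein_frequency(make_family(n_comp = 3, n_syn = 1)),
               0.4)  # one pair: 2 / (3 + 2)
  expect_equal(split_protein_frequency(
    make_family(n_comp = 1, n_syn = 1, members_per_set = 3)), 0.75)
  ## non-syntenic sets never enter either frequency
  expect_equal(split_set_frequency(make_family(n_comp = 3, n_syn = 2,
                                               n_nonsyn = 4)), 0.4)
})

test_that("split-protein frequency dominates split-set frequency", {
  set.seed(29)
  for (rep in 1:50) {
    fam <- make_family(n_comp = sample(1:10, 1), n_syn = sample(1:8, 1),
                       n_nonsyn = sample(0:3, 1),
                       members_per_set = sample(2:4, 1))
    expect_gte(split_protein_frequency(fam), split_set_frequency(fam))
  }
})

test_that("tightening any threshold never adds a passing pair or set", {
  set.seed(31)
  for (rep in 1:40) {
    aln <- make_aln(pct_identity = runif(1, 10, 60),
                    evalue = 10^runif(1, -20, -5),
                    s_start = 1L, s_end = sample(60:200, 1))
    lenient <- pair_passes_filters(aln, split_len = 200)
    strict <- pair_passes_filters(aln, split_len = 200,
                                  min_identity = 35, max_evalue = 1e-12,
                                  min_split_cov = 0.8)
    expect_true(!strict || lenient)
  }
  for (rep in 1:40) {
    n <- sample(2:3, 1)
    qs <- sort(sample(1:300, n))
    alns <- do.call(rbind, lapply(seq_len(n), function(i)
      make_aln(q_start = qs[i], q_end = qs[i] + sample(80:250, 1))))
    lenient <- set_passes_filters(alns, composite_len = 600)
    strict <- set_passes_filters(alns, composite_len = 600,
                                 max_pair_overlap = 40,
                                 min_composite_cov = 0.8)
    expect_true(!strict || lenient)
  }
})

test_that("emitted families always satisfy the family invariants", {
  ds <- generate_synthetic_dataset(small_synth_config(seed = 5))
  res <- run_screen(ds)
  for (f in res$families) {
    expect_gte(length(f$composite_ids), 1L)
    syn <- vapply(f$split_sets, `[[`, TRUE, "syntenic")
    expect_gte(sum(syn), 1L)
    for (s in f$split_sets) expect_gte(length(s$members), 2L)
  }
})
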