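test_that("KO acceptance honors model thresholds and the best-hit rule", {
  row <- function(ko, bits, eval, thr = NA_real_) {
    data.frame(protein_id = "p", ko_id = ko, bitscore = bits,
               evalue = eval, model_threshold = thr, model_coverage = 0.9,
               stringsAsFactors = FALSE)
  }
  ## threshold boundary is inclusive
  expect_equal(ko_accept(row("K1", 100, 1e-20, thr = 100))$ko_id, "K1")
  expect_null(ko_accept(row("K1", 99.9, 1e-20, thr = 100)))
  ## no threshold: strict E-value below 1e-10
  expect_null(ko_accept(row("K1", 50, 1e-10)))
  expect_equal(ko_accept(row("K1", 50, 9e-11))$ko_id, "K1")
  ## no threshold: must be the protein's best hit, so K2 is dropped even
  ## with a tiny E-value
  two <- rbind(row("K1", 80, 1e-40), row("K2", 50, 1e-30))
  expect_equal(ko_accept(two)$ko_id, "K1")
  mixed <- rbind(row("K1", 120, 1e-40, thr = 100), row("K2", 200, 1e-50))
  expect_equal(ko_accept(mixed)$ko_id, "K2")  # best bitscore among kept
})

test_that("bacterial proteins map only through identical-architecture best hits", {
  sigs <- list(compX = c("A", "B"), compY = c("C", "D"))
  clus <- c(compX = "7", compY = "9")
  hit <- function(subj, bits) make_aln("bact1", subj, bitscore = bits)

  r <- map_bacterial(hit("compX", 300), c("A", "B"), sigs, clus)
  expect_equal(r$outcome, "mapped")
  expect_equal(r$cluster_id, "7")

  r2 <- map_bacterial(hit("compX", 300), c("A", "B", "E"), sigs, clus)
  expect_equal(r2$outcome, "architecture_mismatch")

  r3 <- map_bacterial(hit("split9", 300), c("A", "B"), sigs, clus)
  expect_equal(r3$outcome, "none")

  ## equal-best tie: the identical-architecture composite wins
  tie <- rbind(hit("split9", 300), hit("compX", 300))
  expect_equal(map_bacterial(tie, c("A", "B"), sigs, clus)$outcome,
               "mapped")
})

test_that("cluster statistics aggregate families as documented", {
  fam <- make_family(n_comp = 9, n_syn = 1)  # split set lives in G1
  genes <- make_genes(c(fam$composite_ids,
                        unlist(lapply(fam$split_sets, `[[`, "members"))),
                      genome_id = c(sprintf("CG%d", 1:9), "G1", "G1"))
  stats <- compute_stats(fam$composite_ids, list(fam), genes)
  expect_equal(stats$split_set_freq, 0.1)
  expect_true(is.na(stats$n_bact_genomes_with_composite))
  expect_equal(stats$frac_composites_also_split, 0)

  metas <- make_meta(c(sprintf("CG%d", 1:9), "G1"))
  stats2 <- compute_stats(fam$composite_ids, list(fam), genes, metas)
  expect_equal(stats2$complete_genomes_composite, 9L)
  expect_equal(stats2$complete_genomes_split_only, 1L)
})

test_that("the spec'd classification examples come out as dictated", {
  lab <- function(...) classify(stats_for_votes(...))$label
  expect_equal(lab("fission", "fission", "fission", "abstain"),
               "fission_high")
  expect_equal(lab("fusion", "fusion", "fusion", "abstain"), "fusion_high")
  expect_equal(lab("abstain", "abstain", "abstain", "abstain"),
               "unclassified")
  expect_equal(lab("abstain", "fusion", "abstain", "abstain"),
               "fusion_probable")
  ## the fusion-and-fission override precedes voting
  s <- stats_for_votes("fission", "fission", "fission", "fission",
                       frac_both = 0.25)
  expect_equal(classify(s)$label, "fusion_and_fission")
})

test_that("classification is total over the vote cross-product and replayable", {
  states <- c("fission", "fusion", "abstain")
  for (v1 in states) for (v2 in states) for (v3 in states)
    for (v4 in c("fission", "abstain")) {
      res <- classify(stats_for_votes(v1, v2, v3, v4))
      expect_true(res$label %in% c("fusion_high", "fusion_probable",
                                   "fission_high", "fission_probable",
                                   "fusion_and_fission", "unclassified"))
      ## the recorded votes are exactly the requested combination ...
      expect_equal(unname(res$votes), c(v1, v2, v3, v4))
      ## ... and replaying them reproduces the label
      expect_equal(expected_label_from_votes(res$votes), res$label)
    }
})

test_that("strengthening fission evidence never flips a fission label to fusion", {
  set.seed(311)
  base <- stats_for_votes("fission", "fission", "fission", "fission")
  for (rep in 1:200) {
    s <- base
    s$split_set_freq <- max(0, base$split_set_freq - runif(1, 0, 0.05))
    s$n_bact_genomes_with_composite <- base$n_bact_genomes_with_composite +
      sample(0:2000, 1)
    s$n_bact_phyla_with_composite <- base$n_bact_phyla_with_composite +
      sample(0:10, 1)
    lab <- classify(s)$label
    expect_false(lab %in% c("fusion_high", "fusion_probable"))
  }
  base_u <- stats_for_votes("fusion", "fusion", "fusion", "abstain")
  for (rep in 1:200) {
    s <- base_u
    s$split_set_freq <- min(1, base_u$split_set_freq + runif(1, 0, 0.05))
    s$n_bact_genomes_with_composite <- 0L
    lab <- classify(s)$label
    expect_false(lab %in% c("fission_high", "fission_probable"))
  }
})
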