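test_that("the generator is deterministic: same seed, byte-identical files", {
  cfg <- small_synth_config(seed = 17)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_synthetic_dataset(cfg, dir = d1)
  generate_synthetic_dataset(cfg, dir = d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("no planted events means no planted truth rows and no families", {
  cfg <- synth_config(seed = 3, n_genomes = 6,
                      n_planted_fusion_families = 0,
                      n_planted_fission_families = 0,
                      frac_technical_fission = 0,
                      n_background_families = 8,
                      promiscuous_domain_count = 2,
                      fragmented_genome_fraction = 0)
  ds <- generate_synthetic_dataset(cfg)
  expect_true(is.null(ds$truth) || nrow(ds$truth) == 0)
  res <- run_screen(ds)
  expect_length(res$families, 0L)
})

test_that("target identity 1 gives identical homolog copies", {
  cfg <- small_synth_config(seed = 23, target_identity = 1)
  ds <- generate_synthetic_dataset(cfg)
  ev <- ds$truth[ds$truth$kind == "fission", ][1, ]
  comp <- strsplit(ev$composite_ids, ",")[[1]]
  expect_gt(length(comp), 1)
  expect_length(unique(unname(ds$proteins[comp])), 1L)
})

test_that("empirical pairwise identity tracks the configured target", {
  cfg <- small_synth_config(seed = 29)
  ds <- generate_synthetic_dataset(cfg)
  ids <- c()
  for (e in seq_len(nrow(ds$truth))) {
    comp <- strsplit(ds$truth$composite_ids[e], ",")[[1]]
    if (length(comp) < 2) next
    pairs <- utils::combn(comp, 2)
    for (k in seq_len(ncol(pairs))) {
      a <- strsplit(ds$proteins[[pairs[1, k]]], "")[[1]]
      b <- strsplit(ds$proteins[[pairs[2, k]]], "")[[1]]
      ids <- c(ids, mean(a == b))  # homologs are equal length (no indels)
    }
  }
  expect_gte(length(ids), 100)
  expect_lt(abs(mean(ids) - cfg$target_identity), 0.03)
})

test_that("planted syntenic split genes are genomically colocalized", {
  ds <- generate_synthetic_dataset(small_synth_config(seed = 31))
  for (e in seq_len(nrow(ds$truth))) {
    split_ids <- strsplit(ds$truth$split_ids[e], ",")[[1]]
    genomes <- strsplit(ds$truth$split_genomes[e], ",")[[1]]
    for (g in genomes) {
      members <- split_ids[startsWith(split_ids, paste0(g, "_"))]
      expect_true(is_syntenic(members, ds$genes, max_gene_sep = 5))
    }
  }
})

test_that("the truth table is internally consistent with the gene table", {
  ds <- generate_synthetic_dataset(small_synth_config(seed = 37))
  referenced <- unique(unlist(strsplit(
    c(ds$truth$composite_ids, ds$truth$split_ids), ",")))
  expect_true(all(referenced %in% ds$genes$protein_id))
  expect_true(all(referenced %in% names(ds$proteins)))
  ## every gene has a sequence of the declared length
  expect_equal(unname(nchar(ds$proteins[ds$genes$protein_id])),
               ds$genes$length_aa)
})

test_that("truth scoring arithmetic matches its definitions", {
  fam <- make_family(id = "F1", sig = c("A", "B"))
  fam$composite_ids <- "G1_E1_c"
  fam$split_sets <- list(list(set_id = "S001", genome_id = "G2",
                              members = c("G2_E1_s1", "G2_E1_s2"),
                              syntenic = TRUE))
  truth <- data.frame(
    event_id = c("E1", "E2"), kind = c("fusion", "fusion"),
    signature = c("A|B", "C|D"),
    composite_genomes = c("G1", "G3"), split_genomes = c("G2", "G4"),
    composite_ids = c("G1_E1_c", "G3_E2_c"),
    split_ids = c("G2_E1_s1,G2_E1_s2", "G4_E2_s1,G4_E2_s2"),
    stringsAsFactors = FALSE)
  sc <- score_against_truth(list(fam), truth)
  expect_equal(sc$recall[["fusion"]], 0.5)
  expect_equal(sc$precision, 1)

  spurious <- make_family(id = "F2", sig = c("Z", "Z"))
  sc2 <- score_against_truth(list(fam, spurious), truth)
  expect_equal(sc2$precision, 0.5)  # detected_true / (detected_true + 1)
  expect_equal(sc2$n_matched, 1L)
})
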