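## In-code fixture builders shared across test files.

make_genes <- function(protein_id, genome_id = "G1", contig_id = "c1",
                       gene_index = seq_along(protein_id) - 1L,
                       length_aa = 100L) {
  n <- length(protein_id)
  data.frame(protein_id = protein_id,
             genome_id = rep_len(genome_id, n),
             contig_id = rep_len(contig_id, n),
             gene_index = gene_index,
             strand = rep_len("+", n),
             start = 1L + (gene_index * 1000L),
             end = 303L + (gene_index * 1000L),
             length_aa = rep_len(length_aa, n),
             stringsAsFactors = FALSE)
}

make_hit <- function(protein_id, domain_acc, ali_start, ali_end,
                     bitscore = 50, evalue = 1e-20) {
  n <- length(protein_id)
  data.frame(protein_id = protein_id, domain_acc = domain_acc,
             ali_start = ali_start, ali_end = ali_end,
             bitscore = rep_len(bitscore, n), evalue = rep_len(evalue, n),
             stringsAsFactors = FALSE)
}

make_aln <- function(query_id = "q", subject_id = "s", pct_identity = 50,
                     q_start = 1L, q_end = 100L, s_start = 1L,
                     s_end = 100L, evalue = 1e-20, bitscore = 100) {
  data.frame(query_id = query_id, subject_id = subject_id,
             pct_identity = pct_identity,
             aln_length = q_end - q_start + 1L, mismatch = 0L,
             gapopen = 0L, q_start = q_start, q_end = q_end,
             s_start = s_start, s_end = s_end, evalue = evalue,
             bitscore = bitscore, stringsAsFactors = FALSE)
}

make_meta <- function(genome_id, assembly_level = "complete",
                      completeness = 0.95, redundancy = 0.02,
                      taxon_path = "Archaea;PhylumA;GenusX") {
  n <- length(genome_id)
  data.frame(genome_id = genome_id,
             assembly_level = rep_len(assembly_level, n),
             completeness = rep_len(completeness, n),
             redundancy = rep_len(redundancy, n),
             taxon_path = rep_len(taxon_path, n),
             stringsAsFactors = FALSE)
}

## a hand-built family: C composites, n_syn syntenic pairs, n_nonsyn
## non-syntenic pairs, members_per_set proteins per set
make_family <- function(n_comp = 1, n_syn = 1, n_nonsyn = 0,
                        members_per_set = 2, id = "F0001",
                        sig = c("A", "B")) {
  sets <- list()
  for (i in seq_len(n_syn + n_nonsyn)) {
    sets[[i]] <- list(set_id = sprintf("S%03d", i),
                      genome_id = sprintf("G%d", i),
                      members = sprintf("%s_set%d_m%d", id, i,
                                        seq_len(members_per_set)),
                      syntenic = i <= n_syn)
  }
  structure(list(family_id = id, signature = sig,
                 composite_ids = sprintf("%s_comp%d", id, seq_len(n_comp)),
                 split_sets = sets,
                 cluster_id = NA_character_,
                 cluster_subindex = NA_integer_),
            class = "fusion_family")
}

## a random amino-acid string
rand_seq <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                 "F","P","S","T","W","Y","V"), n, replace = TRUE),
        collapse = "")
}

## uniform-weight clique-union graph from a vector of clique sizes
clique_graph <- function(sizes, weight = 60) {
  nodes <- character(0); from <- character(0); to <- character(0)
  for (k in seq_along(sizes)) {
    ids <- sprintf("q%d_%d", k, seq_len(sizes[k]))
    nodes <- c(nodes, ids)
    if (sizes[k] > 1) {
      pr <- t(utils::combn(ids, 2))
      from <- c(from, pr[, 1]); to <- c(to, pr[, 2])
    }
  }
  list(nodes = nodes,
       edges = data.frame(from = from, to = to,
                          weight = rep(weight, length(from)),
                          stringsAsFactors = FALSE))
}

## small synthetic configuration used by pipeline tests
small_synth_config <- function(seed = 11, ...) {
  synth_config(seed = seed, n_genomes = 12,
               n_background_families = 10,
               n_planted_fusion_families = 4,
               n_planted_fission_families = 3,
               frac_technical_fission = 0,
               promiscuous_domain_count = 2,
               fusion_composite_genomes = 1,
               fusion_split_genomes = 10,
               fission_composite_genomes = 10,
               fission_split_genomes = 1,
               n_nonsyntenic_fusion_sets = 1,
               clan_mapped_fusion_families = 1, ...)
}
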