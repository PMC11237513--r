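## Readers, writers and record validation for every table format the
## pipeline consumes or produces.  All coordinates are 1-based inclusive;
## nucleotide and amino-acid coordinate systems are never mixed in one table.

GENE_COLS  <- c("protein_id", "genome_id", "contig_id", "gene_index",
                "strand", "start", "end", "length_aa")
HIT_COLS   <- c("protein_id", "domain_acc", "ali_start", "ali_end",
                "bitscore", "evalue")
ALN_COLS   <- c("query_id", "subject_id", "pct_identity", "aln_length",
                "mismatch", "gapopen", "q_start", "q_end", "s_start",
                "s_end", "evalue", "bitscore")
KO_COLS    <- c("protein_id", "ko_id", "bitscore", "evalue",
                "model_threshold", "model_coverage")
META_COLS  <- c("genome_id", "assembly_level", "completeness",
                "redundancy", "taxon_path")
ASSEMBLY_LEVELS <- c("complete", "chromosome", "scaffold", "contig")

stop_line <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

#' Validate a gene record table
#'
#' Checks the invariants of the gene-record container: `start <= end`,
#' `length_aa >= 1`, strand in `+`/`-`, unique `protein_id`, and unique
#' `gene_index` within each `(genome_id, contig_id)`.
#'
#' @param genes data.frame with columns `protein_id`, `genome_id`,
#'   `contig_id`, `gene_index` (0-based rank along the contig), `strand`,
#'   `start`, `end` (1-based nucleotide, inclusive), `length_aa`.
#' @return `genes`, invisibly, if valid; otherwise an error.
#' @export
validate_gene_table <- function(genes) {
  stopifnot(is.data.frame(genes), all(GENE_COLS %in% names(genes)))
  if (anyDuplicated(genes$protein_id))
    stop("duplicate protein_id: ",
         genes$protein_id[duplicated(genes$protein_id)][1], call. = FALSE)
  if (any(genes$start > genes$end))
    stop("gene with start > end: ",
         genes$protein_id[genes$start > genes$end][1], call. = FALSE)
  if (any(genes$length_aa < 1))
    stop("gene with length_aa < 1", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  key <- paste(genes$genome_id, genes$contig_id, genes$gene_index)
  if (anyDuplicated(key))
    stop("duplicate gene_index within a contig", call. = FALSE)
  invisible(genes)
}

## Assign per-contig 0-based ranks by ascending start and sort the table.
rank_genes <- function(genes) {
  genes <- genes[order(genes$genome_id, genes$contig_id, genes$start,
                       genes$protein_id), , drop = FALSE]
  contig <- paste(genes$genome_id, genes$contig_id, sep = "\r")
  genes$gene_index <- stats::ave(genes$start, contig,
                                 FUN = function(x) seq_along(x) - 1L)
  genes$gene_index <- as.integer(genes$gene_index)
  rownames(genes) <- NULL
  genes[, GENE_COLS]
}

#' Read a gene-coordinate table
#'
#' Two dialects are supported: a flat TSV with header
#' `genome_id, contig_id, protein_id, start, end, strand` (optional
#' `length_aa`), and GFF3 restricted to `CDS` features, whose identity is
#' the first present of the `ID`, `protein_id` or `locus_tag` attribute.
#' In both dialects `gene_index` is assigned per contig by ascending start
#' coordinate and the result is sorted by (genome, contig, gene_index).
#' When `length_aa` is not given it is derived from the nucleotide span as
#' `span %/% 3 - 1` (one codon removed for the stop).
#'
#' @param path file path.
#' @param dialect `"flat_tsv"` or `"gff3"`.
#' @param genome_id genome label for GFF3 input (GFF3 carries no genome
#'   column); defaults to the file name without extension.
#' @return data.frame of gene records (see [validate_gene_table()]).
#' @export
read_gene_table <- function(path, dialect = c("flat_tsv", "gff3"),
                            genome_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "flat_tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("genome_id", "contig_id", "protein_id", "start", "end", "strand")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("gene table missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    bad <- which(is.na(tab$start) | is.na(tab$end))
    if (length(bad))
      stop_line(path, bad[1] + 1L, "unparseable start/end coordinate")
    if (!"length_aa" %in% names(tab))
      tab$length_aa <- pmax(1L, (tab$end - tab$start + 1L) %/% 3L - 1L)
    tab$gene_index <- NA_integer_
    genes <- rank_genes(tab[, GENE_COLS])
  } else {
    lines <- readLines(path)
    rows <- list()
    gid <- genome_id %||% sub("\\.[^.]*$", "", basename(path))
    for (i in seq_along(lines)) {
      ln <- lines[i]
      if (ln == "" || startsWith(ln, "#")) next
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) != 9) stop_line(path, i, "expected 9 tab-separated fields")
      if (f[3] != "CDS") next
      start <- suppressWarnings(as.integer(f[4]))
      end <- suppressWarnings(as.integer(f[5]))
      if (is.na(start) || is.na(end)) stop_line(path, i, "bad coordinates")
      attrs <- strsplit(strsplit(f[9], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
      av <- setNames(vapply(attrs, function(a) if (length(a) > 1) a[2] else "",
                            ""),
                     vapply(attrs, `[`, "", 1))
      get_attr <- function(k) if (k %in% names(av)) av[[k]] else NA_character_
      pid <- get_attr("ID") %||% get_attr("protein_id") %||%
        get_attr("locus_tag") %||% NA_character_
      if (is.na(pid) || !nzchar(pid))
        stop_line(path, i, "CDS without ID/protein_id/locus_tag attribute")
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, genome_id = gid, contig_id = f[1],
        gene_index = NA_integer_, strand = f[7],
        start = start, end = end,
        length_aa = max(1L, (end - start + 1L) %/% 3L - 1L),
        stringsAsFactors = FALSE)
    }
    if (!length(rows))
      return(validate_gene_table(empty_gene_table()))
    genes <- rank_genes(do.call(rbind, rows))
  }
  validate_gene_table(genes)
}

empty_gene_table <- function() {
  data.frame(protein_id = character(), genome_id = character(),
             contig_id = character(), gene_index = integer(),
             strand = character(), start = integer(), end = integer(),
             length_aa = integer(), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Write a gene table in the flat TSV dialect
#' @param genes gene record data.frame.
#' @param path output path.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes[, GENE_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an hmmscan `--domtblout` file
#'
#' Parses the 23+ whitespace-delimited column layout of hmmscan's per-domain
#' table.  The protein is the query (column 4), the domain accession is
#' column 2 (falling back to the target name when the accession is `-`),
#' coordinates come from the `ali coord` columns (18, 19), the bit score
#' from the per-domain score (column 14) and the E-value from the
#' independent E-value (column 13).
#'
#' @param path file path.
#' @return data.frame of domain hits with columns `protein_id`,
#'   `domain_acc`, `ali_start`, `ali_end`, `bitscore`, `evalue`.
#' @export
read_domtblout <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#")) next
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(f) < 23) stop_line(path, i, "expected >= 23 columns")
    acc <- if (f[2] == "-") f[1] else sub("\\.\\d+$", "", f[2])
    ali_from <- suppressWarnings(as.integer(f[18]))
    ali_to   <- suppressWarnings(as.integer(f[19]))
    bits     <- suppressWarnings(as.numeric(f[14]))
    eval     <- suppressWarnings(as.numeric(f[13]))
    if (anyNA(c(ali_from, ali_to, bits, eval)))
      stop_line(path, i, "malformed numeric field")
    if (ali_from > ali_to) stop_line(path, i, "ali_from > ali_to")
    if (eval < 0) stop_line(path, i, "negative E-value")
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = f[4], domain_acc = acc, ali_start = ali_from,
      ali_end = ali_to, bitscore = bits, evalue = eval,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty_domain_hits())
  do.call(rbind, rows)
}

empty_domain_hits <- function() {
  data.frame(protein_id = character(), domain_acc = character(),
             ali_start = integer(), ali_end = integer(),
             bitscore = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

#' Read / write domain hits in the simplified TSV dialect
#'
#' Columns: `protein_id, domain_acc, ali_start, ali_end, bitscore, evalue`.
#' @param path file path.
#' @return data.frame of domain hits.
#' @export
read_domain_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(HIT_COLS, names(tab))
  if (length(miss))
    stop("domain table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(tab$ali_start > tab$ali_end)) stop("ali_start > ali_end", call. = FALSE)
  if (any(tab$evalue < 0)) stop("negative E-value", call. = FALSE)
  tab[, HIT_COLS]
}

#' @rdname read_domain_table
#' @param hits domain hit data.frame.
#' @export
write_domain_table <- function(hits, path) {
  utils::write.table(hits[, HIT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a 12-column BLAST/DIAMOND tabular alignment file
#'
#' Standard `-outfmt 6` column order: qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore.  `pident` is taken
#' verbatim, never recomputed.
#'
#' @param path file path.
#' @return data.frame of alignment hits.
#' @export
read_tabular_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(empty_alignments())
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) == 1) f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(f) != 12)
      stop_line(path, i, sprintf("expected 12 columns, got %d", length(f)))
    num <- suppressWarnings(as.numeric(f[3:12]))
    if (anyNA(num)) stop_line(path, i, "malformed numeric field")
    data.frame(query_id = f[1], subject_id = f[2], pct_identity = num[1],
               aln_length = as.integer(num[2]), mismatch = as.integer(num[3]),
               gapopen = as.integer(num[4]), q_start = as.integer(num[5]),
               q_end = as.integer(num[6]), s_start = as.integer(num[7]),
               s_end = as.integer(num[8]), evalue = num[9], bitscore = num[10],
               stringsAsFactors = FALSE)
  })
  aln <- do.call(rbind, rows)
  if (any(aln$pct_identity < 0 | aln$pct_identity > 100))
    stop("pct_identity outside [0, 100]", call. = FALSE)
  if (any(aln$q_start > aln$q_end) || any(aln$s_start > aln$s_end))
    stop("alignment with start > end", call. = FALSE)
  if (any(aln$evalue < 0)) stop("negative E-value", call. = FALSE)
  aln
}

empty_alignments <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pct_identity = numeric(), aln_length = integer(),
             mismatch = integer(), gapopen = integer(),
             q_start = integer(), q_end = integer(), s_start = integer(),
             s_end = integer(), evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

#' @rdname read_tabular_alignments
#' @param aln alignment data.frame.
#' @export
write_tabular_alignments <- function(aln, path) {
  utils::write.table(aln[, ALN_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a Pfam-to-clan mapping table
#'
#' TSV with columns `domain_acc, clan_acc`; an empty or `NA` clan means the
#' domain belongs to no clan.  A domain maps to at most one clan.
#'
#' @param path file path.
#' @return data.frame with columns `domain_acc`, `clan_acc`.
#' @export
read_clan_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  miss <- setdiff(c("domain_acc", "clan_acc"), names(tab))
  if (length(miss))
    stop("clan table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab <- tab[, c("domain_acc", "clan_acc")]
  tab$clan_acc[!is.na(tab$clan_acc) & tab$clan_acc == ""] <- NA_character_
  dup <- tab$domain_acc[duplicated(tab$domain_acc)]
  if (length(dup))
    stop("domain mapped to more than one clan: ", dup[1], call. = FALSE)
  tab
}

#' @rdname read_clan_table
#' @param clans clan mapping data.frame.
#' @export
write_clan_table <- function(clans, path) {
  out <- clans[, c("domain_acc", "clan_acc")]
  out$clan_acc[is.na(out$clan_acc)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write KEGG Orthology assignment tables
#'
#' TSV with columns `protein_id, ko_id, bitscore, evalue, model_threshold,
#' model_coverage`; `model_threshold` may be empty (models without an
#' adaptive threshold).  `model_coverage` is the fraction of the KO model's
#' length covered by the alignment, in `[0, 1]`.
#'
#' @param path file path.
#' @return data.frame of KO assignments.
#' @export
read_ko_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(KO_COLS, names(tab))
  if (length(miss))
    stop("KO table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("bitscore", "evalue", "model_threshold", "model_coverage"))
    tab[[col]] <- as.numeric(tab[[col]])
  if (any(tab$model_coverage < 0 | tab$model_coverage > 1, na.rm = TRUE))
    stop("model_coverage outside [0, 1]", call. = FALSE)
  tab[, KO_COLS]
}

#' @rdname read_ko_table
#' @param ko KO assignment data.frame.
#' @export
write_ko_table <- function(ko, path) {
  utils::write.table(ko[, KO_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write genome metadata tables
#'
#' TSV with columns `genome_id, assembly_level, completeness, redundancy,
#' taxon_path`; `taxon_path` is a semicolon-joined lineage ordered from
#' domain to species.  Completeness and redundancy (contamination) are
#' fractions in `[0, 1]`.
#'
#' @param path file path.
#' @return data.frame of genome metadata.
#' @export
read_genome_meta <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(META_COLS, names(tab))
  if (length(miss))
    stop("genome metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(tab$assembly_level %in% ASSEMBLY_LEVELS))
    stop("assembly_level must be one of: ",
         paste(ASSEMBLY_LEVELS, collapse = ", "), call. = FALSE)
  rng <- c(tab$completeness, tab$redundancy)
  if (any(rng < 0 | rng > 1, na.rm = TRUE))
    stop("completeness/redundancy outside [0, 1]", call. = FALSE)
  tab[, META_COLS]
}

#' @rdname read_genome_meta
#' @param metas genome metadata data.frame.
#' @export
write_genome_meta <- function(metas, path) {
  utils::write.table(metas[, META_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Filter genomes on redundancy and taxon-aware completeness
#'
#' A genome is retained iff its redundancy (contamination) is at most
#' `max_redundancy` and its completeness is at least the applicable cutoff.
#' Completeness cutoffs may be overridden per taxon (e.g. for lineages with
#' reduced genomes): the most specific label of the genome's `taxon_path`
#' present in `completeness_by_taxon` wins, otherwise
#' `default_completeness` applies.
#'
#' @param metas genome metadata data.frame (see [read_genome_meta()]).
#' @param max_redundancy maximum redundancy fraction, default `0.10`
#'   (inclusive).
#' @param completeness_by_taxon named numeric vector of per-taxon
#'   completeness cutoffs, or `NULL`.
#' @param default_completeness completeness cutoff when no taxon override
#'   applies, default `0.7` (inclusive).
#' @param keep_missing if `TRUE`, genomes with `NA` completeness are kept;
#'   by default they fail the filter.
#' @return character vector of retained `genome_id`s.
#' @export
filter_genomes <- function(metas, max_redundancy = 0.10,
                           completeness_by_taxon = NULL,
                           default_completeness = 0.7,
                           keep_missing = FALSE) {
  stopifnot(is.data.frame(metas))
  cutoff <- vapply(metas$taxon_path, function(tp) {
    if (is.null(completeness_by_taxon)) return(default_completeness)
    labels <- rev(strsplit(tp %||% "", ";", fixed = TRUE)[[1]])
    for (lab in labels)
      if (lab %in% names(completeness_by_taxon))
        return(unname(completeness_by_taxon[[lab]]))
    default_completeness
  }, numeric(1), USE.NAMES = FALSE)
  ok_red <- !is.na(metas$redundancy) & metas$redundancy <= max_redundancy
  ok_cmp <- ifelse(is.na(metas$completeness), keep_missing,
                   metas$completeness >= cutoff)
  metas$genome_id[ok_red & ok_cmp]
}
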