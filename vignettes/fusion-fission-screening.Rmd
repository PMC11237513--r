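---
title: "Screening and classifying gene fusion/fission families"
author: "fusefission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and classifying gene fusion/fission families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusefission)
```

## The problem

Prokaryotic genes merge (fusion) and split (fission) over evolutionary
time.  A *composite* protein carries the domain architecture of two or
more separate *split* proteins; the Rosetta-stone idea is that finding
the fused form in one genome and the unfused forms in another reveals a
fusion/fission event and a functional link.  Fusions confound orthology
assignment — the fused protein matches one of its halves better than the
other — so systematic detection matters for comparative genomics,
especially in lineages dominated by metagenome-assembled genomes (MAGs),
where assembly fragmentation additionally creates *technical fissions*:
apparent splits caused by broken contigs or frameshifts rather than
evolution.

`fusefission` implements the full screen as a reusable package: from
per-protein domain annotations and gene coordinates to detected
composite/split families, Markov clusters of composite proteins, and a
heuristic fusion-vs-fission verdict per cluster.

## The screening procedure

1. **Genome filtering.**  Genomes are retained when redundancy
   (contamination) is at most 10% and completeness reaches a cutoff
   (default 0.7).  Completeness cutoffs are configurable per taxon
   because lineages with naturally reduced genomes need laxer values;
   the package deliberately ships no fixed per-taxon table — the
   overrides are configuration (`filter_genomes()`).
2. **Architectures.**  Raw domain hits are resolved into an ordered,
   non-overlapping token list per protein (`resolve_architecture()`).
   Tokens are Pfam *clan* accessions where a clan exists, otherwise the
   domain accession, widening the match space across divergent domain
   families.  Hits are admitted greedily by descending bit score with an
   overlap tolerance of 15 aa (set it to 0 for strictly non-overlapping
   behaviour); ties break by start coordinate, then accession, so
   resolution is deterministic for any input order.  This greedy rule is
   the package's own design: context-aware domain re-scoring is a
   separate concern and out of scope here, and tests bound the greedy
   selection at no worse than half the brute-force optimal total score.
3. **Composite candidates and split sets.**  Any protein with two or
   more tokens is a candidate composite — repeated tokens count, since
   self-fusions are real.  For each candidate architecture,
   `enumerate_split_sets()` finds every partition into two or more
   contiguous blocks realized by distinct proteins of one genome whose
   whole architecture equals the block, preserving domain order.
4. **Synteny.**  At least one split set per family must be genomically
   colocalized: all members on one contig with consecutive sorted gene
   ranks at most 5 apart.  The five-gene rule is defined pairwise in the
   underlying method; for sets of three or more members this package
   uses *chained* adjacency (each consecutive pair within 5), the
   operon-like reading.  Strand is ignored.
5. **Alignment filters.**  A split candidate must align to its composite
   with identity strictly above 25%, E-value strictly below 1e-9, and at
   least 60% of the split protein covered.  At set level, member
   alignments may overlap on the composite by at most 100 aa pairwise
   and must jointly cover at least 60% of the composite; each member
   contributes its single best-bitscore placement.  Strict vs inclusive
   boundaries follow the wording of the method exactly and are pinned by
   the boundary test suite.
6. **Family assembly.**  A family (one architecture signature) is
   emitted only when at least one composite and one syntenic,
   filter-passing split set exist anywhere in the dataset; after that,
   passing but non-syntenic sets with the same signature are attached to
   the split side, flagged as non-syntenic.

Two frequency statistics summarize each family: the syntenic split-set
frequency `S_syn / (C + S_syn)` and the split-protein variant
`P_syn / (C + P_syn)`.  Both are implemented because the method's
description varies between sets and proteins; classification uses the
**set** version, and since every set has at least two members the
protein version always dominates the set version (a tested invariant).

## Clustering

Composite proteins are aligned globally (Needleman–Wunsch, affine gaps)
and clustered with an in-house dense Markov Clustering at inflation 1.2.
Edge weights are global percent identity with a floor of 25%, mirroring
the screening identity threshold; the method itself does not name the
edge weight, so this is declared configuration.  Self-loops use each
node's maximum incident weight (standard MCL practice), columns are
normalized, and expansion/inflation iterate with pruning at 1e-6 until
the maximum entry change falls below 1e-8.  Clusters are the weakly
connected components of the converged nonzero structure; under this
extraction a node cannot belong to two attractor systems, so no
tie-break between attractors is ever needed.

Clusters with more than 10 members are tentatively re-clustered at
inflation 1.6 to split paralogs.  The split is accepted only when the
maximum identity between members of different subclusters stays below
40% *and* the subclusters separate by annotation or length — no shared
KO label, or all pairwise median-length differences above 20%.  The
40% ceiling comes from the method; the disjoint-KO-or-length
operationalization of "clear separation" is this package's concrete
rule, with both constants exposed.  Distinct architectures within a
cluster get subindices ranked by member count (ties lexicographic).
Singleton clusters are reported but excluded from classification.

## Classification

Each non-singleton cluster receives one label from four voting criteria
(`classify()`):

* **V1 frequency** — split-set frequency below 0.1 votes fission, above
  0.9 votes fusion.
* **V2 bacterial distribution** — the composite state in more than 2
  bacterial phyla or at least 1,000 bacterial genomes votes fission;
  complete absence from a screened bacterial set votes fusion.  Without
  a bacterial screen the criterion abstains.  An optional stricter
  variant requires at least two assemblies per lineage before counting
  a lineage.
* **V3 closed genomes** — among complete assemblies carrying the
  family, a majority with composites votes fission; a majority with
  splits only votes fusion.
* **V4 KO coverage** — full KEGG Orthology model coverage for
  composites (median ≥ 0.8) with halved coverage for splits (≤ 0.6)
  votes fission.  The criterion has no fusion direction, and because KO
  models are largely bacterial-trained it never outranks the others.
  The 0.8/0.6 operationalization of "full"/"halved" is configurable.

A strict majority with at least two cast votes yields a
high-confidence label; a single vote, or a tie broken by V1's (then
V2's) direction, yields a probable label; no signal leaves the cluster
unclassified.  Before voting, a cluster in which at least 20% of
composites are themselves split partners of longer composites is
labelled fusion-and-fission (the method says only "high frequency"; 0.2
is the package default).  KO assignments feed the statistics only after
acceptance: thresholded models at or above their threshold, and
threshold-less models only as the protein's best hit with E-value
strictly below 1e-10.

## The internal aligner

Production runs ingest external DIAMOND/BLAST tabular alignments
verbatim (`read_tabular_alignments()`, `pident` never recomputed).  So
that the pipeline also runs hermetically, the package ships a compiled
affine-gap Smith–Waterman / Needleman–Wunsch pair
(`local_align()`, `global_percent_identity()`), scored with the
BLOSUM62 matrix shipped by Biostrings at gap open 11 / extend 1 (a gap
of length L costs `11 + L`).  E-values use the published
Karlin–Altschul constants for that scheme (λ = 0.267, K = 0.041) and
are declared approximate — only ingested tables are bit-faithful to
external tools.  Percent identity divides identical pairs by all
alignment columns including gaps, the BLAST `pident` convention, so
internal and ingested values are comparable.  Traceback ties prefer the
diagonal, then the vertical, then the horizontal move: determinism over
biological nuance.  Alignments may contain adjacent opposite gaps (each
opening anew); the dynamic program's state space matches the exhaustive
alignment space, which the enumeration-oracle tests check exactly.

## Synthetic data: what it emulates and what it does not

`generate_synthetic_dataset()` builds a genome set with planted events
and full ground truth.  Its defaults are the package's benchmark
conditions: 30 genomes, 40 fusion events (2 composite genomes + 19
syntenic split genomes each, so the split-set frequency 19/21 clears
the 0.9 fusion cutoff), 20 fission events (10 composites + 1 syntenic
pair, frequency 1/11), technical fissions at 10% of planted events with
split pairs confined to contig-level assemblies, target pairwise
identity 0.7, 3 promiscuous distractor domains appended to background
proteins, and one fifth of genomes flagged fragmented.  Each domain has
an ancestral block; each genomic copy substitutes residues at a rate
derived in closed form so that the expected pairwise identity between
homologs equals the target (substitutions always change the residue; no
indels by default).  Domain hits are emitted from construction
coordinates, keeping tests hermetic.  Composites receive a
full-coverage KO, splits the same KO at half coverage, exercising V4 by
construction.  Syntenic split genes are placed at consecutive ranks;
non-syntenic extras are placed at opposite contig ends.

The generator deliberately does **not** model phylogenetic correlation
between genomes, indel evolution, domain gain/loss, promoter/operon
structure, or HMM search noise.  Passing the benchmark therefore shows
that the pipeline's logic — matching, synteny, filtering, clustering and
voting — is correct under clean, well-separated conditions; it does not
certify recall on real, noisy annotations, where domain models missing
a protein or diverged homologs below 25% identity remain the dominant
loss modes.

## Numerical and degenerate-input choices

* MCL convergence: tolerance 1e-8 on the maximum entry change, pruning
  below 1e-6, at most 200 iterations; a numerically emptied column is
  reset to its diagonal.
* Tie-breaks are lexicographic everywhere (architecture resolution,
  cluster labelling, subindex assignment, KO acceptance), making every
  stage deterministic under input permutation — a tested property.
* Empty domain-hit lists yield empty architectures, not errors; genomes
  with a single gene can host composites but never syntenic sets;
  circular contigs are not modelled (rank distance is linear).
* A protein may belong to several split sets and families; no
  exclusivity is imposed, which is what makes fusion-and-fission
  clusters representable.

## Problem sizes used by the checks

The shipped acceptance checks run the full pipeline on the default
30-genome benchmark (about 2,600 proteins, 66 planted events, roughly
half a minute end to end), compare the split-set enumerator against a
brute-force partition oracle on 200 random cases, verify MCL on every
uniform clique union up to 18 nodes at three inflations plus 500 random
graphs, and match both aligners against exhaustive alignment-space
enumeration on 100 random short pairs.  The classifier is checked over
the complete cross-product of vote outcomes and 1,000 randomized
monotonicity perturbations.

## Known limitations

* The bacterial mapping (V2) requires a pre-aligned bacterial proteome;
  the synthetic benchmark does not exercise it end to end, so V2 is
  validated at unit level only.
* Manual curation steps of the original screen (hand-split clusters,
  expert review of ambiguous families) are out of scope; reports note
  where they would apply.
* Internal E-values are approximate stand-ins for DIAMOND statistics;
  reproduction studies should feed real tabular output, which takes
  precedence wherever supplied.
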