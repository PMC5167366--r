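---
title: "Building and mining genome-scale knowledge networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and mining genome-scale knowledge networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The data model

gsknet represents biological knowledge as a typed, labelled, directed
multigraph. Nodes are *concepts* (a gene, a protein, a QTL, an ontology
term, a publication) and edges are *relations* whose types carry the
biological semantics (`encodes`, `ortholog`, `control`, `published_in`,
...). Every graph element is typed against a *meta-model*: controlled
vocabularies of concept classes, relation types, data sources, attribute
names (each with a value kind: text, integer, decimal, location or
sequence) and evidence types. The packaged default vocabulary covers the
classes and relation types that a crop knowledge network built from gene
models, ontologies, GO annotations, genetics, homology, pathway and
literature sources needs. Class and relation-type vocabularies are
hierarchical and validated to be acyclic with resolvable parents.

Two modelling choices matter throughout:

* **Multigraph semantics.** Parallel edges between the same two concepts
  are allowed when their types differ; an identical (from, to, type)
  triple is merged, unioning attributes, provenance and evidence. Types
  declared symmetric (`equal`, `ortholog`, `has_similar_sequence`,
  `interacts_with`) treat `(a, b)` and `(b, a)` as one relation; all other
  types are directed. The storage direction of symmetric relations is an
  arbitrary convention (lower concept id first), so builds are
  reproducible.
* **Reference semantics.** A `kg` is an environment; mapping and
  collapsing operators mutate it in place and return counts, which is how
  an integration pipeline naturally reads. `kg_clone()` gives an
  independent copy when needed.

## Parse, map, collapse

Integration proceeds in three stages. *Parsers* turn each input file into
an independent, self-contained network: `parse_fasta_gff3()` builds the
Gene–Protein backbone (`encodes` relations, chromosome/begin/end/taxid
attributes), `parse_obo()` ontologies, `parse_gaf()` GO annotations,
`parse_publications()` abstracts, `parse_uniprot_min()` reviewed proteins,
and `parse_tabular()` imports any other tabular dataset through a
declarative `table_spec()` column binding (SNPs, QTLs, orthologs, protein
domains, genetic-map positions). Within one parse, concepts sharing a
non-ambiguous accession merge automatically; a record that carries two
accessions already seen on different concepts merges those concepts too,
which makes the result independent of input row order.

*Mapping* operators then link the union of the parsed networks with
`equal` relations: `accession_map()` (shared non-ambiguous accessions,
same class only), `name_map()` (case-folded, whitespace-collapsed names,
with a minimum length of 3 characters because shorter symbols are too
promiscuous), and `sequence_map()` (Smith-Waterman similarity; below).
Other operators create typed evidence edges rather than equivalences:
`colocation_map()` (Gene–QTL interval overlap), `proximity_map()`
(SNP-in-gene windows), `external2go_map()` (domain-to-GO cross-references
from standard external2go files), and `cooccurrence_map()` (text mining).

*Collapsing* (`collapse_equal()`) resolves each connected component of the
`equal` subgraph into one representative concept — the lowest concept id,
whose preferred name wins; all accessions, names, attributes, provenance
and evidence are unioned, all other relations are rewired to the
representative, and duplicates merged. A component mixing concept classes
is always an integration error and is rejected and reported rather than
merged. The operation is idempotent and conserves accessions and
provenance. Attribute conflicts resolve last-writer-wins (in ascending id
order during collapse) with every overwritten value retained in a
per-graph audit trail, so no information is silently lost.

## Genomic locations and co-location

A location is a closed 1-based interval (GFF3 convention) on a named
chromosome, with a map unit (`bp` or `cM`) and a taxid. Concepts may carry
both a physical location (`Location`) and a genetic-map location
(`GenMapLocation`) — crop genes typically get bp coordinates from the gene
models and cM estimates from a POPSEQ-style table. Locations are only ever
compared within an identical (chromosome, unit, taxid) frame: co-location
between datasets is meaningful only when they use the same physical or
genetic map, so a bp interval never matches a cM interval. Overlap is
closed-interval intersection, computed per frame with `IRanges` on an
integer grid (cM values are scaled by 10^4 to accommodate fractional map
positions). Strand is stored but ignored by co-location. Transforming QTL
intervals between genetic and physical maps is out of scope; inputs must
already be on a shared map.

## Sequence similarity

`sequence_map()` uses an affine-gap Smith-Waterman local alignment
(BLOSUM62, gap open 10, gap extend 1, a length-k gap costing
`open + k * ext` — the same convention as `Biostrings::pairwiseAlignment`,
which the test suite uses as an external cross-check alongside a textbook
three-state dynamic programme). The implementation is row-vectorised: the
horizontal gap state is a running prefix maximum, which gives exact optima
without an inner column loop. Hits are filtered by a raw score threshold
and a top-k cut (default 10 per query, mirroring common practice for
similarity-based linking). A raw-score threshold stands in for the usual
E-value cut-off: E-values require database-size calibration that is
meaningless at the scale this package targets, and raw integer scores keep
builds deterministic. Self-hits are excluded and reciprocal hits collapse
onto one symmetric relation.

## Text mining

`cooccurrence_map()` links genes to trait-ontology terms when a gene name
and a term surface form occur in the *same sentence* of a publication
abstract. Sentences are segmented by a deterministic rule: split at
`.`/`!`/`?` followed by whitespace and an upper-case letter or digit, with
an abbreviation guard list (`e.g.`, `et al.`, `Fig.`, ...) and a guard for
single-capital initials; segments concatenate back to the original text
exactly. Matching is whole-token (hyphenated tokens kept intact), with no
stemming or fuzzy matching — the method is a co-occurrence filter, not an
NLP relation extractor. Gene-name matching is case-sensitive because short
gene symbols are case-informative; ontology-term matching is
case-insensitive. Each distinct (gene, term) pair yields one relation
carrying the number of distinct supporting publications (`CoCitations`)
and their PMIDs.

## Mining the integrated network

`kg_neighborhood()` and `kg_shortest_path()` operate under a
`traversal_filter()` (allowed classes, relation types, depth, direction).
Paths default to the undirected view because evidence chains legitimately
cross edge directions — a QTL *controls* a trait while a gene is
*colocated* with the QTL. Among equal-length paths the lexicographically
smallest concept-id sequence is returned, making results reproducible.
`evidence_network()` unions all instances (and partial prefixes) of
configurable class/type meta-path templates anchored at a gene; the
defaults collect co-located QTLs and their traits, the encoded protein's
domains and their GO cross-references, orthologs with phenotypes and
publications, sequence-similarity links and text-mined trait terms — the
chain a candidate-gene analyst reads left to right from trait evidence to
molecular annotation.

## Workflows, logs and the CLI

`load_workflow()`/`run_workflow()` execute a declarative, ordered list of
parse/map/transform/export steps (YAML primary; an equivalent XML form is
accepted). Validation — unknown plugins, missing parameters, graph labels
used before definition — happens before any step runs. The integration log
records, per step, the parameters, duration, concept/relation counts
before and after, the operation's return value and captured warnings, and
is written as both line-oriented text and a JSON twin. Networks are
rebuilt from scratch rather than updated incrementally, which avoids
accumulating stale entities. A thin command-line wrapper
(`gsknet_cli()`; `exec/gsknet`) exposes `fixture`, `build`, `map`,
`collapse`, `search` and `export` subcommands.

The exchange format is a versioned XML document carrying the full
meta-model plus all concepts and relations with explicit value-kind tags;
`read_oxl(write_oxl(g))` reproduces the graph exactly (ids included) and
export is byte-deterministic. The schema is this package's own documented
format in the spirit of graph exchange formats; compatibility with any
historical external schema is not guaranteed. Node-link JSON export serves
generic graph viewers.

## The synthetic data generator

`make_crop_fixture()` writes a miniature but complete input bundle —
default 12 genes (13 transcripts), 4 QTLs, 20 SNPs, 6 publications, a
9-term mini GO, a 6-term mini trait ontology, 4 reference proteins, domain
and ortholog tables, an external2go file, a workflow, and a `truth.json`
manifest computed *by construction* at generation time. The sizes are
chosen so every operator has work to do (multiple chromosomes, a
two-transcript gene, a NOT-qualified GAF row, an obsolete ontology term,
unmatched external2go lines) while a full build stays interactive. It
plants one complete evidence chain emulating a classic candidate-gene
case: a seed-width trait whose QTL on chromosome 5H co-locates (on the
genetic map) with a gene encoding a WRKY-domain protein orthologous to a
reference protein with a "smaller seeds" phenotype and two supporting
publications; one abstract mentions gene and trait term in the same
sentence, a second places them in different sentences as a text-mining
negative control; the two orthologous proteins share a planted 30-residue
block so sequence mapping recovers the link independently. QTL and gene
map positions are genetic (cM) while SNP positions are physical (bp),
exercising the unit-matching rule.

What the generator does **not** emulate: realistic genome statistics,
ontology topology, sequence composition, or literature language. Passing
tests therefore demonstrate the correctness of the integration and mining
machinery on well-formed inputs of every supported type — not parser
robustness against the irregularities of real public database dumps, and
not the statistical behaviour of text mining on real abstracts.

## Numerical and design choices

* Concept ids are opaque integers in insertion order; with fixed inputs
  and seed every output byte is reproducible.
* Data sources and evidence types are open vocabularies (auto-registered
  on first use, e.g. GAF evidence codes); concept classes, relation types
  and attribute names are strict and misuse is a meta-model error.
* Gene–QTL co-location uses its own relation type `colocated` rather than
  overloading `control` (which is reserved for QTL–Trait), and text-mined
  links use `cooccurs_with` with text-mining evidence.
* The SNP–gene proximity window defaults to 0 bp (within the gene);
  it is a workflow parameter.
* Alignment scores are integers (BLOSUM62 with integer gap costs), so
  oracle comparisons are exact, with deterministic top-k tie-breaking by
  subject id.
* Degenerate inputs: empty graphs export and round-trip; empty
  dictionaries and missing sequences are warning no-ops; malformed GFF3 or
  GAF lines fail with the line number; equal relations between classes are
  rejected at collapse time.

## Problem sizes used by the test suite

Property tests run on randomly generated instances at deliberately modest
sizes — 100 random graphs of 20–1000 concepts for collapse/union-find
equivalence, 100 random interval sets, 50 random peptide pairs of length
at most 60, a corpus of the fixture abstracts plus 55 random ones, 100
round-tripped random graphs — sizes at which the quadratic and enumeration
oracles are trivially trustworthy while still exploring the combinatorial
space. The end-to-end build runs the default fixture.

## Known limitations

* No native parsers for UniProt XML, PSI-MI, BioPAX/KEGG or OrthoXML;
  such content enters through the declarative tabular importer.
* No genetic-to-physical map projection; co-location requires a shared map.
* Text mining is strictly same-sentence co-occurrence counting; no
  negation handling, relation extraction or scoring beyond co-citations.
* No ranked candidate-gene scoring on top of evidence networks.
* Single-writer mutation model; no transactions or concurrent access.
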