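---
title: "Methods: taxon-scoped warehousing of genome, protein and structure data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taxon-scoped warehousing of genome, protein and structure data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Comparative-genomics and structure–function studies routinely begin with
the same data-preparation chore: for one organism or clade, collect the
curated genome records, their coding sequences, the reviewed protein
entries with their isoforms, functional annotation, domain families and
solved structures — scattered across seven resources with seven file
dialects — and cross-reference them into one consistent dataset.
`taxomart` automates that chore as a deterministic pipeline ending in an
embedded relational warehouse that can be queried with ordinary SQL.

The pipeline is strictly sequential and *taxonomy-gated*: the user's genus
or species query is resolved against the NCBI taxdump first, and the
resulting set of taxonomy identifiers (the query's full subtree) filters
every downstream record. Nothing enters the warehouse unless it belongs
to the queried clade.

## Pipeline model

1. **Resolve.** `parse_taxdump()` reads `names.dmp`/`nodes.dmp`
   (tab-pipe-tab fields, tab-pipe terminator). `resolve_name()` matches
   the query exactly and case-insensitively against scientific names, then
   synonyms. Matching is deliberately not substring-based: a substring
   match could silently inflate the taxon set (querying a genus prefix
   shared by another genus would pull in foreign species). An ambiguous
   name resolves to *all* matching nodes. The member set is the union of
   the matched nodes' subtrees, computed by breadth-first traversal that
   terminates on the conventional self-parent root. Strain-level nodes
   below a queried species are included: the subtree is taken at any
   depth, with no rank cutoff.
2. **Plan and fetch.** `plan_downloads()` lists one item per source file,
   batching nucleotide retrieval over member taxids (default 50 per
   batch — the "sequence bin" that keeps per-batch parsing bounded).
   `fetch_with_retry()` retries each missing item up to `max_attempts`
   (default 5): iterating "until complete" without a bound is not
   acceptable engineering, so the bound is explicit and an acquisition
   error names whatever is still missing. Partial files are discarded,
   never resumed; completed items are never re-fetched. The transport is
   an injected function, so offline mode (local files, zero transfers) and
   scripted failure tests use the same code path.
3. **Parse.** Streaming readers emit typed records (see below).
4. **Load.** `load_corpus()` applies the taxon filter and referential
   rules inside one transaction.
5. **Report.** `compute_stats()` returns per-entity counts; the CLI prints
   them as a plain-text table.

## Parsers and their dialects

All record-oriented parsers stream: entries are cut at their terminator
(`//` for GenBank and Swiss-Prot DAT) from a bounded line buffer
(`chunk_size` lines per read), so peak memory scales with the largest
entry, not the file. Parsers are *total*: every entry either becomes a
record or increments a named error tally, and parsing continues.

* **GenBank flat file.** LOCUS length, VERSION accession, DEFINITION,
  source-feature taxid (`/db_xref="taxon:N"`), and CDS features with
  `gene`, `locus_tag`, `protein_id`, `product`, `translation`. Only
  RefSeq-style accessions (two letters + underscore) are admitted — the
  warehouse stores the curated, non-redundant subset; others are counted
  and skipped.
* **Feature locations.** The grammar subset is base spans, single bases,
  `join(...)`, `order(...)`, `complement(...)` and the partiality markers
  `<`/`>`. `complement` flips strand only — printed coordinates are stored
  exactly as they appear (1-based inclusive), so any reverse-complement
  arithmetic is the consumer's job. `order` parses like `join` but keeps
  its kind flag. Nested `complement` and external references
  (`accession:span`) are rejected: neither occurs in curated genomic CDS
  annotation at a rate that justifies the ambiguity they introduce.
* **Swiss-Prot DAT.** AC lines accumulate (first accession is primary),
  OX yields the taxid, DR lines yield cross-references for RefSeq, GO,
  Pfam and PDB only; sub-fields after the identifier are kept verbatim as
  qualifier strings rather than interpreted. Isoform accessions are
  collected from `IsoId=` declarations in `ALTERNATIVE PRODUCTS` comment
  blocks; their sequences come from the companion varsplic-style FASTA.
* **OBO.** `[Term]` stanzas only; `alt_id` values build an alias table
  that maps each alternative identifier to exactly one canonical term;
  graph relations are out of scope.
* **SIFTS-style TSVs.** Chain-level mappings with Swiss-Prot coordinates
  validated as integers. PDB residue labels (`pdb_start`, `pdb_stop`)
  stay opaque strings: author-assigned numbering can carry insertion codes
  and negative numbers, and normalising them would destroy information.

## Schema design

Eleven entity tables (organism, nucleotide_sequence, cds, protein,
isoform, go_term, protein_go, domain_family, protein_domain,
structure_chain, refseq_uniprot) plus a `cds_segment` child table.
Surrogate integer keys (OID, NTS ID, CDS ID) are assigned by the loader
where no biological attribute is a satisfactory key; natural keys
(accession, uniprot_ac, go_id, pfam_ac) carry UNIQUE constraints, with
version suffixes kept (uniqueness is on the versioned string). The DDL
(`inst/sql/schema.sql`) avoids engine-specific constructs so it runs
unchanged on the embedded SQLite store and a server-grade system.

Choices that were genuinely open:

* **Spliced locations.** The `cds` row stores the outer envelope
  (min start, max stop) and a strand character; multi-segment detail goes
  to `cds_segment` with an ordinal. This keeps the common single-span
  case flat while preserving splice structure.
* **Orphan policy.** Proteins with no CDS link and CDSs with no protein
  link are both kept; the `refseq_uniprot` association table is the
  neutral rendering of the protein–CDS relationship, since the two entity
  counts cannot be 1:1.
* **CDS export.** The `cds` table carries the amino-acid `translation`
  so `export_cds_fasta()` is self-contained; genomic DNA itself is not
  warehoused (it would dominate storage while the coding content is what
  downstream comparative analyses consume).
* **Lazy annotation loading.** GO terms and Pfam families are inserted
  only when referenced by a retained protein, keeping the warehouse
  organism-centred rather than carrying the full ontology.
* **Domain coordinates.** Protein–domain rows (with Swiss-Prot start/stop)
  come from the Pfam-mode chain-mapping TSV, because DR Pfam lines carry
  no residue coordinates. A consequence worth knowing: in the synthetic
  corpus only structure-bearing proteins carry domain ranges.

## Organism discovery from nucleotide data

Organisms can enter the warehouse by two routes, reported separately:
every member of the resolved subtree (`source = "taxonomy"`), and taxids
that appear in a retrieved nucleotide record but are *absent from the
taxonomy dump entirely* (`source = "nucleotide"`). The second route
models annotation lag: a record can cite a taxid the dump does not yet
carry. A record whose taxid is a known node *outside* the query subtree
is filtered out instead — admitting it would break the guarantee that no
warehouse row lies outside the queried clade, which the test suite
asserts explicitly.

## Load semantics

Loading is idempotent: a natural key already present with an identical
payload is skipped, so re-running a load changes no row counts; the same
key with a *conflicting* payload (different sequence or length) aborts
with an integrity error rather than silently overwriting. Referential
integrity is both enforced by the store's FK constraints and *asserted*
by `fk_sweep()`, an explicit anti-join over every FK pair — integrity is
tested, not just trusted. Protein–GO links whose term is unknown to the
ontology, and domain references without a family row, are skipped and
counted as orphan references in the load report.

## The synthetic corpus

`generate_corpus()` writes all nine files of a fictional clade
("Synthetica", genera such as *Fictibacter*) plus a ground-truth manifest,
and `manifest_stats()` recomputes expected warehouse counts purely in
memory from the manifest's link lists — the independent oracle for the
end-to-end equivalence tests. Identifier namespaces are fictional but
format-valid (taxids in a reserved high range, UniProt-pattern accessions,
`PF` + 5 digits, `GO:` + 7 digits, RefSeq-prefixed accessions), so
pattern validation runs for real. Translations are genuine standard-code
translations of the CDS spans (segments concatenated, reverse-complemented
on the minus strand), so the translation-length invariant and the
coordinate arithmetic are meaningfully exercised, and about 30% of CDSs
are spliced across two segments.

Default parameters describe a small clade a test can afford: 2 genera × 3
species × 1 strain each (15 taxa), one genome per organism, 5 CDSs per
genome, 80% of CDSs with a Swiss-Prot entry, a 15-term GO pool, an
8-family Pfam pool, 30% of proteins with structures, no isoforms
(prokaryote-like; eukaryote-like profiles set
`isoforms_per_protein_mean > 0`), and one nucleotide-only organism.
These sizes give every entity table and every cross-reference path
non-trivial cardinality while a full generate-parse-load cycle stays
around a second.

What the generator does *not* emulate: codon bias and realistic domain
architectures, multi-chromosome eukaryotic genomes, TrEMBL-scale
redundancy, GO graph structure, or release-to-release drift between
sources. Passing tests therefore demonstrate the pipeline's relational
and filtering logic, not robustness to every irregularity of real
snapshots — real dumps can contain dialect corner cases the closed defect
set (`truncated_entry`, `bad_location`, `wrong_column_count`,
`non_refseq_accession`, `orphan_crossref`) does not model.

## Problem sizes and determinism in the test suite

The suite builds its fixtures at run time: 20 randomized corpora for the
end-to-end equivalence property, 1000 random location expressions against
a brute-force span-expansion oracle, random taxonomies up to 1000 nodes
with every node checked as a root against a naive recursive oracle, and
scripted fake transports for the retry contract. All randomness is
seeded; the generator restores the caller's RNG state so corpus creation
never perturbs user simulations. Degenerate inputs are pinned by tests:
empty taxon sets load nothing, empty FASTA streams yield empty tables,
selectors matching nothing export empty output with success status.

## Known limitations

* Merged/deleted taxid remapping (`merged.dmp`, `delnodes.dmp`) is not
  consulted; a query against an outdated name simply fails to resolve.
* Protein–GO links come from Swiss-Prot DR lines only, not from
  association files, so electronically-annotated terms absent from DR
  lines are invisible.
* The PDB entity stores the identifier and verbatim qualifier strings;
  method/resolution are not parsed into typed columns.
* The embedded store is single-writer; concurrent builds are out of
  scope, as is schema migration between package versions.
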