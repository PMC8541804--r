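Package: taxomart
Title: Organism-Centred Integration of Taxonomy, Genome, Protein and
    Structure Data into a Relational Warehouse
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a taxon-scoped relational data warehouse from seven
    standard biological data sources: NCBI taxdump files, RefSeq records in
    GenBank flat-file format, UniProtKB/Swiss-Prot DAT entries with their
    alternative-splicing isoform FASTA, the Gene Ontology in OBO format, a
    Pfam family description table, and SIFTS-style chain-level mappings
    between PDB structures and Swiss-Prot sequences.  A user-supplied genus
    or species name is resolved against the taxonomy tree and every
    downstream record is filtered to the taxonomic subtree of the query.
    Streaming parsers emit typed records, an embedded SQL store enforces
    referential integrity, and a per-entity statistics report summarises the
    warehouse.  A deterministic synthetic-corpus generator emulates all
    seven sources with a ground-truth manifest so the full pipeline is
    testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
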