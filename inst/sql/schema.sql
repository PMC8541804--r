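-- Warehouse schema: organism-centred integration of taxonomy, genome,
-- CDS, protein, ontology, domain-family and structure data.
-- Surrogate keys (OID, NTS ID, CDS ID) are plain integers assigned by the
-- loader; natural keys carry UNIQUE constraints.  The DDL is portable SQL
-- (runs unchanged on SQLite and a server-grade system).

CREATE TABLE organism (
    oid        INTEGER PRIMARY KEY,
    taxid      INTEGER NOT NULL UNIQUE,
    name       TEXT    NOT NULL,
    source     TEXT    NOT NULL CHECK (source IN ('taxonomy', 'nucleotide'))
);

CREATE TABLE nucleotide_sequence (
    nts_id         INTEGER PRIMARY KEY,
    accession      TEXT    NOT NULL UNIQUE,
    oid            INTEGER NOT NULL REFERENCES organism (oid),
    length         INTEGER NOT NULL CHECK (length > 0),
    molecule_label TEXT
);

CREATE TABLE cds (
    cds_id            INTEGER PRIMARY KEY,
    nts_id            INTEGER NOT NULL REFERENCES nucleotide_sequence (nts_id),
    start             INTEGER NOT NULL,
    stop              INTEGER NOT NULL,
    strand            TEXT    NOT NULL CHECK (strand IN ('+', '-')),
    gene              TEXT,
    locus_tag         TEXT,
    refseq_protein_ac TEXT,
    product           TEXT,
    translation       TEXT,
    CHECK (start <= stop)
);

-- multi-segment (spliced) locations keep per-segment detail here; the cds
-- row stores the outer envelope
CREATE TABLE cds_segment (
    cds_id  INTEGER NOT NULL REFERENCES cds (cds_id),
    ordinal INTEGER NOT NULL,
    start   INTEGER NOT NULL,
    stop    INTEGER NOT NULL,
    PRIMARY KEY (cds_id, ordinal),
    CHECK (start <= stop)
);

CREATE TABLE protein (
    uniprot_ac TEXT    PRIMARY KEY,
    oid        INTEGER NOT NULL REFERENCES organism (oid),
    name       TEXT,
    sequence   TEXT    NOT NULL
);

CREATE TABLE isoform (
    isoform_ac TEXT PRIMARY KEY,
    uniprot_ac TEXT NOT NULL REFERENCES protein (uniprot_ac),
    sequence   TEXT
);

CREATE TABLE go_term (
    go_id     TEXT    PRIMARY KEY,
    name      TEXT,
    namespace TEXT,
    obsolete  INTEGER NOT NULL DEFAULT 0
);

CREATE TABLE protein_go (
    uniprot_ac TEXT NOT NULL REFERENCES protein (uniprot_ac),
    go_id      TEXT NOT NULL REFERENCES go_term (go_id),
    PRIMARY KEY (uniprot_ac, go_id)
);

CREATE TABLE domain_family (
    pfam_ac     TEXT PRIMARY KEY,
    family_id   TEXT,
    description TEXT
);

CREATE TABLE protein_domain (
    uniprot_ac TEXT    NOT NULL REFERENCES protein (uniprot_ac),
    pfam_ac    TEXT    NOT NULL REFERENCES domain_family (pfam_ac),
    sp_start   INTEGER NOT NULL,
    sp_stop    INTEGER NOT NULL,
    PRIMARY KEY (uniprot_ac, pfam_ac, sp_start, sp_stop),
    CHECK (sp_start <= sp_stop)
);

CREATE TABLE structure_chain (
    pdb_id     TEXT    NOT NULL,
    chain_id   TEXT    NOT NULL,
    uniprot_ac TEXT    NOT NULL REFERENCES protein (uniprot_ac),
    sp_start   INTEGER NOT NULL,
    sp_stop    INTEGER NOT NULL,
    pdb_start  TEXT,
    pdb_stop   TEXT,
    PRIMARY KEY (pdb_id, chain_id, uniprot_ac, sp_start),
    CHECK (sp_start <= sp_stop)
);

CREATE TABLE refseq_uniprot (
    refseq_protein_ac TEXT NOT NULL,
    uniprot_ac        TEXT NOT NULL REFERENCES protein (uniprot_ac),
    PRIMARY KEY (refseq_protein_ac, uniprot_ac)
);

CREATE INDEX idx_nucleotide_sequence_oid ON nucleotide_sequence (oid);
CREATE INDEX idx_cds_nts ON cds (nts_id);
CREATE INDEX idx_cds_refseq ON cds (refseq_protein_ac);
CREATE INDEX idx_protein_oid ON protein (oid);
CREATE INDEX idx_structure_chain_ac ON structure_chain (uniprot_ac);
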