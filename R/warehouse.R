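# Embedded relational warehouse: schema creation, taxon-filtered load,
# per-entity statistics and CDS FASTA export.  The store is SQLite via DBI;
# the DDL (inst/sql/schema.sql) is portable SQL.  Loads are idempotent:
# natural keys already present are skipped, and a natural key reappearing
# with a conflicting payload raises an integrity error.

WAREHOUSE_TABLES <- c(
  "organism", "nucleotide_sequence", "cds", "protein", "isoform",
  "go_term", "protein_go", "domain_family", "protein_domain",
  "structure_chain", "refseq_uniprot"
)

#' Open (or create) a warehouse database file
#'
#' @param path path to the SQLite database file, or `":memory:"`.
#' @return a DBI connection with foreign-key enforcement enabled.
#' @export
warehouse_connect <- function(path) {
  con <- DBI::dbConnect(RSQLite::SQLite(), path)
  DBI::dbExecute(con, "PRAGMA foreign_keys = ON")
  con
}

#' Create the warehouse schema
#'
#' Executes the shipped portable DDL.  Refuses to touch a store that
#' already contains tables unless `overwrite = TRUE`, in which case all
#' warehouse tables are dropped and recreated.
#'
#' @param con DBI connection from [warehouse_connect()].
#' @param overwrite drop any existing warehouse tables first.
#' @return `con`, invisibly.
#' @export
create_schema <- function(con, overwrite = FALSE) {
  existing <- DBI::dbListTables(con)
  existing <- setdiff(existing, "sqlite_sequence")
  if (length(existing)) {
    if (!overwrite)
      tm_integrity_error("store already contains tables; pass overwrite = TRUE")
    for (t in c("cds_segment", rev(WAREHOUSE_TABLES)))
      if (t %in% existing)
        DBI::dbExecute(con, sprintf("DROP TABLE %s", t))
  }
  for (stmt in schema_statements())
    DBI::dbExecute(con, stmt)
  invisible(con)
}

schema_statements <- function() {
  path <- system.file("sql", "schema.sql", package = "taxomart")
  sql <- paste(readLines(path, warn = FALSE), collapse = "\n")
  sql <- gsub("--[^\n]*", "", sql)
  stmts <- strsplit(sql, ";", fixed = TRUE)[[1L]]
  stmts <- trimws(stmts)
  stmts[nzchar(stmts)]
}

#' Dump the schema definition of a warehouse
#'
#' @param con DBI connection.
#' @return character vector of DDL statements in deterministic order.
#' @export
schema_dump <- function(con) {
  sql <- DBI::dbGetQuery(con,
    "SELECT sql FROM sqlite_master WHERE sql IS NOT NULL ORDER BY name")$sql
  sql
}

#' Load parsed records into the warehouse, filtered by a taxon set
#'
#' Every member taxid becomes an organism row with `source = 'taxonomy'`.
#' A nucleotide record is loaded when its taxid is a member; a record whose
#' taxid is unknown to the taxonomy dump entirely is admitted and its taxid
#' added as an organism with `source = 'nucleotide'` (an organism
#' discoverable only through nucleotide data); a record whose taxid is a
#' known node outside the query subtree is filtered out.  Proteins load
#' only for member taxids.  GO terms, domain families and chain mappings
#' load only when referenced by at least one retained protein; isoforms
#' only when their parent protein is retained.  Re-running the same load
#' changes no row counts.
#'
#' @param con DBI connection with the schema created.
#' @param taxa a `taxon_set` from [resolve_name()].
#' @param parsed named list of parser outputs: `genbank`
#'   ([parse_genbank()]), `swissprot` ([parse_swissprot()]), `varsplic`
#'   ([parse_varsplic()]), `obo` ([parse_obo()]), `pfam`
#'   ([parse_pfam_table()]), `sifts_uniprot` and `sifts_pfam`
#'   ([parse_sifts_chain_tsv()]).  Any element may be `NULL`.
#' @param nodes optional `taxon_nodes` table; supplies organism names and
#'   the known-taxid universe for the nucleotide-discovery rule.
#' @return a load report: named list of inserted/skipped/orphan counts.
#' @export
load_corpus <- function(con, taxa, parsed, nodes = NULL) {
  stopifnot(inherits(taxa, "taxon_set"))
  members <- taxa$member_taxids
  # discovery of nucleotide-only organisms needs the taxonomy universe;
  # without it every non-member record is simply filtered
  known <- if (!is.null(nodes)) nodes$taxid else NULL
  report <- list(orphan_go_refs = 0L, orphan_pfam_refs = 0L,
                 filtered_nucleotide = 0L, filtered_protein = 0L)

  DBI::dbBegin(con)
  ok <- FALSE
  on.exit(if (!ok) DBI::dbRollback(con))

  q1 <- function(sql, ...) {
    p <- list(...)
    if (length(p)) DBI::dbGetQuery(con, sql, params = p)
    else DBI::dbGetQuery(con, sql)
  }
  next_id <- function(table, key) {
    v <- q1(sprintf("SELECT MAX(%s) AS m FROM %s", key, table))$m
    if (is.na(v)) 1L else as.integer(v) + 1L
  }

  # --- organisms from taxonomy -------------------------------------------
  have_org <- q1("SELECT taxid, oid FROM organism")
  oid_of <- stats::setNames(as.integer(have_org$oid), have_org$taxid)
  oid_counter <- next_id("organism", "oid")
  add_organism <- function(taxid, name, source) {
    key <- as.character(taxid)
    if (key %in% names(oid_of)) return(oid_of[[key]])
    DBI::dbExecute(con,
      "INSERT INTO organism (oid, taxid, name, source) VALUES (?, ?, ?, ?)",
      params = list(oid_counter, taxid, name, source))
    oid_of[[key]] <<- oid_counter
    oid_counter <<- oid_counter + 1L
    oid_of[[key]]
  }
  name_of_taxid <- function(taxid) {
    if (!is.null(nodes)) {
      i <- match(taxid, nodes$taxid)
      if (!is.na(i)) return(nodes$scientific_name[[i]])
    }
    sprintf("taxid %d", taxid)
  }
  for (tx in members) add_organism(tx, name_of_taxid(tx), "taxonomy")

  # --- nucleotide records + CDS ------------------------------------------
  have_acc <- q1("SELECT accession, length FROM nucleotide_sequence")
  nts_counter <- next_id("nucleotide_sequence", "nts_id")
  cds_counter <- next_id("cds", "cds_id")
  for (rec in (parsed$genbank$records %||% list())) {
    if (is.na(rec$taxid)) { report$filtered_nucleotide <- report$filtered_nucleotide + 1L; next }
    if (rec$taxid %in% members) {
      oid <- oid_of[[as.character(rec$taxid)]]
    } else if (!is.null(known) && !rec$taxid %in% known) {
      oid <- add_organism(rec$taxid, organism_name_from_record(rec), "nucleotide")
    } else {
      report$filtered_nucleotide <- report$filtered_nucleotide + 1L
      next
    }
    i <- match(rec$accession, have_acc$accession)
    if (!is.na(i)) {
      if (have_acc$length[[i]] != rec$sequence_length)
        tm_integrity_error(sprintf(
          "accession %s already loaded with different length", rec$accession))
      next
    }
    DBI::dbExecute(con, paste(
      "INSERT INTO nucleotide_sequence",
      "(nts_id, accession, oid, length, molecule_label)",
      "VALUES (?, ?, ?, ?, ?)"),
      params = list(nts_counter, rec$accession, oid, rec$sequence_length,
                    rec$molecule_label))
    have_acc <- rbind(have_acc, data.frame(accession = rec$accession,
                                           length = rec$sequence_length))
    for (cds in rec$cds_features) {
      segs <- cds$location$segments
      DBI::dbExecute(con, paste(
        "INSERT INTO cds (cds_id, nts_id, start, stop, strand, gene,",
        "locus_tag, refseq_protein_ac, product, translation)",
        "VALUES (?, ?, ?, ?, ?, ?, ?, ?, ?, ?)"),
        params = list(cds_counter, nts_counter, min(segs$start),
                      max(segs$stop), cds$location$strand,
                      cds$gene_name, cds$locus_tag, cds$refseq_protein_ac,
                      cds$product, cds$translation))
      if (nrow(segs) > 1L)
        for (s in seq_len(nrow(segs)))
          DBI::dbExecute(con, paste(
            "INSERT INTO cds_segment (cds_id, ordinal, start, stop)",
            "VALUES (?, ?, ?, ?)"),
            params = list(cds_counter, s, segs$start[[s]], segs$stop[[s]]))
      cds_counter <- cds_counter + 1L
    }
    nts_counter <- nts_counter + 1L
  }

  # --- proteins and their cross-references -------------------------------
  have_prot <- q1("SELECT uniprot_ac, sequence FROM protein")
  retained <- character(0)
  go_refs <- list(); pfam_refs <- character(0); refseq_links <- list()
  for (rec in (parsed$swissprot$records %||% list())) {
    if (is.na(rec$taxid) || !rec$taxid %in% members) {
      report$filtered_protein <- report$filtered_protein + 1L
      next
    }
    i <- match(rec$primary_ac, have_prot$uniprot_ac)
    if (!is.na(i)) {
      if (have_prot$sequence[[i]] != rec$sequence)
        tm_integrity_error(sprintf(
          "protein %s already loaded with different sequence", rec$primary_ac))
    } else {
      DBI::dbExecute(con,
        "INSERT INTO protein (uniprot_ac, oid, name, sequence) VALUES (?, ?, ?, ?)",
        params = list(rec$primary_ac, oid_of[[as.character(rec$taxid)]],
                      rec$description, rec$sequence))
      have_prot <- rbind(have_prot, data.frame(uniprot_ac = rec$primary_ac,
                                               sequence = rec$sequence))
    }
    retained <- c(retained, rec$primary_ac)
    for (xr in rec$crossrefs) {
      if (xr$target_db == "GO")
        go_refs[[length(go_refs) + 1L]] <- c(rec$primary_ac, xr$target_id)
      else if (xr$target_db == "Pfam")
        pfam_refs <- c(pfam_refs, xr$target_id)
      else if (xr$target_db == "RefSeq")
        refseq_links[[length(refseq_links) + 1L]] <- c(xr$target_id, rec$primary_ac)
    }
  }
  retained <- unique(retained)

  # --- GO terms (lazily: only referenced ones) ---------------------------
  obo <- parsed$obo
  if (!is.null(obo) && length(go_refs)) {
    alias <- stats::setNames(obo$aliases$go_id, obo$aliases$alt_id)
    canon <- function(id) {
      if (id %in% obo$terms$go_id) return(id)
      if (id %in% names(alias)) return(alias[[id]])
      NA_character_
    }
    links <- unique(do.call(rbind, go_refs))
    ids <- vapply(links[, 2L], canon, "", USE.NAMES = FALSE)
    bad <- is.na(ids)
    report$orphan_go_refs <- report$orphan_go_refs + sum(bad)
    links <- cbind(links[!bad, 1L, drop = TRUE], ids[!bad])
    need <- unique(ids[!bad])
    have_go <- q1("SELECT go_id FROM go_term")$go_id
    for (g in setdiff(need, have_go)) {
      t <- obo$terms[obo$terms$go_id == g, ]
      DBI::dbExecute(con,
        "INSERT INTO go_term (go_id, name, namespace, obsolete) VALUES (?, ?, ?, ?)",
        params = list(g, t$name, t$namespace, as.integer(t$obsolete)))
    }
    if (length(links)) {
      links <- matrix(links, ncol = 2L)
      links <- unique(links)
      have_pg <- q1("SELECT uniprot_ac, go_id FROM protein_go")
      for (r in seq_len(nrow(links))) {
        if (any(have_pg$uniprot_ac == links[r, 1L] & have_pg$go_id == links[r, 2L]))
          next
        DBI::dbExecute(con,
          "INSERT INTO protein_go (uniprot_ac, go_id) VALUES (?, ?)",
          params = list(links[r, 1L], links[r, 2L]))
      }
    }
  } else if (length(go_refs)) {
    report$orphan_go_refs <- report$orphan_go_refs + length(go_refs)
  }

  # --- domain families + protein-domain mappings -------------------------
  sifts_pfam <- parsed$sifts_pfam$mappings
  dom_maps <- NULL
  if (!is.null(sifts_pfam) && nrow(sifts_pfam))
    dom_maps <- sifts_pfam[sifts_pfam$uniprot_ac %in% retained, , drop = FALSE]
  need_fam <- unique(c(pfam_refs, dom_maps$pfam_ac))
  fams <- parsed$pfam$families
  if (!is.null(fams) && length(need_fam)) {
    known_fam <- intersect(need_fam, fams$pfam_ac)
    report$orphan_pfam_refs <- report$orphan_pfam_refs +
      length(setdiff(need_fam, known_fam))
    have_fam <- q1("SELECT pfam_ac FROM domain_family")$pfam_ac
    for (p in setdiff(known_fam, have_fam)) {
      f <- fams[fams$pfam_ac == p, ]
      DBI::dbExecute(con,
        "INSERT INTO domain_family (pfam_ac, family_id, description) VALUES (?, ?, ?)",
        params = list(p, f$family_id, f$description))
    }
    if (!is.null(dom_maps) && nrow(dom_maps)) {
      dom_maps <- dom_maps[dom_maps$pfam_ac %in% known_fam, , drop = FALSE]
      have_pd <- q1("SELECT uniprot_ac, pfam_ac, sp_start, sp_stop FROM protein_domain")
      for (r in seq_len(nrow(dom_maps))) {
        d <- dom_maps[r, ]
        if (any(have_pd$uniprot_ac == d$uniprot_ac & have_pd$pfam_ac == d$pfam_ac &
                have_pd$sp_start == d$sp_start & have_pd$sp_stop == d$sp_stop))
          next
        DBI::dbExecute(con, paste(
          "INSERT INTO protein_domain (uniprot_ac, pfam_ac, sp_start, sp_stop)",
          "VALUES (?, ?, ?, ?)"),
          params = list(d$uniprot_ac, d$pfam_ac, d$sp_start, d$sp_stop))
        have_pd <- rbind(have_pd, d[, c("uniprot_ac", "pfam_ac", "sp_start", "sp_stop")])
      }
    }
  }

  # --- structure chains ---------------------------------------------------
  chains <- parsed$sifts_uniprot$mappings
  if (!is.null(chains) && nrow(chains)) {
    chains <- chains[chains$uniprot_ac %in% retained, , drop = FALSE]
    have_ch <- q1("SELECT pdb_id, chain_id, uniprot_ac, sp_start FROM structure_chain")
    for (r in seq_len(nrow(chains))) {
      ch <- chains[r, ]
      if (any(have_ch$pdb_id == ch$pdb_id & have_ch$chain_id == ch$chain_id &
              have_ch$uniprot_ac == ch$uniprot_ac & have_ch$sp_start == ch$sp_start))
        next
      DBI::dbExecute(con, paste(
        "INSERT INTO structure_chain",
        "(pdb_id, chain_id, uniprot_ac, sp_start, sp_stop, pdb_start, pdb_stop)",
        "VALUES (?, ?, ?, ?, ?, ?, ?)"),
        params = list(ch$pdb_id, ch$chain_id, ch$uniprot_ac, ch$sp_start,
                      ch$sp_stop, ch$pdb_start, ch$pdb_stop))
      have_ch <- rbind(have_ch, ch[, c("pdb_id", "chain_id", "uniprot_ac", "sp_start")])
    }
  }

  # --- refseq <-> uniprot links ------------------------------------------
  if (length(refseq_links)) {
    links <- unique(do.call(rbind, refseq_links))
    have_ru <- q1("SELECT refseq_protein_ac, uniprot_ac FROM refseq_uniprot")
    for (r in seq_len(nrow(links)))
      if (!any(have_ru$refseq_protein_ac == links[r, 1L] &
               have_ru$uniprot_ac == links[r, 2L]))
        DBI::dbExecute(con,
          "INSERT INTO refseq_uniprot (refseq_protein_ac, uniprot_ac) VALUES (?, ?)",
          params = list(links[r, 1L], links[r, 2L]))
  }

  # --- isoforms -----------------------------------------------------------
  iso <- parsed$varsplic$isoforms
  if (!is.null(iso) && nrow(iso)) {
    iso <- iso[iso$parent_ac %in% retained, , drop = FALSE]
    have_iso <- q1("SELECT isoform_ac FROM isoform")$isoform_ac
    for (r in seq_len(nrow(iso)))
      if (!iso$isoform_ac[[r]] %in% have_iso)
        DBI::dbExecute(con,
          "INSERT INTO isoform (isoform_ac, uniprot_ac, sequence) VALUES (?, ?, ?)",
          params = list(iso$isoform_ac[[r]], iso$parent_ac[[r]],
                        iso$sequence[[r]]))
  }

  DBI::dbCommit(con)
  ok <- TRUE
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fallback organism label for a record discovered only in nucleotide data:
# first two words of the definition line.
organism_name_from_record <- function(rec) {
  words <- strsplit(trimws(rec$definition), "[[:space:]]+")[[1L]]
  if (length(words) >= 2L) paste(words[1:2], collapse = " ")
  else sprintf("taxid %d", rec$taxid)
}

#' Per-entity statistics of a warehouse
#'
#' Row counts per entity table; `structures` counts distinct PDB
#' identifiers, not chains.
#'
#' @param con DBI connection to a built warehouse.
#' @return object of class `warehouse_stats`: named integer list with
#'   elements `organisms_from_taxonomy`, `organisms_from_nucleotide`,
#'   `genomes`, `cds`, `proteins`, `isoforms`, `go_terms`,
#'   `domain_families`, `structures`.
#' @export
compute_stats <- function(con) {
  have <- DBI::dbListTables(con)
  missing <- setdiff(WAREHOUSE_TABLES, have)
  if (length(missing))
    tm_schema_error(sprintf("missing warehouse table(s): %s",
                            paste(missing, collapse = ", ")))
  n <- function(sql) as.integer(DBI::dbGetQuery(con, sql)[[1L]])
  structure(list(
    organisms_from_taxonomy =
      n("SELECT COUNT(*) FROM organism WHERE source = 'taxonomy'"),
    organisms_from_nucleotide =
      n("SELECT COUNT(*) FROM organism WHERE source = 'nucleotide'"),
    genomes = n("SELECT COUNT(*) FROM nucleotide_sequence"),
    cds = n("SELECT COUNT(*) FROM cds"),
    proteins = n("SELECT COUNT(*) FROM protein"),
    isoforms = n("SELECT COUNT(*) FROM isoform"),
    go_terms = n("SELECT COUNT(*) FROM go_term"),
    domain_families = n("SELECT COUNT(*) FROM domain_family"),
    structures = n("SELECT COUNT(DISTINCT pdb_id) FROM structure_chain")
  ), class = "warehouse_stats")
}

STATS_LABELS <- c(
  organisms_from_taxonomy   = "No of organisms (from Taxonomy)",
  organisms_from_nucleotide = "No of organisms (from Nucleotide)",
  genomes                   = "No of curated genomes/chromosomes",
  cds                       = "No of CDSs",
  proteins                  = "No of proteins",
  isoforms                  = "No of protein isoforms",
  go_terms                  = "No of GO terms",
  domain_families           = "No of protein domain families",
  structures                = "No of protein 3D structures"
)

#' @export
print.warehouse_stats <- function(x, ...) {
  w <- max(nchar(STATS_LABELS))
  for (k in names(STATS_LABELS))
    cat(sprintf("%-*s  %d\n", w, STATS_LABELS[[k]], x[[k]]))
  invisible(x)
}

#' Export CDSs as FASTA, selected by taxon, GO term or Pfam family
#'
#' Selector syntax: `"taxid:N"` exports every CDS of that organism;
#' `"go:GO:NNNNNNN"` and `"pfam:PFNNNNN"` export CDSs whose linked protein
#' (via the RefSeq–UniProt association) carries the annotation.  Records
#' carry the amino-acid translation and are ordered deterministically by
#' RefSeq protein accession.
#'
#' @param con DBI connection to a built warehouse.
#' @param selector selector string (see above).
#' @param file optional path; when given the FASTA is written there.
#' @return character vector of FASTA lines, invisibly when `file` given.
#' @export
export_cds_fasta <- function(con, selector, file = NULL) {
  sel <- parse_selector(selector)
  base <- paste(
    "SELECT c.refseq_protein_ac AS ac, c.gene AS gene, o.name AS organism,",
    "       c.translation AS translation, n.accession AS src",
    "FROM cds c",
    "JOIN nucleotide_sequence n ON n.nts_id = c.nts_id",
    "JOIN organism o ON o.oid = n.oid")
  rows <- switch(sel$kind,
    taxid = DBI::dbGetQuery(con, paste(base, "WHERE o.taxid = ?"),
                            params = list(as.integer(sel$value))),
    go = DBI::dbGetQuery(con, paste(base,
      "JOIN refseq_uniprot ru ON ru.refseq_protein_ac = c.refseq_protein_ac",
      "JOIN protein_go pg ON pg.uniprot_ac = ru.uniprot_ac",
      "WHERE pg.go_id = ?"), params = list(sel$value)),
    pfam = DBI::dbGetQuery(con, paste(base,
      "JOIN refseq_uniprot ru ON ru.refseq_protein_ac = c.refseq_protein_ac",
      "JOIN protein_domain pd ON pd.uniprot_ac = ru.uniprot_ac",
      "WHERE pd.pfam_ac = ?"), params = list(sel$value)))
  rows <- unique(rows)
  rows <- rows[order(rows$ac, rows$src), , drop = FALSE]
  out <- character(0)
  na_blank <- function(x) if (is.na(x)) "" else x
  for (r in seq_len(nrow(rows))) {
    hdr <- sprintf(">%s gene=%s organism=%s",
                   na_blank(rows$ac[[r]]), na_blank(rows$gene[[r]]),
                   rows$organism[[r]])
    seq <- rows$translation[[r]]
    if (is.na(seq)) seq <- ""
    out <- c(out, hdr, wrap_sequence(seq))
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

parse_selector <- function(selector) {
  if (grepl("^taxid:[0-9]+$", selector))
    return(list(kind = "taxid", value = sub("^taxid:", "", selector)))
  if (grepl("^go:GO:[0-9]{7}$", selector))
    return(list(kind = "go", value = sub("^go:", "", selector)))
  if (grepl("^pfam:PF[0-9]{5}$", selector))
    return(list(kind = "pfam", value = sub("^pfam:", "", selector)))
  tm_usage_error(paste(
    "invalid selector; expected one of taxid:<N>, go:GO:<7 digits>,",
    "pfam:PF<5 digits>"))
}

wrap_sequence <- function(seq, width = 60L) {
  if (!nzchar(seq)) return(character(0))
  starts <- seq(1L, nchar(seq), by = width)
  vapply(starts, function(s) substr(seq, s, min(s + width - 1L, nchar(seq))), "")
}

#' Sweep every foreign-key relation for dangling references
#'
#' Independent of SQLite's constraint enforcement: each FK pair is checked
#' with an explicit anti-join so integrity is asserted, not just trusted.
#'
#' @param con DBI connection.
#' @return named integer vector of dangling-row counts, one per FK
#'   relation (all zero for a sound warehouse).
#' @export
fk_sweep <- function(con) {
  fks <- list(
    c("nucleotide_sequence", "oid", "organism", "oid"),
    c("cds", "nts_id", "nucleotide_sequence", "nts_id"),
    c("cds_segment", "cds_id", "cds", "cds_id"),
    c("protein", "oid", "organism", "oid"),
    c("isoform", "uniprot_ac", "protein", "uniprot_ac"),
    c("protein_go", "uniprot_ac", "protein", "uniprot_ac"),
    c("protein_go", "go_id", "go_term", "go_id"),
    c("protein_domain", "uniprot_ac", "protein", "uniprot_ac"),
    c("protein_domain", "pfam_ac", "domain_family", "pfam_ac"),
    c("structure_chain", "uniprot_ac", "protein", "uniprot_ac"),
    c("refseq_uniprot", "uniprot_ac", "protein", "uniprot_ac")
  )
  out <- integer(0)
  for (fk in fks) {
    n <- DBI::dbGetQuery(con, sprintf(
      "SELECT COUNT(*) AS n FROM %s t WHERE t.%s IS NOT NULL AND NOT EXISTS
         (SELECT 1 FROM %s p WHERE p.%s = t.%s)",
      fk[[1L]], fk[[2L]], fk[[3L]], fk[[4L]], fk[[2L]]))$n
    out[sprintf("%s.%s -> %s", fk[[1L]], fk[[2L]], fk[[3L]])] <- as.integer(n)
  }
  out
}
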