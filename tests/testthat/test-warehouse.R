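# Builds small corpora and checks schema creation, taxon-filtered loading,
# statistics, idempotence, FK soundness and FASTA export.

local_warehouse <- function(path = ":memory:") {
  con <- warehouse_connect(path)
  withr::defer(DBI::dbDisconnect(con), envir = parent.frame())
  con
}

test_that("schema creation makes all 11 entity tables, refuses double creation, and replays identically", {
  con <- local_warehouse()
  create_schema(con)
  tables <- DBI::dbListTables(con)
  expect_true(all(c("organism", "nucleotide_sequence", "cds", "protein",
                    "isoform", "go_term", "protein_go", "domain_family",
                    "protein_domain", "structure_chain", "refseq_uniprot")
                  %in% tables))
  expect_error(create_schema(con), class = "tm_integrity_error")
  expect_silent(create_schema(con, overwrite = TRUE))

  con2 <- local_warehouse()
  create_schema(con2)
  expect_identical(schema_dump(con), schema_dump(con2))
})

test_that("an empty warehouse reports all-zero statistics", {
  con <- local_warehouse()
  create_schema(con)
  s <- compute_stats(con)
  expect_true(all(unlist(s) == 0L))
})

test_that("compute_stats on a foreign database raises a schema error", {
  con <- local_warehouse()
  DBI::dbExecute(con, "CREATE TABLE unrelated (x INTEGER)")
  expect_error(compute_stats(con), class = "tm_schema_error")
})

test_that("loading honours the taxon filter and the manifest counts", {
  corp <- gen_corpus(seed = 101L)
  m <- corp$manifest
  nodes <- parse_taxdump(corp$config$taxonomy_names,
                         corp$config$taxonomy_nodes)
  parsed <- parse_all(corp$config)

  # full clade
  taxa <- resolve_name(nodes, m$root_name)
  con <- local_warehouse()
  create_schema(con)
  load_corpus(con, taxa, parsed, nodes = nodes)
  expect_equal(unclass(compute_stats(con)), unclass(manifest_stats(m)))

  # one genus only: the other genus' records must be absent
  g1 <- resolve_name(nodes, m$genus_names[[1]])
  con1 <- local_warehouse()
  create_schema(con1)
  load_corpus(con1, g1, parsed, nodes = nodes)
  expect_equal(unclass(compute_stats(con1)),
               unclass(manifest_stats(m, g1$member_taxids)))

  allowed <- c(g1$member_taxids, m$novel$taxid)
  db_taxids <- DBI::dbGetQuery(con1, "SELECT taxid FROM organism")$taxid
  expect_true(all(db_taxids %in% allowed))
  prot_taxids <- DBI::dbGetQuery(con1, paste(
    "SELECT o.taxid FROM protein p JOIN organism o ON o.oid = p.oid"))$taxid
  expect_true(all(prot_taxids %in% g1$member_taxids))
})

test_that("an empty taxon set loads nothing", {
  corp <- gen_corpus(seed = 103L, nucleotide_only_taxa = 0L)
  parsed <- parse_all(corp$config)
  con <- local_warehouse()
  create_schema(con)
  load_corpus(con, empty_taxon_set(), parsed)
  expect_true(all(unlist(compute_stats(con)) == 0L))
})

test_that("double load is idempotent for every table", {
  corp <- gen_corpus(seed = 105L, isoforms_per_protein_mean = 0.5)
  nodes <- parse_taxdump(corp$config$taxonomy_names,
                         corp$config$taxonomy_nodes)
  parsed <- parse_all(corp$config)
  taxa <- resolve_name(nodes, corp$manifest$root_name)
  con <- local_warehouse()
  create_schema(con)
  load_corpus(con, taxa, parsed, nodes = nodes)
  once <- stats_vector(compute_stats(con))
  load_corpus(con, taxa, parsed, nodes = nodes)
  expect_identical(stats_vector(compute_stats(con)), once)
})

test_that("a conflicting payload under an existing natural key aborts the load", {
  corp <- gen_corpus(seed = 107L, n_genera = 1L, n_species = 1L,
                     strains_per_species = 0L, nucleotide_only_taxa = 0L)
  nodes <- parse_taxdump(corp$config$taxonomy_names,
                         corp$config$taxonomy_nodes)
  parsed <- parse_all(corp$config)
  taxa <- resolve_name(nodes, corp$manifest$root_name)
  con <- local_warehouse()
  create_schema(con)
  load_corpus(con, taxa, parsed, nodes = nodes)

  conflicted <- parsed
  conflicted$swissprot$records[[1]]$sequence <- "MDIFFERENT"
  expect_error(load_corpus(con, taxa, conflicted, nodes = nodes),
               "different sequence", class = "tm_integrity_error")
})

test_that("the FK sweep finds zero dangling references after a build", {
  corp <- gen_corpus(seed = 109L, isoforms_per_protein_mean = 1)
  res <- build_warehouse(corp$manifest$root_name, corp$config,
                         withr::local_tempfile(fileext = ".db"))
  con <- local_warehouse(res$db_path)
  sweep <- fk_sweep(con)
  expect_true(all(sweep == 0L))
})

test_that("repeated chains of one structure count as a single 3D structure", {
  con <- local_warehouse()
  create_schema(con)
  DBI::dbExecute(con,
    "INSERT INTO organism (oid, taxid, name, source) VALUES (1, 5, 'x', 'taxonomy')")
  DBI::dbExecute(con,
    "INSERT INTO protein (uniprot_ac, oid, name, sequence) VALUES ('P1', 1, 'p', 'MK')")
  for (ch in c("A", "B", "C"))
    DBI::dbExecute(con, sprintf(paste(
      "INSERT INTO structure_chain",
      "(pdb_id, chain_id, uniprot_ac, sp_start, sp_stop, pdb_start, pdb_stop)",
      "VALUES ('1abc', '%s', 'P1', 1, 2, '1', '2')"), ch))
  expect_equal(compute_stats(con)$structures, 1L)
})

test_that("CDS FASTA export is selector-driven, deterministic and manifest-consistent", {
  corp <- gen_corpus(seed = 111L)
  m <- corp$manifest
  db <- withr::local_tempfile(fileext = ".db")
  build_warehouse(m$root_name, corp$config, db)
  con <- local_warehouse(db)

  tax <- m$organisms$taxid[[1]]
  fasta <- export_cds_fasta(con, sprintf("taxid:%d", tax))
  n_expected <- sum(m$cds$taxid == tax)
  expect_equal(sum(startsWith(fasta, ">")), n_expected)

  # repeated export is byte-identical
  expect_identical(export_cds_fasta(con, sprintf("taxid:%d", tax)), fasta)

  # GO selector: every exported CDS links to a protein with that term
  go <- m$protein_go$go_id[[1]]
  acs <- m$protein_go$uniprot_ac[m$protein_go$go_id == go]
  refseqs <- m$refseq_uniprot$refseq_protein_ac[
    m$refseq_uniprot$uniprot_ac %in% acs]
  fasta_go <- export_cds_fasta(con, sprintf("go:%s", go))
  got <- sub(" .*", "", sub("^>", "", fasta_go[startsWith(fasta_go, ">")]))
  expect_setequal(got, refseqs)

  # selector matching nothing: empty output, no error
  expect_length(export_cds_fasta(con, "go:GO:9999990"), 0L)
  expect_error(export_cds_fasta(con, "go=123"), class = "tm_usage_error")
})

test_that("count conservation: SQL statistics equal an in-memory streaming recount", {
  corp <- gen_corpus(seed = 113L)
  m <- corp$manifest
  nodes <- parse_taxdump(corp$config$taxonomy_names,
                         corp$config$taxonomy_nodes)
  parsed <- parse_all(corp$config)
  taxa <- resolve_name(nodes, m$genus_names[[2]])
  con <- local_warehouse()
  create_schema(con)
  load_corpus(con, taxa, parsed, nodes = nodes)

  # recount from the parsed streams (not the manifest, not SQL)
  members <- taxa$member_taxids
  gb_keep <- Filter(function(r) r$taxid %in% members ||
                      !(r$taxid %in% nodes$taxid), parsed$genbank$records)
  prot_keep <- Filter(function(r) r$taxid %in% members,
                      parsed$swissprot$records)
  acs <- vapply(prot_keep, function(r) r$primary_ac, "")
  go_ids <- unique(unlist(lapply(prot_keep, function(r)
    vapply(Filter(function(x) x$target_db == "GO", r$crossrefs),
           function(x) x$target_id, ""))))
  go_ids <- intersect(go_ids, parsed$obo$terms$go_id)
  sifts_p <- parsed$sifts_pfam$mappings
  sifts_u <- parsed$sifts_uniprot$mappings
  s <- compute_stats(con)
  expect_equal(s$genomes, length(gb_keep))
  expect_equal(s$cds, sum(vapply(gb_keep, function(r)
    length(r$cds_features), 0L)))
  expect_equal(s$proteins, length(prot_keep))
  expect_equal(s$go_terms, length(go_ids))
  expect_equal(s$domain_families,
               length(unique(sifts_p$pfam_ac[sifts_p$uniprot_ac %in% acs])))
  expect_equal(s$structures,
               length(unique(sifts_u$pdb_id[sifts_u$uniprot_ac %in% acs])))
  expect_equal(s$isoforms,
               sum(parsed$varsplic$isoforms$parent_ac %in% acs))
})
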