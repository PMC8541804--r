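# The generator is first-class code: parameter arithmetic, determinism,
# cross-file referential closure and the defect-planting contract.

test_that("entity counts follow the parameter arithmetic", {
  corp <- gen_corpus(seed = 7L, n_genera = 1L, n_species = 3L,
                     strains_per_species = 0L, genomes_per_organism = 1L,
                     cds_per_genome = 4L, nucleotide_only_taxa = 0L)
  m <- corp$manifest
  expect_equal(nrow(m$genomes), 3L)   # one per species
  expect_equal(nrow(m$cds), 12L)      # 3 genomes x 4 CDSs
  # taxa: root + genus + 3 species
  expect_equal(nrow(m$taxa), 5L)
})

test_that("invalid parameters fail before any file is written", {
  expect_error(corpus_params(proteins_linked_fraction = 1.2),
               class = "tm_usage_error")
  expect_error(corpus_params(n_species = 0L), class = "tm_usage_error")
  out <- tempfile()
  expect_error(generate_corpus(corpus_params(), out, defects = "no-such-kind"),
               class = "tm_usage_error")
  expect_false(dir.exists(out))
})

test_that("the same seed and parameters give a byte-identical corpus", {
  d1 <- tempfile(); d2 <- tempfile(); d3 <- tempfile()
  m1 <- generate_corpus(corpus_params(seed = 42L), d1)
  m2 <- generate_corpus(corpus_params(seed = 42L), d2)
  m3 <- generate_corpus(corpus_params(seed = 43L), d3)
  digest <- function(d) vapply(sort(list.files(d)), function(f)
    paste(tools::md5sum(file.path(d, f))), "")
  expect_identical(digest(d1), digest(d2))
  expect_false(all(digest(d1) == digest(d3)))
  expect_equal(unclass(manifest_stats(m1)), unclass(manifest_stats(m2)))
  invisible(m3)
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  generate_corpus(corpus_params(seed = 1L, n_genera = 1L, n_species = 1L),
                  tempfile())
  b <- runif(1)
  expect_identical(a, b)
})

test_that("cross-file referential closure holds (independent sweep over the files)", {
  corp <- gen_corpus(seed = 55L, isoforms_per_protein_mean = 0.7)
  cfg <- corp$config
  parsed <- parse_all(cfg)

  cds_protein_ids <- unlist(lapply(parsed$genbank$records, function(r)
    vapply(r$cds_features, function(x) x$refseq_protein_ac, "")))
  taxdump_taxids <- parse_taxdump(cfg$taxonomy_names, cfg$taxonomy_nodes)$taxid
  protein_acs <- vapply(parsed$swissprot$records, function(r) r$primary_ac, "")

  for (rec in parsed$swissprot$records) {
    refseq <- Filter(function(x) x$target_db == "RefSeq", rec$crossrefs)
    # every DR RefSeq id appears as a protein_id of some CDS
    for (xr in refseq) expect_true(xr$target_id %in% cds_protein_ids)
    expect_true(rec$taxid %in% taxdump_taxids)
  }
  # every SIFTS accession is a generated protein
  expect_true(all(parsed$sifts_uniprot$mappings$uniprot_ac %in% protein_acs))
  expect_true(all(parsed$sifts_pfam$mappings$uniprot_ac %in% protein_acs))
  # every isoform parent is a generated protein
  expect_true(all(parsed$varsplic$isoforms$parent_ac %in% protein_acs))
  # manifest refers only to identifiers in the files
  expect_true(all(corp$manifest$cds$refseq_protein_ac %in% cds_protein_ids))
})

test_that("CDS translations are genuine codon translations of their spans", {
  corp <- gen_corpus(seed = 57L, n_genera = 1L, n_species = 2L,
                     strains_per_species = 0L, nucleotide_only_taxa = 0L)
  gb_lines <- readLines(corp$config$nucleotide)
  parsed <- parse_genbank(corp$config$nucleotide)
  for (rec in parsed$records) {
    # reassemble the genome from the ORIGIN block
    start <- grep("^ORIGIN", gb_lines)
    vstart <- grep(paste0("^VERSION\\s+", rec$accession), gb_lines)
    ostart <- min(start[start > vstart])
    oend <- min(grep("^//$", gb_lines)[grep("^//$", gb_lines) > ostart])
    seqtxt <- toupper(gsub("[^a-z]", "",
                           paste(gb_lines[(ostart + 1):(oend - 1)],
                                 collapse = "")))
    expect_equal(nchar(seqtxt), rec$sequence_length)
    for (cds in rec$cds_features) {
      segs <- cds$location$segments
      nt <- paste(vapply(seq_len(nrow(segs)), function(i)
        substr(seqtxt, segs$start[i], segs$stop[i]), ""), collapse = "")
      if (cds$location$strand == "-")
        nt <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(nt)))
      aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
      expect_equal(sub("\\*$", "", aa), cds$translation)
      # translation-length invariant
      expect_lte(nchar(cds$translation) * 3, location_length(cds$location))
    }
  }
})

test_that("isoform profiles mirror the eukaryote/prokaryote pattern", {
  euk <- gen_corpus(seed = 61L, isoforms_per_protein_mean = 1.2)
  prok <- gen_corpus(seed = 61L, isoforms_per_protein_mean = 0)
  expect_gt(manifest_stats(euk$manifest)$isoforms, 0L)
  expect_equal(manifest_stats(prok$manifest)$isoforms, 0L)
})

test_that("planted defects are tallied in the manifest and exercised by the parsers", {
  defects <- c("bad_location", "bad_location", "non_refseq_accession",
               "orphan_crossref")
  dir <- tempfile()
  m <- plant_defects(corpus_params(seed = 63L), defects, dir)
  expect_equal(m$defects$bad_location, 2L)
  expect_equal(m$defects$non_refseq_accession, 1L)
  expect_equal(m$defects$orphan_crossref, 1L)
  gb <- parse_genbank(corpus_config(dir)$nucleotide)
  expect_equal(gb$errors[["bad_location"]], 2L)
})

test_that("defect corpora still build a manifest-consistent warehouse with the planted error tallies", {
  dir <- tempfile()
  defects <- c("bad_location", "non_refseq_accession", "wrong_column_count",
               "truncated_entry", "orphan_crossref")
  m <- plant_defects(corpus_params(seed = 65L), defects, dir)
  cfg <- corpus_config(dir)
  gb <- parse_genbank(cfg$nucleotide)
  expect_equal(gb$errors[["bad_location"]], 1L)
  expect_equal(gb$errors[["non_refseq"]], 1L)
  expect_equal(gb$errors[["missing_header"]], 1L)
  su <- parse_sifts_chain_tsv(cfg$sifts_uniprot, "uniprot")
  expect_equal(su$errors, 1L)

  db <- tempfile(fileext = ".db")
  res <- build_warehouse(m$root_name, cfg, db)
  expect_equal(unclass(res$stats), unclass(manifest_stats(m)))
  expect_equal(res$load_report$orphan_go_refs, 1L)

  # empty defect list is identical to plain generation
  d_a <- tempfile(); d_b <- tempfile()
  generate_corpus(corpus_params(seed = 66L), d_a)
  plant_defects(corpus_params(seed = 66L), character(0), d_b)
  digest <- function(d) vapply(sort(list.files(d)), function(f)
    paste(tools::md5sum(file.path(d, f))), "")
  expect_identical(digest(d_a), digest(d_b))
})

test_that("manifest-vs-warehouse equality holds across randomized parameter draws", {
  set.seed(202)
  for (i in 1:8) {
    corp <- gen_corpus(
      seed = sample.int(10000L, 1L),
      n_genera = sample(1:2, 1L), n_species = sample(1:3, 1L),
      strains_per_species = sample(0:1, 1L),
      genomes_per_organism = sample(1:2, 1L),
      cds_per_genome = sample(2:5, 1L),
      proteins_linked_fraction = runif(1, 0.3, 1),
      isoforms_per_protein_mean = sample(c(0, 0.8), 1L),
      pdb_chain_fraction = runif(1, 0, 0.8),
      nucleotide_only_taxa = sample(0:2, 1L))
    res <- build_warehouse(corp$manifest$root_name, corp$config, ":memory:")
    expect_equal(unclass(res$stats), unclass(manifest_stats(corp$manifest)),
                 info = sprintf("draw %d seed %d", i, corp$params$seed))
  }
})
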