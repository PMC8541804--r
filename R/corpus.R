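# Deterministic synthetic seven-source corpus for a fictional clade.
# Every cross-file identifier is consistent: each Swiss-Prot DR RefSeq id
# is a protein_id of some CDS, every SIFTS accession is a generated
# protein, every organism taxid is in the taxdump (except deliberately
# "novel" taxa that emulate organisms discoverable only through nucleotide
# records).  Identifiers are fictional but format-valid (taxids in a
# reserved high range, UniProt-pattern ACs, PF+5-digit, GO:+7-digit,
# RefSeq-prefixed accessions) so pattern validators run for real.
# Translations are genuine codon translations of the CDS spans.

GENUS_POOL <- c("Fictibacter", "Imaginococcus", "Mirabacillus",
                "Exemplaria", "Pseudofictus", "Synthomonas",
                "Fabricatella", "Inventium")
EPITHET_POOL <- c("alphaensis", "betae", "gammicus", "deltae",
                  "epsilonis", "zetae", "etaensis", "thetae")
AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
DEFECT_KINDS <- c("truncated_entry", "bad_location", "wrong_column_count",
                  "non_refseq_accession", "orphan_crossref")

#' Parameters for the synthetic corpus generator
#'
#' Defaults describe a small two-genus prokaryote-like clade: no isoforms
#' (set `isoforms_per_protein_mean > 0` for a eukaryote-like profile), a
#' modest ontology and domain pool, and one organism discoverable only
#' through nucleotide records.
#'
#' @param n_genera number of genera under the fictional root clade.
#' @param n_species species per genus.
#' @param strains_per_species strain-rank children per species.
#' @param genomes_per_organism nucleotide records per species/strain.
#' @param cds_per_genome CDS features per record.
#' @param proteins_linked_fraction fraction of CDSs with a Swiss-Prot
#'   entry cross-referencing them.
#' @param isoforms_per_protein_mean Poisson mean of splice isoforms per
#'   protein (0 = prokaryote/virus-like profile).
#' @param go_terms_pool size of the ontology term pool.
#' @param pfam_pool size of the domain-family pool.
#' @param pdb_chain_fraction fraction of proteins with solved structures.
#' @param nucleotide_only_taxa organisms present in nucleotide records but
#'   absent from the taxonomy dump.
#' @param seed integer seed; same seed + params give a byte-identical
#'   corpus.
#' @return validated `corpus_params` list.
#' @export
corpus_params <- function(n_genera = 2L, n_species = 3L,
                          strains_per_species = 1L,
                          genomes_per_organism = 1L, cds_per_genome = 5L,
                          proteins_linked_fraction = 0.8,
                          isoforms_per_protein_mean = 0,
                          go_terms_pool = 15L, pfam_pool = 8L,
                          pdb_chain_fraction = 0.3,
                          nucleotide_only_taxa = 1L, seed = 1L) {
  p <- list(n_genera = as.integer(n_genera), n_species = as.integer(n_species),
            strains_per_species = as.integer(strains_per_species),
            genomes_per_organism = as.integer(genomes_per_organism),
            cds_per_genome = as.integer(cds_per_genome),
            proteins_linked_fraction = proteins_linked_fraction,
            isoforms_per_protein_mean = isoforms_per_protein_mean,
            go_terms_pool = as.integer(go_terms_pool),
            pfam_pool = as.integer(pfam_pool),
            pdb_chain_fraction = pdb_chain_fraction,
            nucleotide_only_taxa = as.integer(nucleotide_only_taxa),
            seed = as.integer(seed))
  with(p, {
    if (n_genera < 1L || n_genera > length(GENUS_POOL))
      tm_usage_error(sprintf("n_genera must be in 1..%d", length(GENUS_POOL)))
    if (n_species < 1L || n_species > length(EPITHET_POOL))
      tm_usage_error(sprintf("n_species must be in 1..%d", length(EPITHET_POOL)))
    if (strains_per_species < 0L) tm_usage_error("strains_per_species < 0")
    if (genomes_per_organism < 1L) tm_usage_error("genomes_per_organism < 1")
    if (cds_per_genome < 1L) tm_usage_error("cds_per_genome < 1")
    if (proteins_linked_fraction < 0 || proteins_linked_fraction > 1)
      tm_usage_error("proteins_linked_fraction outside [0, 1]")
    if (isoforms_per_protein_mean < 0)
      tm_usage_error("isoforms_per_protein_mean < 0")
    if (go_terms_pool < 3L) tm_usage_error("go_terms_pool < 3")
    if (pfam_pool < 1L) tm_usage_error("pfam_pool < 1")
    if (pdb_chain_fraction < 0 || pdb_chain_fraction > 1)
      tm_usage_error("pdb_chain_fraction outside [0, 1]")
    if (nucleotide_only_taxa < 0L) tm_usage_error("nucleotide_only_taxa < 0")
  })
  structure(p, class = "corpus_params")
}

# first codon listed for each amino acid in the standard genetic code
aa_to_codons <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  vapply(strsplit(aa, "")[[1L]], function(a) names(gc)[match(a, gc)], "")
}

revcomp <- function(nt) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
}

#' Generate a synthetic seven-source corpus
#'
#' Writes `names.dmp`, `nodes.dmp`, a GenBank flat file, a Swiss-Prot DAT
#' file, a varsplic-style isoform FASTA, an OBO ontology, a Pfam family
#' table and two SIFTS-style TSVs into `out_dir`, together with a
#' ground-truth `manifest.json`.  The `defects` argument plants malformed
#' records from a closed set of kinds (see [DEFECT_KINDS]) to exercise
#' parser error paths; planted records never enter the manifest's entity
#' counts.
#'
#' @param params a `corpus_params` object.
#' @param out_dir output directory (created if missing).
#' @param defects character vector of defect kinds, possibly repeated.
#' @return the `corpus_manifest` (also written as `manifest.json`).
#' @export
generate_corpus <- function(params, out_dir, defects = character(0)) {
  stopifnot(inherits(params, "corpus_params"))
  bad <- setdiff(defects, DEFECT_KINDS)
  if (length(bad))
    tm_usage_error(sprintf("unknown defect kind(s): %s",
                           paste(unique(bad), collapse = ", ")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(params$seed, generate_corpus_impl(params, out_dir, defects))
}

#' Generate a corpus with planted parser defects
#'
#' Convenience wrapper over [generate_corpus()] with a non-empty defect
#' list.
#'
#' @inheritParams generate_corpus
#' @export
plant_defects <- function(params, defects, out_dir) {
  generate_corpus(params, out_dir, defects = defects)
}

generate_corpus_impl <- function(p, out, defects) {
  taxid0 <- 900000000L
  tax_counter <- 0L
  next_taxid <- function() { tax_counter <<- tax_counter + 1L; taxid0 + tax_counter }

  root_taxid <- next_taxid()
  taxa <- data.frame(taxid = root_taxid, parent_taxid = root_taxid,
                     rank = "clade", name = "Synthetica",
                     genus = NA_character_, stringsAsFactors = FALSE)
  organisms <- list()   # data-bearing taxa (species + strains)
  for (g in seq_len(p$n_genera)) {
    genus <- GENUS_POOL[[g]]
    g_taxid <- next_taxid()
    taxa <- rbind(taxa, data.frame(taxid = g_taxid, parent_taxid = root_taxid,
                                   rank = "genus", name = genus, genus = genus))
    for (s in seq_len(p$n_species)) {
      sp_name <- paste(genus, EPITHET_POOL[[s]])
      sp_taxid <- next_taxid()
      taxa <- rbind(taxa, data.frame(taxid = sp_taxid, parent_taxid = g_taxid,
                                     rank = "species", name = sp_name,
                                     genus = genus))
      organisms[[length(organisms) + 1L]] <-
        data.frame(taxid = sp_taxid, name = sp_name, genus = genus)
      for (st in seq_len(p$strains_per_species)) {
        st_name <- sprintf("%s str. S%d", sp_name, st)
        st_taxid <- next_taxid()
        taxa <- rbind(taxa, data.frame(taxid = st_taxid,
                                       parent_taxid = sp_taxid,
                                       rank = "strain", name = st_name,
                                       genus = genus))
        organisms[[length(organisms) + 1L]] <-
          data.frame(taxid = st_taxid, name = st_name, genus = genus)
      }
    }
  }
  organisms <- do.call(rbind, organisms)

  # novel taxa: in nucleotide records only, never in the taxdump
  novel <- if (p$nucleotide_only_taxa > 0L) data.frame(
    taxid = 910000000L + seq_len(p$nucleotide_only_taxa),
    name = sprintf("Incognitum cryptum %d", seq_len(p$nucleotide_only_taxa)),
    genus = NA_character_, stringsAsFactors = FALSE
  ) else NULL

  # --- identifier counters ----------------------------------------------
  acc_c <- 0L; prot_c <- 0L; cds_c <- 0L; pdb_c <- 0L
  genbank_entries <- character(0)
  sp_entries <- character(0)
  varsplic_lines <- character(0)
  sifts_u_rows <- character(0)
  sifts_p_rows <- character(0)

  go_pool <- sprintf("GO:%07d", seq_len(p$go_terms_pool))
  n_obsolete <- if (p$go_terms_pool >= 5L) 1L else 0L
  go_assignable <- go_pool[seq_len(p$go_terms_pool - n_obsolete)]
  pfam_pool <- sprintf("PF%05d", seq_len(p$pfam_pool))

  cds_rows <- list(); prot_rows <- list(); link_go <- list()
  link_pfam <- list(); link_chain <- list(); link_iso <- list()
  link_refseq <- list(); genome_rows <- list()

  orphan_crossref_pending <- sum(defects == "orphan_crossref")

  emit_genome <- function(taxid, orgname, novel_taxon = FALSE) {
    acc_c <<- acc_c + 1L
    accession <- sprintf("NC_%06d.1", 900000L + acc_c)
    cds_list <- list()
    pos <- 40L
    for (ci in seq_len(p$cds_per_genome)) {
      cds_c <<- cds_c + 1L
      n_aa <- sample(20:45, 1L)
      aa <- paste(c("M", sample(AA20, n_aa - 1L, replace = TRUE)),
                  collapse = "")
      nt <- paste(c(aa_to_codons(aa), "TAA"), collapse = "")
      strand <- sample(c("+", "-"), 1L)
      placed <- if (strand == "-") revcomp(nt) else nt
      len <- nchar(placed)
      multi <- stats::runif(1L) < 0.3
      gap <- sample(30:80, 1L)
      s1 <- pos + gap
      if (multi) {
        k <- sample(seq(6L, len - 6L, by = 3L), 1L)
        intron <- sample(10:40, 1L)
        segs <- data.frame(start = c(s1, s1 + k + intron),
                           stop = c(s1 + k - 1L, s1 + k + intron + (len - k) - 1L))
      } else {
        segs <- data.frame(start = s1, stop = s1 + len - 1L)
      }
      pos <- max(segs$stop)
      inner <- paste(sprintf("%d..%d", segs$start, segs$stop), collapse = ",")
      loc <- if (nrow(segs) > 1L) sprintf("join(%s)", inner) else inner
      if (strand == "-") loc <- sprintf("complement(%s)", loc)
      protein_id <- sprintf("WP_%09d.1", cds_c)
      cds_list[[ci]] <- list(
        location = loc, segs = segs, strand = strand, placed = placed,
        protein_id = protein_id, gene = sprintf("fg%04d", cds_c),
        locus_tag = sprintf("SYN_%05d", cds_c),
        product = sprintf("hypothetical protein %d", cds_c),
        translation = aa
      )
      cds_rows[[length(cds_rows) + 1L]] <<- data.frame(
        accession = accession, taxid = taxid, refseq_protein_ac = protein_id,
        strand = strand, n_segments = nrow(segs),
        start = min(segs$start), stop = max(segs$stop),
        location = loc, translation = aa, stringsAsFactors = FALSE
      )
    }
    genome_len <- pos + sample(30:60, 1L)
    genome <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE)
    for (cds in cds_list) {
      placed <- strsplit(cds$placed, "")[[1L]]
      off <- 0L
      for (si in seq_len(nrow(cds$segs))) {
        w <- cds$segs$stop[[si]] - cds$segs$start[[si]] + 1L
        genome[cds$segs$start[[si]]:cds$segs$stop[[si]]] <-
          placed[(off + 1L):(off + w)]
        off <- off + w
      }
    }
    genome_rows[[length(genome_rows) + 1L]] <<- data.frame(
      accession = accession, taxid = taxid, length = genome_len,
      novel = novel_taxon, stringsAsFactors = FALSE
    )
    genbank_entries[[length(genbank_entries) + 1L]] <<-
      format_genbank_entry(accession, orgname, taxid, genome, cds_list)
    cds_list
  }

  emit_protein <- function(taxid, orgname, cds) {
    prot_c <<- prot_c + 1L
    ac <- sprintf("P%05d", 10000L + prot_c)
    aa <- cds$translation
    go_ids <- sample(go_assignable, sample(1:3, 1L))
    has_structure <- stats::runif(1L) < p$pdb_chain_fraction
    pdb_id <- NA_character_
    chains <- character(0)
    doms <- NULL
    if (has_structure) {
      pdb_c <<- pdb_c + 1L
      pdb_id <- sprintf("9%s", paste(
        letters[1L + (c(pdb_c %/% 676L, (pdb_c %/% 26L) %% 26L,
                        pdb_c %% 26L))], collapse = ""))
      chains <- LETTERS[seq_len(sample(1:3, 1L))]
      for (ch in chains) {
        sp_stop <- nchar(aa)
        pdb_stop <- if (stats::runif(1L) < 0.15) sprintf("%dA", sp_stop)
                    else as.character(sp_stop)
        sifts_u_rows[[length(sifts_u_rows) + 1L]] <<-
          paste(pdb_id, ch, ac, 1L, sp_stop, "1", pdb_stop, sep = "\t")
        link_chain[[length(link_chain) + 1L]] <<- data.frame(
          pdb_id = pdb_id, chain_id = ch, uniprot_ac = ac,
          sp_start = 1L, sp_stop = sp_stop, stringsAsFactors = FALSE
        )
      }
      n_dom <- sample(1:2, 1L)
      dom_acs <- sample(pfam_pool, n_dom)
      dstart <- 1L
      doms <- lapply(dom_acs, function(pf) {
        w <- max(5L, nchar(aa) %/% (n_dom + 1L))
        s <- min(dstart, nchar(aa) - 1L)
        e <- min(s + w, nchar(aa))
        dstart <<- e + 2L
        sifts_p_rows[[length(sifts_p_rows) + 1L]] <<-
          paste(pdb_id, chains[[1L]], ac, pf, s, e, sep = "\t")
        link_pfam[[length(link_pfam) + 1L]] <<- data.frame(
          uniprot_ac = ac, pfam_ac = pf, sp_start = s, sp_stop = e,
          stringsAsFactors = FALSE
        )
        list(pfam_ac = pf, sp_start = s, sp_stop = e)
      })
    }
    n_iso <- stats::rpois(1L, p$isoforms_per_protein_mean)
    iso_acs <- if (n_iso > 0L) sprintf("%s-%d", ac, 1L + seq_len(n_iso))
               else character(0)
    for (ia in iso_acs) {
      cut <- sample(seq(5L, max(6L, nchar(aa) - 3L)), 1L)
      iso_seq <- substr(aa, 1L, cut)
      varsplic_lines <<- c(varsplic_lines,
        sprintf(">sp|%s|ISO_%s Isoform of %s", ia, ia, ac),
        wrap_sequence(iso_seq))
      link_iso[[length(link_iso) + 1L]] <<- data.frame(
        isoform_ac = ia, parent_ac = ac, stringsAsFactors = FALSE)
    }
    extra_go <- character(0)
    if (orphan_crossref_pending > 0L) {
      extra_go <- "GO:9999999"   # unknown to the ontology: orphan crossref
      orphan_crossref_pending <<- orphan_crossref_pending - 1L
    }
    for (g in go_ids)
      link_go[[length(link_go) + 1L]] <<- data.frame(
        uniprot_ac = ac, go_id = g, stringsAsFactors = FALSE)
    link_refseq[[length(link_refseq) + 1L]] <<- data.frame(
      refseq_protein_ac = cds$protein_id, uniprot_ac = ac,
      stringsAsFactors = FALSE)
    prot_rows[[length(prot_rows) + 1L]] <<- data.frame(
      uniprot_ac = ac, taxid = taxid, refseq_protein_ac = cds$protein_id,
      length = nchar(aa), pdb_id = pdb_id, n_isoforms = n_iso,
      stringsAsFactors = FALSE)
    sp_entries[[length(sp_entries) + 1L]] <<- format_swissprot_entry(
      ac, cds, taxid, orgname, go_ids, extra_go, doms, pdb_id, iso_acs)
  }

  for (o in seq_len(nrow(organisms)))
    for (gg in seq_len(p$genomes_per_organism)) {
      cds_list <- emit_genome(organisms$taxid[[o]], organisms$name[[o]])
      for (cds in cds_list)
        if (stats::runif(1L) < p$proteins_linked_fraction)
          emit_protein(organisms$taxid[[o]], organisms$name[[o]], cds)
    }
  if (!is.null(novel))
    for (o in seq_len(nrow(novel)))
      emit_genome(novel$taxid[[o]], novel$name[[o]], novel_taxon = TRUE)

  # --- planted defects ---------------------------------------------------
  defect_tally <- stats::setNames(integer(length(DEFECT_KINDS)), DEFECT_KINDS)
  first_member_taxid <- organisms$taxid[[1L]]
  for (d in defects) {
    defect_tally[[d]] <- defect_tally[[d]] + 1L
    if (d == "truncated_entry") {
      genbank_entries <- c(genbank_entries, paste(
        "LOCUS       NC_999999              100 bp    DNA     linear",
        "DEFINITION  truncated synthetic record.", "//", sep = "\n"))
    } else if (d == "bad_location") {
      genome <- sample(c("A", "C", "G", "T"), 200L, replace = TRUE)
      ent <- format_genbank_entry(
        sprintf("NC_%06d.1", 990000L + defect_tally[[d]]),
        organisms$name[[1L]], first_member_taxid, genome,
        list(list(location = "join(50..40)", gene = "bad", locus_tag = "BAD",
                  product = "bad", protein_id = "WP_999999999.1",
                  translation = "MK")))
      genbank_entries <- c(genbank_entries, ent)
    } else if (d == "non_refseq_accession") {
      genome <- sample(c("A", "C", "G", "T"), 150L, replace = TRUE)
      ent <- format_genbank_entry(
        sprintf("AB%06d.1", 100000L + defect_tally[[d]]),
        organisms$name[[1L]], first_member_taxid, genome, list())
      genbank_entries <- c(genbank_entries, ent)
    } else if (d == "wrong_column_count") {
      sifts_u_rows[[length(sifts_u_rows) + 1L]] <-
        paste("9zzz", "A", "P99999", "1", sep = "\t")
    }
    # orphan_crossref handled while emitting proteins
  }
  planted_orphans <- sum(defects == "orphan_crossref") - orphan_crossref_pending
  defect_tally[["orphan_crossref"]] <- planted_orphans

  # --- write files -------------------------------------------------------
  write_taxdump(taxa, out)
  writeLines(unlist(genbank_entries), file.path(out, "nucleotide.gb"))
  writeLines(unlist(sp_entries), file.path(out, "swissprot.dat"))
  writeLines(varsplic_lines, file.path(out, "varsplic.fasta"))
  write_obo(go_pool, n_obsolete, file.path(out, "ontology.obo"))
  write_pfam_table(pfam_pool, file.path(out, "pfam_families.tsv"))
  writeLines(c("# synthetic chain-level mapping 2020-08",
               paste("PDB", "CHAIN", "SP_PRIMARY", "SP_BEG", "SP_END",
                     "PDB_BEG", "PDB_END", sep = "\t"),
               unlist(sifts_u_rows)),
             file.path(out, "sifts_uniprot.tsv"))
  writeLines(c("# synthetic domain mapping 2020-08",
               paste("PDB", "CHAIN", "SP_PRIMARY", "PFAM_AC", "SP_BEG",
                     "SP_END", sep = "\t"),
               unlist(sifts_p_rows)),
             file.path(out, "sifts_pfam.tsv"))

  bind_or_empty <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  manifest <- structure(list(
    params = unclass(p),
    root_name = "Synthetica",
    genus_names = GENUS_POOL[seq_len(p$n_genera)],
    taxa = taxa,
    organisms = organisms,
    novel = if (is.null(novel)) data.frame(taxid = integer(0), name = character(0))
            else novel[, c("taxid", "name")],
    genomes = bind_or_empty(genome_rows,
      data.frame(accession = character(0), taxid = integer(0),
                 length = integer(0), novel = logical(0))),
    cds = bind_or_empty(cds_rows,
      data.frame(accession = character(0), taxid = integer(0),
                 refseq_protein_ac = character(0), strand = character(0),
                 n_segments = integer(0), start = integer(0),
                 stop = integer(0), location = character(0),
                 translation = character(0))),
    proteins = bind_or_empty(prot_rows,
      data.frame(uniprot_ac = character(0), taxid = integer(0),
                 refseq_protein_ac = character(0), length = integer(0),
                 pdb_id = character(0), n_isoforms = integer(0))),
    protein_go = bind_or_empty(link_go,
      data.frame(uniprot_ac = character(0), go_id = character(0))),
    protein_pfam = bind_or_empty(link_pfam,
      data.frame(uniprot_ac = character(0), pfam_ac = character(0),
                 sp_start = integer(0), sp_stop = integer(0))),
    chains = bind_or_empty(link_chain,
      data.frame(pdb_id = character(0), chain_id = character(0),
                 uniprot_ac = character(0), sp_start = integer(0),
                 sp_stop = character(0))),
    isoforms = bind_or_empty(link_iso,
      data.frame(isoform_ac = character(0), parent_ac = character(0))),
    refseq_uniprot = bind_or_empty(link_refseq,
      data.frame(refseq_protein_ac = character(0), uniprot_ac = character(0))),
    defects = as.list(defect_tally),
    files = list(
      taxonomy_names = "names.dmp", taxonomy_nodes = "nodes.dmp",
      nucleotide = "nucleotide.gb", swissprot = "swissprot.dat",
      varsplic = "varsplic.fasta", go_obo = "ontology.obo",
      pfam = "pfam_families.tsv", sifts_uniprot = "sifts_uniprot.tsv",
      sifts_pfam = "sifts_pfam.tsv")
  ), class = "corpus_manifest")

  jsonlite::write_json(unclass(manifest), file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  manifest
}

#' Read a corpus manifest back from disk
#'
#' @param path path to a `manifest.json` written by [generate_corpus()].
#' @return a `corpus_manifest`.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "corpus_manifest")
}

#' Expected warehouse statistics for a manifest under a taxon filter
#'
#' Recomputes, purely in memory from the manifest's link lists, the entity
#' counts the warehouse should report after loading the corpus with the
#' given member set — the independent oracle for the end-to-end pipeline.
#' Novel (nucleotide-only) organisms are always admitted, mirroring the
#' loader's discovery rule.
#'
#' @param manifest a `corpus_manifest`.
#' @param member_taxids taxids of the query subtree; default all taxa in
#'   the corpus (a root-clade query).
#' @return a `warehouse_stats` object.
#' @export
manifest_stats <- function(manifest, member_taxids = NULL) {
  if (is.null(member_taxids)) member_taxids <- manifest$taxa$taxid
  g <- manifest$genomes
  keep_g <- g$taxid %in% member_taxids | g$novel
  cds <- manifest$cds
  keep_cds <- cds$accession %in% g$accession[keep_g]
  prot <- manifest$proteins
  keep_p <- prot$taxid %in% member_taxids
  acs <- prot$uniprot_ac[keep_p]
  structure(list(
    organisms_from_taxonomy = length(member_taxids),
    organisms_from_nucleotide = sum(g$novel & keep_g & !duplicated(g$taxid)),
    genomes = sum(keep_g),
    cds = sum(keep_cds),
    proteins = length(acs),
    isoforms = sum(manifest$isoforms$parent_ac %in% acs),
    go_terms = length(unique(
      manifest$protein_go$go_id[manifest$protein_go$uniprot_ac %in% acs])),
    domain_families = length(unique(
      manifest$protein_pfam$pfam_ac[manifest$protein_pfam$uniprot_ac %in% acs])),
    structures = length(unique(
      manifest$chains$pdb_id[manifest$chains$uniprot_ac %in% acs]))
  ), class = "warehouse_stats")
}

# ---- file writers --------------------------------------------------------

write_taxdump <- function(taxa, out) {
  nodes <- sprintf("%d\t|\t%d\t|\t%s\t|\t\t|", taxa$taxid,
                   taxa$parent_taxid, taxa$rank)
  names_l <- sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", taxa$taxid,
                     taxa$name)
  genus <- taxa[taxa$rank == "genus", ]
  syn <- sprintf("%d\t|\t%s group\t|\t\t|\tsynonym\t|", genus$taxid,
                 genus$name)
  writeLines(nodes, file.path(out, "nodes.dmp"))
  writeLines(c(names_l, syn), file.path(out, "names.dmp"))
}

format_genbank_entry <- function(accession, orgname, taxid, genome, cds_list) {
  acc_base <- sub("\\.[0-9]+$", "", accession)
  len <- length(genome)
  lines <- c(
    sprintf("LOCUS       %-12s %9d bp    DNA     linear   CON 01-JAN-2020",
            acc_base, len),
    sprintf("DEFINITION  %s chromosome 1, complete sequence.", orgname),
    sprintf("ACCESSION   %s", acc_base),
    sprintf("VERSION     %s", accession),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", len),
    sprintf("                     /organism=\"%s\"", orgname),
    "                     /mol_type=\"genomic DNA\"",
    "                     /chromosome=\"1\"",
    sprintf("                     /db_xref=\"taxon:%d\"", taxid)
  )
  for (cds in cds_list) {
    lines <- c(lines,
      sprintf("     CDS             %s", cds$location),
      sprintf("                     /gene=\"%s\"", cds$gene),
      sprintf("                     /locus_tag=\"%s\"", cds$locus_tag),
      sprintf("                     /product=\"%s\"", cds$product),
      sprintf("                     /codon_start=1"),
      sprintf("                     /protein_id=\"%s\"", cds$protein_id),
      format_translation_qualifier(cds$translation)
    )
  }
  lines <- c(lines, "ORIGIN", format_origin(genome), "//")
  paste(lines, collapse = "\n")
}

format_translation_qualifier <- function(aa) {
  txt <- sprintf("/translation=\"%s\"", aa)
  pieces <- substring(txt, seq(1L, nchar(txt), by = 45L),
                      pmin(seq(1L, nchar(txt), by = 45L) + 44L, nchar(txt)))
  paste0(strrep(" ", 21L), pieces)
}

format_origin <- function(genome) {
  s <- tolower(paste(genome, collapse = ""))
  starts <- seq(1L, nchar(s), by = 60L)
  vapply(starts, function(st) {
    chunk <- substr(s, st, min(st + 59L, nchar(s)))
    groups <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(1L, nchar(chunk), by = 10L) + 9L, nchar(chunk)))
    sprintf("%9d %s", st, paste(groups, collapse = " "))
  }, "")
}

format_swissprot_entry <- function(ac, cds, taxid, orgname, go_ids, extra_go,
                                   doms, pdb_id, iso_acs) {
  aa <- cds$translation
  lines <- c(
    sprintf("ID   %s_SYNTH              Reviewed;     %d AA.",
            toupper(cds$gene), nchar(aa)),
    sprintf("AC   %s;", ac),
    sprintf("DE   RecName: Full=%s;", cds$product),
    sprintf("GN   Name=%s;", cds$gene),
    sprintf("OS   %s.", orgname),
    sprintf("OX   NCBI_TaxID=%d;", taxid),
    sprintf("DR   RefSeq; %s; %s.", cds$protein_id, "NC_000000.1"),
    sprintf("DR   EMBL; X%05d; -; Genomic_DNA.", sample(1:99999, 1L))
  )
  for (g in c(go_ids, extra_go))
    lines <- c(lines, sprintf("DR   GO; %s; P:synthetic process; IEA:Synth.", g))
  if (!is.null(doms))
    for (d in doms)
      lines <- c(lines, sprintf("DR   Pfam; %s; Fam_%s; 1.", d$pfam_ac,
                                sub("^PF0*", "", d$pfam_ac)))
  if (!is.na(pdb_id))
    lines <- c(lines, sprintf("DR   PDB; %s; X-ray; 2.00 A; A=1-%d.",
                              toupper(pdb_id), nchar(aa)))
  if (length(iso_acs)) {
    lines <- c(lines,
      "CC   -!- ALTERNATIVE PRODUCTS:",
      sprintf("CC       Event=Alternative splicing; Named isoforms=%d;",
              length(iso_acs) + 1L),
      "CC       Name=1;",
      sprintf("CC         IsoId=%s-1; Sequence=Displayed;", ac))
    for (i in seq_along(iso_acs))
      lines <- c(lines,
        sprintf("CC       Name=%d;", i + 1L),
        sprintf("CC         IsoId=%s; Sequence=VSP_%06d;", iso_acs[[i]], i))
  }
  lines <- c(lines,
    sprintf("SQ   SEQUENCE   %d AA;  %d MW;  0000000000000000 CRC64;",
            nchar(aa), nchar(aa) * 110L),
    format_sq_block(aa),
    "//")
  paste(lines, collapse = "\n")
}

format_sq_block <- function(aa) {
  starts <- seq(1L, nchar(aa), by = 60L)
  vapply(starts, function(st) {
    chunk <- substr(aa, st, min(st + 59L, nchar(aa)))
    groups <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(1L, nchar(chunk), by = 10L) + 9L, nchar(chunk)))
    paste0("     ", paste(groups, collapse = " "))
  }, "")
}

write_obo <- function(go_pool, n_obsolete, path) {
  ns <- GO_NAMESPACES
  lines <- c("format-version: 1.2", "ontology: synthetic-go", "")
  for (i in seq_along(go_pool)) {
    obsolete <- i > length(go_pool) - n_obsolete
    lines <- c(lines, "[Term]",
               sprintf("id: %s", go_pool[[i]]),
               sprintf("name: synthetic term %d", i),
               sprintf("namespace: %s", ns[[1L + (i - 1L) %% 3L]]))
    if (i == 1L) lines <- c(lines, "alt_id: GO:1000001")
    if (obsolete) lines <- c(lines, "is_obsolete: true")
    lines <- c(lines, "")
  }
  writeLines(lines, path)
}

write_pfam_table <- function(pfam_pool, path) {
  writeLines(c("# synthetic family descriptions",
               paste("PFAM_AC", "ID", "DESCRIPTION", sep = "\t"),
               sprintf("%s\tFam_%d\tSynthetic domain family %d",
                       pfam_pool, seq_along(pfam_pool),
                       seq_along(pfam_pool))),
             path)
}

#' @export
print.corpus_manifest <- function(x, ...) {
  cat(sprintf(
    "<corpus_manifest> %d taxa, %d genomes, %d CDSs, %d proteins, %d isoforms\n",
    nrow(x$taxa), nrow(x$genomes), nrow(x$cds), nrow(x$proteins),
    nrow(x$isoforms)))
  invisible(x)
}
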