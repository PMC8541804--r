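# End-to-end pipeline: resolve organism -> plan/fetch sources -> parse ->
# load -> stats.  The sequential order mirrors the acquisition flow of the
# warehouse: the taxonomy subtree is resolved first and gates everything
# downstream.

#' Build an organism-centred warehouse from the seven sources
#'
#' Resolves `organism` against the taxonomy dump named in `config`, plans
#' and (if needed) fetches the source files, parses each of them, loads
#' the warehouse filtered by the resolved taxon set and returns the
#' per-entity statistics.
#'
#' @param organism genus or species name to query.
#' @param config named list (or path read by [read_config()]) mapping each
#'   source key (see [SOURCE_KEYS]) to a local path (offline mode) or URL.
#' @param db_path SQLite file to create (or `":memory:"`).
#' @param overwrite replace an existing populated database.
#' @param offline require every source to resolve locally; no transport is
#'   invoked beyond copying (and none at all when sources are in place).
#' @param transport transfer function for remote sources (ignored when the
#'   plan is already satisfied); defaults to a local-copy transport.
#' @param dest_dir where fetched files would land.
#' @return list with elements `stats` (a `warehouse_stats`), `taxa`,
#'   `load_report`, `parse_errors` and `db_path`.
#' @export
build_warehouse <- function(organism, config, db_path, overwrite = FALSE,
                            offline = TRUE, transport = local_transport(),
                            dest_dir = tempdir()) {
  if (is.character(config) && length(config) == 1L) config <- read_config(config)
  missing <- setdiff(SOURCE_KEYS, names(config))
  if (length(missing))
    tm_config_error(sprintf("configuration missing source(s): %s",
                            paste(missing, collapse = ", ")))

  nodes <- parse_taxdump(config$taxonomy_names, config$taxonomy_nodes)
  taxa <- resolve_name(nodes, organism)

  plan <- plan_downloads(taxa, config, dest_dir = dest_dir)
  if (!plan_satisfied(plan)) {
    if (offline)
      tm_acquisition_error(paste(
        "offline mode but source file(s) missing:",
        paste(setdiff(plan$items$name, plan$completed), collapse = ", ")))
    plan <- fetch_with_retry(plan, transport)
  }

  src <- function(key) config[[key]]
  gb <- parse_genbank(src("nucleotide"))
  sp <- parse_swissprot(src("swissprot"))
  vs <- parse_varsplic(src("varsplic"))
  ob <- parse_obo(src("go_obo"))
  pf <- parse_pfam_table(src("pfam"))
  su <- parse_sifts_chain_tsv(src("sifts_uniprot"), mode = "uniprot")
  sf <- parse_sifts_chain_tsv(src("sifts_pfam"), mode = "pfam")

  con <- warehouse_connect(db_path)
  on.exit(DBI::dbDisconnect(con))
  create_schema(con, overwrite = overwrite)
  report <- load_corpus(con, taxa, list(
    genbank = gb, swissprot = sp, varsplic = vs, obo = ob, pfam = pf,
    sifts_uniprot = su, sifts_pfam = sf
  ), nodes = nodes)
  stats <- compute_stats(con)

  list(stats = stats, taxa = taxa, load_report = report,
       parse_errors = list(genbank = gb$errors, swissprot = sp$errors,
                           varsplic_skipped = vs$skipped, obo = ob$errors,
                           sifts_uniprot = su$errors, sifts_pfam = sf$errors,
                           pfam = pf$errors),
       db_path = db_path)
}

#' Configuration for a generated corpus directory
#'
#' Maps every source key to the file the generator wrote in `dir`.
#'
#' @param dir a directory produced by [generate_corpus()].
#' @return named list usable as the `config` of [build_warehouse()].
#' @export
corpus_config <- function(dir) {
  files <- list(
    taxonomy_names = "names.dmp", taxonomy_nodes = "nodes.dmp",
    nucleotide = "nucleotide.gb", swissprot = "swissprot.dat",
    varsplic = "varsplic.fasta", go_obo = "ontology.obo",
    pfam = "pfam_families.tsv", sifts_uniprot = "sifts_uniprot.tsv",
    sifts_pfam = "sifts_pfam.tsv")
  lapply(files, function(f) file.path(dir, f))
}
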