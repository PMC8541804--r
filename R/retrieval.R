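# Acquisition orchestration.  The transport is an injected function so the
# retry contract is testable with scripted fakes, and an offline mode
# sources every item from a local fixture directory with zero transfers.

#' Configuration keys for the seven data sources
#'
#' Every pipeline configuration must map each of these keys to a URL or
#' local path: the two taxonomy dump files, the nucleotide (GenBank flat
#' file) source, the Swiss-Prot DAT, the isoform FASTA, the ontology OBO,
#' the Pfam family table and the two SIFTS-style mapping files.
#'
#' @format character vector of nine key names.
#' @export
SOURCE_KEYS <- c("taxonomy_names", "taxonomy_nodes", "nucleotide",
                 "swissprot", "varsplic", "go_obo", "pfam",
                 "sifts_uniprot", "sifts_pfam")

#' Plan the acquisition of the seven data sources
#'
#' Builds a `download_plan` listing every file the pipeline needs: the two
#' taxonomy dump files, nucleotide record batches (one item per
#' `batch_size` member taxids), the Swiss-Prot DAT, the isoform FASTA, the
#' ontology OBO, the Pfam family table and the two SIFTS-style mapping
#' files.  Config entries pointing at existing local files are marked
#' completed immediately, so a fully local (offline) config yields a
#' satisfied plan with zero transfers.
#'
#' @param taxa a `taxon_set`.
#' @param config named list mapping each source key (see
#'   [SOURCE_KEYS]) to a URL or local path.
#' @param dest_dir directory where fetched files land.
#' @param batch_size member taxids per nucleotide batch.
#' @param max_attempts per-item retry bound for [fetch_with_retry()].
#' @return object of class `download_plan`.
#' @export
plan_downloads <- function(taxa, config, dest_dir = tempdir(),
                           batch_size = 50L, max_attempts = 5L) {
  stopifnot(inherits(taxa, "taxon_set"))
  missing <- setdiff(SOURCE_KEYS, names(config))
  if (length(missing))
    tm_config_error(sprintf("configuration missing source(s): %s",
                            paste(missing, collapse = ", ")))
  items <- list()
  add <- function(source, name) {
    items[[length(items) + 1L]] <<-
      data.frame(source = source, name = name, required = TRUE,
                 stringsAsFactors = FALSE)
  }
  for (k in setdiff(SOURCE_KEYS, "nucleotide")) add(config[[k]], paste0(k, ".dat"))
  n_batches <- ceiling(length(taxa$member_taxids) / batch_size)
  for (b in seq_len(max(n_batches, 1L)))
    add(config[["nucleotide"]], sprintf("nucleotide_batch_%03d.gb", b))
  items <- do.call(rbind, items)

  completed <- character(0)
  local <- file.exists(items$source)
  completed <- items$name[local]
  structure(
    list(items = items, max_attempts = as.integer(max_attempts),
         completed = completed, dest_dir = dest_dir,
         attempts = 0L),
    class = "download_plan"
  )
}

#' @export
print.download_plan <- function(x, ...) {
  cat(sprintf("<download_plan> %d item(s), %d completed, max %d attempt(s)\n",
              nrow(x$items), length(x$completed), x$max_attempts))
  invisible(x)
}

#' Is a download plan satisfied?
#'
#' @param plan a `download_plan`.
#' @return `TRUE` iff every required item is completed.
#' @export
plan_satisfied <- function(plan) {
  all(plan$items$name[plan$items$required] %in% plan$completed)
}

#' Fetch plan items, retrying until complete or attempts exhausted
#'
#' Iterates over incomplete items in rounds, calling
#' `transport(source, dest_path)` for each; a transport returning `TRUE`
#' (and leaving a non-empty file) marks the item completed.  Failed partial
#' files are discarded, never resumed, and completed items are never
#' re-fetched or overwritten.  After `max_attempts` failures per item an
#' acquisition error lists the missing names.
#'
#' @param plan a `download_plan`.
#' @param transport `function(source, dest) -> logical`; tests inject
#'   scripted fakes, production use wraps `utils::download.file`.
#' @return the updated plan, with `attempts` holding the total transport
#'   call count and `attempt_log` the per-call record.
#' @export
fetch_with_retry <- function(plan, transport) {
  stopifnot(inherits(plan, "download_plan"))
  attempts_by_item <- stats::setNames(rep(0L, nrow(plan$items)),
                                      plan$items$name)
  log <- list()
  while (!plan_satisfied(plan)) {
    todo <- which(!(plan$items$name %in% plan$completed) &
                  attempts_by_item[plan$items$name] < plan$max_attempts)
    if (!length(todo)) break
    for (i in todo) {
      name <- plan$items$name[[i]]
      dest <- file.path(plan$dest_dir, name)
      attempts_by_item[[name]] <- attempts_by_item[[name]] + 1L
      plan$attempts <- plan$attempts + 1L
      ok <- isTRUE(tryCatch(transport(plan$items$source[[i]], dest),
                            error = function(e) FALSE))
      ok <- ok && file.exists(dest) && file.info(dest)$size > 0
      log[[length(log) + 1L]] <- list(name = name, ok = ok)
      if (ok) plan$completed <- c(plan$completed, name)
      else if (file.exists(dest)) unlink(dest)   # discard partials
    }
  }
  plan$attempt_log <- log
  if (!plan_satisfied(plan)) {
    missing <- setdiff(plan$items$name[plan$items$required], plan$completed)
    tm_acquisition_error(
      sprintf("unable to acquire after %d attempt(s) per item: %s",
              plan$max_attempts, paste(missing, collapse = ", ")),
      missing = missing)
  }
  plan
}

#' Transport that copies local files (offline mode)
#'
#' @return a transport function for [fetch_with_retry()] that copies the
#'   source path into place; it never touches the network.
#' @export
local_transport <- function() {
  function(source, dest) {
    if (!file.exists(source)) return(FALSE)
    file.copy(source, dest, overwrite = FALSE)
  }
}

#' Read a key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment.  Values are
#' taken verbatim (paths or URLs).
#'
#' @param path config file path.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) tm_config_error(sprintf("config not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- stats::setNames(
    lapply(kv, function(x) paste(x[-1L], collapse = "=")),
    vapply(kv, `[[`, "", 1L)
  )
  out
}
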