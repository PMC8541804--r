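# UniProtKB/Swiss-Prot DAT reader (two-letter line codes, "//" entry
# terminator) and the companion alternative-splicing isoform FASTA.
# Cross-references are restricted to the four target databases the
# warehouse stores: RefSeq, GO, Pfam and PDB.

CROSSREF_DBS <- c("RefSeq", "GO", "Pfam", "PDB")

#' Parse UniProtKB/Swiss-Prot DAT entries
#'
#' Per entry: all AC accessions (the first is primary), the ID entry name,
#' the OX taxid, the DE description (first RecName full name), the SQ
#' sequence with whitespace stripped, DR cross-references to RefSeq, GO,
#' Pfam and PDB (other target databases are ignored), and isoform
#' accessions declared in CC "ALTERNATIVE PRODUCTS" blocks (`IsoId=`).
#'
#' Entries lacking AC or SQ are counted as record-level errors and skipped.
#'
#' @param src path or connection to a DAT stream.
#' @param chunk_size lines read per I/O call.
#' @return list with `records` (list of `protein_record`) and `errors`
#'   (named integer tally: `missing_field`).
#' @export
parse_swissprot <- function(src, chunk_size = 2000L) {
  records <- list()
  errors <- c(missing_field = 0L)
  stream_entries(src, function(lines) {
    rec <- tryCatch(parse_swissprot_entry(lines),
                    tm_parse_error = function(e) e)
    if (inherits(rec, "tm_parse_error")) errors[["missing_field"]] <<- errors[["missing_field"]] + 1L
    else records[[length(records) + 1L]] <<- rec
  }, chunk_size = chunk_size)
  list(records = records, errors = errors)
}

parse_swissprot_entry <- function(lines) {
  code <- substr(lines, 1L, 2L)
  body <- trimws(substr(lines, 6L, nchar(lines)))

  entry_name <- if (any(code == "ID"))
    strsplit(body[code == "ID"][[1L]], "[[:space:]]+")[[1L]][[1L]] else ""

  acs <- unlist(strsplit(paste(body[code == "AC"], collapse = " "), ";\\s*"))
  acs <- acs[nzchar(acs)]
  sq_i <- which(code == "SQ")
  if (!length(acs) || !length(sq_i))
    tm_parse_error(sprintf("entry %s missing AC or SQ",
                           if (nzchar(entry_name)) entry_name else "<unnamed>"))

  taxid <- NA_integer_
  ox <- body[code == "OX"]
  if (length(ox)) {
    m <- regmatches(ox[[1L]], regexec("NCBI_TaxID=([0-9]+)", ox[[1L]]))[[1L]]
    if (length(m) == 2L) taxid <- as.integer(m[[2L]])
  }

  de <- body[code == "DE"]
  description <- ""
  full <- grep("Full=", de, value = TRUE)
  if (length(full))
    description <- sub(";.*$", "", sub(".*Full=", "", full[[1L]]))

  crossrefs <- list()
  for (dr in body[code == "DR"]) {
    parts <- strsplit(sub("\\.$", "", dr), ";\\s*")[[1L]]
    if (length(parts) < 2L) next
    db <- parts[[1L]]
    if (!db %in% CROSSREF_DBS) next
    crossrefs[[length(crossrefs) + 1L]] <- list(
      target_db = db, target_id = parts[[2L]],
      qualifiers = if (length(parts) > 2L) parts[-(1:2)] else character(0)
    )
  }

  cc <- body[code == "CC"]
  iso <- regmatches(cc, regexpr("IsoId=[A-Z0-9-]+(,[ ]?[A-Z0-9-]+)*", cc))
  isoform_ids <- unique(unlist(lapply(iso, function(x)
    trimws(strsplit(sub("^IsoId=", "", x), ",")[[1L]]))))

  seq_lines <- lines[(sq_i[[1L]] + 1L):length(lines)]
  sequence <- gsub("[[:space:]0-9]", "", paste(seq_lines, collapse = ""))
  if (!nzchar(sequence))
    tm_parse_error(sprintf("entry %s has empty sequence", entry_name))

  structure(
    list(primary_ac = acs[[1L]],
         secondary_acs = if (length(acs) > 1L) acs[-1L] else character(0),
         entry_name = entry_name, taxid = taxid, description = description,
         sequence = sequence, crossrefs = crossrefs,
         isoform_ids = if (length(isoform_ids)) isoform_ids else character(0)),
    class = "protein_record"
  )
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%s) taxid %s, %d aa, %d crossref(s)\n",
              x$primary_ac, x$entry_name, x$taxid, nchar(x$sequence),
              length(x$crossrefs)))
  invisible(x)
}

#' Parse an alternative-splicing isoform FASTA
#'
#' Headers must contain an isoform accession of the form `AC-n`
#' (e.g. `sp|P00001-2|...`); the parent accession is the prefix before the
#' final dash-ordinal.  Records without such an accession are skipped and
#' counted.
#'
#' @param src path to a FASTA file.
#' @return list with `isoforms` (data.frame `isoform_ac`, `parent_ac`,
#'   `sequence`) and `skipped` (count of headers without an isoform
#'   accession).
#' @export
parse_varsplic <- function(src) {
  if (!file.exists(src)) tm_config_error(sprintf("file not found: %s", src))
  info <- file.info(src)
  if (info$size == 0)
    return(list(isoforms = empty_isoforms(), skipped = 0L))
  seqs <- Biostrings::readAAStringSet(src)
  if (!length(seqs))
    return(list(isoforms = empty_isoforms(), skipped = 0L))
  headers <- names(seqs)
  m <- regmatches(headers, regexec("([A-Z][A-Z0-9]{5,9})-([0-9]+)", headers))
  ok <- lengths(m) == 3L
  iso <- vapply(m[ok], function(g) paste0(g[[2L]], "-", g[[3L]]), "")
  parent <- vapply(m[ok], `[[`, "", 2L)
  list(
    isoforms = data.frame(isoform_ac = iso, parent_ac = parent,
                          sequence = as.character(seqs[ok]),
                          stringsAsFactors = FALSE, row.names = NULL),
    skipped = sum(!ok)
  )
}

empty_isoforms <- function() {
  data.frame(isoform_ac = character(0), parent_ac = character(0),
             sequence = character(0), stringsAsFactors = FALSE)
}
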