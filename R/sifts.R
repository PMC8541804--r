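# SIFTS-style chain-level TSV mappings (PDB chain <-> Swiss-Prot sequence,
# and PDB chain <-> Pfam domain with Swiss-Prot coordinates), plus the
# Pfam family description table.  Swiss-Prot coordinates are validated as
# integers; PDB residue labels stay opaque strings because author-assigned
# numbering may carry insertion codes or negatives.

#' Parse a SIFTS-style chain mapping TSV
#'
#' Lines starting with `#` and a header row (detected by non-integer
#' Swiss-Prot coordinates) contribute no mappings.  `uniprot` mode expects
#' columns `pdb, chain, uniprot_ac, sp_start, sp_stop, pdb_start,
#' pdb_stop`; `pfam` mode expects `pdb, chain, uniprot_ac, pfam_ac,
#' sp_start, sp_stop`.  Rows with the wrong column count or non-integer
#' Swiss-Prot coordinates are counted as row-level errors with their row
#' numbers.  PDB identifiers are lower-cased on ingest.
#'
#' @param src path or connection to the TSV.
#' @param mode `"uniprot"` or `"pfam"`.
#' @return list with `mappings` (data.frame; see modes above), `errors`
#'   (integer count of bad rows) and `error_rows` (their line numbers).
#' @export
parse_sifts_chain_tsv <- function(src, mode = c("uniprot", "pfam")) {
  mode <- match.arg(mode)
  ncol_expected <- if (mode == "uniprot") 7L else 6L
  sp_cols <- if (mode == "uniprot") 4:5 else 5:6
  lines <- read_source_lines(src)

  rows <- list(); bad <- integer(0)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    sp <- suppressWarnings(as.integer(f[sp_cols[sp_cols <= length(f)]]))
    if (length(f) == ncol_expected && all(!is.na(sp))) {
      rows[[length(rows) + 1L]] <- f
    } else if (looks_like_header(f)) {
      next
    } else {
      bad <- c(bad, i)
    }
  }

  mk <- function(j) vapply(rows, `[[`, "", j)
  mappings <- if (mode == "uniprot") {
    if (length(rows)) data.frame(
      pdb_id = tolower(mk(1L)), chain_id = mk(2L), uniprot_ac = mk(3L),
      sp_start = as.integer(mk(4L)), sp_stop = as.integer(mk(5L)),
      pdb_start = mk(6L), pdb_stop = mk(7L), stringsAsFactors = FALSE
    ) else data.frame(pdb_id = character(0), chain_id = character(0),
                      uniprot_ac = character(0), sp_start = integer(0),
                      sp_stop = integer(0), pdb_start = character(0),
                      pdb_stop = character(0))
  } else {
    if (length(rows)) data.frame(
      pdb_id = tolower(mk(1L)), chain_id = mk(2L), uniprot_ac = mk(3L),
      pfam_ac = mk(4L), sp_start = as.integer(mk(5L)),
      sp_stop = as.integer(mk(6L)), stringsAsFactors = FALSE
    ) else data.frame(pdb_id = character(0), chain_id = character(0),
                      uniprot_ac = character(0), pfam_ac = character(0),
                      sp_start = integer(0), sp_stop = integer(0))
  }
  if (nrow(mappings) && any(mappings$sp_start > mappings$sp_stop))
    tm_parse_error("sp_start > sp_stop in mapping row")
  list(mappings = mappings, errors = length(bad), error_rows = bad)
}

# A header row repeats column names: all-alpha fields in the coordinate
# positions and a first field that is not a 4-character PDB id.
looks_like_header <- function(fields) {
  any(grepl("^(PDB|SP_|RES_|CHAIN|PFAM)", toupper(fields)))
}

#' Parse a Pfam family description table
#'
#' Tab-separated columns: Pfam accession (`PF` + 5 digits), short family
#' id, free-text description.  Comment lines start with `#`.  Rows whose
#' accession does not match the Pfam pattern are counted as errors.
#'
#' @param src path or connection.
#' @return list with `families` (data.frame `pfam_ac`, `family_id`,
#'   `description`) and `errors` (bad-row count).
#' @export
parse_pfam_table <- function(src) {
  lines <- read_source_lines(src)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  errors <- 0L
  rows <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L || !grepl("^PF[0-9]{5}$", f[[1L]])) {
      if (looks_like_header(f)) next
      errors <- errors + 1L
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(pfam_ac = f[[1L]], family_id = f[[2L]],
                 description = paste(f[-(1:2)], collapse = " "),
                 stringsAsFactors = FALSE)
  }
  families <- if (length(rows)) do.call(rbind, rows) else
    data.frame(pfam_ac = character(0), family_id = character(0),
               description = character(0))
  list(families = families, errors = errors)
}
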