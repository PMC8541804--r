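# Streaming GenBank flat-file reader.  Entries are processed one at a time
# from a bounded line buffer, so peak memory scales with the largest entry,
# not the file.  Only records with a RefSeq-style accession (two letters +
# underscore) are admitted; others are counted and skipped, implementing a
# curated-subset policy.

# Feed complete "//"-terminated entries to `handler` while reading the
# source in chunks of `chunk_size` lines.
stream_entries <- function(src, handler, chunk_size = 2000L) {
  con <- if (inherits(src, "connection")) src else {
    if (!file.exists(src)) tm_config_error(sprintf("file not found: %s", src))
    file(src, open = "rt")
  }
  if (!inherits(src, "connection")) on.exit(close(con))
  buf <- character(0)
  repeat {
    chunk <- readLines(con, n = chunk_size, warn = FALSE)
    buf <- c(buf, chunk)
    term <- which(buf == "//")
    start <- 1L
    for (t in term) {
      if (t > start) handler(buf[start:(t - 1L)])
      start <- t + 1L
    }
    buf <- if (start <= length(buf)) buf[start:length(buf)] else character(0)
    if (!length(chunk)) break
  }
  if (length(buf) && any(nzchar(trimws(buf)))) handler(buf)  # unterminated tail
  invisible(NULL)
}

#' Parse RefSeq records in GenBank flat-file format
#'
#' Extracts, per entry: the LOCUS sequence length, the VERSION accession,
#' the DEFINITION line, the source organism taxid (`/db_xref="taxon:N"`)
#' and molecule label (`/chromosome`, `/plasmid` or `/segment` qualifier),
#' and every CDS feature with its location and the qualifiers `gene`,
#' `locus_tag`, `protein_id`, `product` and `translation`.
#'
#' Entries missing LOCUS or VERSION, carrying a non-RefSeq accession, or
#' containing an unparseable CDS location are counted in the error tally
#' and parsing continues with the next entry.
#'
#' @param src path or connection to a flat file of `//`-terminated entries.
#' @param chunk_size lines read per I/O call (memory/IO trade-off).
#' @return list with `records` (list of `nucleotide_record`) and `errors`
#'   (named integer tally: `missing_header`, `non_refseq`, `bad_location`).
#' @export
parse_genbank <- function(src, chunk_size = 2000L) {
  records <- list()
  errors <- c(missing_header = 0L, non_refseq = 0L, bad_location = 0L)
  stream_entries(src, function(lines) {
    rec <- tryCatch(parse_genbank_entry(lines),
                    tm_parse_error = function(e) e)
    if (inherits(rec, "tm_parse_error")) {
      kind <- if (!is.null(rec$kind)) rec$kind else "missing_header"
      errors[[kind]] <<- errors[[kind]] + 1L
    } else records[[length(records) + 1L]] <<- rec
  }, chunk_size = chunk_size)
  list(records = records, errors = errors)
}

parse_genbank_entry <- function(lines) {
  locus <- grep("^LOCUS ", lines, value = TRUE)
  version <- grep("^VERSION ", lines, value = TRUE)
  if (!length(locus) || !length(version))
    tm_parse_error("entry missing LOCUS or VERSION", kind = "missing_header")
  lf <- strsplit(trimws(locus[[1L]]), "[[:space:]]+")[[1L]]
  bp <- suppressWarnings(as.integer(lf[[3L]]))
  if (is.na(bp)) tm_parse_error("LOCUS without length", kind = "missing_header")
  accession <- strsplit(trimws(version[[1L]]), "[[:space:]]+")[[1L]][[2L]]
  if (!grepl("^[A-Z]{2}_", accession))
    tm_parse_error(sprintf("non-RefSeq accession %s", accession),
                   kind = "non_refseq")

  def_i <- grep("^DEFINITION", lines)
  definition <- ""
  if (length(def_i)) {
    j <- def_i[[1L]]
    def <- sub("^DEFINITION[[:space:]]+", "", lines[[j]])
    while (j + 1L <= length(lines) && grepl("^ {10}", lines[[j + 1L]])) {
      j <- j + 1L
      def <- paste(def, trimws(lines[[j]]))
    }
    definition <- def
  }

  feats <- parse_feature_table(lines)
  taxid <- NA_integer_
  molecule <- ""
  src_feat <- Filter(function(f) f$key == "source", feats)
  if (length(src_feat)) {
    q <- src_feat[[1L]]$qualifiers
    tx <- grep("^taxon:", q[names(q) == "db_xref"], value = TRUE)
    if (length(tx)) taxid <- as.integer(sub("^taxon:", "", tx[[1L]]))
    for (k in c("chromosome", "plasmid", "segment"))
      if (k %in% names(q)) { molecule <- paste(k, q[[k]]); break }
  }

  cds <- lapply(Filter(function(f) f$key == "CDS", feats), function(f) {
    loc <- tryCatch(parse_location(f$location),
                    tm_parse_error = function(e)
                      tm_parse_error(conditionMessage(e), kind = "bad_location"))
    q <- f$qualifiers
    pick <- function(k) if (k %in% names(q)) unname(q[[k]][1L]) else NA_character_
    structure(
      list(location = loc, gene_name = pick("gene"),
           locus_tag = pick("locus_tag"),
           refseq_protein_ac = pick("protein_id"),
           product = pick("product"),
           translation = pick("translation")),
      class = "coding_sequence"
    )
  })

  structure(
    list(accession = accession, taxid = taxid, definition = definition,
         sequence_length = bp, molecule_label = molecule,
         cds_features = cds),
    class = "nucleotide_record"
  )
}

# Minimal feature-table reader: feature keys start at column 6, qualifiers
# and location continuations at column 22.
parse_feature_table <- function(lines) {
  fstart <- grep("^FEATURES", lines)
  if (!length(fstart)) return(list())
  fend <- grep("^(ORIGIN|CONTIG)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart[[1L]]]) - 1L else length(lines)
  block <- lines[(fstart[[1L]] + 1L):fend]
  block <- block[nzchar(trimws(block))]

  feats <- list()
  cur <- NULL
  in_location <- FALSE
  qual_name <- NULL
  flush <- function() if (!is.null(cur)) feats[[length(feats) + 1L]] <<- cur
  for (ln in block) {
    if (grepl("^ {5}[A-Za-z]", ln)) {            # new feature
      flush()
      key <- trimws(substr(ln, 1L, 20L))
      cur <- list(key = key, location = trimws(substr(ln, 21L, nchar(ln))),
                  qualifiers = character(0))
      in_location <- TRUE
      qual_name <- NULL
    } else if (!is.null(cur)) {
      body <- trimws(ln)
      if (grepl("^/", body)) {                   # qualifier
        in_location <- FALSE
        eq <- regexpr("=", body, fixed = TRUE)
        if (eq > 0L) {
          qual_name <- substr(body, 2L, eq - 1L)
          val <- substr(body, eq + 1L, nchar(body))
        } else { qual_name <- substr(body, 2L, nchar(body)); val <- "" }
        val <- gsub("^\"|\"$", "", val)
        q <- cur$qualifiers
        cur$qualifiers <- c(q, stats::setNames(val, qual_name))
      } else if (in_location) {
        cur$location <- paste0(cur$location, body)
      } else if (!is.null(qual_name)) {          # qualifier continuation
        body <- gsub("\"$", "", body)
        i <- length(cur$qualifiers)
        sep <- if (qual_name == "translation") "" else " "
        cur$qualifiers[[i]] <- paste0(cur$qualifiers[[i]], sep, body)
      }
    }
  }
  flush()
  feats
}

#' @export
print.nucleotide_record <- function(x, ...) {
  cat(sprintf("<nucleotide_record> %s taxid %s, %d bp, %d CDS feature(s)\n",
              x$accession, x$taxid, x$sequence_length, length(x$cds_features)))
  invisible(x)
}
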