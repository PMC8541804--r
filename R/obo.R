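# Gene Ontology OBO 1.2 reader: term records only.  Graph relations
# (is_a / part_of) are out of scope; alt_id values become aliases that
# resolve to the canonical term.

GO_NAMESPACES <- c("biological_process", "molecular_function",
                   "cellular_component")

#' Parse GO terms from an OBO 1.2 stream
#'
#' One term per `[Term]` stanza carrying an `id:` tag.  `is_obsolete: true`
#' flags the term obsolete; `alt_id:` values are collected into an alias
#' table mapping each alternative identifier to its canonical term.
#' Stanzas with a malformed id (not `GO:` + 7 digits) are counted and
#' skipped.
#'
#' @param src path or connection to an OBO file.
#' @return list with `terms` (data.frame `go_id`, `name`, `namespace`,
#'   `obsolete`), `aliases` (data.frame `alt_id`, `go_id`) and `errors`
#'   (named tally: `bad_id`).
#' @export
parse_obo <- function(src) {
  lines <- read_source_lines(src)
  starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  errors <- c(bad_id = 0L)
  terms <- list(); aliases <- list()

  for (s in term_starts) {
    nxt <- starts[starts > s]
    block <- lines[(s + 1L):(if (length(nxt)) min(nxt) - 1L else length(lines))]
    tag <- sub(":.*$", "", block)
    val <- trimws(sub("^[a-z_]+:", "", block))
    id <- val[tag == "id"]
    if (!length(id) || !grepl("^GO:[0-9]{7}$", id[[1L]])) {
      errors[["bad_id"]] <- errors[["bad_id"]] + 1L
      next
    }
    id <- id[[1L]]
    nm <- if (any(tag == "name")) val[tag == "name"][[1L]] else ""
    ns <- if (any(tag == "namespace")) val[tag == "namespace"][[1L]] else ""
    obs <- any(tag == "is_obsolete" & val == "true")
    terms[[length(terms) + 1L]] <-
      data.frame(go_id = id, name = nm, namespace = ns, obsolete = obs,
                 stringsAsFactors = FALSE)
    alt <- val[tag == "alt_id"]
    if (length(alt))
      aliases[[length(aliases) + 1L]] <-
        data.frame(alt_id = alt, go_id = id, stringsAsFactors = FALSE)
  }

  terms <- if (length(terms)) do.call(rbind, terms) else
    data.frame(go_id = character(0), name = character(0),
               namespace = character(0), obsolete = logical(0))
  aliases <- if (length(aliases)) do.call(rbind, aliases) else
    data.frame(alt_id = character(0), go_id = character(0))
  if (anyDuplicated(terms$go_id))
    tm_integrity_error(sprintf("duplicate GO id %s",
                               terms$go_id[duplicated(terms$go_id)][[1L]]))
  # an alias must point at exactly one canonical term
  aliases <- aliases[aliases$go_id %in% terms$go_id, , drop = FALSE]
  aliases <- aliases[!duplicated(aliases$alt_id), , drop = FALSE]
  list(terms = terms, aliases = aliases, errors = errors)
}
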