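# NCBI taxdump parsing and subtree resolution.  The resolved taxon set
# gates every downstream loader: nothing enters the warehouse unless its
# taxid lies in the subtree of the queried organism.

#' Parse NCBI taxdump files
#'
#' Reads `names.dmp` and `nodes.dmp` in the taxdump dialect (fields
#' separated by `"\t|\t"`, records terminated by `"\t|"`) and joins them
#' into one node table.  Only the name record of class `"scientific name"`
#' becomes the node's name; other name classes are kept as a synonym table
#' used for lookup by [resolve_name()].
#'
#' @param names_source path to (or connection for) `names.dmp`.
#' @param nodes_source path to (or connection for) `nodes.dmp`.
#' @return An object of class `taxon_nodes`: a `data.frame` with columns
#'   `taxid`, `parent_taxid`, `rank`, `scientific_name`, and a `synonyms`
#'   attribute (`data.frame` of `taxid`, `name`, `name_class`).
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' writeLines("1\t|\t1\t|\tno rank\t|", file.path(dir, "nodes.dmp"))
#' writeLines("1\t|\troot\t|\t\t|\tscientific name\t|",
#'            file.path(dir, "names.dmp"))
#' nodes <- parse_taxdump(file.path(dir, "names.dmp"),
#'                        file.path(dir, "nodes.dmp"))
#' @export
parse_taxdump <- function(names_source, nodes_source) {
  names_lines <- read_source_lines(names_source)
  nodes_lines <- read_source_lines(nodes_source)

  nodes_f <- split_dmp(nodes_lines, min_fields = 3L, file = "nodes.dmp")
  names_f <- split_dmp(names_lines, min_fields = 4L, file = "names.dmp")

  taxid  <- as.integer(vapply(nodes_f, `[[`, "", 1L))
  parent <- as.integer(vapply(nodes_f, `[[`, "", 2L))
  rank   <- vapply(nodes_f, `[[`, "", 3L)
  if (anyNA(taxid) || anyNA(parent))
    tm_parse_error("nodes.dmp: non-integer taxid or parent taxid")
  dup <- taxid[duplicated(taxid)]
  if (length(dup))
    tm_integrity_error(sprintf("nodes.dmp: duplicate taxid %s", dup[[1L]]))

  ntax   <- as.integer(vapply(names_f, `[[`, "", 1L))
  nname  <- vapply(names_f, `[[`, "", 2L)
  nclass <- vapply(names_f, `[[`, "", 4L)

  sci <- nclass == "scientific name"
  sci_map <- nname[sci][match(taxid, ntax[sci])]
  keep <- !is.na(sci_map) & nzchar(sci_map)
  if (!all(keep))
    warning(sprintf("%d node(s) without a scientific-name record dropped",
                    sum(!keep)), call. = FALSE)

  nodes <- data.frame(
    taxid = taxid[keep], parent_taxid = parent[keep],
    rank = rank[keep], scientific_name = sci_map[keep],
    stringsAsFactors = FALSE
  )
  syn <- data.frame(taxid = ntax[!sci], name = nname[!sci],
                    name_class = nclass[!sci], stringsAsFactors = FALSE)
  syn <- syn[syn$taxid %in% nodes$taxid, , drop = FALSE]
  attr(nodes, "synonyms") <- syn
  class(nodes) <- c("taxon_nodes", "data.frame")
  nodes
}

read_source_lines <- function(src) {
  if (inherits(src, "connection")) return(readLines(src, warn = FALSE))
  if (!file.exists(src))
    tm_config_error(sprintf("file not found: %s", src))
  readLines(src, warn = FALSE)
}

# Split taxdump lines into fields; errors name the offending line number.
split_dmp <- function(lines, min_fields, file) {
  lines <- lines[nzchar(lines)]
  lines <- sub("\t\\|$", "", lines)
  fields <- strsplit(lines, "\t|\t", fixed = TRUE)
  n <- lengths(fields)
  bad <- which(n < min_fields)
  if (length(bad))
    tm_parse_error(sprintf("%s: malformed line %d (%d field(s), expected >= %d)",
                           file, bad[[1L]], n[bad[[1L]]], min_fields),
                   line = bad[[1L]])
  fields
}

#' Resolve an organism name to its taxonomic subtree
#'
#' Matching is exact and case-insensitive on the scientific name; synonym
#' name classes from `names.dmp` are consulted as a fallback.  When the
#' match is an internal node (a genus, say) the member set contains the
#' matched node and every descendant at any depth.  A name matching several
#' taxids resolves to all of them.
#'
#' @param nodes a `taxon_nodes` table from [parse_taxdump()].
#' @param query organism name, genus or species; leading/trailing
#'   whitespace is ignored.
#' @return An object of class `taxon_set`: list with `query_name`,
#'   `root_taxids` and `member_taxids`.
#' @export
resolve_name <- function(nodes, query) {
  stopifnot(inherits(nodes, "taxon_nodes"))
  query <- trimws(query)
  if (!nzchar(query)) tm_usage_error("empty organism query")
  q <- tolower(query)
  roots <- nodes$taxid[tolower(nodes$scientific_name) == q]
  if (!length(roots)) {
    syn <- attr(nodes, "synonyms")
    if (!is.null(syn) && nrow(syn))
      roots <- unique(syn$taxid[tolower(syn$name) == q])
  }
  if (!length(roots))
    tm_not_found_error(sprintf("organism not found: '%s'", query),
                       query = query)
  members <- unique(unlist(lapply(roots, function(r) descendant_taxa(nodes, r))))
  structure(
    list(query_name = query, root_taxids = roots,
         member_taxids = sort(members)),
    class = "taxon_set"
  )
}

#' @export
print.taxon_set <- function(x, ...) {
  cat(sprintf("<taxon_set> query '%s': %d root(s), %d member taxid(s)\n",
              x$query_name, length(x$root_taxids), length(x$member_taxids)))
  invisible(x)
}

#' All taxa in the subtree of a root
#'
#' Breadth-first traversal of the child relation; returns the root plus all
#' transitive descendants.  The conventional self-parent root node does not
#' loop.
#'
#' @param nodes a `taxon_nodes` table.
#' @param root a taxid present in `nodes`.
#' @return integer vector of taxids.
#' @export
descendant_taxa <- function(nodes, root) {
  stopifnot(inherits(nodes, "taxon_nodes"))
  root <- as.integer(root)
  if (!root %in% nodes$taxid)
    tm_not_found_error(sprintf("unknown root taxid %d", root))
  kids <- split(nodes$taxid, nodes$parent_taxid)
  out <- integer(0)
  frontier <- root
  while (length(frontier)) {
    out <- c(out, frontier)
    nxt <- unlist(kids[as.character(frontier)], use.names = FALSE)
    frontier <- setdiff(nxt, out)  # drops the self-parent root re-visit
  }
  sort(unique(out))
}
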