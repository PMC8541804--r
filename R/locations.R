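# GenBank feature-location grammar.  The supported subset is base spans,
# single bases, join(...), order(...), complement(...) and the partiality
# markers "<" and ">".  complement() flips strand; printed coordinates are
# kept as-is (1-based inclusive), so downstream consumers own any
# reverse-complement arithmetic.  Nested complement and external
# (accession:span) references are rejected.

#' Parse a GenBank feature location
#'
#' @param text a location expression, e.g. `"join(10..20,30..40)"` or
#'   `"complement(<5..>20)"`.
#' @return An object of class `genomic_location`: list with `segments`
#'   (data.frame of `start`, `stop`), `strand` (`"+"` or `"-"`), `partial5`,
#'   `partial3`, and `kind` (`"span"`, `"join"` or `"order"`).
#' @examples
#' loc <- parse_location("complement(join(2..10,20..28))")
#' location_length(loc)  # 18
#' @export
parse_location <- function(text) {
  text <- gsub("[[:space:]]", "", text)
  if (!nzchar(text)) tm_parse_error("empty location expression")
  if (grepl("[A-Za-z0-9_.]+:", text))
    tm_parse_error(sprintf("external-reference location not supported: '%s'", text))

  strand <- "+"
  body <- text
  if (grepl("^complement\\(", body)) {
    strand <- "-"
    body <- strip_call(body, "complement")
    if (grepl("complement\\(", body))
      tm_parse_error(sprintf("nested complement in '%s'", text))
  }

  kind <- "span"
  if (grepl("^join\\(", body)) {
    kind <- "join"; body <- strip_call(body, "join")
  } else if (grepl("^order\\(", body)) {
    kind <- "order"; body <- strip_call(body, "order")
  }
  if (grepl("[()]", body))
    tm_parse_error(sprintf("unbalanced or misplaced parentheses in '%s'", text))

  parts <- strsplit(body, ",", fixed = TRUE)[[1L]]
  if (!length(parts) || any(!nzchar(parts)))
    tm_parse_error(sprintf("empty segment in '%s'", text))
  if (kind == "span" && length(parts) > 1L)
    tm_parse_error(sprintf("multiple segments outside join/order in '%s'", text))

  partial5 <- FALSE; partial3 <- FALSE
  seg <- lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    if (grepl("^<", p)) { if (i == 1L) partial5 <<- TRUE; p <- sub("^<", "", p) }
    m <- regexec("^([0-9]+)(\\.\\.(>?)([0-9]+))?$", p)[[1L]]
    if (m[1L] == -1L)
      tm_parse_error(sprintf("cannot parse segment '%s' in '%s'", parts[[i]], text))
    g <- regmatches(p, regexec("^([0-9]+)(\\.\\.(>?)([0-9]+))?$", p))[[1L]]
    start <- as.numeric(g[2L])
    if (nzchar(g[3L])) {
      if (nzchar(g[4L]) && i == length(parts)) partial3 <<- TRUE
      stop_ <- as.numeric(g[5L])
    } else stop_ <- start
    if (stop_ < start)
      tm_parse_error(sprintf("stop < start in segment '%s'", parts[[i]]))
    c(start, stop_)
  })
  segs <- do.call(rbind, seg)
  structure(
    list(segments = data.frame(start = segs[, 1L], stop = segs[, 2L]),
         strand = strand, partial5 = partial5, partial3 = partial3,
         kind = kind),
    class = "genomic_location"
  )
}

# Remove "name(" prefix and the matching final ")"; the contents must be
# balanced.
strip_call <- function(text, name) {
  inner <- substr(text, nchar(name) + 2L, nchar(text))
  if (!grepl("\\)$", inner))
    tm_parse_error(sprintf("unbalanced parentheses in '%s'", text))
  substr(inner, 1L, nchar(inner) - 1L)
}

#' Total length of a genomic location
#'
#' Sum of `stop - start + 1` over all segments.
#'
#' @param loc a `genomic_location`.
#' @return integer length in bases.
#' @export
location_length <- function(loc) {
  stopifnot(inherits(loc, "genomic_location"))
  as.integer(sum(loc$segments$stop - loc$segments$start + 1))
}

#' Enumerate the positions covered by a location
#'
#' Expands every segment into its covered 1-based coordinates (ignoring
#' strand), mainly for cross-checks against brute-force interpretation.
#'
#' @param loc a `genomic_location`.
#' @return sorted integer vector of covered positions.
#' @export
location_positions <- function(loc) {
  stopifnot(inherits(loc, "genomic_location"))
  sort(unique(unlist(
    mapply(seq, loc$segments$start, loc$segments$stop, SIMPLIFY = FALSE)
  )))
}

#' @export
print.genomic_location <- function(x, ...) {
  cat(sprintf("<genomic_location> %s strand %s, %d segment(s), length %d\n",
              x$kind, x$strand, nrow(x$segments), location_length(x)))
  invisible(x)
}
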