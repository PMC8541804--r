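# Independent oracles and fixture builders.  These deliberately avoid the
# package's own parsing/traversal code paths: locations are interpreted by
# brute-force span expansion, subtrees by naive recursion over the parent
# table, and expected warehouse counts come from the generator manifest.

# Brute-force location interpreter: extract every "a..b" or bare-base span
# textually and expand it; strand from the presence of "complement".
oracle_location <- function(text) {
  clean <- gsub("[<>[:space:]]", "", text)
  strand <- if (grepl("complement", clean)) "-" else "+"
  body <- gsub("complement|join|order|\\(|\\)", "", clean)
  spans <- strsplit(body, ",")[[1]]
  pos <- unlist(lapply(spans, function(s) {
    n <- as.integer(strsplit(s, "..", fixed = TRUE)[[1]])
    if (length(n) == 1) n else seq(n[1], n[2])
  }))
  list(positions = sort(unique(pos)), strand = strand)
}

# Random well-formed location expression: <= max_segments spans,
# coordinates <= max_coord, optional complement/order, partial markers.
rand_location <- function(max_segments = 5L, max_coord = 10000L) {
  k <- sample(seq_len(max_segments), 1)
  pos <- 1L
  spans <- character(k)
  for (i in seq_len(k)) {
    start <- pos + sample(1:50, 1)
    w <- sample(0:80, 1)
    stop <- min(start + w, max_coord)
    spans[i] <- if (w == 0 && runif(1) < 0.3) as.character(start)
                else sprintf("%d..%d", start, stop)
    pos <- stop
  }
  body <- if (k > 1) {
    wrapper <- if (runif(1) < 0.15) "order" else "join"
    sprintf("%s(%s)", wrapper, paste(spans, collapse = ","))
  } else spans[1]
  if (runif(1) < 0.5) body <- sprintf("complement(%s)", body)
  body
}

# Naive recursive subtree oracle over the raw parent table.
oracle_descendants <- function(df, root) {
  kids <- df$taxid[df$parent_taxid == root & df$taxid != root]
  sort(unique(c(root, unlist(lapply(kids, oracle_descendants, df = df)))))
}

# Random taxonomy tree written as taxdump files; node 1 is a self-parent
# root.  Returns the data.frame of truth alongside the file paths.
rand_tree_files <- function(n, dir) {
  taxid <- 1000L + seq_len(n)
  parent <- c(taxid[1], if (n > 1) taxid[sapply(seq_len(n - 1), function(i)
    sample(seq_len(i), 1))])
  df <- data.frame(taxid = taxid, parent_taxid = parent,
                   rank = sample(c("species", "genus", "no rank"), n, TRUE),
                   name = sprintf("Node %d", taxid))
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|\t\t|", df$taxid, df$parent_taxid,
                     df$rank), file.path(dir, "nodes.dmp"))
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", df$taxid,
                     df$name), file.path(dir, "names.dmp"))
  df
}

# Generate a corpus in a fresh temp dir; returns dir, manifest and config.
gen_corpus <- function(seed = 1L, ..., defects = character(0)) {
  dir <- tempfile("corpus")
  params <- corpus_params(..., seed = seed)
  manifest <- generate_corpus(params, dir, defects = defects)
  list(dir = dir, manifest = manifest, config = corpus_config(dir),
       params = params)
}

# Parse all seven sources of a corpus config.
parse_all <- function(cfg) {
  list(
    genbank = parse_genbank(cfg$nucleotide),
    swissprot = parse_swissprot(cfg$swissprot),
    varsplic = parse_varsplic(cfg$varsplic),
    obo = parse_obo(cfg$go_obo),
    pfam = parse_pfam_table(cfg$pfam),
    sifts_uniprot = parse_sifts_chain_tsv(cfg$sifts_uniprot, "uniprot"),
    sifts_pfam = parse_sifts_chain_tsv(cfg$sifts_pfam, "pfam")
  )
}

# An empty taxon set (no members), for degenerate-load tests.
empty_taxon_set <- function() {
  structure(list(query_name = "none", root_taxids = integer(0),
                 member_taxids = integer(0)), class = "taxon_set")
}

stats_vector <- function(s) unlist(unclass(s))
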