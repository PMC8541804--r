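test_that("taxdump parsing maps fields, joins names and honours the self-parent root", {
  dir <- withr::local_tempdir()
  writeLines(c("1\t|\t1\t|\tno rank\t|\t\t|",
               "2\t|\t131567\t|\tsuperkingdom\t|\t\t|",
               "131567\t|\t1\t|\tno rank\t|\t\t|"),
             file.path(dir, "nodes.dmp"))
  writeLines(c("1\t|\troot\t|\t\t|\tscientific name\t|",
               "2\t|\tBacteria\t|\t\t|\tscientific name\t|",
               "2\t|\teubacteria\t|\t\t|\tgenbank common name\t|",
               "131567\t|\tcellular organisms\t|\t\t|\tscientific name\t|"),
             file.path(dir, "names.dmp"))
  nodes <- parse_taxdump(file.path(dir, "names.dmp"), file.path(dir, "nodes.dmp"))

  expect_equal(nrow(nodes), 3L)
  b <- nodes[nodes$taxid == 2L, ]
  expect_equal(b$parent_taxid, 131567L)
  expect_equal(b$rank, "superkingdom")
  expect_equal(b$scientific_name, "Bacteria")
  root <- nodes[nodes$taxid == 1L, ]
  expect_equal(root$parent_taxid, root$taxid)
  syn <- attr(nodes, "synonyms")
  expect_true("eubacteria" %in% syn$name)
})

test_that("malformed lines and duplicate taxids are rejected with diagnostics", {
  dir <- withr::local_tempdir()
  writeLines(c("1\t|\t1\t|\tno rank\t|", "garbage-line"),
             file.path(dir, "nodes.dmp"))
  writeLines("1\t|\troot\t|\t\t|\tscientific name\t|",
             file.path(dir, "names.dmp"))
  expect_error(
    parse_taxdump(file.path(dir, "names.dmp"), file.path(dir, "nodes.dmp")),
    "line 2", class = "tm_parse_error")

  writeLines(c("1\t|\t1\t|\tno rank\t|", "1\t|\t1\t|\tno rank\t|"),
             file.path(dir, "nodes.dmp"))
  expect_error(
    parse_taxdump(file.path(dir, "names.dmp"), file.path(dir, "nodes.dmp")),
    "duplicate taxid", class = "tm_integrity_error")
})

test_that("name resolution is exact, case-insensitive, and subtree-closed", {
  dir <- withr::local_tempdir()
  df <- data.frame(
    taxid = c(10L, 20L, 21L, 22L, 23L),
    parent_taxid = c(10L, 10L, 20L, 20L, 20L),
    rank = c("no rank", "genus", "species", "species", "species"),
    name = c("rootclade", "Genusone", "Genusone alpha", "Genusone beta",
             "Genusone gamma"))
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|\t\t|", df$taxid, df$parent_taxid,
                     df$rank), file.path(dir, "nodes.dmp"))
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", df$taxid,
                     df$name), file.path(dir, "names.dmp"))
  nodes <- parse_taxdump(file.path(dir, "names.dmp"), file.path(dir, "nodes.dmp"))

  # genus query: the node plus its 3 species children
  ts <- resolve_name(nodes, "genusone")
  expect_equal(ts$root_taxids, 20L)
  expect_equal(ts$member_taxids, c(20L, 21L, 22L, 23L))
  expect_true(all(ts$root_taxids %in% ts$member_taxids))

  # leaf query: subtree is itself
  leaf <- resolve_name(nodes, "Genusone beta")
  expect_equal(leaf$member_taxids, 22L)

  expect_error(resolve_name(nodes, "zzz-nonexistent"),
               "organism not found", class = "tm_not_found_error")
  expect_error(resolve_name(nodes, "   "), class = "tm_usage_error")

  # substring must not match
  expect_error(resolve_name(nodes, "Genus"), class = "tm_not_found_error")
})

test_that("descendant traversal equals a naive recursive oracle on random trees", {
  for (seed in 1:5) {
    set.seed(seed)
    dir <- withr::local_tempdir()
    df <- rand_tree_files(50L, dir)
    nodes <- parse_taxdump(file.path(dir, "names.dmp"),
                           file.path(dir, "nodes.dmp"))
    for (root in sample(df$taxid, 10L))
      expect_equal(descendant_taxa(nodes, root), oracle_descendants(df, root))
  }
})

test_that("linear chains, leaves and unknown roots behave per contract", {
  dir <- withr::local_tempdir()
  writeLines(c("1\t|\t1\t|\tno rank\t|", "2\t|\t1\t|\tgenus\t|",
               "3\t|\t2\t|\tspecies\t|"), file.path(dir, "nodes.dmp"))
  writeLines(sprintf("%d\t|\tn%d\t|\t\t|\tscientific name\t|", 1:3, 1:3),
             file.path(dir, "names.dmp"))
  nodes <- parse_taxdump(file.path(dir, "names.dmp"), file.path(dir, "nodes.dmp"))
  expect_equal(descendant_taxa(nodes, 1L), c(1L, 2L, 3L))
  expect_equal(descendant_taxa(nodes, 3L), 3L)
  expect_error(descendant_taxa(nodes, 99L), class = "tm_not_found_error")
})

test_that("parsing is insensitive to record order in the dump files", {
  dir <- withr::local_tempdir()
  set.seed(11)
  df <- rand_tree_files(30L, dir)
  nodes1 <- parse_taxdump(file.path(dir, "names.dmp"), file.path(dir, "nodes.dmp"))

  # shuffle both files
  perm <- sample(nrow(df))
  writeLines(sprintf("%d\t|\t%d\t|\t%s\t|\t\t|", df$taxid[perm],
                     df$parent_taxid[perm], df$rank[perm]),
             file.path(dir, "nodes.dmp"))
  writeLines(sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|",
                     rev(df$taxid), rev(df$name)),
             file.path(dir, "names.dmp"))
  nodes2 <- parse_taxdump(file.path(dir, "names.dmp"), file.path(dir, "nodes.dmp"))
  o1 <- nodes1[order(nodes1$taxid), ]
  o2 <- nodes2[order(nodes2$taxid), ]
  rownames(o1) <- rownames(o2) <- NULL
  attr(o1, "synonyms") <- attr(o2, "synonyms") <- NULL
  expect_equal(o1, o2)
})
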