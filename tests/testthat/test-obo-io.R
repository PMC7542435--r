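three_term_obo <- function(extra = character(0)) {
  c("format-version: 1.2",
    "data-version: releases/2026-01-01",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: root term",
    "namespace: biological_process",
    "",
    "[Term]",
    "id: GO:0000002",
    "name: child",
    "namespace: biological_process",
    "alt_id: GO:0999999",
    "is_a: GO:0000001 ! root term",
    "",
    "[Term]",
    "id: GO:0000003",
    "name: grandchild",
    "namespace: biological_process",
    "relationship: part_of GO:0000002 ! child",
    "",
    extra)
}

test_that("parseOBO filters namespace, relations and obsolete terms", {
  recs <- parseOBO(three_term_obo(), "biological_process",
                   relations = c("is_a", "part_of"))
  expect_length(recs, 3)
  n_links <- sum(vapply(recs, function(r) nrow(r$parents), integer(1)))
  expect_equal(n_links, 2)
  expect_equal(attr(recs, "data_version"), "releases/2026-01-01")

  # restricting the relations drops the part_of link of the grandchild
  isa_only <- parseOBO(three_term_obo(), "BP", relations = "is_a")
  gc <- isa_only[[which(vapply(isa_only, `[[`, character(1), "id") ==
                          "GO:0000003")]]
  expect_equal(nrow(gc$parents), 0)

  # obsolete terms vanish entirely
  obs <- three_term_obo(c("[Term]", "id: GO:0000004",
                          "namespace: biological_process",
                          "is_obsolete: true",
                          "is_a: GO:0000001"))
  expect_length(parseOBO(obs, "BP"), 3)

  # other-namespace terms vanish too
  mf <- three_term_obo(c("[Term]", "id: GO:0000005",
                         "namespace: molecular_function"))
  expect_length(parseOBO(mf, "BP"), 3)
  expect_length(parseOBO(mf, "MF"), 1)

  expect_error(parseOBO(three_term_obo(), "not_a_namespace"),
               "unknown namespace")
  expect_error(parseOBO(three_term_obo(), "BP", relations = "has_part"),
               "subset")
  expect_error(parseOBO(c("[Term]", "name: no id here"), "BP"), "missing id")
})

test_that("parseOBO relation filtering is union-compatible and alt_ids map", {
  links_under <- function(rel) {
    recs <- parseOBO(three_term_obo(), "BP", relations = rel)
    unlist(lapply(recs, function(r) {
      if (nrow(r$parents)) paste(r$id, r$parents$parent)
    }))
  }
  both <- links_under(c("is_a", "part_of"))
  expect_setequal(both, union(links_under("is_a"), links_under("part_of")))

  recs <- parseOBO(three_term_obo(), "BP")
  al <- attr(recs, "aliases")
  expect_equal(unname(al["GO:0999999"]), "GO:0000002")
  # aliases survive into the DAG so user lists may carry superseded ids
  g <- buildDAG(recs)
  lv <- assignLevels(g)
  expect_equal(distRanking(g, lv, "GO:0999999")$term, "GO:0000002")
})

gaf_fixture <- function(rows) {
  row <- function(gene, qual, term, aspect) {
    paste(c("DB", gene, gene, qual, term, "PMID:1", "IEA", "", aspect,
            "", "", "protein", "taxon:9606", "20260101", "DB", ""),
          collapse = "\t")
  }
  c("!gaf-version: 2.2", vapply(rows, function(r) do.call(row, r),
                                character(1)))
}

test_that("parseGAF maps genes to terms with aspect and NOT filtering", {
  txt <- gaf_fixture(list(
    list("geneA", "involved_in", "GO:0000002", "P"),
    list("geneB", "involved_in", "GO:0000003", "P")))
  m <- parseGAF(txt, "biological_process")
  expect_named(m, c("geneA", "geneB"))
  expect_equal(m$geneA, "GO:0000002")

  # NOT-qualified rows and wrong-aspect rows are excluded
  txt2 <- gaf_fixture(list(
    list("geneA", "NOT|involved_in", "GO:0000002", "P"),
    list("geneB", "enables", "GO:0000003", "F"),
    list("geneC", "involved_in", "GO:0000003", "P")))
  m2 <- parseGAF(txt2, "BP")
  expect_named(m2, "geneC")

  expect_error(parseGAF(c("!header", "too\tfew\tcols"), "BP"), "row 2")
})

test_that("DOT export renders nodes, edges and one rank per level", {
  dot <- writeDOT(toyDAG())
  expect_length(grep("\\[label=", dot), 9)
  expect_length(grep(" -> ", dot), 9)
  expect_length(grep("rank=same", dot), 5)

  single <- chainDAG("solo")
  dot1 <- writeDOT(single)
  expect_length(grep("\\[label=", dot1), 1)
  expect_length(grep(" -> ", dot1), 0)

  g <- toyDAG()
  rd <- reduceDAG(g, assignLevels(g))
  dotr <- writeDOT(rd)
  expect_length(grep("rank=same", dotr), 5)  # levels 0..4
  expect_true(any(grepl("LN\\\\nlevel 4\\\\nn=2", dotr)))
  # braces balance, so Graphviz can parse it
  expect_equal(sum(lengths(regmatches(dotr, gregexpr("\\{", dotr)))),
               sum(lengths(regmatches(dotr, gregexpr("\\}", dotr)))))
})

test_that("GraphML export round-trips through igraph", {
  g <- toyDAG()
  f <- withr::local_tempfile(fileext = ".graphml")
  writeGraphML(g, f)
  back <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(back), 9)
  expect_equal(igraph::ecount(back), 9)
  expect_setequal(igraph::V(back)$name, dagNodes(g))

  rd <- reduceDAG(g, assignLevels(g))
  f2 <- withr::local_tempfile(fileext = ".graphml")
  writeGraphML(rd, f2)
  back2 <- igraph::read_graph(f2, format = "graphml")
  expect_equal(igraph::vcount(back2), nrow(summaryNodes(rd)))
})

test_that("writeOBO/parseOBO round-trips fixture and random graphs", {
  for (g in list(toyDAG(), randomDAG(15, 5, 0.4, seed = 11))) {
    recs <- parseOBO(writeOBO(g), "biological_process")
    g2 <- buildDAG(recs)
    expect_setequal(dagNodes(g2), dagNodes(g))
    for (t in dagNodes(g)) {
      expect_setequal(dagChildren(g2, t), dagChildren(g, t))
    }
  }
})
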