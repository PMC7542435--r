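test_that("categorisation matches the worked example and the definitions", {
  g <- toyDAG()
  lv <- assignLevels(g)
  expect_equal(categoryOf(g, lv, "x3"), list(category = "RN", level = 1L))
  expect_equal(categoryOf(g, lv, "x2"), list(category = "JN", level = 1L))
  expect_equal(categoryOf(g, lv, "x5"), list(category = "LN", level = 2L))
  expect_equal(categoryOf(g, lv, "x9"), list(category = "LN", level = 4L))
  expect_error(categoryOf(g, lv, "x1"), "root")

  edge <- buildDAG(list(list(id = "r", parents = character(0)),
                        list(id = "a", parents = "r")))
  elv <- assignLevels(edge)
  expect_equal(categoryOf(edge, elv, "a"), list(category = "LN", level = 1L))

  ca <- categories(categorize(g, lv))
  expect_setequal(ca$term, setdiff(dagNodes(g), "x1"))
  expect_equal(ca$level, unname(termLevels(lv)[ca$term]))
})

test_that("toy DAG reduces to seven category nodes plus the root node", {
  g <- toyDAG()
  lv <- assignLevels(g)
  rd <- reduceDAG(g, lv)
  nd <- summaryNodes(rd)
  cat_nd <- nd[nd$category != "root", ]
  expect_setequal(cat_nd$id,
                  c("JN_1", "RN_1", "LN_2", "RN_2", "LN_3", "RN_3", "LN_4"))
  expect_equal(sum(cat_nd$count), 8)  # all non-root terms accounted for
  expect_true("root_0" %in% nd$id)
  expect_equal(sort(summaryEdges(rd)$from), sort(c(
    "root_0", "root_0", "JN_1", "RN_1", "RN_1", "RN_2", "RN_2", "RN_3")))
  # the doubled original edge pair x6->x8, x6->x9 collapses with multiplicity
  e <- summaryEdges(rd)
  expect_equal(e$n[e$from == "RN_3" & e$to == "LN_4"], 2L)

  no_root <- reduceDAG(g, lv, includeRoot = FALSE)
  expect_false("root_0" %in% summaryNodes(no_root)$id)
  expect_false(any(summaryEdges(no_root)$from == "root_0"))
})

test_that("a DAG without level-skipping edges reduces to RN/LN only", {
  g <- randomDAG(20, n_levels = 5, jump_probability = 0, seed = 42)
  lv <- assignLevels(g)
  ca <- categories(categorize(g, lv))
  expect_false(any(ca$category == "JN"))
})

test_that("restricted reductions cover only the listed members", {
  g <- toyDAG()
  lv <- assignLevels(g)

  leaves <- reduceSubDAG(g, lv, terms = c("x8", "x9"))
  expect_equal(summaryNodes(leaves)$id, "LN_4")
  expect_equal(summaryNodes(leaves)$count, 2L)
  expect_equal(nrow(summaryEdges(leaves)), 0)

  solo <- reduceSubDAG(g, lv, terms = "x2")
  expect_equal(summaryNodes(solo)$id, "JN_1")
  expect_equal(nrow(summaryEdges(solo)), 0)

  # identity restriction reproduces the full reduction
  all_in <- reduceSubDAG(g, lv, terms = dagNodes(g), includeRoot = TRUE)
  full <- reduceDAG(g, lv)
  expect_equal(summaryNodes(all_in), summaryNodes(full))
  expect_equal(summaryEdges(all_in), summaryEdges(full))

  expect_error(reduceSubDAG(g, lv, terms = character(0)), "empty")
})

test_that("reduction invariants hold against brute force on random DAGs", {
  for (seed in 1:50) {
    g <- random_case(seed, max_nodes = 15L)
    lv <- assignLevels(g)
    rd <- reduceDAG(g, lv)
    nd <- summaryNodes(rd)
    cat_nd <- nd[nd$category != "root", ]

    # partition: every non-root term in exactly one node, at most 3 per level
    expect_equal(sum(cat_nd$count), length(dagNodes(g)) - 1L)
    expect_true(all(table(cat_nd$level) <= 3))

    # level preservation: all original non-root levels survive
    expect_setequal(cat_nd$level,
                    unique(termLevels(lv)[setdiff(dagNodes(g), dagRoot(g))]))

    # edge soundness and completeness versus the brute-force scan through f
    got <- sort(paste(summaryEdges(rd)$from, summaryEdges(rd)$to))
    expect_equal(got, brute_reduced_edges(g), info = sprintf("seed %d", seed))

    # a JN exists on level l iff some edge out of level l skips a level
    jn_levels <- sort(unique(cat_nd$level[cat_nd$category == "JN"]))
    lvv <- termLevels(lv)
    skip_levels <- as.integer(sort(unique(unlist(lapply(
      setdiff(dagNodes(g), dagRoot(g)),
      function(u) {
        kids <- dagChildren(g, u)
        if (length(kids) && any(lvv[kids] > lvv[[u]] + 1L)) lvv[[u]]
      })))))
    expect_equal(jn_levels, skip_levels, info = sprintf("seed %d", seed))
  }
})
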