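test_that("buildDAG validates structure and reports defects precisely", {
  g <- buildDAG(toy_records())
  expect_s4_class(g, "OntologyDAG")
  expect_length(dagNodes(g), 9)
  expect_equal(dagRoot(g), "x1")

  expect_error(
    buildDAG(list(list(id = "a", parents = "b"),
                  list(id = "b", parents = "a"))),
    "cycle")
  expect_error(
    buildDAG(list(list(id = "a", parents = character(0)),
                  list(id = "b", parents = character(0)))),
    "multiple root")
  expect_error(
    buildDAG(list(list(id = "a", parents = character(0)),
                  list(id = "b", parents = "ghost"))),
    "unknown parent")
  expect_error(buildDAG(list()), "empty")
})

test_that("level assignment follows the largest-value rule", {
  g <- toyDAG()
  lv <- termLevels(assignLevels(g))
  expect_equal(
    lv[paste0("x", 1:9)],
    c(x1 = 0L, x2 = 1L, x3 = 1L, x4 = 2L, x5 = 2L,
      x6 = 3L, x7 = 3L, x8 = 4L, x9 = 4L))
  # x8 keeps the deeper of its two provisional levels {2, 4}
  expect_equal(levelSets(g)$x8, c(2L, 4L))
  expect_equal(levelSets(g)$x1, 0L)

  ch <- chainDAG(letters[1:7])
  chl <- assignLevels(ch)
  expect_equal(unname(termLevels(chl)), 0:6)
  expect_equal(dagDepth(chl), 6)
})

test_that("level queries slice and partition the node set", {
  g <- toyDAG()
  lv <- assignLevels(g)
  expect_setequal(termsOnLevel(g, lv, 1), c("x2", "x3"))
  expect_setequal(termsOnLevel(g, lv, 4), c("x8", "x9"))
  expect_equal(termsOnLevel(g, lv, 0), "x1")
  expect_error(termsOnLevel(g, lv, 5), "\\[0, 4\\]")
  expect_error(termsOnLevel(g, lv, -1), "\\[0, 4\\]")

  all_terms <- unlist(lapply(0:dagDepth(lv), termsOnLevel, dag = g,
                             levels = lv))
  expect_setequal(all_terms, dagNodes(g))
  expect_equal(length(all_terms), length(dagNodes(g)))
})

test_that("children/parent queries expose jumps and invert edges", {
  g <- toyDAG()
  lv <- assignLevels(g)
  ch2 <- childrenWithLevels(g, lv, "x2")
  expect_equal(ch2$child, "x8")
  expect_equal(ch2$level, 4L)  # the jump: parent level 1, child level 4
  expect_equal(nrow(childrenWithLevels(g, lv, "x5")), 0)
  ch4 <- childrenWithLevels(g, lv, "x4")
  expect_setequal(ch4$child, c("x6", "x7"))
  expect_equal(unique(ch4$level), 3L)

  expect_setequal(parentsOf(g, "x8"), c("x2", "x6"))
  expect_length(parentsOf(g, "x1"), 0)
  expect_equal(parentsOf(g, "x9"), "x6")
  expect_error(parentsOf(g, "nope"), "unknown term")
})

test_that("descendants, ancestors and max depth through a term", {
  g <- toyDAG()
  lv <- assignLevels(g)
  expect_setequal(termDescendants(g, "x4"), c("x6", "x7", "x8", "x9"))
  expect_setequal(termAncestors(g, "x8"), c("x1", "x2", "x3", "x4", "x6"))
  expect_length(termDescendants(g, "x5"), 0)
  expect_length(termAncestors(g, "x1"), 0)

  expect_equal(maxDepthThrough(g, lv, "x2"), 4)
  expect_equal(maxDepthThrough(g, lv, "x8"), 4)  # leaf: its own level
  expect_equal(maxDepthThrough(g, lv, "x3"), 4)
  expect_equal(maxDepthThrough(g, lv, "x5"), 2)
})

test_that("organism sub-DAG induction is ancestor-closed and idempotent", {
  g <- toyDAG()
  lv <- assignLevels(g)

  sub9 <- organismSubDAG(g, "x9")
  expect_setequal(dagNodes(sub9), c("x1", "x3", "x4", "x6", "x9"))
  n_edges <- sum(lengths(adjacency_of(sub9)))
  expect_equal(n_edges, 4)

  expect_setequal(dagNodes(organismSubDAG(g, "x5")), c("x1", "x3", "x5"))

  full <- organismSubDAG(g, dagNodes(g))
  expect_setequal(dagNodes(full), dagNodes(g))
  for (t in dagNodes(g)) {
    expect_setequal(dagChildren(full, t), dagChildren(g, t))
  }

  # idempotence, and sub-DAG levels never exceed full-DAG levels
  twice <- organismSubDAG(sub9, dagNodes(sub9))
  expect_setequal(dagNodes(twice), dagNodes(sub9))
  sub_lv <- termLevels(assignLevels(sub9))
  expect_true(all(sub_lv <= termLevels(lv)[names(sub_lv)]))

  expect_error(organismSubDAG(g, character(0)), "empty")
  expect_warning(sub <- organismSubDAG(g, c("x9", "bogus")), "unknown")
  expect_setequal(dagNodes(sub), dagNodes(sub9))
})

test_that("levels match brute-force longest-path enumeration on random DAGs", {
  for (seed in 1:60) {
    g <- random_case(seed)
    lv <- termLevels(assignLevels(g))
    expect_equal(lv[dagNodes(g)], brute_levels(g)[dagNodes(g)],
                 info = sprintf("seed %d", seed))
    # strict monotonicity along every edge
    for (u in dagNodes(g)) {
      for (v in dagChildren(g, u)) {
        expect_lt(lv[[u]], lv[[v]])
      }
    }
    # max over the provisional level sets reproduces the final levels
    sets <- levelSets(g)
    expect_equal(vapply(sets, max, integer(1))[dagNodes(g)], lv[dagNodes(g)])
    expect_equal(sets, brute_level_sets(g))
  }
})
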