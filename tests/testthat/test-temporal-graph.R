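test_that("sequential order builds a chain with single hidden parents", {
  dag <- buildTemporalDAG("sequential", 3)
  expect_equal(nrow(dag@nodes), 3L)
  expect_equal(nrow(dag@edges), 2L)
  indeg <- table(factor(dag@edges$to, levels = dag@nodes$id))
  expect_true(all(indeg <= 1))
  expect_true(all(dag@nodes$role == "hidden"))
})

test_that("interpenetrated order makes the present a collider", {
  dag <- buildTemporalDAG("interpenetrated", 3)
  indeg <- sum(dag@edges$to == dag@reference)
  expect_equal(indeg, 2L)
})

test_that("horizon and depth are validated", {
  expect_error(buildTemporalDAG("sequential", 0), "objectiveHorizon")
  expect_error(buildTemporalDAG("sequential", 1), "objectiveHorizon")
  expect_error(buildTemporalDAG("integrated", 3, 0), "subjectiveDepth")
})

test_that("integrated lattice satisfies the homogeneous parent rule", {
  dag <- buildTemporalDAG("integrated", 4, 2)
  nd <- dag@nodes
  for (i in which(nd$role == "hidden" & !nd$boundary)) {
    t <- nd$objective[i]; tau <- nd$subjective[i]
    par <- dag@edges$from[dag@edges$to == nd$id[i]]
    expect_setequal(par, c(sprintf("s.t%d.tau%d", t - 1, tau + 1),
                           sprintf("s.t%d.tau%d", t, tau + 1),
                           sprintf("o.t%d.tau%d", t, tau - 1)))
  }
  ## every hidden node, boundary or not, keeps its observation parent
  for (i in which(nd$role == "hidden")) {
    par <- dag@edges$from[dag@edges$to == nd$id[i]]
    expect_true(sprintf("o.t%d.tau%d", nd$objective[i],
                        nd$subjective[i] - 1) %in% par)
  }
})

test_that("all constructed graphs are acyclic", {
  for (order in c("sequential", "interpenetrated", "integrated"))
    for (H in 2:5)
      for (D in 1:2) {
        dag <- buildTemporalDAG(order, H, D)
        g <- igraph::graph_from_data_frame(dag@edges, directed = TRUE,
                                           vertices = dag@nodes$id)
        expect_true(igraph::is_dag(g))
      }
})

test_that("d-separation follows the standard blocking rules", {
  chain <- buildTemporalDAG("sequential", 3)
  ids <- chain@nodes$id
  expect_false(isDSeparated(chain, ids[1], ids[3]))
  expect_true(isDSeparated(chain, ids[1], ids[3], ids[2]))

  coll <- buildTemporalDAG("interpenetrated", 3)
  past <- coll@nodes$id[coll@nodes$subjective == -1]
  fut <- coll@nodes$id[coll@nodes$subjective == 1]
  expect_true(isDSeparated(coll, past, fut))
  expect_false(isDSeparated(coll, past, fut, coll@reference))

  expect_error(isDSeparated(chain, ids[1], ids[1]), "distinct")
  expect_error(isDSeparated(chain, ids[1], ids[2], ids[1]), "conditioning")
  expect_error(isDSeparated(chain, "nope", ids[2]), "unknown")
})

test_that("markov blanket collects parents, children and co-parents", {
  chain <- buildTemporalDAG("sequential", 3)
  ids <- chain@nodes$id
  expect_setequal(blanketMembers(markovBlanket(chain, ids[2])),
                  ids[c(1, 3)])

  coll <- buildTemporalDAG("interpenetrated", 3)
  past <- coll@nodes$id[coll@nodes$subjective == -1]
  fut <- coll@nodes$id[coll@nodes$subjective == 1]
  expect_setequal(blanketMembers(markovBlanket(coll, past)),
                  c(coll@reference, fut))

  expect_error(markovBlanket(chain, "missing"), "not found")
})

test_that("present-moment blanket of the integrated lattice is verified and asynchronous", {
  dag <- buildTemporalDAG("integrated", 4, 2)
  bl <- markovBlanket(dag)
  ## regression fixture: the living-inference triplet of the reference node
  expect_setequal(blanketMembers(bl),
                  c("s.t0.tau1", "s.t1.tau1", "o.t1.tau-1"))
  expect_true(verifyBlanket(bl, checkMinimal = FALSE)$separated)
  asyn <- blanketAsynchrony(bl)
  expect_equal(asyn$pastCount, 1L)
  expect_equal(asyn$futureCount, 0L)
  expect_true(asyn$imbalanced)
  expect_gte(asyn$objectiveSpan, 1L)
})

test_that("blankets are correct and minimal for every target on small graphs", {
  graphs <- list(buildTemporalDAG("integrated", 2, 1),
                 buildTemporalDAG("integrated", 3, 1),
                 buildTemporalDAG("sequential", 5),
                 buildTemporalDAG("interpenetrated", 5))
  for (dag in graphs) {
    expect_lte(nrow(dag@nodes), 12L)
    for (i in seq_len(nrow(dag@nodes))) {
      bl <- markovBlanket(dag, dag@nodes$id[i])
      chk <- verifyBlanket(bl, checkMinimal = !dag@nodes$boundary[i])
      expect_true(chk$separated)
      if (!dag@nodes$boundary[i] && length(blanketMembers(bl)))
        expect_true(chk$minimal)
    }
  }
})

test_that("blanket asynchrony handles chains and single-member blankets", {
  chain <- buildTemporalDAG("sequential", 3)
  ids <- chain@nodes$id
  asyn <- blanketAsynchrony(markovBlanket(chain, ids[2]))
  expect_equal(asyn$objectiveSpan, 2L)
  expect_equal(asyn$pastCount, 1L)
  expect_equal(asyn$futureCount, 1L)
  expect_false(asyn$imbalanced)

  two <- buildTemporalDAG("sequential", 2)
  one <- blanketAsynchrony(markovBlanket(two, two@nodes$id[1]))
  expect_equal(one$objectiveSpan, 0L)

  empty <- new("MarkovBlanket", target = ids[1], members = character(),
               dag = chain)
  expect_error(blanketAsynchrony(empty), "no members")
})

test_that("graphs round-trip through JSON and export to DOT", {
  dag <- buildTemporalDAG("integrated", 3, 1)
  jf <- tempfile(fileext = ".json")
  writeGraphJSON(dag, jf)
  back <- readGraphJSON(jf)
  expect_equal(back@order, dag@order)
  expect_equal(back@reference, dag@reference)
  expect_setequal(back@nodes$id, dag@nodes$id)
  expect_equal(nrow(back@edges), nrow(dag@edges))
  expect_setequal(blanketMembers(markovBlanket(back)),
                  blanketMembers(markovBlanket(dag)))

  df <- tempfile(fileext = ".dot")
  writeGraphDOT(dag, df)
  txt <- readLines(df)
  expect_true(any(grepl("digraph", txt)))
  expect_true(all(vapply(dag@nodes$id, function(id)
    any(grepl(id, txt, fixed = TRUE)), logical(1))))
  expect_equal(sum(grepl(" -> ", txt, fixed = TRUE)), nrow(dag@edges))
})
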