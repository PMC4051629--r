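test_that("a single informative character resolves four taxa to its split", {
  m <- char_matrix(matrix(c(0L, 0L, 1L, 1L), 4, 1,
                          dimnames = list(c("A", "B", "C", "D"), NULL)))
  for (fit in list(exhaustive_search(m), branch_and_bound(m))) {
    expect_equal(fit$best_length, 1L)
    expect_equal(length(fit$best_trees_binary), 1L)
    expect_equal(canonical_id(fit$best_trees_binary[[1]]),
                 canonical_id(parse_newick("((A,B),(C,D));")))
  }
})

test_that("perfectly compatible data are recovered uniquely at length = characters", {
  tr <- caterpillar6()
  m <- simulate_perfect_hierarchy(tr)
  fit <- exhaustive_search(m)
  expect_equal(fit$best_length, ncol(m$states))
  expect_equal(length(fit$best_trees_binary), 1L)
  expect_equal(canonical_id(fit$best_trees_binary[[1]]), canonical_id(tr))
})

test_that("exact search on the bundled matrix finds 24 steps, three binary optima, one collapsed tree", {
  m <- saltans_matrix()
  fit <- branch_and_bound(m)
  expect_equal(fit$best_length, 24L)
  expect_equal(length(fit$best_trees_binary), 3L)
  expect_equal(length(fit$best_trees_collapsed), 1L)
  # the three optima differ only in the resolution of the saltans trio
  cons <- strict_consensus(fit$best_trees_binary)
  expected <- parse_newick(paste0(
    "(willistoni,(neocordata,((emarginata,(sturtevanti,(dacunhai,milleri))),",
    "(parasaltans,(saltans,(lusaltans,prosaltans,austrosaltans))))));"))
  expect_equal(canonical_id(cons), canonical_id(expected))
  expect_equal(canonical_id(fit$best_trees_collapsed[[1]]),
               canonical_id(expected))
  # the certificate is one of the optima
  ids <- vapply(fit$best_trees_binary, canonical_id, "")
  expect_true(canonical_id(parse_newick(saltans_certificate_newick())) %in% ids)
  # pruning fired: far fewer complete topologies scored than exist
  expect_lt(fit$n_topologies_examined, n_topologies(11))
  expect_gt(fit$n_pruned, 0)
  # the greedy upper bound is never better than the optimum
  expect_gte(fit$search_log$initial_upper_bound, fit$best_length)
})

test_that("branch and bound returns exactly the exhaustive optimum set", {
  for (seed in 1:6) {
    n <- 6 + seed %% 2
    tt <- rand_tree(paste0("t", 1:n), 900 + seed)
    sim <- simulate_mk(tt, 15, mean_changes = 0.4, seed = seed)
    fb <- branch_and_bound(sim$matrix, collapse = FALSE)
    fe <- exhaustive_search(sim$matrix, collapse = FALSE)
    expect_equal(fb$best_length, fe$best_length)
    expect_setequal(vapply(fb$best_trees_binary, canonical_id, ""),
                    vapply(fe$best_trees_binary, canonical_id, ""))
  }
})

test_that("exhaustive search refuses oversized inputs with a cap condition", {
  m <- rand_matrix(12, 5, seed = 1)
  expect_error(exhaustive_search(m), class = "mp_cap_error")
})

test_that("the ratchet is seed-deterministic and exact on easy data", {
  ph <- simulate_perfect_hierarchy(caterpillar6())
  r1 <- ratchet_search(ph, iterations = 1, seed = 5)
  expect_equal(r1$best_length, ncol(ph$states))
  expect_equal(canonical_id(r1$best_trees_binary[[1]]),
               canonical_id(caterpillar6()))
  m <- saltans_matrix()
  a <- ratchet_search(m, iterations = 3, seed = 42)
  b <- ratchet_search(m, iterations = 3, seed = 42)
  expect_identical(lapply(a$best_trees_binary, canonical_id),
                   lapply(b$best_trees_binary, canonical_id))
  expect_equal(a$best_length, b$best_length)
  # a short run already reaches the exact optimum on the bundled data
  expect_equal(ratchet_search(m, iterations = 10, seed = 7)$best_length, 24L)
  expect_error(ratchet_search(m, iterations = 3), "seed")
})

test_that("collapsing is idempotent, length-preserving and deduplicating", {
  m <- saltans_matrix()
  fit <- branch_and_bound(m)
  once <- fit$best_trees_collapsed
  twice <- collapse_and_dedup(once, m)
  expect_equal(vapply(twice, canonical_id, ""),
               vapply(once, canonical_id, ""))
  expect_equal(tree_length(once[[1]], m)$total, fit$best_length)
  # duplicate inputs collapse to a single output
  dup <- collapse_and_dedup(list(fit$best_trees_binary[[1]],
                                 fit$best_trees_binary[[1]]), m)
  expect_equal(length(dup), 1L)
  # a tree whose every internal branch is forced keeps its resolution
  ph <- simulate_perfect_hierarchy(caterpillar6())
  tr <- exhaustive_search(ph)$best_trees_binary[[1]]
  kept <- collapse_and_dedup(list(tr), ph)
  expect_equal(canonical_id(kept[[1]]), canonical_id(tr))
})

test_that("strict consensus keeps exactly the shared splits", {
  t1 <- parse_newick("((a,b),(c,d));")
  t2 <- parse_newick("((a,c),(b,d));")
  star <- strict_consensus(list(t1, t2))
  expect_equal(star$Nnode, 1L)
  expect_identical(canonical_id(strict_consensus(list(t1, t1))),
                   canonical_id(t1))
  expect_error(strict_consensus(list(t1, parse_newick("((a,b),(c,e));"))),
               "leaf set")
  # containment: consensus splits are a subset of every input's splits
  trees <- lapply(1:4, function(s) rand_tree(letters[1:7], 70 + s))
  cs <- splits_of(strict_consensus(trees))
  for (tr in trees) expect_true(all(cs %in% splits_of(tr)))
})
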