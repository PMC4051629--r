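test_that("the certificate tree scores 24 steps with the expected per-character profile", {
  m <- saltans_matrix()
  len <- tree_length(parse_newick(saltans_certificate_newick()), m)
  expect_equal(len$total, 24L)
  expect_equal(unname(len$per_character),
               c(1L, 1L, 1L, 1L, 2L, 3L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 1L,
                 2L, 1L, 1L, 1L, 1L))
})

test_that("step bounds on the bundled matrix sum to 21 and 53", {
  m <- saltans_matrix()
  b <- char_bounds(m)
  expect_equal(attr(b, "sum_m"), 21)
  expect_equal(attr(b, "sum_g"), 53)
  expect_equal(b$m, c(rep(1L, 4), 2L, rep(1L, 7), 2L, rep(1L, 6)))
  expect_equal(b$g, c(4L, 3L, 2L, 3L, 4L, 5L, 4L, 1L, 1L, 1L, 3L, 5L, 5L,
                      1L, 3L, 1L, 1L, 1L, 5L))
  const <- char_matrix(matrix(0L, 4, 2, dimnames = list(letters[1:4], NULL)))
  bc <- char_bounds(const)
  expect_equal(bc$m, c(0L, 0L))
  expect_equal(bc$g, c(0L, 0L))
})

test_that("the star tree scores the maxsteps sum", {
  m <- saltans_matrix()
  star <- parse_newick(paste0("(", paste(m$taxa, collapse = ","), ");"))
  len <- tree_length(star, m)
  expect_equal(len$total, 53L)
  expect_equal(unname(len$per_character), char_bounds(m)$g)
})

test_that("tree length is invariant to root placement", {
  m <- saltans_matrix()
  tr <- parse_newick(saltans_certificate_newick())
  for (lab in m$taxa)
    expect_equal(tree_length(root_at_outgroup(tr, lab), m)$total, 24L)
  r <- rand_matrix(6, 10, n_states = 3, seed = 5)
  t6 <- rand_tree(r$taxa, 6)
  ref <- tree_length(t6, r)$total
  for (lab in r$taxa)
    expect_equal(tree_length(root_at_outgroup(t6, lab), r)$total, ref)
})

test_that("Fitch steps equal the brute-force minimum over internal assignments", {
  for (seed in 1:8) {
    r <- rand_matrix(5 + seed %% 2, 6, n_states = 2 + seed %% 2,
                     seed = 200 + seed, missing_frac = if (seed > 5) 0.2 else 0)
    tr <- rand_tree(r$taxa, 300 + seed)
    got <- tree_length(tr, r)$per_character
    for (j in seq_along(got))
      expect_equal(unname(got[j]), bf_steps(tr, r, j),
                   info = paste("seed", seed, "char", j))
  }
})

test_that("Hartigan on polytomies matches brute force and reduces to Fitch on binary trees", {
  m <- rand_matrix(6, 8, n_states = 3, seed = 17)
  poly <- parse_newick("((t1,t2,t3),(t4,t5),t6);")
  got <- tree_length(poly, m)$per_character
  for (j in seq_along(got))
    expect_equal(unname(got[j]), bf_steps(poly, m, j))
  # binary rooted vs unrooted presentations agree
  tb <- rand_tree(m$taxa, 21)
  expect_equal(tree_length(ape::unroot(root_at_outgroup(tb, "t1")), m)$total,
               tree_length(tb, m)$total)
})

test_that("independent phangorn scoring agrees on random matrices", {
  for (seed in 1:5) {
    r <- rand_matrix(7, 12, n_states = 3, seed = 400 + seed)
    tr <- rand_tree(r$taxa, 500 + seed)
    pd <- phangorn::phyDat(r$states, type = "USER",
                           levels = sort(unique(as.vector(r$states))))
    expect_equal(tree_length(tr, r)$total, phangorn::fitch(tr, pd))
  }
})

test_that("observed steps always sit within the m..g bounds", {
  for (seed in 1:6) {
    r <- rand_matrix(6, 9, n_states = 3, seed = 600 + seed)
    b <- char_bounds(r)
    tr <- rand_tree(r$taxa, 700 + seed)
    s <- unname(tree_length(tr, r)$per_character)
    expect_true(all(s >= b$m))
    expect_true(all(s <= b$g))
  }
})

test_that("leaf-set mismatches are reported with the symmetric difference", {
  m <- saltans_matrix()
  expect_error(tree_length(parse_newick("(a,(b,c));"), m),
               "only in tree.*only in matrix")
})

test_that("weighted lengths scale the per-character contributions", {
  m <- saltans_matrix()
  m$weights[6] <- 3
  tr <- parse_newick(saltans_certificate_newick())
  expect_equal(tree_length(tr, m)$total, 24 + 2 * 3)   # char 6 has 3 steps
  expect_equal(tree_length(tr, m, use_weights = FALSE)$total, 24L)
})
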