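cert <- parse_newick(saltans_certificate_newick())

test_that("characters with a single clean origin have exactly one reconstruction", {
  m <- saltans_matrix()
  mp3 <- mpr_enumerate(cert, m, 3)
  expect_equal(mp3$steps, 1L)
  expect_equal(mp3$n_mprs, 1L)
  mp12 <- mpr_enumerate(cert, m, 12)
  expect_equal(mp12$steps, 1L)
  expect_equal(mp12$n_mprs, 1L)
  ch <- unambiguous_changes(cert, m, chars = c(3, 12))
  expect_equal(ch$ambiguity, c("unambiguous", "unambiguous"))
  expect_equal(ch$clade[ch$char == 3], "dacunhai|milleri")
  expect_equal(sort(strsplit(ch$clade[ch$char == 12], "\\|")[[1]]),
               sort(c("parasaltans", "saltans", "lusaltans", "prosaltans",
                      "austrosaltans")))
  expect_equal(ch$from, c(0L, 0L))
  expect_equal(ch$to, c(1L, 1L))
})

test_that("a constant character has one zero-change reconstruction", {
  m <- char_matrix(matrix(c(1L, 1L, 1L, 1L, 0L, 1L, 0L, 1L), 4, 2,
                          dimnames = list(letters[1:4], NULL)))
  mp <- mpr_enumerate(parse_newick("((a,b),(c,d));"), m, 1)
  expect_equal(mp$steps, 0L)
  expect_equal(mp$n_mprs, 1L)
})

test_that("every enumerated reconstruction attains the Fitch minimum", {
  m <- saltans_matrix()
  sc_steps <- tree_length(cert, m)$per_character
  for (ch in c(5, 6, 13, 15)) {
    mp <- mpr_enumerate(cert, m, ch)
    expect_equal(mp$steps, unname(sc_steps[as.character(ch)]))
    tr <- mp$tree
    # count changed edges per assignment row directly
    n_changes <- apply(mp$assignments, 1, function(st)
      sum(st[tr$edge[, 1]] != st[tr$edge[, 2]]))
    expect_true(all(n_changes == mp$steps))
  }
})

test_that("enumeration reproduces the brute-force MPR set on small trees", {
  for (seed in 1:5) {
    r <- rand_matrix(5, 4, n_states = 3, seed = 40 + seed,
                     missing_frac = if (seed > 3) 0.2 else 0)
    tr <- rand_tree(r$taxa, 50 + seed)
    for (j in 1:4) {
      mp <- mpr_enumerate(tr, r, j)
      got <- mp$assignments[do.call(order,
               as.data.frame(mp$assignments)), , drop = FALSE]
      want <- bf_mprs(tr, r, j)
      expect_equal(unname(got), unname(want),
                   info = paste("seed", seed, "char", j))
    }
  }
})

test_that("terminal autapomorphies are unambiguous on any topology", {
  m <- saltans_matrix()
  for (seed in 1:3) {
    tr <- rand_tree(m$taxa, 60 + seed)
    ch <- unambiguous_changes(tr, m, chars = 17)
    expect_equal(nrow(ch), 1L)
    expect_equal(ch$ambiguity, "unambiguous")
    expect_equal(ch$clade, "neocordata")
    expect_equal(ch$clade_size, 1L)
    expect_equal(c(ch$from, ch$to), c(0L, 1L))
  }
})

test_that("change multiplicities reconcile with per-character steps and tree length", {
  m <- saltans_matrix()
  ch <- unambiguous_changes(cert, m)
  s <- tree_length(cert, m)$per_character
  for (id in unique(ch$char)) {
    sub <- ch[ch$char == id, ]
    # per MPR, the witnessed multiplicities sum to s_i
    expect_equal(sum(sub$n_mprs_with) / sub$n_mprs[1],
                 unname(s[as.character(id)]))
  }
  expect_equal(sum(ch$n_mprs_with / ch$n_mprs), 24)
})
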