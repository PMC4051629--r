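test_that("the bundled terminalia matrix loads with its documented structure", {
  m <- saltans_matrix()
  expect_s3_class(m, "char_matrix")
  expect_equal(nrow(m$states), 11L)
  expect_equal(ncol(m$states), 19L)
  expect_equal(m$taxa[1], "willistoni")
  expect_equal(m$outgroup, "willistoni")
  expect_equal(m$char_ids, 1:19)
  # outgroup row is all-absent (guard against fixture drift)
  expect_true(all(m$states["willistoni", ] == 0L))
  expect_false(anyNA(m$states))
  # exactly characters 5 and 13 show three states, the rest are binary
  nstates <- apply(m$states, 2, function(col) length(unique(col)))
  expect_equal(which(nstates == 3L), c(`5` = 5L, `13` = 13L))
  expect_true(all(nstates[-c(5, 13)] == 2L))
  expect_equal(m$states["parasaltans", 5], 2L)
  expect_equal(m$states["saltans", 13], 2L)
  # pure function: loading twice gives identical objects
  expect_identical(saltans_matrix(), m)
})

test_that("matrix summary classifies constant, autapomorphic and informative characters", {
  m <- saltans_matrix()
  s <- summary(m)
  expect_equal(s$n_taxa, 11L)
  expect_equal(s$n_ingroup, 10L)
  expect_equal(s$n_constant, 0L)
  expect_equal(s$n_autapomorphic, 7L)
  expect_equal(s$n_informative, 12L)
  expect_equal(unname(which(s$flags == "autapomorphic")),
               c(8L, 9L, 10L, 14L, 16L, 17L, 18L))
  # counts always partition the characters
  for (seed in 1:5) {
    r <- rand_matrix(5, 12, n_states = 3, seed = seed, missing_frac = 0.1)
    rs <- summary(r)
    expect_equal(rs$n_constant + rs$n_autapomorphic + rs$n_informative,
                 rs$n_characters)
  }
  const <- char_matrix(matrix(1L, 4, 3, dimnames = list(letters[1:4], NULL)))
  cs <- summary(const)
  expect_equal(cs$n_constant, 3L)
  expect_equal(cs$n_informative, 0L)
})

test_that("csv parsing accepts the smallest legal inputs and rejects malformed ones", {
  m <- parse_char_matrix("A,0\nB,0\nC,0", "csv")
  expect_equal(dim(m$states), c(3L, 1L))
  expect_equal(summary(m)$n_constant, 1L)
  # missing marker
  mq <- parse_char_matrix("A,?,1\nB,0,1\nC,0,0", "csv")
  expect_true(is.na(mq$states["A", 1]))
  # ragged row names the offending taxon
  expect_error(parse_char_matrix("#taxon,1,2\nA,0,1\nB,0\nC,1,1", "csv"),
               "ragged.*'B'")
  # unknown symbol reports row and column; '-' has no gap semantics here
  expect_error(parse_char_matrix("A,0\nB,x\nC,0", "csv"), "'x'.*'B'.*1")
  expect_error(parse_char_matrix("A,0\nB,-\nC,0", "csv"), "'-'")
  expect_error(parse_char_matrix("A,0\nA,1\nC,0", "csv"), "duplicate.*A")
  expect_error(parse_char_matrix("", "csv"), "empty")
  expect_error(parse_char_matrix("A,0\nB,1", "csv"), "3 taxa")
})

test_that("tnt and nexus dialects parse equivalent content", {
  tnt <- c("xread 'demo' 4 3", "A 0101", "B 01?1", "C 1100", ";")
  m1 <- parse_char_matrix(tnt, "tnt")
  expect_equal(m1$taxa, c("A", "B", "C"))
  expect_equal(unname(m1$states["C", ]), c(1L, 1L, 0L, 0L))
  expect_true(is.na(m1$states["B", 3]))
  nex <- c("#NEXUS", "BEGIN CHARACTERS;",
           "  DIMENSIONS NTAX=3 NCHAR=4;",
           "  FORMAT SYMBOLS=\"0123456789\" MISSING=?;",
           "  MATRIX", "    A 0101", "    B 01?1", "    C 1100", "  ;",
           "END;")
  m2 <- parse_char_matrix(nex, "nexus")
  expect_equal(m2$states, m1$states)
  expect_error(parse_char_matrix(c("xread 'demo' 4 3", "A 010", "B 0111",
                                   "C 1100", ";"), "tnt"), "ragged.*'A'")
})

test_that("every dialect round-trips arbitrary matrices", {
  for (seed in 1:6) {
    m <- rand_matrix(4 + seed %% 3, 7, n_states = 3, seed = 100 + seed,
                     missing_frac = if (seed %% 2) 0.15 else 0)
    for (d in c("csv", "tnt", "nexus")) {
      back <- parse_char_matrix(write_char_matrix(m, dialect = d), d)
      expect_equal(back$states, m$states, info = paste(d, seed))
      expect_equal(back$taxa, m$taxa)
    }
  }
})
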