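cert <- parse_newick(saltans_certificate_newick())

test_that("changes are classified as synapomorphy, autapomorphy or homoplasy", {
  m <- saltans_matrix()
  ann <- annotate_tree(cert, m)
  ch <- ann$changes
  # character 3: one unambiguous gain uniting dacunhai+milleri
  r3 <- ch[ch$char == 3, ]
  expect_equal(nrow(r3), 1L)
  expect_equal(r3$classification, "synapomorphy")
  expect_equal(r3$clade, "dacunhai|milleri")
  expect_equal(c(r3$from, r3$to), c(0L, 1L))
  # character 17: neocordata terminal autapomorphy
  r17 <- ch[ch$char == 17, ]
  expect_equal(r17$classification, "autapomorphy")
  expect_equal(r17$clade, "neocordata")
  # characters with excess steps are homoplastic throughout
  s <- tree_length(cert, m)$per_character
  b <- char_bounds(m)
  for (id in b$char[unname(s) > b$m]) {
    expect_true(all(ch$classification[ch$char == id] == "homoplasy"),
                info = paste("char", id))
  }
  expect_true(all(ch$classification[ch$char == 6] == "homoplasy"))
  # record multiplicities reconcile with the tree length
  expect_equal(sum(ch$n_mprs_with / ch$n_mprs), 24)
})

test_that("every autapomorphic character maps once to the same terminal branch on any topology", {
  m <- saltans_matrix()
  aut <- which(summary(m)$flags == "autapomorphic")
  ref <- annotate_tree(cert, m)$changes
  for (seed in 1:2) {
    tr <- rand_tree(m$taxa, 130 + seed)
    ch <- annotate_tree(tr, m)$changes
    for (id in aut) {
      got <- ch[ch$char == id, ]
      expect_equal(nrow(got), 1L, info = paste("char", id))
      expect_equal(got$clade, ref$clade[ref$char == id][1])
      expect_equal(got$clade_size, 1L)
    }
  }
})

test_that("annotated newick output carries change comments", {
  m <- saltans_matrix()
  nw <- write_annotated_newick(annotate_tree(cert, m))
  expect_match(nw, "\\[&changes=3:0>1\\]")
  expect_match(nw, "17:0>1")
  tmp <- tempfile(fileext = ".tsv")
  write_annotated_newick(annotate_tree(cert, m), tsv = tmp)
  tab <- read.delim(tmp)
  expect_true(all(tab$ambiguity == "unambiguous"))
})

test_that("the four reported topology claims hold on the certificate and its collapsed form", {
  m <- saltans_matrix()
  got <- check_topology_statements(cert, saltans_statements(), "willistoni")
  expect_true(all(got))
  expect_named(got, c("cordata_most_basal", "dacunhai_milleri_sisters",
                      "parasaltans_sister_to_saltans_subgroup",
                      "prosaltans_austrosaltans_closer"))
  collapsed <- branch_and_bound(m)$best_trees_collapsed[[1]]
  expect_true(all(check_topology_statements(collapsed, saltans_statements(),
                                            "willistoni")))
})

test_that("false and ill-formed claims are handled", {
  # emarginata is sister to the whole sturtevanti-subgroup clade, not to
  # the single leaf sturtevanti
  st <- topology_statement("sister_taxa", "sturtevanti", "emarginata")
  expect_false(check_topology_statements(cert, st, "willistoni"))
  expect_true(check_topology_statements(
    cert, topology_statement("sister_clades", "emarginata",
                             c("sturtevanti", "dacunhai", "milleri")),
    "willistoni"))
  expect_error(topology_statement("closer_than", "a", "b", "a"), "overlap")
  expect_error(check_topology_statements(
    cert, topology_statement("sister_taxa", "saltans", "nope"),
    "willistoni"), "unknown taxon")
})

test_that("statement checks are invariant to child ordering", {
  flipped <- parse_newick(paste0(
    "(((((((austrosaltans,prosaltans),lusaltans),saltans),parasaltans),",
    "((sturtevanti,(milleri,dacunhai)),emarginata)),neocordata),willistoni);"))
  expect_equal(canonical_id(flipped), canonical_id(cert))
  expect_true(all(check_topology_statements(flipped, saltans_statements(),
                                            "willistoni")))
})
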