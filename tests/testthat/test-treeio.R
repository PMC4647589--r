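test_that("parse_newick reads structure, lengths and polytomies", {
  tr <- parse_newick("((A:1,B:1):1,C:1);")
  expect_s3_class(tr, "phylo")
  expect_equal(ape::Ntip(tr), 3)
  expect_equal(tr$Nnode, 2)
  expect_true(all(tr$edge.length == 1))

  poly <- parse_newick("(A,B,C);")
  expect_equal(ape::Ntip(poly), 3)
  expect_equal(poly$Nnode, 1) # root with three children
  expect_null(poly$edge.length) # lengths missing until set
})

test_that("quoted labels with spaces survive a round trip", {
  tr <- parse_newick("(('Centris analis':1,'Apis mellifera':1):1,'Bombus terrestris':1);")
  expect_true("Centris analis" %in% tr$tip.label)
  tr2 <- parse_newick(write_newick(tr))
  expect_setequal(tr2$tip.label, tr$tip.label)
  expect_true(trees_isomorphic(tr, tr2))
})

test_that("malformed or invalid input fails with informative errors", {
  expect_error(parse_newick("((A,B);"), "unclosed")
  expect_error(parse_newick("(A,B));"), "character")
  expect_error(parse_newick("(A,B)"), "';'")
  expect_error(parse_newick("('A,B);"), "unterminated quote")
  expect_error(parse_newick("((A,B),A);"), "duplicate")
  expect_error(parse_newick("[&U]((A,B),C);"), "rooted")
})

test_that("parse/write round trip preserves topology and lengths on random trees", {
  for (i in 1:40) {
    n <- sample(4:40, 1)
    tr <- simulate_yule_tree(n, seed = 1000 + i)
    tr2 <- parse_newick(write_newick(tr))
    expect_true(trees_isomorphic(tr, tr2))
  }
  # multifurcating trees round trip too
  for (i in 1:10) {
    tr <- random_polytomy_tree(10, seed = 2000 + i)
    expect_true(trees_isomorphic(tr, parse_newick(write_newick(tr))))
  }
})

test_that("set_unit_branch_lengths forces 1, is idempotent, keeps topology", {
  tr <- parse_newick("((A:0.3,B:7):1,C);") # mixed incl. missing
  u <- set_unit_branch_lengths(tr)
  expect_true(all(u$edge.length == 1))
  expect_identical(u$edge, tr$edge)
  expect_identical(set_unit_branch_lengths(u), u)
  # sum of edge lengths = number of non-root nodes
  expect_equal(sum(u$edge.length), ape::Ntip(u) + u$Nnode - 1)
})

test_that("mrca_node matches examples and the path-intersection oracle", {
  tr <- parse_newick("((A,B),C);")
  cherry <- mrca_node(tr, c("A", "B"))
  expect_equal(cherry, 5L) # the cherry's internal node
  expect_equal(mrca_node(tr, c("A", "B", "C")), 4L) # root
  expect_error(mrca_node(tr, c("A", "Z")), "unknown tip")

  for (i in 1:10) {
    n <- sample(4:8, 1)
    rt <- simulate_yule_tree(n, seed = 3000 + i)
    for (k in 2:n) {
      tips <- sample(rt$tip.label, k)
      expect_equal(mrca_node(rt, tips), bf_mrca(rt, tips))
    }
  }
})

test_that("graft attaches subtrees, preserves backbone relations, rejects collisions", {
  backbone <- parse_newick("((A,B),C);")
  g1 <- graft(backbone, "X", attach_at = 4L)
  expect_equal(ape::Ntip(g1), 4)
  expect_true("X" %in% g1$tip.label)

  sub <- parse_newick("((P,Q),R);")
  g2 <- graft(backbone, sub, attach_at = mrca_node(backbone, c("A", "B")))
  expect_equal(ape::Ntip(g2), ape::Ntip(backbone) + ape::Ntip(sub))
  # backbone MRCA relations preserved: A,B still form a clade excluding C
  anc_ab <- bf_mrca(g2, c("A", "B"))
  anc_ac <- bf_mrca(g2, c("A", "C"))
  expect_false(anc_ab == anc_ac)
  desc <- ape::extract.clade(g2, bf_mrca(g2, c("A", "B")))
  expect_true(all(c("A", "B", "P", "Q", "R") %in% desc$tip.label))
  expect_false("C" %in% desc$tip.label)

  expect_error(graft(backbone, parse_newick("(A,Z);"), 4L), "collision")
})

test_that("clade definitions load from YAML and resolve against the fixture tree", {
  tr <- read_newick(fertsig_example("bee_supertree_reconstructed.nwk"))
  clades <- read_clade_definitions(fertsig_example("clades_bees.yml"))
  expect_length(clades, 7)
  expect_equal(clades[["Meliponini"]]$tips |> length(), 5)
  nd <- mrca_node(tr, clades[["Corbiculate bees"]]$tips)
  inside <- ape::extract.clade(tr, nd)$tip.label
  expect_setequal(inside, clades[["Corbiculate bees"]]$tips)
})
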