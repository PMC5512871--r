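test_that("parse_newick reads minimal trees, support labels, and multi-tree input", {
  tr <- parse_newick("(A:1.0,B:2.0);")
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(sort(tr$edge.length), c(1, 2))

  tr2 <- parse_newick("((A:0.1,B:0.2)0.95:0.3,C:0.6);")
  expect_equal(node_support(tr2), c(NA_real_, 0.95))

  multi <- parse_newick("(A:1,B:1);\n((A:1,B:1):1,C:1);")
  expect_s3_class(multi, "multiPhylo")
  expect_length(multi, 2)
})

test_that("parse_newick rejects malformed and invalid input", {
  expect_error(parse_newick("((A:1,(B:1);"), "unclosed")
  expect_error(parse_newick("(A:1,B:1));"), "unbalanced")
  expect_error(parse_newick("(A:1,A:2);"), "duplicate tip")
  expect_error(parse_newick("(A:-1,B:2);"), "negative branch length")
  expect_error(parse_newick("((A:1,B:1)200:1,C:1);"), "label > 100")
})

test_that("bootstrap-percentage labels are rescaled to [0,1] support", {
  tr <- parse_newick("((A:1,B:1)95:1,C:1);")
  expect_equal(node_support(tr), c(NA_real_, 0.95))
})

test_that("Newick round-trips through writer (topology, lengths, labels)", {
  set.seed(42)
  for (rep in 1:5) {
    tr <- ape::rtree(12)
    tr$node.label <- c("", sprintf("%.2f", runif(tr$Nnode - 1)))
    txt <- write_newick(tr)
    back <- parse_newick(txt)
    expect_equal(back$tip.label, tr$tip.label)
    expect_equal(back$node.label, tr$node.label)
    expect_equal(back$edge.length, tr$edge.length, tolerance = 1e-9)
    expect_true(ape::all.equal.phylo(back, tr, use.edge.length = TRUE))
  }
})

test_that("lineage_depths accumulates branch lengths tip-to-root", {
  tr <- parse_newick("((A:0.1,B:0.2):0.3,C:0.6);")
  prof <- lineage_depths(tr, "A")
  expect_equal(prof$S, c(0.1, 0.4))
  expect_equal(prof$node[length(prof$node)], 4L)  # root

  zero <- parse_newick("((A:0,B:0):0,C:0);")
  expect_equal(lineage_depths(zero, "A")$S, c(0, 0))

  expect_error(lineage_depths(tr, "Z"), "unknown tip")
})

test_that("lineage_depths matches an explicit path-walk oracle on random trees", {
  set.seed(7)
  for (rep in 1:5) {
    tr <- ape::rtree(20)
    tip <- sample(tr$tip.label, 1)
    prof <- lineage_depths(tr, tip)
    for (k in seq_len(nrow(prof))) {
      expect_equal(prof$S[k], oracle_path_sum(tr, tip, prof$node[k]),
                   tolerance = 1e-12)
    }
    ## root entry equals full root-to-tip depth
    depths <- ape::node.depth.edgelength(tr)
    expect_equal(prof$S[nrow(prof)], depths[match(tip, tr$tip.label)],
                 tolerance = 1e-12)
  }
})

test_that("collapse_low_support forms polytomies exactly at weak nodes", {
  tr <- parse_newick("((A:1,B:1)0.5:1,C:1);")
  col <- collapse_low_support(tr, 0.8)
  expect_equal(col$Nnode, 1L)
  expect_equal(sort(col$tip.label), c("A", "B", "C"))
  ## children keep their own lengths; the weak edge's length is discarded
  expect_equal(sort(col$edge.length), c(1, 1, 1))

  ## below-threshold cut-off leaves the tree unchanged
  same <- collapse_low_support(tr, 0.4)
  expect_true(ape::all.equal.phylo(same, tr, use.edge.length = TRUE))
})

test_that("collapse handles a caterpillar with mixed supports (hand-checked)", {
  ## supports root-ward: 0.95 (D-group), 0.3 (C-group), 0.9 (AB)
  tr <- parse_newick("((((A:1,B:1)0.9:1,C:1)0.3:1,D:1)0.95:1,E:1);")
  col <- collapse_low_support(tr, 0.8)
  ## exactly one node collapsed: the 0.3 node merges into the 0.95 node,
  ## which then has children {(A,B), C, D}
  expect_equal(col$Nnode, tr$Nnode - 1L)
  ab <- mrca_node(col, c("A", "B"))
  abc <- mrca_node(col, c("A", "C"))
  abd <- mrca_node(col, c("A", "D"))
  expect_equal(abc, abd)  # C and D now attach at the same polytomy
  expect_true(ab != abc)
  kids <- tabulate(col$edge[, 1])
  expect_equal(sort(kids[kids > 0]), c(2, 2, 3))
})

test_that("collapse_low_support is idempotent and preserves nodes without support", {
  set.seed(11)
  tr <- ape::rtree(15)
  tr$node.label <- c("", sprintf("%.2f", runif(tr$Nnode - 1)))
  once <- collapse_low_support(tr, 0.8)
  twice <- collapse_low_support(once, 0.8)
  expect_true(ape::all.equal.phylo(once, twice, use.edge.length = TRUE))
  ## nodes lacking support are treated as fully supported
  nolab <- ape::rtree(8)
  expect_true(ape::all.equal.phylo(collapse_low_support(nolab, 0.99), nolab,
                                   use.edge.length = TRUE))
})

test_that("mrca_node matches the ancestor-set-intersection oracle", {
  tr <- parse_newick("((A,B),C);")
  expect_equal(mrca_node(tr, c("A", "B")), 5L)
  expect_equal(mrca_node(tr, c("A", "C")), 4L)
  expect_error(mrca_node(tr, c("A", "Z")), "not in tree")

  set.seed(3)
  for (rep in 1:10) {
    tr <- ape::rtree(sample(4:8, 1))
    labs <- sample(tr$tip.label, sample(2:4, 1))
    expect_equal(mrca_node(tr, labs), oracle_mrca(tr, labs))
  }
  ## exhaustive over all label pairs on small trees
  tr <- ape::rtree(8)
  prs <- utils::combn(tr$tip.label, 2)
  for (i in seq_len(ncol(prs))) {
    expect_equal(mrca_node(tr, prs[, i]), oracle_mrca(tr, prs[, i]))
  }
})

test_that("node spec TSV round-trips", {
  specs <- list(node_X = c("tipA", "tipB"), node_Y = c("tipA", "tipC", "tipD"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_node_specs(specs, path)
  expect_equal(read_node_specs(path), specs)
})
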