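test_that("monophyly detection matches the induced bipartitions", {
  t1 <- ape::read.tree(text = "((R1:1,R2:1):1,(S1:1,S2:1):1);")
  expect_true(satisfies_constraint(t1, c("R1", "R2")))
  t2 <- ape::read.tree(text = "((R1:1,S1:1):1,(R2:1,S2:1):1);")
  expect_false(satisfies_constraint(t2, c("R1", "R2")))
  # size n-1 constraints hold on every 4-taxon topology
  allt <- phangorn::allTrees(4, rooted = FALSE,
                             tip.label = c("a", "b", "c", "d"))
  for (i in seq_along(allt)) {
    tr <- allt[[i]]
    tr$edge.length <- rep(0.1, nrow(tr$edge))
    expect_true(satisfies_constraint(tr, c("a", "b", "c")))
  }
  expect_error(satisfies_constraint(t1, c("R1", "ZZ")), "unknown")
  expect_error(satisfies_constraint(t1, character(0)), "non-empty")
})

test_that("search recovers a well-supported 4-taxon topology exactly", {
  truth <- ape::read.tree(text = "((A:0.05,B:0.05):0.2,(C:0.05,D:0.05):0.2);")
  m <- subst_model("JC69")
  aln <- simulate_alignment(truth, m, 2000, seed = 13)
  s <- ml_search(aln, m, n_replicates = 2, seed = 1)
  # exhaustive scoring of all three topologies
  ex <- vapply(phangorn::allTrees(4, rooted = FALSE,
                                  tip.label = c("A", "B", "C", "D")),
               function(t) {
                 t$edge.length <- rep(0.1, nrow(t$edge))
                 optimize_branch_lengths(t, aln, m, tol = 1e-8,
                                         max_sweeps = 50)$loglik
               }, numeric(1))
  expect_equal(s$loglik, max(ex), tolerance = 1e-6)
  expect_equal(kdrorigins:::canonical_newick(s$tree),
               kdrorigins:::canonical_newick(truth))
})

test_that("constrained search respects the constraint and never wins", {
  set.seed(4)
  tr <- ape::rtree(10, br = function(n) runif(n, 0.03, 0.25))
  m <- subst_model("JC69")
  aln <- simulate_alignment(tr, m, 300, seed = 6)
  for (k in c(3, 5)) {
    cons <- sample(tr$tip.label, k)
    unc <- ml_search(aln, m, 2, seed = 10 + k)
    con <- ml_search(aln, m, 2, seed = 20 + k, constraint = cons)
    expect_true(satisfies_constraint(con$tree, cons))
    expect_lte(con$loglik, unc$loglik + 1e-6)
  }
  expect_error(ml_search(random_alignment(3, 20, 1), m), "4 taxa")
})

test_that("search is deterministic given a seed", {
  set.seed(30)
  tr <- ape::rtree(8, br = function(n) runif(n, 0.03, 0.3))
  m <- subst_model("JC69")
  aln <- simulate_alignment(tr, m, 200, seed = 2)
  s1 <- ml_search(aln, m, 3, seed = 99)
  s2 <- ml_search(aln, m, 3, seed = 99)
  expect_identical(s1$replicate_loglik, s2$replicate_loglik)
  expect_equal(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
})

test_that("bootstrap saturates on strongly informative data", {
  truth <- ape::read.tree(
    text = "((A:0.05,B:0.05):0.3,((C:0.05,D:0.05):0.3,(E:0.05,F:0.05):0.3):0.05);")
  m <- subst_model("JC69")
  aln <- simulate_alignment(truth, m, 1500, seed = 44)
  b <- bootstrap_support(aln, m, n_boot = 10, search_reps = 1, seed = 5)
  expect_true(all(b$table$support >= 0 & b$table$support <= 100))
  expect_true(all(b$table$support == 100))
})

test_that("bootstrap with zero replicates yields an empty support map", {
  aln <- random_alignment(5, 40, seed = 8)
  m <- subst_model("JC69")
  tr <- nj_tree(aln)
  b <- bootstrap_support(aln, m, tree = tr, n_boot = 0)
  expect_equal(nrow(b$table), 0)
})

test_that("midpoint rooting splits the longest path and is display-only", {
  two <- ape::read.tree(text = "(a:1.5,b:0.5);")
  r <- midpoint_root(two)
  expect_equal(sort(r$edge.length), c(1, 1))
  sym <- ape::read.tree(text = "((a:1,b:1):0.5,(c:1,d:1):0.5);")
  rs <- midpoint_root(sym)
  d <- ape::node.depth.edgelength(rs)
  expect_equal(max(d[1:4]) , 1.5, tolerance = 1e-9)
  # rooting does not change the unrooted likelihood
  m <- subst_model("JC69")
  aln <- random_alignment(4, 50, seed = 3)
  rownames(aln$seq) <- sym$tip.label
  expect_equal(tree_loglik(midpoint_root(sym), aln, m),
               tree_loglik(sym, aln, m), tolerance = 1e-8)
  zero <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  expect_warning(midpoint_root(zero), "arbitrar")
})

test_that("tie-breaking uses the canonical Newick form", {
  t1 <- ape::read.tree(text = "((b:1,a:1):1,(d:1,c:1):1);")
  t2 <- ape::read.tree(text = "((c:2,d:2):2,(a:2,b:2):2);")
  expect_equal(kdrorigins:::canonical_newick(t1),
               kdrorigins:::canonical_newick(t2))
  t3 <- ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1);")
  expect_false(kdrorigins:::canonical_newick(t1) ==
               kdrorigins:::canonical_newick(t3))
})
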