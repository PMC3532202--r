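test_that("single-site identical pair at zero distance gives ln(1/4)", {
  aln <- alignment(c(a = "A", b = "A"))
  tr <- ape::read.tree(text = "(a:0,b:0);")
  m <- subst_model("JC69")
  expect_equal(tree_loglik(tr, aln, m), log(0.25), tolerance = 1e-12)
})

test_that("pruning equals interior-state enumeration on small trees", {
  set.seed(21)
  models <- list(subst_model("JC69"),
                 subst_model("HKY85", freq = c(0.3, 0.2, 0.2, 0.3),
                             kappa = 3, alpha = 0.5, ncat = 2))
  for (ntaxa in 4:5) {
    for (rep in 1:2) {
      tr <- ape::rtree(ntaxa, br = function(n) runif(n, 0.05, 0.4))
      aln <- random_alignment(ntaxa, 12, seed = 100 * ntaxa + rep)
      rownames(aln$seq) <- tr$tip.label
      for (m in models) {
        expect_equal(tree_loglik(tr, aln, m), brute_loglik(tr, aln, m),
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("gaps and ambiguity codes act as missing data", {
  tr <- ape::rtree(4, br = function(n) runif(n, 0.05, 0.3))
  m <- matrix(c("A", "C", "G", "T",
                "-", "N", "Y", "A",
                "A", "A", "R", "G"), nrow = 4)
  rownames(m) <- tr$tip.label
  aln <- alignment(m)
  mod <- subst_model("HKY85", freq = c(.3, .2, .2, .3), kappa = 2)
  ll <- tree_loglik(tr, aln, mod)
  expect_true(is.finite(ll))
  expect_equal(ll, brute_loglik(tr, aln, mod), tolerance = 1e-8)
  # an all-missing column contributes exactly zero log-likelihood
  m2 <- cbind(m, rep("-", 4))
  expect_equal(tree_loglik(tr, alignment(m2), mod), ll, tolerance = 1e-10)
})

test_that("likelihood is invariant under re-rooting (pulley principle)", {
  set.seed(5)
  tr <- ape::rtree(6, br = function(n) runif(n, 0.05, 0.3))
  aln <- random_alignment(6, 40, seed = 9)
  rownames(aln$seq) <- tr$tip.label
  m <- subst_model("GTR", freq = c(.28, .22, .26, .24),
                   exch = c(1, 3, 0.6, 1.4, 4, 1))
  base <- tree_loglik(ape::unroot(tr), aln, m)
  for (tip in tr$tip.label[1:3]) {
    rr <- ape::root(ape::unroot(tr), outgroup = tip, resolve.root = TRUE)
    expect_equal(tree_loglik(rr, aln, m), base, tolerance = 1e-8)
  }
})

test_that("the site mask excludes columns from the likelihood", {
  set.seed(2)
  tr <- ape::rtree(5, br = function(n) runif(n, 0.05, 0.3))
  aln <- random_alignment(5, 30, seed = 3)
  rownames(aln$seq) <- tr$tip.label
  mask <- rep(c(TRUE, FALSE), 15)
  masked <- alignment(aln$seq, mask = mask)
  subset_only <- alignment(aln$seq[, mask])
  m <- subst_model("JC69")
  expect_equal(tree_loglik(tr, masked, m), tree_loglik(tr, subset_only, m),
               tolerance = 1e-10)
})

test_that("label mismatches are rejected", {
  aln <- random_alignment(4, 10, seed = 1)
  tr <- ape::rtree(4)
  tr$tip.label <- paste0("x", 1:4)
  expect_error(tree_loglik(tr, aln, subst_model("JC69")), "labels")
})

test_that("branch-length optimization ascends monotonically", {
  set.seed(11)
  tr <- ape::rtree(8, br = function(n) runif(n, 0.02, 0.3))
  m <- subst_model("HKY85", freq = c(.3, .2, .2, .3), kappa = 3)
  aln <- simulate_alignment(tr, m, 300, seed = 12)
  start <- ape::unroot(tr)
  start$edge.length <- rep(0.05, nrow(start$edge))
  o <- optimize_branch_lengths(start, aln, m, tol = 1e-7, max_sweeps = 30)
  expect_true(all(diff(o$trace) >= -1e-9))
  expect_gte(o$loglik, tree_loglik(start, aln, m))
})

test_that("identical sequences drive branch lengths to the lower bound", {
  m <- matrix(rep(strsplit("ACGTACGTACGTACGTACGT", "")[[1]], 4),
              nrow = 4, byrow = TRUE)
  rownames(m) <- paste0("t", 1:4)
  aln <- alignment(m)
  tr <- ape::unroot(ape::rtree(4))
  tr$tip.label <- paste0("t", 1:4)
  tr$edge.length <- rep(0.2, nrow(tr$edge))
  o <- optimize_branch_lengths(tr, aln, subst_model("JC69"))
  expect_true(all(o$tree$edge.length < 1e-6))
})

test_that("two-sequence JC distance matches the analytic estimator", {
  for (p in c(0.05, 0.10, 0.20)) {
    aln <- two_seq_alignment(p, 100)
    tr <- ape::read.tree(text = "(a:0.05,b:0.05);")
    o <- optimize_branch_lengths(tr, aln, subst_model("JC69"))
    expected <- -3 / 4 * log(1 - 4 / 3 * p)
    expect_equal(sum(o$tree$edge.length), expected, tolerance = 1e-6)
  }
})

test_that("likelihood agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  set.seed(31)
  tr <- ape::rtree(10, br = function(n) runif(n, 0.02, 0.3))
  m <- subst_model("HKY85", freq = c(.3, .2, .2, .3), kappa = 3,
                   alpha = 0.5, ncat = 4)
  aln <- simulate_alignment(tr, m, 400, seed = 7)
  dat <- phangorn::phyDat(aln$seq, type = "DNA")
  ref <- phangorn::pml(tr, dat, bf = m$freq, k = 4, shape = 0.5,
                       model = "HKY", Q = c(1, 3, 1, 1, 3, 1))
  expect_equal(tree_loglik(tr, aln, m), ref$logLik, tolerance = 1e-6)
})

test_that("BIC model selection prefers the generating family", {
  set.seed(17)
  tr <- ape::rtree(8, br = function(n) runif(n, 0.03, 0.25))
  wins <- 0
  for (rep in 1:3) {
    aln <- simulate_alignment(tr, subst_model("JC69"), 1500, seed = 40 + rep)
    sel <- select_model_bic(aln, candidate_models())
    if (sel$model$family == "JC69" && is.null(sel$model$alpha))
      wins <- wins + 1
  }
  expect_gte(wins, 2)
})

test_that("BIC arithmetic and trivial selection", {
  expect_equal(bic(-100, 5, 350), 200 + 5 * log(350))
  aln <- random_alignment(5, 60, seed = 2)
  one <- select_model_bic(aln, list(only = subst_model("K80", kappa = 2)))
  expect_equal(one$name, "only")
  expect_error(select_model_bic(aln, list()), "empty")
})
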