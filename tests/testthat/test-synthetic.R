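test_that("Yule trees have the right shape, height and determinism", {
  tr <- simulate_tree(4, seed = 1, height = 0.2)
  expect_equal(nrow(ape::unroot(tr)$edge), 5)  # 2n-3 unrooted branches
  expect_equal(max(ape::node.depth.edgelength(tr)), 0.2, tolerance = 1e-12)
  t1 <- simulate_tree(16, seed = 9)
  t2 <- simulate_tree(16, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_false(identical(ape::write.tree(simulate_tree(16, seed = 10)),
                         ape::write.tree(t1)))
  expect_error(simulate_tree(3), ">= 4")
})

test_that("a single planted origin makes the resistant set monophyletic", {
  tr <- simulate_tree(16, seed = 2)
  sc <- plant_origins(tr, k_kdr = 1, k_kdrhis = 0, k_superkdr = 0,
                      seed = 3, min_clade = 3)
  resist <- names(sc$classes)[sc$classes != "susceptible"]
  expect_gte(length(resist), 3)
  expect_true(satisfies_constraint(tr, resist))
  expect_equal(sc$counts[["kdr"]], 1L)
})

test_that("planted origin counts equal the origin-module clade counts", {
  grid <- list(c(3, 0, 0), c(2, 3, 0), c(2, 2, 2), c(1, 1, 1))
  for (i in seq_along(grid)) {
    k <- grid[[i]]
    tr <- simulate_tree(64, seed = 100 + i)
    sc <- plant_origins(tr, k[1], k[2], k[3], seed = 200 + i)
    expect_equal(unname(sc$counts),
                 c(count_maximal_clades(tr, sc$classes, "kdr")$count,
                   count_maximal_clades(tr, sc$classes, "kdr-his")$count,
                   count_maximal_clades(tr, sc$classes, "super-kdr")$count))
    expect_equal(unname(sc$counts), k)
    expect_true(any(sc$classes == "susceptible"))
  }
})

test_that("the nesting rule rejects super-kdr without kdr", {
  tr <- simulate_tree(16, seed = 4)
  expect_error(plant_origins(tr, k_kdr = 0, k_kdrhis = 0, k_superkdr = 1),
               "nesting")
})

test_that("simulated fragments follow the layout and class codons", {
  sim <- simulate_vssc_dataset(n_taxa = 24, k_kdr = 2, k_kdrhis = 2,
                               k_superkdr = 1, seed = 31)
  expect_equal(ncol(sim$aln$seq), 350)
  expect_equal(sim$layout$intron_end - sim$layout$intron_start, 250)
  expect_equal(sim$layout$intron_start, sim$layout$codon1014_offset + 6)
  # classification recovers every planted class exactly
  res <- classify_sequences(sim$aln, sim$layout)
  got <- setNames(res$assignments$class, res$assignments$label)
  expect_equal(got[names(sim$classes)], sim$classes)
  # ambiguity masking is confined to the intron and sized as requested
  excluded <- which(!sim$aln$mask)
  expect_length(excluded, round(0.1 * 250))
  expect_true(all(excluded > sim$layout$intron_start))
})

test_that("a zero exon rate freezes the non-focal exon columns", {
  tr <- simulate_tree(12, seed = 6, height = 0.5)
  sc <- plant_origins(tr, 1, 0, 0, seed = 7)
  sim <- simulate_vssc_alignment(sc, n_sites = 120, intron_len = 100,
                                 exon_rate = 0, seed = 8,
                                 ambiguous_frac = 0)
  exon_cols <- seq_len(20)
  focal <- c(sim$layout$codon918_offset + 1:3,
             sim$layout$codon1014_offset + 1:3)
  for (j in setdiff(exon_cols, focal))
    expect_length(unique(sim$aln$seq[, j]), 1)
  # the intron, by contrast, varies on a tall tree
  expect_gt(mean(apply(sim$aln$seq[, -exon_cols], 2,
                       function(x) length(unique(x)) > 1)), 0.2)
})

test_that("simulation is deterministic given the seed", {
  s1 <- simulate_vssc_dataset(n_taxa = 12, seed = 55, k_kdr = 1,
                              k_kdrhis = 1, k_superkdr = 0,
                              n_sites = 100, intron_len = 80)
  s2 <- simulate_vssc_dataset(n_taxa = 12, seed = 55, k_kdr = 1,
                              k_kdrhis = 1, k_superkdr = 0,
                              n_sites = 100, intron_len = 80)
  expect_identical(s1$aln$seq, s2$aln$seq)
  expect_identical(s1$classes, s2$classes)
  expect_identical(s1$aln$mask, s2$aln$mask)
})

test_that("tip frequencies converge to the stationary distribution", {
  # one long branch: tip composition approaches the model's pi
  tr <- ape::read.tree(text = "(a:8,b:8);")
  m <- subst_model("HKY85", freq = c(0.4, 0.15, 0.15, 0.3), kappa = 3)
  aln <- simulate_alignment(tr, m, 10000, seed = 91)
  obs <- table(factor(aln$seq[1, ], levels = c("A", "C", "G", "T"))) / 10000
  se <- sqrt(m$freq * (1 - m$freq) / 10000)
  expect_true(all(abs(as.numeric(obs) - m$freq) < 3.5 * se))
})

test_that("zero branch lengths copy the root state everywhere", {
  tr <- ape::rtree(6)
  tr$edge.length <- rep(0, nrow(tr$edge))
  aln <- simulate_alignment(tr, subst_model("JC69"), 50, seed = 3)
  for (j in seq_len(50)) expect_length(unique(aln$seq[, j]), 1)
})
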