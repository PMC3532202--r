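t_mono <- ape::read.tree(text = "((R1:1,R2:1):1,(S1:1,S2:1):1);")
t_para <- ape::read.tree(text = "((R1:1,S1:1):1,(R2:1,S2:1):1);")
st_mono <- c(R1 = "kdr", R2 = "kdr", S1 = "susceptible", S2 = "susceptible")
st_para <- c(R1 = "kdr", S1 = "susceptible", R2 = "kdr", S2 = "susceptible")

test_that("maximal-clade counting handles the canonical cases", {
  cm <- count_maximal_clades(t_mono, st_mono, "kdr")
  expect_equal(cm$count, 1)
  expect_equal(cm$clades[[1]], c("R1", "R2"))
  cp <- count_maximal_clades(t_para, st_para, "kdr")
  expect_equal(cp$count, 2)
  expect_equal(count_maximal_clades(t_mono, st_mono, "super-kdr")$count, 0)
  all_focal <- setNames(rep("kdr", 4), names(st_mono))
  expect_equal(count_maximal_clades(t_mono, all_focal, "kdr")$count, 1)
  expect_error(count_maximal_clades(ape::unroot(t_mono), st_mono, "kdr"),
               "rooted")
})

test_that("gains-only minimum matches intuition on the canonical cases", {
  expect_equal(min_gains(t_mono, st_mono, "kdr"), 1L)
  expect_equal(min_gains(t_para, st_para, "kdr"), 2L)
  all_focal <- setNames(rep("kdr", 4), names(st_mono))
  expect_equal(min_gains(t_mono, all_focal, "kdr"), 1L)  # gain on the stem
  expect_equal(min_gains(t_mono, st_mono, "super-kdr"), 0L)
})

test_that("parsimony counts equal exhaustive-labeling minima on small trees", {
  set.seed(14)
  for (case in 1:30) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    k <- sample(seq_len(n - 1), 1)
    states <- setNames(rep("susceptible", n), tr$tip.label)
    states[sample(n, k)] <- "kdr"
    expect_equal(min_gains(tr, states, "kdr"),
                 brute_min_gains(tr, states, "kdr"))
    expect_equal(fitch_changes(tr, states, "kdr"),
                 brute_fitch(tr, states, "kdr"))
    expect_equal(count_maximal_clades(tr, states, "kdr")$count,
                 brute_clades(tr, states, "kdr"))
    # a gain per maximal clade always suffices
    expect_lte(min_gains(tr, states, "kdr"),
               count_maximal_clades(tr, states, "kdr")$count)
  }
})

test_that("origin counts are invariant to child rotation", {
  set.seed(8)
  tr <- ape::rtree(10)
  states <- setNames(sample(c("kdr", "susceptible"), 10, replace = TRUE),
                     tr$tip.label)
  states[1] <- "kdr"
  lad <- ape::ladderize(tr)
  expect_equal(count_maximal_clades(tr, states, "kdr")$count,
               count_maximal_clades(lad, states, "kdr")$count)
  expect_equal(min_gains(tr, states, "kdr"),
               min_gains(lad, states, "kdr"))
  expect_equal(fitch_changes(tr, states, "kdr"),
               fitch_changes(lad, states, "kdr"))
})

test_that("the origin report covers all classes with root sensitivity", {
  sim <- simulate_vssc_dataset(n_taxa = 20, k_kdr = 2, k_kdrhis = 1,
                               k_superkdr = 1, seed = 21, n_sites = 150,
                               intron_len = 100)
  rep_ <- origin_report(sim$tree, sim$classes)
  expect_s3_class(rep_, "origin_report")
  expect_setequal(rep_$class, c("kdr", "kdr-his", "super-kdr"))
  expect_true(all(rep_$clades_min_over_roots <= rep_$clades))
  expect_true(all(rep_$clades <= rep_$clades_max_over_roots))
  expect_true(all(rep_$min_gains <= rep_$clades))
  expect_equal(rep_$clades[rep_$class == "kdr"], 2L)
})

test_that("super-kdr haplotypes pair with kdr haplotypes via intron identity", {
  ref <- simulate_reference_haplotypes(seed = 7)
  pairs <- derive_sequential_pairs(ref$catalog)
  expect_equal(nrow(pairs), 3)
  expect_true(all(pairs$paired))
  got <- setNames(pairs$kdr, pairs$super_kdr)
  expect_equal(got[["super-kdr1"]], "kdr2")
  expect_equal(got[["super-kdr2"]], "kdr3")
  expect_equal(got[["super-kdr3"]], "kdr1")
  # no super-kdr at all -> empty
  cat0 <- ref$catalog
  cat0$records <- cat0$records[cat0$records$class != "super-kdr", ]
  expect_equal(nrow(derive_sequential_pairs(cat0)), 0)
  # super-kdr alone in its intron group -> flagged unpaired
  cat1 <- ref$catalog
  cat1$records$intron[cat1$records$name == "super-kdr1"] <-
    paste(rep("A", nchar(cat1$records$intron[1])), collapse = "")
  p1 <- derive_sequential_pairs(cat1)
  expect_false(p1$paired[p1$super_kdr == "super-kdr1"])
  expect_true(is.na(p1$kdr[p1$super_kdr == "super-kdr1"]))
})
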