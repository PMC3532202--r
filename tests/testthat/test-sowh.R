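test_that("the observed delta is the difference of the two search scores", {
  d <- observed_delta(-1330.985567, -1524.707019)
  expect_equal(d, 193.721452, tolerance = 1e-6)
  expect_equal(round(d, 2), 193.72)
  expect_equal(observed_delta(-5, -5), 0)
  # invariant to adding a constant to both scores
  expect_equal(observed_delta(-1330.985567 + 7, -1524.707019 + 7), d,
               tolerance = 1e-9)
  expect_error(observed_delta(-10, -9), "constrained search beat")
})

test_that("the Monte-Carlo p-value follows the tie and bound conventions", {
  deltas <- seq(0.5, 50, length.out = 100)
  out <- p_value(193.72, deltas)
  expect_equal(out$p, 0)
  expect_true(out$is_bound)
  expect_equal(out$display, "p < 0.01")
  expect_equal(out$p_corrected, 1 / 101)
  # observed zero: every nonnegative replicate counts
  expect_equal(p_value(0, deltas)$p, 1)
  # a replicate equal to the observed value counts against rejection
  expect_gte(p_value(max(deltas), deltas)$p, 1 / length(deltas))
  # monotonicity: larger observed delta never increases p
  ps <- vapply(c(0, 1, 10, 25, 49, 60), function(o) p_value(o, deltas)$p,
               numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(p_value(1, numeric(0)), "non-empty")
})

test_that("sowh_test satisfies its invariants and is seed-reproducible", {
  sim <- simulate_vssc_dataset(n_taxa = 12, k_kdr = 1, k_kdrhis = 0,
                               k_superkdr = 0, seed = 5, n_sites = 150,
                               intron_len = 100, min_clade = 3)
  resist <- names(sim$classes)[sim$classes != "susceptible"]
  s1 <- sowh_test(sim$aln, sim$model, resist, n_reps = 4, seed = 77,
                  search_reps = 2)
  expect_s3_class(s1, "sowh")
  expect_gte(s1$observed_delta, 0)
  expect_true(all(s1$replicate_deltas >= 0))
  expect_true(s1$p_value >= 0 && s1$p_value <= 1)
  expect_length(s1$replicate_deltas, 4)
  expect_true(satisfies_constraint(s1$constrained_tree, resist))
  s2 <- sowh_test(sim$aln, sim$model, resist, n_reps = 4, seed = 77,
                  search_reps = 2)
  expect_identical(s1$replicate_deltas, s2$replicate_deltas)
  expect_identical(s1$observed_delta, s2$observed_delta)
  expect_error(sowh_test(sim$aln, sim$model, resist[1], n_reps = 2),
               "at least two")
})

test_that("scattering the constraint set across clades produces a bound p", {
  # strong multi-origin signal: resistant tips in three separated clades
  sim <- simulate_vssc_dataset(n_taxa = 24, k_kdr = 3, k_kdrhis = 0,
                               k_superkdr = 0, seed = 11, n_sites = 300,
                               intron_len = 220, min_clade = 2,
                               height = 0.2)
  resist <- names(sim$classes)[sim$classes != "susceptible"]
  s <- sowh_test(sim$aln, sim$model, resist, n_reps = 10, seed = 3,
                 search_reps = 2)
  expect_true(s$p_is_bound)
  expect_match(s$p_display, "^p < ")
  expect_gt(s$observed_delta, max(s$replicate_deltas))
})
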