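test_that("codon translation honours the standard code and ambiguity", {
  expect_equal(translate_codon("ATG"), "M")
  expect_equal(translate_codon("TTT"), "F")
  expect_equal(translate_codon("CTT"), "L")
  expect_equal(translate_codon("CAY"), "H")   # CAT/CAC both His
  expect_equal(translate_codon("TTR"), "L")   # TTA/TTG both Leu
  expect_equal(translate_codon("RAT"), "?")   # AAT=N vs GAT=D disagree
  expect_equal(translate_codon("A-G"), "?")
  expect_equal(translate_codon("NNN"), "?")
  expect_error(translate_codon("AXG"), "non-nucleotide")
  expect_error(translate_codon("AT"), "3-character")
})

test_that("allele classification is total with image in the five classes", {
  expect_equal(classify_allele("M", "F"), "kdr")
  expect_equal(classify_allele("T", "F"), "super-kdr")
  expect_equal(classify_allele("M", "L"), "susceptible")
  expect_equal(classify_allele("M", "H"), "kdr-his")
  letters_ <- c("M", "T", "L", "F", "H", "K", "*", "?")
  classes <- c("susceptible", "kdr", "kdr-his", "super-kdr", "other")
  for (a in letters_) for (b in letters_)
    expect_true(classify_allele(a, b) %in% classes)
  expect_equal(classify_allele("?", "F"), "other")
  expect_equal(classify_allele("T", "H"), "other")
})

test_that("feature extraction reads codons and the aligned intron slice", {
  lay <- fragment_layout(codon1014_offset = 0, intron_start = 6,
                         intron_end = 30, canonical_geometry = TRUE)
  s <- paste0("TTAGGG", paste(rep("ACGT", 6), collapse = ""))
  f <- extract_features(s, lay)
  expect_equal(f$aa1014, "L")
  expect_equal(f$intron, substr(s, 7, 30))
  s2 <- paste0("CATGGG", substr(s, 7, 30))
  expect_equal(extract_features(s2, lay)$aa1014, "H")
  # gap columns inside the intron are retained verbatim
  s3 <- paste0("TTAGGG", "AC--", substr(s, 11, 30))
  expect_equal(extract_features(s3, lay)$intron, paste0("AC--", substr(s, 11, 30)))
  expect_error(extract_features("TTAGG", lay), "exceed")
})

test_that("canonical fragment geometry is asserted only when flagged", {
  expect_error(fragment_layout(0, 5, 30, canonical_geometry = TRUE),
               "three bases downstream")
  expect_s3_class(fragment_layout(0, 5, 30), "fragment_layout")
  expect_error(fragment_layout(0, 10, 10), "intron_start")
})

test_that("intron grouping reproduces the published sharing structure", {
  ref <- simulate_reference_haplotypes(seed = 42)
  g <- group_by_intron(ref$catalog)
  expect_length(g$groups, 8)
  grp_kdr2 <- g$groups[[g$group_of[["kdr2"]]]]
  expect_setequal(grp_kdr2, c("kdr2", "super-kdr1", "kdr-his4", "v39"))
  # every super-kdr haplotype shares its intron group with a kdr haplotype
  rec <- ref$catalog$records
  for (s in rec$name[rec$class == "super-kdr"]) {
    members <- g$groups[[g$group_of[[s]]]]
    expect_true(any(members %in% rec$name[rec$class == "kdr"]))
  }
})

test_that("intron grouping is a partition ordered by discovery", {
  set.seed(1)
  for (rep in 1:5) {
    n <- sample(5:20, 1)
    rec <- data.frame(
      label = paste0("h", seq_len(n)),
      intron = sample(paste0("INT", 1:4), n, replace = TRUE),
      stringsAsFactors = FALSE)
    g <- group_by_intron(rec)
    members <- unlist(g$groups)
    expect_setequal(members, rec$label)        # covering
    expect_equal(anyDuplicated(members), 0L)   # disjoint
    expect_equal(g$groups[[1]][1], "h1")       # first-discovered leads
  }
  g1 <- group_by_intron(data.frame(label = "only", intron = "AAA"))
  expect_length(g1$groups, 1)
})

test_that("naming follows discovery order and is idempotent", {
  lay <- fragment_layout(codon1014_offset = 6, intron_start = 12,
                         intron_end = 20, codon918_offset = 0)
  mk <- function(c918, c1014, intron) paste0(c918, "AAA", c1014, "GGG", intron)
  seqs <- c(s1 = mk("ATG", "CTT", "AAAAAAAA"),
            k1 = mk("ATG", "TTT", "CCCCCCCC"),
            k2 = mk("ATG", "TTT", "GGGGGGGG"),
            k3 = mk("ATG", "TTT", "TTTTTTTT"),
            s2 = mk("ATG", "CTT", "ACACACAC"))
  res <- classify_sequences(seqs, lay)
  expect_equal(res$assignments$name,
               c("v1", "kdr1", "kdr2", "kdr3", "v2"))
  # replay: same names, catalog unchanged
  rec <- kdrorigins:::build_records(seqs, lay)
  again <- assign_names(rec, res$catalog)
  expect_equal(again$names, res$assignments$name)
  expect_identical(again$catalog$records, res$catalog$records)
  # a record matching an existing (intron, codon state) reuses the name
  res2 <- classify_sequences(c(new = mk("ATG", "TTT", "CCCCCCCC")), lay,
                             catalog = res$catalog)
  expect_equal(res2$assignments$name, "kdr1")
  expect_equal(nrow(res2$catalog$records), nrow(res$catalog$records))
})

test_that("classification round-trip is deterministic", {
  sim <- simulate_vssc_dataset(n_taxa = 16, k_kdr = 1, k_kdrhis = 1,
                               k_superkdr = 1, seed = 8, n_sites = 120,
                               intron_len = 80)
  r1 <- classify_sequences(sim$aln, sim$layout)
  r2 <- classify_sequences(sim$aln, sim$layout)
  expect_identical(r1$assignments, r2$assignments)
  got <- setNames(r1$assignments$class, r1$assignments$label)
  expect_equal(got[names(sim$classes)], sim$classes)
})
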