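# Synthetic-data generator: Yule trees, planted resistance-origin
# scenarios (kdr / kdr-his gains on branches, super-kdr nested inside kdr
# lineages), and Vssc-like intron+exon alignments with a hypervariable
# intron, a slow exon, deterministic class codons at 918/1014, and a
# configurable fraction of alignment-ambiguous intron columns.

#' Simulate a pure-birth (Yule) tree
#'
#' Branch lengths are rescaled so the maximum root-to-tip path equals
#' `height` (substitutions per site at the neutral intron rate).
#'
#' @param n_taxa Number of tips (`>= 4`).
#' @param birth Birth rate of the Yule process.
#' @param seed Optional integer seed.
#' @param height Target tree height.
#' @return A rooted `phylo` with tip labels `t1..tn`.
#' @export
simulate_tree <- function(n_taxa, birth = 1, seed = NULL, height = 0.1) {
  if (n_taxa < 4) stop("n_taxa must be >= 4")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = birth, death = 0)
  tr$edge.length <- tr$edge.length *
    (height / max(ape::node.depth.edgelength(tr)))
  tr
}

edge_tipsets <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- i
  for (i in seq_len(nrow(po$edge)))
    below[[po$edge[i, 1]]] <- c(below[[po$edge[i, 1]]],
                                below[[po$edge[i, 2]]])
  lapply(seq_len(nrow(tree$edge)),
         function(i) sort(below[[tree$edge[i, 2]]]))
}

#' Plant resistance origins on a tree
#'
#' Samples origin branches for the requested numbers of kdr, kdr-his and
#' super-kdr gains: kdr and kdr-his origin subtrees are disjoint;
#' each super-kdr origin is nested strictly inside a kdr origin subtree
#' (the sequential model: M918T arises on an L1014F background) and leaves
#' at least one plain-kdr tip in its host clade; at least one susceptible
#' tip always remains.  The realized per-class independent-clade counts on
#' the true tree are checked to equal the request.
#'
#' @param tree Rooted `phylo` (e.g. [simulate_tree()]).
#' @param k_kdr,k_kdrhis,k_superkdr Requested origin counts.
#' @param seed Optional integer seed.
#' @param min_clade Minimum number of tips under each origin branch.
#' @param max_tries Resampling attempts before declaring infeasibility.
#' @return An object of class `sim_scenario`: `tree`, `classes` (named tip
#'   vector), `origins` (edges per class), `counts`.
#' @export
plant_origins <- function(tree, k_kdr = 2, k_kdrhis = 3, k_superkdr = 2,
                          seed = NULL, min_clade = 1, max_tries = 500) {
  if (!is.null(seed)) set.seed(seed)
  if (k_superkdr > 0 && k_kdr == 0)
    stop("super-kdr origins require a kdr origin (nesting rule)")
  if (any(c(k_kdr, k_kdrhis, k_superkdr) < 0)) stop("negative origin count")
  ntip <- length(tree$tip.label)
  ts <- edge_tipsets(tree)
  sizes <- lengths(ts)
  cand <- which(sizes < ntip & sizes >= min_clade)
  for (attempt in seq_len(max_tries)) {
    pool <- sample(cand)
    picked <- integer(0)
    covered <- integer(0)
    for (e in pool) {
      if (length(picked) == k_kdr + k_kdrhis) break
      if (length(intersect(ts[[e]], covered))) next
      if (length(covered) + sizes[e] >= ntip) next  # keep a susceptible tip
      picked <- c(picked, e)
      covered <- c(covered, ts[[e]])
    }
    if (length(picked) < k_kdr + k_kdrhis) next
    kdr_e <- picked[seq_len(k_kdr)]
    his_e <- if (k_kdrhis) picked[k_kdr + seq_len(k_kdrhis)] else integer(0)
    sk_e <- integer(0)
    if (k_superkdr > 0) {
      sk_cov <- integer(0)
      in_kdr <- which(vapply(seq_along(ts), function(e) {
        sizes[e] >= min_clade &&
          any(vapply(kdr_e, function(h)
            all(ts[[e]] %in% ts[[h]]) && sizes[e] < sizes[h], logical(1)))
      }, logical(1)))
      in_kdr <- sample(in_kdr)
      for (e in in_kdr) {
        if (length(sk_e) == k_superkdr) break
        if (length(intersect(ts[[e]], sk_cov))) next
        host <- kdr_e[vapply(kdr_e, function(h)
          all(ts[[e]] %in% ts[[h]]), logical(1))][1]
        left <- setdiff(ts[[host]], c(sk_cov, ts[[e]]))
        if (!length(left)) next  # host clade must keep a kdr tip
        sk_e <- c(sk_e, e)
        sk_cov <- c(sk_cov, ts[[e]])
      }
      if (length(sk_e) < k_superkdr) next
    }
    classes <- setNames(rep("susceptible", ntip), tree$tip.label)
    for (e in kdr_e) classes[ts[[e]]] <- "kdr"
    for (e in his_e) classes[ts[[e]]] <- "kdr-his"
    for (e in sk_e) classes[ts[[e]]] <- "super-kdr"
    got <- vapply(c(kdr = "kdr", `kdr-his` = "kdr-his",
                    `super-kdr` = "super-kdr"),
                  function(cl) count_maximal_clades(tree, classes, cl)$count,
                  integer(1))
    if (got[["kdr"]] == k_kdr && got[["kdr-his"]] == k_kdrhis &&
        got[["super-kdr"]] == k_superkdr &&
        any(classes == "susceptible")) {
      return(structure(list(tree = tree, classes = classes,
                            origins = list(kdr = kdr_e, `kdr-his` = his_e,
                                           `super-kdr` = sk_e),
                            counts = got),
                       class = "sim_scenario"))
    }
  }
  stop("could not place ", k_kdr, "/", k_kdrhis, "/", k_superkdr,
       " origins on this tree (infeasible configuration)")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Planted-origin scenario:", length(x$classes), "tips\n")
  print(table(x$classes))
  cat("  independent origins:",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

CLASS_CODONS <- list(
  susceptible  = c(c918 = "ATG", c1014 = "CTT"),
  kdr          = c(c918 = "ATG", c1014 = "TTT"),
  `kdr-his`    = c(c918 = "ATG", c1014 = "CAT"),
  `super-kdr`  = c(c918 = "ACG", c1014 = "TTT"))

#' Simulate a Vssc-like intron+exon alignment from a scenario
#'
#' The intron evolves neutrally under the generating model; the remaining
#' exon columns evolve at `exon_rate` times the intron rate; the 918 and
#' 1014 codons are overwritten deterministically from each tip's planted
#' class (CTT Leu -> TTT Phe for kdr, -> CAT His for kdr-his, plus
#' ATG Met -> ACG Thr at 918 for super-kdr), so classification truth is
#' unambiguous.  A fraction of intron columns is flagged
#' alignment-ambiguous and excluded by the mask (the "strict" matrix).
#'
#' @param scenario A [plant_origins()] result.
#' @param model Generating [subst_model()]; default HKY85 with AT-rich
#'   insect-like base frequencies and kappa = 3.
#' @param n_sites Total fragment length.
#' @param intron_len Number of intron columns.
#' @param exon_rate Exon/intron rate multiplier in `[0, 1]`.
#' @param ambiguous_frac Fraction of intron columns flagged ambiguous.
#' @param seed Optional integer seed.
#' @return A list of class `vssc_sim`: `aln` (masked [alignment()]),
#'   `layout`, `classes`, `tree`, `model`, `scenario`.
#' @export
simulate_vssc_alignment <- function(scenario, model = NULL, n_sites = 350,
                                    intron_len = 250, exon_rate = 0.1,
                                    ambiguous_frac = 0.1, seed = NULL) {
  if (!inherits(scenario, "sim_scenario")) stop("scenario must come from plant_origins")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(model))
    model <- subst_model("HKY85", freq = c(0.3, 0.2, 0.2, 0.3), kappa = 3)
  exon_len <- n_sites - intron_len
  if (exon_len < 12) stop("need at least 12 exon columns")
  layout <- fragment_layout(codon1014_offset = exon_len - 6,
                            intron_start = exon_len, intron_end = n_sites,
                            codon918_offset = exon_len - 12,
                            canonical_geometry = TRUE)
  rates <- c(rep(exon_rate, exon_len), rep(1, intron_len))
  aln <- simulate_alignment(scenario$tree, model, n_sites,
                            site_rates = rates)
  m <- aln$seq
  for (lab in rownames(m)) {
    cc <- CLASS_CODONS[[scenario$classes[[lab]]]]
    if (is.null(cc)) cc <- CLASS_CODONS$susceptible
    m[lab, layout$codon918_offset + 1:3] <- strsplit(cc[["c918"]], "")[[1]]
    m[lab, layout$codon1014_offset + 1:3] <- strsplit(cc[["c1014"]], "")[[1]]
  }
  mask <- rep(TRUE, n_sites)
  n_amb <- round(ambiguous_frac * intron_len)
  if (n_amb > 0)
    mask[sample(seq(exon_len + 1, n_sites), n_amb)] <- FALSE
  structure(list(aln = alignment(m, mask = mask), layout = layout,
                 classes = scenario$classes, tree = scenario$tree,
                 model = model, scenario = scenario),
            class = "vssc_sim")
}

#' One-call synthetic data set
#'
#' Convenience preset: Yule tree, planted origins, simulated fragment.
#' The default mirrors the geometry the pipeline targets (64 taxa,
#' 350 sites of which 250 are intron) with a multiple-origin scenario
#' (2 kdr, 3 kdr-his, 2 super-kdr); `k_kdr = 1, k_kdrhis = 0,
#' k_superkdr = 0` gives a single-origin null data set.
#'
#' @param n_taxa Tips in the Yule tree.
#' @param k_kdr,k_kdrhis,k_superkdr Planted origin counts.
#' @param seed Integer seed driving the whole construction.
#' @param height Tree height (root-to-tip, intron substitutions/site).
#' @param min_clade Minimum tips per origin clade (see [plant_origins()]).
#' @param ... Passed to [simulate_vssc_alignment()].
#' @return A `vssc_sim` list (see [simulate_vssc_alignment()]).
#' @export
simulate_vssc_dataset <- function(n_taxa = 64, k_kdr = 2, k_kdrhis = 3,
                                  k_superkdr = 2, seed = NULL,
                                  height = 0.1, min_clade = 1, ...) {
  if (!is.null(seed)) set.seed(seed)
  tr <- simulate_tree(n_taxa, height = height)
  sc <- plant_origins(tr, k_kdr, k_kdrhis, k_superkdr,
                      min_clade = min_clade)
  simulate_vssc_alignment(sc, ...)
}

# The published intron-sharing structure used as a compact reference
# fixture: 15 haplotypes in 8 intron-identity columns, each super-kdr
# sharing its column with a kdr.  Sequences are synthetic: the intron
# strings are random but the sharing pattern and codon states are real.
REFERENCE_SHARING <- list(
  A = c("kdr1", "super-kdr3"),
  B = c("v39", "kdr2", "kdr-his4", "super-kdr1"),
  C = c("kdr3", "super-kdr2"),
  D = c("v40", "kdr4"),
  E = c("v85", "kdr5"),
  F = c("v54", "kdr-his1"),
  G = c("v41", "kdr-his2"),
  H = c("v42", "kdr-his3"))

#' Synthetic sequences realizing the published intron-sharing structure
#'
#' Generates one sequence per haplotype of the 15-haplotype reference
#' sharing table (8 intron-identity columns; every super-kdr paired with a
#' kdr).  Introns are random but identical within a column and distinct
#' between columns; 918/1014 codons follow each haplotype's class.
#'
#' @param seed Integer seed.
#' @param intron_len Intron length in the synthetic fragment.
#' @return List with `sequences` (named), `layout`, `expected_groups`.
#' @export
simulate_reference_haplotypes <- function(seed = 1, intron_len = 40) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  repeat {
    introns <- vapply(seq_along(REFERENCE_SHARING), function(i)
      paste(sample(bases, intron_len, replace = TRUE), collapse = ""),
      character(1))
    if (!anyDuplicated(introns)) break
  }
  names(introns) <- names(REFERENCE_SHARING)
  spacer <- paste(sample(bases, 3, replace = TRUE), collapse = "")
  after1014 <- paste(sample(bases, 3, replace = TRUE), collapse = "")
  layout <- fragment_layout(codon1014_offset = 6, intron_start = 12,
                            intron_end = 12 + intron_len,
                            codon918_offset = 0, canonical_geometry = TRUE)
  seqs <- character(0)
  for (col in names(REFERENCE_SHARING)) {
    for (h in REFERENCE_SHARING[[col]]) {
      cl <- if (startsWith(h, "super-kdr")) "super-kdr"
            else if (startsWith(h, "kdr-his")) "kdr-his"
            else if (startsWith(h, "kdr")) "kdr" else "susceptible"
      cc <- CLASS_CODONS[[cl]]
      seqs[[h]] <- paste0(cc[["c918"]], spacer, cc[["c1014"]], after1014,
                          introns[[col]])
    }
  }
  rec <- build_records(seqs, layout)
  cat_ <- haplotype_catalog()
  cat_$records <- data.frame(name = rec$label, class = rec$class,
                             aa918 = rec$aa918, aa1014 = rec$aa1014,
                             intron = rec$intron, sequence = rec$sequence,
                             stringsAsFactors = FALSE)
  list(sequences = seqs, layout = layout,
       expected_groups = REFERENCE_SHARING, catalog = cat_)
}
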