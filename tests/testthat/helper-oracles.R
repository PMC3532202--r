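# Independent oracles used by the tests: brute-force likelihood by
# enumeration of interior states, exhaustive-labeling parsimony counts,
# and a subset-relation clade scan.  These deliberately share no code with
# the package's implementations.

# enumerate interior-state assignments site by site
brute_loglik <- function(tree, aln, model) {
  tr <- if (ape::is.rooted(tree) && length(tree$tip.label) > 2)
    ape::unroot(tree) else tree
  ntip <- length(tr$tip.label)
  nint <- tr$Nnode
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
  rates <- kdrorigins:::gamma_rates(model)
  Ps <- lapply(rates, function(r)
    lapply(seq_len(nrow(tr$edge)), function(i)
      transition_matrix(model, tr$edge.length[i], r)))
  mseq <- aln$seq[tr$tip.label, aln$mask, drop = FALSE]
  mask_of <- kdrorigins:::IUPAC_MASK
  comp <- function(ch) which(bitwAnd(mask_of[[ch]], c(1L, 2L, 4L, 8L)) > 0)
  states <- as.matrix(expand.grid(rep(list(1:4), nint)))
  lnl <- 0
  for (s in seq_len(ncol(mseq))) {
    tipsets <- lapply(seq_len(ntip), function(i) comp(mseq[i, s]))
    sitelik <- 0
    for (r in seq_along(rates)) {
      for (a in seq_len(nrow(states))) {
        st <- function(node) {
          if (node <= ntip) tipsets[[node]] else states[a, node - ntip]
        }
        term <- model$freq[st(root)][1]
        if (length(st(root)) > 1) next  # root is interior, always length 1
        for (i in seq_len(nrow(tr$edge))) {
          pa <- st(tr$edge[i, 1]); ch <- st(tr$edge[i, 2])
          term <- term * sum(Ps[[r]][[i]][pa, ch])
        }
        sitelik <- sitelik + term / length(rates)
      }
    }
    lnl <- lnl + log(sitelik)
  }
  lnl
}

# exhaustive minimum gains: no losses allowed, non-focal stem above the root
brute_min_gains <- function(tree, states, class) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  focal <- as.integer(states[tree$tip.label] == class)
  root <- ntip + 1
  lab <- as.matrix(expand.grid(rep(list(0:1), nint)))
  best <- Inf
  for (a in seq_len(nrow(lab))) {
    st <- c(focal, lab[a, ])
    gains <- st[root] # stem transition if root focal
    ok <- TRUE
    for (i in seq_len(nrow(tree$edge))) {
      pa <- st[tree$edge[i, 1]]; ch <- st[tree$edge[i, 2]]
      if (pa == 1 && ch == 0) { ok <- FALSE; break }
      if (pa == 0 && ch == 1) gains <- gains + 1
    }
    if (ok) best <- min(best, gains)
  }
  as.integer(best)
}

# exhaustive Fitch count: free root, gains and losses both allowed
brute_fitch <- function(tree, states, class) {
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  focal <- as.integer(states[tree$tip.label] == class)
  lab <- as.matrix(expand.grid(rep(list(0:1), nint)))
  best <- Inf
  for (a in seq_len(nrow(lab))) {
    st <- c(focal, lab[a, ])
    ch <- sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
    best <- min(best, ch)
  }
  as.integer(best)
}

# maximal pure clades via tip-set subset relations
brute_clades <- function(tree, states, class) {
  ntip <- length(tree$tip.label)
  focal <- states[tree$tip.label] == class
  sets <- list()
  for (node in seq_len(ntip + tree$Nnode)) {
    tips <- if (node <= ntip) node
            else which(tree$tip.label %in%
                       ape::extract.clade(tree, node)$tip.label)
    if (all(focal[tips])) sets[[length(sets) + 1]] <- sort(tips)
  }
  if (!length(sets)) return(0L)
  maximal <- vapply(seq_along(sets), function(i) {
    !any(vapply(seq_along(sets), function(j)
      j != i && all(sets[[i]] %in% sets[[j]]) &&
        length(sets[[j]]) > length(sets[[i]]), logical(1)))
  }, logical(1))
  sum(maximal)
}

# random alignment helper over plain ACGT
random_alignment <- function(ntaxa, nsites, seed) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), ntaxa * nsites, replace = TRUE),
              nrow = ntaxa)
  rownames(m) <- paste0("t", seq_len(ntaxa))
  alignment(m)
}

# two-sequence alignment with an exact proportion of differing sites
two_seq_alignment <- function(p, nsites = 100) {
  s1 <- rep(c("A", "C", "G", "T"), length.out = nsites)
  s2 <- s1
  k <- round(p * nsites)
  if (k > 0) {
    swap <- c(A = "G", C = "T", G = "A", T = "C")
    s2[seq_len(k)] <- swap[s1[seq_len(k)]]
  }
  m <- rbind(a = s1, b = s2)
  alignment(m)
}
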