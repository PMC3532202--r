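# Replicated heuristic ML topology search (random-perturbation + NNI
# hill-climbing), optionally under a monophyly constraint enforced by
# rejection, plus nonparametric bootstrap support and midpoint rooting.

#' Does a tree contain a given monophyly bipartition?
#'
#' TRUE iff the unrooted tree has a branch whose induced bipartition
#' separates exactly the constraint set from its complement.  A single tip
#' or the full taxon set is trivially monophyletic.
#'
#' @param tree An ape `phylo` tree.
#' @param constraint Character vector of tip labels.
#' @return Logical scalar.
#' @export
satisfies_constraint <- function(tree, constraint) {
  if (length(constraint) == 0) stop("constraint must be non-empty")
  unknown <- setdiff(constraint, tree$tip.label)
  if (length(unknown))
    stop("constraint names unknown taxa: ", paste(unknown, collapse = ", "))
  n <- length(tree$tip.label)
  K <- length(unique(constraint))
  if (K <= 1 || K >= n - 1 || n <= 3) return(TRUE)
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  flags <- as.integer(tr$tip.label %in% constraint)
  eng_satisfies(n, tr$edge, flags)
}

# JC-corrected pairwise distances; saturated/NA entries are capped so NJ
# always gets a finite matrix
jc_distance <- function(aln) {
  m <- aln$seq[, aln$mask, drop = FALSE]
  d <- ape::dist.dna(ape::as.DNAbin(m), model = "JC69",
                     pairwise.deletion = TRUE)
  d <- as.matrix(d)
  bad <- !is.finite(d)
  if (any(bad)) {
    mx <- max(d[!bad], 0.5)
    d[bad] <- 2 * mx + 1
  }
  diag(d) <- 0
  d
}

#' Neighbor-joining starting tree
#'
#' @param aln A [alignment()].
#' @return An unrooted `phylo` tree with nonnegative branch lengths.
#' @export
nj_tree <- function(aln) {
  if (n_taxa(aln) == 2) {
    d <- jc_distance(aln)[1, 2]
    return(ape::read.tree(text = sprintf("(%s:%f,%s:%f);",
                                         aln_labels(aln)[1], d / 2,
                                         aln_labels(aln)[2], d / 2)))
  }
  if (n_taxa(aln) == 3) {
    d <- jc_distance(aln)
    l <- aln_labels(aln)
    b <- pmax(c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
                (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
                (d[1, 3] + d[2, 3] - d[1, 2]) / 2), 1e-8)
    return(ape::read.tree(text = sprintf("(%s:%f,%s:%f,%s:%f);",
                                         l[1], b[1], l[2], b[2], l[3], b[3])))
  }
  tr <- ape::nj(jc_distance(aln))
  tr <- ape::unroot(tr)
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  tr
}

# Constraint-compatible starting tree: a rooted average-linkage subtree for
# the constrained taxa grafted onto an NJ backbone of the remaining taxa,
# built through a placeholder leaf carrying the subtree's mean distances.
constrained_start_tree <- function(aln, constraint) {
  labs <- aln_labels(aln)
  C <- intersect(labs, constraint)
  D <- setdiff(labs, C)
  if (length(C) <= 1 || length(D) == 0) return(nj_tree(aln))
  d <- jc_distance(aln)
  sub_nwk <- if (length(C) == 2) {
    sprintf("(%s:%f,%s:%f)", C[1], max(d[C[1], C[2]], 2e-8) / 2,
            C[2], max(d[C[1], C[2]], 2e-8) / 2)
  } else {
    hc <- hclust(as.dist(d[C, C]), method = "average")
    tr <- ape::as.phylo(hc)
    tr$edge.length <- pmax(tr$edge.length, 1e-8)
    sub("; *$", "", ape::write.tree(tr))
  }
  ph <- "zz_constraint_clade_zz"
  pd <- rowMeans(d[D, C, drop = FALSE])
  dx <- rbind(cbind(d[D, D, drop = FALSE], pd), c(pd, 0))
  rownames(dx) <- colnames(dx) <- c(D, ph)
  bk <- if (length(D) == 1) {
    sprintf("(%s:%f,%s:%f);", D[1], dx[1, 2] / 2, ph, dx[1, 2] / 2)
  } else if (length(D) == 2) {
    sprintf("(%s:%f,%s:%f,%s:%f);", D[1], 0.01, D[2], 0.01, ph, 0.01)
  } else {
    tr <- ape::unroot(ape::nj(dx))
    tr$edge.length <- pmax(tr$edge.length, 1e-8)
    ape::write.tree(tr)
  }
  nwk <- sub(paste0(ph, ":([0-9eE.+-]+)"), paste0(sub_nwk, ":\\1"), bk)
  out <- ape::read.tree(text = nwk)
  out$edge.length <- pmax(out$edge.length, 1e-8)
  if (ape::is.rooted(out) && length(out$tip.label) > 3) out <- ape::unroot(out)
  out
}

# deterministic canonical Newick of the unrooted topology (no branch
# lengths): children ordered by smallest descendant label; used for
# equal-likelihood tie-breaking and topology identity
canonical_newick <- function(tree) {
  tr <- if (ape::is.rooted(tree) && length(tree$tip.label) > 2)
    ape::unroot(tree) else tree
  ntip <- length(tr$tip.label)
  if (ntip > 3) {
    # fix the basal arrangement: root at the smallest tip label so the
    # string depends only on the unrooted topology
    g <- sort(tr$tip.label)[1]
    tr <- ape::root(tr, outgroup = g, resolve.root = TRUE)
  }
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  rec <- function(node) {
    if (node <= ntip) {
      lab <- tr$tip.label[node]
      return(list(str = lab, min = lab))
    }
    ch <- lapply(kids[[as.character(node)]], rec)
    ord <- order(vapply(ch, `[[`, character(1), "min"))
    ch <- ch[ord]
    list(str = paste0("(", paste(vapply(ch, `[[`, character(1), "str"),
                                 collapse = ","), ")"),
         min = ch[[1]]$min)
  }
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
  paste0(rec(root)$str, ";")
}

#' Replicated heuristic maximum-likelihood tree search
#'
#' Each replicate hill-climbs by nearest-neighbor interchange (NNI) with
#' branch-length re-optimization from a starting tree: replicate 1 starts
#' from neighbor joining, later replicates from randomly NNI-perturbed
#' copies.  With a `constraint`, starting trees are built
#' constraint-compatible and only constraint-preserving rearrangements are
#' accepted.  Deterministic given `seed`.  Ties between equal-likelihood
#' topologies break toward the lexicographically smallest canonical Newick.
#'
#' @param aln A [alignment()].
#' @param model A [subst_model()].
#' @param n_replicates Number of independent search replicates.
#' @param seed Integer seed (optional).
#' @param constraint Optional character vector of tip labels required to be
#'   monophyletic.
#' @param max_rounds Maximum NNI improvement rounds per replicate.
#' @param tol_final Branch-length convergence tolerance for the final
#'   optimization pass.
#' @return An object of class `ml_search`: list with `tree`, `loglik`,
#'   `replicate_loglik`, `seeds`, `constraint`.
#' @export
ml_search <- function(aln, model, n_replicates = 20, seed = NULL,
                      constraint = NULL, max_rounds = 100,
                      tol_final = 1e-6) {
  if (n_taxa(aln) < 4) stop("ml_search needs at least 4 taxa")
  if (!is.null(seed)) set.seed(seed)
  labs <- aln_labels(aln)
  cflag <- integer(0)
  if (!is.null(constraint)) {
    unknown <- setdiff(constraint, labs)
    if (length(unknown))
      stop("constraint names unknown taxa: ",
           paste(unknown, collapse = ", "))
    if (length(constraint) >= 2 && length(constraint) < length(labs))
      cflag <- 1L # marker; real flags assigned per tree below
  }
  start <- if (length(cflag)) constrained_start_tree(aln, constraint)
           else nj_tree(aln)
  a0 <- prep_engine(start, aln, model)
  flags <- if (length(cflag))
    as.integer(a0$tree$tip.label %in% constraint) else integer(0)
  seeds <- sample.int(.Machine$integer.max, n_replicates)
  best <- NULL
  reps <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    npert <- if (r == 1) 0L else max(2L, n_taxa(aln) %/% 4L)
    res <- eng_search(a0$ntip, a0$edge, a0$elen, a0$pat, a0$w, a0$U, a0$Ui,
                      a0$lambda, a0$pi, a0$rates, flags, npert, seeds[r],
                      max_rounds, tol_final, 30L, 1e-8, 10)
    reps[r] <- res$loglik
    tr <- structure(list(edge = res$edge, edge.length = res$edge.length,
                         Nnode = res$Nnode, tip.label = a0$tree$tip.label),
                    class = "phylo")
    if (is.null(best) || res$loglik > best$loglik + 1e-9 ||
        (abs(res$loglik - best$loglik) <= 1e-9 &&
         canonical_newick(tr) < canonical_newick(best$tree))) {
      best <- list(tree = tr, loglik = res$loglik)
    }
  }
  structure(list(tree = best$tree, loglik = best$loglik,
                 replicate_loglik = reps, seeds = seeds,
                 constraint = constraint, model = model),
            class = "ml_search")
}

#' @export
print.ml_search <- function(x, ...) {
  cat("ML search:", length(x$tree$tip.label), "taxa,",
      length(x$replicate_loglik), "replicates",
      if (!is.null(x$constraint)) "(constrained)" else "", "\n")
  cat(sprintf("  best lnL = %.6f\n", x$loglik))
  invisible(x)
}

# bipartition keys of the unrooted topology: for every internal edge, the
# sorted tip set on the side not containing the first taxon
bipartitions <- function(tree, ref = NULL) {
  tr <- if (ape::is.rooted(tree) && length(tree$tip.label) > 2)
    ape::unroot(tree) else tree
  ntip <- length(tr$tip.label)
  if (is.null(ref)) ref <- sort(tr$tip.label)[1]
  po <- ape::reorder.phylo(tr, "postorder")
  below <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tr$tip.label[i]
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  keys <- character(0)
  sets <- list()
  for (i in seq_len(nrow(po$edge))) {
    ch <- po$edge[i, 2]
    if (ch <= ntip) next
    s <- below[[ch]]
    if (ref %in% s) s <- setdiff(tr$tip.label, s)
    if (length(s) < 2 || length(s) > ntip - 2) next
    k <- paste(sort(s), collapse = "|")
    if (!(k %in% keys)) { keys <- c(keys, k); sets[[length(sets) + 1]] <- sort(s) }
  }
  names(sets) <- keys
  sets
}

#' Nonparametric bootstrap support for the bipartitions of a tree
#'
#' Sites (restricted to the inclusion mask) are resampled with replacement;
#' each pseudo-replicate is analysed by [ml_search()] and support is the
#' percentage of replicates whose best tree contains each focal bipartition.
#'
#' @inheritParams ml_search
#' @param tree Focal tree whose bipartitions are scored; computed by
#'   [ml_search()] with `search_reps` replicates when missing.
#' @param n_boot Number of bootstrap replicates (`0` gives an empty table).
#' @param search_reps Search replicates per bootstrap replicate.
#' @return A list of class `boot_support`: `table` (bipartition, size,
#'   support in `[0, 100]`), `tree` (focal tree with `node.label` set to
#'   rounded support), `n_boot`.
#' @export
bootstrap_support <- function(aln, model, tree = NULL, n_boot = 100,
                              search_reps = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(tree)) tree <- ml_search(aln, model, search_reps)$tree
  focal <- bipartitions(tree)
  hits <- setNames(numeric(length(focal)), names(focal))
  if (n_boot > 0) {
    idx_inc <- which(aln$mask)
    bseeds <- sample.int(.Machine$integer.max, n_boot)
    for (b in seq_len(n_boot)) {
      take <- sample(idx_inc, length(idx_inc), replace = TRUE)
      baln <- alignment(aln$seq[, take, drop = FALSE])
      rownames(baln$seq) <- rownames(aln$seq)
      res <- ml_search(baln, model, n_replicates = search_reps,
                       seed = bseeds[b])
      bk <- names(bipartitions(res$tree))
      hits[names(focal) %in% bk] <- hits[names(focal) %in% bk] + 1
    }
  }
  support <- if (n_boot > 0) 100 * hits / n_boot else numeric(0)
  tab <- if (n_boot > 0)
    data.frame(bipartition = names(focal),
               size = vapply(focal, length, integer(1)),
               support = unname(support), row.names = NULL)
  else data.frame(bipartition = character(0), size = integer(0),
                  support = numeric(0))
  tree2 <- annotate_support(tree, support)
  structure(list(table = tab, tree = tree2, n_boot = n_boot),
            class = "boot_support")
}

# write support values onto internal node labels of the (unrooted) tree
annotate_support <- function(tree, support) {
  tr <- if (ape::is.rooted(tree) && length(tree$tip.label) > 2)
    ape::unroot(tree) else tree
  ntip <- length(tr$tip.label)
  po <- ape::reorder.phylo(tr, "postorder")
  below <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tr$tip.label[i]
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; ch <- po$edge[i, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  ref <- sort(tr$tip.label)[1]
  labs <- rep("", tr$Nnode)
  for (nd in (ntip + 1):(ntip + tr$Nnode)) {
    s <- below[[nd]]
    if (ref %in% s) s <- setdiff(tr$tip.label, s)
    k <- paste(sort(s), collapse = "|")
    if (k %in% names(support)) labs[nd - ntip] <- sprintf("%.0f", support[k])
  }
  tr$node.label <- labs
  tr
}

#' @export
print.boot_support <- function(x, ...) {
  cat("Bootstrap support (", x$n_boot, "replicates ):\n")
  shown <- x$table[x$table$support > 50, , drop = FALSE]
  if (nrow(shown) == 0) cat("  no bipartition above 50%\n")
  else print(shown, row.names = FALSE)
  invisible(x)
}

#' Midpoint-root a tree for display and origin counting
#'
#' Places the root at the midpoint of the longest tip-to-tip path.  Display
#' convention only: the likelihood of the unrooted tree is unchanged under
#' reversible models.  A zero-diameter tree is rooted arbitrarily and
#' flagged with attribute `arbitrary_root`.
#'
#' @param tree An ape `phylo` tree with finite branch lengths.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  if (any(!is.finite(tree$edge.length)))
    stop("tree has non-finite branch lengths")
  if (sum(tree$edge.length) == 0) {
    out <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
    attr(out, "arbitrary_root") <- TRUE
    warning("zero-diameter tree: root placed arbitrarily")
    return(out)
  }
  phangorn::midpoint(tree)
}
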