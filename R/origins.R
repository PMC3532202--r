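# Counting independent evolutionary origins of each resistance class on a
# rooted tree, under the assumption that susceptibility is ancestral.

# children list and postorder node sequence of a rooted tree
tree_index <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  kids <- split(po$edge[, 2], po$edge[, 1])
  list(ntip = ntip, nnode = ntip + tree$Nnode,
       root = po$edge[nrow(po$edge), 1], edge = po$edge, kids = kids)
}

check_states <- function(tree, states) {
  if (is.null(names(states))) stop("states must be named by tip label")
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss))
    stop("states missing for tips: ", paste(miss, collapse = ", "))
  states[tree$tip.label]
}

#' Maximal clades made entirely of one allele class
#'
#' Counts the maximal subtrees of a rooted tree in which every tip carries
#' the focal class (the parent clade of each contains a non-focal tip, or
#' the clade is the whole tree).
#'
#' @param tree A rooted `phylo` tree (e.g. from [midpoint_root()]).
#' @param states Named character vector: tip label -> allele class.
#' @param class Focal class, e.g. `"kdr"`.
#' @return A list with `count` and `clades` (list of tip-label vectors).
#' @export
count_maximal_clades <- function(tree, states, class) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted (see midpoint_root)")
  states <- check_states(tree, states)
  ix <- tree_index(tree)
  focal <- states == class
  if (!any(focal)) return(list(count = 0L, clades = list()))
  pure <- logical(ix$nnode)
  below <- vector("list", ix$nnode)
  pure[seq_len(ix$ntip)] <- focal
  for (i in seq_len(ix$ntip)) below[[i]] <- tree$tip.label[i]
  for (i in seq_len(nrow(ix$edge))) {
    p <- ix$edge[i, 1]; ch <- ix$edge[i, 2]
    if (is.null(below[[p]])) { below[[p]] <- below[[ch]]; pure[p] <- pure[ch] }
    else { below[[p]] <- c(below[[p]], below[[ch]]); pure[p] <- pure[p] && pure[ch] }
  }
  parent <- integer(ix$nnode)
  parent[ix$edge[, 2]] <- ix$edge[, 1]
  parent[ix$root] <- 0L
  # a node is maximal iff pure and (it is the root or its parent is impure)
  cand <- which(pure)
  maximal <- cand[parent[cand] == 0L | !pure[pmax(parent[cand], 1L)]]
  clades <- lapply(maximal, function(nd) sort(below[[nd]]))
  list(count = length(clades), clades = clades)
}

#' Minimum number of independent gains of a class (losses forbidden)
#'
#' Minimum number of susceptible-to-focal transitions needed to explain
#' the tip states when the ancestral condition (on a stem above the root)
#' is non-focal and reversions are not allowed.  Computed by dynamic
#' programming over ancestral labelings.
#'
#' @inheritParams count_maximal_clades
#' @return Integer gain count (0 if the class is absent).
#' @export
min_gains <- function(tree, states, class) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted (see midpoint_root)")
  states <- check_states(tree, states)
  ix <- tree_index(tree)
  focal <- states == class
  if (!any(focal)) return(0L)
  INF <- 1e9
  c0 <- numeric(ix$nnode); c1 <- numeric(ix$nnode)
  c0[seq_len(ix$ntip)] <- ifelse(focal, INF, 0)
  c1[seq_len(ix$ntip)] <- ifelse(focal, 0, INF)
  done <- logical(ix$nnode)
  for (i in seq_len(nrow(ix$edge))) {
    p <- ix$edge[i, 1]; ch <- ix$edge[i, 2]
    add0 <- min(c0[ch], c1[ch] + 1)
    add1 <- c1[ch]                      # losses forbidden: focal stays focal
    if (!done[p]) { c0[p] <- add0; c1[p] <- add1; done[p] <- TRUE }
    else { c0[p] <- c0[p] + add0; c1[p] <- c1[p] + add1 }
  }
  as.integer(min(c0[ix$root], c1[ix$root] + 1))
}

#' Unconstrained parsimony change count (gains and losses)
#'
#' Standard Fitch small-parsimony count of state changes for the binary
#' focal-vs-rest character, with a free root state.
#'
#' @inheritParams count_maximal_clades
#' @return Integer minimum number of changes.
#' @export
fitch_changes <- function(tree, states, class) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  states <- check_states(tree, states)
  ix <- tree_index(tree)
  focal <- states == class
  # state sets as bitmasks: 1 = non-focal, 2 = focal
  set <- integer(ix$nnode)
  set[seq_len(ix$ntip)] <- ifelse(focal, 2L, 1L)
  changes <- 0L
  done <- logical(ix$nnode)
  for (i in seq_len(nrow(ix$edge))) {
    p <- ix$edge[i, 1]; ch <- ix$edge[i, 2]
    if (!done[p]) { set[p] <- set[ch]; done[p] <- TRUE }
    else {
      inter <- bitwAnd(set[p], set[ch])
      if (inter == 0L) { set[p] <- bitwOr(set[p], set[ch]); changes <- changes + 1L }
      else set[p] <- inter
    }
  }
  changes
}

# clade counts of a class under every possible root placement (one rooting
# per branch of the unrooted tree)
clade_count_over_roots <- function(tree, states, class) {
  tr <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  ntip <- length(tr$tip.label)
  counts <- integer(0)
  for (i in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[i, 2]
    og <- if (ch <= ntip) tr$tip.label[ch] else {
      keep <- ape::extract.clade(tr, ch)$tip.label
      keep
    }
    if (length(og) >= ntip - 1) next
    rt <- tryCatch(ape::root(tr, outgroup = og, resolve.root = TRUE),
                   error = function(e) NULL)
    if (is.null(rt)) next
    counts <- c(counts, count_maximal_clades(rt, states, class)$count)
  }
  if (!length(counts)) counts <- count_maximal_clades(
    ape::root(tr, outgroup = tr$tip.label[1], resolve.root = TRUE),
    states, class)$count
  range(counts)
}

#' Origin report for all resistance classes
#'
#' For each class present: number of maximal pure clades on the supplied
#' rooted (display) tree, the minimum gains under the susceptible-ancestor
#' no-loss model, the unconstrained parsimony change count, and the
#' sensitivity of the clade count to root placement (min/max over all
#' rootings of the unrooted tree, since display rooting is conventional).
#'
#' @param tree A rooted `phylo` (typically midpoint-rooted).
#' @param states Named tip -> class vector.
#' @param classes Classes to report (default: the resistant classes).
#' @return A data frame of class `origin_report`.
#' @export
origin_report <- function(tree, states,
                          classes = RESISTANT_CLASSES) {
  rows <- lapply(classes, function(cl) {
    cm <- count_maximal_clades(tree, states, cl)
    rng <- if (cm$count > 0) clade_count_over_roots(tree, states, cl)
           else c(0L, 0L)
    data.frame(class = cl, n_tips = sum(states[tree$tip.label] == cl),
               clades = cm$count,
               min_gains = min_gains(tree, states, cl),
               parsimony_changes = fitch_changes(tree, states, cl),
               clades_min_over_roots = rng[1],
               clades_max_over_roots = rng[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "clades") <- lapply(setNames(classes, classes), function(cl)
    count_maximal_clades(tree, states, cl)$clades)
  class(out) <- c("origin_report", "data.frame")
  out
}

#' Pair super-kdr haplotypes with kdr haplotypes sharing their intron
#'
#' Under the sequential model, super-kdr (M918T on an L1014F background)
#' arises within a kdr lineage, so each super-kdr haplotype is expected to
#' share an identical intron with a kdr haplotype.  Unpaired super-kdr
#' haplotypes are flagged.
#'
#' @param x A `haplotype_catalog` or `haplotype_result`.
#' @return Data frame with columns `super_kdr`, `kdr` (NA when unpaired)
#'   and `paired`.
#' @export
derive_sequential_pairs <- function(x) {
  cat_ <- if (inherits(x, "haplotype_result")) x$catalog else x
  rec <- cat_$records
  g <- group_by_intron(cat_)
  sk <- rec$name[rec$class == "super-kdr"]
  if (!length(sk))
    return(data.frame(super_kdr = character(0), kdr = character(0),
                      paired = logical(0), stringsAsFactors = FALSE))
  rows <- lapply(sk, function(s) {
    members <- g$groups[[g$group_of[[s]]]]
    mates <- members[members %in% rec$name[rec$class == "kdr"]]
    if (length(mates))
      data.frame(super_kdr = s, kdr = mates, paired = TRUE,
                 stringsAsFactors = FALSE)
    else data.frame(super_kdr = s, kdr = NA_character_, paired = FALSE,
                    stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
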