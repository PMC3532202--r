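# Pruning-algorithm likelihood, branch-length optimization, model parameter
# fitting and BIC model selection.  The numerical core lives in src/engine.cpp;
# these wrappers handle ape 'phylo' containers, masking and pattern
# compression.  Gaps and IUPAC ambiguities are missing data (partial
# likelihood 1 over the compatible states).

# Assemble the argument list for the C++ engine.  The tree is unrooted
# (rooted input is unrooted first; the likelihood is invariant under the
# pulley principle for reversible models).
prep_engine <- function(tree, aln, model) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  labs <- aln_labels(aln)
  if (!setequal(tree$tip.label, labs))
    stop("tree tip labels do not match alignment taxa")
  if (ape::is.rooted(tree) && length(tree$tip.label) > 2)
    tree <- ape::unroot(tree)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  cp <- compress_patterns(aln)
  # engine tip i = ape tip i; reorder pattern rows to tree tip order
  pat <- cp$pat[match(tree$tip.label, cp$labels), , drop = FALSE]
  ed <- model_eigen(model)
  list(ntip = length(tree$tip.label), edge = tree$edge,
       elen = pmax(tree$edge.length, 0), pat = pat, w = cp$w,
       U = ed$U, Ui = ed$Ui, lambda = ed$lambda, pi = model$freq,
       rates = gamma_rates(model), tree = tree)
}

# two-taxon trees have no internal node; handle them directly in R
loglik_two_taxa <- function(t, aln, model) {
  cp <- compress_patterns(aln)
  rates <- gamma_rates(model)
  lik <- numeric(ncol(cp$pat))
  for (r in rates) {
    P <- transition_matrix(model, t, r)
    for (p in seq_along(lik)) {
      m1 <- bitwAnd(cp$pat[1, p], c(1L, 2L, 4L, 8L)) > 0
      m2 <- bitwAnd(cp$pat[2, p], c(1L, 2L, 4L, 8L)) > 0
      lik[p] <- lik[p] +
        sum(model$freq[m1] * rowSums(P[m1, m2, drop = FALSE]))
    }
  }
  sum(cp$w * log(lik / length(rates)))
}

#' Log-likelihood of an alignment on a tree
#'
#' Sum over included sites of the log pruning-algorithm site likelihoods,
#' averaging gamma categories with equal weights.  Sites excluded by the
#' alignment mask do not contribute.
#'
#' @param tree An ape `phylo` tree whose tip labels match the alignment taxa.
#' @param aln A [alignment()] object.
#' @param model A [subst_model()].
#' @return The log-likelihood (a scalar).
#' @export
tree_loglik <- function(tree, aln, model) {
  if (length(tree$tip.label) == 2)
    return(loglik_two_taxa(sum(tree$edge.length), aln, model))
  a <- prep_engine(tree, aln, model)
  eng_loglik(a$ntip, a$edge, a$elen, a$pat, a$w, a$U, a$Ui, a$lambda,
             a$pi, a$rates)
}

#' Optimize branch lengths by coordinate ascent
#'
#' Each branch is optimized in turn by bounded Brent search on
#' `[min_len, max_len]`, sweeping until the log-likelihood improvement
#' falls below `tol`.  The log-likelihood never decreases across sweeps.
#'
#' @inheritParams tree_loglik
#' @param tol Convergence tolerance in log-likelihood units.
#' @param max_sweeps Maximum number of full sweeps over the branches.
#' @param min_len,max_len Branch-length bounds.
#' @return A list with `tree` (optimized branch lengths), `loglik` and
#'   `trace` (log-likelihood after each sweep).
#' @export
optimize_branch_lengths <- function(tree, aln, model, tol = 1e-6,
                                    max_sweeps = 20, min_len = 1e-8,
                                    max_len = 10) {
  if (length(tree$tip.label) == 2) {
    f <- function(t) loglik_two_taxa(t, aln, model)
    o <- optimize(f, c(min_len, max_len), maximum = TRUE, tol = 1e-10)
    tree$edge.length <- rep(o$maximum / length(tree$edge.length),
                            length(tree$edge.length))
    return(list(tree = tree, loglik = o$objective, trace = o$objective))
  }
  a <- prep_engine(tree, aln, model)
  r <- eng_optim(a$ntip, a$edge, a$elen, a$pat, a$w, a$U, a$Ui, a$lambda,
                 a$pi, a$rates, tol, max_sweeps, min_len, max_len)
  tr <- a$tree
  tr$edge.length <- r$edge.length
  if (!is.finite(r$loglik))
    stop("non-finite likelihood during branch-length optimization (",
         "n=", a$ntip, " taxa, ", sum(a$w), " sites)")
  list(tree = tr, loglik = r$loglik, trace = r$trace)
}

#' Fit free model parameters on a fixed topology
#'
#' Alternates branch-length optimization with numerical optimization of the
#' family's free parameters (kappa, GTR exchangeabilities, gamma shape).
#' Base frequencies are empirical (+1 pseudocount per state), a common
#' default that deviates slightly from full ML.
#'
#' @inheritParams tree_loglik
#' @param n_outer Maximum number of alternation rounds.
#' @param brlen_tol Branch-length convergence tolerance per round.
#' @return A list with the updated `model`, the `tree` with optimized
#'   branch lengths, and the final `loglik`.
#' @export
fit_model <- function(aln, tree, model, n_outer = 3, brlen_tol = 1e-4) {
  if (model$family %in% c("HKY85", "GTR")) model$freq <- empirical_freq(aln)
  enc <- function(m) {
    th <- numeric(0)
    if (m$family %in% c("K80", "HKY85")) th <- c(th, logk = log(m$kappa))
    if (m$family == "GTR") th <- c(th, log(m$exch[1:5]))
    if (!is.null(m$alpha)) th <- c(th, loga = log(m$alpha))
    th
  }
  dec <- function(m, th) {
    i <- 1
    if (m$family %in% c("K80", "HKY85")) {
      m$kappa <- exp(th[i])
      m$exch <- c(1, m$kappa, 1, 1, m$kappa, 1)
      i <- i + 1
    }
    if (m$family == "GTR") { m$exch <- c(exp(th[i:(i + 4)]), 1); i <- i + 5 }
    if (!is.null(m$alpha)) m$alpha <- exp(th[i])
    m
  }
  op <- optimize_branch_lengths(tree, aln, model, tol = 0.01, max_sweeps = 5)
  tree <- op$tree
  lnl <- op$loglik
  th <- enc(model)
  for (outer in seq_len(n_outer)) {
    if (length(th)) {
      a <- prep_engine(tree, aln, model)
      obj <- function(t) {
        m2 <- dec(model, t)
        ed <- model_eigen(m2)
        -eng_loglik(a$ntip, a$edge, a$elen, a$pat, a$w, ed$U, ed$Ui,
                    ed$lambda, m2$freq, gamma_rates(m2))
      }
      o <- if (length(th) == 1)
        optim(th, obj, method = "Brent", lower = log(1e-3), upper = log(1e3))
      else optim(th, obj, method = "Nelder-Mead",
                 control = list(maxit = 200 * length(th)))
      th <- o$par
      model <- dec(model, th)
    }
    op <- optimize_branch_lengths(tree, aln, model, tol = brlen_tol,
                                  max_sweeps = 10)
    tree <- op$tree
    if (op$loglik - lnl < 0.01 && outer > 1) { lnl <- op$loglik; break }
    lnl <- op$loglik
  }
  list(model = model, tree = tree, loglik = lnl)
}

#' Bayesian Information Criterion for a fitted model
#'
#' `BIC = -2 lnL + k log(n)` where `n` is the number of included sites and
#' `k` counts branch lengths plus the family's free parameters (kappa: 1;
#' GTR exchangeabilities: 5; non-uniform base frequencies: 3; gamma shape: 1).
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters.
#' @param n Number of sites.
#' @return The BIC value.
#' @export
bic <- function(loglik, k, n) -2 * loglik + k * log(n)

#' Select a substitution model by BIC
#'
#' Fits each candidate on a fixed topology (neighbor joining by default,
#' mirroring the usual model-selection practice of conditioning on one
#' reasonable tree) and returns the minimum-BIC fit; ties break toward
#' fewer parameters.
#'
#' @param aln A [alignment()].
#' @param candidates Named list of [subst_model()] candidates
#'   (default [candidate_models()]).
#' @param tree Optional fixed topology; defaults to the NJ tree.
#' @return A list of class `model_fit` with the winning `model`, `tree`,
#'   `loglik`, `bic`, and a `table` of all candidates.
#' @export
select_model_bic <- function(aln, candidates = candidate_models(),
                             tree = NULL) {
  if (length(candidates) == 0) stop("empty candidate set")
  if (is.null(names(candidates)))
    names(candidates) <- paste0("model", seq_along(candidates))
  if (is.null(tree)) tree <- nj_tree(aln)
  n <- n_sites_included(aln)
  rows <- list()
  fits <- list()
  for (nm in names(candidates)) {
    f <- fit_model(aln, tree, candidates[[nm]])
    k <- model_free_params(f$model) + length(f$tree$edge.length)
    rows[[nm]] <- data.frame(model = nm, loglik = f$loglik, k = k,
                             bic = bic(f$loglik, k, n))
    fits[[nm]] <- f
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ord <- order(tab$bic, tab$k)
  best <- tab$model[ord[1]]
  out <- fits[[best]]
  out$bic <- tab$bic[ord[1]]
  out$name <- best
  out$table <- tab[ord, ]
  class(out) <- "model_fit"
  out
}

#' @export
print.model_fit <- function(x, ...) {
  cat("Best-fit model by BIC:", x$name,
      sprintf("(lnL = %.4f, BIC = %.2f)\n", x$loglik, x$bic))
  print(x$table, row.names = FALSE)
  invisible(x)
}
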