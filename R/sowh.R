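# Parametric-bootstrap (SOWH-style) test of the single-origin hypothesis:
# compare the observed log-likelihood difference between the best tree and
# the best resistant-monophyly-constrained tree against its distribution
# under data simulated on the constrained tree.

#' Observed likelihood difference between best and best-constrained trees
#'
#' `delta = lnL(best) - lnL(best constrained)`.  The unconstrained search
#' explores a superset of the constrained space, so delta must be
#' nonnegative; a materially negative value indicates a failed
#' unconstrained search and raises an error rather than passing silently.
#'
#' @param lnl_best Log-likelihood of the best unconstrained tree.
#' @param lnl_constrained Log-likelihood of the best constrained tree.
#' @param tol Numerical slack below zero treated as 0.
#' @return Nonnegative numeric delta.
#' @export
observed_delta <- function(lnl_best, lnl_constrained, tol = 1e-6) {
  d <- lnl_best - lnl_constrained
  if (d < -tol)
    stop("constrained search beat the unconstrained search (delta = ",
         format(d), "); increase search replicates")
  max(d, 0)
}

#' Monte-Carlo p-value for an observed delta
#'
#' `p = #(delta_i >= observed) / n`.  Ties count against rejection
#' (conservative).  When no replicate reaches the observed value the
#' p-value is reported as the bound `p < 1/n`; the `(r+1)/(n+1)`
#' corrected value is also returned.
#'
#' @param observed Observed delta.
#' @param replicate_deltas Nonempty numeric vector of null deltas.
#' @return List with `p`, `p_corrected`, `display`, `is_bound`.
#' @export
p_value <- function(observed, replicate_deltas) {
  n <- length(replicate_deltas)
  if (n == 0) stop("replicate_deltas must be non-empty")
  r <- sum(replicate_deltas >= observed)
  p <- r / n
  disp <- if (r == 0) paste0("p < ", format(1 / n, digits = 3))
          else paste0("p = ", format(p, digits = 3))
  list(p = p, p_corrected = (r + 1) / (n + 1), display = disp,
       is_bound = (r == 0))
}

#' Parametric bootstrap test of the single-origin (monophyly) hypothesis
#'
#' Runs unconstrained and constrained ML searches on the data to get the
#' observed delta; fits the model parameters on the constrained tree;
#' simulates `n_reps` replicate alignments of the same (included) length
#' on that tree; re-runs both searches on every replicate; and locates the
#' observed delta in the null distribution.
#'
#' Replicate deltas that come out marginally negative (both searches are
#' heuristic) are clamped to zero, which is conservative: it can only
#' enlarge the p-value.
#'
#' @param aln A [alignment()].
#' @param model A [subst_model()] (its free parameters are re-fitted on
#'   the constrained tree before simulation).
#' @param constraint Tip labels required to be monophyletic under the null
#'   (the resistant haplotypes).
#' @param n_reps Number of parametric-bootstrap replicates.
#' @param seed Integer seed; every random draw derives from it.
#' @param search_reps Search replicates for the observed-data searches.
#' @param rep_search_reps Search replicates within each bootstrap
#'   replicate (kept small, mirroring bootstrap practice).
#' @param tol_final Branch-length tolerance handed to [ml_search()] for
#'   replicate searches.
#' @param progress Print a dot per replicate.
#' @return An object of class `sowh`.
#' @export
sowh_test <- function(aln, model, constraint, n_reps = 100, seed = NULL,
                      search_reps = 20, rep_search_reps = 2,
                      tol_final = 1e-3, progress = FALSE) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (length(constraint) < 2)
    stop("constraint must contain at least two taxa")
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2 * n_reps + 3)
  unc <- ml_search(aln, model, search_reps, seed = seeds[1])
  con <- ml_search(aln, model, search_reps, seed = seeds[2],
                   constraint = constraint)
  # the constrained optimum is itself an unconstrained candidate: pool it,
  # so heuristic-search noise can never produce a negative delta
  if (con$loglik > unc$loglik) {
    unc$tree <- con$tree
    unc$loglik <- con$loglik
  }
  dobs <- observed_delta(unc$loglik, con$loglik)
  fit <- fit_model(aln, con$tree, model)
  nsite <- n_sites_included(aln)
  deltas <- numeric(n_reps)
  clamped <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    sim <- tryCatch(
      simulate_alignment(fit$tree, fit$model, nsite, seed = seeds[2 + i]),
      error = function(e) stop("replicate ", i, ": simulation failed: ",
                               conditionMessage(e)))
    d <- tryCatch({
      u <- ml_search(sim, fit$model, rep_search_reps,
                     seed = seeds[2 + n_reps + i], tol_final = tol_final)
      k <- ml_search(sim, fit$model, rep_search_reps,
                     seed = seeds[2 + n_reps + i], constraint = constraint,
                     tol_final = tol_final)
      u$loglik - k$loglik
    }, error = function(e) stop("replicate ", i, ": search failed: ",
                                conditionMessage(e)))
    clamped[i] <- d < 0
    deltas[i] <- max(d, 0)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  pv <- p_value(dobs, deltas)
  structure(list(observed_delta = dobs, lnl_best = unc$loglik,
                 lnl_constrained = con$loglik,
                 replicate_deltas = deltas, p_value = pv$p,
                 p_corrected = pv$p_corrected, p_display = pv$display,
                 p_is_bound = pv$is_bound, n_reps = n_reps, seed = seed,
                 clamped = clamped,
                 best_tree = unc$tree, constrained_tree = con$tree,
                 generating_model = fit$model,
                 constraint = constraint),
            class = "sowh")
}

#' @export
print.sowh <- function(x, ...) {
  cat("Parametric bootstrap test of resistant monophyly (single origin)\n")
  cat(sprintf("  lnL best tree:        %.6f\n", x$lnl_best))
  cat(sprintf("  lnL constrained tree: %.6f\n", x$lnl_constrained))
  cat(sprintf("  observed delta:       %.2f\n", x$observed_delta))
  cat(sprintf("  null replicates:      %d (max delta %.2f)\n",
              x$n_reps, max(x$replicate_deltas)))
  cat("  ", x$p_display, "\n")
  invisible(x)
}

#' @export
summary.sowh <- function(object, ...) {
  q <- quantile(object$replicate_deltas, c(0.5, 0.95, 0.99))
  cat("SOWH-style parametric bootstrap\n")
  print(object)
  cat(sprintf("  null delta quantiles: 50%% %.2f  95%% %.2f  99%% %.2f\n",
              q[1], q[2], q[3]))
  cat(sprintf("  corrected p ((r+1)/(n+1)): %.4f\n", object$p_corrected))
  if (any(object$clamped))
    cat("  note:", sum(object$clamped),
        "replicate deltas clamped to 0 (heuristic search noise)\n")
  invisible(object)
}

#' @export
plot.sowh <- function(x, ...) {
  hist(x$replicate_deltas, breaks = 20, col = "grey80",
       main = "Null distribution of delta", xlab = "delta (lnL units)",
       xlim = range(c(x$replicate_deltas, x$observed_delta)), ...)
  abline(v = x$observed_delta, col = "red", lwd = 2)
  legend("topright", legend = sprintf("observed = %.2f", x$observed_delta),
         col = "red", lwd = 2, bty = "n")
  invisible(x)
}
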