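# Reversible nucleotide substitution models (JC69, K80, HKY85, GTR) with
# optional discrete-gamma rate heterogeneity.  State order is A, C, G, T
# throughout.  Q is always rescaled so the expected number of substitutions
# per site per unit branch length equals 1.

#' Construct a reversible nucleotide substitution model
#'
#' Builds a substitution model of one of the four nested reversible families.
#' The instantaneous rate matrix is scaled so branch lengths are in expected
#' substitutions per site.  Rate heterogeneity across sites uses the standard
#' discrete-gamma approximation (equal-weight mean categories).
#'
#' @param family One of `"JC69"`, `"K80"`, `"HKY85"`, `"GTR"`.
#' @param freq Base frequencies (A, C, G, T).  Forced to `rep(0.25, 4)` for
#'   JC69 and K80.  Normalised to sum to 1.
#' @param kappa Transition/transversion rate ratio (K80, HKY85).
#' @param exch GTR exchangeabilities in the order AC, AG, AT, CG, CT, GT.
#'   The GT rate acts as the reference; five are free.
#' @param alpha Gamma shape for among-site rate variation, or `NULL` for
#'   rate homogeneity.
#' @param ncat Number of discrete gamma categories (ignored when
#'   `alpha` is `NULL`).
#' @return An object of class `subst_model`.
#' @examples
#' m <- subst_model("HKY85", freq = c(0.3, 0.2, 0.2, 0.3), kappa = 3)
#' transition_matrix(m, 0.1)
#' @export
subst_model <- function(family = c("JC69", "K80", "HKY85", "GTR"),
                        freq = rep(0.25, 4), kappa = 2,
                        exch = rep(1, 6), alpha = NULL, ncat = 4L) {
  family <- match.arg(family)
  if (family %in% c("JC69", "K80")) freq <- rep(0.25, 4)
  if (length(freq) != 4 || any(!is.finite(freq)) || any(freq <= 0))
    stop("freq must be 4 positive numbers")
  freq <- freq / sum(freq)
  if (family %in% c("K80", "HKY85")) {
    if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0")
    exch <- c(1, kappa, 1, 1, kappa, 1)
  }
  if (family == "JC69") exch <- rep(1, 6)
  if (length(exch) != 6 || any(!is.finite(exch)) || any(exch <= 0))
    stop("exch must be 6 positive numbers (AC, AG, AT, CG, CT, GT)")
  if (!is.null(alpha)) {
    if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
    ncat <- as.integer(ncat)
    if (ncat < 1L) stop("ncat must be >= 1")
  } else ncat <- 1L
  structure(list(family = family, freq = freq,
                 kappa = if (family %in% c("K80", "HKY85")) kappa else NA_real_,
                 exch = exch, alpha = alpha, ncat = ncat),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat("Substitution model:", x$family,
      if (!is.null(x$alpha)) sprintf("+G(%d cat, alpha=%.4g)", x$ncat, x$alpha)
      else "", "\n")
  cat("  base frequencies (ACGT):", sprintf("%.4f", x$freq), "\n")
  if (!is.na(x$kappa)) cat("  kappa:", format(x$kappa, digits = 5), "\n")
  if (x$family == "GTR")
    cat("  exchangeabilities (AC AG AT CG CT GT):",
        sprintf("%.4g", x$exch), "\n")
  invisible(x)
}

# instantaneous rate matrix, scaled to 1 expected substitution / site / unit t
rate_matrix <- function(model) {
  s <- model$exch
  S <- matrix(0, 4, 4)
  S[1, 2] <- S[2, 1] <- s[1] # AC
  S[1, 3] <- S[3, 1] <- s[2] # AG
  S[1, 4] <- S[4, 1] <- s[3] # AT
  S[2, 3] <- S[3, 2] <- s[4] # CG
  S[2, 4] <- S[4, 2] <- s[5] # CT
  S[3, 4] <- S[4, 3] <- s[6] # GT
  Q <- S * rep(model$freq, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(model$freq * diag(Q))
  Q / mu
}

# spectral decomposition of Q via the pi-symmetrised form; exact for
# reversible models and reused by the C++ engine to build P(t) = U e^{L t} U^-1
model_eigen <- function(model) {
  Q <- rate_matrix(model)
  pi <- model$freq
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  U <- diag(1 / d) %*% e$vectors
  Ui <- t(e$vectors) %*% diag(d)
  list(U = U, Ui = Ui, lambda = e$values)
}

# equal-weight discrete gamma category rates (mean 1)
gamma_rates <- function(model) {
  if (is.null(model$alpha) || model$ncat == 1L) return(1)
  r <- phangorn::discrete.gamma(model$alpha, model$ncat)
  r / mean(r)
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q t r)` for a branch of length `t` and relative rate `r`,
#' computed from the spectral decomposition of the reversible rate matrix.
#'
#' @param model A [subst_model()].
#' @param t Branch length in expected substitutions per site (`t >= 0`).
#' @param rate Relative rate multiplier (e.g. a gamma category rate).
#' @return A 4x4 row-stochastic matrix over states A, C, G, T.
#' @export
transition_matrix <- function(model, t, rate = 1) {
  if (!inherits(model, "subst_model")) stop("model must be a subst_model")
  if (!is.finite(t) || t < 0) stop("branch length t must be >= 0")
  ed <- model_eigen(model)
  P <- ed$U %*% diag(exp(ed$lambda * t * rate)) %*% ed$Ui
  P[P < 0] <- 0
  dimnames(P) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  P
}

# number of free parameters for BIC; branch lengths counted separately
model_free_params <- function(model) {
  k <- switch(model$family, JC69 = 0L, K80 = 1L, HKY85 = 1L + 3L,
              GTR = 5L + 3L)
  if (!is.null(model$alpha)) k <- k + 1L
  k
}

#' Default model-selection candidate set
#'
#' The four nested reversible families, each with and without 4-category
#' discrete-gamma rate heterogeneity.
#'
#' @param ncat Gamma category count for the +G variants.
#' @return A named list of eight [subst_model()] objects.
#' @export
candidate_models <- function(ncat = 4L) {
  fam <- c("JC69", "K80", "HKY85", "GTR")
  out <- list()
  for (f in fam) {
    out[[f]] <- subst_model(f)
    out[[paste0(f, "+G")]] <- subst_model(f, alpha = 1, ncat = ncat)
  }
  out
}
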