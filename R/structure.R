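# Population structure: genotype PCA and the admixture model (EM + CV).

#' Principal component analysis of a genotype matrix
#'
#' Missing calls are mean-imputed per variant (logged). With
#' `scaling = "patterson"` (default for genotype data) each variant is
#' centered at its mean dosage 2p and divided by `sqrt(p(1-p))`; with
#' `"center"` variants are only centered. Coordinates are the projections
#' of samples on the eigenvectors of the sample covariance of the scaled
#' matrix; the explained fraction of each component is its eigenvalue over
#' the covariance trace. Monomorphic variants are dropped with a log note
#' (their Patterson scale is zero).
#'
#' @param g a [GenotypeMatrix-class].
#' @param nComponents number of components (at most min(samples, variants)).
#' @param scaling `"patterson"` or `"center"`.
#' @return A [PCAResult-class].
#' @export
pcaGenotypes <- function(g, nComponents = 10L,
                         scaling = c("patterson", "center")) {
  scaling <- match.arg(scaling)
  stopifnot(is(g, "GenotypeMatrix"))
  X <- g@calls
  if (nComponents > min(dim(X)))
    stop("nComponents exceeds min(samples, variants)")
  nMiss <- sum(is.na(X))
  if (nMiss) {
    message("pcaGenotypes: mean-imputing ", nMiss, " missing call(s)")
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2L]]
  }
  p <- colMeans(X) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    message("pcaGenotypes: dropped ", sum(mono), " monomorphic variant(s)")
    X <- X[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  X <- sweep(X, 2L, 2 * p)
  if (scaling == "patterson")
    X <- sweep(X, 2L, sqrt(p * (1 - p)), "/")
  sv <- svd(X, nu = nComponents, nv = 0L)
  coords <- sv$u %*% diag(sv$d[seq_len(nComponents)], nComponents)
  rownames(coords) <- sampleIDs(g)
  colnames(coords) <- paste0("PC", seq_len(nComponents))
  expl <- sv$d[seq_len(nComponents)]^2 / sum(X^2)
  new("PCAResult", coordinates = coords,
      explainedVarianceFraction = expl, scaling = scaling)
}

# Binomial admixture log-likelihood (without the constant binomial
# coefficient): sum_ij w_ij [ g_ij ln p_ij + (2 - g_ij) ln(1 - p_ij) ].
admixtureLoglik <- function(G, W, Q, F, eps = 1e-9) {
  P <- Q %*% F
  P[P < eps] <- eps; P[P > 1 - eps] <- 1 - eps
  sum(W * (G * log(P) + (2 - G) * log(1 - P)))
}

# One EM pass; returns updated Q, F. W is the 0/1 observation-weight
# matrix (0 = missing or held out).
admixtureEMStep <- function(G, W, Q, F, eps = 1e-6) {
  P <- Q %*% F
  P[P < eps] <- eps; P[P > 1 - eps] <- 1 - eps
  A <- W * G / P              # expected derived-copy weight / q_ik f_kj
  B <- W * (2 - G) / (1 - P)  # expected ancestral-copy weight / q_ik (1-f_kj)
  U <- F * crossprod(Q, A)    # K x M expected derived copies from pop k
  V <- (1 - F) * crossprod(Q, B)
  Fnew <- U / (U + V)
  Fnew[!is.finite(Fnew)] <- 0.5
  Qnew <- Q * (A %*% t(F) + B %*% t(1 - F))
  Qnew <- Qnew / pmax(2 * rowSums(W), 1)
  Qnew <- Qnew / rowSums(Qnew)
  Fnew[Fnew < eps] <- eps; Fnew[Fnew > 1 - eps] <- 1 - eps
  Qnew[Qnew < eps] <- eps
  Qnew <- Qnew / rowSums(Qnew)
  list(Q = Qnew, F = Fnew)
}

admixtureEMRun <- function(G, W, Q, F, maxIter, tol) {
  trace <- numeric(0)
  ll <- admixtureLoglik(G, W, Q, F)
  for (it in seq_len(maxIter)) {
    up <- admixtureEMStep(G, W, Q, F)
    Q <- up$Q; F <- up$F
    llNew <- admixtureLoglik(G, W, Q, F)
    if (!is.finite(llNew))
      stop("non-finite admixture log-likelihood at iteration ", it)
    trace <- c(trace, llNew)
    if (llNew - ll < tol && it > 1L) { ll <- llNew; break }
    ll <- llNew
  }
  list(Q = Q, F = F, trace = trace)
}

#' Fit the admixture model for one K
#'
#' Maximizes the binomial admixture log-likelihood
#' `l = sum_ij [ g_ij ln(sum_k q_ik f_kj) + (2 - g_ij) ln(1 - sum_k q_ik f_kj) ]`
#' by plain EM (ascent guaranteed; the trace is checked non-decreasing).
#' Initialization draws Q rows from Dirichlet(1) and F as pooled allele
#' frequencies with seeded perturbation; `nStarts` restarts are run and the
#' best log-likelihood kept. Missing genotypes carry zero weight.
#' Monomorphic variants are dropped with a log note.
#'
#' @param g a [GenotypeMatrix-class].
#' @param K number of ancestral populations (>= 1).
#' @param seed integer seed for initialization.
#' @param maxIter,tol EM stopping rule: stop when the log-likelihood gain
#'   drops below `tol` or after `maxIter` iterations.
#' @param nStarts number of seeded restarts.
#' @return An [AncestryFit-class].
#' @export
fitAdmixture <- function(g, K, seed = 1L, maxIter = 200L, tol = 1e-4,
                         nStarts = 5L) {
  stopifnot(is(g, "GenotypeMatrix"), K >= 1L)
  G <- g@calls
  W <- matrix(as.numeric(!is.na(G)), nrow(G))
  G[is.na(G)] <- 0L
  p <- colSums(G) / pmax(2 * colSums(W), 1)
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    message("fitAdmixture: dropped ", sum(mono), " monomorphic variant(s)")
    G <- G[, !mono, drop = FALSE]; W <- W[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  best <- NULL
  for (r in seq_len(nStarts)) {
    set.seed(seed + r - 1L)
    Q <- matrix(-log(runif(nrow(G) * K)), ncol = K)   # Dirichlet(1)
    Q <- Q / rowSums(Q)
    F <- matrix(rep(p, each = K), nrow = K)
    F <- F + matrix(rnorm(K * length(p), 0, 0.05), nrow = K)
    F[F < 0.01] <- 0.01; F[F > 0.99] <- 0.99
    fit <- admixtureEMRun(G, W, Q, F, maxIter, tol)
    if (is.null(best) || tail(fit$trace, 1L) > tail(best$trace, 1L))
      best <- fit
  }
  rownames(best$Q) <- sampleIDs(g)
  new("AncestryFit", K = as.integer(K), Q = best$Q, F = best$F,
      loglikTrace = best$trace, cvError = NA_real_)
}

#' Cross-validation over the number of ancestral populations
#'
#' Entry-masking CV: a random fraction `1/folds` of the observed genotype
#' entries is held out per fold; the model is fitted on the rest and the
#' held-out entries are scored by their mean binomial deviance under the
#' predicted dosage `2 sum_k q_ik f_kj`. The K with the lowest mean CV
#' error across folds is flagged. A mask that would leave a variant with
#' no observed call is redrawn (logged).
#'
#' @param g a [GenotypeMatrix-class].
#' @param KRange integer vector of K values (conventionally 2..16 for the
#'   full-scale analysis; choose to fit the panel).
#' @param folds number of folds (>= 2).
#' @param seed integer seed (drives masks and EM initialization).
#' @param maxIter,tol,nStarts passed to the EM (see [fitAdmixture()]).
#' @return data.frame (K, cv_error) with attribute `best_K`.
#' @export
cvAdmixture <- function(g, KRange = 2:16, folds = 5L, seed = 1L,
                        maxIter = 100L, tol = 1e-3, nStarts = 2L) {
  stopifnot(is(g, "GenotypeMatrix"), folds >= 2L)
  G0 <- g@calls
  Wobs <- matrix(as.numeric(!is.na(G0)), nrow(G0))
  G <- G0; G[is.na(G)] <- 0L
  p <- colSums(G) / pmax(2 * colSums(Wobs), 1)
  keep <- p > 0 & p < 1
  G <- G[, keep, drop = FALSE]; Wobs <- Wobs[, keep, drop = FALSE]

  obsIdx <- which(Wobs == 1)
  set.seed(seed)
  foldOf <- sample(rep_len(seq_len(folds), length(obsIdx)))
  # redraw masks that empty a variant
  for (tries in 1:100) {
    ok <- TRUE
    for (f in seq_len(folds)) {
      W <- Wobs; W[obsIdx[foldOf == f]] <- 0
      if (any(colSums(W) == 0)) { ok <- FALSE; break }
    }
    if (ok) break
    message("cvAdmixture: mask left a variant unobserved; redrawing")
    foldOf <- sample(rep_len(seq_len(folds), length(obsIdx)))
  }

  eps <- 1e-9
  res <- data.frame(K = KRange, cv_error = NA_real_)
  for (ki in seq_along(KRange)) {
    K <- KRange[ki]
    devs <- numeric(folds)
    for (f in seq_len(folds)) {
      W <- Wobs
      held <- obsIdx[foldOf == f]
      W[held] <- 0
      set.seed(seed * 1000L + K * 10L + f)
      bestFit <- NULL
      for (r in seq_len(nStarts)) {
        Q <- matrix(-log(runif(nrow(G) * K)), ncol = K)
        Q <- Q / rowSums(Q)
        F <- matrix(rep(colSums(W * G) / pmax(2 * colSums(W), 1), each = K),
                    nrow = K)
        F <- F + matrix(rnorm(length(F), 0, 0.05), nrow = K)
        F[F < 0.01] <- 0.01; F[F > 0.99] <- 0.99
        fit <- admixtureEMRun(G, W, Q, F, maxIter, tol)
        if (is.null(bestFit) ||
            tail(fit$trace, 1L) > tail(bestFit$trace, 1L)) bestFit <- fit
      }
      P <- bestFit$Q %*% bestFit$F
      P[P < eps] <- eps; P[P > 1 - eps] <- 1 - eps
      gh <- G[held]; ph <- P[held]
      gfrac <- gh / 2
      sat <- ifelse(gh %in% c(0L, 2L), 0,
                    gh * log(gfrac) + (2 - gh) * log(1 - gfrac))
      devs[f] <- mean(2 * (sat - (gh * log(ph) + (2 - gh) * log(1 - ph))))
    }
    res$cv_error[ki] <- mean(devs)
  }
  attr(res, "best_K") <- res$K[which.min(res$cv_error)]
  res
}
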