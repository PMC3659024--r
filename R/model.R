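#' Restricted (REML) log-likelihood of a variance-component mixed model
#'
#' For \eqn{y \sim N(X\beta, V)} with
#' \eqn{V = \sum_k \sigma^2_k K_k + \sigma^2_R I}, returns
#' \deqn{\ell_R = -\tfrac12\left[(n-p)\log 2\pi + \log|V| +
#'   \log|X^T V^{-1} X| + y^T P y\right]}
#' where \eqn{P = V^{-1} - V^{-1}X(X^TV^{-1}X)^{-1}X^TV^{-1}} is the REML
#' projection and \eqn{p = \mathrm{rank}(X)}.  The \eqn{-(n-p)/2\log 2\pi}
#' constant is included, so values are comparable across implementations
#' that use the same convention.
#'
#' @param y numeric phenotype vector.
#' @param X fixed-effect design matrix (full column rank; include the
#'   intercept column).
#' @param Klist list of covariance-structure matrices (each n x n,
#'   [RelationshipMatrix] or plain matrix), possibly empty.
#' @param sigma2 named numeric vector of variances: one entry per element
#'   of `Klist` (matched by position) plus a final residual entry; the
#'   residual multiplies the identity.
#' @return the restricted log-likelihood (scalar).
#' @export
restrictedLoglik <- function(y, X, Klist = list(), sigma2) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stopf("X must have length(y) rows")
  p <- qr(X)$rank
  if (p < ncol(X)) stopf("X is singular (rank %d < %d columns)", p, ncol(X))
  if (length(sigma2) != length(Klist) + 1L)
    stopf("sigma2 must hold one variance per K matrix plus the residual")
  V <- diag(sigma2[length(sigma2)], n)
  for (k in seq_along(Klist)) {
    Kk <- Klist[[k]]
    if (is(Kk, "RelationshipMatrix")) Kk <- Kk@values
    V <- V + sigma2[k] * Kk
  }
  R <- tryCatch(chol(V), error = function(e)
    stopf("V is not positive definite at the supplied variances"))
  logdetV <- 2 * sum(log(diag(R)))
  ViX <- backsolve(R, forwardsolve(t(R), X))
  Viy <- backsolve(R, forwardsolve(t(R), y))
  M <- crossprod(X, ViX)
  Rm <- tryCatch(chol(M), error = function(e)
    stopf("X'V^-1X is singular"))
  logdetM <- 2 * sum(log(diag(Rm)))
  Xty <- crossprod(X, Viy)
  beta <- backsolve(Rm, forwardsolve(t(Rm), Xty))
  yPy <- sum(y * Viy) - sum(Xty * beta)
  -0.5 * ((n - p) * log(2 * pi) + logdetV + logdetM + yPy)
}

# --- internal REML engine on residual contrasts -----------------------------
# Projecting onto an orthonormal null-space basis Q2 of X turns REML into
# plain ML on z = Q2'y with cov  sum sigma2_k Q2'K_k Q2 + sigma2_R I;
# the residual variance is profiled out, leaving only log variance ratios.

remlData <- function(y, X, Klist) {
  n <- length(y)
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) stopf("X is singular")
  Q <- qr.Q(qrX, complete = TRUE)
  Q2 <- Q[, (p + 1):n, drop = FALSE]
  z <- drop(crossprod(Q2, y))
  Kt <- lapply(Klist, function(K) {
    if (is(K, "RelationshipMatrix")) K <- K@values
    crossprod(Q2, K %*% Q2)
  })
  list(z = z, Kt = Kt, m = n - p)
}

# negative profiled restricted loglik at log variance ratios theta
negProfiledNll <- function(theta, rd) {
  m <- rd$m
  W <- diag(1, m)
  for (k in seq_along(rd$Kt)) W <- W + exp(theta[k]) * rd$Kt[[k]]
  R <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(R)) return(1e10)
  u <- forwardsolve(t(R), rd$z)
  rss <- sum(u^2)
  0.5 * (m * log(2 * pi) + m * log(rss / m) + 2 * sum(log(diag(R))) + m)
}

# exact restricted nll as a function of the full variance vector (for the
# observed information); uses the contrast representation
contrastNll <- function(s2, rd) {
  m <- rd$m
  W <- diag(s2[length(s2)], m)
  for (k in seq_along(rd$Kt)) W <- W + s2[k] * rd$Kt[[k]]
  R <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(R)) return(1e10)
  u <- forwardsolve(t(R), rd$z)
  0.5 * (m * log(2 * pi) + 2 * sum(log(diag(R))) + sum(u^2))
}

#' Fit the (extended) animal model by REML
#'
#' Maximizes the restricted likelihood over the nonnegative orthant using a
#' log parameterization of the variance ratios (residual profiled out),
#' with seeded multi-start Nelder-Mead (a golden-section search when only
#' one ratio is free, after an eigendecomposition that makes each
#' likelihood evaluation linear in n).  Fixed effects are estimated by
#' generalized least squares at the optimum; standard errors of the
#' variance components come from the observed information (numerical
#' Hessian on the variance scale), when invertible.
#'
#' @param phenotypes data.frame with columns `id`, `y`, plus any fixed or
#'   grouping columns referenced below.
#' @param random named list of random terms (order kept): each element is a
#'   [RelationshipMatrix] whose ids cover `phenotypes$id` (e.g. A, C, or a
#'   Hadamard interaction matrix), or the *name* of a column of
#'   `phenotypes` to use as an i.i.d. grouping factor (maternal id, brood
#'   id, environment id).  The residual is always added.
#' @param fixed character vector of fixed-effect column names (the
#'   intercept is always included); factors are expanded by
#'   [stats::model.matrix()].
#' @param nStarts number of optimizer starts (first at equal ratios, the
#'   rest jittered; seeded).
#' @param seed integer seed for the start jitter.
#' @param maxit,reltol Nelder-Mead iteration cap and relative convergence
#'   tolerance per start.
#' @param ridgeTol absolute correlation between two projected covariance
#'   structures above which a collinearity ridge warning is attached to the
#'   fit (the A-C confounding of unmanipulated designs).
#' @return an [AnimalModelFit].
#' @export
fitAnimalModel <- function(phenotypes, random = list(), fixed = character(0),
                           nStarts = 3L, seed = 1L, maxit = 500L,
                           reltol = 1e-8, ridgeTol = 0.999) {
  if (!all(c("id", "y") %in% names(phenotypes)))
    stopf("phenotypes needs 'id' and 'y' columns")
  keep <- !is.na(phenotypes$y)
  phenotypes <- phenotypes[keep, , drop = FALSE]
  idv <- as.character(phenotypes$id)
  y <- as.numeric(phenotypes$y)
  n <- length(y)
  if (length(random)) {
    if (is.null(names(random)) || any(!nzchar(names(random))))
      stopf("every random term must be named")
    if (anyDuplicated(names(random)))
      stopf("duplicated random-term names")
  }
  X <- fixedDesign(phenotypes, fixed)
  if (n < ncol(X) + length(random) + 1L)
    stopf("fewer records (%d) than parameters", n)
  Klist <- lapply(seq_along(random), function(k) {
    r <- random[[k]]
    if (is(r, "RelationshipMatrix")) {
      as.matrix(subsetMatrix(r, idv))
    } else if (is.character(r) && length(r) == 1L) {
      if (!r %in% names(phenotypes))
        stopf("grouping column '%s' not found in phenotypes", r)
      g <- as.character(phenotypes[[r]])
      # records with no group level (NA) get a zero Z row: they carry none
      # of this component's variance
      outer(g, g, function(a, b) !is.na(a) & !is.na(b) & a == b) * 1
    } else stopf("random term %d is neither a RelationshipMatrix nor a column name", k)
  })
  names(Klist) <- names(random)
  rd <- remlData(y, X, Klist)
  q <- length(Klist)
  warn <- character(0)
  if (q >= 2L) {
    for (a in seq_len(q - 1L)) for (b in (a + 1L):q) {
      r <- stats::cor(as.vector(rd$Kt[[a]]), as.vector(rd$Kt[[b]]))
      if (is.finite(r) && abs(r) > ridgeTol)
        warn <- c(warn, sprintf(
          "covariance structures '%s' and '%s' are nearly collinear (r = %.4f); estimates lie on a ridge",
          names(Klist)[a], names(Klist)[b], r))
    }
  }
  opt <- remlOptimize(rd, q, nStarts, seed, maxit, reltol)
  s2R <- opt$s2R
  est <- c(exp(opt$theta) * s2R, R = s2R)
  names(est) <- c(names(Klist), "R")
  ll <- restrictedLoglik(y, X, Klist, est)
  # GLS fixed effects at the optimum
  V <- diag(s2R, n)
  for (k in seq_len(q)) V <- V + est[k] * Klist[[k]]
  R <- chol(V)
  ViX <- backsolve(R, forwardsolve(t(R), X))
  Viy <- backsolve(R, forwardsolve(t(R), y))
  M <- crossprod(X, ViX)
  beta <- drop(solve(M, crossprod(X, Viy)))
  names(beta) <- colnames(X)
  # observed information on the variance scale
  sev <- rep(NA_real_, q + 1L)
  vc <- matrix(NA_real_, q + 1L, q + 1L)
  H <- tryCatch(stats::optimHess(est, contrastNll, rd = rd),
                error = function(e) NULL)
  if (!is.null(H)) {
    Vth <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Vth) && all(diag(Vth) > 0)) {
      vc <- Vth
      sev <- sqrt(diag(Vth))
    }
  }
  names(sev) <- names(est)
  dimnames(vc) <- list(names(est), names(est))
  new("AnimalModelFit", estimates = est, fixedEstimates = beta,
      loglik = ll, aic = -2 * ll + 2 * (q + 1L), se = sev, vcov = vc,
      converged = opt$converged, nUsed = as.integer(n),
      dataHash = objectHash(list(y, unname(X))),
      terms = if (q) names(Klist) else character(0),
      fixedTerms = fixed, warnings = warn)
}

fixedDesign <- function(phenotypes, fixed) {
  if (!length(fixed)) return(matrix(1, nrow(phenotypes), 1,
                                    dimnames = list(NULL, "(Intercept)")))
  lack <- setdiff(fixed, names(phenotypes))
  if (length(lack))
    stopf("fixed-effect column(s) not found: %s", paste(lack, collapse = ", "))
  df <- phenotypes[, fixed, drop = FALSE]
  for (j in seq_along(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  stats::model.matrix(~ ., data = df)
}

remlOptimize <- function(rd, q, nStarts, seed, maxit, reltol) {
  if (q == 0L) {
    rss <- sum(rd$z^2)
    return(list(theta = numeric(0), s2R = rss / rd$m, converged = TRUE))
  }
  if (q == 1L) {
    ev <- eigen(rd$Kt[[1]], symmetric = TRUE)
    zt <- drop(crossprod(ev$vectors, rd$z))
    lam <- ev$values
    f <- function(theta) {
      w <- 1 + exp(theta) * lam
      if (any(w <= 0)) return(1e10)
      rss <- sum(zt^2 / w)
      0.5 * (rd$m * log(2 * pi) + rd$m * log(rss / rd$m) + sum(log(w)) + rd$m)
    }
    o <- stats::optimize(f, interval = c(-30, 30), tol = 1e-10)
    # fold the boundary: ratios below ~e-25 are zero for all purposes
    theta <- o$minimum
    W <- 1 + exp(theta) * lam
    s2R <- sum(zt^2 / W) / rd$m
    return(list(theta = theta, s2R = s2R, converged = TRUE))
  }
  starts <- list(rep(0, q))
  if (nStarts > 1L) {
    jit <- withSeed(seed, matrix(stats::runif((nStarts - 1L) * q, -1.5, 1.5),
                                 ncol = q))
    for (s in seq_len(nStarts - 1L))
      starts[[s + 1L]] <- jit[s, ] + if (s %% 2L) log(0.2) else log(5)
  }
  best <- NULL
  for (st in starts) {
    o <- stats::optim(st, negProfiledNll, rd = rd, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol))
    if (is.null(best) || o$value < best$value) best <- o
  }
  theta <- pmax(best$par, -30)
  m <- rd$m
  W <- diag(1, m)
  for (k in seq_len(q)) W <- W + exp(theta[k]) * rd$Kt[[k]]
  R <- chol(W)
  u <- forwardsolve(t(R), rd$z)
  list(theta = theta, s2R = sum(u^2) / m, converged = best$convergence == 0L)
}

setMethod("show", "AnimalModelFit", function(object) {
  cat("Animal model REML fit (n =", object@nUsed, ")\n")
  cat("  converged:", object@converged, "\n")
  tab <- data.frame(variance = object@estimates, se = object@se)
  print(round(tab, 4))
  cat("  restricted logLik:", format(object@loglik), " AIC:",
      format(object@aic), "\n")
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
  invisible(object)
})

#' Variance estimates, log-likelihood and AIC accessors
#' @param fit an [AnimalModelFit].
#' @return named numeric vector / scalar.
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
varianceEstimates <- function(fit) fit@estimates

#' @rdname fit-accessors
#' @export
fixedEstimates <- function(fit) fit@fixedEstimates

#' @rdname fit-accessors
#' @export
restrictedLogLik <- function(fit) fit@loglik

#' @rdname fit-accessors
#' @export
modelAIC <- function(fit) fit@aic

#' @rdname fit-accessors
#' @export
isConverged <- function(fit) fit@converged

#' Genetic and cultural heritabilities from a fit
#'
#' Each ratio is an estimated component over the sum of all estimated
#' components (the total phenotypic variance of the fitted model):
#' \eqn{\sigma^2_A/\sigma^2_P} is the narrow-sense genetic heritability and
#' \eqn{\sigma^2_C/\sigma^2_P} the cultural component of inclusive
#' heritability.  Ratios sum to 1 over the included components and are
#' invariant to rescaling the trait.  Standard errors by the delta method
#' from the fit's variance-component covariance matrix, when available.
#'
#' @param fit a converged [AnimalModelFit].
#' @return data.frame with columns component, ratio, se.
#' @export
setMethod("heritabilities", "AnimalModelFit", function(fit) {
  if (!fit@converged) stopf("fit did not converge")
  v <- fit@estimates
  S <- sum(v)
  if (S <= 0) stopf("total estimated variance is zero")
  ratio <- v / S
  se <- rep(NA_real_, length(v))
  if (all(is.finite(fit@vcov))) {
    for (k in seq_along(v)) {
      grad <- -v[k] / S^2 + (seq_along(v) == k) / S
      se[k] <- sqrt(drop(t(grad) %*% fit@vcov %*% grad))
    }
  }
  data.frame(component = names(v), ratio = unname(ratio), se = se,
             row.names = NULL, stringsAsFactors = FALSE)
})

#' Boundary-corrected likelihood-ratio test for one variance component
#'
#' The reduced model must be nested in the full model by dropping exactly
#' one random term, on identical data and fixed effects.  Because the null
#' value (a zero variance) lies on the boundary of the parameter space,
#' the statistic is referred to the 50:50 mixture of a point mass at 0 and
#' a chi-square with 1 df: the corrected p-value is
#' `0.5 * P(chisq(1) > stat)` (so a statistic of 0 gives p = 0.5).  The
#' naive chi-square(1) p-value is reported alongside.
#'
#' @param fitFull,fitReduced [AnimalModelFit] objects.
#' @return list with `statistic`, `dropped`, `p_corrected`, `p_naive`.
#' @export
lrtComponent <- function(fitFull, fitReduced) {
  if (!identical(fitFull@dataHash, fitReduced@dataHash))
    stopf("fits are not on identical data")
  if (!identical(fitFull@fixedTerms, fitReduced@fixedTerms))
    stopf("fits differ in fixed effects")
  dropped <- setdiff(fitFull@terms, fitReduced@terms)
  if (length(dropped) != 1L || !all(fitReduced@terms %in% fitFull@terms))
    stopf("reduced model must drop exactly one random term of the full model")
  stat <- max(0, 2 * (fitFull@loglik - fitReduced@loglik))
  list(statistic = stat, dropped = dropped,
       p_corrected = 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE),
       p_naive = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' AIC comparison of animal-model fits
#'
#' `AIC = -2 logLik_R + 2 k`, with `k` the number of estimated variance
#' parameters (fixed effects are excluded: under REML the restricted
#' likelihood is only comparable across models sharing the same fixed
#' structure, and fits with different fixed effects or different data are
#' refused).
#'
#' @param fits named list of [AnimalModelFit] objects on identical data
#'   with identical fixed effects.
#' @return data.frame ranked by AIC with columns model, nVariance, logLik,
#'   AIC, dAIC, rank.
#' @export
compareModels <- function(fits) {
  if (!length(fits)) stopf("no fits supplied")
  if (is.null(names(fits)))
    names(fits) <- paste0("model", seq_along(fits))
  h <- vapply(fits, function(f) f@dataHash, character(1))
  if (length(unique(h)) != 1L)
    stopf("fits are not all on identical data (mismatched data hash)")
  fx <- vapply(fits, function(f) paste(f@fixedTerms, collapse = "+"),
               character(1))
  if (length(unique(fx)) != 1L)
    stopf("REML AIC comparison across different fixed effects is refused")
  aic <- vapply(fits, function(f) f@aic, numeric(1))
  out <- data.frame(
    model = names(fits),
    nVariance = vapply(fits, function(f) length(f@estimates), integer(1)),
    logLik = vapply(fits, function(f) f@loglik, numeric(1)),
    AIC = aic, dAIC = aic - min(aic), stringsAsFactors = FALSE,
    row.names = NULL)
  out <- out[order(out$AIC), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Gene-by-culture interaction covariance structure
#'
#' The direct analogue of the variance-structure treatment of
#' gene-by-environment interaction: the Hadamard (elementwise) product
#' \eqn{A \circ C}, positive semidefinite by the Schur product theorem
#' whenever A and C are.  The diagonal (which equals
#' \eqn{(1+F_i)(1+F^c_i)}) is rescaled to exactly 1 by the congruence
#' \eqn{D^{-1/2} (A \circ C) D^{-1/2}}, which preserves positive
#' semidefiniteness.
#'
#' @param A,C [RelationshipMatrix] objects over the same ids in the same
#'   order.
#' @return a [RelationshipMatrix] with unit diagonal.
#' @export
gxcInteractionMatrix <- function(A, C) {
  if (!identical(A@ids, C@ids))
    stopf("A and C must be over the same ids in the same order")
  H <- A@values * C@values
  d <- diag(H)
  if (any(d <= 0)) stopf("interaction diagonal must be positive")
  s <- 1 / sqrt(d)
  relationshipMatrix(H * outer(s, s), A@ids)
}
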