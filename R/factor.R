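#' Partial correlations from the precision matrix
#'
#' The partial correlation of each pair of variables controlling for all
#' remaining variables, obtained from the inverse of the correlation
#' matrix: `pr_ij = -P_ij / sqrt(P_ii P_jj)` off the diagonal, where `P`
#' is the precision (inverse correlation) matrix.  Two-sided p-values use
#' the t approximation on `n - 2 - g` degrees of freedom, `g` being the
#' number of controlled variables.
#'
#' @param data numeric data frame or matrix (observations x variables);
#'   rows with missing values are dropped.
#' @return object of class `dc_pcor`: `estimate` (symmetric matrix, unit
#'   diagonal), `p.value`, `n`, `df`.
#' @export
partial_correlations <- function(data) {
  x <- as.matrix(data)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); p <- ncol(x)
  if (n <= p) stop("need more observations than variables")
  R <- stats::cor(x)
  P <- tryCatch(solve(R), error = function(e) {
    stop("correlation matrix is singular; drop collinear variables")
  })
  d <- 1 / sqrt(diag(P))
  pr <- -P * outer(d, d)
  diag(pr) <- 1
  df <- n - p  # n - 2 - (p - 2) controls
  tstat <- pr * sqrt(df / pmax(1 - pr^2, .Machine$double.eps))
  pv <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  diag(pv) <- NA_real_
  dimnames(pr) <- dimnames(pv) <- dimnames(R)
  structure(list(estimate = pr, p.value = pv, n = n, df = df),
            class = "dc_pcor")
}

#' @export
print.dc_pcor <- function(x, digits = 2, ...) {
  cat(sprintf("Partial correlations (n = %d, df = %d):\n", x$n, x$df))
  print(round(x$estimate, digits))
  invisible(x)
}

#' Squared multiple correlations
#'
#' SMC of each variable with all others, `1 - 1/diag(R^-1)`; used as the
#' communality estimates placed on the diagonal of the reduced
#' correlation matrix for common-factors parallel analysis.
#'
#' @param R correlation matrix.
#' @return numeric vector of SMCs.
#' @export
smc <- function(R) {
  1 - 1 / diag(solve(R))
}

reduced_eigenvalues <- function(R) {
  Rr <- R
  diag(Rr) <- smc(R)
  eigen(Rr, symmetric = TRUE, only.values = TRUE)$values
}

smooth_correlation <- function(R, eps = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) > eps) return(R)
  vals <- pmax(e$values, eps)
  S <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- 1 / sqrt(diag(S))
  S * outer(d, d)
}

#' Horn's parallel analysis with a common-factors model
#'
#' Suggests the number of factors to retain: eigenvalues of the reduced
#' correlation matrix (squared multiple correlations on the diagonal) are
#' compared with the average (or an upper quantile) of the corresponding
#' eigenvalues from `n_iter` random standard-normal datasets of the same
#' shape.  The suggested count is the number of leading observed
#' eigenvalues exceeding their random counterparts.
#'
#' @param data numeric data frame/matrix (observations x items).
#' @param n_iter number of random datasets (>= 100).
#' @param seed integer seed for the random eigenvalue reference.
#' @param quantile `NULL` (default) compares against the mean random
#'   eigenvalue; a value such as 0.95 compares against that quantile.
#' @return object of class `dc_parallel`: `n_factors`, `eigen_observed`,
#'   `eigen_reference`, `n_iter`, `criterion`.
#' @export
parallel_analysis <- function(data, n_iter = 200L, seed = 1L, quantile = NULL) {
  x <- as.matrix(data)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x); p <- ncol(x)
  if (n_iter < 100L) stop("n_iter must be at least 100")
  R <- stats::cor(x)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 1e-8) {
    warning("correlation matrix not positive definite; smoothing applied")
    R <- smooth_correlation(R)
  }
  ev_obs <- reduced_eigenvalues(R)
  ev_rand <- with_local_seed(seed, {
    t(vapply(seq_len(n_iter), function(i) {
      reduced_eigenvalues(stats::cor(matrix(stats::rnorm(n * p), n, p)))
    }, numeric(p)))
  })
  ref <- if (is.null(quantile)) {
    colMeans(ev_rand)
  } else {
    apply(ev_rand, 2L, stats::quantile, probs = quantile, names = FALSE)
  }
  exceeds <- ev_obs > ref
  n_factors <- if (exceeds[1]) {
    runs <- rle(exceeds)
    runs$lengths[1]
  } else 0L
  structure(list(n_factors = as.integer(n_factors),
                 eigen_observed = ev_obs, eigen_reference = ref,
                 n_iter = n_iter,
                 criterion = if (is.null(quantile)) "mean"
                             else sprintf("q%.2f", quantile)),
            class = "dc_parallel")
}

#' @export
print.dc_parallel <- function(x, ...) {
  cat(sprintf("Parallel analysis (common factors, %d iterations, %s criterion): retain %d factor(s)\n",
              x$n_iter, x$criterion, x$n_factors))
  tab <- rbind(observed = round(x$eigen_observed, 3),
               reference = round(x$eigen_reference, 3))
  colnames(tab) <- seq_len(ncol(tab))
  print(tab)
  invisible(x)
}

# quartimin criterion value and gradient (oblimin with gamma = 0)
vgq_quartimin <- function(L) {
  L2 <- L^2
  k <- ncol(L)
  N <- matrix(1, k, k) - diag(k)
  list(f = sum(L2 * (L2 %*% N)) / 4, Gq = L * (L2 %*% N))
}

#' Oblimin (quartimin) rotation by gradient projection
#'
#' Oblique rotation of an unrotated loading matrix minimizing the
#' quartimin criterion (oblimin family with gamma = 0) via the gradient
#' projection algorithm on the manifold of oblique rotation matrices.
#'
#' @param A unrotated loadings (items x factors).
#' @param maxit,eps iteration cap and convergence tolerance on the
#'   projected gradient norm.
#' @return list `loadings` (pattern matrix), `Phi` (factor correlation
#'   matrix), `criterion`, `converged`, `iterations`.
#' @export
oblimin_rotate <- function(A, maxit = 1000L, eps = 1e-6) {
  k <- ncol(A)
  if (k < 2L) return(list(loadings = A, Phi = diag(1), criterion = 0,
                          converged = TRUE, iterations = 0L))
  Tm <- diag(k)
  L <- A
  vg <- vgq_quartimin(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% solve(Tm))
  al <- 1
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < eps) { converged <- TRUE; break }
    al <- 2 * al
    repeat {
      X <- Tm - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Lt <- A %*% t(solve(Tt))
      vg_t <- vgq_quartimin(Lt)
      if (vg_t$f < f - 0.5 * s^2 * al || al < 1e-12) break
      al <- al / 2
    }
    Tm <- Tt; L <- Lt; f <- vg_t$f
    G <- -t(t(L) %*% vg_t$Gq %*% solve(Tm))
  }
  list(loadings = L, Phi = t(Tm) %*% Tm, criterion = f,
       converged = converged, iterations = iter)
}

#' Exploratory factor analysis: maximum likelihood + oblimin
#'
#' Fits a common-factor model by maximum likelihood and applies an
#' oblique oblimin (quartimin) rotation.  Output follows the standard
#' EFA reporting layout: standardized pattern loadings, communalities
#' (h^2), the factor correlation matrix, and the per-factor variance
#' decomposition (sum-of-squares loadings, proportion of total variance,
#' cumulative variance, proportion explained, cumulative proportion).
#'
#' Deterministic conventions: factors are ordered by descending
#' sum-of-squares loadings and each factor's largest-magnitude loading is
#' made positive.
#'
#' @param data numeric data frame/matrix (observations x items); items
#'   are standardized internally.
#' @param n_factors number of factors to extract (>= 1 and admissible for
#'   the item count).
#' @param rotation `"oblimin"` (default) or `"none"`.
#' @return object of class `dc_efa`: `loadings`, `Phi`, `h2`,
#'   `uniquenesses`, `variance` (decomposition table), `n_factors`,
#'   `n_obs`, `heywood`, `converged`.
#' @export
efa <- function(data, n_factors, rotation = c("oblimin", "none")) {
  rotation <- match.arg(rotation)
  x <- as.matrix(data)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  p <- ncol(x)
  n_factors <- as.integer(n_factors)
  if (n_factors < 1L) stop("n_factors must be >= 1")
  dof <- 0.5 * ((p - n_factors)^2 - p - n_factors)
  if (dof < 0) stop(n_factors, " factors is inadmissible for ", p, " items")
  fa <- tryCatch(
    stats::factanal(x, factors = n_factors, rotation = "none",
                    control = list(nstart = 4)),
    error = function(e) stop("ML factor extraction failed to converge: ",
                             conditionMessage(e)))
  A <- matrix(fa$loadings, p, n_factors,
              dimnames = list(colnames(x), NULL))
  if (rotation == "oblimin" && n_factors > 1L) {
    rot <- oblimin_rotate(A)
    L <- rot$loadings
    Phi <- rot$Phi
    rot_converged <- rot$converged
  } else {
    L <- A
    Phi <- diag(n_factors)
    rot_converged <- TRUE
  }
  # deterministic sign and order conventions
  for (j in seq_len(n_factors)) {
    sgn <- sign(L[which.max(abs(L[, j])), j])
    if (sgn < 0) {
      L[, j] <- -L[, j]
      Phi[j, ] <- -Phi[j, ]
      Phi[, j] <- -Phi[, j]
    }
  }
  ss <- diag(Phi %*% t(L) %*% L)
  ord <- order(ss, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  Phi <- Phi[ord, ord, drop = FALSE]
  ss <- ss[ord]
  h2 <- rowSums((L %*% Phi) * L)
  heywood <- any(h2 > 1 + 1e-6) || any(fa$uniquenesses <= 0.005 + 1e-8)
  if (heywood) warning("Heywood case: communality at or above 1")
  fac_names <- paste0("Factor", seq_len(n_factors))
  dimnames(L) <- list(colnames(x), fac_names)
  dimnames(Phi) <- list(fac_names, fac_names)
  variance <- rbind(
    `SS loadings` = ss,
    `Proportion variance` = ss / p,
    `Cumulative variance` = cumsum(ss / p),
    `Proportion explained` = ss / sum(ss),
    `Cumulative proportion` = cumsum(ss / sum(ss)))
  colnames(variance) <- fac_names
  structure(list(loadings = L, Phi = Phi,
                 h2 = stats::setNames(h2, colnames(x)),
                 uniquenesses = fa$uniquenesses,
                 variance = variance,
                 n_factors = n_factors, n_obs = nrow(x),
                 heywood = heywood,
                 converged = fa$converged && rot_converged),
            class = "dc_efa")
}

#' @export
print.dc_efa <- function(x, digits = 2, cutoff = 0.1, ...) {
  cat(sprintf("ML exploratory factor analysis: %d factors, %d observations%s\n",
              x$n_factors, x$n_obs,
              if (x$heywood) " [Heywood case]" else ""))
  L <- round(x$loadings, digits)
  Lc <- format(L)
  Lc[abs(x$loadings) < cutoff] <- ""
  tab <- cbind(as.data.frame(Lc), h2 = round(x$h2, digits))
  print(tab)
  cat("\nVariance decomposition:\n")
  print(round(x$variance, digits))
  if (x$n_factors > 1L) {
    cat("\nFactor correlations:\n")
    print(round(x$Phi, digits))
  }
  invisible(x)
}

#' @export
summary.dc_efa <- function(object, threshold = 0.40, ...) {
  mask <- substantial_loadings(object, threshold)
  cross <- rownames(mask$mask)[mask$cross_loading]
  cat(sprintf("%d-factor solution over %d items; %d substantial loadings (|loading| >= %.2f)\n",
              object$n_factors, nrow(object$loadings),
              sum(mask$mask), threshold))
  if (length(cross)) {
    cat("cross-loading items:", paste(cross, collapse = ", "), "\n")
  } else {
    cat("no cross-loading items\n")
  }
  invisible(mask)
}

#' Flag substantial loadings
#'
#' Marks loadings whose magnitude is at or above the threshold
#' (inclusive; default 0.40), and reports items loading substantially on
#' more than one factor.
#'
#' @param result a [efa()] result.
#' @param threshold magnitude cutoff.
#' @return list `mask` (items x factors logical matrix), `cross_loading`
#'   (logical per item).
#' @export
substantial_loadings <- function(result, threshold = 0.40) {
  stopifnot(inherits(result, "dc_efa"))
  mask <- abs(result$loadings) >= threshold
  list(mask = mask, cross_loading = rowSums(mask) > 1L)
}
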