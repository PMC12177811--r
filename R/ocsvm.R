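## nu-one-class SVM with RBF kernel, solved by SMO on the standard one-class
## dual:  min 1/2 a'Qa  s.t.  0 <= a_i <= 1, sum(a) = nu * n.
## KKT at the optimum: free SVs have gradient == rho, bounded SVs (a = 1,
## the outliers) have gradient <= rho, inliers (a = 0) have gradient >= rho.
## The nu-property follows: at most a nu fraction of training points get a
## negative decision value, at least (nu - #free/n) do. No SVM package is
## assumed; the solver is self-contained (maximal-violating-pair selection).

.rbf_kernel <- function(X, Y = X, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-gamma * pmax(d2, 0))
}

#' Median-heuristic RBF bandwidth
#'
#' `gamma = 1 / (2 * median(pairwise distance)^2)` estimated on a subsample
#' of at most `max_n` rows; the parameter-free default used by
#' [ocsvm_fit()].
#'
#' @param X feature matrix.
#' @param max_n subsample cap for the median estimate.
#' @return scalar gamma.
#' @export
median_heuristic_gamma <- function(X, max_n = 500L) {
  n <- nrow(X)
  idx <- if (n > max_n) round(seq(1L, n, length.out = max_n)) else seq_len(n)
  med <- median(dist(X[idx, , drop = FALSE]))
  if (!is.finite(med) || med <= 0) med <- 1
  1 / (2 * med^2)
}

#' Fit a nu-one-class SVM (RBF kernel)
#'
#' @param X numeric n x p feature matrix.
#' @param nu fraction of the data to treat as outliers, in (0, 1).
#' @param gamma RBF width; default median heuristic.
#' @param tol KKT violation tolerance.
#' @param max_iter SMO iteration cap.
#' @return list with `alpha`, `rho`, `gamma`, `decision` (n training decision
#'   values; negative = outlier), `iterations`, `converged`.
#' @export
ocsvm_fit <- function(X, nu = 0.1, gamma = NULL, tol = 1e-5,
                      max_iter = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(nu > 0, nu < 1, n >= 2L)
  if (is.null(gamma)) gamma <- median_heuristic_gamma(X)
  if (is.null(max_iter)) max_iter <- max(200L * n, 20000L)
  Q <- .rbf_kernel(X, gamma = gamma)
  ## feasible start (LIBSVM convention): first floor(nu*n) at the bound
  alpha <- numeric(n)
  nfull <- floor(nu * n)
  if (nfull > 0L) alpha[seq_len(nfull)] <- 1
  if (nfull < n) alpha[nfull + 1L] <- nu * n - nfull
  g <- as.numeric(Q %*% alpha)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    gi <- g; gi[alpha >= 1 - 1e-12] <- Inf
    i <- which.min(gi)
    gj <- g; gj[alpha <= 1e-12] <- -Inf
    j <- which.max(gj)
    if (g[j] - g[i] < tol) {
      converged <- TRUE
      break
    }
    eta <- Q[i, i] + Q[j, j] - 2 * Q[i, j]
    delta <- (g[j] - g[i]) / max(eta, 1e-12)
    delta <- min(delta, 1 - alpha[i], alpha[j])
    alpha[i] <- alpha[i] + delta
    alpha[j] <- alpha[j] - delta
    g <- g + delta * (Q[, i] - Q[, j])
  }
  free <- alpha > 1e-8 & alpha < 1 - 1e-8
  rho <- if (any(free)) {
    mean(g[free])
  } else {
    lo <- suppressWarnings(max(g[alpha >= 1 - 1e-8]))
    hi <- suppressWarnings(min(g[alpha <= 1e-8]))
    mean(c(lo, hi)[is.finite(c(lo, hi))])
  }
  structure(list(alpha = alpha, rho = rho, gamma = gamma,
                 decision = g - rho, X = X, iterations = it,
                 converged = converged),
            class = "ocsvm")
}

#' Decision values for new points
#' @param object an `ocsvm` fit; @param newdata matrix of rows to score.
#' @param ... unused.
#' @return numeric decision values (negative = outlier).
#' @export
predict.ocsvm <- function(object, newdata, ...) {
  sv <- object$alpha > 1e-12
  K <- .rbf_kernel(as.matrix(newdata), object$X[sv, , drop = FALSE],
                   gamma = object$gamma)
  as.numeric(K %*% object$alpha[sv]) - object$rho
}

#' Remove outlier streamlines with a one-class SVM
#'
#' Streamlines are resampled to a common vertex count, flattened to
#' coordinate vectors, and scored by a nu-one-class SVM with RBF kernel
#' (median-heuristic width). Streamlines with negative decision values are
#' removed; by the nu-property the removed fraction is approximately `nu`.
#'
#' @param b a `tract_bundle`.
#' @param nu outlier fraction parameter (default 0.1).
#' @param n_vertices resampling target before flattening (default 50).
#' @param gamma optional RBF width override.
#' @return list with `kept` and `removed` bundles (`removed` may have an
#'   empty streamline list) and `decision` values. Bundles with fewer than
#'   10 streamlines are returned unfiltered with a warning.
#' @export
remove_outliers <- function(b, nu = 0.1, n_vertices = 50L, gamma = NULL) {
  n <- n_streamlines(b)
  if (n < 10L) {
    warning("fewer than 10 streamlines; skipping outlier removal")
    removed <- b
    removed$streamlines <- list()
    return(list(kept = b, removed = removed, decision = rep(Inf, n)))
  }
  rs <- lapply(b$streamlines, resample_streamline, n = n_vertices)
  X <- t(vapply(rs, function(s) as.numeric(unclass(s)),
                numeric(3L * n_vertices)))
  fit <- ocsvm_fit(X, nu = nu, gamma = gamma)
  keep <- fit$decision >= 0
  kept <- b; kept$streamlines <- b$streamlines[keep]
  removed <- b; removed$streamlines <- b$streamlines[!keep]
  if (length(kept$streamlines) == 0L)
    stop("one-class SVM removed every streamline; check nu/gamma")
  list(kept = kept, removed = removed, decision = fit$decision)
}
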