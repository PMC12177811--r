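## Bin-wise nonparametric comparison with TFCE + max-statistic permutation
## FWE correction, whole-tract tests, Barnard's unconditional exact test,
## crowding classification and the logistic crowding models.

#' Mann-Whitney U z-score
#'
#' U for group a against group b with the tie-corrected normal
#' approximation: `z = (U - m*n/2) / sqrt(var)`, positive when group a is
#' stochastically larger. The reported two-sided p applies a 0.5 continuity
#' correction (the z itself, which TFCE consumes, does not).
#'
#' @param a,b numeric vectors (each length >= 2 after `NA` removal).
#' @return list with `U`, `z`, `p`.
#' @export
mannwhitney_z <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  m <- length(a); n <- length(b)
  if (m < 2L || n < 2L) stop("each group needs at least 2 non-missing values")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  N <- m + n
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties)
  v <- m * n / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (v <= 0) return(list(U = U, z = 0, p = 1))
  z <- (U - m * n / 2) / sqrt(v)
  zcc <- max(abs(U - m * n / 2) - 0.5, 0) / sqrt(v)
  list(U = U, z = z, p = min(1, 2 * pnorm(-zcc)))
}

#' Threshold-free cluster enhancement of a 1-D z-profile
#'
#' `TFCE_j = sum_i e(i*dh, j)^E * (i*dh)^H * dh` over threshold heights
#' `i*dh <= max(z)`, where `e` is the contiguous supra-threshold run length
#' (in bins) containing bin j. With `two_sided = TRUE` (default) the same
#' sum over `-z` is added, so both directions share one score.
#'
#' @param z numeric vector of per-bin z-scores.
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh threshold step (default 0.01).
#' @param two_sided enhance both signs (default TRUE).
#' @return numeric vector of per-bin TFCE scores.
#' @export
tfce_1d <- function(z, E = 0.5, H = 2, dh = 0.01, two_sided = TRUE) {
  stopifnot(all(is.finite(z)), dh > 0)
  .tfce_scores_cpp(as.numeric(z), E, H, dh, two_sided)
}

#' TFCE parameter bundle
#' @param E,H,dh TFCE exponents and step (defaults 0.5, 2, 0.01).
#' @param n_permutations permutation count (default 10000).
#' @param seed RNG seed for the permutation draw.
#' @export
tfce_params <- function(E = 0.5, H = 2, dh = 0.01, n_permutations = 10000L,
                        seed = 1L) {
  stopifnot(n_permutations >= 100L)
  list(E = E, H = H, dh = dh, n_permutations = as.integer(n_permutations),
       seed = seed)
}

## z-scores for many label permutations at once. ranks/ties per bin are
## label-invariant, so each permutation only needs the group-a rank sum.
.perm_z_matrix <- function(profiles, G) {
  N <- nrow(G)
  M <- ncol(profiles)
  Z <- matrix(0, N, M)
  n_all <- ncol(G)
  for (j in seq_len(M)) {
    S <- which(!is.na(profiles[, j]))
    nj <- length(S)
    if (nj < 4L) next
    r <- rank(profiles[S, j])
    ties <- table(profiles[S, j])
    tie_term <- sum(ties^3 - ties)
    Gs <- G[, S, drop = FALSE]
    m <- as.numeric(Gs %*% rep(1, nj))
    R <- as.numeric(Gs %*% r)
    U <- R - m * (m + 1) / 2
    v <- m * (nj - m) / 12 * ((nj + 1) - tie_term / (nj * (nj - 1)))
    ok <- v > 0 & m >= 2 & (nj - m) >= 2
    Z[ok, j] <- (U[ok] - m[ok] * (nj - m[ok]) / 2) / sqrt(v[ok])
  }
  Z
}

#' Bin-wise group comparison with TFCE and permutation FWE correction
#'
#' Observed per-bin Mann-Whitney z-scores are TFCE-enhanced (both signs);
#' `N` uniform label permutations are re-scored the same way, the per-
#' permutation maximum over bins (and signs) forms the null distribution
#' `D0`, and `p_j = (1/N) * sum_i 1[D0_i >= TFCE_j(obs)]`. Subjects with a
#' missing bin are dropped pairwise per bin. If the distinct label
#' assignments number at most `N`, complete enumeration replaces sampling.
#'
#' @param profiles subjects x bins matrix (`NA` = missing bin).
#' @param labels length-`nrow(profiles)` group labels (2 levels; the first
#'   level encountered is "group a", the positive z direction).
#' @param params a [tfce_params()].
#' @param alpha significance level for the reported mask (default 0.05).
#' @param smoothing use `(1 + count) / (1 + N)` instead of the raw `count/N`
#'   estimator (default FALSE, the formula-faithful choice; raw p can be 0).
#' @return a `tfce_result` list: `z_obs`, `tfce_obs`, `null_maxima`,
#'   `p_corrected`, `significant`, `n_permutations`, `complete_enumeration`.
#' @export
permutation_fwe <- function(profiles, labels, params = tfce_params(),
                            alpha = 0.05, smoothing = FALSE) {
  profiles <- as.matrix(profiles)
  labels <- as.character(labels)
  stopifnot(nrow(profiles) == length(labels))
  lev <- unique(labels)
  if (length(lev) != 2L) stop("labels must have exactly 2 levels")
  is_a <- labels == lev[1L]
  if (sum(is_a) < 2L || sum(!is_a) < 2L) stop(">= 2 subjects per group required")
  n <- length(labels)
  m_a <- sum(is_a)

  z_obs <- vapply(seq_len(ncol(profiles)), function(j) {
    x <- profiles[is_a, j]; y <- profiles[!is_a, j]
    if (sum(!is.na(x)) < 2L || sum(!is.na(y)) < 2L) return(0)
    mannwhitney_z(x, y)$z
  }, numeric(1))
  tfce_obs <- tfce_1d(z_obs, params$E, params$H, params$dh)

  n_distinct <- choose(n, m_a)
  complete <- is.finite(n_distinct) && n_distinct <= params$n_permutations
  G <- .with_seed(params$seed, {
    if (complete) {
      combos <- utils::combn(n, m_a)
      G <- matrix(0, ncol(combos), n)
      G[cbind(rep(seq_len(ncol(combos)), each = m_a), as.integer(combos))] <- 1
      G
    } else {
      t(replicate(params$n_permutations, {
        g <- numeric(n)
        g[sample.int(n, m_a)] <- 1
        g
      }))
    }
  })
  Znull <- .perm_z_matrix(profiles, G)
  D0 <- .tfce_max_batch_cpp(Znull, params$E, params$H, params$dh)
  N <- length(D0)
  counts <- vapply(tfce_obs, function(tj) sum(D0 >= tj), numeric(1))
  p <- if (smoothing) (1 + counts) / (1 + N) else counts / N
  structure(list(z_obs = z_obs, tfce_obs = tfce_obs, null_maxima = D0,
                 p_corrected = p, significant = p < alpha,
                 n_permutations = N, complete_enumeration = complete,
                 params = params, alpha = alpha),
            class = "tfce_result")
}

#' @export
print.tfce_result <- function(x, ...) {
  df <- data.frame(bin = seq_along(x$z_obs), z = round(x$z_obs, 3),
                   tfce = round(x$tfce_obs, 3),
                   p_corrected = round(x$p_corrected, 4),
                   significant = x$significant)
  cat(sprintf("<tfce_result> %d permutations%s\n", x$n_permutations,
              if (x$complete_enumeration) " (complete enumeration)" else ""))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Whole-tract group comparison
#'
#' Welch two-sided t-test (default) with pooled-SD Cohen's d
#' `(mean_a - mean_b) / s_pooled`; a Mann-Whitney alternative is available.
#'
#' @param values_a,values_b per-subject whole-tract means.
#' @param method `"welch"` or `"mannwhitney"`.
#' @return list with `p`, `cohens_d`, `mean_a`, `mean_b`, `method`.
#' @export
whole_tract_compare <- function(values_a, values_b,
                                method = c("welch", "mannwhitney")) {
  method <- match.arg(method)
  a <- values_a[!is.na(values_a)]; b <- values_b[!is.na(values_b)]
  if (length(a) < 2L || length(b) < 2L) stop("each group needs >= 2 values")
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  if (sp == 0) stop("zero pooled SD; Cohen's d undefined")
  d <- (mean(a) - mean(b)) / sp
  p <- if (method == "welch") {
    stats::t.test(a, b)$p.value
  } else {
    mannwhitney_z(a, b)$p
  }
  list(p = p, cohens_d = d, mean_a = mean(a), mean_b = mean(b),
       method = method)
}

#' Barnard's unconditional exact test for a 2 x 2 table
#'
#' Columns are the two groups (column sums fixed by design), rows the binary
#' outcome. The two-sided p maximizes, over a nuisance success probability
#' grid of step `grid_step`, the total probability of tables whose pooled-
#' variance score statistic is at least as extreme as observed.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @param grid_step nuisance grid resolution (default 0.001).
#' @return list with `p`, `statistic`, `nuisance_at_max`.
#' @export
barnard_exact <- function(table, grid_step = 0.001) {
  tb <- as.matrix(table)
  stopifnot(all(dim(tb) == c(2L, 2L)), all(tb >= 0), all(tb == round(tb)))
  c1 <- sum(tb[, 1L]); c2 <- sum(tb[, 2L])
  if (c1 == 0L || c2 == 0L) return(list(p = 1, statistic = 0,
                                        nuisance_at_max = NA_real_))
  score <- function(a, b) {
    ph <- (a + b) / (c1 + c2)
    den <- sqrt(ph * (1 - ph) * (1 / c1 + 1 / c2))
    ifelse(den > 0, (a / c1 - b / c2) / den, 0)
  }
  t_obs <- score(tb[1L, 1L], tb[1L, 2L])
  a <- rep(0:c1, times = c2 + 1L)
  b <- rep(0:c2, each = c1 + 1L)
  extreme <- abs(score(a, b)) >= abs(t_obs) - 1e-12
  a <- a[extreme]; b <- b[extreme]
  lchoose_ab <- lchoose(c1, a) + lchoose(c2, b)
  grid <- seq(grid_step, 1 - grid_step, by = grid_step)
  pmax_val <- 0; pi_at <- NA_real_
  for (pi0 in grid) {
    pr <- sum(exp(lchoose_ab + (a + b) * log(pi0) +
                    (c1 + c2 - a - b) * log(1 - pi0)))
    if (pr > pmax_val) { pmax_val <- pr; pi_at <- pi0 }
  }
  list(p = min(1, pmax_val), statistic = t_obs, nuisance_at_max = pi_at)
}

#' Classify the crowding cognitive profile
#'
#' Crowding: verbal IQ exceeds performance IQ by at least `threshold`
#' points (default 10), i.e. relative verbal preservation at the expense of
#' nonverbal function.
#'
#' @param viq,piq Wechsler verbal / performance IQ scores.
#' @param threshold minimum VIQ - PIQ difference (default 10).
#' @return list with `delta` and logical `crowding` (`NA` when a score is
#'   missing).
#' @export
classify_crowding <- function(viq, piq, threshold = 10) {
  delta <- viq - piq
  list(delta = delta, crowding = ifelse(is.na(delta), NA, delta >= threshold))
}

## ridge-stabilized logistic fit for separated data: penalized IRLS with a
## small L2 penalty on the slopes (not the intercept)
.ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 100L) {
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- numeric(p)
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    H <- crossprod(X, X * W) + pen
    gr <- crossprod(X, y - mu) - pen %*% beta
    step <- solve(H, gr)
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  se <- sqrt(diag(solve(crossprod(X, X * (mu * (1 - mu))) + pen)))
  list(beta = as.numeric(beta), se = se)
}

.fit_one_logistic <- function(df, age_var) {
  form <- stats::as.formula(paste("crowding ~", age_var,
                                  "+ norm_fa + affected_right"))
  X <- stats::model.matrix(form, df)
  y <- df$crowding
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = df),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  if (sep || anyNA(coef(fit)) || any(!is.finite(co)) ||
      isTRUE(max(abs(coef(fit)), na.rm = TRUE) > 50)) {
    sep <- TRUE
    rg <- .ridge_logistic(X, y)
    est <- rg$beta; se <- rg$se
  } else {
    est <- co[, 1L]; se <- co[, 2L]
  }
  zv <- est / se
  pv <- 2 * pnorm(-abs(zv))
  k <- length(est)
  eta <- as.numeric(X %*% est)
  mu <- 1 / (1 + exp(-eta))
  ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  nobs <- length(y)
  tab <- data.frame(term = colnames(X), coefficient = est, se = se,
                    z = zv, p = pv, row.names = NULL)
  list(terms = tab,
       aic = -2 * ll + 2 * k,
       bic = -2 * ll + log(nobs) * k,
       pseudo_r2 = 1 - ll / ll0,
       llr_p = pchisq(2 * (ll - ll0), df = k - 1L, lower.tail = FALSE),
       condition_number = kappa(X, exact = TRUE),
       separation = sep, n = nobs, age_variable = age_var)
}

#' Logistic models of crowding
#'
#' Fits the three standard specifications -- crowding on one age covariate
#' (`age_at_surgery`, `age_at_onset`, or `age_at_scan`) plus normalized
#' whole-tract FA and the affected-hemisphere indicator (right affected =
#' contralesional left). Continuous covariates are z-scored. Each model
#' reports coefficients/SE/z/p, AIC, BIC, McFadden pseudo-R2, the
#' likelihood-ratio p against the intercept-only model, and the design
#' matrix condition number. Perfect separation triggers a flagged
#' ridge-stabilized refit.
#'
#' @param subjects subject data.frame (patients only are used) with `viq`,
#'   `piq`, ages and `contralesional_hemisphere`.
#' @param whole_tract_norm_fa normalized whole-tract FA per subject row.
#' @param crowding_threshold VIQ - PIQ cut (default 10).
#' @return list of three model summaries, class `crowding_models`.
#' @export
fit_crowding_models <- function(subjects, whole_tract_norm_fa,
                                crowding_threshold = 10) {
  stopifnot(nrow(subjects) == length(whole_tract_norm_fa))
  keep <- subjects$group == "patient"
  df <- subjects[keep, , drop = FALSE]
  df$norm_fa <- whole_tract_norm_fa[keep]
  cl <- classify_crowding(df$viq, df$piq, crowding_threshold)
  df$crowding <- as.numeric(cl$crowding)
  df$affected_right <- as.numeric(df$contralesional_hemisphere == "left")
  need <- c("crowding", "norm_fa", "age_at_surgery", "age_at_onset",
            "age_at_scan", "affected_right")
  df <- df[stats::complete.cases(df[, need]), , drop = FALSE]
  if (nrow(df) < 10L) stop(">= 10 labeled subjects with complete covariates required")
  zscore <- function(x) (x - mean(x)) / sd(x)
  for (v in c("norm_fa", "age_at_surgery", "age_at_onset", "age_at_scan"))
    df[[v]] <- zscore(df[[v]])
  models <- lapply(c("age_at_surgery", "age_at_onset", "age_at_scan"),
                   function(v) .fit_one_logistic(df, v))
  names(models) <- c("model1_age_at_surgery", "model2_age_at_onset",
                     "model3_age_at_scan")
  structure(models, class = "crowding_models")
}

#' @export
print.crowding_models <- function(x, ...) {
  for (nm in names(x)) {
    m <- x[[nm]]
    cat(sprintf("\n%s (n=%d)%s\n", nm, m$n,
                if (m$separation) " [ridge-stabilized: separation]" else ""))
    print(transform(m$terms, coefficient = round(coefficient, 3),
                    se = round(se, 3), z = round(z, 2), p = round(p, 4)),
          row.names = FALSE)
    cat(sprintf("  AIC %.2f  BIC %.2f  pseudo-R2 %.3f  LLR p %.4g  cond %.2f\n",
                m$aic, m$bic, m$pseudo_r2, m$llr_p, m$condition_number))
  }
  invisible(x)
}
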