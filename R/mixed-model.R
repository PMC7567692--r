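#' Fit a single-kernel G-BLUP mixed model by REML
#'
#' Fits `y = 1 mu + u + e` with `u ~ N(0, sigma_a^2 K)` and
#' `e ~ N(0, sigma_e^2 I)` by restricted maximum likelihood. A single
#' eigendecomposition of `K` reduces the problem to a one-dimensional
#' search over the log variance ratio `log(sigma_a^2 / sigma_e^2)` in
#' `[-10, 10]` (Brent, tolerance 1e-8); boundary fits (`sigma_a^2 = 0`) are
#' returned, not errored. GEBVs are the conditional means of `u` given the
#' data.
#'
#' @param y Numeric phenotype vector, aligned to `K` (names, when present
#'   on both, are checked).
#' @param K Kinship matrix (symmetric PSD; see [make_psd()]).
#' @return A list of class `gblup_fit`: `mu_hat`, `sigma_a2`, `sigma_e2`,
#'   `gebv`, `loglik` (REML), `h2` (narrow-sense, [heritability()]),
#'   `converged`, `boundary`, `flags`.
#' @examples
#' set.seed(1)
#' K <- tcrossprod(matrix(rnorm(200), 20)) / 10
#' u <- drop(chol(K + diag(1e-6, 20)) %*% rnorm(20))
#' fit <- fit_gblup(u + rnorm(20, 0, 0.5), K)
#' fit$h2
#' @export
fit_gblup <- function(y, K) {
  stopifnot(is.numeric(y), length(y) == nrow(K))
  if (any(!is.finite(y))) stop("non-finite phenotype values")
  if (length(y) < 10) stop("need at least 10 observations")
  if (!is.null(names(y)) && !is.null(rownames(K)) &&
      !identical(names(y), rownames(K)))
    stop("phenotype names do not match kinship individual IDs")
  n <- length(y)
  flags <- character()
  if (stats::var(y) < 1e-14) {
    gebv <- stats::setNames(numeric(n), names(y))
    return(structure(list(mu_hat = mean(y), sigma_a2 = 0, sigma_e2 = 0,
                          gebv = gebv, loglik = NA_real_, h2 = 0,
                          converged = TRUE, boundary = TRUE,
                          flags = "constant_response"),
                     class = "gblup_fit"))
  }
  eg <- eigen(unclass(K), symmetric = TRUE)
  d <- pmax(eg$values, 0)
  if (max(d) - min(d) < 1e-10 * max(1, max(d)))
    flags <- c(flags, "unidentifiable")  # K proportional to I: ratio not estimable
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))

  # profiled REML log-likelihood at log ratio t = log(sigma_a2/sigma_e2)
  reml_ll <- function(t) {
    lam <- exp(t)
    h <- lam * d + 1
    xhx <- sum(xt^2 / h)
    bh <- sum(xt * yt / h) / xhx
    r2 <- sum((yt - xt * bh)^2 / h)
    se2 <- r2 / (n - 1)
    -0.5 * ((n - 1) * log(2 * pi * se2) + sum(log(h)) + log(xhx) + (n - 1))
  }
  opt <- stats::optimize(reml_ll, c(-10, 10), maximum = TRUE, tol = 1e-8)
  # compare against the sigma_a2 = 0 boundary (OLS residual REML)
  ll0 <- {
    bh0 <- mean(y)
    se20 <- sum((y - bh0)^2) / (n - 1)
    -0.5 * ((n - 1) * log(2 * pi * se20) + log(n) + (n - 1))
  }
  at_lower <- opt$maximum < -10 + 1e-3
  if (ll0 >= opt$objective - 1e-8 || at_lower) {
    lam <- 0; ll <- ll0
  } else {
    lam <- exp(opt$maximum); ll <- opt$objective
  }
  h <- lam * d + 1
  xhx <- sum(xt^2 / h)
  mu <- sum(xt * yt / h) / xhx
  rt <- yt - xt * mu
  se2 <- sum(rt^2 / h) / (n - 1)
  sa2 <- lam * se2
  gebv <- if (lam == 0) numeric(n) else drop(U %*% (lam * d / h * rt))
  names(gebv) <- names(y)
  boundary <- lam == 0 || opt$maximum > 10 - 1e-3
  structure(list(mu_hat = mu, sigma_a2 = sa2, sigma_e2 = se2, gebv = gebv,
                 loglik = ll, h2 = if (sa2 + se2 > 0) sa2 / (sa2 + se2) else 0,
                 converged = TRUE, boundary = boundary, flags = flags),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("<gblup_fit> mu=%.4g  sigma_a2=%.4g  sigma_e2=%.4g  h2=%.3f  REML logLik=%.3f%s\n",
              x$mu_hat, x$sigma_a2, x$sigma_e2, x$h2, x$loglik,
              if (isTRUE(x$boundary)) "  [boundary]" else ""))
  invisible(x)
}

#' Predict GEBVs for unphenotyped (holdout) individuals
#'
#' Fits the single-kernel model on the training individuals and projects to
#' the holdout set through the kinship:
#' `u_ho = K[ho, tr] (K[tr, tr] + (sigma_e2/sigma_a2) I)^-1 (y_tr - mu)`.
#' When the training fit is at the `sigma_a2 = 0` boundary all holdout
#' GEBVs are 0.
#'
#' @param y_train Phenotypes of the training individuals.
#' @param K Kinship over all individuals (training and holdout).
#' @param train,holdout Integer or character indices into `K`.
#' @return List: `gebv` (named holdout GEBVs), `fit` (the training
#'   [fit_gblup()] result).
#' @export
predict_holdout <- function(y_train, K, train, holdout) {
  Kt <- unclass(K)[train, train, drop = FALSE]
  fit <- fit_gblup(y_train, Kt)
  ids <- if (is.character(holdout)) holdout else rownames(K)[holdout]
  if (fit$sigma_a2 <= 0) {
    gebv <- stats::setNames(numeric(length(holdout)), ids)
    return(list(gebv = gebv, fit = fit))
  }
  delta <- fit$sigma_e2 / fit$sigma_a2
  A <- Kt + diag(delta, nrow(Kt))
  sol <- tryCatch(solve(A, y_train - fit$mu_hat),
                  error = function(e) stop("singular training system: ",
                                           conditionMessage(e)))
  gebv <- drop(unclass(K)[holdout, train, drop = FALSE] %*% sol)
  names(gebv) <- ids
  list(gebv = gebv, fit = fit)
}

#' Fit a two-kernel (Q + G) mixed model by REML
#'
#' Fits `y = 1 mu + u_1 + u_2 + e` with `u_k ~ N(0, sigma_k^2 K_k)`. The
#' residual variance is profiled out and the two log variance ratios are
#' optimized by Nelder-Mead from several deterministic starting points.
#' Total GEBVs are the sum of the two component BLUPs.
#'
#' @param y Phenotype vector.
#' @param K1,K2 Kinship matrices (e.g. a QTL-peak haplotype kernel and a
#'   genome-background kernel).
#' @param n_starts Number of deterministic restarts (up to 5).
#' @param max_eval Nelder-Mead evaluation budget per start.
#' @return A list of class `gblup_fit2`: `mu_hat`, `sigma1_2`, `sigma2_2`,
#'   `sigma_e2`, `gebv`, `gebv1`, `gebv2`, `loglik`, `converged`, `flags`.
#'   When `K1` and `K2` are (near) identical the split between the two
#'   components is not unique; the fit is flagged `non_unique_split`.
#' @export
fit_two_kernel <- function(y, K1, K2, n_starts = 5, max_eval = 2000) {
  stopifnot(length(y) == nrow(K1), all(dim(K1) == dim(K2)))
  if (any(!is.finite(y))) stop("non-finite phenotype values")
  n <- length(y)
  K1u <- unclass(K1); K2u <- unclass(K2)
  one <- rep(1, n)
  reml_ll <- function(par) {
    l1 <- exp(par[1]); l2 <- exp(par[2])
    H <- l1 * K1u + l2 * K2u + diag(n)
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) return(-1e10)
    ldet <- 2 * sum(log(diag(ch)))
    Hi_y <- backsolve(ch, forwardsolve(t(ch), y))
    Hi_1 <- backsolve(ch, forwardsolve(t(ch), one))
    xhx <- sum(one * Hi_1)
    mu <- sum(one * Hi_y) / xhx
    r2 <- sum(y * Hi_y) - mu^2 * xhx
    if (r2 <= 0) return(-1e10)
    se2 <- r2 / (n - 1)
    -0.5 * ((n - 1) * log(2 * pi * se2) + ldet + log(xhx) + (n - 1))
  }
  starts <- list(c(0, 0), c(-3, 0), c(0, -3), c(2, 2), c(-3, -3))[seq_len(min(n_starts, 5))]
  best <- NULL
  conv <- FALSE
  for (s in starts) {
    o <- stats::optim(s, reml_ll, method = "Nelder-Mead",
                      control = list(fnscale = -1, maxit = max_eval, reltol = 1e-10))
    if (is.null(best) || o$value > best$value) best <- o
    if (o$convergence == 0) conv <- TRUE
  }
  l1 <- exp(best$par[1]); l2 <- exp(best$par[2])
  # boundary checks: also evaluate with each component removed
  single1 <- fit_gblup(y, K1u); single2 <- fit_gblup(y, K2u)
  if (!is.na(single1$loglik) && single1$loglik >= best$value + 1e-6) {
    l1 <- if (single1$sigma_e2 > 0) single1$sigma_a2 / single1$sigma_e2 else 0
    l2 <- 0; best$value <- single1$loglik
  } else if (!is.na(single2$loglik) && single2$loglik >= best$value + 1e-6) {
    l2 <- if (single2$sigma_e2 > 0) single2$sigma_a2 / single2$sigma_e2 else 0
    l1 <- 0; best$value <- single2$loglik
  }
  l1 <- if (l1 < 1e-8) 0 else l1
  l2 <- if (l2 < 1e-8) 0 else l2
  H <- l1 * K1u + l2 * K2u + diag(n)
  Hi <- solve(H)
  xhx <- sum(Hi %*% one * one)
  mu <- sum((Hi %*% y) * one) / xhx
  r <- y - mu
  Hir <- Hi %*% r
  se2 <- max(sum(r * Hir) / (n - 1), 0)
  u1 <- drop(l1 * K1u %*% Hir); u2 <- drop(l2 * K2u %*% Hir)
  names(u1) <- names(u2) <- names(y)
  flags <- character()
  if (max(abs(K1u - K2u)) < 1e-10 && l1 + l2 > 0)
    flags <- c(flags, "non_unique_split")
  if (!conv) flags <- c(flags, "not_converged")
  structure(list(mu_hat = mu, sigma1_2 = l1 * se2, sigma2_2 = l2 * se2,
                 sigma_e2 = se2, gebv = u1 + u2, gebv1 = u1, gebv2 = u2,
                 loglik = best$value, converged = conv, flags = flags),
            class = "gblup_fit2")
}

#' Narrow-sense heritability from variance components
#'
#' `h2 = sigma_a2 / (sigma_a2 + sigma_e2)`.
#'
#' @param sigma_a2 Additive genetic variance (>= 0).
#' @param sigma_e2 Residual variance (>= 0).
#' @return Heritability in `[0, 1]`.
#' @examples
#' heritability(4.0035, 2.0762)  # 0.66
#' @export
heritability <- function(sigma_a2, sigma_e2) {
  if (any(sigma_a2 < 0) || any(sigma_e2 < 0))
    stop("variance components must be non-negative")
  tot <- sigma_a2 + sigma_e2
  if (any(tot == 0)) stop("sigma_a2 and sigma_e2 cannot both be zero")
  sigma_a2 / tot
}

#' Expected rate of genetic gain from genomic selection
#'
#' `dGG = i * sqrt(sigma_a2) * PA / L`: selection intensity times the
#' additive genetic standard deviation times the predictive ability, per
#' breeding-cycle year. Typical cycle lengths are 5 years for sweetpotato
#' under accelerated breeding and 8 years for potato.
#'
#' @param sigma_a2 Additive genetic variance (>= 0).
#' @param pa Predictive ability (correlation, in `[-1, 1]`).
#' @param i Selection intensity (dimensionless, default 1).
#' @param L Breeding-cycle length in years (> 0).
#' @return Gain in trait units per year.
#' @examples
#' genetic_gain(1.6935, 0.33, i = 1, L = 5)   # 0.085889
#' genetic_gain(0.0189, 0.68, i = 1, L = 8)   # 0.011686
#' @export
genetic_gain <- function(sigma_a2, pa, i = 1, L) {
  stopifnot(all(sigma_a2 >= 0), all(abs(pa) <= 1), i >= 0)
  if (any(L <= 0)) stop("breeding-cycle length L must be positive")
  i * sqrt(sigma_a2) * pa / L
}
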