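#' Haplotype kinships on a genetic-map grid
#'
#' Evaluates the identity-by-descent haplotype kinship
#' ([haplotype_kinship()]) at positions spaced `step_cM` apart along every
#' chromosome of a phased full-sib population. These locus kernels are the
#' inputs of the score-based QTL scan and of the map-based G-BLUP /
#' Q-BLUP / Q+G-BLUP prediction modes.
#'
#' @param pop A phased `sim_population` (with `homolog_origin`).
#' @param step_cM Grid spacing in centiMorgans (default 2).
#' @return A list of class `kinship_grid`: `positions` (data frame `chrom`,
#'   `pos`), `kinships` (list of `kinship_matrix`, one per grid point).
#' @export
kinship_grid <- function(pop, step_cM = 2) {
  if (is.null(pop$homolog_origin))
    stop("kinship_grid requires a phased population with homolog-origin labels")
  pos_list <- do.call(rbind, lapply(unique(pop$map$chrom), function(ch) {
    len <- max(pop$map$pos[pop$map$chrom == ch])
    data.frame(chrom = ch, pos = seq(0, len, by = step_cM))
  }))
  ks <- lapply(seq_len(nrow(pos_list)), function(i)
    haplotype_kinship(pop, pos_list$pos[i], pos_list$chrom[i]))
  structure(list(positions = pos_list, kinships = ks), class = "kinship_grid")
}

#' Score statistic for adding a locus variance component
#'
#' Standardized variance-component score test for `sigma_locus^2 = 0` in the
#' model `y = 1 mu + u_current + u_locus + e`: with `P` the REML projection
#' matrix of the null model (intercept plus any already-selected kernels),
#' the statistic is
#' `max(0, y' P K P y - tr(P K)) / sqrt(2 tr((P K)^2))`.
#' It is invariant to adding a constant to `y`, non-negative, and larger
#' under stronger locus signal; significance is assessed by permutation in
#' [forward_search()].
#'
#' @param y Phenotype vector.
#' @param K_locus Locus (haplotype) kinship at the tested position.
#' @param K_current Kinship of already-selected QTL (averaged), or `NULL`
#'   for the intercept-only null.
#' @return The score statistic (0, with attribute `flag`, for
#'   quasi-monomorphic locus kernels).
#' @export
score_position <- function(y, K_locus, K_current = NULL) {
  P <- null_projection(y, K_current)
  score_from_projection(y, unclass(K_locus), P)
}

# REML projection matrix P = V^-1 - V^-1 X (X'V^-1X)^-1 X'V^-1 of the null
# model, with V from a REML fit of the current kernels (or sigma_e2 I).
null_projection <- function(y, K_current = NULL) {
  n <- length(y)
  one <- rep(1, n)
  if (is.null(K_current)) {
    se2 <- sum((y - mean(y))^2) / (n - 1)
    C <- diag(n) - tcrossprod(one) / n
    return(C / se2)
  }
  fit <- fit_gblup(y, unclass(K_current))
  V <- fit$sigma_a2 * unclass(K_current) + diag(max(fit$sigma_e2, 1e-12), n)
  Vi <- solve(V)
  Vi1 <- Vi %*% one
  Vi - tcrossprod(Vi1) / sum(one * Vi1)
}

score_from_projection <- function(y, K, P) {
  off <- K[lower.tri(K)]
  if (length(off) && stats::sd(off) < 1e-10)
    return(structure(0, flag = "quasi_monomorphic"))
  PK <- P %*% K
  denom <- sqrt(2 * sum(PK * t(PK)))
  if (denom < 1e-12) return(structure(0, flag = "quasi_monomorphic"))
  Py <- P %*% y
  s <- drop(crossprod(Py, K %*% Py)) - sum(diag(PK))
  max(0, s) / denom
}

#' Forward search for QTL on a kinship grid
#'
#' Score-based sequential forward selection of QTL positions on a
#' genetic-map grid: at each round every eligible position is scored
#' against the current model ([score_position()]), and the maximum is added
#' if it exceeds a genome-wide threshold calibrated by permutation of the
#' phenotype (the `1 - alpha` quantile of the permuted maximum statistic).
#' A window of `window_cM` around each selected position on the same
#' chromosome becomes ineligible, so no two selected QTL can be closer than
#' the window. An optional backward pass re-tests each selected QTL against
#' the final model and drops those below threshold.
#'
#' @param y Phenotype vector.
#' @param grid A [kinship_grid()].
#' @param alpha Genome-wide significance level (relaxed default 0.20).
#' @param window_cM Exclusion half-width in cM around a selected position
#'   (default 20; positions within `window_cM` on either side are excluded).
#' @param n_perm Number of phenotype permutations for the threshold.
#' @param seed Integer seed for the permutations.
#' @param backward Run the backward-elimination pass.
#' @param max_qtl Safety cap on the number of selected QTL.
#' @return A list of class `qtl_model`: `positions` (data frame `chrom`,
#'   `pos`, `score`), `threshold`, `alpha`, `window_cM`. An empty model is
#'   a valid result.
#' @export
forward_search <- function(y, grid, alpha = 0.20, window_cM = 20,
                           n_perm = 200, seed = 1L, backward = FALSE,
                           max_qtl = 10L) {
  stopifnot(inherits(grid, "kinship_grid"))
  pos <- grid$positions
  Ks <- lapply(grid$kinships, unclass)
  n <- length(y)
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))
  eligible <- rep(TRUE, nrow(pos))
  selected <- integer(0)
  sel_scores <- numeric(0)
  threshold <- NA_real_
  current <- NULL
  repeat {
    if (!any(eligible) || length(selected) >= max_qtl) break
    P <- null_projection(y, current)
    obs <- vapply(Ks[eligible], function(K) as.numeric(score_from_projection(y, K, P)), 0)
    # permutation null of the genome-wide maximum statistic
    Ymat <- matrix(y[perms], n, n_perm)
    PY <- P %*% Ymat
    max_perm <- rep(-Inf, n_perm)
    for (K in Ks[eligible]) {
      off <- K[lower.tri(K)]
      if (length(off) && stats::sd(off) < 1e-10) next
      PK <- P %*% K
      denom <- sqrt(2 * sum(PK * t(PK)))
      if (denom < 1e-12) next
      s <- (colSums(PY * (K %*% PY)) - sum(diag(PK))) / denom
      max_perm <- pmax(max_perm, pmax(s, 0))
    }
    threshold <- stats::quantile(max_perm, 1 - alpha, names = FALSE, type = 7)
    best <- which.max(obs)
    if (obs[best] <= threshold) break
    gi <- which(eligible)[best]
    selected <- c(selected, gi)
    sel_scores <- c(sel_scores, obs[best])
    eligible[pos$chrom == pos$chrom[gi] &
             abs(pos$pos - pos$pos[gi]) <= window_cM] <- FALSE
    current <- average_kinships(grid$kinships[selected])
  }
  if (backward && length(selected) > 1) {
    drop_any <- TRUE
    while (drop_any && length(selected) > 1) {
      drop_any <- FALSE
      for (k in seq_along(selected)) {
        others <- selected[-k]
        Kc <- if (length(others)) average_kinships(grid$kinships[others]) else NULL
        s <- as.numeric(score_position(y, grid$kinships[[selected[k]]], Kc))
        if (s <= threshold) {
          selected <- others; sel_scores <- sel_scores[-k]
          drop_any <- TRUE; break
        }
      }
    }
  }
  structure(list(
    positions = if (length(selected))
      data.frame(chrom = pos$chrom[selected], pos = pos$pos[selected],
                 score = sel_scores, grid_index = selected)
    else data.frame(chrom = integer(), pos = numeric(), score = numeric(),
                    grid_index = integer()),
    threshold = threshold, alpha = alpha, window_cM = window_cM),
    class = "qtl_model")
}

#' @export
print.qtl_model <- function(x, ...) {
  cat(sprintf("<qtl_model> %d QTL (alpha = %.2f, window %g cM, threshold %.3g)\n",
              nrow(x$positions), x$alpha, x$window_cM, x$threshold))
  if (nrow(x$positions)) print(x$positions, row.names = FALSE)
  invisible(x)
}

#' Cross-validated prediction with map-based and QTL-informed kernels
#'
#' Runs the replicated cross-validation of [run_cv()] in one of three
#' modes, all built from grid haplotype kinships:
#' * `"G-BLUP"`: one kernel, the average of the locus kinships at every
#'   grid position (genome-wide haplotype relationship).
#' * `"Q-BLUP"`: inside each training fold a [forward_search()] is run on
#'   the training phenotypes only; the kernel is the average of the
#'   QTL-peak locus kinships, falling back to the G-BLUP kernel when no
#'   QTL is selected.
#' * `"Q+G-BLUP"`: two kernels per fold, the QTL-peak average and the
#'   average of the remaining grid positions (selected positions
#'   excluded); falls back to G-BLUP when no QTL is selected.
#'
#' The QTL search never sees holdout phenotypes.
#'
#' @param y Phenotype vector.
#' @param grid A [kinship_grid()].
#' @param mode One of `"G-BLUP"`, `"Q-BLUP"`, `"Q+G-BLUP"`.
#' @param splits Output of [make_splits()].
#' @param alpha,window_cM,n_perm,seed Passed to [forward_search()].
#' @return A `cv_result` with an extra element `n_qtl_per_rep`.
#' @export
predict_mode <- function(y, grid, mode = c("G-BLUP", "Q-BLUP", "Q+G-BLUP"),
                         splits, alpha = 0.20, window_cM = 20, n_perm = 200,
                         seed = 1L) {
  mode <- match.arg(mode)
  Kg <- average_kinships(grid$kinships, tag = "Hap_genome")
  if (mode == "G-BLUP") {
    out <- run_cv(y, Kg, splits, model_tag = "G-BLUP")
    out$n_qtl_per_rep <- rep(0L, length(splits))
    return(out)
  }
  pa <- numeric(length(splits))
  nq <- integer(length(splits))
  for (r in seq_along(splits)) {
    tr <- splits[[r]]$train; ho <- splits[[r]]$holdout
    sub <- structure(list(
      positions = grid$positions,
      kinships = lapply(grid$kinships, function(K) K[tr, tr])),
      class = "kinship_grid")
    qm <- forward_search(y[tr], sub, alpha = alpha, window_cM = window_cM,
                         n_perm = n_perm, seed = seed + r)
    nq[r] <- nrow(qm$positions)
    if (nq[r] == 0) {
      gebv <- predict_holdout(y[tr], Kg, tr, ho)$gebv
    } else {
      sel <- qm$positions$grid_index
      Kq <- average_kinships(grid$kinships[sel], tag = "Hap_QTL")
      if (mode == "Q-BLUP") {
        gebv <- predict_holdout(y[tr], Kq, tr, ho)$gebv
      } else {
        rest <- setdiff(seq_along(grid$kinships), sel)
        Kbg <- if (length(rest)) average_kinships(grid$kinships[rest], tag = "Hap_bg") else Kg
        fit <- fit_two_kernel(y[tr], unclass(Kq)[tr, tr], unclass(Kbg)[tr, tr])
        gebv <- project_two_kernel(fit, list(Kq, Kbg), tr, ho, y[tr])
      }
    }
    pa[r] <- if (stats::sd(gebv) < 1e-12 || stats::sd(y[ho]) < 1e-12) 0
             else stats::cor(y[ho], gebv)
  }
  z <- fisher_z(pa)
  structure(list(model_tag = mode, trait = NA_character_, pa_per_rep = pa,
                 z_per_rep = z, mean_pa_backtransformed = inverse_fisher_z(mean(z)),
                 n_reps = length(splits), n_zero_var = sum(pa == 0),
                 n_qtl_per_rep = nq),
            class = "cv_result")
}
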