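#' Generate replicated train/holdout splits
#'
#' Random 80/20-style partitions: each replicate sets `round(n * holdout_frac)`
#' individuals aside as the validation set and trains on the rest. Fully
#' seeded and reproducible.
#'
#' @param n Number of individuals.
#' @param holdout_frac Fraction held out per replicate (0 < frac < 1).
#' @param n_reps Number of replicates.
#' @param seed Integer seed.
#' @return List of length `n_reps`; each element is
#'   `list(train = ..., holdout = ...)` of disjoint integer index vectors
#'   covering `1:n`.
#' @export
make_splits <- function(n, holdout_frac = 0.2, n_reps = 1000, seed = 1L) {
  stopifnot(holdout_frac > 0, holdout_frac < 1)
  n_ho <- round(n * holdout_frac)
  if (n_ho < 2 || n - n_ho < 2) stop("degenerate split sizes for n = ", n)
  set.seed(seed)
  lapply(seq_len(n_reps), function(r) {
    ho <- sort(sample.int(n, n_ho))
    list(train = setdiff(seq_len(n), ho), holdout = ho)
  })
}

#' Cross-validated predictive ability of a G-BLUP model
#'
#' For each replicate, fits the mixed model on the training individuals
#' only and computes the predictive ability (PA) as the Pearson correlation
#' between the holdout phenotypes and their predicted GEBVs. The kinship is
#' built once on all individuals and only phenotypes are masked, as is
#' standard for G-BLUP cross-validation. Replicates where the predicted
#' GEBVs have zero variance (boundary fits) contribute PA = 0.
#'
#' @param y Phenotype vector aligned to `K`.
#' @param K A kinship matrix, or a list of two kinship matrices for a
#'   two-kernel (Q + G) model.
#' @param splits Output of [make_splits()].
#' @param model_tag Label stored on the result (defaults to the kinship's
#'   tag).
#' @param trait Optional trait label.
#' @return A list of class `cv_result`: `model_tag`, `trait`, `pa_per_rep`,
#'   `z_per_rep` (Fisher-Z), `mean_pa_backtransformed`, `n_reps`,
#'   `n_zero_var` (replicates with degenerate predictions).
#' @export
run_cv <- function(y, K, splits, model_tag = NULL, trait = NA_character_) {
  two <- is.list(K) && !inherits(K, "kinship_matrix")
  if (is.null(model_tag))
    model_tag <- if (two) "two_kernel" else
      if (!is.null(attr(K, "model_tag"))) attr(K, "model_tag") else "K"
  pa <- numeric(length(splits))
  n_zero <- 0L; n_fail <- 0L
  for (r in seq_along(splits)) {
    tr <- splits[[r]]$train; ho <- splits[[r]]$holdout
    gebv <- tryCatch({
      if (two) {
        fit <- fit_two_kernel(y[tr], unclass(K[[1]])[tr, tr], unclass(K[[2]])[tr, tr])
        project_two_kernel(fit, K, tr, ho, y[tr])
      } else {
        predict_holdout(y[tr], K, tr, ho)$gebv
      }
    }, error = function(e) NULL)
    if (is.null(gebv)) { n_fail <- n_fail + 1L; pa[r] <- NA_real_; next }
    if (stats::sd(gebv) < 1e-12 || stats::sd(y[ho]) < 1e-12) {
      n_zero <- n_zero + 1L
      pa[r] <- 0
    } else {
      pa[r] <- stats::cor(y[ho], gebv)
    }
  }
  if (n_fail > length(splits) / 2)
    stop("more than 50% of cross-validation replicates failed")
  pa[is.na(pa)] <- 0
  z <- fisher_z(pa)
  structure(list(model_tag = model_tag, trait = trait, pa_per_rep = pa,
                 z_per_rep = z, mean_pa_backtransformed = inverse_fisher_z(mean(z)),
                 n_reps = length(splits), n_zero_var = n_zero),
            class = "cv_result")
}

# holdout projection for a two-kernel fit:
# u_ho = sum_k sigma_k^2 K_k[ho,tr] V_tr^-1 (y_tr - mu)
project_two_kernel <- function(fit, Ks, tr, ho, y_tr) {
  n <- length(tr)
  V <- fit$sigma1_2 * unclass(Ks[[1]])[tr, tr] +
       fit$sigma2_2 * unclass(Ks[[2]])[tr, tr] + diag(fit$sigma_e2, n)
  if (fit$sigma1_2 + fit$sigma2_2 <= 0) return(numeric(length(ho)))
  sol <- solve(V, y_tr - fit$mu_hat)
  drop((fit$sigma1_2 * unclass(Ks[[1]])[ho, tr, drop = FALSE] +
        fit$sigma2_2 * unclass(Ks[[2]])[ho, tr, drop = FALSE]) %*% sol)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> model %s%s: mean PA (back-transformed) = %.3f over %d reps\n",
              x$model_tag, if (!is.na(x$trait)) paste0(", trait ", x$trait) else "",
              x$mean_pa_backtransformed, x$n_reps))
  invisible(x)
}

#' Fisher Z transform of a correlation
#'
#' `z = atanh(r)`; values at exactly +/- 1 are clamped to
#' `+/- atanh(1 - 1e-12)` with a warning so that every replicate remains
#' usable in the ANOVA.
#'
#' @param r Correlation(s) in `[-1, 1]`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  stopifnot(all(abs(r) <= 1 + 1e-12, na.rm = TRUE))
  hit <- !is.na(r) & abs(r) >= 1
  if (any(hit)) {
    warning("correlation(s) at +/-1 clamped for Fisher-Z transform")
    r[hit] <- sign(r[hit]) * (1 - 1e-12)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @param z Fisher-Z value(s).
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Compare cross-validated models by one-way ANOVA on Fisher-Z values
#'
#' Pools the per-replicate Fisher-Z transformed PA values of several
#' [run_cv()] results, tests for model differences with a one-way ANOVA
#' (models as factor), assigns compact letter groupings from Tukey HSD
#' pairwise comparisons at `alpha`, and reports each model's average PA as
#' the back-transformed mean Z.
#'
#' @param results List of `cv_result` objects with equal `n_reps`.
#' @param alpha Significance level for the letter display.
#' @return A list of class `cv_summary`: `table` (data frame `model`,
#'   `mean_pa`, `sd_pa`, `group`), `anova_F`, `anova_p` (both `NA` for a
#'   single model), `alpha`.
#' @export
summarize_cv <- function(results, alpha = 0.05) {
  stopifnot(length(results) >= 1)
  tags <- vapply(results, function(r) r$model_tag, "")
  if (anyDuplicated(tags))
    tags <- make.unique(tags)
  tab <- data.frame(
    model = tags,
    mean_pa = vapply(results, function(r) r$mean_pa_backtransformed, 0),
    sd_pa = vapply(results, function(r) stats::sd(r$pa_per_rep), 0),
    stringsAsFactors = FALSE)
  if (length(results) == 1) {
    tab$group <- "a"
    return(structure(list(table = tab, anova_F = NA_real_, anova_p = NA_real_,
                          alpha = alpha), class = "cv_summary"))
  }
  nr <- vapply(results, function(r) r$n_reps, 0L)
  if (length(unique(nr)) != 1) stop("all models must have equal n_reps")
  df <- data.frame(
    z = unlist(lapply(results, function(r) r$z_per_rep)),
    model = factor(rep(tags, each = nr[1]), levels = tags))
  fit <- stats::aov(z ~ model, data = df)
  an <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$model
  pmat <- matrix(1, length(tags), length(tags), dimnames = list(tags, tags))
  for (k in rownames(tuk)) {
    pr <- strsplit(k, "-", fixed = TRUE)[[1]]
    pmat[pr[1], pr[2]] <- pmat[pr[2], pr[1]] <- tuk[k, "p adj"]
  }
  ord <- order(-tab$mean_pa)
  letters_ord <- cld_letters(pmat[tags[ord], tags[ord], drop = FALSE], alpha)
  tab$group <- letters_ord[match(tags, tags[ord])]
  structure(list(table = tab, anova_F = an[["F value"]][1],
                 anova_p = an[["Pr(>F)"]][1], alpha = alpha),
            class = "cv_summary")
}

# compact letter display by insert-and-absorb on a pairwise p-value matrix
# whose rows/cols are ordered best-first
cld_letters <- function(pmat, alpha) {
  k <- nrow(pmat)
  groups <- list()   # each group: vector of member indices, mutually n.s.
  for (i in seq_len(k)) {
    placed <- FALSE
    for (gi in seq_along(groups)) {
      if (all(pmat[i, groups[[gi]]] > alpha)) {
        groups[[gi]] <- c(groups[[gi]], i); placed <- TRUE
      }
    }
    if (!placed) {
      # new group: i plus every earlier model not distinguishable from it
      groups[[length(groups) + 1]] <- c(which(pmat[i, seq_len(i - 1)] > alpha), i)
    }
  }
  # absorb groups contained in others
  keep <- rep(TRUE, length(groups))
  for (a in seq_along(groups)) for (b in seq_along(groups))
    if (a != b && keep[a] && keep[b] && all(groups[[a]] %in% groups[[b]]))
      keep[a] <- FALSE
  groups <- groups[keep]
  out <- character(k)
  for (gi in seq_along(groups))
    out[groups[[gi]]] <- paste0(out[groups[[gi]]], letters[gi])
  out
}

#' @export
print.cv_summary <- function(x, ...) {
  cat("Cross-validation model comparison (Fisher-Z ANOVA)\n")
  if (!is.na(x$anova_F))
    cat(sprintf("  F = %.3f, p = %.3g\n", x$anova_F, x$anova_p))
  print(x$table, row.names = FALSE)
  invisible(x)
}
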