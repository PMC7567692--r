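#' Run a full genomic-selection experiment from a specification
#'
#' Orchestrates the standard experiment grids — kinship-model comparison,
#' marker-filter and marker-number sweeps — over one or more traits, from a
#' single specification (an R list or a YAML file). For each filter setting
#' it records the retained marker count; for each (filter, model, trait)
#' cell it runs replicated cross-validation, summarizes models with the
#' Fisher-Z ANOVA, and reports heritability and expected genetic gain from
#' the full-data additive fit.
#'
#' The specification fields (all optional unless noted):
#' * `genotype_csv` + `ploidy`, or `simulation` (a list of [sim_config()]
#'   arguments) — the genotype source (required).
#' * `blues_csv` — phenotype table ([read_blues_csv()] layout); simulated
#'   populations use their own phenotype when absent.
#' * `models` — subset of `c("add", "full", "pseudo", "dominance")`
#'   (default `"add"`).
#' * `filters` — list of `c(maf, call_rate)` pairs (default one pair,
#'   `0.30 / 0.90`).
#' * `subsample_sizes` — optional marker counts for random-subsample sweeps.
#' * `cv` — list with `n_reps`, `holdout_frac`, `seed`.
#' * `gain` — list with `i` and `L` for [genetic_gain()].
#' * `output_dir` — when set, summary CSVs are written there.
#'
#' @param spec List, or path to a YAML file with the fields above.
#' @return A list of class `gs_experiment`: `marker_counts` (data frame per
#'   filter), `summary` (data frame: trait, filter, n_markers, model,
#'   mean_pa, sd_pa, group, h2, gain, seed), and `cv_summaries`.
#' @export
run_experiment <- function(spec) {
  if (is.character(spec)) spec <- yaml::read_yaml(spec)
  stopifnot(is.list(spec))
  cvs <- spec$cv %||% list()
  n_reps <- cvs$n_reps %||% 100L
  holdout <- cvs$holdout_frac %||% 0.2
  seed <- cvs$seed %||% 1L
  gain <- spec$gain %||% list(i = 1, L = 5)
  models <- spec$models %||% "add"
  filters <- spec$filters %||% list(c(0.30, 0.90))

  # genotype + phenotype source
  if (!is.null(spec$genotype_csv)) {
    g0 <- read_dosage_csv(spec$genotype_csv, spec$ploidy)
    if (is.null(spec$blues_csv)) stop("genotype_csv requires blues_csv")
    blues <- read_blues_csv(spec$blues_csv, genotype_ids = colnames(g0))
  } else if (!is.null(spec$simulation)) {
    cfg <- do.call(sim_config, spec$simulation)
    pop <- attach_phenotype(simulate_f1_family(cfg))
    g0 <- pop$dosage
    blues <- data.frame(individual = names(pop$phenotype), trait = "sim_trait",
                        value = unname(pop$phenotype))
  } else stop("spec must provide genotype_csv or simulation")

  marker_counts <- do.call(rbind, lapply(filters, function(f)
    data.frame(maf = f[1], call_rate = f[2],
               n_markers = nrow(filter_markers(g0, f[1], f[2], quiet = TRUE)))))

  build_K <- function(g, model) {
    switch(model,
      add = vanraden_additive(g),
      full = full_model(g),
      pseudo = vanraden_additive(pseudo_diploidize(g), tag = "Pseudo_2x"),
      dominance = vitezica_dominance(if (ploidy(g) == 2) g else pseudo_diploidize(g)),
      stop("unknown model tag: ", model))
  }

  summary_rows <- list(); cv_summaries <- list()
  for (fi in seq_along(filters)) {
    f <- filters[[fi]]
    g <- filter_markers(g0, f[1], f[2], quiet = TRUE)
    if (nrow(g) < 2) {
      warning(sprintf("filter (%g, %g) leaves < 2 markers; skipped", f[1], f[2]))
      next
    }
    for (tr in unique(blues$trait)) {
      ph <- blues[blues$trait == tr, ]
      ids <- intersect(colnames(g), ph$individual)
      y <- stats::setNames(ph$value[match(ids, ph$individual)], ids)
      keep <- !is.na(y); y <- y[keep]; ids <- ids[keep]
      gi <- g[, ids, drop = FALSE]
      splits <- make_splits(length(y), holdout, n_reps, seed)
      res <- list(); ok_models <- character()
      for (m in models) {
        cell <- tryCatch(run_cv(y, build_K(gi, m), splits, trait = tr),
                         error = function(e) {
                           warning(sprintf("model '%s' failed for trait '%s': %s",
                                           m, tr, conditionMessage(e)))
                           NULL
                         })
        if (!is.null(cell)) {
          res[[length(res) + 1]] <- cell
          ok_models <- c(ok_models, m)
        }
      }
      if (!length(res)) next
      smry <- summarize_cv(res)
      cv_summaries[[sprintf("%s_f%d", tr, fi)]] <- smry
      for (ri in seq_along(res)) {
        m <- res[[ri]]$model_tag
        Kfull <- build_K(gi, ok_models[[ri]])
        fit <- fit_gblup(y, Kfull)
        summary_rows[[length(summary_rows) + 1]] <- data.frame(
          trait = tr, maf = f[1], call_rate = f[2], n_markers = nrow(gi),
          model = m, mean_pa = smry$table$mean_pa[ri], sd_pa = smry$table$sd_pa[ri],
          group = smry$table$group[ri], h2 = fit$h2,
          gain = genetic_gain(fit$sigma_a2, smry$table$mean_pa[ri],
                              i = gain$i %||% 1, L = gain$L %||% 5),
          seed = seed, stringsAsFactors = FALSE)
      }
    }
  }
  out <- structure(list(marker_counts = marker_counts,
                        summary = do.call(rbind, summary_rows),
                        cv_summaries = cv_summaries),
                   class = "gs_experiment")
  if (!is.null(spec$output_dir)) {
    dir.create(spec$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$marker_counts,
                     file.path(spec$output_dir, "marker_counts.csv"), row.names = FALSE)
    utils::write.csv(format(out$summary, digits = 6),
                     file.path(spec$output_dir, "model_summary.csv"), row.names = FALSE)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gs_experiment <- function(x, ...) {
  cat("<gs_experiment>\nMarker counts per filter:\n")
  print(x$marker_counts, row.names = FALSE)
  cat("\nModel summary:\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
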