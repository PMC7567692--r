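#' Simulation configuration for polyploid populations
#'
#' Collects the knobs of the polysomic-inheritance simulator: ploidy, family
#' size, marker density, genetic-map lengths, trait architecture and the
#' sequencing-degradation model.
#'
#' @param ploidy Even integer, 4 (e.g. potato) or 6 (e.g. sweetpotato).
#' @param n_offspring Number of offspring (F1 family) or panel individuals.
#' @param n_markers Total number of biallelic markers.
#' @param map_length_cM Numeric vector of per-chromosome genetic lengths in
#'   centiMorgans; markers are spread evenly along each chromosome.
#' @param n_qtl Number of trait loci sampled among the markers.
#' @param qtl_effect_sizes Additive effect per alternative-allele copy, one
#'   per QTL (recycled); `NULL` draws standard-normal effects.
#' @param dominance_mode `"none"`, `"digenic"` (pairwise interaction term per
#'   locus) or `"full-class"` (an arbitrary value per dosage class).
#' @param target_h2 Target narrow-sense heritability in `[0, 1]`.
#' @param mean_depth Expected sequencing reads per locus and individual, for
#'   [degrade_by_depth()].
#' @param missing_rate Additional completely-at-random missing fraction.
#' @param double_reduction Probability of a double-reduction gamete, in
#'   `[0, 0.25]`.
#' @param seed Integer RNG seed; every simulation entry point is fully
#'   seeded and bit-reproducible.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(ploidy = 6, n_offspring = 315, n_markers = 500,
                       map_length_cM = c(100, 100, 100), n_qtl = 20,
                       qtl_effect_sizes = NULL, dominance_mode = "none",
                       target_h2 = 0.5, mean_depth = 60, missing_rate = 0.02,
                       double_reduction = 0, seed = 1L) {
  check_ploidy(ploidy)
  dominance_mode <- match.arg(dominance_mode, c("none", "digenic", "full-class"))
  stopifnot(target_h2 >= 0, target_h2 <= 1,
            missing_rate >= 0, missing_rate <= 1,
            double_reduction >= 0, double_reduction <= 0.25,
            n_offspring >= 1, n_markers >= 1, all(map_length_cM > 0))
  structure(list(ploidy = as.integer(ploidy), n_offspring = as.integer(n_offspring),
                 n_markers = as.integer(n_markers), map_length_cM = map_length_cM,
                 n_qtl = as.integer(n_qtl), qtl_effect_sizes = qtl_effect_sizes,
                 dominance_mode = dominance_mode, target_h2 = target_h2,
                 mean_depth = mean_depth, missing_rate = missing_rate,
                 double_reduction = double_reduction, seed = as.integer(seed)),
            class = "sim_config")
}

#' Gamete dosage distribution under polysomic inheritance
#'
#' Probability mass function of the alternative-allele dosage transmitted by
#' a single gamete from a parent of known dosage, under random bivalent
#' pairing of all homologs. With no double reduction the gamete dosage `g`
#' is hypergeometric:
#' `P(g) = C(d, g) C(p - d, p/2 - g) / C(p, p/2)`.
#' With double-reduction probability `alpha`, a fraction `alpha` of gametes
#' carry a duplicated copy of one sampled allele: `p/2 - 1` homologs are
#' drawn without replacement and one of them is duplicated to fill the
#' gamete.
#'
#' @param parent_dosage Integer dosage `0..ploidy` of the parent.
#' @param ploidy Even integer ploidy `p`.
#' @param double_reduction Probability `alpha` in `[0, 0.25]` (requires
#'   `ploidy >= 4` when positive).
#' @return Numeric vector of length `p/2 + 1`: `P(g)` for `g = 0..p/2`.
#' @examples
#' gamete_pmf(3, 6)        # 0.05 0.45 0.45 0.05
#' gamete_pmf(2, 4, 0.1)
#' @export
gamete_pmf <- function(parent_dosage, ploidy, double_reduction = 0) {
  p <- check_ploidy(ploidy)
  d <- parent_dosage
  if (length(d) != 1 || is.na(d) || d < 0 || d > p || d != round(d))
    stop("parent_dosage must be an integer in [0, ", p, "], got: ", d)
  stopifnot(double_reduction >= 0, double_reduction <= 0.25)
  m <- p / 2
  g <- 0:m
  base <- choose(d, g) * choose(p - d, m - g) / choose(p, m)
  if (double_reduction == 0) return(base)
  if (p < 4) stop("double reduction requires ploidy >= 4")
  # draw m-1 homologs without replacement, then duplicate one of them
  k <- 0:(m - 1)
  hk <- choose(d, k) * choose(p - d, (m - 1) - k) / choose(p, m - 1)
  dr <- numeric(m + 1)
  for (i in seq_along(k)) {
    kk <- k[i]
    pr_dup_alt <- if (m - 1 > 0) kk / (m - 1) else 0
    dr[kk + 2] <- dr[kk + 2] + hk[i] * pr_dup_alt         # duplicated allele is alt
    dr[kk + 1] <- dr[kk + 1] + hk[i] * (1 - pr_dup_alt)   # duplicated allele is ref
  }
  (1 - double_reduction) * base + double_reduction * dr
}

#' Sample gamete dosages
#'
#' Random draws from [gamete_pmf()].
#'
#' @inheritParams gamete_pmf
#' @param n Number of gametes.
#' @return Integer vector of gamete dosages in `0..ploidy/2`.
#' @export
sample_gamete_dosage <- function(parent_dosage, ploidy, double_reduction = 0, n = 1) {
  pmf <- gamete_pmf(parent_dosage, ploidy, double_reduction)
  sample(0:(ploidy / 2), n, replace = TRUE, prob = pmf)
}

# evenly spaced marker map across chromosomes, proportional to length
build_map <- function(n_markers, map_length_cM) {
  n_chr <- length(map_length_cM)
  per <- diff(round(seq(0, n_markers, length.out = n_chr + 1)))
  map <- do.call(rbind, lapply(seq_len(n_chr), function(c) {
    k <- per[c]
    if (k == 0) return(NULL)
    data.frame(chrom = c, pos = seq(0, map_length_cM[c], length.out = max(k, 2))[seq_len(k)])
  }))
  map$marker <- sprintf("M%04d", seq_len(nrow(map)))
  map[, c("marker", "chrom", "pos")]
}

# one meiosis: p/2 recombinant homologs from a p x n_markers haplotype
# matrix; returns list(alleles = m x n matrix, origin = m x n label matrix).
# Random bivalent pairing; Haldane map function for inter-marker
# recombination; optional whole-product double reduction.
meiosis <- function(hap, map, double_reduction = 0) {
  p <- nrow(hap); m <- p / 2
  pairing <- matrix(sample.int(p), nrow = 2)
  alle <- matrix(0L, m, ncol(hap))
  orig <- matrix(0L, m, ncol(hap))
  for (b in seq_len(m)) {
    pair <- pairing[, b]
    cur <- integer(ncol(hap))
    for (ch in unique(map$chrom)) {
      idx <- which(map$chrom == ch)
      pos <- map$pos[idx]
      r <- 0.5 * (1 - exp(-2 * diff(pos) / 100))   # Haldane
      pick <- integer(length(idx))
      pick[1] <- sample(1:2, 1)
      if (length(idx) > 1) {
        sw <- stats::runif(length(r)) < r
        for (i in seq_along(sw)) pick[i + 1] <- if (sw[i]) 3L - pick[i] else pick[i]
      }
      cur[idx] <- pair[pick]
    }
    alle[b, ] <- hap[cbind(cur, seq_len(ncol(hap)))]
    orig[b, ] <- cur
  }
  if (double_reduction > 0 && m >= 2 && stats::runif(1) < double_reduction) {
    drop <- sample.int(m, 1)
    keep <- sample(setdiff(seq_len(m), drop), 1)
    alle[drop, ] <- alle[keep, ]
    orig[drop, ] <- orig[keep, ]
  }
  list(alleles = alle, origin = orig)
}

#' Simulate a polyploid biparental F1 full-sib family
#'
#' Generates phased parental haplotypes (unless supplied), performs
#' polysomic meioses with random bivalent pairing, Haldane recombination
#' along a multi-chromosome map, and optional double reduction, and records
#' for every offspring which parental homolog was inherited at every marker
#' (`homolog_origin`), so that identity-by-descent haplotype kinships can be
#' computed at any map position.
#'
#' @param config A [sim_config()].
#' @param parents Optional list of two phased haplotype matrices
#'   (`ploidy x n_markers`, 0/1). Defaults to random haplotypes with
#'   per-marker founder allele frequencies drawn uniformly on (0.05, 0.5).
#' @return A list of class `sim_population` with elements
#'   `parental_haplotypes`, `homolog_origin` (array
#'   `n_offspring x ploidy x n_markers` of labels `1..2*ploidy`; labels
#'   `1..p` are maternal homologs, `p+1..2p` paternal), `dosage`
#'   (a [dosage_matrix]), `map`, and `config`. Phenotypes are attached by
#'   [attach_phenotype()].
#' @export
simulate_f1_family <- function(config, parents = NULL) {
  set.seed(config$seed)
  p <- config$ploidy; m <- p / 2
  map <- build_map(config$n_markers, config$map_length_cM)
  nm <- nrow(map)
  if (is.null(parents)) {
    f <- stats::runif(nm, 0.05, 0.5)
    parents <- lapply(1:2, function(i)
      matrix(stats::rbinom(p * nm, 1, rep(f, each = p)), p, nm))
  }
  if (!all(vapply(parents, function(h) all(dim(h) == c(p, nm)), TRUE)))
    stop("parental haplotypes must be two ", p, " x ", nm, " matrices")
  n <- config$n_offspring
  dosage <- matrix(0L, nm, n, dimnames = list(map$marker, sprintf("F1_%03d", 1:n)))
  origin <- array(0L, dim = c(n, p, nm))
  for (i in seq_len(n)) {
    gm <- meiosis(parents[[1]], map, config$double_reduction)
    gp <- meiosis(parents[[2]], map, config$double_reduction)
    origin[i, 1:m, ] <- gm$origin
    origin[i, (m + 1):p, ] <- gp$origin + p
    dosage[, i] <- colSums(gm$alleles) + colSums(gp$alleles)
  }
  structure(list(parental_haplotypes = parents, homolog_origin = origin,
                 dosage = dosage_matrix(dosage, p), map = map,
                 true_bv = NULL, phenotype = NULL, qtl = NULL, config = config),
            class = "sim_population")
}

#' Simulate a polyploid diversity panel
#'
#' Unrelated individuals under polysomic Hardy-Weinberg equilibrium: the
#' dosage at each locus is Binomial(`ploidy`, allele frequency),
#' independently per individual. Default frequencies are drawn from a
#' Beta(1.2, 6) spectrum truncated below at 0.03, giving a realized mean
#' minor allele frequency near 0.15 as is typical of hard-filtered GBS
#' panels.
#'
#' @param config A [sim_config()].
#' @param allele_freqs Optional vector of per-marker alternative-allele
#'   frequencies in `[0, 1]`.
#' @return A `sim_population` (without `homolog_origin`: panel individuals
#'   are unphased and unrelated).
#' @export
simulate_panel <- function(config, allele_freqs = NULL) {
  set.seed(config$seed)
  p <- config$ploidy
  map <- build_map(config$n_markers, config$map_length_cM)
  nm <- nrow(map)
  if (is.null(allele_freqs)) {
    allele_freqs <- stats::rbeta(nm, 1.2, 6)
    allele_freqs <- pmax(allele_freqs, 0.03)
  }
  if (length(allele_freqs) != nm) allele_freqs <- rep_len(allele_freqs, nm)
  if (any(allele_freqs < 0 | allele_freqs > 1))
    stop("allele frequencies must lie in [0, 1]")
  n <- config$n_offspring
  dosage <- matrix(stats::rbinom(nm * n, p, rep(allele_freqs, n)), nm, n,
                   dimnames = list(map$marker, sprintf("P%03d", 1:n)))
  structure(list(parental_haplotypes = NULL, homolog_origin = NULL,
                 dosage = dosage_matrix(dosage, p), map = map,
                 allele_freqs = allele_freqs,
                 true_bv = NULL, phenotype = NULL, qtl = NULL, config = config),
            class = "sim_population")
}

#' Attach a quantitative trait to a simulated population
#'
#' Samples QTL among the markers, builds additive breeding values (and a
#' non-additive component under `dominance_mode`), and adds Gaussian noise
#' scaled so the realized narrow-sense heritability
#' `var(bv) / var(phenotype)` matches `target_h2`. With `target_h2 = 0` the
#' phenotype is pure noise.
#'
#' @param pop A `sim_population`.
#' @param config A [sim_config()]; defaults to `pop$config`.
#' @param qtl_idx Optional integer vector of marker indices to use as QTL.
#' @return The population with `true_bv`, `phenotype` (named numeric
#'   vectors) and `qtl` (data frame `marker`, `chrom`, `pos`, `effect`)
#'   filled in.
#' @export
attach_phenotype <- function(pop, config = pop$config, qtl_idx = NULL) {
  set.seed(config$seed + 7919L)
  p <- config$ploidy
  X <- t(unclass(pop$dosage))                      # individuals x markers
  n <- nrow(X); nm <- ncol(X)
  nq <- min(config$n_qtl, nm)
  if (is.null(qtl_idx)) qtl_idx <- sort(sample.int(nm, nq))
  a <- config$qtl_effect_sizes
  a <- if (is.null(a)) stats::rnorm(length(qtl_idx)) else rep_len(a, length(qtl_idx))
  bv <- drop(X[, qtl_idx, drop = FALSE] %*% a)
  bv <- bv - mean(bv)
  na_val <- numeric(n)
  if (config$dominance_mode == "digenic") {
    d <- stats::rnorm(length(qtl_idx), 0, stats::sd(a))
    H <- X[, qtl_idx, drop = FALSE] * (p - X[, qtl_idx, drop = FALSE]) / (p^2 / 4)
    na_val <- drop(H %*% d); na_val <- na_val - mean(na_val)
  } else if (config$dominance_mode == "full-class") {
    for (j in seq_along(qtl_idx)) {
      cls_val <- stats::rnorm(p + 1, 0, stats::sd(a))
      na_val <- na_val + cls_val[X[, qtl_idx[j]] + 1L]
    }
    na_val <- na_val - mean(na_val)
  }
  h2 <- config$target_h2
  v_bv <- stats::var(bv); v_na <- stats::var(na_val)
  if (h2 == 0) {
    pheno <- stats::rnorm(n, 0, 1)
  } else {
    if (v_bv <= 0) stop("no additive genetic variance; cannot reach target_h2 > 0")
    ve <- v_bv / h2 - v_bv - v_na
    if (ve < 0) {
      warning("non-additive variance too large for target_h2; residual clamped at 0")
      ve <- 0
    }
    pheno <- bv + na_val + stats::rnorm(n, 0, sqrt(ve))
  }
  ids <- colnames(pop$dosage)
  names(bv) <- names(pheno) <- ids
  pop$true_bv <- bv
  pop$phenotype <- pheno
  pop$qtl <- data.frame(pop$map[qtl_idx, ], effect = a, row.names = NULL)
  pop
}

#' Degrade dosages through a finite-depth sequencing model
#'
#' Emulates naive genotyping-by-sequencing dosage calling: per entry, the
#' read depth is Poisson(`mean_depth`), alternative-allele reads are
#' Binomial(depth, dosage/ploidy), and the returned dosage is the
#' maximum-likelihood call under the binomial read model with a uniform
#' prior over `0..ploidy` (ties resolved toward the lower dosage). Zero
#' depth yields a missing call; additional calls are masked completely at
#' random at `missing_rate`. Heterozygous dosage classes need high depth to
#' be distinguished reliably, so lowering `mean_depth` raises the
#' call-error rate.
#'
#' @param pop A `sim_population` (or a [dosage_matrix]).
#' @param mean_depth Expected reads per locus per individual (> 0).
#' @param missing_rate Extra completely-at-random missing fraction.
#' @param seed Integer seed.
#' @return A [dosage_matrix] of called dosages with `NA` for missing.
#' @export
degrade_by_depth <- function(pop, mean_depth = NULL, missing_rate = NULL, seed = NULL) {
  g <- if (inherits(pop, "dosage_matrix")) pop else pop$dosage
  cfg <- if (inherits(pop, "sim_population")) pop$config else NULL
  if (is.null(mean_depth)) mean_depth <- cfg$mean_depth
  if (is.null(missing_rate)) missing_rate <- if (is.null(cfg)) 0 else cfg$missing_rate
  if (is.null(seed)) seed <- if (is.null(cfg)) 1L else cfg$seed + 104729L
  stopifnot(mean_depth > 0, missing_rate >= 0, missing_rate <= 1)
  set.seed(seed)
  p <- ploidy(g)
  ne <- length(g)
  depth <- stats::rpois(ne, mean_depth)
  truth <- as.vector(unclass(g))
  alt <- stats::rbinom(ne, depth, ifelse(is.na(truth), 0, truth) / p)
  called <- call_dosage_ml(alt, depth, p)
  called[depth == 0] <- NA_integer_
  if (missing_rate > 0)
    called[stats::runif(ne) < missing_rate] <- NA_integer_
  out <- matrix(called, nrow(g), ncol(g), dimnames = dimnames(g))
  out[is.na(unclass(g))] <- NA_integer_
  dosage_matrix(out, p)
}

#' Maximum-likelihood dosage from read counts
#'
#' Argmax over dosage `d` of `Binomial(alt | depth, d/ploidy)` with a
#' uniform prior; the building block of [degrade_by_depth()].
#'
#' @param alt Alternative-allele read counts.
#' @param depth Total read depths (same length).
#' @param ploidy Even integer ploidy.
#' @return Integer vector of called dosages (`NA` where `depth == 0`).
#' @export
call_dosage_ml <- function(alt, depth, ploidy) {
  p <- check_ploidy(ploidy)
  ll <- vapply(0:p, function(d)
    stats::dbinom(alt, depth, d / p, log = TRUE), numeric(length(alt)))
  if (length(alt) == 1) ll <- matrix(ll, nrow = 1)
  out <- max.col(ll, ties.method = "first") - 1L
  out[depth == 0] <- NA_integer_
  out
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("<sim_population> ploidy %d, %d individuals, %d markers%s%s\n",
              ploidy(x$dosage), ncol(x$dosage), nrow(x$dosage),
              if (!is.null(x$phenotype)) ", phenotyped" else "",
              if (!is.null(x$homolog_origin)) ", phased (F1)" else " (panel)"))
  invisible(x)
}
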