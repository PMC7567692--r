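# Small simulated populations shared across test files, built once per run.

.pop_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.pop_cache[[key]])) .pop_cache[[key]] <- force(expr)
  .pop_cache[[key]]
}

# hexaploid F1 family with an additive trait
small_f1 <- function(n = 120, nm = 150, h2 = 0.5, seed = 101, nq = 15,
                     ploidy = 6, dominance = "none") {
  key <- paste("f1", n, nm, h2, seed, nq, ploidy, dominance, sep = "_")
  cached(key, {
    cfg <- sim_config(ploidy = ploidy, n_offspring = n, n_markers = nm,
                      map_length_cM = c(100, 100), n_qtl = nq,
                      target_h2 = h2, dominance_mode = dominance, seed = seed)
    attach_phenotype(simulate_f1_family(cfg))
  })
}

# tetraploid HWE panel
small_panel <- function(n = 150, nm = 200, seed = 202) {
  key <- paste("panel", n, nm, seed, sep = "_")
  cached(key, {
    cfg <- sim_config(ploidy = 4, n_offspring = n, n_markers = nm,
                      map_length_cM = 100, seed = seed)
    simulate_panel(cfg)
  })
}

# enumeration oracle for the gamete dosage pmf: label the p chromosomes,
# mark `d` of them as carrying the alt allele, enumerate all C(p, p/2)
# gamete subsets
enumerate_gamete_pmf <- function(d, p) {
  subsets <- utils::combn(p, p / 2)
  alt <- seq_len(d)
  counts <- table(factor(apply(subsets, 2, function(s) sum(s %in% alt)),
                         levels = 0:(p / 2)))
  as.numeric(counts) / ncol(subsets)
}

# independent diploid VanRaden implementation (textbook form)
diploid_vanraden_oracle <- function(M) {
  # M: individuals x markers, dosages 0/1/2, no missing
  pfreq <- colMeans(M) / 2
  Z <- sweep(M, 2, 2 * pfreq)
  tcrossprod(Z) / (2 * sum(pfreq * (1 - pfreq)))
}

# dense-algebra REML log-likelihood used as an independent oracle: profiled
# residual variance, grid search over the variance ratio
reml_ll_dense <- function(y, K, lambda) {
  n <- length(y)
  H <- lambda * unclass(K) + diag(n)
  Hi <- solve(H)
  one <- rep(1, n)
  xhx <- drop(crossprod(one, Hi %*% one))
  mu <- drop(crossprod(one, Hi %*% y)) / xhx
  r <- y - mu
  se2 <- drop(crossprod(r, Hi %*% r)) / (n - 1)
  -0.5 * ((n - 1) * log(2 * pi * se2) + determinant(H)$modulus[1] +
            log(xhx) + (n - 1))
}

grid_reml_oracle <- function(y, K) {
  lgrid <- seq(-10, 10, by = 0.02)                # coarse pass
  ll <- vapply(lgrid, function(t) reml_ll_dense(y, K, exp(t)), 0)
  t0 <- lgrid[which.max(ll)]
  fine <- seq(t0 - 0.05, t0 + 0.05, by = 1e-4)    # refine at 1e-4 resolution
  llf <- vapply(fine, function(t) reml_ll_dense(y, K, exp(t)), 0)
  exp(fine[which.max(llf)])
}
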