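test_that("gamete pmf matches hand-derived values and edge cases", {
  expect_equal(gamete_pmf(0, 6), c(1, 0, 0, 0))
  expect_equal(gamete_pmf(6, 6), c(0, 0, 0, 1))
  expect_equal(gamete_pmf(3, 6), c(0.05, 0.45, 0.45, 0.05))
  expect_error(gamete_pmf(7, 6), "parent_dosage")
  expect_error(gamete_pmf(2, 5), "even")
})

test_that("gamete pmf equals exhaustive enumeration over labeled chromosomes", {
  for (p in c(2, 4, 6)) {
    for (d in 0:p) {
      expect_equal(gamete_pmf(d, p), enumerate_gamete_pmf(d, p),
                   info = sprintf("p=%d d=%d", p, d))
      expect_equal(sum(gamete_pmf(d, p)), 1)
    }
  }
})

test_that("double-reduction pmf sums to 1 and shifts mass toward homozygous gametes", {
  for (d in 0:6) {
    pmf <- gamete_pmf(d, 6, double_reduction = 0.1)
    expect_equal(sum(pmf), 1)
  }
  # a simplex parent can only transmit a duplex gamete through double reduction
  expect_equal(gamete_pmf(1, 4)[3], 0)
  expect_gt(gamete_pmf(1, 4, double_reduction = 0.1)[3], 0)
})

test_that("F1 offspring dosage distribution is the convolution of parental gamete pmfs", {
  p <- 6
  nm <- 4
  cfg <- sim_config(ploidy = p, n_offspring = 5000, n_markers = nm,
                    map_length_cM = 100, seed = 77)
  # parent 1 dosage 3 at every marker, parent 2 dosage 0
  par1 <- rbind(matrix(1L, 3, nm), matrix(0L, 3, nm))
  par2 <- matrix(0L, p, nm)
  pop <- simulate_f1_family(cfg, parents = list(par1, par2))
  expected <- c(0.05, 0.45, 0.45, 0.05)   # gamete pmf of the dosage-3 parent
  for (j in c(1, nm)) {
    obs <- table(factor(unclass(pop$dosage)[j, ], levels = 0:3))
    pval <- stats::chisq.test(as.numeric(obs), p = expected)$p.value
    expect_gt(pval, 0.01)
  }
  # both parents nulliplex at a locus -> all offspring dosage 0
  par1b <- matrix(0L, p, nm)
  popb <- simulate_f1_family(cfg, parents = list(par1b, par2))
  expect_true(all(unclass(popb$dosage) == 0L))
})

test_that("dosage equals the allele sum over inherited homologs and runs are reproducible", {
  pop <- small_f1(n = 40, nm = 60, seed = 5)
  p <- ploidy(pop$dosage)
  hap_all <- rbind(pop$parental_haplotypes[[1]], pop$parental_haplotypes[[2]])
  for (i in c(1, 17, 40)) {
    lab <- pop$homolog_origin[i, , ]           # ploidy x markers
    re <- sapply(seq_len(nrow(pop$map)), function(m) sum(hap_all[lab[, m], m]))
    expect_equal(unname(unclass(pop$dosage)[, i]), re)
  }
  cfg <- pop$config
  pop2 <- attach_phenotype(simulate_f1_family(cfg))
  expect_identical(unclass(pop$dosage), unclass(pop2$dosage))
  expect_identical(pop$phenotype, pop2$phenotype)
  expect_identical(pop$homolog_origin, pop2$homolog_origin)
})

test_that("markers on different chromosomes are in linkage equilibrium", {
  pop <- small_f1(n = 300, nm = 100, seed = 31)
  chr1 <- which(pop$map$chrom == 1)
  chr2 <- which(pop$map$chrom == 2)
  M <- t(unclass(pop$dosage))
  r2 <- outer(utils::head(chr1, 10), utils::head(chr2, 10),
              Vectorize(function(a, b) {
                if (stats::sd(M[, a]) == 0 || stats::sd(M[, b]) == 0) return(0)
                stats::cor(M[, a], M[, b])^2
              }))
  expect_lt(mean(r2), 0.05)
})

test_that("panel dosages follow Binomial(ploidy, freq) and report a realistic MAF spectrum", {
  cfg <- sim_config(ploidy = 4, n_offspring = 4000, n_markers = 3,
                    map_length_cM = 50, seed = 13)
  pop <- simulate_panel(cfg, allele_freqs = c(0, 0.5, 1))
  d <- unclass(pop$dosage)
  expect_true(all(d[1, ] == 0))
  expect_true(all(d[3, ] == 4))
  expect_equal(mean(d[2, ] == 2), stats::dbinom(2, 4, 0.5), tolerance = 0.05)
  expect_equal(mean(d[2, ]), 2, tolerance = 0.1)
  # default frequency spectrum: mean MAF near 0.15 as in hard-filtered GBS panels
  big <- simulate_panel(sim_config(ploidy = 4, n_offspring = 200,
                                   n_markers = 2000, seed = 17))
  maf <- marker_stats(big$dosage)$maf
  expect_lt(abs(mean(maf, na.rm = TRUE) - 0.15), 0.03)
})

test_that("attach_phenotype hits the target heritability and respects dominance_mode", {
  # realized h2 averaged over seeds, n >= 300
  h2s <- sapply(1:12, function(s) {
    pop <- small_f1(n = 320, nm = 80, h2 = 0.5, seed = 1000 + s, nq = 25)
    stats::var(pop$true_bv) / stats::var(pop$phenotype)
  })
  expect_equal(mean(h2s), 0.5, tolerance = 0.05)
  # h2 = 0: phenotype unrelated to breeding values
  cfg0 <- sim_config(ploidy = 6, n_offspring = 300, n_markers = 60,
                     target_h2 = 0, seed = 3)
  pop0 <- attach_phenotype(simulate_f1_family(cfg0))
  b <- stats::coef(stats::lm(pop0$phenotype ~ pop0$true_bv))[2]
  expect_lt(abs(b), 0.15)
  # no dominance: phenotype minus noise is linear in dosages
  pop <- small_f1(n = 60, nm = 50, seed = 21, nq = 5)
  X <- t(unclass(pop$dosage))[, match(pop$qtl$marker, rownames(pop$dosage))]
  expect_equal(unname(pop$true_bv),
               unname(drop(X %*% pop$qtl$effect) - mean(X %*% pop$qtl$effect)))
  # full-class dominance adds non-additive variance; when it exceeds the
  # additive budget for the target h2 the residual is clamped with a warning
  cfgd <- sim_config(ploidy = 6, n_offspring = 200, n_markers = 60, n_qtl = 10,
                     target_h2 = 0.8, dominance_mode = "full-class", seed = 22)
  expect_warning(popd <- attach_phenotype(simulate_f1_family(cfgd)),
                 "clamped")
  expect_s3_class(popd, "sim_population")
  cfgd2 <- sim_config(ploidy = 6, n_offspring = 200, n_markers = 60, n_qtl = 10,
                      target_h2 = 0.3, dominance_mode = "digenic", seed = 23)
  popd2 <- attach_phenotype(simulate_f1_family(cfgd2))
  expect_false(isTRUE(all.equal(unname(popd2$phenotype - popd2$true_bv),
                                rep(0, 200))))
})

test_that("ML dosage calling is consistent at high depth and degrades at low depth", {
  expect_equal(call_dosage_ml(3, 3, 4), 4L)       # all-alt reads -> full homozygote
  expect_equal(call_dosage_ml(0, 10, 6), 0L)
  expect_true(is.na(call_dosage_ml(0, 0, 4)))
  pop <- small_f1(n = 60, nm = 80, seed = 41)
  hi <- degrade_by_depth(pop, mean_depth = 10000, missing_rate = 0, seed = 9)
  expect_equal(unclass(hi), unclass(pop$dosage))
  lo <- degrade_by_depth(pop, mean_depth = 5, missing_rate = 0, seed = 9)
  md <- degrade_by_depth(pop, mean_depth = 100, missing_rate = 0, seed = 9)
  err <- function(called) mean(unclass(called) != unclass(pop$dosage), na.rm = TRUE)
  expect_gt(err(lo), err(md))
  # depth-0 entries and extra missingness become NA
  miss <- degrade_by_depth(pop, mean_depth = 1, missing_rate = 0.2, seed = 9)
  expect_gt(mean(is.na(miss)), 0.2)
})
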