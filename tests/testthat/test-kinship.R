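test_that("vanraden_additive reproduces the hand-computed tetraploid example", {
  # two individuals; marker rows give per-individual dosages (2,2) and (0,4)
  g <- dosage_matrix(rbind(c(2L, 2L), c(0L, 4L)), 4)
  K <- vanraden_additive(g)
  expect_equal(unname(as.matrix(K)), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
  expect_identical(model_tag(K), "Add_4x")
})

test_that("vanraden_additive at ploidy 2 equals an independent diploid implementation", {
  set.seed(8)
  M <- matrix(rbinom(30 * 80, 2, 0.4), 30, 80)       # individuals x markers
  g <- dosage_matrix(t(M), 2)
  K <- vanraden_additive(g)
  expect_equal(unname(as.matrix(K)), unname(diploid_vanraden_oracle(M)),
               tolerance = 1e-10)
})

test_that("kinship builders are symmetric, PSD after repair, and respect ID order", {
  pop <- small_f1()
  builders <- list(
    vanraden_additive(pop$dosage),
    full_model(pop$dosage),
    vanraden_additive(pseudo_diploidize(pop$dosage), tag = "Pseudo_2x"),
    vitezica_dominance(pseudo_diploidize(pop$dosage)),
    haplotype_kinship(pop, 50, 1))
  for (K in builders) {
    expect_lt(max(abs(unclass(K) - t(unclass(K)))), 1e-10)
    ev <- eigen(unclass(K), symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
    expect_identical(rownames(K), colnames(pop$dosage))
  }
})

test_that("duplicating an individual or every marker behaves as expected", {
  pop <- small_f1(n = 40, nm = 60, seed = 5)
  g <- pop$dosage
  # duplicated individual -> identical rows/columns and equal diagonals
  gdup <- dosage_matrix(cbind(unclass(g), dup = unclass(g)[, 1]), ploidy(g))
  K <- vanraden_additive(gdup)
  n <- ncol(gdup)
  expect_equal(unclass(K)[n, -n], unclass(K)[1, -n], tolerance = 1e-12)
  expect_equal(unclass(K)[n, n], unclass(K)[1, 1], tolerance = 1e-12)
  # duplicating every marker leaves the additive kinship unchanged
  g2 <- dosage_matrix(rbind(unclass(g),
                            `rownames<-`(unclass(g), paste0(rownames(g), "_b"))),
                      ploidy(g))
  expect_equal(as.matrix(vanraden_additive(g2)), as.matrix(vanraden_additive(g)),
               tolerance = 1e-10)
})

test_that("mean imputation of missing dosages does not change allele frequencies", {
  pop <- small_f1(n = 40, nm = 60, seed = 5)
  g <- unclass(pop$dosage) * 1.0
  q_full <- colMeans(t(g)) / ploidy(pop$dosage)
  gm <- unclass(pop$dosage)
  set.seed(2); gm[sample(length(gm), 100)] <- NA
  gm <- dosage_matrix(gm, ploidy(pop$dosage))
  # frequency computed after imputation inside the builder must equal the
  # called-only frequency
  st <- marker_stats(gm)
  M <- t(unclass(gm)) * 1.0
  mu <- colMeans(M, na.rm = TRUE)
  idx <- which(is.na(M), arr.ind = TRUE)
  M[idx] <- mu[idx[, 2]]
  expect_equal(unname(colMeans(M) / ploidy(gm)), st$alt_freq, tolerance = 1e-12)
  expect_s3_class(vanraden_additive(gm), "kinship_matrix")
})

test_that("full_model matches a brute-force one-hot oracle and flags monomorphic pops", {
  # 3 hexaploid individuals with classes 0, 3, 6 at one marker
  g <- dosage_matrix(matrix(c(0L, 3L, 6L), 1, 3), 6)
  K <- full_model(g)
  X <- matrix(0, 3, 7); X[cbind(1:3, c(1, 4, 7))] <- 1
  X <- sweep(X, 2, colMeans(X))
  G <- tcrossprod(X); G <- G * 3 / sum(diag(G))
  expect_equal(unname(as.matrix(K)), unname(G), tolerance = 1e-10)

  g_mono <- dosage_matrix(matrix(2L, 5, 10), 6)
  expect_true("quasi_monomorphic" %in% attr(full_model(g_mono), "flags"))

  # two individuals sharing the same class at every marker -> maximal entry
  pop <- small_f1(n = 30, nm = 40, seed = 9)
  gd <- dosage_matrix(cbind(unclass(pop$dosage), twin = unclass(pop$dosage)[, 3]),
                      6)
  Kd <- unclass(full_model(gd))
  off <- Kd; diag(off) <- -Inf
  expect_equal(which(off == max(off), arr.ind = TRUE)[1, 2] %in% c(3, 31), TRUE)
})

test_that("pseudo_diploidize implements the hexaploid design coding and is idempotent", {
  g <- dosage_matrix(matrix(0:6, 7, 1), 6)
  pd <- pseudo_diploidize(g)
  expect_equal(unname(unclass(pd)[, 1]), c(0L, 1L, 1L, 1L, 1L, 1L, 2L))
  expect_identical(unclass(pseudo_diploidize(pd)), unclass(pd))
  expect_identical(ploidy(pd), 2L)
  gna <- dosage_matrix(matrix(c(3L, NA), 1, 2), 6)
  expect_true(is.na(unclass(pseudo_diploidize(gna))[1, 2]))
})

test_that("vitezica_dominance uses the orthogonal dominance coding", {
  # q = 0.5 marker: codings (-0.5, 0.5, -0.5), denominator term 0.25
  g <- dosage_matrix(matrix(c(0L, 1L, 1L, 2L), 1, 4), 2)
  D <- vitezica_dominance(g)
  h <- c(-0.5, 0.5, 0.5, -0.5)
  expect_equal(unname(as.matrix(D)), outer(h, h) / 0.25, tolerance = 1e-10)
  expect_error(vitezica_dominance(dosage_matrix(matrix(2L, 1, 3), 4)), "diploid")
  # heterozygous-everywhere pair gets the maximal positive entry
  g2 <- dosage_matrix(rbind(c(1L, 1L, 0L, 2L), c(1L, 1L, 2L, 0L)), 2)
  D2 <- unclass(vitezica_dominance(g2))
  expect_gte(D2[1, 2], max(D2[1, 3], D2[1, 4]))
})

test_that("haplotype_kinship counts shared parental homolog labels", {
  lab <- rbind(i1 = c(1, 2, 3, 7, 8, 9),
               i2 = c(1, 2, 3, 10, 11, 12),   # shares 3 of 6 labels with i1
               i3 = c(4, 5, 6, 10, 11, 12))   # disjoint from i1
  K <- haplotype_kinship(lab)
  expect_equal(diag(unclass(K)), c(i1 = 1, i2 = 1, i3 = 1))
  expect_equal(unclass(K)["i1", "i2"], 0.5)
  expect_equal(unclass(K)["i1", "i3"], 0)
  # multiplicity: a double-reduced duplicated label counts twice
  lab2 <- rbind(a = c(1, 1, 2, 3), b = c(1, 1, 4, 5))
  expect_equal(unclass(haplotype_kinship(lab2))["a", "b"], 0.5)
})

test_that("average_kinships is the element-wise mean with ID checking", {
  pop <- small_f1(n = 30, nm = 40, seed = 9)
  K1 <- haplotype_kinship(pop, 10, 1)
  K2 <- haplotype_kinship(pop, 90, 2)
  K3 <- haplotype_kinship(pop, 50, 1)
  avg <- average_kinships(list(K1, K2, K3))
  brute <- (as.matrix(K1) + as.matrix(K2) + as.matrix(K3)) / 3
  expect_equal(as.matrix(avg), brute, tolerance = 1e-12)
  expect_equal(as.matrix(average_kinships(list(K1, K1))), as.matrix(K1))
  Kz <- new_k <- K1; rownames(new_k) <- rev(rownames(K1))
  expect_error(average_kinships(list(K1, new_k)), "mismatched")
})

test_that("kinship CSV round-trip preserves values and IDs", {
  pop <- small_f1(n = 30, nm = 40, seed = 9)
  K <- vanraden_additive(pop$dosage)
  f <- withr::local_tempfile(fileext = ".csv")
  write_kinship_csv(K, f)
  K2 <- read_kinship_csv(f, tag = "Add_6x")
  expect_equal(as.matrix(K2), as.matrix(K), tolerance = 1e-6)
  expect_identical(rownames(K2), rownames(K))
})
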