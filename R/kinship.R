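#' Kinship (genomic relationship) matrices for polyploids
#'
#' All builders return an n x n symmetric matrix of class `kinship_matrix`
#' carrying a `model_tag` attribute and, where relevant, diagnostic flags.
#' Missing dosages are mean-imputed per marker before centering (which
#' leaves the allele frequency unchanged); matrices whose smallest
#' eigenvalue is negative are repaired by adding the smallest ridge
#' `(|min eigenvalue| + 1e-8) I`.
#'
#' @name kinship
NULL

new_kinship <- function(values, model_tag, flags = character()) {
  values <- (values + t(values)) / 2
  structure(values, model_tag = model_tag, flags = flags,
            class = c("kinship_matrix", "matrix"))
}

#' @export
print.kinship_matrix <- function(x, ...) {
  fl <- attr(x, "flags")
  cat(sprintf("<kinship_matrix> %d x %d, model %s%s\n", nrow(x), ncol(x),
              attr(x, "model_tag"),
              if (length(fl)) paste0(" [", paste(fl, collapse = ", "), "]") else ""))
  invisible(x)
}

#' @export
`[.kinship_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, model_tag = attr(x, "model_tag"),
                     flags = attr(x, "flags"),
                     class = c("kinship_matrix", "matrix"))
  out
}

#' @rdname kinship
#' @param K A `kinship_matrix`.
#' @export
model_tag <- function(K) attr(K, "model_tag")

#' @export
as.matrix.kinship_matrix <- function(x, ...) {
  a <- attributes(x)
  attributes(x) <- a[names(a) %in% c("dim", "dimnames")]
  x
}

# markers x individuals -> individuals x markers with per-marker mean
# imputation of missing entries; also returns ploidy-scaled frequencies
impute_and_freq <- function(g) {
  p <- ploidy(g)
  M <- t(unclass(g)) * 1.0                   # individuals x markers
  mu <- colMeans(M, na.rm = TRUE)
  idx <- which(is.na(M), arr.ind = TRUE)
  if (nrow(idx)) M[idx] <- mu[idx[, 2]]
  list(M = M, q = mu / p, p = p)
}

#' Repair a matrix to positive semi-definiteness
#'
#' Adds the smallest diagonal ridge making the minimum eigenvalue
#' non-negative; a no-op for matrices already PSD.
#'
#' @param K Symmetric matrix.
#' @param quiet Suppress the message when a ridge is applied.
#' @return The (possibly ridged) matrix; attribute `ridge` records the
#'   amount added.
#' @export
make_psd <- function(K, quiet = TRUE) {
  ev_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  ridge <- 0
  if (ev_min < -1e-10) {
    ridge <- abs(ev_min) + 1e-8
    K <- K + diag(ridge, nrow(K))
    if (!quiet) message(sprintf("make_psd: added ridge %.3g", ridge))
  }
  attr(K, "ridge") <- ridge
  K
}

#' VanRaden additive relationship matrix at arbitrary even ploidy
#'
#' Centers the dosage matrix at the ploidy-scaled allele frequency
#' (`W = M - p q_j` per marker `j`) and normalizes by the expected variance
#' sum: `G = W W' / (p * sum_j q_j (1 - q_j))`. At ploidy 2 this is the
#' classical diploid VanRaden matrix; at higher ploidy it is the
#' dosage-additive kinship used for autopolyploid G-BLUP.
#'
#' @param g A [dosage_matrix] (missing entries mean-imputed per marker).
#' @param tag Model tag stored on the result.
#' @return A `kinship_matrix`.
#' @export
vanraden_additive <- function(g, tag = sprintf("Add_%dx", ploidy(g))) {
  f <- impute_and_freq(g)
  poly <- f$q > 0 & f$q < 1
  if (sum(poly) < 1)
    stop("all markers are monomorphic; additive kinship undefined")
  W <- sweep(f$M[, poly, drop = FALSE], 2, f$p * f$q[poly])
  denom <- f$p * sum(f$q[poly] * (1 - f$q[poly]))
  G <- tcrossprod(W) / denom
  new_kinship(make_psd(G), tag)
}

#' Full (additive + non-additive) dosage-class relationship matrix
#'
#' One-hot encodes each marker into `ploidy + 1` dosage-class indicator
#' columns (the hexaploid design coding: class AAAAAA -> 1000000, AAAAAB ->
#' 0100000, ..., BBBBBB -> 0000001, and its tetraploid analogue), centers
#' the indicators, and normalizes `X X'` so its mean diagonal is 1
#' (trace/n = 1). The resulting kernel captures additive plus all
#' dosage-class (non-additive) contrasts. In populations where most
#' individuals share the same class at most markers the off-diagonal
#' entries collapse; such matrices are flagged `quasi_monomorphic` (over
#' 99% of off-diagonal entries within 1e-6 of their median), which in
#' practice yields unstable, often negative predictive ability.
#'
#' @param g A [dosage_matrix].
#' @param tag Model tag.
#' @return A `kinship_matrix`, possibly flagged `quasi_monomorphic`.
#' @export
full_model <- function(g, tag = sprintf("Full_%dx", ploidy(g))) {
  p <- ploidy(g)
  M <- t(unclass(g))                         # individuals x markers
  n <- nrow(M); nm <- ncol(M)
  G <- matrix(0, n, n)
  for (j in seq_len(nm)) {
    x <- M[, j]
    X <- matrix(0, n, p + 1)
    ok <- !is.na(x)
    X[cbind(which(ok), x[ok] + 1L)] <- 1
    # missing row gets the observed class frequencies (mean imputation)
    if (any(!ok)) {
      fr <- colMeans(X[ok, , drop = FALSE])
      X[!ok, ] <- matrix(fr, sum(!ok), p + 1, byrow = TRUE)
    }
    X <- sweep(X, 2, colMeans(X))
    G <- G + tcrossprod(X)
  }
  tr <- sum(diag(G))
  if (tr <= 0) {
    flags <- "quasi_monomorphic"
    G <- diag(n) * 0
  } else {
    G <- G * n / tr
    off <- G[lower.tri(G)]
    flags <- if (length(off) && mean(abs(off - stats::median(off)) < 1e-6) > 0.99)
      "quasi_monomorphic" else character()
  }
  dimnames(G) <- list(colnames(g), colnames(g))
  new_kinship(make_psd(G), tag, flags)
}

#' Pseudo-diploidize a polyploid dosage matrix
#'
#' Collapses all heterozygous dosage classes between the nulliplex and the
#' full homozygote into one heterozygote class: dosage `0 -> 0`,
#' `ploidy -> 2`, anything in between `-> 1`; missing stays missing. The
#' operation is idempotent, and the returned matrix has ploidy 2 so the
#' standard diploid kinship builders apply.
#'
#' @param g A [dosage_matrix].
#' @return A [dosage_matrix] at ploidy 2.
#' @export
pseudo_diploidize <- function(g) {
  p <- ploidy(g)
  v <- unclass(g)
  out <- ifelse(v == 0L, 0L, ifelse(v == p, 2L, 1L))
  dimnames(out) <- dimnames(g)
  dosage_matrix(out, 2)
}

#' Dominance (digenic) relationship matrix for diploid-coded data
#'
#' Vitezica-style orthogonal dominance coding per marker with allele
#' frequency `q`: genotype 0 -> `-2 q^2`, 1 -> `2 q (1 - q)`,
#' 2 -> `-2 (1 - q)^2`; `D = H H' / sum_j (2 q_j (1 - q_j))^2`.
#'
#' @param g A [dosage_matrix] at ploidy 2 (diploid or pseudo-diploidized).
#' @param tag Model tag.
#' @return A `kinship_matrix`.
#' @export
vitezica_dominance <- function(g, tag = "NonAdd_2x") {
  if (ploidy(g) != 2)
    stop("dominance coding requires diploid (ploidy 2) input; pseudo_diploidize() first")
  f <- impute_and_freq(g)
  q <- f$q
  poly <- q > 0 & q < 1
  if (sum(poly) < 1) stop("all markers monomorphic; dominance kinship undefined")
  M <- f$M[, poly, drop = FALSE]; q <- q[poly]
  H <- matrix(0, nrow(M), ncol(M))
  for (j in seq_len(ncol(M))) {
    cod <- c(-2 * q[j]^2, 2 * q[j] * (1 - q[j]), -2 * (1 - q[j])^2)
    x <- M[, j]
    # linear interpolation of the coding for fractional (imputed) dosages
    H[, j] <- stats::approx(0:2, cod, xout = x, rule = 2)$y
  }
  denom <- sum((2 * q * (1 - q))^2)
  D <- tcrossprod(H) / denom
  dimnames(D) <- list(colnames(g), colnames(g))
  new_kinship(make_psd(D), tag)
}

#' Haplotype-sharing kinship at a map position
#'
#' Identity-by-descent relationship among full sibs from the labels of the
#' parental homologs inherited at a locus: entry `(i, j)` is the number of
#' shared labels, counted with multiplicity, divided by the ploidy; the
#' diagonal is fixed at 1.
#'
#' @param pop A `sim_population` with `homolog_origin` (phased F1), or an
#'   `n x ploidy` integer label matrix directly.
#' @param locus Map position (cM) at which to take the labels; the nearest
#'   marker is used. Ignored when a label matrix is supplied.
#' @param chrom Chromosome of `locus` (defaults to 1).
#' @return A `kinship_matrix` with tag `Hap_locus`.
#' @export
haplotype_kinship <- function(pop, locus = NULL, chrom = 1) {
  if (inherits(pop, "sim_population")) {
    if (is.null(pop$homolog_origin))
      stop("population has no homolog-origin labels (unphased panel?)")
    idx <- which(pop$map$chrom == chrom)
    if (!length(idx)) stop("no markers on chromosome ", chrom)
    mk <- idx[which.min(abs(pop$map$pos[idx] - locus))]
    lab <- pop$homolog_origin[, , mk]
    ids <- colnames(pop$dosage)
  } else {
    lab <- as.matrix(pop)
    ids <- rownames(lab)
  }
  n <- nrow(lab); p <- ncol(lab)
  # shared-label count with multiplicity = sum over labels of min(count_i, count_j)
  labs <- sort(unique(as.vector(lab)))
  cnt <- vapply(labs, function(l) rowSums(lab == l), numeric(n))
  K <- matrix(0, n, n)
  for (l in seq_along(labs))
    K <- K + outer(cnt[, l], cnt[, l], pmin)
  K <- K / p
  diag(K) <- 1
  if (!is.null(ids)) dimnames(K) <- list(ids, ids)
  new_kinship(K, "Hap_locus")
}

#' Element-wise average of kinship matrices
#'
#' Used to combine the haplotype kinships of several QTL peaks into one
#' kernel.
#'
#' @param ks List of conformable `kinship_matrix` objects with identical
#'   individual order.
#' @param tag Model tag of the result.
#' @return A `kinship_matrix`.
#' @export
average_kinships <- function(ks, tag = "Hap_avg") {
  stopifnot(length(ks) >= 1)
  ids <- rownames(ks[[1]])
  for (K in ks) {
    if (!all(dim(K) == dim(ks[[1]]))) stop("kinship matrices not conformable")
    if (!is.null(ids) && !identical(rownames(K), ids))
      stop("kinship matrices have mismatched individual IDs")
  }
  new_kinship(Reduce(`+`, lapply(ks, unclass)) / length(ks), tag)
}

#' Write / read a kinship matrix as CSV
#'
#' Square layout with individual IDs as header row and first column.
#'
#' @param K A `kinship_matrix`.
#' @param path File path.
#' @export
write_kinship_csv <- function(K, path) {
  df <- data.frame(id = rownames(K), unclass(K), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kinship_csv
#' @param tag Model tag to attach on read.
#' @export
read_kinship_csv <- function(path, tag = "unknown") {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  new_kinship(m, tag)
}
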