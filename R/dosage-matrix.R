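#' Dosage genotype matrix
#'
#' Container for biallelic marker genotypes of an autopolyploid population,
#' stored as the dosage (copy number) of the alternative allele: an integer
#' matrix with markers as rows and individuals as columns, entries in
#' `0..ploidy`, missing calls as `NA`.
#'
#' @param values Integer matrix, markers x individuals. Row names are marker
#'   IDs, column names individual IDs; generated when absent.
#' @param ploidy Even positive integer (2, 4, 6, ...).
#' @return An object of class `dosage_matrix`: the integer matrix with a
#'   `ploidy` attribute.
#' @examples
#' g <- dosage_matrix(matrix(c(0L, 3L, 6L, 2L), 2, 2), ploidy = 6)
#' ploidy(g)
#' @export
dosage_matrix <- function(values, ploidy) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "integer"
  check_ploidy(ploidy)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("M%04d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("Ind%04d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate marker IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate individual IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  bad <- which(!is.na(values) & (values < 0L | values > ploidy), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "dosage out of range [0, %d] at marker '%s', individual '%s' (value %d)",
      ploidy, rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]],
      values[bad[1, , drop = FALSE]]))
  }
  structure(values, ploidy = as.integer(ploidy), class = c("dosage_matrix", "matrix"))
}

#' @rdname dosage_matrix
#' @param x A `dosage_matrix`.
#' @export
ploidy <- function(x) attr(x, "ploidy")

#' @export
as.matrix.dosage_matrix <- function(x, ...) {
  a <- attributes(x)
  attributes(x) <- a[names(a) %in% c("dim", "dimnames")]
  x
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix> %d markers x %d individuals, ploidy %d, %.1f%% missing\n",
              nrow(x), ncol(x), ploidy(x), 100 * mean(is.na(x))))
  invisible(x)
}

# keep class + ploidy through marker/individual subsetting
#' @export
`[.dosage_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, ploidy = ploidy(x), class = c("dosage_matrix", "matrix"))
  out
}

check_ploidy <- function(p) {
  if (length(p) != 1 || is.na(p) || p < 2 || p %% 2 != 0)
    stop("ploidy must be a single even integer >= 2, got: ", p)
  invisible(as.integer(p))
}
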