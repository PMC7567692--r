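#' Read a dosage matrix from CSV
#'
#' Expects the layout used for polyploid dosage tables: first column marker
#' ID, remaining columns one per individual (header row of IDs), cells the
#' integer dosage of the alternative allele. Missing calls may be coded
#' `NA`, `-` or an empty cell.
#'
#' @param path CSV file path.
#' @param ploidy Even integer ploidy of the population.
#' @param missing_codes Character vector of strings treated as missing.
#' @return A [dosage_matrix].
#' @seealso [write_dosage_csv()]
#' @export
read_dosage_csv <- function(path, ploidy, missing_codes = c("NA", "-", "")) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = missing_codes)
  if (ncol(df) < 2) stop("expected a marker-ID column plus >= 1 individual column")
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = list(ids, colnames(vals))))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric dosage '%s' at marker '%s', individual '%s'",
                 vals[bad[1, , drop = FALSE]], ids[bad[1, 1]],
                 colnames(vals)[bad[1, 2]]))
  if (any(abs(num - round(num)) > 1e-9, na.rm = TRUE))
    stop("dosages must be integers")
  dosage_matrix(num, ploidy)
}

#' Write a dosage matrix to CSV
#'
#' Inverse of [read_dosage_csv()]: marker IDs in the first column, individual
#' IDs as header, missing entries written as `NA`.
#'
#' @param g A [dosage_matrix].
#' @param path Output file path.
#' @export
write_dosage_csv <- function(g, path) {
  df <- data.frame(marker = rownames(g), unclass(g), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Per-marker summary statistics from dosage genotypes
#'
#' Allele frequencies are obtained by counting alleles in each dosage-coded
#' genotype: the alternative-allele frequency of a marker is the summed
#' dosage over called individuals divided by `ploidy * n_called`.
#' Informativeness (`pic`) is the expected heterozygosity
#' `1 - q^2 - (1-q)^2 = 2q(1-q)`, which for a biallelic locus ranges from 0
#' to 0.5.
#'
#' @param g A [dosage_matrix].
#' @return A data frame with one row per marker: `marker`, `alt_freq`,
#'   `maf`, `call_rate`, `pic`. Markers with no called individuals get `NA`
#'   frequencies and `call_rate` 0.
#' @export
marker_stats <- function(g) {
  p <- ploidy(g)
  n_called <- rowSums(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE)
  q <- ifelse(n_called > 0, alt / (p * n_called), NA_real_)
  data.frame(
    marker = rownames(g),
    alt_freq = q,
    maf = pmin(q, 1 - q),
    call_rate = n_called / ncol(g),
    pic = 2 * q * (1 - q),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Filter markers by minor allele frequency and call rate
#'
#' Retains markers with `maf >= min_maf` and `call_rate >= min_call_rate`
#' (both inclusive); marker order is preserved. The standard stringent
#' setting for model comparison in polyploid panels is MAF >= 0.30 and call
#' rate >= 0.90.
#'
#' @param g A [dosage_matrix].
#' @param min_maf Minimum minor allele frequency in `[0, 0.5]`.
#' @param min_call_rate Minimum fraction of called individuals in `[0, 1]`.
#' @param quiet Suppress the retained-count message.
#' @return The filtered [dosage_matrix]; the number of retained markers is
#'   available as `nrow()`.
#' @export
filter_markers <- function(g, min_maf = 0.30, min_call_rate = 0.90, quiet = FALSE) {
  stopifnot(min_maf >= 0, min_maf <= 0.5, min_call_rate >= 0, min_call_rate <= 1)
  st <- marker_stats(g)
  keep <- !is.na(st$maf) & st$maf >= min_maf & st$call_rate >= min_call_rate
  if (!quiet)
    message(sprintf("filter_markers: retained %d of %d markers (MAF >= %g, call rate >= %g)",
                    sum(keep), nrow(g), min_maf, min_call_rate))
  if (sum(keep) == 0 && !quiet) message("filter_markers: no markers retained")
  g[keep, , drop = FALSE]
}

#' Randomly subsample markers
#'
#' Uniform sample of `k` markers without replacement, reproducible under
#' `seed`; used for marker-density experiments.
#'
#' @param g A [dosage_matrix].
#' @param k Number of markers to keep, `k <= nrow(g)`.
#' @param seed Optional integer seed.
#' @return A [dosage_matrix] with `k` rows (in original order).
#' @export
subsample_markers <- function(g, k, seed = NULL) {
  if (k > nrow(g)) stop("k (", k, ") exceeds number of markers (", nrow(g), ")")
  if (!is.null(seed)) set.seed(seed)
  idx <- sort(sample.int(nrow(g), k))
  g[idx, , drop = FALSE]
}

#' Read a phenotype (BLUE) table
#'
#' Long-format CSV with columns `individual`, `trait`, `value`: one adjusted
#' genotype mean (BLUE) per individual and trait. When `genotype_ids` is
#' given, individuals absent from the genotype data are reported and
#' dropped.
#'
#' @param path CSV file path.
#' @param genotype_ids Optional character vector of genotyped individual IDs.
#' @return Data frame `individual`, `trait`, `value`.
#' @export
read_blues_csv <- function(path, genotype_ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual", "trait", "value")
  if (!all(need %in% names(df)))
    stop("phenotype CSV must have columns: ", paste(need, collapse = ", "))
  for (tr in unique(df$trait)) {
    v <- df$value[df$trait == tr]
    if (all(is.na(v))) stop("trait '", tr, "' has no non-missing values")
  }
  if (!is.numeric(df$value)) stop("phenotype values must be numeric")
  dup <- duplicated(df[, c("individual", "trait")])
  if (any(dup))
    stop("duplicated individual-trait pair(s): ",
         paste(df$individual[dup][1], df$trait[dup][1]),
         " (BLUEs are one value per genotype)")
  if (!is.null(genotype_ids)) {
    miss <- setdiff(unique(df$individual), genotype_ids)
    if (length(miss) == length(unique(df$individual)))
      stop("no phenotyped individual has genotype data")
    if (length(miss) > 0) {
      warning(length(miss), " phenotyped individual(s) without genotypes dropped: ",
              paste(utils::head(miss, 5), collapse = ", "))
      df <- df[df$individual %in% genotype_ids, , drop = FALSE]
    }
  }
  df[, need]
}

#' Write a phenotype table to CSV
#'
#' @param pheno Data frame with `individual`, `trait`, `value`.
#' @param path Output file path.
#' @export
write_blues_csv <- function(pheno, path) {
  utils::write.csv(pheno[, c("individual", "trait", "value")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read dosages from a VCF file
#'
#' Maps the GT field of a biallelic VCF to alternative-allele dosage
#' (`0/0/0/1 -> 1` etc.) and masks genotypes failing optional per-call
#' quality thresholds, following the usual GBS hard-filter style
#' (genotype quality and read depth).
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param ploidy Even integer ploidy; GT fields with a different number of
#'   alleles become missing.
#' @param min_gq Minimum genotype quality (GQ), or `NULL` to ignore.
#' @param min_dp Minimum read depth (DP), or `NULL` to ignore.
#' @return A [dosage_matrix].
#' @export
read_dosage_vcf <- function(path, ploidy, min_gq = NULL, min_dp = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_dosage_vcf requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- rownames(gt)
  if (is.null(ids)) ids <- sprintf("M%04d", seq_len(nrow(gt)))
  dos <- apply(gt, c(1, 2), function(s) {
    if (is.na(s)) return(NA_integer_)
    alleles <- strsplit(s, "[/|]")[[1]]
    if (length(alleles) != ploidy || any(alleles == ".")) return(NA_integer_)
    sum(alleles == "1")
  })
  mask_below <- function(dos, elem, thr) {
    x <- suppressWarnings(apply(vcfR::extract.gt(v, element = elem),
                                c(1, 2), as.numeric))
    dos[!is.na(x) & x < thr] <- NA_integer_
    dos
  }
  if (!is.null(min_gq)) dos <- mask_below(dos, "GQ", min_gq)
  if (!is.null(min_dp)) dos <- mask_below(dos, "DP", min_dp)
  rownames(dos) <- make.unique(ids)
  dosage_matrix(dos, ploidy)
}
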