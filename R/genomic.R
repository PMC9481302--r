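#' SNP quality control
#'
#' Removes markers with folded minor allele frequency below `maf_min` or call
#' rate below `call_rate_min`. Allele frequency is computed from non-missing
#' calls of the allele coded +1 and folded to at most 0.5.
#'
#' @param geno Numeric matrix, lines in rows (rownames = line ids), SNPs in
#'   columns, calls coded -1/0/1 with `NA` for missing.
#' @param maf_min,call_rate_min Thresholds; markers strictly below either are
#'   dropped (defaults 0.05 and 0.90).
#' @return The filtered genotype matrix; a per-reason removal report is
#'   attached as attribute `"qc_report"`.
#' @export
qc_snps <- function(geno, maf_min = 0.05, call_rate_min = 0.90) {
  geno <- as.matrix(geno)
  if (length(geno) == 0) abort("empty genotype matrix")
  call_rate <- colMeans(!is.na(geno))
  p <- colMeans((geno + 1) / 2, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0

  low_cr <- call_rate < call_rate_min
  low_maf <- !low_cr & maf < maf_min
  keep <- !(low_cr | low_maf)
  if (!any(keep)) abort("all SNPs removed by quality control")

  out <- geno[, keep, drop = FALSE]
  attr(out, "qc_report") <- tibble::tibble(
    snp = colnames(geno) %||% as.character(seq_len(ncol(geno))),
    maf = maf, call_rate = call_rate,
    removed = !keep,
    reason = dplyr::case_when(low_cr ~ "call_rate", low_maf ~ "maf",
                              TRUE ~ NA_character_)
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' VanRaden (method 1) genomic relationship matrix
#'
#' Centers the -1/0/1 SNP codes by twice the deviation of the +1-allele
#' frequency from one half (`Z = M - P`, `P[, i] = 2 (p_i - 0.5)`) and scales
#' the cross-product by twice the summed heterozygosity:
#' `G = Z Z' / (2 sum p_i (1 - p_i))`. Missing calls are imputed to the
#' per-SNP mean of the coded values before centering. The mean diagonal of
#' `G` equals one plus the average genomic inbreeding of the population.
#'
#' @param geno Genotype matrix (post-QC), lines in rows, coded -1/0/1 with
#'   `NA` for missing.
#' @return A symmetric positive semidefinite matrix over lines; attribute
#'   `"mean_diag"` holds its mean diagonal.
#' @export
build_grm <- function(geno) {
  M <- as.matrix(geno)
  p <- colMeans((M + 1) / 2, na.rm = TRUE)
  if (anyNA(M)) {
    mu <- 2 * p - 1
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- mu[idx[, 2]]
  }
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) abort("all SNPs monomorphic: GRM denominator is zero")
  Z <- sweep(M, 2, 2 * (p - 0.5))
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  attr(G, "mean_diag") <- mean(diag(G))
  G
}

#' Genomic-by-environmental Hadamard interaction kernel
#'
#' The observation-level kernel of the marker-by-environmental-covariate
#' reaction-norm effect is the cell-by-cell (Hadamard) product of the
#' observation-expanded genomic relationships with the environmental kernel:
#' `GW[i, j] = G[line(i), line(j)] * Omega[i, j]`. By the Schur product
#' theorem it is positive semidefinite whenever `G` and `Omega` are.
#'
#' @param G Genomic relationship matrix over lines ([build_grm()]).
#' @param omega Observation-level environmental kernel ([build_omega()]).
#' @param obs2line Data frame with columns `obs_id`, `line_id` mapping every
#'   observation (row of `omega`) to one line (row of `G`).
#' @param max_n Guard against accidental huge dense materialization; raise it
#'   for larger problems.
#' @return A symmetric matrix with `obs_id` dimnames.
#' @export
build_gw_kernel <- function(G, omega, obs2line, max_n = 20000L) {
  obs2line <- tibble::as_tibble(obs2line)[c("obs_id", "line_id")]
  obs <- rownames(omega)
  if (is.null(obs)) abort("omega must carry obs_id dimnames")
  n <- nrow(omega)
  if (n > max_n) abort(sprintf("n = %d exceeds max_n = %d for dense kernel", n, max_n))
  map <- obs2line$line_id[match(obs, obs2line$obs_id)]
  if (anyNA(map)) abort("some omega observations are missing from obs2line")
  bad <- setdiff(map, rownames(G))
  if (length(bad) > 0) {
    abort(sprintf("lines absent from G: %s", paste(unique(bad)[1:min(5, length(unique(bad)))],
                                                   collapse = ", ")))
  }
  gw <- G[map, map, drop = FALSE] * omega
  dimnames(gw) <- list(obs, obs)
  gw
}

#' Read a line-by-SNP genotype matrix
#'
#' `read_genotypes()` reads a CSV of -1/0/1 calls with line ids in the first
#' column (empty cells are missing). `read_genotypes_vcf()` converts the GT
#' field of a biallelic VCF to the same coding (0/0 -> -1, 0/1 -> 0,
#' 1/1 -> +1) with samples as lines.
#'
#' @param path File path.
#' @return Numeric matrix, lines in rows.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_genotypes
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("package 'vcfR' is required to read VCF genotypes")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(x) {
    x <- gsub("\\|", "/", x)
    dplyr::case_when(x == "0/0" ~ -1, x %in% c("0/1", "1/0") ~ 0,
                     x == "1/1" ~ 1, TRUE ~ NA_real_)
  }
  m <- apply(gt, 2, code)
  rownames(m) <- rownames(gt)
  t(m)
}
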