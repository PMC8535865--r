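#' Case-control genotype dataset
#'
#' Container for a samples-by-SNPs table of categorical genotype calls together
#' with an aligned binary phenotype. Genotypes are two-letter strings over
#' \{A,C,G,T\} (e.g. \code{"CC"}, \code{"CT"}, \code{"TT"}); heterozygotes are
#' canonicalised to alphabetical order so \code{"TC"} and \code{"CT"} are the
#' same category. Each SNP carries an ordered (major, minor) allele pair used
#' for additive 0/1/2 coding.
#'
#' @param genotypes character matrix, samples in rows, SNPs in columns;
#'   dimnames give sample and SNP identifiers (generated when absent).
#' @param phenotype binary vector (0 = control/acute, 1 = case/chronic),
#'   length \code{nrow(genotypes)}.
#' @param missing_code string standing for a missing call (default
#'   \code{"NN"}); \code{NA} entries are also treated as missing.
#' @param allele_map optional 2-row character matrix (rows \code{major},
#'   \code{minor}) with one column per SNP; inferred from allele frequencies
#'   when \code{NULL} (most frequent allele = major; ties broken
#'   alphabetically).
#'
#' @return An object of class \code{"genotype_data"}: a list with elements
#'   \code{genotypes}, \code{phenotype}, \code{sample_ids}, \code{snp_ids},
#'   \code{allele_map}, \code{missing_code}.
#'
#' @examples
#' g <- matrix(c("CC", "CT", "TT", "AA", "AG", "AA"), nrow = 3,
#'             dimnames = list(paste0("s", 1:3), c("snp1", "snp2")))
#' gd <- genotype_data(g, phenotype = c(0, 1, 1))
#' additive_coding(gd)
#' @export
genotype_data <- function(genotypes, phenotype, missing_code = "NN",
                          allele_map = NULL) {
  if (!is.matrix(genotypes) || !is.character(genotypes))
    stop("'genotypes' must be a character matrix")
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- sprintf("sample%d", seq_len(nrow(genotypes)))
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- sprintf("SNP%d", seq_len(ncol(genotypes)))
  if (anyDuplicated(rownames(genotypes)))
    stop("duplicated sample identifiers")
  if (anyDuplicated(colnames(genotypes)))
    stop("duplicated SNP identifiers")
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != nrow(genotypes))
    stop("phenotype length (", length(phenotype),
         ") does not match sample count (", nrow(genotypes), ")")
  if (length(phenotype) && !all(phenotype %in% c(0L, 1L)))
    stop("phenotype must be strictly binary 0/1")

  genotypes <- canonicalize_genotypes(genotypes, missing_code)
  validate_genotype_tokens(genotypes, missing_code)
  if (is.null(allele_map)) {
    allele_map <- infer_allele_map(genotypes, missing_code)
  } else {
    if (!is.matrix(allele_map) || nrow(allele_map) != 2 ||
        ncol(allele_map) != ncol(genotypes))
      stop("'allele_map' must be a 2 x n_snps matrix")
    rownames(allele_map) <- c("major", "minor")
    colnames(allele_map) <- colnames(genotypes)
  }

  structure(list(genotypes = genotypes,
                 phenotype = phenotype,
                 sample_ids = rownames(genotypes) %||% character(),
                 snp_ids = colnames(genotypes) %||% character(),
                 allele_map = allele_map,
                 missing_code = missing_code),
            class = "genotype_data")
}

# alphabetical canonical form for heterozygotes ("TC" -> "CT")
canonicalize_genotypes <- function(g, missing_code) {
  idx <- which(!is.na(g) & g != missing_code)
  if (length(idx)) {
    v <- g[idx]
    a1 <- substr(v, 1L, 1L); a2 <- substr(v, 2L, 2L)
    swap <- a1 > a2
    if (any(swap)) v[swap] <- paste0(a2[swap], a1[swap])
    g[idx] <- v
  }
  g
}

validate_genotype_tokens <- function(g, missing_code) {
  ok <- is.na(g) | g == missing_code |
    (nchar(g) == 2L &
       substr(g, 1L, 1L) %in% c("A", "C", "G", "T") &
       substr(g, 2L, 2L) %in% c("A", "C", "G", "T"))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("malformed genotype token '", g[bad[1], bad[2]], "' at sample '",
         rownames(g)[bad[1]], "', SNP '", colnames(g)[bad[2]], "'")
  }
  invisible(TRUE)
}

# major/minor per SNP by allele frequency; alphabetical tie-break
infer_allele_map <- function(g, missing_code) {
  am <- vapply(seq_len(ncol(g)), function(j) {
    v <- g[, j]
    v <- v[!is.na(v) & v != missing_code]
    if (!length(v)) return(c(NA_character_, NA_character_))
    alleles <- c(substr(v, 1L, 1L), substr(v, 2L, 2L))
    tab <- table(alleles)
    if (length(tab) > 2L)
      stop("SNP '", colnames(g)[j], "' has ", length(tab),
           " distinct alleles (at most 2 allowed)")
    nm <- names(sort(tab, decreasing = TRUE))
    # stable alphabetical tie-break at exactly equal frequency
    if (length(tab) == 2L && tab[[1]] == tab[[2]]) nm <- sort(names(tab))
    if (length(nm) == 1L) nm <- c(nm, NA_character_)
    nm[1:2]
  }, character(2))
  dimnames(am) <- list(c("major", "minor"), colnames(g))
  am
}

#' Additive 0/1/2 genotype coding
#'
#' Maps each genotype to the count of minor alleles it carries, using the
#' dataset's per-SNP (major, minor) allele assignment. Missing genotypes map
#' to \code{NA}.
#'
#' @param data a [genotype_data] object.
#' @return Integer matrix of the same shape as \code{data$genotypes}.
#' @export
additive_coding <- function(data) {
  stopifnot(inherits(data, "genotype_data"))
  g <- data$genotypes
  out <- matrix(NA_integer_, nrow(g), ncol(g), dimnames = dimnames(g))
  for (j in seq_len(ncol(g))) {
    minor <- data$allele_map["minor", j]
    v <- g[, j]
    known <- !is.na(v) & v != data$missing_code
    if (is.na(minor)) { out[known, j] <- 0L; next }
    cnt <- (substr(v, 1L, 1L) == minor) + (substr(v, 2L, 2L) == minor)
    out[known, j] <- as.integer(cnt[known])
  }
  out
}

#' Drop samples with any missing genotype
#'
#' The analysis modules require complete data; apply this first when the input
#' contains missing calls.
#'
#' @param data a [genotype_data] object.
#' @return A [genotype_data] object restricted to complete samples.
#' @export
drop_incomplete_samples <- function(data) {
  stopifnot(inherits(data, "genotype_data"))
  bad <- is.na(data$genotypes) | data$genotypes == data$missing_code
  keep <- rowSums(bad) == 0L
  subset_samples(data, keep)
}

subset_samples <- function(data, keep) {
  genotype_data(data$genotypes[keep, , drop = FALSE],
                data$phenotype[keep],
                missing_code = data$missing_code,
                allele_map = data$allele_map)
}

#' @export
print.genotype_data <- function(x, ...) {
  cat("genotype_data: ", length(x$sample_ids), " samples x ",
      length(x$snp_ids), " SNPs\n", sep = "")
  cat("  cases (phenotype = 1): ", sum(x$phenotype), ", controls: ",
      sum(x$phenotype == 0L), "\n", sep = "")
  miss <- sum(is.na(x$genotypes) | x$genotypes == x$missing_code)
  if (miss) cat("  missing genotype calls: ", miss, "\n", sep = "")
  invisible(x)
}

#' @export
summary.genotype_data <- function(object, ...) {
  ad <- additive_coding(object)
  maf <- colMeans(ad, na.rm = TRUE) / 2
  out <- list(n_samples = length(object$sample_ids),
              n_snps = length(object$snp_ids),
              n_cases = sum(object$phenotype),
              maf = maf)
  class(out) <- "summary.genotype_data"
  out
}

#' @export
print.summary.genotype_data <- function(x, ...) {
  cat("genotype_data: ", x$n_samples, " samples x ", x$n_snps, " SNPs; ",
      x$n_cases, " cases\n", sep = "")
  cat("minor allele frequency: ")
  print(summary(x$maf))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
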