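#' Read a case-control genotype dataset from delimited text
#'
#' Expects a header row; one column per SNP holding two-letter genotype calls
#' (or the missing code) plus one phenotype column of 0/1 labels. A column
#' named \code{sample_id} (if present) supplies sample identifiers.
#'
#' @param path file path (CSV by default; set \code{sep = "\t"} for TSV).
#' @param phenotype_column name of the phenotype column (default
#'   \code{"phenotype"}).
#' @param missing_code genotype token standing for a missing call.
#' @param sep field separator.
#' @return A [genotype_data] object.
#' @seealso [write_genotypes()], [read_plink_raw()]
#' @export
read_genotypes <- function(path, phenotype_column = "phenotype",
                           missing_code = "NN", sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  if (!phenotype_column %in% names(df))
    stop("phenotype column '", phenotype_column, "' not found in ", path)
  ids <- if ("sample_id" %in% names(df)) df[["sample_id"]] else
    paste0("sample", seq_len(nrow(df)))
  pheno <- suppressWarnings(as.integer(df[[phenotype_column]]))
  if (nrow(df) && (anyNA(pheno) || !all(pheno %in% c(0L, 1L))))
    stop("phenotype column must contain only 0/1 values")
  snp_cols <- setdiff(names(df), c(phenotype_column, "sample_id"))
  g <- as.matrix(df[, snp_cols, drop = FALSE])
  rownames(g) <- ids
  genotype_data(g, pheno, missing_code = missing_code)
}

#' Write a genotype dataset as delimited text
#'
#' Produces a file re-readable by [read_genotypes()] with identical content
#' (a sample_id column, one column per SNP, and a phenotype column).
#'
#' @param data a [genotype_data] object.
#' @param path output file path.
#' @param sep field separator.
#' @return Invisibly, \code{path}.
#' @export
write_genotypes <- function(data, path, sep = ",") {
  stopifnot(inherits(data, "genotype_data"))
  df <- data.frame(sample_id = data$sample_ids,
                   data$genotypes,
                   phenotype = data$phenotype,
                   check.names = FALSE, stringsAsFactors = FALSE)
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Read a PLINK .raw additive-coded export
#'
#' Parses the standard PLINK \code{--recode A} layout: six metadata columns
#' (FID IID PAT MAT SEX PHENOTYPE) followed by one \code{SNP_allele} column
#' per SNP with additive counts 0/1/2 or NA. PLINK phenotype coding 1/2 is
#' mapped to 0/1. The counted allele in the column suffix is taken as the
#' minor allele; since the original genotype letters are not recoverable from
#' a .raw file, genotype categories are reconstructed as major/minor pairs
#' (e.g. suffix \code{_T} with counted allele T and inferred partner gives
#' the categories used downstream).
#'
#' @param path file path to the .raw export (whitespace-delimited).
#' @param partner_alleles optional named character vector giving, per SNP, the
#'   non-counted (major) allele; defaults to a complement-letter convention
#'   when absent, which preserves additive codes exactly.
#' @return A [genotype_data] object whose additive coding equals the .raw
#'   counts.
#' @export
read_plink_raw <- function(path, partner_alleles = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(meta %in% names(df)))
    stop("not a PLINK .raw file: missing mandatory column(s) ",
         paste(setdiff(meta, names(df)), collapse = ", "))
  snp_cols <- setdiff(names(df), meta)
  ph_raw <- df$PHENOTYPE
  if (nrow(df) && !all(ph_raw %in% c(1, 2)))
    stop("PHENOTYPE must use PLINK 1/2 case-control coding")
  pheno <- as.integer(ph_raw == 2)

  snp_ids <- sub("_[ACGT]$", "", snp_cols)
  counted <- toupper(sub("^.*_", "", snp_cols))
  n <- nrow(df)
  g <- matrix(NA_character_, n, length(snp_cols),
              dimnames = list(df$IID, snp_ids))
  am <- matrix(NA_character_, 2, length(snp_cols),
               dimnames = list(c("major", "minor"), snp_ids))
  complement <- c(A = "G", C = "T", G = "A", T = "C")  # arbitrary partner
  for (j in seq_along(snp_cols)) {
    x <- df[[snp_cols[j]]]
    if (n && !all(is.na(x) | x %in% 0:2))
      stop("SNP column '", snp_cols[j], "' has genotype values outside 0/1/2/NA")
    minor <- counted[j]
    major <- if (!is.null(partner_alleles) && snp_ids[j] %in% names(partner_alleles))
      partner_alleles[[snp_ids[j]]] else complement[[minor]]
    cats <- c(paste0(major, major),
              paste0(sort(c(major, minor)), collapse = ""),
              paste0(minor, minor))
    g[, j] <- ifelse(is.na(x), NA_character_, cats[x + 1L])
    am[, j] <- c(major, minor)
  }
  genotype_data(g, pheno, allele_map = am)
}

#' Write a genotype dataset as a PLINK .raw additive export
#'
#' Companion writer for [read_plink_raw()]; mainly used to exercise
#' cross-format round trips on synthetic data.
#'
#' @param data a [genotype_data] object.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_plink_raw <- function(data, path) {
  stopifnot(inherits(data, "genotype_data"))
  ad <- additive_coding(data)
  minor <- data$allele_map["minor", ]
  minor[is.na(minor)] <- "A"
  cols <- as.data.frame(ad)
  names(cols) <- paste0(data$snp_ids, "_", minor)
  df <- data.frame(FID = data$sample_ids, IID = data$sample_ids,
                   PAT = 0L, MAT = 0L, SEX = 0L,
                   PHENOTYPE = data$phenotype + 1L,
                   cols, check.names = FALSE)
  utils::write.table(df, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
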