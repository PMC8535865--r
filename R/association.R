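#' 2x2 contingency table for an exposure grouping vs. outcome
#'
#' Cell layout follows the case-control convention used throughout the
#' package: \code{a} exposed controls, \code{b} exposed cases, \code{c}
#' unexposed controls, \code{d} unexposed cases.
#'
#' @param a,b,c,d non-negative integer counts.
#' @param exposure_label human-readable grouping, e.g.
#'   \code{"rs6487213=CC"} or \code{"rs6487213=CC and rs3785157=CC"}.
#' @return An object of class \code{"contingency_2x2"}.
#' @export
contingency_2x2 <- function(a, b, c, d, exposure_label = "exposed") {
  counts <- c(a = a, b = b, c = c, d = d)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("empty table: total count is zero")
  structure(list(a = as.integer(a), b = as.integer(b),
                 c = as.integer(c), d = as.integer(d),
                 exposure_label = exposure_label),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c(x$exposure_label, "others"),
                              c("control", "case")))
  print(m)
  invisible(x)
}

as_matrix_2x2 <- function(table) {
  matrix(c(table$a, table$b, table$c, table$d), 2, 2, byrow = TRUE)
}

#' Build a 2x2 table from a multilocus genotype grouping
#'
#' A sample is "exposed" when it carries the specified genotype at every SNP
#' of the grouping (all-of rule); all other samples are unexposed. Genotype
#' specifications are canonicalised, so \code{"TC"} and \code{"CT"} name the
#' same category. Each grouping entry may name a single genotype or a set of
#' categories (e.g. \code{c("CT", "TT")} for carriers).
#'
#' @param data a [genotype_data] object.
#' @param grouping named list (or named character vector) mapping SNP id to
#'   the exposed genotype category (or category set). An empty grouping makes
#'   every sample exposed.
#' @return A [contingency_2x2] with the grouping as exposure label.
#' @examples
#' sim <- make_epistasis_dataset(epistasis_sim_config(seed = 1))
#' build_table(sim, list(SNP4 = c("GT", "TT")))
#' @export
build_table <- function(data, grouping) {
  stopifnot(inherits(data, "genotype_data"))
  grouping <- as.list(grouping)
  if (length(grouping)) {
    if (is.null(names(grouping)) || any(!nzchar(names(grouping))))
      stop("grouping must be named by SNP id")
    unknown <- setdiff(names(grouping), data$snp_ids)
    if (length(unknown))
      stop("unknown SNP(s) in grouping: ", paste(unknown, collapse = ", "))
  }
  exposed <- rep(TRUE, length(data$sample_ids))
  for (snp in names(grouping)) {
    cats <- canonicalize_genotypes(matrix(as.character(grouping[[snp]])),
                                   data$missing_code)[, 1]
    observed <- unique(data$genotypes[, snp])
    bad <- setdiff(cats, c(observed, data$missing_code))
    # allow specifying unobserved-but-valid categories; reject malformed ones
    ok <- nchar(bad) == 2L & substr(bad, 1, 1) %in% c("A", "C", "G", "T") &
      substr(bad, 2, 2) %in% c("A", "C", "G", "T")
    if (length(bad) && !all(ok))
      stop("invalid genotype category '", bad[!ok][1], "' for SNP '", snp, "'")
    exposed <- exposed & data$genotypes[, snp] %in% cats
  }
  y <- data$phenotype
  lab <- if (length(grouping))
    paste(vapply(names(grouping), function(s)
      paste0(s, "=", paste(grouping[[s]], collapse = "/")), ""),
      collapse = " and ") else "all samples"
  contingency_2x2(sum(exposed & y == 0L), sum(exposed & y == 1L),
                  sum(!exposed & y == 0L), sum(!exposed & y == 1L),
                  exposure_label = lab)
}

#' Sample odds ratio of a 2x2 table
#'
#' Cross-product ratio \code{(b*c)/(a*d)} comparing the odds of being a case
#' among exposed vs. unexposed samples. With any zero cell the
#' Haldane-Anscombe correction (+0.5 to all cells) is applied and the result
#' is flagged via the \code{"haldane"} attribute.
#'
#' @param table a [contingency_2x2].
#' @return The odds ratio (numeric scalar; attribute \code{haldane} = TRUE
#'   when the correction was applied).
#' @export
odds_ratio <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  k <- c(table$a, table$b, table$c, table$d)
  if (all(k == 0)) stop("odds ratio undefined for an all-zero table")
  haldane <- any(k == 0)
  if (haldane) k <- k + 0.5
  structure((k[2] * k[3]) / (k[1] * k[4]), haldane = haldane)
}

#' Two-sided Fisher exact test
#'
#' Point-probability (minimum-likelihood) two-sided rule: the p-value sums the
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table. Backed by
#' \code{stats::fisher.test}.
#'
#' @param table a [contingency_2x2].
#' @return Two-sided p-value.
#' @export
fisher_exact_two_sided <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  stats::fisher.test(as_matrix_2x2(table))$p.value
}

#' Confidence interval for an odds ratio
#'
#' Three constructions are available: \describe{
#'   \item{wald}{\code{exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))}; with
#'     a zero cell the Haldane correction is applied and flagged.}
#'   \item{profile}{profile-likelihood interval from the logistic regression
#'     of case status on the exposure indicator (the construction that matches
#'     published genotype-association tables produced with \code{glm}).}
#'   \item{exact-conditional}{inversion of noncentral hypergeometric tail
#'     probabilities (\code{stats::fisher.test}).}}
#'
#' @param table a [contingency_2x2].
#' @param method one of \code{"wald"}, \code{"profile"},
#'   \code{"exact-conditional"}.
#' @param level coverage probability in (0, 1).
#' @return Numeric vector \code{c(low, high)}; attribute \code{haldane} set
#'   when the Wald correction was applied.
#' @export
or_confidence_interval <- function(table,
                                   method = c("profile", "wald",
                                              "exact-conditional"),
                                   level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  method <- match.arg(method)
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  k <- c(table$a, table$b, table$c, table$d)
  if (method == "wald") {
    haldane <- any(k == 0)
    if (haldane) k <- k + 0.5
    or <- (k[2] * k[3]) / (k[1] * k[4])
    z <- stats::qnorm(1 - (1 - level) / 2)
    se <- sqrt(sum(1 / k))
    ci <- exp(log(or) + c(-1, 1) * z * se)
    return(structure(ci, haldane = haldane))
  }
  if (method == "profile") {
    y <- rep(c(0L, 1L, 0L, 1L), k)
    x <- rep(c(1L, 1L, 0L, 0L), k)
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    ci <- suppressWarnings(suppressMessages(
      exp(stats::confint(fit, parm = "x", level = level))))
    return(as.numeric(ci))
  }
  ft <- stats::fisher.test(as_matrix_2x2(table), conf.level = level)
  # fisher.test orients its OR as a*d/(b*c); invert to our case-exposure odds
  sort(1 / ft$conf.int)
}

#' Wald test of association on the log odds-ratio scale
#'
#' The z-test of log(OR) against 0 with standard error
#' \code{sqrt(1/a + 1/b + 1/c + 1/d)}; equivalent to the logistic-regression
#' coefficient test of the exposure indicator. Haldane correction applied and
#' flagged with a zero cell.
#'
#' @param table a [contingency_2x2].
#' @return Two-sided p-value.
#' @export
wald_p_value <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  k <- c(table$a, table$b, table$c, table$d)
  if (any(k == 0)) k <- k + 0.5
  z <- log((k[2] * k[3]) / (k[1] * k[4])) / sqrt(sum(1 / k))
  2 * stats::pnorm(-abs(z))
}

#' Association summary for a genotype grouping
#'
#' Builds the 2x2 table for a grouping and reports the odds ratio, a
#' confidence interval, the two-sided Fisher exact p-value and the Wald
#' p-value in one classed record.
#'
#' @inheritParams build_table
#' @inheritParams or_confidence_interval
#' @return Object of class \code{"assoc_result"} with elements \code{table},
#'   \code{odds_ratio}, \code{ci_low}, \code{ci_high}, \code{ci_method},
#'   \code{p_fisher}, \code{p_wald}.
#' @examples
#' tab <- contingency_2x2(76, 20, 162, 13, "rs6487213=CC")
#' snp_association(table = tab)
#' @export
snp_association <- function(data = NULL, grouping = NULL, table = NULL,
                            method = "profile", level = 0.95) {
  if (is.null(table)) table <- build_table(data, grouping)
  ci <- or_confidence_interval(table, method = method, level = level)
  structure(list(table = table,
                 odds_ratio = as.numeric(odds_ratio(table)),
                 ci_low = ci[1], ci_high = ci[2], ci_method = method,
                 ci_level = level,
                 p_fisher = fisher_exact_two_sided(table),
                 p_wald = wald_p_value(table)),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, digits = 2, ...) {
  cat(x$table$exposure_label, ": OR = ",
      formatC(x$odds_ratio, format = "f", digits = digits),
      " (", round(100 * x$ci_level), "% CI ",
      formatC(x$ci_low, format = "f", digits = digits), "-",
      formatC(x$ci_high, format = "f", digits = digits),
      ", ", x$ci_method, "), Fisher p = ", signif(x$p_fisher, 3),
      ", Wald p = ", signif(x$p_wald, 3), "\n", sep = "")
  invisible(x)
}
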