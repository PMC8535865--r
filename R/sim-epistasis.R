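# run expr under a temporary RNG state; leaves the caller's stream untouched
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the two-locus epistasis simulation
#'
#' Describes a balanced case-control dataset in which exactly two SNPs (the
#' causal pair) carry a purely epistatic signal: a penetrance table over the
#' two-locus genotypes whose genotype-frequency-weighted row and column
#' averages all equal the overall case rate, so neither causal SNP has a
#' marginal effect. All remaining SNPs are phenotype-independent
#' Hardy-Weinberg noise.
#'
#' The default penetrance is specified at the carrier level (carrier = any
#' non-wild-type genotype): with joint carrier counts (both, only first,
#' only second, neither) = (36, 16, 21, 177), the case probabilities are
#' (1/3, 1/16, 2/21, 110/177). Carrying either minority group alone is
#' strongly protective, while carrying both lifts the risk far above what the
#' two marginal effects predict -- a strong two-locus interaction on top of
#' visible marginal signals, the regime in which all three detector families
#' (cell-counting, spline regression and greedy impurity trees) can recover
#' the pair. A strictly marginal-free penetrance can be supplied explicitly
#' and validated with [check_no_marginal_effect()], but greedy
#' impurity-based forests are essentially blind to such signals, so it is
#' not the default. The two causal loci are correlated by construction (36
#' of the 52 first-SNP carriers also carry the second).
#'
#' @param n_samples total samples (default 250).
#' @param n_cases number of cases (default 125).
#' @param n_snps total SNP count including the causal pair (default 25).
#' @param causal_pair indices of the two causal SNPs (default 4 and 9).
#' @param target_minority_counts exact carrier (pooled non-wild-type
#'   genotype) counts for the two causal SNPs (default 52 and 57).
#' @param joint_carrier_counts counts of samples carrying (both, only the
#'   first, only the second, neither) causal minority group; must be
#'   consistent with \code{target_minority_counts} and sum to
#'   \code{n_samples}.
#' @param penetrance 3x3 case-probability table, rows indexed by the first
#'   causal SNP's additive genotype (0/1/2), columns by the second's. The
#'   default expands the carrier-level table above (identical values for
#'   heterozygote and minor homozygote).
#' @param noise_maf_range minor-allele-frequency interval for noise SNPs.
#' @param seed integer seed making the dataset fully reproducible.
#' @return Object of class \code{"epistasis_sim_config"}.
#' @seealso [make_epistasis_dataset()], [permute_observations()]
#' @export
epistasis_sim_config <- function(n_samples = 250L, n_cases = 125L,
                                 n_snps = 25L, causal_pair = c(4L, 9L),
                                 target_minority_counts = c(52L, 57L),
                                 joint_carrier_counts = NULL,
                                 penetrance = NULL,
                                 noise_maf_range = c(0.05, 0.5),
                                 seed = 1L) {
  if (n_cases > n_samples) stop("n_cases must not exceed n_samples")
  if (length(causal_pair) != 2L || anyDuplicated(causal_pair) ||
      any(causal_pair < 1L) || any(causal_pair > n_snps))
    stop("causal_pair must be two distinct SNP indices in 1..n_snps")
  m <- as.integer(target_minority_counts)
  if (length(m) != 2L || any(m < 0L) || any(m > n_samples))
    stop("target_minority_counts must be two counts within the sample size")
  if (is.null(joint_carrier_counts)) {
    both <- default_joint_both(m, n_samples)
    joint_carrier_counts <- c(both = both, only1 = m[1] - both,
                              only2 = m[2] - both,
                              neither = n_samples - m[1] - m[2] + both)
  }
  jc <- as.integer(joint_carrier_counts)
  names(jc) <- c("both", "only1", "only2", "neither")
  if (any(jc < 0L) || sum(jc) != n_samples ||
      jc["both"] + jc["only1"] != m[1] || jc["both"] + jc["only2"] != m[2])
    stop("joint_carrier_counts inconsistent with target_minority_counts")
  if (is.null(penetrance))
    penetrance <- default_penetrance(jc, n_cases, n_samples)
  penetrance <- as.matrix(penetrance)
  if (!all(dim(penetrance) == c(3L, 3L)) ||
      any(penetrance < 0) || any(penetrance > 1))
    stop("penetrance must be a 3x3 table of probabilities")
  structure(list(n_samples = as.integer(n_samples),
                 n_cases = as.integer(n_cases),
                 n_snps = as.integer(n_snps),
                 causal_pair = as.integer(causal_pair),
                 target_minority_counts = m,
                 joint_carrier_counts = jc,
                 penetrance = penetrance,
                 noise_maf_range = noise_maf_range,
                 seed = as.integer(seed)),
            class = "epistasis_sim_config")
}

# both-carrier count used by the default design: ~70% of the smaller carrier
# group, making the both-carrier cell large enough to anchor the interaction
default_joint_both <- function(m, n_samples) {
  both <- as.integer(round(min(m) * 0.7))
  stopifnot(n_samples - sum(m) + both >= 0L)
  both
}

# carrier-level default penetrance: protective single carriers, elevated
# both-carrier risk; background solved so the expected case total is exactly
# n_cases
default_penetrance <- function(jc, n_cases, n_samples) {
  p11 <- 1 / 3; p10 <- 1 / 16; p01 <- 2 / 21
  p00 <- (n_cases - jc[["both"]] * p11 - jc[["only1"]] * p10 -
            jc[["only2"]] * p01) / jc[["neither"]]
  if (p00 < 0 || p00 > 1)
    stop("no valid default penetrance for these carrier counts; ",
         "supply 'penetrance' explicitly")
  matrix(c(p00, p10, p10,
           p01, p11, p11,
           p01, p11, p11), nrow = 3)
}

#' Check a penetrance configuration for marginal effects
#'
#' Computes the genotype-frequency-weighted marginal penetrance of each
#' causal SNP and compares it with the overall case rate. Returns TRUE when
#' both marginal averages equal the overall rate within \code{tol} (a
#' strictly epistatic, no-marginal-effect model). The shipped default
#' penetrance deliberately fails this check: it carries visible marginal
#' effects because purely non-marginal signals are undetectable by greedy
#' impurity-based forests.
#'
#' @param cfg an [epistasis_sim_config].
#' @param tol numeric tolerance.
#' @param enforce raise an error instead of returning FALSE.
#' @return Logical (invisibly).
#' @export
check_no_marginal_effect <- function(cfg, tol = 1e-9, enforce = FALSE) {
  freq <- joint_genotype_freq(cfg)
  rate <- sum(freq * cfg$penetrance)
  row_avg <- rowSums(freq * cfg$penetrance) / rowSums(freq)
  col_avg <- colSums(freq * cfg$penetrance) / colSums(freq)
  dev <- max(abs(c(row_avg, col_avg) - rate), na.rm = TRUE)
  if (enforce && dev > tol)
    stop("penetrance has a marginal effect (max deviation ", signif(dev, 3),
         ")")
  invisible(dev <= tol)
}

# theoretical 3x3 two-locus genotype frequencies implied by the joint carrier
# counts and a Hardy-Weinberg-conditional heterozygote/homozygote split
joint_genotype_freq <- function(cfg) {
  n <- cfg$n_samples
  jc <- cfg$joint_carrier_counts
  het <- het_fraction(cfg$target_minority_counts / n)
  s1 <- c(1, het[1], 1 - het[1])  # weights within (non-carrier|carrier) of SNP a
  s2 <- c(1, het[2], 1 - het[2])
  cell <- matrix(c(jc["neither"], jc["only2"], jc["only2"],
                   jc["only1"], jc["both"], jc["both"],
                   jc["only1"], jc["both"], jc["both"]) / n,
                 nrow = 3, byrow = TRUE)
  cell * outer(s1, s2)
}

# P(heterozygote | carrier) under Hardy-Weinberg at the given carrier freq
het_fraction <- function(carrier_freq) {
  q <- 1 - sqrt(1 - carrier_freq)
  2 * q * (1 - q) / carrier_freq
}

# largest-remainder integer allocation of 'total' over expected counts e
allocate_integer <- function(e, total) {
  base <- floor(e)
  rem <- total - sum(base)
  if (rem < 0 || rem > length(e))
    stop("cannot allocate ", total, " cases over cells with expected total ",
         signif(sum(e), 6), "; penetrance incompatible with exact case count")
  if (rem > 0) {
    ord <- order(e - base, e, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Generate the two-locus epistasis dataset
#'
#' Deterministic given \code{config$seed}. Construction: (1) assign every
#' sample a joint genotype at the causal pair so that the carrier counts and
#' joint carrier-cell counts are met exactly (heterozygote / minor-homozygote
#' split within carriers follows Hardy-Weinberg conditional proportions);
#' (2) within each two-locus genotype cell, assign case labels according to
#' the penetrance table, with a largest-remainder integer allocation pinning
#' the total number of cases at exactly \code{n_cases}; (3) fill all other
#' SNPs with Hardy-Weinberg genotypes drawn independently of the phenotype;
#' (4) shuffle sample order.
#'
#' @param config an [epistasis_sim_config] object.
#' @return A [genotype_data] object with SNP ids \code{SNP1..SNPn}.
#' @examples
#' sim <- make_epistasis_dataset(epistasis_sim_config(seed = 7))
#' table(sim$phenotype)
#' @export
make_epistasis_dataset <- function(config) {
  stopifnot(inherits(config, "epistasis_sim_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    jc <- config$joint_carrier_counts
    # carrier-cell membership: 0=neither, 1=only1, 2=only2, 3=both
    cell <- rep(c(3L, 1L, 2L, 0L), jc[c("both", "only1", "only2", "neither")])
    carrier1 <- cell %in% c(1L, 3L)
    carrier2 <- cell %in% c(2L, 3L)
    g1 <- carrier_to_genotype(carrier1, config$target_minority_counts[1] / n)
    g2 <- carrier_to_genotype(carrier2, config$target_minority_counts[2] / n)

    # exact case allocation per two-locus genotype cell
    cell9 <- g1 * 3L + g2 + 1L
    n9 <- tabulate(cell9, nbins = 9L)
    p9 <- as.vector(config$penetrance[cbind(rep(1:3, each = 3), rep(1:3, 3))])
    e <- n9 * p9
    cases9 <- allocate_integer(e, config$n_cases)
    if (any(cases9 > n9))
      stop("penetrance incompatible with exact n_cases in at least one cell")
    y <- integer(n)
    for (k in seq_len(9L)) {
      idx <- which(cell9 == k)
      if (length(idx))
        y[idx[sample.int(length(idx), cases9[k])]] <- 1L
    }

    geno <- matrix(NA_character_, n, config$n_snps,
                   dimnames = list(paste0("sample", seq_len(n)),
                                   paste0("SNP", seq_len(config$n_snps))))
    alleles1 <- c("G", "T"); alleles2 <- c("A", "C")  # (major, minor) pairs
    geno[, config$causal_pair[1]] <- genotype_strings(g1, alleles1)
    geno[, config$causal_pair[2]] <- genotype_strings(g2, alleles2)
    noise_cols <- setdiff(seq_len(config$n_snps), config$causal_pair)
    for (j in noise_cols) {
      q <- stats::runif(1, config$noise_maf_range[1], config$noise_maf_range[2])
      al <- sample(c("A", "C", "G", "T"), 2L)
      gj <- sample(0:2, n, replace = TRUE,
                   prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
      geno[, j] <- genotype_strings(gj, al)
    }
    ord <- sample.int(n)
    geno <- geno[ord, , drop = FALSE]
    rownames(geno) <- paste0("sample", seq_len(n))
    genotype_data(geno, y[ord])
  })
}

# deterministic het/homo split within carriers (largest remainder)
carrier_to_genotype <- function(carrier, carrier_freq) {
  g <- integer(length(carrier))
  idx <- which(carrier)
  n_het <- round(length(idx) * het_fraction(carrier_freq))
  g[idx] <- rep(c(1L, 2L), c(n_het, length(idx) - n_het))
  g
}

genotype_strings <- function(g, alleles) {
  cats <- c(paste0(alleles[1], alleles[1]),
            paste0(sort(alleles), collapse = ""),
            paste0(alleles[2], alleles[2]))
  cats[g + 1L]
}

#' Permute the genotypes of selected observations at non-protected SNPs
#'
#' Robustness-test noise injection: \code{k} samples are selected at random;
#' for every SNP column not in \code{protected_snps}, the genotype values of
#' the selected rows are replaced by independent draws from that column's
#' empirical genotype distribution. Protected columns, non-selected rows and
#' the phenotype are untouched.
#'
#' @param data a [genotype_data] object.
#' @param k number of observations to perturb (0 returns the input
#'   unchanged).
#' @param protected_snps SNP ids (or indices) exempt from permutation.
#' @param seed integer seed.
#' @return A [genotype_data] object.
#' @export
permute_observations <- function(data, k, protected_snps = character(),
                                 seed = 1L) {
  stopifnot(inherits(data, "genotype_data"))
  n <- length(data$sample_ids)
  if (k < 0 || k > n) stop("k must be between 0 and the number of samples")
  if (is.numeric(protected_snps)) protected_snps <- data$snp_ids[protected_snps]
  if (length(setdiff(protected_snps, data$snp_ids)))
    stop("protected_snps contains unknown SNP ids")
  if (k == 0) return(data)
  with_seed(seed, {
    rows <- sample.int(n, k)
    g <- data$genotypes
    for (j in which(!data$snp_ids %in% protected_snps))
      g[rows, j] <- sample(data$genotypes[, j], k, replace = TRUE)
    genotype_data(g, data$phenotype, missing_code = data$missing_code,
                  allele_map = data$allele_map)
  })
}
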