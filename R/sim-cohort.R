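#' Default anchor tables for the DILI-like cohort simulation
#'
#' The five individually anchored SNPs and three anchored genotype
#' combinations, with their exact 2x2 exposed counts per phenotype class
#' (control = acute, case = chronic). These are the contingency structures
#' the cohort generator reproduces exactly.
#'
#' @return A list with elements \code{singles} (data frame: snp, genotype,
#'   others, control_exposed, case_exposed) and \code{combos} (list of
#'   detector-tagged combinations with snps, genotypes and exposed counts).
#' @export
published_anchors <- function() {
  singles <- data.frame(
    snp = c("rs6487213", "rs5417", "rs7658048", "rs12453290", "rs3785157"),
    genotype = c("CC", "AA", "AG", "AA", "CC"),
    other1 = c("CT", "AC", "AA", "AG", "CT"),
    other2 = c("TT", "CC", "GG", "GG", "TT"),
    control_exposed = c(76L, 74L, 113L, 105L, 106L),
    case_exposed = c(20L, 19L, 18L, 19L, 18L),
    stringsAsFactors = FALSE)
  combos <- list(
    list(name = "MARS", snps = c("rs6487213", "rs3785157"),
         genotypes = c("CC", "CC"), control_exposed = 32L, case_exposed = 14L),
    list(name = "MDR", snps = c("rs5417", "rs7658048", "rs12453290"),
         genotypes = c("AA", "AG", "AA"), control_exposed = 12L,
         case_exposed = 6L),
    list(name = "RF-LR", snps = c("rs5417", "rs3785157"),
         genotypes = c("AA", "CC"), control_exposed = 36L, case_exposed = 10L))
  list(singles = singles, combos = combos)
}

#' Default background joint-cell constraints for the cohort simulation
#'
#' The published table pins the 2x2 margins of five SNPs and three detector
#' combinations, but not the joint distribution of the remaining anchored
#' SNP pairs. Left free, the joint cell of the two strongest single SNPs
#' (rs6487213 CC x rs5417 AA) lands near within-class independence, where
#' its odds ratio (about 4.9) would exceed the strongest anchored
#' interaction (4.74) and the synthetic cohort's top pairwise signal would
#' no longer be the published one. This default pins that cell at 9 chronic
#' (the minimum forced by the rs3785157 chronic margin) and 26 acute
#' (OR about 3.1), below every anchored interaction.
#'
#' @return A list of combination records in the [published_anchors()] format.
#' @export
default_background_cells <- function() {
  list(list(name = "background:rs6487213xrs5417",
            snps = c("rs6487213", "rs5417"), genotypes = c("CC", "AA"),
            control_exposed = 26L, case_exposed = 9L))
}

#' Configuration for the cohort simulation
#'
#' Describes an imbalanced case-control cohort (by default 33 chronic vs. 238
#' acute DILI patients over 872 SNPs) in which a handful of SNPs and genotype
#' combinations have exactly prescribed 2x2 contingency tables against the
#' phenotype, while every other SNP is phenotype-independent Hardy-Weinberg
#' noise.
#'
#' @param n_samples total samples (default 271).
#' @param n_cases number of cases (default 33).
#' @param n_snps total SNPs (default 872).
#' @param anchors anchor specification as produced by [published_anchors()].
#' @param background_cells additional exact joint-cell constraints (see
#'   [default_background_cells()]); set to \code{list()} to disable.
#' @param noise_maf_range minor-allele-frequency interval for noise SNPs.
#' @param seed integer seed.
#' @return Object of class \code{"cohort_sim_config"}.
#' @export
cohort_sim_config <- function(n_samples = 271L, n_cases = 33L,
                              n_snps = 872L, anchors = published_anchors(),
                              background_cells = default_background_cells(),
                              noise_maf_range = c(0.05, 0.5), seed = 1L) {
  if (n_cases > n_samples) stop("n_cases must not exceed n_samples")
  anchors$combos <- c(anchors$combos, background_cells)
  s <- anchors$singles
  if (nrow(s) > n_snps) stop("more anchored SNPs than n_snps")
  n_controls <- n_samples - n_cases
  if (any(s$control_exposed > n_controls) || any(s$case_exposed > n_cases))
    stop("anchor exposed counts exceed class sizes")
  for (cb in anchors$combos) {
    for (i in seq_along(cb$snps)) {
      k <- match(cb$snps[i], s$snp)
      if (is.na(k))
        stop("combination anchor uses un-anchored SNP '", cb$snps[i], "'")
      if (cb$genotypes[i] != s$genotype[k])
        stop("combination genotype for '", cb$snps[i],
             "' differs from its single-SNP anchor")
      if (cb$control_exposed > s$control_exposed[k] ||
          cb$case_exposed > s$case_exposed[k])
        stop("anchor tables inconsistent: combination '", cb$name,
             "' exposed count exceeds constituent '", cb$snps[i], "'")
    }
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_cases = as.integer(n_cases),
                 n_snps = as.integer(n_snps),
                 anchors = anchors,
                 noise_maf_range = noise_maf_range,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Generate the anchored case-control cohort
#'
#' Deterministic cell allocation: within each phenotype class, designated
#' members of each anchored combination are laid out first (with the minimal
#' combination overlaps forced by tight single-SNP margins), then each
#' anchored SNP's remaining exposed count is filled by a safety-checked
#' greedy pass that never creates an additional, undesignated member of any
#' anchored combination. Every anchor table is verified exactly before the
#' dataset is returned; an infeasible anchor set raises an error naming the
#' violated constraint. Unexposed genotypes at anchored SNPs and all noise
#' SNPs are drawn independently of the phenotype; sample order is shuffled
#' under the seed.
#'
#' @param config a [cohort_sim_config] object.
#' @return A [genotype_data] object.
#' @examples
#' cfg <- cohort_sim_config(n_snps = 20, seed = 1)
#' cohort <- make_cohort_dataset(cfg)
#' build_table(cohort, list(rs6487213 = "CC"))
#' @export
make_cohort_dataset <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  a <- config$anchors
  n_controls <- config$n_samples - config$n_cases
  with_seed(config$seed, {
    e_ctrl <- allocate_exposures(a, a$singles$control_exposed,
                                 vapply(a$combos, `[[`, 0L, "control_exposed"),
                                 n_controls, "control")
    e_case <- allocate_exposures(a, a$singles$case_exposed,
                                 vapply(a$combos, `[[`, 0L, "case_exposed"),
                                 config$n_cases, "case")
    E <- rbind(e_ctrl, e_case)
    y <- rep(c(0L, 1L), c(n_controls, config$n_cases))

    n <- config$n_samples
    n_noise <- config$n_snps - nrow(a$singles)
    snp_ids <- c(a$singles$snp,
                 if (n_noise > 0L) paste0("snp", seq_len(n_noise)))
    geno <- matrix(NA_character_, n, config$n_snps,
                   dimnames = list(NULL, snp_ids))
    for (j in seq_len(nrow(a$singles))) {
      exposed_freq <- (a$singles$control_exposed[j] + a$singles$case_exposed[j]) / n
      pr <- other_category_split(a$singles$genotype[j], exposed_freq)
      others <- sample(c(a$singles$other1[j], a$singles$other2[j]), n,
                       replace = TRUE, prob = pr)
      geno[, j] <- ifelse(E[, j], a$singles$genotype[j], others)
    }
    for (j in seq.int(nrow(a$singles) + 1L, length.out = config$n_snps - nrow(a$singles))) {
      q <- stats::runif(1, config$noise_maf_range[1], config$noise_maf_range[2])
      al <- sample(c("A", "C", "G", "T"), 2L)
      geno[, j] <- genotype_strings(
        sample(0:2, n, replace = TRUE, prob = c((1 - q)^2, 2 * q * (1 - q), q^2)),
        al)
    }
    ord <- sample.int(n)
    geno <- geno[ord, , drop = FALSE]
    rownames(geno) <- sprintf("patient%03d", seq_len(n))
    out <- genotype_data(geno, y[ord])
    verify_anchors(out, config)
    out
  })
}

# plausible split of the two non-exposed categories (cosmetic realism only):
# Hardy-Weinberg conditional proportions at the allele frequency implied by
# the exposed-genotype frequency
other_category_split <- function(exposed_genotype, exposed_freq) {
  hom <- substr(exposed_genotype, 1, 1) == substr(exposed_genotype, 2, 2)
  if (hom) {
    p <- sqrt(max(exposed_freq, 1e-6))
    q <- 1 - p
    c(2 * p * q, q^2) / (2 * p * q + q^2)  # (heterozygote, opposite homozygote)
  } else {
    r <- suppressWarnings(sqrt(max(0, 1 - 2 * exposed_freq)))
    p <- (1 + r) / 2
    c(p^2, (1 - p)^2) / (p^2 + (1 - p)^2)
  }
}

# ---- exact exposure allocation within one phenotype class ----------------

# margins: exposed count per anchored SNP; demands: exposed count per combo.
# Returns an n_class x n_anchored logical matrix meeting every count exactly.
allocate_exposures <- function(anchors, margins, demands, n_class, class_label) {
  s <- anchors$singles
  n_snp <- nrow(s)
  combos <- anchors$combos
  combo_idx <- lapply(combos, function(cb) match(cb$snps, s$snp))

  # groups: designated membership patterns (set of combos) with counts;
  # start disjoint, then merge to relieve over-demanded SNP margins
  groups <- lapply(seq_along(combos), function(i)
    list(members = i, count = demands[i]))
  repeat {
    demand_j <- snp_demand(groups, combo_idx, n_snp)
    over <- which(demand_j > margins)
    if (!length(over)) break
    j <- over[1]
    merged <- merge_one(groups, combo_idx, j, combos)
    if (is.null(merged))
      stop("infeasible anchor set (", class_label, " class): SNP '",
           s$snp[j], "' needs ", demand_j[j],
           " exposed samples for its combinations but its margin is ",
           margins[j])
    groups <- merged
  }

  counts <- vapply(groups, `[[`, 0, "count")
  if (sum(counts) > n_class)
    stop("infeasible anchor set (", class_label,
         " class): designated combination members (", sum(counts),
         ") exceed class size ", n_class)
  E <- matrix(FALSE, n_class, n_snp)
  designated <- matrix(FALSE, n_class, length(combos))
  row <- 0L
  for (g in groups) {
    if (g$count == 0L) next
    cols <- unique(unlist(combo_idx[g$members]))
    idx <- row + seq_len(g$count)
    E[idx, cols] <- TRUE
    designated[idx, g$members] <- TRUE
    row <- row + g$count
  }

  # fill remaining per-SNP exposed counts without creating undesignated
  # combination members; sample order is randomised so that anchored SNPs
  # carry no joint structure beyond the anchors themselves (a few random
  # restarts, then the deterministic order as a feasibility fallback)
  for (attempt in 1:6) {
    orders <- lapply(seq_len(n_snp), function(j)
      if (attempt < 6L) sample.int(n_class) else seq_len(n_class))
    res <- fill_deficits(E, designated, margins, combo_idx, orders)
    if (!is.null(res)) return(res)
  }
  stop("infeasible anchor set (", class_label, " class): cannot place the ",
       "remaining exposed samples without breaking a combination anchor")
}

fill_deficits <- function(E, designated, margins, combo_idx, orders) {
  n_snp <- length(margins)
  for (j in seq_len(n_snp)) {
    deficit <- margins[j] - sum(E[, j])
    if (deficit < 0) return(NULL)
    for (i in orders[[j]]) {
      if (deficit == 0L) break
      if (!E[i, j] && safe_to_expose(E, designated, i, j, combo_idx)) {
        E[i, j] <- TRUE
        deficit <- deficit - 1L
      }
    }
    if (deficit > 0L) return(NULL)
  }
  E
}

snp_demand <- function(groups, combo_idx, n_snp) {
  d <- integer(n_snp)
  for (g in groups) {
    cols <- unique(unlist(combo_idx[g$members]))
    d[cols] <- d[cols] + g$count
  }
  d
}

# merge one sample from two groups that both expose SNP j. If the union
# pattern swallows a further combination, that combination's remaining count
# is decremented too (the merged sample becomes a designated member of it);
# the merge is rejected when a swallowed combination has no count left.
merge_one <- function(groups, combo_idx, j, combos) {
  touching <- which(vapply(groups, function(g)
    g$count > 0L && j %in% unlist(combo_idx[g$members]), TRUE))
  if (length(touching) < 2L) return(NULL)
  for (g1 in touching) for (g2 in touching) {
    if (g1 >= g2) next
    members <- sort(unique(c(groups[[g1]]$members, groups[[g2]]$members)))
    cols <- unique(unlist(combo_idx[members]))
    swallowed <- setdiff(which(vapply(seq_along(combos), function(k)
      all(combo_idx[[k]] %in% cols), TRUE)), members)
    new_groups <- groups
    new_groups[[g1]]$count <- new_groups[[g1]]$count - 1L
    new_groups[[g2]]$count <- new_groups[[g2]]$count - 1L
    ok <- TRUE
    for (k in swallowed) {
      donor <- which(vapply(new_groups, function(g)
        identical(g$members, k) && g$count > 0L, TRUE))
      if (!length(donor)) { ok <- FALSE; break }
      new_groups[[donor[1]]]$count <- new_groups[[donor[1]]]$count - 1L
    }
    if (!ok) next
    members <- sort(unique(c(members, swallowed)))
    new_groups[[length(new_groups) + 1L]] <- list(members = members,
                                                  count = 1L)
    return(Filter(function(g) g$count > 0L, new_groups))
  }
  NULL
}

safe_to_expose <- function(E, designated, i, j, combo_idx) {
  for (k in seq_along(combo_idx)) {
    cols <- combo_idx[[k]]
    if (j %in% cols && !designated[i, k] &&
        all(E[i, setdiff(cols, j)]))
      return(FALSE)
  }
  TRUE
}

# exact post-construction check of every anchor table
verify_anchors <- function(data, config) {
  a <- config$anchors
  n_controls <- config$n_samples - config$n_cases
  for (j in seq_len(nrow(a$singles))) {
    tab <- build_table(data, stats::setNames(list(a$singles$genotype[j]),
                                             a$singles$snp[j]))
    if (tab$a != a$singles$control_exposed[j] ||
        tab$b != a$singles$case_exposed[j])
      stop("anchor verification failed for SNP '", a$singles$snp[j], "': got (",
           tab$a, ", ", tab$b, "), expected (",
           a$singles$control_exposed[j], ", ", a$singles$case_exposed[j], ")")
  }
  for (cb in a$combos) {
    tab <- build_table(data, stats::setNames(as.list(cb$genotypes), cb$snps))
    if (tab$a != cb$control_exposed || tab$b != cb$case_exposed)
      stop("anchor verification failed for combination '", cb$name,
           "': got (", tab$a, ", ", tab$b, "), expected (",
           cb$control_exposed, ", ", cb$case_exposed, ")")
  }
  if (sum(data$phenotype) != config$n_cases)
    stop("case total mismatch")
  invisible(TRUE)
}
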