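#' Random-Forest variable-importance ranking of SNPs
#'
#' Grows a classification forest on the additively coded genotypes (each
#' tree on a bootstrap sample and a random subset of SNP predictors;
#' majority voting) and ranks SNPs by mean decrease in Gini impurity.
#'
#' @param data a [genotype_data] object with complete genotypes and both
#'   phenotype classes present.
#' @param n_trees number of trees (default 500).
#' @param seed integer seed; the ranking is reproducible given the seed.
#' @return Object of class \code{"importance_ranking"}: data frame of
#'   \code{snp} and \code{importance} sorted non-increasing, with
#'   \code{n_trees} and \code{seed} attributes.
#' @export
rf_rank <- function(data, n_trees = 500L, seed = 1L) {
  stopifnot(inherits(data, "genotype_data"))
  if (n_trees < 1L) stop("n_trees must be >= 1")
  y <- data$phenotype
  if (length(unique(y)) < 2L) stop("phenotype has a single class")
  x <- additive_coding(data)
  if (anyNA(x))
    stop("missing genotypes present; apply drop_incomplete_samples() first")
  fit <- with_seed(seed,
                   randomForest::randomForest(x = x, y = factor(y),
                                              ntree = n_trees,
                                              importance = FALSE))
  imp <- fit$importance[, "MeanDecreaseGini"]
  ord <- order(-imp, data$snp_ids)
  out <- data.frame(snp = data$snp_ids[ord], importance = unname(imp[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "n_trees") <- n_trees
  attr(out, "seed") <- seed
  class(out) <- c("importance_ranking", class(out))
  out
}

#' Logistic-regression interaction scan over top-ranked SNPs
#'
#' Fits \code{logit P(Y=1) = b0 + b1*A + b2*B + b3*A*B} (additive genotype
#' coding) for every pair among \code{top_snps} by maximum likelihood, and
#' returns the pair with the smallest Wald p-value for the interaction
#' coefficient \code{b3} when it is below \code{alpha}; otherwise
#' \code{NULL}. Pairs whose likelihood does not converge (separation) are
#' skipped with a warning.
#'
#' @param data a [genotype_data] object.
#' @param top_snps character vector of SNP ids (at least 2), e.g. the head
#'   of an [rf_rank()] ranking.
#' @param alpha significance level for the interaction term (default 0.05;
#'   no multiplicity correction across pairs).
#' @return \code{NULL}, or a list of class \code{"lr_interaction"} with
#'   \code{snp_pair}, \code{coefficients} (b0, b1, b2, b3),
#'   \code{interaction_p} and \code{all_pairs} (the full scan table).
#' @export
lr_interaction_scan <- function(data, top_snps, alpha = 0.05) {
  stopifnot(inherits(data, "genotype_data"))
  top_snps <- as.character(top_snps)
  if (length(top_snps) < 2L) stop("need at least 2 SNPs to scan")
  if (length(setdiff(top_snps, data$snp_ids)))
    stop("unknown SNP id(s) in top_snps")
  x <- additive_coding(data)[, top_snps, drop = FALSE]
  y <- data$phenotype
  pairs <- utils::combn(top_snps, 2L)
  rows <- vector("list", ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    A <- x[, pairs[1, i]]; B <- x[, pairs[2, i]]
    fit <- suppressWarnings(stats::glm(y ~ A * B, family = stats::binomial()))
    sm <- summary(fit)$coefficients
    ok <- fit$converged && "A:B" %in% rownames(sm) &&
      !is.na(sm["A:B", "Pr(>|z|)"]) && abs(stats::coef(fit)["A:B"]) < 15
    if (!ok) {
      warning("pair (", pairs[1, i], ", ", pairs[2, i],
              ") skipped: non-converging or separated logistic fit")
      next
    }
    rows[[i]] <- data.frame(snp_a = pairs[1, i], snp_b = pairs[2, i],
                            b0 = stats::coef(fit)[["(Intercept)"]],
                            b1 = stats::coef(fit)[["A"]],
                            b2 = stats::coef(fit)[["B"]],
                            b3 = stats::coef(fit)[["A:B"]],
                            interaction_p = sm["A:B", "Pr(>|z|)"],
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || !nrow(tab)) return(NULL)
  tab <- tab[order(tab$interaction_p, tab$snp_a, tab$snp_b), ]
  best <- tab[1, ]
  if (best$interaction_p >= alpha) return(NULL)
  structure(list(snp_pair = c(best$snp_a, best$snp_b),
                 coefficients = c(b0 = best$b0, b1 = best$b1,
                                  b2 = best$b2, b3 = best$b3),
                 interaction_p = best$interaction_p,
                 alpha = alpha, all_pairs = tab),
            class = "lr_interaction")
}

#' @export
print.lr_interaction <- function(x, ...) {
  cat("logistic interaction: ", x$snp_pair[1], " x ", x$snp_pair[2],
      ", b3 = ", signif(x$coefficients[["b3"]], 4),
      ", p = ", signif(x$interaction_p, 3), "\n", sep = "")
  invisible(x)
}

#' Random Forest + logistic regression interaction detector
#'
#' Convenience wrapper chaining [rf_rank()] and [lr_interaction_scan()] over
#' the \code{top_k} highest-importance SNPs.
#'
#' @inheritParams rf_rank
#' @param top_k number of top-ranked SNPs carried into the scan (default 5).
#' @param alpha significance level for the interaction term.
#' @return As [lr_interaction_scan()], with the ranking attached as
#'   \code{$ranking}.
#' @export
rf_lr_detect <- function(data, n_trees = 500L, top_k = 5L, alpha = 0.05,
                         seed = 1L) {
  rk <- rf_rank(data, n_trees = n_trees, seed = seed)
  res <- lr_interaction_scan(data, rk$snp[seq_len(min(top_k, nrow(rk)))],
                             alpha = alpha)
  if (!is.null(res)) res$ranking <- rk
  res
}
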