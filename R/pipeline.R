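#' MARS interaction detector
#'
#' Fits [mars_fit()] and returns at most one interaction candidate: among the
#' pruned model's degree-2+ SNP sets, the one whose high-risk genotype cell
#' has the strongest association with the phenotype (smallest Fisher exact
#' p). Returns \code{NULL} when the model has no interaction terms.
#'
#' @param data a [genotype_data] object.
#' @param ... passed to [mars_fit()].
#' @return A candidate list (detector, snps, risk_combination, association,
#'   fit) or \code{NULL}.
#' @export
mars_detect <- function(data, ...) {
  fit <- mars_fit(data, ...)
  ints <- extract_interactions(fit)
  if (!length(ints)) return(NULL)
  assoc <- lapply(ints, function(it)
    snp_association(data, as.list(it$risk_combination)))
  best <- which.min(vapply(assoc, `[[`, 0, "p_fisher"))
  list(detector = "MARS", snps = ints[[best]]$snps,
       risk_combination = ints[[best]]$risk_combination,
       association = assoc[[best]], fit = fit)
}

#' MDR interaction detector
#'
#' Runs [mdr_fit()] and returns the final model as an interaction candidate
#' (the best order >= 2 winner when the overall final model is a single
#' SNP). The high-risk genotype combination is the observed high-risk cell
#' with the largest odds ratio against all other samples.
#'
#' @param data a [genotype_data] object.
#' @param max_order,n_folds,seed,prefilter_top passed to [mdr_fit()];
#'   \code{prefilter_top} defaults to 20 when the exhaustive search would be
#'   too large.
#' @param ... passed to [mdr_fit()].
#' @return A candidate list or \code{NULL}.
#' @export
mdr_detect <- function(data, max_order = 3L, n_folds = 10L, seed = 1L,
                       prefilter_top = NULL, ...) {
  if (is.null(prefilter_top)) {
    n_eval <- sum(choose(length(data$snp_ids), seq_len(max_order)))
    if (n_eval > 5e6) prefilter_top <- 20L
  }
  fit <- mdr_fit(data, max_order = max_order, n_folds = n_folds, seed = seed,
                 prefilter_top = prefilter_top, ...)
  model <- fit$final
  if (model$order < 2L) {
    higher <- fit$per_order[vapply(fit$per_order, `[[`, 0L, "order") >= 2L]
    if (!length(higher)) return(NULL)
    model <- higher[[which.min(vapply(higher, `[[`, 0, "test_error"))]]
  }
  cells <- label_cells(data, model$snp_subset)
  high <- cells[cells$label == "high" & !cells$unobserved, , drop = FALSE]
  if (!nrow(high)) return(NULL)
  # stability floor: ignore very small cells when larger ones exist
  big <- high$cases + high$controls >= 5L
  if (any(big)) high <- high[big, , drop = FALSE]
  ors <- vapply(seq_len(nrow(high)), function(i) {
    tab <- build_table(data, as.list(unlist(high[i, model$snp_subset])))
    as.numeric(odds_ratio(tab))
  }, 0)
  combo <- unlist(high[which.max(ors), model$snp_subset])
  assoc <- snp_association(data, as.list(combo))
  list(detector = "MDR", snps = model$snp_subset,
       risk_combination = combo, association = assoc, fit = fit)
}

#' Random Forest + logistic regression detector (pipeline wrapper)
#'
#' Runs [rf_lr_detect()] and, when a significant interaction pair is found,
#' reports as the high-risk combination the observed two-locus genotype cell
#' maximising the fitted log-odds \code{b1*A + b2*B + b3*A*B}.
#'
#' @param data a [genotype_data] object.
#' @param ... passed to [rf_lr_detect()].
#' @return A candidate list or \code{NULL}.
#' @export
rflr_detect <- function(data, ...) {
  res <- rf_lr_detect(data, ...)
  if (is.null(res)) return(NULL)
  ad <- additive_coding(data)[, res$snp_pair, drop = FALSE]
  cells <- unique(ad)
  b <- res$coefficients
  lo <- b[["b1"]] * cells[, 1] + b[["b2"]] * cells[, 2] +
    b[["b3"]] * cells[, 1] * cells[, 2]
  top <- cells[which.max(lo), ]
  combo <- vapply(seq_along(res$snp_pair), function(i) {
    snp <- res$snp_pair[i]
    unique(data$genotypes[additive_coding(data)[, snp] == top[i], snp])[1]
  }, "")
  names(combo) <- res$snp_pair
  assoc <- snp_association(data, as.list(combo))
  list(detector = "RF-LR", snps = res$snp_pair, risk_combination = combo,
       association = assoc, fit = res)
}

#' Run the three interaction detectors
#'
#' Applies MARS, MDR and RF-LR to the dataset; each detector contributes at
#' most one [InteractionCandidate]-style record. A failing detector is
#' dropped with a warning and the pipeline continues.
#'
#' @param data a [genotype_data] object.
#' @param seed master seed; detector-specific seeds are derived at fixed
#'   offsets.
#' @param detectors character subset of \code{c("MARS", "MDR", "RF-LR")}.
#' @param mars_args,mdr_args,rf_args named argument lists forwarded to the
#'   respective detectors.
#' @return List of candidate records (possibly empty).
#' @export
run_detectors <- function(data, seed = 1L,
                          detectors = c("MARS", "MDR", "RF-LR"),
                          mars_args = list(), mdr_args = list(),
                          rf_args = list()) {
  out <- list()
  try_det <- function(label, expr) {
    res <- tryCatch(expr, error = function(e) {
      warning(label, " detector failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) out[[length(out) + 1L]] <<- res
  }
  if ("MARS" %in% detectors)
    try_det("MARS", do.call(mars_detect, c(list(data), mars_args)))
  if ("MDR" %in% detectors)
    try_det("MDR", do.call(mdr_detect,
                           c(list(data, seed = seed + 101L), mdr_args)))
  if ("RF-LR" %in% detectors)
    try_det("RF-LR", do.call(rflr_detect,
                             c(list(data, seed = seed + 202L), rf_args)))
  out
}

#' Keep only interactions that beat their constituent SNPs
#'
#' A candidate survives when its combined-genotype odds ratio strictly
#' exceeds the marginal odds ratio of every constituent SNP, where each
#' SNP's marginal grouping is its highest-odds-ratio single-genotype
#' exposure (the per-SNP rows of a published association table). P-values
#' are reported but play no part in the filter.
#'
#' @param candidates list of detector candidates ([run_detectors()]).
#' @param data the [genotype_data] the candidates were detected on.
#' @return The surviving candidates, each annotated with its
#'   \code{marginals} (per-SNP grouping, OR) and \code{kept} flag; dropped
#'   candidates are returned in the \code{"dropped"} attribute.
#' @export
select_improved <- function(candidates, data) {
  kept <- list(); dropped <- list()
  for (cand in candidates) {
    marg <- lapply(cand$snps, function(s) best_marginal_grouping(data, s))
    names(marg) <- cand$snps
    cand$marginals <- marg
    or_comb <- cand$association$odds_ratio
    cand$kept <- all(or_comb > vapply(marg, `[[`, 0, "odds_ratio"))
    if (cand$kept) kept[[length(kept) + 1L]] <- cand
    else dropped[[length(dropped) + 1L]] <- cand
  }
  structure(kept, dropped = dropped)
}

# the single-genotype grouping of a SNP with the largest odds ratio
best_marginal_grouping <- function(data, snp) {
  cats <- sort(unique(data$genotypes[, snp]))
  tabs <- lapply(cats, function(g)
    build_table(data, stats::setNames(list(g), snp)))
  ors <- vapply(tabs, function(t) as.numeric(odds_ratio(t)), 0)
  i <- which.max(ors)
  list(snp = snp, genotype = cats[i], odds_ratio = ors[i], table = tabs[[i]])
}

#' Pool the SNPs of the selected interactions
#'
#' Union of the candidates' SNP sets, de-duplicated, in detector order then
#' lexicographic within each candidate.
#'
#' @param selected list of candidates (e.g. from [select_improved()]).
#' @return Character vector of SNP ids (possibly empty).
#' @export
pool_snps <- function(selected) {
  out <- character()
  for (cand in selected) out <- c(out, sort(cand$snps))
  unique(out)
}

#' Fit a CART risk tree on pooled SNPs
#'
#' CART with Gini impurity on categorical genotype predictors, grown under a
#' minimum leaf size and complexity parameter; class priors are empirical
#' and the positive class is chronic (phenotype 1).
#'
#' @param data a [genotype_data] object.
#' @param features SNP ids used as predictors (non-empty).
#' @param min_leaf minimum samples per leaf (default 3).
#' @param cp complexity parameter (default 0.01).
#' @return An \code{rpart} object.
#' @export
fit_risk_tree <- function(data, features, min_leaf = 3L, cp = 0.01) {
  stopifnot(inherits(data, "genotype_data"))
  if (!length(features)) stop("'features' must name at least one SNP")
  df <- tree_frame(data, features)
  rpart::rpart(phenotype ~ ., data = df, method = "class",
               parms = list(split = "gini"),
               control = rpart::rpart.control(minbucket = min_leaf,
                                              minsplit = 2L * min_leaf,
                                              cp = cp, xval = 0))
}

tree_frame <- function(data, features) {
  df <- as.data.frame(data$genotypes[, features, drop = FALSE],
                      stringsAsFactors = TRUE)
  df[] <- lapply(df, factor)
  df$phenotype <- factor(data$phenotype, levels = c(0, 1),
                         labels = c("acute", "chronic"))
  df
}

#' Classification metrics from a pooled confusion matrix
#'
#' @param tp,fn,tn,fp confusion counts with chronic (phenotype 1) as the
#'   positive class.
#' @return Object of class \code{"cv_metrics"}: sensitivity, specificity,
#'   accuracy and balanced accuracy = (sensitivity + specificity) / 2.
#' @export
cv_metrics <- function(tp, fn, tn, fp) {
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  structure(list(sensitivity = sens, specificity = spec,
                 accuracy = (tp + tn) / (tp + fn + tn + fp),
                 balanced_accuracy = (sens + spec) / 2,
                 confusion = c(tp = tp, fn = fn, tn = tn, fp = fp)),
            class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf(paste0("sensitivity %.1f%%, specificity %.1f%%, accuracy ",
                     "%.1f%%, balanced accuracy %.1f%%\n"),
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy,
              100 * x$balanced_accuracy))
  invisible(x)
}

#' Stratified cross-validation of the CART risk tree
#'
#' Folds preserve the class proportions; the tree is refit on each training
#' fold and confusion counts are accumulated over the held-out folds, giving
#' pooled sensitivity, specificity, accuracy and balanced accuracy (chronic
#' = positive class).
#'
#' @inheritParams fit_risk_tree
#' @param n_folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @return A [cv_metrics] object.
#' @export
stratified_cv_tree <- function(data, features, n_folds = 5L, seed = 1L,
                               min_leaf = 3L, cp = 0.01) {
  y <- data$phenotype
  if (min(table(y)) < n_folds)
    stop("a phenotype class has fewer members than folds; cannot stratify")
  foldid <- stratified_folds(y, n_folds, seed)
  df <- tree_frame(data, features)
  tp <- fn <- tn <- fp <- 0L
  for (f in seq_len(n_folds)) {
    tr <- df[foldid != f, , drop = FALSE]
    te <- df[foldid == f, , drop = FALSE]
    fit <- rpart::rpart(phenotype ~ ., data = tr, method = "class",
                        parms = list(split = "gini"),
                        control = rpart::rpart.control(minbucket = min_leaf,
                                                       minsplit = 2L * min_leaf,
                                                       cp = cp, xval = 0))
    pred <- predict(fit, te, type = "class")
    tp <- tp + sum(pred == "chronic" & te$phenotype == "chronic")
    fn <- fn + sum(pred == "acute" & te$phenotype == "chronic")
    tn <- tn + sum(pred == "acute" & te$phenotype == "acute")
    fp <- fp + sum(pred == "chronic" & te$phenotype == "acute")
  }
  cv_metrics(tp, fn, tn, fp)
}

#' End-to-end SNP-interaction risk pipeline
#'
#' Orchestrates the full workflow: run the MARS, MDR and RF-LR detectors,
#' keep only interactions whose combined-genotype odds ratio beats every
#' constituent SNP's marginal odds ratio, pool the surviving SNPs, fit a
#' CART decision tree on them and evaluate it by stratified cross-validation.
#'
#' @param data a [genotype_data] object.
#' @param seed master seed controlling every stochastic step (detector
#'   seeds and CV fold assignments are derived at fixed offsets).
#' @param detectors which detectors to run.
#' @param cv_folds folds for the final tree evaluation (default 5).
#' @param min_leaf,cp CART growth parameters.
#' @param mars_args,mdr_args,rf_args forwarded to the detectors.
#' @return Object of class \code{"dili_pipeline"} with elements
#'   \code{candidates}, \code{selected}, \code{dropped}, \code{pooled_snps},
#'   \code{tree}, \code{cv} and \code{seed}.
#' @examples
#' \donttest{
#' cohort <- make_cohort_dataset(cohort_sim_config(n_snps = 30, seed = 1))
#' res <- dili_pipeline(cohort, seed = 1)
#' print(res)
#' }
#' @export
dili_pipeline <- function(data, seed = 1L,
                          detectors = c("MARS", "MDR", "RF-LR"),
                          cv_folds = 5L, min_leaf = 3L, cp = 0.01,
                          mars_args = list(), mdr_args = list(),
                          rf_args = list()) {
  candidates <- run_detectors(data, seed = seed, detectors = detectors,
                              mars_args = mars_args, mdr_args = mdr_args,
                              rf_args = rf_args)
  selected <- select_improved(candidates, data)
  pooled <- pool_snps(selected)
  tree <- NULL; cv <- NULL
  if (length(pooled)) {
    tree <- fit_risk_tree(data, pooled, min_leaf = min_leaf, cp = cp)
    cv <- stratified_cv_tree(data, pooled, n_folds = cv_folds,
                             seed = seed + 303L, min_leaf = min_leaf,
                             cp = cp)
  }
  structure(list(candidates = candidates, selected = selected,
                 dropped = attr(selected, "dropped"),
                 pooled_snps = pooled, tree = tree, cv = cv, seed = seed),
            class = "dili_pipeline")
}

#' @export
print.dili_pipeline <- function(x, ...) {
  cat("SNP-SNP interaction pipeline (seed ", x$seed, ")\n", sep = "")
  show_cand <- function(cand, verdict) {
    cat("  [", cand$detector, "] {",
        paste(cand$snps, collapse = " + "), "} cell ",
        paste(names(cand$risk_combination), cand$risk_combination,
              sep = "=", collapse = ", "),
        ": OR ", formatC(cand$association$odds_ratio, format = "f",
                         digits = 2),
        " (Fisher p ", signif(cand$association$p_fisher, 2), ") -> ",
        verdict, "\n", sep = "")
  }
  for (cand in x$selected) show_cand(cand, "kept")
  for (cand in x$dropped)
    show_cand(cand, paste0("dropped (marginal OR ",
                           paste(formatC(vapply(cand$marginals, `[[`, 0,
                                                "odds_ratio"),
                                         format = "f", digits = 2),
                                 collapse = "/"), ")"))
  if (!length(x$candidates)) cat("  no detector produced a candidate\n")
  cat("pooled SNPs: ",
      if (length(x$pooled_snps)) paste(x$pooled_snps, collapse = ", ")
      else "(none)", "\n", sep = "")
  if (!is.null(x$cv)) { cat("cross-validated tree: "); print(x$cv) }
  invisible(x)
}

#' @export
summary.dili_pipeline <- function(object, ...) {
  print(object)
  if (!is.null(object$tree)) {
    cat("\ndecision tree:\n")
    print(object$tree)
  }
  invisible(object)
}
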