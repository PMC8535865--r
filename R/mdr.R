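#' Label multilocus genotype cells as high- or low-risk
#'
#' The core MDR reduction: samples are cross-classified by their joint
#' genotype over a SNP subset, and each cell is labelled high-risk when its
#' case/control ratio is at least the threshold \code{T} (ties go to
#' high-risk). Cells with cases but no controls are high-risk; cells with no
#' samples are labelled low-risk and flagged unobserved.
#'
#' @param data a [genotype_data] object (complete genotypes required).
#' @param snp_subset character vector of SNP ids (or integer indices).
#' @param threshold case/control ratio threshold \code{T}; defaults to the
#'   dataset's overall case/control ratio.
#' @return Data frame with one row per multilocus cell: the genotype
#'   categories, case and control counts, the label (\code{"high"} /
#'   \code{"low"}) and an \code{unobserved} flag.
#' @export
label_cells <- function(data, snp_subset, threshold = NULL) {
  stopifnot(inherits(data, "genotype_data"))
  if (!length(data$phenotype)) stop("no samples")
  if (is.numeric(snp_subset)) snp_subset <- data$snp_ids[snp_subset]
  g <- data$genotypes[, snp_subset, drop = FALSE]
  if (anyNA(g) || any(g == data$missing_code))
    stop("missing genotypes present; apply drop_incomplete_samples() first")
  y <- data$phenotype
  if (is.null(threshold)) threshold <- sum(y == 1L) / sum(y == 0L)
  if (!(threshold > 0)) stop("threshold must be positive")

  key <- apply(g, 1L, paste, collapse = "/")
  cells <- sort(unique(key))
  cases <- vapply(cells, function(k) sum(y[key == k] == 1L), 0L)
  controls <- vapply(cells, function(k) sum(y[key == k] == 0L), 0L)
  ratio <- cases / controls
  label <- ifelse(controls == 0L,
                  ifelse(cases > 0L, "high", "low"),
                  ifelse(ratio >= threshold, "high", "low"))
  cats <- do.call(rbind, strsplit(cells, "/", fixed = TRUE))
  colnames(cats) <- snp_subset
  out <- data.frame(cats, cases = cases, controls = controls,
                    label = label, unobserved = cases + controls == 0L,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  out
}

# integer cell codes (1..3^n) for a subset of additively coded SNPs
cell_codes <- function(codes, subset_idx) {
  z <- codes[, subset_idx[1]]
  if (length(subset_idx) > 1L)
    for (i in 2L:length(subset_idx)) z <- z * 3L + codes[, subset_idx[i]]
  z + 1L
}

# per-fold train/test misclassification for one SNP subset.
# codes: integer matrix of additive genotypes (0..2); foldid in 1..K
mdr_eval_core <- function(z, ncell, y, foldid, K) {
  idx <- (foldid - 1L) * ncell + z
  tot_all <- tabulate(z, nbins = ncell)
  tot_case <- tabulate(z[y == 1L], nbins = ncell)
  fold_all <- matrix(tabulate(idx, nbins = ncell * K), ncell, K)
  fold_case <- matrix(tabulate(idx[y == 1L], nbins = ncell * K), ncell, K)
  tr_case <- tot_case - fold_case          # ncell x K training counts
  tr_ctrl <- (tot_all - tot_case) - (fold_all - fold_case)
  n_case <- sum(y == 1L); n_ctrl <- length(y) - n_case
  fold_ncase <- colSums(fold_case); fold_nctrl <- colSums(fold_all - fold_case)
  # high-risk iff case/control ratio >= T with T = train-fold case/control
  # ratio (>= tie rule); the integer cross-product form is exact and makes
  # 0-control cells with cases high-risk; empty training cells are low
  high <- sweep(tr_case, 2, n_ctrl - fold_nctrl, `*`) >=
    sweep(tr_ctrl, 2, n_case - fold_ncase, `*`)
  high[tr_case == 0L & tr_ctrl == 0L] <- FALSE
  tr_err <- colSums(ifelse(high, tr_ctrl, tr_case)) /
    (length(y) - colSums(fold_all))
  te_err <- colSums(ifelse(high, fold_all - fold_case, fold_case)) /
    colSums(fold_all)
  list(train = tr_err, test = te_err)
}

#' Cross-validated evaluation of one MDR model
#'
#' For each fold, high/low-risk cell labels are learned on the training
#' portion (threshold = training-fold case/control ratio) and
#' misclassification is measured on both portions; cells unobserved in
#' training predict low-risk. Errors are averaged over folds.
#'
#' @param data a [genotype_data] object.
#' @param snp_subset SNP ids or indices defining the model.
#' @param n_folds number of stratified CV folds.
#' @param seed seed for the fold assignment.
#' @param foldid optional explicit fold assignment (overrides
#'   \code{n_folds}/\code{seed}).
#' @return List with \code{train_error} and \code{test_error} (fold means)
#'   and the per-fold errors.
#' @export
mdr_evaluate <- function(data, snp_subset, n_folds = 10L, seed = 1L,
                         foldid = NULL) {
  stopifnot(inherits(data, "genotype_data"))
  if (is.numeric(snp_subset)) snp_subset <- data$snp_ids[snp_subset]
  codes <- additive_coding(data)
  if (anyNA(codes))
    stop("missing genotypes present; apply drop_incomplete_samples() first")
  if (is.null(foldid))
    foldid <- stratified_folds(data$phenotype, n_folds, seed)
  K <- max(foldid)
  check_fold_classes(data$phenotype, foldid)
  idx <- match(snp_subset, data$snp_ids)
  res <- mdr_eval_core(cell_codes(codes, idx), 3L^length(idx),
                       data$phenotype, foldid, K)
  list(train_error = mean(res$train), test_error = mean(res$test),
       fold_train_errors = res$train, fold_test_errors = res$test)
}

stratified_folds <- function(y, K, seed) {
  with_seed(seed, {
    foldid <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      foldid[idx] <- sample(rep_len(seq_len(K), length(idx)))
    }
    foldid
  })
}

check_fold_classes <- function(y, foldid) {
  for (f in unique(foldid)) {
    tr <- y[foldid != f]
    if (length(unique(tr)) < 2L)
      stop("fold ", f, " leaves a single-class training set; ",
           "use fewer folds or stratify")
  }
  invisible(TRUE)
}

#' Exhaustive MDR search with cross-validated model selection
#'
#' For each interaction order n = 1..\code{max_order}, every SNP subset of
#' size n is scored; the subset minimising the average training
#' classification error is kept as the order-n winner. The final model is
#' the per-order winner minimising the average prediction (testing) error,
#' with ties broken by higher cross-validation consistency, then smaller
#' order, then lexicographic SNP ids.
#'
#' @param data a [genotype_data] object with complete genotypes.
#' @param max_order largest interaction order to search.
#' @param n_folds number of stratified CV folds (default 10).
#' @param seed seed for the fold assignment.
#' @param prefilter_top if non-NULL, restrict the search to the top-m SNPs by
#'   marginal Fisher exact p-value (best single-genotype grouping per SNP);
#'   required when the exhaustive search would exceed \code{budget}.
#' @param budget maximum number of subset evaluations (default 5e6).
#' @return Object of class \code{"mdr"}: per-order winners (SNP ids, train /
#'   test error, CV consistency), the final model with its full-data cell
#'   labels, and the search metadata.
#' @examples
#' sim <- make_epistasis_dataset(epistasis_sim_config(seed = 1))
#' fit <- mdr_fit(sim, max_order = 2)
#' fit$final$snp_subset
#' @export
mdr_fit <- function(data, max_order = 2L, n_folds = 10L, seed = 1L,
                    prefilter_top = NULL, budget = 5e6) {
  stopifnot(inherits(data, "genotype_data"))
  if (max_order < 1L) stop("max_order must be >= 1")
  codes <- additive_coding(data)
  if (anyNA(codes))
    stop("missing genotypes present; apply drop_incomplete_samples() first")
  y <- data$phenotype
  candidates <- seq_along(data$snp_ids)
  if (!is.null(prefilter_top) && prefilter_top < length(candidates)) {
    p <- marginal_fisher_p(data)
    candidates <- sort(order(p)[seq_len(prefilter_top)])
  }
  n_eval <- sum(choose(length(candidates), seq_len(max_order)))
  if (n_eval > budget)
    stop("exhaustive MDR search needs ", format(n_eval, big.mark = ","),
         " subset evaluations (budget ", format(budget, big.mark = ","),
         "); set prefilter_top to restrict the search")
  foldid <- stratified_folds(y, n_folds, seed)
  K <- max(foldid)
  check_fold_classes(y, foldid)

  per_order <- vector("list", max_order)
  for (ord in seq_len(max_order)) {
    subs <- utils::combn(candidates, ord)
    best <- NULL
    fold_best_err <- rep(Inf, K)
    fold_best_sub <- vector("list", K)
    for (s in seq_len(ncol(subs))) {
      idx <- subs[, s]
      res <- mdr_eval_core(cell_codes(codes, idx), 3L^ord, y, foldid, K)
      m_tr <- mean(res$train)
      upd <- fold_best_err > res$train + 1e-15
      fold_best_err[upd] <- res$train[upd]
      for (f in which(upd)) fold_best_sub[[f]] <- idx
      if (is.null(best) || m_tr < best$train_error - 1e-15 ||
          (abs(m_tr - best$train_error) <= 1e-15 &&
           subset_label(data, idx) < subset_label(data, best$idx))) {
        best <- list(idx = idx, train_error = m_tr,
                     test_error = mean(res$test))
      }
    }
    consistency <- sum(vapply(fold_best_sub, function(fs)
      !is.null(fs) && identical(fs, best$idx), TRUE))
    per_order[[ord]] <- list(order = ord,
                             snp_subset = data$snp_ids[best$idx],
                             train_error = best$train_error,
                             test_error = best$test_error,
                             cv_consistency = consistency)
  }

  final <- per_order[[select_final_order(per_order, data)]]
  cells <- label_cells(data, final$snp_subset)
  out <- list(per_order = per_order, final = final, cell_labels = cells,
              n_folds = K, seed = seed,
              candidates = data$snp_ids[candidates],
              snp_ids = data$snp_ids)
  class(out) <- "mdr"
  out
}

subset_label <- function(data, idx) paste(sort(data$snp_ids[idx]), collapse = ",")

select_final_order <- function(per_order, data) {
  best <- 1L
  for (k in seq_along(per_order)[-1]) {
    a <- per_order[[k]]; b <- per_order[[best]]
    d <- a$test_error - b$test_error
    if (d < -1e-15) best <- k
    else if (abs(d) <= 1e-15) {
      if (a$cv_consistency > b$cv_consistency) best <- k
      # equal consistency: smaller order (b) then lexicographic ids wins
      else if (a$cv_consistency == b$cv_consistency &&
               a$order == b$order &&
               paste(sort(a$snp_subset), collapse = ",") <
               paste(sort(b$snp_subset), collapse = ","))
        best <- k
    }
  }
  best
}

# per-SNP marginal Fisher p: best (smallest) over the SNP's single-genotype
# groupings
marginal_fisher_p <- function(data) {
  vapply(data$snp_ids, function(s) {
    cats <- unique(data$genotypes[, s])
    min(vapply(cats, function(g)
      fisher_exact_two_sided(build_table(data, stats::setNames(list(g), s))),
      0))
  }, 0)
}

#' @export
print.mdr <- function(x, ...) {
  cat("MDR search (", x$n_folds, "-fold CV, ", length(x$candidates),
      " candidate SNPs)\n", sep = "")
  for (po in x$per_order)
    cat(sprintf("  order %d: {%s}  train %.4f  test %.4f  consistency %d/%d\n",
                po$order, paste(po$snp_subset, collapse = ", "),
                po$train_error, po$test_error, po$cv_consistency, x$n_folds))
  cat("final model: {", paste(x$final$snp_subset, collapse = ", "), "}\n",
      sep = "")
  invisible(x)
}

#' @export
summary.mdr <- function(object, ...) {
  cells <- object$cell_labels
  cat("final MDR model {", paste(object$final$snp_subset, collapse = ", "),
      "}: test error ", round(object$final$test_error, 4), "\n", sep = "")
  print(cells[order(-(cells$cases / pmax(cells$controls, 1))), ],
        row.names = FALSE)
  invisible(object)
}

#' Predict case/control status from a fitted MDR model
#'
#' @param object an object of class \code{"mdr"}.
#' @param newdata a [genotype_data] object containing the final model's SNPs.
#' @param ... unused.
#' @return Integer vector of predicted labels (1 = case for high-risk cells,
#'   0 otherwise; unseen cells predict low-risk).
#' @export
predict.mdr <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "genotype_data"))
  snps <- object$final$snp_subset
  key <- apply(newdata$genotypes[, snps, drop = FALSE], 1L, paste,
               collapse = "/")
  cell_key <- apply(object$cell_labels[, snps, drop = FALSE], 1L, paste,
                    collapse = "/")
  lab <- object$cell_labels$label[match(key, cell_key)]
  as.integer(!is.na(lab) & lab == "high")
}
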