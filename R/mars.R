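#' Generalized cross-validation score
#'
#' \code{GCV = RSS / (1 - C/N)^2} with effective cost \code{C = 1 + p * k},
#' where \code{k} is the number of independent basis functions (intercept
#' excluded) and \code{p} the penalty per basis function. Note there is no
#' 1/N prefactor; the factor is constant for a given dataset and does not
#' change model selection.
#'
#' @param rss residual sum of squares.
#' @param N number of observations.
#' @param k number of basis functions.
#' @param penalty_p cost per basis function.
#' @return The GCV score (non-negative scalar).
#' @examples
#' gcv_score(25, N = 100, k = 3, penalty_p = 3)  # 25 / 0.81
#' @export
gcv_score <- function(rss, N, k, penalty_p) {
  C <- 1 + penalty_p * k
  if (C >= N)
    stop("degenerate model: effective cost C = ", C, " >= N = ", N)
  rss / (1 - C / N)^2
}

# ---- atoms ---------------------------------------------------------------

# atomic terms: indicator I(genotype in category set) and, optionally, hinge
# max(0, +/-(x - t)) on the additive coding
build_atoms <- function(data, basis = "indicator") {
  g <- data$genotypes
  atoms <- list(); cols <- list()
  n <- nrow(g)
  for (j in seq_len(ncol(g))) {
    snp <- data$snp_ids[j]
    cats <- sort(unique(g[, j]))
    if (length(cats) < 2L) next
    sets <- as.list(cats)
    if (length(cats) > 2L)  # complements let products express pooled groups
      sets <- c(sets, lapply(cats, function(cc) setdiff(cats, cc)))
    if (basis %in% c("indicator", "both")) {
      for (s in sets) {
        atoms[[length(atoms) + 1L]] <- list(type = "indicator", snp = snp,
                                            cats = s)
        cols[[length(cols) + 1L]] <- as.numeric(g[, j] %in% s)
      }
    }
    if (basis %in% c("hinge", "both")) {
      x <- NULL
      for (knot in 0:2) for (dir in c(1, -1)) {
        if (is.null(x)) {
          minor <- data$allele_map["minor", j]
          x <- (substr(g[, j], 1, 1) == minor) + (substr(g[, j], 2, 2) == minor)
        }
        h <- pmax(0, dir * (x - knot))
        if (stats::var(h) > 0) {
          atoms[[length(atoms) + 1L]] <- list(type = "hinge", snp = snp,
                                              knot = knot, dir = dir)
          cols[[length(cols) + 1L]] <- h
        }
      }
    }
  }
  if (!length(atoms)) stop("no usable atoms: all SNPs are monomorphic")
  A <- matrix(unlist(cols), nrow = n)
  keep <- !duplicated(t(A)) & apply(A, 2, stats::var) > 0
  list(A = A[, keep, drop = FALSE], atoms = atoms[keep],
       snp = vapply(atoms[keep], `[[`, "", "snp"))
}

atom_label <- function(a) {
  if (a$type == "indicator")
    paste0("I(", a$snp, " in {", paste(a$cats, collapse = ","), "})")
  else
    paste0("h(", if (a$dir > 0) paste0(a$snp, "-", a$knot)
           else paste0(a$knot, "-", a$snp), ")")
}

term_label <- function(factors)
  paste(vapply(factors, atom_label, ""), collapse = " * ")

eval_factors <- function(factors, data) {
  out <- rep(1, length(data$sample_ids))
  for (a in factors) {
    if (a$type == "indicator") {
      out <- out * (data$genotypes[, a$snp] %in% a$cats)
    } else {
      minor <- data$allele_map["minor", a$snp]
      x <- (substr(data$genotypes[, a$snp], 1, 1) == minor) +
        (substr(data$genotypes[, a$snp], 2, 2) == minor)
      out <- out * pmax(0, a$dir * (x - a$knot))
    }
  }
  out
}

# ---- forward pass --------------------------------------------------------

#' Fit a genotype-specialised MARS model
#'
#' Forward pass: greedily adds the basis function (a product of atomic
#' genotype terms) that maximally reduces the least-squares RSS of the 0/1
#' response, until \code{max_terms} terms or no candidate improves the RSS by
#' more than \code{forward_tol * RSS}. Candidates comprise every atom, every
#' product of an existing term with an atom of a SNP it does not already use
#' (up to \code{max_degree}), and -- the feature that makes strictly
#' no-marginal-effect interactions reachable -- direct atom-pair products.
#' For wide datasets the pair scan is restricted to atoms of the
#' \code{pair_scan_top} SNPs with the smallest marginal Fisher p-values.
#' Backward pass: [mars_prune()] is applied unless \code{prune = FALSE}.
#'
#' @param data a [genotype_data] object with complete genotypes.
#' @param max_terms maximum number of basis functions added by the forward
#'   pass (default 13, about one per twenty observations at the simulation
#'   scale: enough for an interacting pair plus marginal structure while
#'   limiting how much noise the forward pass can absorb).
#' @param max_degree maximum interaction degree (distinct SNPs per term,
#'   default 2).
#' @param penalty_p GCV cost per basis function; default 3 when
#'   \code{max_degree >= 2}, else 2 (the classical MARS costs).
#' @param forward_tol minimum relative RSS improvement to keep adding terms.
#' @param basis atom family: \code{"indicator"} (default; genotype-category
#'   indicators and their complements), \code{"hinge"} (linear splines on the
#'   additive 0/1/2 coding with data-determined knots), or \code{"both"}.
#' @param pair_scan logical; include direct atom-pair candidates.
#' @param pair_scan_top SNP budget for the pair scan on wide datasets.
#' @param prune apply GCV backward pruning (default TRUE).
#' @return Object of class \code{"snp_mars"} with elements \code{intercept},
#'   \code{terms} (list of coefficient + factor list), \code{k}, \code{gcv},
#'   \code{rss}, \code{N}, \code{penalty_p}, \code{gcv_path} and the training
#'   data reference.
#' @examples
#' sim <- make_epistasis_dataset(epistasis_sim_config(seed = 1))
#' fit <- mars_fit(sim)
#' extract_interactions(fit)
#' @export
mars_fit <- function(data, max_terms = 13L, max_degree = 2L,
                     penalty_p = if (max_degree >= 2) 3 else 2,
                     forward_tol = 1e-3, basis = "indicator",
                     pair_scan = TRUE, pair_scan_top = 30L,
                     prune = TRUE) {
  stopifnot(inherits(data, "genotype_data"))
  if (max_degree < 1L) stop("max_degree must be >= 1")
  y <- as.numeric(data$phenotype)
  N <- length(y)
  if (stats::var(y) == 0) stop("constant response: nothing to fit")
  if (anyNA(data$genotypes) || any(data$genotypes == data$missing_code))
    stop("missing genotypes present; apply drop_incomplete_samples() first")

  # the GCV denominator needs C = 1 + p*k < N
  max_terms <- min(max_terms, floor((N - 2) / penalty_p))
  if (max_terms < 1L) stop("too few observations for any basis function")

  at <- build_atoms(data, basis)
  A <- at$A; M0 <- ncol(A)

  # candidate bookkeeping: factors per candidate + orthogonalised columns
  cand_factors <- vector("list", 0L)
  Cp <- NULL
  add_candidates <- function(cols, factors, Q) {
    cols <- cols - Q %*% crossprod(Q, cols)
    Cp <<- cbind(Cp, cols)
    cand_factors <<- c(cand_factors, factors)
  }

  Q <- matrix(1 / sqrt(N), N, 1)
  # singles
  add_candidates(A, lapply(seq_len(M0), function(m) at$atoms[m]), Q)
  # direct pairs (different SNPs), possibly restricted to top SNPs
  if (pair_scan && max_degree >= 2L) {
    pair_atoms <- seq_len(M0)
    snps <- unique(at$snp)
    if (length(snps) > pair_scan_top) {
      p <- marginal_fisher_p(data)
      top <- names(sort(p))[seq_len(pair_scan_top)]
      pair_atoms <- which(at$snp %in% top)
    }
    pr <- pair_index(at$snp[pair_atoms])
    if (nrow(pr)) {
      i1 <- pair_atoms[pr[, 1]]; i2 <- pair_atoms[pr[, 2]]
      add_candidates(A[, i1, drop = FALSE] * A[, i2, drop = FALSE],
                     lapply(seq_along(i1), function(m)
                       c(at$atoms[i1[m]], at$atoms[i2[m]])), Q)
    }
  }

  terms <- list()
  B <- NULL                      # raw basis columns (non-intercept)
  ybar <- mean(y)
  rss <- sum((y - ybar)^2)
  num <- as.vector(crossprod(y, Cp))
  den <- colSums(Cp^2)
  alive <- den > 1e-10 * N

  while (length(terms) < max_terms) {
    score <- ifelse(alive, num^2 / pmax(den, 1e-300), -Inf)
    b <- which.max(score)
    if (!is.finite(score[b]) || score[b] <= forward_tol * rss) break
    factors <- cand_factors[[b]]
    raw <- eval_factors(factors, data)
    q <- raw - Q %*% crossprod(Q, raw)
    nq <- sqrt(sum(q^2))
    if (nq < 1e-8) { alive[b] <- FALSE; next }
    q <- q / nq
    terms[[length(terms) + 1L]] <- list(factors = factors)
    B <- cbind(B, raw)
    Q <- cbind(Q, q)
    rss <- rss - score[b]
    # rank-1 downdate of the candidate projections
    w <- as.vector(crossprod(q, Cp))
    Cp <- Cp - q %*% t(w)
    num <- num - sum(y * q) * w
    den <- den - w^2
    alive <- alive & den > 1e-10 * N
    alive[b] <- FALSE
    # children of the new term
    used <- vapply(factors, `[[`, "", "snp")
    deg <- length(unique(used))
    if (deg < max_degree) {
      elig <- which(!(at$snp %in% used))
      if (length(elig))
        add_children <- {
          cols <- raw * A[, elig, drop = FALSE]
          keep <- colSums(cols != 0) > 0
          if (any(keep)) {
            add_candidates(cols[, keep, drop = FALSE],
                           lapply(elig[keep], function(m)
                             c(factors, at$atoms[m])), Q)
            num <- c(num[seq_len(length(num))],
                     as.vector(crossprod(y, Cp[, seq.int(length(num) + 1L,
                                                         ncol(Cp)),
                                               drop = FALSE])))
            newd <- colSums(Cp[, seq.int(length(den) + 1L, ncol(Cp)),
                               drop = FALSE]^2)
            den <- c(den, newd)
            alive <- c(alive, newd > 1e-10 * N)
          }
        }
    }
  }

  model <- refit_mars(terms, B, y, data, penalty_p)
  model$forward_k <- length(terms)
  if (prune && length(terms)) model <- mars_prune(model)
  model
}

pair_index <- function(snp_of_atom) {
  m <- length(snp_of_atom)
  if (m < 2L) return(matrix(0L, 0, 2))
  idx <- utils::combn(m, 2L)
  keep <- snp_of_atom[idx[1, ]] != snp_of_atom[idx[2, ]]
  t(idx[, keep, drop = FALSE])
}

refit_mars <- function(terms, B, y, data, penalty_p) {
  N <- length(y)
  k <- length(terms)
  X <- cbind(`(Intercept)` = rep(1, N), B)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  out <- list(intercept = coefs[1],
              terms = lapply(seq_len(k), function(i)
                list(coef = unname(coefs[i + 1L]),
                     factors = terms[[i]]$factors)),
              k = k, penalty_p = penalty_p, N = N, rss = rss,
              gcv = gcv_score(rss, N, k, penalty_p),
              data = data, basis_matrix = B)
  class(out) <- "snp_mars"
  out
}

#' Backward pruning by GCV
#'
#' From the forward model, repeatedly deletes the single basis function whose
#' removal yields the lowest GCV (refitting the remaining coefficients at
#' each step), down to the intercept-only model, and returns the model along
#' the deletion path with the globally minimal GCV.
#'
#' @param model an unpruned \code{"snp_mars"} model.
#' @return The pruned \code{"snp_mars"} model, with the deletion path GCVs in
#'   \code{$gcv_path}.
#' @export
mars_prune <- function(model) {
  stopifnot(inherits(model, "snp_mars"))
  y <- as.numeric(model$data$phenotype)
  N <- model$N
  keep <- seq_len(model$k)
  path <- list(list(keep = keep, gcv = model$gcv))
  current <- keep
  while (length(current) > 0L) {
    gcvs <- vapply(seq_along(current), function(i) {
      cols <- current[-i]
      X <- cbind(1, model$basis_matrix[, cols, drop = FALSE])
      rss <- sum(stats::lm.fit(X, y)$residuals^2)
      gcv_score(rss, N, length(cols), model$penalty_p)
    }, 0)
    drop_i <- which.min(gcvs)
    current <- current[-drop_i]
    path[[length(path) + 1L]] <- list(keep = current, gcv = gcvs[drop_i])
  }
  best <- which.min(vapply(path, `[[`, 0, "gcv"))
  sel <- path[[best]]$keep
  out <- refit_mars(lapply(model$terms[sel], function(t)
    list(factors = t$factors)),
    model$basis_matrix[, sel, drop = FALSE], y, model$data, model$penalty_p)
  out$gcv_path <- vapply(path, `[[`, 0, "gcv")
  out$forward_k <- model$forward_k
  out
}

#' Extract interacting SNP sets from a pruned MARS model
#'
#' Returns the distinct SNP sets of degree-2-or-higher terms, ordered by
#' their total contribution to the fit (the RSS increase when all terms on
#' the SNP set are dropped and the rest refitted). For each set, the
#' high-risk genotype combination is the single-genotype multilocus cell,
#' consistent with the terms' category sets, that maximises the model's
#' fitted risk (ties broken by the observed case ratio).
#'
#' @param model a \code{"snp_mars"} model.
#' @return A list of records with elements \code{snps},
#'   \code{risk_combination} (named genotype vector) and
#'   \code{contribution}; empty when the model has no interaction terms.
#' @export
extract_interactions <- function(model) {
  stopifnot(inherits(model, "snp_mars"))
  if (!length(model$terms)) return(list())
  sets <- lapply(model$terms, function(t)
    sort(unique(vapply(t$factors, `[[`, "", "snp"))))
  deg2 <- which(lengths(sets) >= 2L)
  if (!length(deg2)) return(list())
  keys <- unique(vapply(sets[deg2], paste, "", collapse = ","))
  y <- as.numeric(model$data$phenotype)
  out <- lapply(keys, function(kk) {
    snps <- strsplit(kk, ",", fixed = TRUE)[[1]]
    drop <- which(vapply(sets, function(s) identical(s, snps), TRUE))
    cols <- setdiff(seq_len(model$k), drop)
    X <- cbind(1, model$basis_matrix[, cols, drop = FALSE])
    contribution <- sum(stats::lm.fit(X, y)$residuals^2) - model$rss
    list(snps = snps,
         risk_combination = best_risk_cell(model, snps),
         contribution = contribution)
  })
  out[order(-vapply(out, `[[`, 0, "contribution"))]
}

# single-genotype cell (one category per SNP) with maximal fitted risk
best_risk_cell <- function(model, snps) {
  data <- model$data
  g <- data$genotypes[, snps, drop = FALSE]
  key <- apply(g, 1L, paste, collapse = "/")
  fitted <- predict(model)
  cells <- unique(key)
  stat <- vapply(cells, function(k) {
    idx <- key == k
    c(mean(fitted[idx]), mean(data$phenotype[idx]))
  }, numeric(2))
  ord <- order(-stat[1, ], -stat[2, ])
  combo <- strsplit(cells[ord[1]], "/", fixed = TRUE)[[1]]
  stats::setNames(combo, snps)
}

#' @export
predict.snp_mars <- function(object, newdata = NULL, type = c("response",
                                                              "class"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  f <- rep(object$intercept, length(newdata$sample_ids))
  for (t in object$terms)
    f <- f + t$coef * eval_factors(t$factors, newdata)
  if (type == "class") as.integer(f >= 0.5) else f
}

#' @export
coef.snp_mars <- function(object, ...) {
  stats::setNames(c(object$intercept,
                    vapply(object$terms, `[[`, 0, "coef")),
                  c("(Intercept)",
                    vapply(object$terms, function(t) term_label(t$factors),
                           "")))
}

#' @export
print.snp_mars <- function(x, ...) {
  cat("MARS genotype model: ", x$k, " basis function(s), GCV = ",
      signif(x$gcv, 5), ", RSS = ", signif(x$rss, 5), " (N = ", x$N, ")\n",
      sep = "")
  cf <- coef(x)
  for (i in seq_along(cf))
    cat(sprintf("  %+.4f  %s\n", cf[i], names(cf)[i]))
  invisible(x)
}

#' @export
summary.snp_mars <- function(object, ...) {
  print(object)
  ints <- extract_interactions(object)
  if (length(ints)) {
    cat("interactions (by contribution):\n")
    for (it in ints)
      cat("  {", paste(it$snps, collapse = ", "), "} risk cell ",
          paste(names(it$risk_combination), it$risk_combination,
                sep = "=", collapse = ", "),
          "  contribution ", signif(it$contribution, 4), "\n", sep = "")
  } else cat("no interaction terms\n")
  invisible(object)
}

#' @export
residuals.snp_mars <- function(object, ...) {
  as.numeric(object$data$phenotype) - predict(object)
}
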