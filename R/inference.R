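# Expression-based network inference methods.  Each returns a
# confidence_matrix; stochastic methods take an explicit seed and are
# bit-reproducible.  Undirected outputs are exactly symmetric with zero
# diagonals.

check_samples <- function(X, min_samples) {
  if (ncol(X) < min_samples) {
    stop(sprintf("need at least %d samples, got %d", min_samples, ncol(X)))
  }
}

check_variance <- function(X) {
  v <- apply(X, 1, sd)
  if (any(v == 0)) {
    stop("zero-variance gene(s): ", paste(rownames(X)[v == 0], collapse = ", "))
  }
}

#' Correlation-based inference
#'
#' Edge confidence is the absolute Pearson or Spearman correlation of the two
#' gene profiles.
#'
#' @param expr An [expression_set()] or genes x samples matrix.
#' @param flavor `"pearson"` or `"spearman"`.
#' @return An undirected [new_confidence_matrix()].
#' @export
infer_correlation <- function(expr, flavor = c("pearson", "spearman")) {
  flavor <- match.arg(flavor)
  X <- expr_matrix(expr)
  check_samples(X, 3)
  check_variance(X)
  cm <- abs(cor(t(X), method = flavor))
  cm <- (cm + t(cm)) / 2
  diag(cm) <- 0
  new_confidence_matrix(cm, directed = FALSE, method = paste0("cor_", flavor))
}

default_bins <- function(n_samples) max(2L, floor(sqrt(n_samples)))

# equal-frequency discretization; errors when ties collapse the grid
discretize_ef <- function(x, n_bins, gene = "") {
  breaks <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                            names = FALSE, type = 7))
  if (length(breaks) < 3) {
    stop(sprintf("degenerate binning for gene %s: all samples fall in one bin",
                 gene))
  }
  cut(x, breaks, include.lowest = TRUE, labels = FALSE)
}

mi_bits <- function(dx, dy) {
  tab <- table(dx, dy)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log2(p[idx] / outer(px, py)[idx]))
}

discretize_matrix <- function(X, n_bins) {
  D <- matrix(0L, nrow(X), ncol(X), dimnames = dimnames(X))
  for (i in seq_len(nrow(X))) {
    D[i, ] <- discretize_ef(X[i, ], n_bins, gene = rownames(X)[i])
  }
  D
}

#' Mutual-information inference
#'
#' Plug-in mutual information (in bits) from equal-frequency binned joint
#' counts.  The default number of bins is `floor(sqrt(n_samples))`.
#'
#' @inheritParams infer_correlation
#' @param n_bins Number of equal-frequency bins (>= 2).
#' @return An undirected [new_confidence_matrix()].
#' @export
infer_mutual_information <- function(expr, n_bins = NULL) {
  X <- expr_matrix(expr)
  if (is.null(n_bins)) n_bins <- default_bins(ncol(X))
  stopifnot(n_bins >= 2)
  check_samples(X, n_bins)
  D <- discretize_matrix(X, n_bins)
  n <- nrow(X)
  cm <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cm[i, j] <- cm[j, i] <- mi_bits(D[i, ], D[j, ])
    }
  }
  new_confidence_matrix(cm, directed = FALSE, method = "mi")
}

#' Context-likelihood-of-relatedness (CLR) inference
#'
#' Each mutual information value is z-scored against the background MI
#' distribution of each of its two genes; the confidence is
#' `sqrt(max(0, z_i)^2 + max(0, z_j)^2)`.
#'
#' @inheritParams infer_mutual_information
#' @return An undirected [new_confidence_matrix()].
#' @export
infer_clr <- function(expr, n_bins = NULL) {
  mi <- unclass(infer_mutual_information(expr, n_bins))
  n <- nrow(mi)
  mu <- numeric(n); sdv <- numeric(n)
  for (i in seq_len(n)) {
    bg <- mi[i, -i]
    mu[i] <- mean(bg)
    sdv[i] <- sd(bg)
  }
  cm <- matrix(0, n, n, dimnames = dimnames(mi))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      zi <- if (sdv[i] > 0) (mi[i, j] - mu[i]) / sdv[i] else 0
      zj <- if (sdv[j] > 0) (mi[i, j] - mu[j]) / sdv[j] else 0
      cm[i, j] <- cm[j, i] <- sqrt(max(0, zi)^2 + max(0, zj)^2)
    }
  }
  new_confidence_matrix(cm, directed = FALSE, method = "clr")
}

#' ARACNE inference (MI + data-processing inequality)
#'
#' Starts from the mutual-information matrix and prunes every triangle by the
#' data-processing inequality: the weakest of the three MI values is zeroed
#' whenever it is below `(1 - dpi_tolerance)` times the smaller of the other
#' two.  `dpi_tolerance = 1` disables pruning.
#'
#' @inheritParams infer_mutual_information
#' @param dpi_tolerance DPI tolerance in \[0, 1\] (default 0.15).
#' @return An undirected [new_confidence_matrix()].
#' @export
infer_aracne <- function(expr, n_bins = NULL, dpi_tolerance = 0.15) {
  stopifnot(dpi_tolerance >= 0)
  mi <- unclass(infer_mutual_information(expr, n_bins))
  out <- mi
  n <- nrow(mi)
  if (n >= 3) {
    for (tri in combn(n, 3, simplify = FALSE)) {
      i <- tri[1]; j <- tri[2]; k <- tri[3]
      e <- c(mi[i, j], mi[i, k], mi[j, k])
      w <- which.min(e)
      if (e[w] < (1 - dpi_tolerance) * min(e[-w])) {
        pair <- list(c(i, j), c(i, k), c(j, k))[[w]]
        out[pair[1], pair[2]] <- out[pair[2], pair[1]] <- 0
      }
    }
  }
  new_confidence_matrix(out, directed = FALSE, method = "aracne")
}

#' MRNETB-style maximum-relevance / minimum-redundancy inference
#'
#' For each target gene, candidate regulators are scored by greedy
#' forward-selection MRMR on the mutual-information matrix: at each step the
#' candidate maximizing `MI(candidate, target) - mean MI(candidate, selected)`
#' is added and its score recorded.  The pairwise confidence is the larger of
#' the two directed scores, floored at 0.
#'
#' @inheritParams infer_mutual_information
#' @return An undirected [new_confidence_matrix()].
#' @export
infer_mrnetb <- function(expr, n_bins = NULL) {
  mi <- unclass(infer_mutual_information(expr, n_bins))
  n <- nrow(mi)
  genes <- rownames(mi)
  dir_score <- matrix(0, n, n, dimnames = dimnames(mi))
  for (t in seq_len(n)) {
    cand <- setdiff(seq_len(n), t)
    sel <- integer()
    while (length(cand) > 0) {
      scores <- vapply(cand, function(cc) {
        red <- if (length(sel) == 0) 0 else mean(mi[cc, sel])
        mi[cc, t] - red
      }, numeric(1))
      best <- cand[which.max(scores)]
      dir_score[best, t] <- max(scores)
      sel <- c(sel, best)
      cand <- setdiff(cand, best)
    }
  }
  cm <- pmax(dir_score, t(dir_score), 0)
  new_confidence_matrix(cm, directed = FALSE, method = "mrnetb")
}

#' Tree-ensemble importance inference (GENIE3-style)
#'
#' For each target gene a random regression forest predicts its profile from
#' all other genes; the impurity importance of each regulator, normalized to
#' sum to one per target, is the directed confidence regulator -> target.
#'
#' @inheritParams infer_correlation
#' @param n_trees Number of trees per target (>= 1).
#' @param seed Integer seed (forests are stochastic).
#' @return A directed [new_confidence_matrix()].
#' @export
infer_tree_ensemble <- function(expr, n_trees = 500, seed = 1) {
  X <- expr_matrix(expr)
  check_samples(X, 5)
  stopifnot(n_trees >= 1)
  genes <- rownames(X)
  n <- length(genes)
  cm <- matrix(0, n, n, dimnames = list(genes, genes))
  dat <- as.data.frame(t(X))
  names(dat) <- sprintf("g%03d", seq_len(n))
  for (t in seq_len(n)) {
    pred <- setdiff(seq_len(n), t)
    fit <- ranger(
      x = dat[, pred, drop = FALSE], y = dat[[t]],
      num.trees = n_trees, importance = "impurity",
      seed = seed + t, num.threads = 1
    )
    imp <- pmax(fit$variable.importance, 0)
    if (sum(imp) > 0) imp <- imp / sum(imp)
    cm[pred, t] <- imp
  }
  new_confidence_matrix(cm, directed = TRUE, method = "tree_ensemble")
}

#' Stability-selection sparse regression inference (TIGRESS-style)
#'
#' For each target gene, a lasso path is fitted on randomized half-sample
#' resamples with random predictor reweighting; a regulator's directed
#' confidence is the fraction of resamples in which it is selected among the
#' first `ceiling(selection_fraction * n_regulators)` predictors entering the
#' path.
#'
#' @inheritParams infer_correlation
#' @param n_resamples Number of half-sample resamples (>= 2).
#' @param selection_fraction Fraction of regulators allowed into each sparse
#'   model.
#' @param seed Integer seed.
#' @return A directed [new_confidence_matrix()] of selection frequencies in
#'   \[0, 1\].
#' @export
infer_stability_regression <- function(expr, n_resamples = 50,
                                       selection_fraction = 0.2, seed = 1) {
  stability_engine(expr, prior = NULL, g = 0, n_resamples = n_resamples,
                   selection_fraction = selection_fraction, seed = seed,
                   method = "stability_regression")
}

# shared engine for the no-prior and prior-weighted stability selection;
# the RNG stream is independent of the penalty factors so that runs at
# different prior strengths share resamples and reweightings exactly
stability_engine <- function(expr, prior, g, n_resamples, selection_fraction,
                             seed, reweight_min = 0.4, method = "stability") {
  X <- expr_matrix(expr)
  stopifnot(n_resamples >= 2, g >= 0)
  check_samples(X, 6)
  check_variance(X)
  genes <- rownames(X)
  n_g <- length(genes)
  n_s <- ncol(X)
  Xstd <- t(scale(t(X)))
  penalty <- matrix(1, n_g, n_g, dimnames = list(genes, genes))
  if (!is.null(prior) && g > 0) {
    common <- intersect(rownames(prior), genes)
    penalty[common, common] <- 1 / (1 + g * abs(unclass(prior)[common, common]))
  }
  half <- floor(n_s / 2)
  counts <- matrix(0, n_g, n_g, dimnames = list(genes, genes))
  with_seed(seed, {
    for (r in seq_len(n_resamples)) {
      idx <- sample.int(n_s, half)
      w <- runif(n_g, reweight_min, 1)
      for (t in seq_len(n_g)) {
        p_idx <- setdiff(seq_len(n_g), t)
        Z <- t(Xstd[p_idx, idx, drop = FALSE]) *
          rep(w[p_idx], each = length(idx))
        y <- Xstd[t, idx]
        pf <- penalty[p_idx, t]
        if (length(p_idx) < 2) {  # glmnet needs >= 2 columns
          Z <- cbind(Z, 0)
          pf <- c(pf, 1)
        }
        fit <- glmnet(Z, y, family = "gaussian", standardize = FALSE,
                      penalty.factor = pf)
        L <- max(1L, ceiling(selection_fraction * length(p_idx)))
        # first L regulators to enter the path (lambda-grid-robust; ties at
        # the same grid point broken by coefficient magnitude at entry)
        B <- as.matrix(fit$beta)[seq_along(p_idx), , drop = FALSE]
        entry <- apply(B != 0, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
        entry_mag <- ifelse(is.na(entry), 0, abs(B[cbind(seq_along(entry), entry)]))
        ord <- order(entry, -entry_mag, seq_along(entry), na.last = NA)
        sel <- p_idx[head(ord, L)]
        counts[sel, t] <- counts[sel, t] + 1
      }
    }
  })
  new_confidence_matrix(counts / n_resamples, directed = TRUE, method = method)
}

#' Shrinkage partial-correlation inference (GGM-style)
#'
#' Confidence is the absolute partial correlation obtained from the inverse
#' of a correlation matrix shrunk toward the identity.  The default
#' (`shrinkage = "auto"`) uses the Schafer-Strimmer analytic shrinkage
#' intensity; a numeric value in \[0, 1\] fixes the intensity (0 = plain
#' inverse-correlation partial correlations).
#'
#' @inheritParams infer_correlation
#' @param shrinkage `"auto"` or a numeric intensity in \[0, 1\].
#' @return An undirected [new_confidence_matrix()].
#' @export
infer_partial_correlation <- function(expr, shrinkage = "auto") {
  X <- expr_matrix(expr)
  check_samples(X, 4)
  check_variance(X)
  n <- ncol(X)
  R <- cor(t(X))
  if (identical(shrinkage, "auto")) {
    Xs <- t(scale(t(X)))  # gene-standardized, sd uses n-1
    p <- nrow(X)
    num <- 0; den <- 0
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        w <- Xs[i, ] * Xs[j, ]
        v <- n / (n - 1)^3 * sum((w - mean(w))^2)
        num <- num + v
        den <- den + R[i, j]^2
      }
    }
    lambda <- if (den > 0) min(1, max(0, num / den)) else 1
  } else {
    stopifnot(is.numeric(shrinkage), shrinkage >= 0, shrinkage <= 1)
    lambda <- shrinkage
  }
  Rs <- (1 - lambda) * R + lambda * diag(nrow(R))
  omega <- tryCatch(solve(Rs), error = function(e) {
    stop("shrunk covariance matrix is not invertible; increase shrinkage")
  })
  d <- sqrt(diag(omega))
  pcor <- -omega / outer(d, d)
  diag(pcor) <- 0
  cm <- abs((pcor + t(pcor)) / 2)
  new_confidence_matrix(cm, directed = FALSE, method = "partial_correlation")
}

bdeu_local_score <- function(child, parents, D, levels, ess = 1) {
  x <- D[child, ]
  r <- levels[child]
  if (length(parents) == 0) {
    cfg <- rep(1L, ncol(D))
    q <- 1
  } else {
    cfg <- as.integer(interaction(as.data.frame(t(D[parents, , drop = FALSE])),
                                  drop = TRUE))
    q <- prod(levels[parents])
  }
  a_j <- ess / q
  a_jk <- ess / (q * r)
  score <- 0
  tab <- table(cfg, x)
  for (jj in seq_len(nrow(tab))) {
    n_j <- sum(tab[jj, ])
    score <- score + lgamma(a_j) - lgamma(a_j + n_j) +
      sum(lgamma(a_jk + tab[jj, ]) - lgamma(a_jk))
  }
  score
}

#' Exhaustive Bayesian-score inference
#'
#' Discretizes the data (equal-frequency bins) and, for each target gene,
#' scores every candidate parent set of size up to `max_parents` with a
#' Bayesian-Dirichlet (BDeu) metric under a uniform structure prior.  The
#' directed confidence of regulator -> target is the posterior-weighted
#' frequency of parent sets containing the regulator.  Exhaustive scoring is
#' exponential in `max_parents`, so the method is gated to small gene sets.
#'
#' @inheritParams infer_mutual_information
#' @param max_parents Maximum parent-set size (0 to 3).
#' @param ess Equivalent sample size of the Dirichlet prior.
#' @return A directed [new_confidence_matrix()] with entries in \[0, 1\].
#' @export
infer_bayesian_score <- function(expr, n_bins = NULL, max_parents = 2, ess = 1) {
  X <- expr_matrix(expr)
  if (nrow(X) > 15) {
    stop("exhaustive Bayesian scoring is limited to <= 15 genes; ",
         "use the other inference methods for larger sets")
  }
  stopifnot(max_parents >= 0, max_parents <= 3)
  if (is.null(n_bins)) n_bins <- default_bins(ncol(X))
  D <- discretize_matrix(X, n_bins)
  levels <- apply(D, 1, function(z) length(unique(z)))
  genes <- rownames(X)
  n <- length(genes)
  cm <- matrix(0, n, n, dimnames = list(genes, genes))
  for (t in seq_len(n)) {
    cand <- setdiff(seq_len(n), t)
    sets <- list(integer())
    for (sz in seq_len(min(max_parents, length(cand)))) {
      sets <- c(sets, combn(cand, sz, simplify = FALSE))
    }
    scores <- vapply(sets, function(s) bdeu_local_score(t, s, D, levels, ess),
                     numeric(1))
    wts <- exp(scores - max(scores))
    post <- wts / sum(wts)
    for (k in seq_along(sets)) {
      cm[sets[[k]], t] <- cm[sets[[k]], t] + post[k]
    }
  }
  new_confidence_matrix(cm, directed = TRUE, method = "bayesian_score")
}

#' Run a panel of inference methods
#'
#' Convenience wrapper running the requested methods on the same expression
#' set and packaging each result (confidence matrix + derived ranked edge
#' list + seed) for [consensus_rank()].
#'
#' @inheritParams infer_correlation
#' @param methods Character vector naming methods among `"pearson"`,
#'   `"spearman"`, `"mi"`, `"clr"`, `"aracne"`, `"mrnetb"`,
#'   `"tree_ensemble"`, `"stability_regression"`, `"partial_correlation"`,
#'   `"bayesian"`.
#' @param seed Integer seed used by the stochastic methods.
#' @param n_trees,n_resamples Hyperparameters forwarded to the tree-ensemble
#'   and stability-selection methods.
#' @return A named list of `method_result` objects.
#' @export
run_inference_methods <- function(expr,
                                  methods = c("pearson", "spearman", "mi",
                                              "clr", "aracne", "mrnetb",
                                              "tree_ensemble",
                                              "stability_regression",
                                              "partial_correlation",
                                              "bayesian"),
                                  seed = 1, n_trees = 500, n_resamples = 50) {
  run1 <- function(m) {
    cm <- switch(
      m,
      pearson = infer_correlation(expr, "pearson"),
      spearman = infer_correlation(expr, "spearman"),
      mi = infer_mutual_information(expr),
      clr = infer_clr(expr),
      aracne = infer_aracne(expr),
      mrnetb = infer_mrnetb(expr),
      tree_ensemble = infer_tree_ensemble(expr, n_trees = n_trees, seed = seed),
      stability_regression = infer_stability_regression(
        expr, n_resamples = n_resamples, seed = seed),
      partial_correlation = infer_partial_correlation(expr),
      bayesian = infer_bayesian_score(expr),
      stop("unknown inference method: ", m)
    )
    structure(list(method = m, cm = cm, ranked = rank_edges(cm),
                   seed = if (m %in% c("tree_ensemble", "stability_regression"))
                     seed else NA_integer_),
              class = "method_result")
  }
  setNames(lapply(methods, run1), methods)
}

#' @exportS3Method base::print
print.method_result <- function(x, ...) {
  cat(sprintf("<method_result> %s (%s)\n", x$method,
              if (attr(x$cm, "directed")) "directed" else "undirected"))
  print(head(x$ranked, 5))
  invisible(x)
}

#' @export
tidy.method_result <- function(x, ...) x$ranked
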