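# ROC / precision-recall evaluation of a ranked edge list against a
# (pseudo-)gold-standard network.

#' Label ranked predictions against a gold-standard network
#'
#' Completes the prediction over the full candidate-pair universe of the gold
#' network's node set (all unordered non-self pairs in undirected mode, all
#' ordered non-self pairs in directed mode): pairs absent from the prediction
#' are appended in lexicographic order with score `-Inf`.  In undirected mode
#' a pair is a true prediction iff the gold network contains an edge between
#' the two nodes in either direction.  Self-pairs are excluded throughout.
#'
#' @param pred A ranked edge list tibble (columns `from`, `to`, `score`).
#' @param gold A [regulatory_network()] gold standard; `pred` nodes must be a
#'   subset of its nodes.
#' @param mode `"undirected"` or `"directed"`.
#' @return A tibble with columns `from`, `to`, `score`, `label` (logical),
#'   ordered by decreasing score (ties lexicographic).
#' @export
label_predictions <- function(pred, gold, mode = c("undirected", "directed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(gold, "grn_network"))
  pred <- as_tibble(pred)
  pred$from <- canonical_gene_names(pred$from)
  pred$to <- canonical_gene_names(pred$to)
  nodes <- network_nodes(gold)
  unknown <- setdiff(unique(c(pred$from, pred$to)), nodes)
  if (length(unknown) > 0) {
    stop("prediction references node(s) absent from the gold network: ",
         paste(unknown, collapse = ", "))
  }
  pred <- pred[pred$from != pred$to, , drop = FALSE]  # self-pairs excluded
  if (mode == "undirected") pred <- collapse_undirected(pred)
  universe <- all_pairs(nodes, directed = (mode == "directed"))
  key <- function(from, to) paste(from, to, sep = "\r")
  pk <- key(pred$from, pred$to)
  if (anyDuplicated(pk)) stop("duplicate (pair, direction) entries in prediction")
  scores <- setNames(pred$score, pk)
  uk <- key(universe$from, universe$to)
  universe$score <- unname(scores[uk])
  universe$score[is.na(universe$score)] <- -Inf
  edges <- gold$edges[gold$edges$from != gold$edges$to, , drop = FALSE]
  if (mode == "undirected") {
    ek <- unique(key(pmin_chr(edges$from, edges$to), pmax_chr(edges$from, edges$to)))
  } else {
    ek <- unique(key(edges$from, edges$to))
  }
  universe$label <- uk %in% ek
  arrange(universe, desc(.data$score), .data$from, .data$to)
}

pmin_chr <- function(a, b) ifelse(canonicalize_pairs(a, b)$from == a, a, b)
pmax_chr <- function(a, b) ifelse(canonicalize_pairs(a, b)$from == a, b, a)

as_labels <- function(labels) {
  if (is.logical(labels)) {
    return(tibble(score = rev(seq_along(labels)), label = labels))
  }
  labels <- as_tibble(labels)
  stopifnot(all(c("score", "label") %in% names(labels)))
  labels
}

#' ROC curve and area under it
#'
#' Builds the cumulative ROC step curve over score thresholds (a tied score
#' block contributes a single step) and returns its trapezoidal area, which
#' equals the Mann-Whitney probability of correct ordering with ties counted
#' one half.
#'
#' @param labels Either a logical vector of labels in rank order (each
#'   position its own threshold) or a tibble with `score` and `label`
#'   columns as produced by [label_predictions()].
#' @return A list with `roc_points` (tibble of `fpr`, `tpr`, starting at
#'   (0, 0) and ending at (1, 1)) and `auroc`.
#' @export
roc_auroc <- function(labels) {
  lab <- as_labels(labels)
  lab <- lab[order(-lab$score), , drop = FALSE]
  n_pos <- sum(lab$label); n_neg <- sum(!lab$label)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs at least one positive and one negative label")
  }
  blocks <- cumsum(!duplicated(lab$score))
  tp <- cumsum(lab$label); fp <- cumsum(!lab$label)
  last <- !duplicated(blocks, fromLast = TRUE)
  pts <- tibble(fpr = c(0, fp[last] / n_neg), tpr = c(0, tp[last] / n_pos))
  auroc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
  list(roc_points = pts, auroc = auroc)
}

#' Precision-recall curve and area under it
#'
#' Precision and recall are computed at each cumulative cutoff in rank order
#' and the area is the non-interpolated step sum
#' `sum(precision@k * delta recall)`, the standard in GRN benchmarking.  A
#' ranking that places all gold edges first yields an AUPR of exactly 1.
#'
#' @inheritParams roc_auroc
#' @return A list with `pr_points` (tibble of `recall`, `precision`) and
#'   `aupr`.
#' @export
pr_aupr <- function(labels) {
  lab <- as_labels(labels)
  lab <- lab[order(-lab$score), , drop = FALSE]
  n_pos <- sum(lab$label)
  if (n_pos == 0) stop("PR needs at least one positive label")
  k <- seq_len(nrow(lab))
  tp <- cumsum(lab$label)
  precision <- tp / k
  recall <- tp / n_pos
  aupr <- sum(precision[lab$label]) / n_pos
  list(pr_points = tibble(recall = recall, precision = precision), aupr = aupr)
}

#' Evaluate a ranked edge list against a gold-standard network
#'
#' Wraps [label_predictions()], [roc_auroc()] and [pr_aupr()] into one
#' result object.
#'
#' @inheritParams label_predictions
#' @return An object of class `grn_eval` with elements `labels`,
#'   `roc_points`, `pr_points`, `auroc`, `aupr`, `n_positives`,
#'   `n_negatives` and `mode`.
#' @export
evaluate_ranking <- function(pred, gold, mode = c("undirected", "directed")) {
  mode <- match.arg(mode)
  labels <- label_predictions(pred, gold, mode)
  roc <- roc_auroc(labels)
  pr <- pr_aupr(labels)
  structure(list(labels = labels, roc_points = roc$roc_points,
                 pr_points = pr$pr_points, auroc = roc$auroc, aupr = pr$aupr,
                 n_positives = sum(labels$label),
                 n_negatives = sum(!labels$label), mode = mode),
            class = "grn_eval")
}

#' Precision among the top k predictions
#'
#' @param eval A `grn_eval` object (or labelled tibble).
#' @param k Number of top-ranked predictions to consider.
#' @return Precision at rank `k`.
#' @export
precision_at_k <- function(eval, k) {
  lab <- if (inherits(eval, "grn_eval")) eval$labels else as_labels(eval)
  stopifnot(k >= 1, k <= nrow(lab))
  mean(head(lab$label, k))
}

#' @exportS3Method base::print
print.grn_eval <- function(x, ...) {
  cat(sprintf("<grn_eval> %s: AUROC %.3f, AUPR %.3f (%d positives / %d pairs)\n",
              x$mode, x$auroc, x$aupr, x$n_positives,
              x$n_positives + x$n_negatives))
  invisible(x)
}

#' @export
tidy.grn_eval <- function(x, ...) x$labels

#' @export
glance.grn_eval <- function(x, ...) {
  tibble(auroc = x$auroc, aupr = x$aupr, n_positives = x$n_positives,
         n_negatives = x$n_negatives, mode = x$mode)
}
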