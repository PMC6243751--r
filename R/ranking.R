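# Ranked edge lists and confidence matrices.
#
# A ranked edge list is a tibble with columns `from`, `to`, `direction`
# ("undirected" or "source_to_target"), `score` and `rank`; scores are
# non-increasing with rank and ties carry the average of the tied positions.
# For undirected entries the pair is canonical: `from` precedes `to` in
# C-locale lexicographic order.

#' Construct a confidence matrix
#'
#' A square non-negative matrix of edge confidences over a fixed gene order.
#' The diagonal is ignored and forced to zero; undirected matrices must be
#' symmetric.
#'
#' @param values Square numeric matrix with gene dimnames.
#' @param directed Logical; is entry (i, j) specific to direction i -> j?
#' @param method Optional method label carried along for provenance.
#' @return A `confidence_matrix` object.
#' @export
new_confidence_matrix <- function(values, directed, method = NULL) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values), !is.null(rownames(values)))
  if (!identical(rownames(values), colnames(values))) {
    stop("confidence matrix dimnames must agree")
  }
  diag(values) <- 0
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("confidences must be finite and >= 0")
  }
  if (!directed && !isTRUE(all.equal(values, t(values)))) {
    stop("undirected confidence matrix must be symmetric")
  }
  structure(values, class = c("confidence_matrix", "matrix", "array"),
            directed = directed, method = method)
}

#' @exportS3Method base::print
print.confidence_matrix <- function(x, ...) {
  cat(sprintf("<confidence_matrix> %d genes, %s, method: %s\n",
              nrow(x), if (attr(x, "directed")) "directed" else "undirected",
              attr(x, "method") %||% "?"))
  print(head(unclass(x), 6L))
  invisible(x)
}

lex_sorted <- function(x) sort(x, method = "radix")

# canonical unordered pair: from <= to in C-locale order
canonicalize_pairs <- function(from, to) {
  swap <- vapply(seq_along(from), function(i) {
    order(c(from[i], to[i]), method = "radix")[1L] == 2L
  }, logical(1))
  new_from <- ifelse(swap, to, from)
  new_to <- ifelse(swap, from, to)
  tibble(from = new_from, to = new_to)
}

rank_desc <- function(score) rank(-score, ties.method = "average")

#' Convert a confidence matrix to a ranked edge list
#'
#' Directed matrices yield one entry per ordered non-self pair; undirected
#' matrices one entry per canonical unordered pair.  Ranks are assigned by
#' descending score with average-rank ties; the list is sorted by rank with
#' lexicographic pair order breaking ties.
#'
#' @param cm A [new_confidence_matrix()] object.
#' @return A ranked edge list tibble.
#' @export
rank_edges <- function(cm) {
  stopifnot(inherits(cm, "confidence_matrix"))
  nodes <- rownames(cm)
  if (attr(cm, "directed")) {
    grid <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    grid <- grid[grid$from != grid$to, , drop = FALSE]
    out <- tibble(from = grid$from, to = grid$to, direction = "source_to_target",
                  score = unclass(cm)[cbind(grid$from, grid$to)])
  } else {
    pr <- t(combn(lex_sorted(nodes), 2L))
    out <- tibble(from = pr[, 1], to = pr[, 2], direction = "undirected",
                  score = unclass(cm)[pr])
  }
  out$rank <- rank_desc(out$score)
  arrange(out, .data$rank, .data$from, .data$to)
}

#' Collapse a ranked edge list to undirected entries
#'
#' Each unordered pair appears once with score equal to the larger of its two
#' directed scores ("the interaction exists" is an existence claim, carried by
#' the stronger evidence), and the list is re-ranked.  Already-undirected
#' lists are returned re-ranked but otherwise unchanged; the operation is
#' idempotent and never increases the number of entries.
#'
#' @param ranked A ranked edge list tibble (columns `from`, `to`, `score`;
#'   `direction` optional).
#' @return An undirected ranked edge list tibble.
#' @export
collapse_undirected <- function(ranked) {
  ranked <- as_tibble(ranked)
  stopifnot(all(c("from", "to", "score") %in% names(ranked)))
  pairs <- canonicalize_pairs(ranked$from, ranked$to)
  out <- tibble(from = pairs$from, to = pairs$to, score = ranked$score) |>
    group_by(.data$from, .data$to) |>
    summarise(score = max(.data$score), .groups = "drop") |>
    mutate(direction = "undirected", .after = "to")
  out$rank <- rank_desc(out$score)
  arrange(out, .data$rank, .data$from, .data$to)
}

all_pairs <- function(nodes, directed = FALSE) {
  if (directed) {
    grid <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    grid <- grid[grid$from != grid$to, , drop = FALSE]
    tibble(from = grid$from, to = grid$to)
  } else {
    pr <- t(combn(lex_sorted(nodes), 2L))
    tibble(from = pr[, 1], to = pr[, 2])
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
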