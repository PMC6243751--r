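#' Average-rank consensus of multiple inference results
#'
#' Implements the voting approach used in DREAM-style benchmarking: each
#' method's output is collapsed to an undirected ranking over all candidate
#' gene pairs (average-rank ties), and the consensus score of a pair is its
#' mean rank across methods, sorted ascending (best first).  Because only
#' ranks enter, the consensus is invariant to the order of the inputs and to
#' any strictly monotone rescaling of a method's scores.
#'
#' A pair missing from a method's ranked list is imputed at that method's
#' worst possible rank (the number of candidate pairs): absence of evidence
#' is ranked last.
#'
#' @param results A list (length >= 2) of `method_result` objects,
#'   [new_confidence_matrix()] objects or ranked edge list tibbles, all over
#'   the same node set.
#' @return An undirected ranked edge list tibble with an extra `mean_rank`
#'   column; `score = -mean_rank` so that scores are non-increasing with
#'   rank.  Ties are ordered lexicographically.
#' @export
consensus_rank <- function(results) {
  stopifnot(length(results) >= 2)
  get_nodes <- function(r) {
    if (inherits(r, "method_result")) return(rownames(r$cm))
    if (inherits(r, "confidence_matrix")) return(rownames(r))
    lex_sorted(unique(c(r$from, r$to)))
  }
  node_sets <- lapply(results, function(r) lex_sorted(get_nodes(r)))
  if (!all(vapply(node_sets, identical, logical(1), y = node_sets[[1]]))) {
    stop("all results must cover the same node set")
  }
  nodes <- node_sets[[1]]
  universe <- all_pairs(nodes)
  P <- nrow(universe)
  key <- function(from, to) paste(from, to, sep = "\r")
  ukey <- key(universe$from, universe$to)
  rank_of <- function(r) {
    if (inherits(r, "method_result")) r <- r$cm
    if (inherits(r, "confidence_matrix")) {
      v <- unclass(r)
      sym <- pmax(v, t(v))
      score <- sym[cbind(universe$from, universe$to)]
      return(rank_desc(score))
    }
    und <- collapse_undirected(r)
    rk <- setNames(rank_desc(und$score), key(und$from, und$to))
    out <- rep(P, P)  # worst-rank imputation for absent pairs
    hit <- ukey %in% names(rk)
    out[hit] <- rk[ukey[hit]]
    out
  }
  ranks <- vapply(results, rank_of, numeric(P))
  out <- universe
  out$direction <- "undirected"
  out$mean_rank <- rowMeans(ranks)
  out$score <- -out$mean_rank
  out$rank <- rank(out$mean_rank, ties.method = "average")
  arrange(out, .data$mean_rank, .data$from, .data$to)
}
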