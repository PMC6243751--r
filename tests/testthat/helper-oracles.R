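# Independent oracles and fixture builders used across the suite.  The
# oracles deliberately avoid the package's own code paths.

# Brute-force Boolean attractor oracle: enumerate all 2^n states of a signed
# network (weights ignored up to sign, all edges treated alike) under the
# threshold rule "on iff weighted sum > 0, off iff < 0, hold on ties"; a
# state is a fixed point iff every node's update leaves it unchanged.
# Works directly from the edge table, not from the simulator.
boolean_fixed_points <- function(net) {
  nodes <- net$nodes$name
  n <- length(nodes)
  e <- net$edges
  states <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  colnames(states) <- nodes
  fixed <- apply(states, 1, function(v) {
    for (nd in nodes) {
      inc <- e[e$to == nd, , drop = FALSE]
      if (nrow(inc) == 0) next  # input node holds its value
      s <- sum(inc$sign * inc$weight * v[inc$from]) / sum(inc$weight)
      target <- if (s > 0) 1 else if (s < 0) 0 else v[[nd]]
      if (target != v[[nd]]) return(FALSE)
    }
    TRUE
  })
  states[fixed, , drop = FALSE]
}

# Mann-Whitney AUROC oracle: fraction of positive-negative score pairs
# correctly ordered, ties counted one half.
mw_auroc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# average-precision oracle computed directly from the definition
ap_oracle <- function(label) {
  tp <- cumsum(label)
  sum((tp / seq_along(label))[label]) / sum(label)
}

toggle_network <- function() {
  regulatory_network(
    nodes = data.frame(name = c("X", "Y"), category = "transcription_factor"),
    edges = data.frame(from = c("X", "X", "Y", "Y"),
                       to = c("X", "Y", "X", "Y"),
                       sign = c(1, -1, -1, 1))
  )
}

toggle_model <- function(activation = "step", ...) {
  additive_model(toggle_network(), activation = activation,
                 markers = c("X", "Y"), ...)
}

# random signed network over n nodes with all-fast kinetics (for the
# Boolean-limit battery); self-loops allowed
random_fast_network <- function(n, seed, density = 0.5) {
  set.seed(seed)
  nodes <- LETTERS[seq_len(n)]
  grid <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  keep <- runif(nrow(grid)) < density
  e <- grid[keep, , drop = FALSE]
  if (nrow(e) == 0) e <- grid[1, , drop = FALSE]
  e$sign <- sample(c(-1, 1), nrow(e), replace = TRUE)
  e$weight <- 1
  e$kinetics <- "fast"
  regulatory_network(data.frame(name = nodes, category = "other"), e)
}

# small deterministic expression fixture: 4 genes, n samples, linear chain
# A -> B -> C plus independent D; moderate coupling so that the correlation
# structure is informative without being near-singular
chain_expression <- function(n = 200, seed = 42, noise = 0.6) {
  set.seed(seed)
  A <- rnorm(n)
  B <- 0.8 * A + noise * rnorm(n)
  C <- 0.8 * B + noise * rnorm(n)
  D <- rnorm(n)
  m <- rbind(A = A, B = B, C = C, D = D)
  colnames(m) <- sprintf("s%03d", seq_len(n))
  m
}

# strip the provenance attributes of a confidence matrix for raw comparisons
cm_mat <- function(cm) {
  m <- unclass(cm)
  attr(m, "directed") <- NULL
  attr(m, "method") <- NULL
  m
}

expect_symmetric_cm <- function(cm) {
  expect_false(attr(cm, "directed"))
  v <- unclass(cm)
  expect_identical(v, t(v))
  expect_true(all(diag(v) == 0))
  expect_true(all(is.finite(v)) && all(v >= 0))
}
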