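#' Construct a signed, weighted, directed regulatory network
#'
#' The central container shared by the simulator, the inference pipeline and
#' the evaluator.  Nodes carry a category (`"growth_factor"`,
#' `"transcription_factor"` or `"other"`); edges carry a sign (+1 activation,
#' -1 inhibition), a non-negative weight and a kinetics class (`"fast"` for
#' protein-activity-like reactions, `"slow"` for gene-expression-like ones).
#'
#' Node names are canonicalized through [canonical_gene_names()].  At most one
#' edge is allowed per ordered (source, target) pair and every edge endpoint
#' must be a declared node.
#'
#' @param nodes A data frame with columns `name` and optionally `category`
#'   (defaults to `"other"`), or a character vector of node names.
#' @param edges A data frame with columns `from`, `to` and optionally `sign`
#'   (+1/-1, default +1), `weight` (>= 0, default 1) and `kinetics`
#'   (`"fast"`/`"slow"`, default `"slow"`).  May have zero rows.
#' @return An object of class `grn_network`: a list with tibbles `nodes` and
#'   `edges`.
#' @export
#' @examples
#' net <- regulatory_network(
#'   nodes = data.frame(name = c("X", "Y"), category = "transcription_factor"),
#'   edges = data.frame(from = c("X", "Y"), to = c("Y", "X"), sign = -1)
#' )
#' net
regulatory_network <- function(nodes, edges = NULL) {
  if (is.character(nodes)) nodes <- tibble(name = nodes)
  nodes <- as_tibble(nodes)
  stopifnot("name" %in% names(nodes))
  if (!"category" %in% names(nodes)) nodes$category <- "other"
  nodes$name <- canonical_gene_names(nodes$name)
  bad_cat <- !nodes$category %in% c("growth_factor", "transcription_factor", "other")
  nodes$category[bad_cat] <- "other"
  if (anyDuplicated(nodes$name)) {
    stop("duplicate node names after canonicalization: ",
         paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "))
  }
  if (is.null(edges)) {
    edges <- tibble(from = character(), to = character(), sign = integer(),
                    weight = numeric(), kinetics = character())
  }
  edges <- as_tibble(edges)
  if (nrow(edges) > 0) {
    stopifnot(all(c("from", "to") %in% names(edges)))
    if (!"sign" %in% names(edges)) edges$sign <- 1L
    if (!"weight" %in% names(edges)) edges$weight <- 1
    if (!"kinetics" %in% names(edges)) edges$kinetics <- "slow"
    edges$from <- canonical_gene_names(edges$from)
    edges$to <- canonical_gene_names(edges$to)
    edges$sign <- as.integer(edges$sign)
    missing <- setdiff(c(edges$from, edges$to), nodes$name)
    if (length(missing) > 0) {
      stop("edge endpoint(s) not declared as nodes: ",
           paste(missing, collapse = ", "))
    }
    key <- paste(edges$from, edges$to, sep = "\r")
    if (anyDuplicated(key)) {
      dup <- edges[duplicated(key), , drop = FALSE][1, ]
      stop(sprintf("duplicate edge for pair (%s, %s)", dup$from, dup$to))
    }
    if (!all(edges$sign %in% c(-1L, 1L))) stop("edge sign must be +1 or -1")
    if (any(edges$weight < 0) || any(!is.finite(edges$weight))) {
      stop("edge weights must be finite and >= 0")
    }
    if (!all(edges$kinetics %in% c("fast", "slow"))) {
      stop("edge kinetics must be 'fast' or 'slow'")
    }
    edges <- edges[, c("from", "to", "sign", "weight", "kinetics")]
  }
  structure(list(nodes = nodes[, c("name", "category")], edges = edges),
            class = "grn_network")
}

#' @exportS3Method base::print
print.grn_network <- function(x, ...) {
  cat(sprintf("<grn_network> %d nodes, %d edges (%d activating, %d inhibiting)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == 1), sum(x$edges$sign == -1)))
  cats <- table(x$nodes$category)
  cat("  categories:", paste(sprintf("%s=%d", names(cats), cats), collapse = ", "), "\n")
  invisible(x)
}

network_nodes <- function(net) net$nodes$name

#' Read a regulatory network from disk
#'
#' Two plain-text formats are supported.  `"sif"` is a minimal
#' tab-separated dialect `source<TAB>relation<TAB>target` with relation
#' `activates` or `inhibits`.  `"tsv"` is a signed weighted adjacency matrix
#' with gene names in the header row and first column; entry (i, j) is the
#' signed weight of the edge i -> j (0 = no edge).
#'
#' A parse report (counts, flagged self-loops, alias substitutions) is
#' attached as attribute `"parse_report"`.
#'
#' @param path Path to the network file.
#' @param format `"sif"` or `"tsv"`.
#' @param categories Optional named character vector giving node categories
#'   (names are gene names, canonicalized); unknown categories default to
#'   `"other"`.
#' @return A [regulatory_network()] object.
#' @export
read_network <- function(path, format = c("sif", "tsv"), categories = NULL) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    from <- to <- character(length(parts))
    sign <- integer(length(parts))
    for (i in seq_along(parts)) {
      p <- parts[[i]]
      if (length(p) != 3) {
        stop(sprintf("line %d: expected 3 tab-separated fields, got %d", i, length(p)))
      }
      rel <- trimws(p[2])
      if (rel == "activates") sign[i] <- 1L
      else if (rel == "inhibits") sign[i] <- -1L
      else stop(sprintf("line %d: unknown interaction tag '%s'", i, rel))
      from[i] <- p[1]; to[i] <- p[3]
    }
    raw_names <- unique(c(from, to))
    canon_from <- canonical_gene_names(from)
    canon_to <- canonical_gene_names(to)
    aliases_mapped <- unique(c(from[from != canon_from], to[to != canon_to]))
    node_names <- unique(c(canon_from, canon_to))
    edges <- tibble(from = canon_from, to = canon_to, sign = sign,
                    weight = 1, kinetics = "slow")
  } else {
    m <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
    rownames(m) <- canonical_gene_names(rownames(m))
    colnames(m) <- canonical_gene_names(colnames(m))
    node_names <- rownames(m)
    idx <- which(m != 0, arr.ind = TRUE)
    edges <- tibble(
      from = rownames(m)[idx[, 1]], to = colnames(m)[idx[, 2]],
      sign = as.integer(sign(m[idx])), weight = abs(m[idx]), kinetics = "slow"
    )
    aliases_mapped <- character()
  }
  cat_vec <- rep("other", length(node_names))
  if (!is.null(categories)) {
    names(categories) <- canonical_gene_names(names(categories))
    hit <- node_names %in% names(categories)
    cat_vec[hit] <- unname(categories[node_names[hit]])
  }
  net <- regulatory_network(tibble(name = node_names, category = cat_vec), edges)
  self <- net$edges$from == net$edges$to
  attr(net, "parse_report") <- list(
    path = path, format = format, n_nodes = nrow(net$nodes),
    n_edges = nrow(net$edges),
    self_loops = paste(net$edges$from[self], net$edges$to[self], sep = "->"),
    aliases_mapped = aliases_mapped
  )
  net
}

#' Write a regulatory network to disk
#'
#' @param net A [regulatory_network()] object.
#' @param path Output path.
#' @param format `"sif"` or `"tsv"` (see [read_network()]).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("sif", "tsv")) {
  format <- match.arg(format)
  if (format == "sif") {
    rel <- ifelse(net$edges$sign > 0, "activates", "inhibits")
    writeLines(paste(net$edges$from, rel, net$edges$to, sep = "\t"), path)
  } else {
    nodes <- network_nodes(net)
    m <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    if (nrow(net$edges) > 0) {
      m[cbind(net$edges$from, net$edges$to)] <- net$edges$sign * net$edges$weight
    }
    write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  }
  invisible(path)
}

#' Select the inference node set (transcription factors)
#'
#' Network inference in this package is run between transcription factors
#' only: their action is the most directly reflected in transcript levels and
#' restricting to them keeps the optimization problem small.
#'
#' @param net A [regulatory_network()] object whose nodes carry categories.
#' @return Character vector of transcription-factor node names, in the
#'   network's canonical declaration order.
#' @export
select_inference_nodes <- function(net) {
  stopifnot(inherits(net, "grn_network"))
  tf <- net$nodes$name[net$nodes$category == "transcription_factor"]
  if (length(tf) == 0) {
    stop("network contains no transcription-factor nodes; ",
         "the inference node set would be empty")
  }
  tf
}

#' Build a prior sign matrix from a network
#'
#' Entry (i, j) of the result is the sign of the edge i -> j if present in
#' the network and 0 otherwise.
#'
#' @param net A [regulatory_network()].
#' @param node_order Character vector of node names (subset of the network's
#'   nodes) giving row/column order.
#' @return A `prior_matrix`: a square integer matrix over `node_order` with
#'   entries in {-1, 0, +1}.
#' @export
prior_from_network <- function(net, node_order = network_nodes(net)) {
  stopifnot(inherits(net, "grn_network"))
  node_order <- canonical_gene_names(node_order)
  missing <- setdiff(node_order, network_nodes(net))
  if (length(missing) > 0) {
    stop("node(s) in node_order absent from network: ", paste(missing, collapse = ", "))
  }
  m <- matrix(0L, length(node_order), length(node_order),
              dimnames = list(node_order, node_order))
  e <- net$edges[net$edges$from %in% node_order & net$edges$to %in% node_order, ]
  if (nrow(e) > 0) m[cbind(e$from, e$to)] <- as.integer(e$sign)
  new_prior_matrix(m)
}

#' Construct / validate a prior sign matrix
#'
#' @param values Square numeric matrix with entries in {-1, 0, +1} and gene
#'   names as dimnames.
#' @return The validated matrix with class `prior_matrix`.
#' @export
new_prior_matrix <- function(values) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("prior matrix needs gene names as dimnames")
  }
  if (!identical(rownames(values), colnames(values))) {
    stop("prior matrix row and column order must agree")
  }
  if (!all(values %in% c(-1, 0, 1))) stop("prior entries must be in {-1, 0, +1}")
  storage.mode(values) <- "integer"
  structure(values, class = c("prior_matrix", "matrix", "array"))
}

#' Turn a prior sign matrix into a network
#'
#' Non-zero entries become signed edges (row regulates column).  All nodes are
#' labelled transcription factors, matching the TF-only inference set.
#'
#' @param prior A `prior_matrix`.
#' @return A [regulatory_network()].
#' @export
prior_to_network <- function(prior) {
  nodes <- tibble(name = rownames(prior), category = "transcription_factor")
  idx <- which(prior != 0, arr.ind = TRUE)
  edges <- tibble(from = rownames(prior)[idx[, 1]], to = colnames(prior)[idx[, 2]],
                  sign = as.integer(prior[idx]), weight = 1, kinetics = "slow")
  regulatory_network(nodes, edges)
}

#' Read / write a prior sign matrix (TSV with header row and column)
#' @param path File path.
#' @return `read_prior()` returns a `prior_matrix`; `write_prior()` returns
#'   `path` invisibly.
#' @export
read_prior <- function(path) {
  m <- as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
  rownames(m) <- canonical_gene_names(rownames(m))
  colnames(m) <- canonical_gene_names(colnames(m))
  new_prior_matrix(m)
}

#' @rdname read_prior
#' @param prior A `prior_matrix`.
#' @export
write_prior <- function(prior, path) {
  write.table(unclass(prior), path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}

#' @export
tidy.grn_network <- function(x, ...) x$edges
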