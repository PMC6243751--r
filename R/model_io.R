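# JSON serialization of additive logical models and stable-state reports.

#' Write / read an additive model specification as JSON
#'
#' The JSON records the nodes (with categories), the signed weighted edges
#' with their kinetics class, the activation settings, the marker
#' declarations and any clamps, so that a simulation is fully reproducible
#' from the file.
#'
#' @param model An [additive_model()].
#' @param path Output path.
#' @return `path` invisibly; `read_model_json()` returns the rebuilt model.
#' @export
write_model_json <- function(model, path) {
  spec <- list(
    nodes = model$network$nodes,
    edges = model$network$edges,
    activation = model$activation,
    steepness = model$steepness,
    convergence_tol = model$convergence_tol,
    fast_relaxation_max_iters = model$fast_relaxation_max_iters,
    markers = model$markers,
    clamps = as.list(model$clamps)
  )
  write_json(spec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  spec <- read_json(path, simplifyVector = TRUE)
  net <- regulatory_network(as_tibble(spec$nodes), as_tibble(spec$edges))
  clamps <- unlist(spec$clamps)
  if (is.null(clamps)) clamps <- numeric()
  additive_model(
    net, activation = spec$activation, steepness = spec$steepness,
    convergence_tol = spec$convergence_tol,
    fast_relaxation_max_iters = spec$fast_relaxation_max_iters,
    markers = as.character(unlist(spec$markers)), clamps = clamps
  )
}

fmt6 <- function(x) {
  if (is.numeric(x)) return(trimws(formatC(x, digits = 6, format = "g")))
  x
}

write_result_tsv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt6), check.names = FALSE,
                       stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
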