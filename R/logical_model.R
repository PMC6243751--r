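#' Build an additive multi-valued logical model from a regulatory network
#'
#' The simulator assigns every node two variables in \[0, 1\]: a fast one
#' ("protein activity") and a slow one ("gene expression"); the node's total
#' activity is always their product.  A variable is updated by the activation
#' function applied to the normalized weighted sum of the total activities of
#' its upstream nodes, activators entering positively and inhibitors
#' negatively, restricted to the edges of the variable's kinetics class.
#' Fast reactions have priority: before each (asynchronous) slow update the
#' fast variables are relaxed to a quasi-steady state.
#'
#' Two activation functions are available: a logistic centred at 0 with
#' configurable steepness (giving graded, multi-valued dynamics) and its
#' infinite-steepness limit, a step function that reproduces Boolean
#' behaviour (a zero input holds the current value).
#'
#' @param network A [regulatory_network()]; edge `kinetics` decides the
#'   priority class of each interaction.
#' @param activation `"logistic"` or `"step"`.
#' @param steepness Slope of the logistic at 0 (ignored for `"step"`).
#' @param convergence_tol Fixed-point tolerance.
#' @param fast_relaxation_max_iters Sweep budget for the fast relaxation.
#' @param markers Character vector of marker nodes used to label stable
#'   states (e.g. `c("Sox9", "Runx2")`).
#' @param clamps Named numeric vector of clamped total activities (nodes held
#'   fixed, e.g. by knockout); see [apply_perturbation()].
#' @return An object of class `additive_model`.
#' @export
additive_model <- function(network, activation = c("logistic", "step"),
                           steepness = 10, convergence_tol = 1e-6,
                           fast_relaxation_max_iters = 1000,
                           markers = character(), clamps = numeric()) {
  stopifnot(inherits(network, "grn_network"))
  activation <- match.arg(activation)
  stopifnot(steepness > 0, convergence_tol > 0, fast_relaxation_max_iters >= 1)
  nodes <- network_nodes(network)
  n <- length(nodes)
  idx <- setNames(seq_len(n), nodes)
  markers <- canonical_gene_names(markers)
  stopifnot(all(markers %in% nodes))
  if (length(clamps) > 0) {
    names(clamps) <- canonical_gene_names(names(clamps))
    stopifnot(all(names(clamps) %in% nodes), all(clamps >= 0 & clamps <= 1))
  }
  incoming <- function(kin) {
    e <- network$edges[network$edges$kinetics == kin, , drop = FALSE]
    lapply(seq_len(n), function(i) {
      sub <- e[e$to == nodes[i], , drop = FALSE]
      if (nrow(sub) == 0 || sum(sub$weight) == 0) return(NULL)
      list(src = unname(idx[sub$from]), w = sub$sign * sub$weight,
           wsum = sum(sub$weight))
    })
  }
  structure(list(
    network = network, nodes = nodes,
    in_fast = incoming("fast"), in_slow = incoming("slow"),
    activation = activation, steepness = steepness,
    convergence_tol = convergence_tol,
    fast_relaxation_max_iters = fast_relaxation_max_iters,
    markers = markers, clamps = clamps
  ), class = "additive_model")
}

#' @exportS3Method base::print
print.additive_model <- function(x, ...) {
  cat(sprintf("<additive_model> %d nodes, activation = %s", length(x$nodes),
              x$activation))
  if (x$activation == "logistic") cat(sprintf(" (steepness %g)", x$steepness))
  cat("\n")
  if (length(x$clamps) > 0) {
    cat("  clamped:", paste(sprintf("%s=%g", names(x$clamps), x$clamps),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

activate <- function(model, s, current) {
  if (model$activation == "logistic") return(plogis(model$steepness * s))
  if (s > 0) 1 else if (s < 0) 0 else current
}

clamp_fast_slow <- function(level) {
  # knockout (0) zeroes both variables, any positive clamp keeps the protein
  # fully active and sets expression to the clamp level, so total == level
  c(fast = if (level <= 0) 0 else 1, slow = level)
}

#' Build a system state from per-node initial levels
#'
#' The slow variable carries the initial level and fast starts fully active,
#' except for nodes regulated only through fast edges (there the fast
#' variable carries the level).  Total activity therefore equals the
#' requested level for every node.  Clamped nodes take their clamp value.
#'
#' @param model An [additive_model()].
#' @param values Numeric vector of initial levels in \[0, 1\], named or in
#'   node order.
#' @return A `system_state`: list of named vectors `fast`, `slow`, `total`.
#' @export
initial_state <- function(model, values) {
  n <- length(model$nodes)
  if (!is.null(names(values))) {
    values <- values[model$nodes]
  } else {
    stopifnot(length(values) == n)
  }
  values <- as.numeric(values)
  stopifnot(all(values >= 0 & values <= 1))
  fast <- rep(1, n)
  slow <- values
  fast_only <- vapply(seq_len(n), function(i) {
    !is.null(model$in_fast[[i]]) && is.null(model$in_slow[[i]])
  }, logical(1))
  fast[fast_only] <- values[fast_only]
  slow[fast_only] <- 1
  for (nm in names(model$clamps)) {
    i <- match(nm, model$nodes)
    fs <- clamp_fast_slow(model$clamps[[nm]])
    fast[i] <- fs[["fast"]]; slow[i] <- fs[["slow"]]
  }
  names(fast) <- names(slow) <- model$nodes
  structure(list(fast = fast, slow = slow, total = fast * slow),
            class = "system_state")
}

#' Normalized regulatory input of a node
#'
#' Returns `s = (sum of activator weights x source totals - sum of inhibitor
#' weights x source totals) / (sum of absolute weights)` over the incoming
#' edges of the requested kinetics class, which lies in \[-1, 1\].  A node
#' with no incoming edge of the class returns the current value of the
#' corresponding variable (input nodes hold their level).
#'
#' @param model An [additive_model()].
#' @param state A `system_state`.
#' @param node Node name.
#' @param kinetics `"fast"` or `"slow"`.
#' @return A scalar.
#' @export
regulatory_input <- function(model, state, node, kinetics = c("slow", "fast")) {
  kinetics <- match.arg(kinetics)
  i <- match(canonical_gene_names(node), model$nodes)
  if (is.na(i)) stop("unknown node: ", node)
  inc <- if (kinetics == "fast") model$in_fast[[i]] else model$in_slow[[i]]
  if (is.null(inc)) {
    return(if (kinetics == "fast") state$fast[[i]] else state$slow[[i]])
  }
  sum(inc$w * state$total[inc$src]) / inc$wsum
}

updatable <- function(model, class_list) {
  has_in <- !vapply(class_list, is.null, logical(1))
  clamped <- model$nodes %in% names(model$clamps)
  which(has_in & !clamped)
}

relax_fast <- function(model, state) {
  cand <- updatable(model, model$in_fast)
  if (length(cand) == 0) {
    attr(state, "fast_converged") <- TRUE
    return(state)
  }
  tol <- model$convergence_tol
  converged <- FALSE
  for (it in seq_len(model$fast_relaxation_max_iters)) {
    ord <- cand[sample.int(length(cand))]
    maxd <- 0
    for (i in ord) {
      inc <- model$in_fast[[i]]
      s <- sum(inc$w * state$total[inc$src]) / inc$wsum
      val <- activate(model, s, state$fast[[i]])
      if (!is.finite(val)) stop("non-finite fast value for node ", model$nodes[i])
      maxd <- max(maxd, abs(val - state$fast[[i]]))
      state$fast[[i]] <- val
      state$total[[i]] <- val * state$slow[[i]]
    }
    if (maxd <= tol) { converged <- TRUE; break }
  }
  attr(state, "fast_converged") <- converged
  state
}

#' One asynchronous macro-step of the logical model
#'
#' Applies the priority-class scheduler: (1) fast variables are relaxed by
#' random-order asynchronous updates until no fast variable moves by more
#' than `convergence_tol` (or the sweep budget is hit, which flags the state
#' via attribute `"fast_converged"`); (2) exactly one randomly chosen slow
#' variable is updated.  Clamped nodes are never touched and totals are
#' recomputed as fast x slow.
#'
#' @param model An [additive_model()].
#' @param state A `system_state`.
#' @param seed Optional integer seed making the step reproducible.
#' @return The updated `system_state`.
#' @export
update_step <- function(model, state, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- relax_fast(model, state)
  if (!isTRUE(attr(state, "fast_converged"))) return(state)
  cand <- updatable(model, model$in_slow)
  if (length(cand) > 0) {
    i <- cand[sample.int(length(cand), 1L)]
    inc <- model$in_slow[[i]]
    s <- sum(inc$w * state$total[inc$src]) / inc$wsum
    val <- activate(model, s, state$slow[[i]])
    if (!is.finite(val)) stop("non-finite slow value for node ", model$nodes[i])
    state$slow[[i]] <- val
    state$total[[i]] <- state$fast[[i]] * val
  }
  state
}

#' Fixed-point certificate
#'
#' Checks that re-evaluating every unclamped fast and slow variable moves
#' none of them by more than `convergence_tol`.
#'
#' @inheritParams update_step
#' @return Logical scalar.
#' @export
is_fixed_point <- function(model, state) {
  tol <- model$convergence_tol
  for (i in updatable(model, model$in_fast)) {
    inc <- model$in_fast[[i]]
    s <- sum(inc$w * state$total[inc$src]) / inc$wsum
    if (abs(activate(model, s, state$fast[[i]]) - state$fast[[i]]) > tol) return(FALSE)
  }
  for (i in updatable(model, model$in_slow)) {
    inc <- model$in_slow[[i]]
    s <- sum(inc$w * state$total[inc$src]) / inc$wsum
    if (abs(activate(model, s, state$slow[[i]]) - state$slow[[i]]) > tol) return(FALSE)
  }
  TRUE
}

marker_label <- function(model, total) {
  if (length(model$markers) == 0) return("")
  pos <- model$markers[total[model$markers] > 0.5]
  if (length(pos) == 0) return("none")
  paste0(pos, "+", collapse = "")
}

#' Discover stable states and their basins of attraction
#'
#' Simulates the asynchronous dynamics from a battery of initial conditions:
#' all Boolean corners of the unclamped nodes when there are no more corners
#' than `n_initial_states`, otherwise uniform random states.  Trajectories
#' that pass the fixed-point certificate are grouped (within a small state
#' tolerance) into stable states; each state's `basin_fraction` is the share
#' of initial conditions that reached it, so the fractions over all
#' discovered states sum to at most 1.  Non-converged trajectories trigger a
#' warning and are reported in the `non_converged_fraction` attribute.
#'
#' @param model An [additive_model()].
#' @param n_initial_states Number of initial conditions (>= 1).
#' @param max_steps Macro-step budget per trajectory; defaults to
#'   `10 * n_nodes^2` (at least 50).
#' @param seed Integer seed; fixed seed gives identical results.
#' @param group_tol State-matching tolerance used to group endpoints.
#' @return A tibble of class `stable_states`: one row per stable state with
#'   `label`, `basin_fraction`, `n_reached` and one `total_<node>` column per
#'   node; full states are kept in the `"states"` attribute.
#' @export
find_stable_states <- function(model, n_initial_states = 64, max_steps = NULL,
                               seed = 1, group_tol = 1e-4) {
  stopifnot(n_initial_states >= 1)
  n <- length(model$nodes)
  free <- setdiff(model$nodes, names(model$clamps))
  k <- length(free)
  if (is.null(max_steps)) max_steps <- max(50L, 10L * n^2)
  with_seed(seed, {
    if (k == 0) {
      inits <- matrix(0, 1, 0)
    } else if (2^k <= n_initial_states) {
      inits <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
    } else {
      inits <- matrix(runif(n_initial_states * k), ncol = k)
    }
    colnames(inits) <- free
    n_init <- nrow(inits)
    endpoints <- vector("list", n_init)
    converged <- logical(n_init)
    for (r in seq_len(n_init)) {
      vals <- setNames(rep(0, n), model$nodes)
      vals[free] <- inits[r, ]
      st <- initial_state(model, vals)
      for (step in seq_len(max_steps + 1L)) {
        if (is_fixed_point(model, st)) { converged[r] <- TRUE; break }
        st <- update_step(model, st)
        if (!isTRUE(attr(st, "fast_converged"))) break
      }
      endpoints[[r]] <- st
    }
  })
  reps <- list(); counts <- integer()
  for (r in which(converged)) {
    sig <- c(endpoints[[r]]$fast, endpoints[[r]]$slow)
    hit <- 0L
    for (g in seq_along(reps)) {
      if (max(abs(sig - reps[[g]]$sig)) <= group_tol) { hit <- g; break }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- list(sig = sig, state = endpoints[[r]])
      counts <- c(counts, 1L)
    } else {
      counts[hit] <- counts[hit] + 1L
    }
  }
  ncf <- 1 - sum(converged) / n_init
  if (ncf > 0) {
    warning(sprintf("%.1f%% of trajectories did not converge within max_steps",
                    100 * ncf))
  }
  totals <- do.call(rbind, lapply(reps, function(r) r$state$total))
  out <- tibble(
    state_id = seq_along(reps),
    label = vapply(reps, function(r) marker_label(model, r$state$total),
                   character(1)),
    basin_fraction = counts / n_init,
    n_reached = counts
  )
  if (length(reps) > 0) {
    tot_tbl <- as_tibble(totals, .name_repair = "minimal")
    names(tot_tbl) <- paste0("total_", model$nodes)
    out <- bind_cols(out, tot_tbl)
  }
  out <- arrange(out, desc(.data$basin_fraction), .data$state_id)
  attr(out, "states") <- lapply(reps, `[[`, "state")[out$state_id]
  attr(out, "non_converged_fraction") <- ncf
  attr(out, "n_initial_states") <- n_init
  class(out) <- c("stable_states", class(out))
  out
}

#' Clamp a node at a fixed total activity
#'
#' The clamped node is removed from the update schedule: its total activity
#' never deviates from the clamp value in any trajectory.
#'
#' @param model An [additive_model()].
#' @param node Node name.
#' @param level Clamp level in \[0, 1\].
#' @return A modified copy of the model.
#' @export
clamp_node <- function(model, node, level) {
  node <- canonical_gene_names(node)
  if (!node %in% model$nodes) stop("unknown node: ", node)
  stopifnot(level >= 0, level <= 1)
  clamps <- model$clamps
  clamps[node] <- level
  additive_model(model$network,
                 activation = model$activation, steepness = model$steepness,
                 convergence_tol = model$convergence_tol,
                 fast_relaxation_max_iters = model$fast_relaxation_max_iters,
                 markers = model$markers, clamps = clamps)
}

#' Apply an in silico perturbation (knockout or over-activation)
#'
#' Knockout clamps the node's fast and slow variables at 0, over-activation
#' at 1; the clamped node is never updated during simulation.  The operation
#' is idempotent.
#'
#' @param model An [additive_model()].
#' @param node Node to perturb.
#' @param mode `"knockout"` or `"overactivation"`.
#' @return A modified copy of the model.
#' @export
apply_perturbation <- function(model, node, mode = c("knockout", "overactivation")) {
  mode <- match.arg(mode)
  clamp_node(model, node, if (mode == "knockout") 0 else 1)
}

marker_positive_basin <- function(model, states, marker) {
  marker <- canonical_gene_names(marker)
  col <- paste0("total_", marker)
  if (nrow(states) == 0) return(0)
  rivals <- setdiff(model$markers, marker)
  pos <- states[[col]] > 0.5
  if (length(rivals) > 0) {
    for (rv in rivals) pos <- pos & states[[paste0("total_", rv)]] <= 0.5
  }
  sum(states$basin_fraction[pos])
}

#' Single-node perturbation screen
#'
#' Runs [find_stable_states()] for the unperturbed model and for every
#' single-node knockout and over-activation, reporting for each run the
#' basin fraction of the marker-positive stable state (marker total > 0.5,
#' rival markers <= 0.5).  A factor is flagged `required` when the
#' marker-positive state disappears under its knockout.
#'
#' @param model An [additive_model()].
#' @param marker Marker node defining the phenotype of interest.
#' @param seed Integer seed reused for every run (reproducible screen).
#' @param ... Passed on to [find_stable_states()].
#' @return A tibble with columns `node`, `mode`, `marker_basin`, `reachable`
#'   and `required`; the first row (`mode == "none"`) is the unperturbed
#'   reference.
#' @export
perturbation_screen <- function(model, marker, seed = 1, ...) {
  marker <- canonical_gene_names(marker)
  if (!marker %in% model$nodes) stop("unknown marker node: ", marker)
  one <- function(m, node, mode) {
    ss <- suppressWarnings(find_stable_states(m, seed = seed, ...))
    basin <- marker_positive_basin(model, ss, marker)
    tibble(node = node, mode = mode, marker_basin = basin,
           reachable = basin > 0,
           required = identical(mode, "knockout") && basin == 0)
  }
  rows <- list(one(model, NA_character_, "none"))
  for (nd in model$nodes) {
    rows <- c(rows,
              list(one(apply_perturbation(model, nd, "knockout"), nd, "knockout")),
              list(one(apply_perturbation(model, nd, "overactivation"), nd,
                       "overactivation")))
  }
  bind_rows(rows)
}

#' Dose-response analysis of an input node
#'
#' Clamps `input_node` at each requested level and re-runs the stable-state
#' search, tabulating how the attractor landscape (labels and basin
#' fractions) responds to the stimulus level.
#'
#' @param model An [additive_model()].
#' @param input_node Node receiving the stimulus.
#' @param levels Numeric vector of clamp levels in \[0, 1\] (non-empty).
#' @param seed Integer seed reused across levels.
#' @param ... Passed on to [find_stable_states()].
#' @return A tibble with columns `level`, `label`, `basin_fraction` and the
#'   per-node totals of each stable state.
#' @export
dose_response <- function(model, input_node, levels, seed = 1, ...) {
  if (length(levels) == 0) stop("empty level list")
  stopifnot(all(levels >= 0 & levels <= 1))
  out <- lapply(levels, function(lv) {
    ss <- suppressWarnings(
      find_stable_states(clamp_node(model, input_node, lv), seed = seed, ...))
    mutate(as_tibble(ss), level = lv, .before = 1)
  })
  bind_rows(out)
}
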