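# Ground-truth network and expression-data generator emulating a multi-study
# growth-plate design: multifactorial replicates, knockout panels, zonal
# gradients (resting -> proliferating -> maturing -> hypertrophic) and
# treatment/control contrasts, all simulated from a known network so that
# inference, consensus, prior integration and evaluation are testable
# without external data.

GROWTH_PLATE_ZONES <- c("resting", "proliferating", "maturing", "hypertrophic")

#' Generate a random ground-truth regulatory network
#'
#' Samples a signed directed graph without self-loops: each ordered non-self
#' pair carries an edge with probability `edge_density` (expected edge count
#' `density * n * (n - 1)`), the sign is +1 with probability
#' `activating_fraction`, and weights are uniform on \[0.5, 1\].  Graphs with
#' an isolated node are resampled (bounded retries) so that every gene can in
#' principle be recovered by inference.  All nodes are labelled transcription
#' factors.
#'
#' @param n_genes Number of genes (default 13, the growth-plate inference
#'   set size).
#' @param edge_density Edge probability per ordered pair, in (0, 1).
#' @param activating_fraction Probability that an edge is activating.
#' @param seed Integer seed (mandatory for reproducibility).
#' @param max_tries Resampling budget for the no-isolated-node constraint.
#' @return A [regulatory_network()].
#' @export
generate_network <- function(n_genes = 13, edge_density = 0.15,
                             activating_fraction = 0.5, seed = 1,
                             max_tries = 100) {
  stopifnot(n_genes >= 2, edge_density > 0, edge_density < 1,
            activating_fraction >= 0, activating_fraction <= 1)
  if (edge_density * n_genes * (n_genes - 1) < 1) {
    stop("requested density yields an expected empty graph")
  }
  genes <- sprintf("G%02d", seq_len(n_genes))
  grid <- all_pairs(genes, directed = TRUE)
  with_seed(seed, {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      keep <- runif(nrow(grid)) < edge_density
      incident <- unique(c(grid$from[keep], grid$to[keep]))
      if (sum(keep) >= 1 && length(incident) == n_genes) { ok <- TRUE; break }
    }
    if (!ok) {
      stop("could not sample a network without isolated nodes; ",
           "increase edge_density")
    }
    e <- grid[keep, , drop = FALSE]
    e$sign <- ifelse(runif(nrow(e)) < activating_fraction, 1L, -1L)
    e$weight <- runif(nrow(e), 0.5, 1)
  })
  e$kinetics <- "slow"
  regulatory_network(tibble(name = genes, category = "transcription_factor"), e)
}

# signed weighted adjacency (target x source), scaled to spectral radius 0.8
# so that the steady state x = Wx + u has a unique solution
interaction_matrix <- function(truth, radius = 0.8) {
  nodes <- network_nodes(truth)
  W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  e <- truth$edges
  if (nrow(e) > 0) W[cbind(e$to, e$from)] <- e$sign * e$weight
  rho <- max(Mod(eigen(W, only.values = TRUE)$values))
  if (rho > 0) W <- W * (radius / rho)
  rho2 <- max(Mod(eigen(W, only.values = TRUE)$values))
  if (rho2 >= 1) stop("interaction matrix spectral radius >= 1 after scaling")
  W
}

driver_genes <- function(truth) {
  nodes <- network_nodes(truth)
  with_in <- unique(truth$edges$to)
  drivers <- setdiff(nodes, with_in)
  if (length(drivers) == 0) drivers <- nodes[1]
  drivers
}

#' Simulate expression data from a ground-truth network
#'
#' Steady-state linear-Gaussian generator: for every sample the expression
#' vector solves `x = W x + p + e`, where `W` is the signed weighted
#' adjacency scaled to spectral radius 0.8, `p` a design-dependent
#' perturbation and `e` iid Gaussian noise with standard deviation
#' `noise_sd`.  Designs:
#'
#' * `"multifactorial"`: all genes receive small random perturbations
#'   (sd `perturb_sd`) in every sample — replicate/patient-style data.
#' * `"knockout"`: each sample clamps one gene at exactly 0 (cycling through
#'   the genes), the rest receive multifactorial perturbations.
#' * `"zones"`: the network's input (driver) genes are shifted along an
#'   ordered gradient over the growth-plate zones, `n_replicates` samples
#'   per zone.
#' * `"treatment"`: half the samples receive a treatment shift
#'   (`treatment_effect` on the driver genes), half are controls.
#'
#' Sample metadata (study, zone, treatment, replicate) is filled per design.
#'
#' @param truth A [regulatory_network()] ground truth (non-empty).
#' @param design Study design (see above).
#' @param n_samples Number of samples (multifactorial/knockout/treatment).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param perturb_sd Perturbation standard deviation for multifactorial-style
#'   sampling.
#' @param n_replicates Replicates per zone (zones design).
#' @param zones Ordered zone labels (zones design).
#' @param treatment_effect Driver shift applied to treated samples.
#' @param study Study label written to the metadata.
#' @param seed Integer seed.
#' @param perturbations Optional genes x samples matrix overriding the random
#'   perturbations (multifactorial design only).
#' @return An [expression_set()].
#' @export
simulate_expression <- function(truth,
                                design = c("multifactorial", "knockout",
                                           "zones", "treatment"),
                                n_samples = 60, noise_sd = 0.25,
                                perturb_sd = 1, n_replicates = 2,
                                zones = GROWTH_PLATE_ZONES,
                                treatment_effect = 1, study = "S1", seed = 1,
                                perturbations = NULL) {
  design <- match.arg(design)
  stopifnot(inherits(truth, "grn_network"), nrow(truth$nodes) > 0,
            noise_sd >= 0, n_samples >= 1)
  nodes <- network_nodes(truth)
  n <- length(nodes)
  W <- interaction_matrix(truth)
  IW <- diag(n) - W
  drivers <- driver_genes(truth)
  solve_sample <- function(p, eps, ko = NULL) {
    if (is.null(ko)) return(solve(IW, p + eps))
    free <- setdiff(seq_len(n), ko)
    x <- numeric(n)
    x[free] <- solve(IW[free, free, drop = FALSE], (p + eps)[free])
    x
  }
  with_seed(seed, {
    if (design == "zones") {
      n_samples <- length(zones) * n_replicates
      meta <- tibble(
        zone = rep(zones, each = n_replicates),
        replicate = rep(seq_len(n_replicates), times = length(zones)),
        treatment = ""
      )
      grad <- seq(-1, 1, length.out = length(zones)) * perturb_sd
      P <- matrix(0, n, n_samples)
      P[match(drivers, nodes), ] <- rep(rep(grad, each = n_replicates),
                                        each = length(drivers))
      ko_idx <- rep(list(NULL), n_samples)
    } else if (design == "treatment") {
      treated <- seq_len(n_samples) > n_samples / 2
      meta <- tibble(
        zone = "",
        replicate = ave(seq_len(n_samples), treated, FUN = seq_along),
        treatment = ifelse(treated, "treated", "control")
      )
      P <- matrix(rnorm(n * n_samples, 0, perturb_sd * 0.2), n, n_samples)
      P[match(drivers, nodes), treated] <-
        P[match(drivers, nodes), treated] + treatment_effect
      ko_idx <- rep(list(NULL), n_samples)
    } else if (design == "knockout") {
      ko_gene <- rep_len(seq_len(n), n_samples)
      meta <- tibble(
        zone = "",
        replicate = ave(ko_gene, ko_gene, FUN = seq_along),
        treatment = paste0("KO:", nodes[ko_gene])
      )
      P <- matrix(rnorm(n * n_samples, 0, perturb_sd), n, n_samples)
      ko_idx <- as.list(ko_gene)
    } else {
      meta <- tibble(zone = "", replicate = seq_len(n_samples), treatment = "")
      if (is.null(perturbations)) {
        P <- matrix(rnorm(n * n_samples, 0, perturb_sd), n, n_samples)
      } else {
        stopifnot(nrow(perturbations) == n, ncol(perturbations) == n_samples)
        P <- perturbations
      }
      ko_idx <- rep(list(NULL), n_samples)
    }
    E <- matrix(rnorm(n * n_samples, 0, noise_sd), n, n_samples)
    X <- matrix(0, n, n_samples, dimnames = list(nodes, NULL))
    for (s in seq_len(n_samples)) {
      X[, s] <- solve_sample(P[, s], E[, s], ko = ko_idx[[s]])
    }
  })
  colnames(X) <- sprintf("%s_%02d", study, seq_len(n_samples))
  meta <- mutate(meta, sample_id = colnames(X), study = study, .before = 1)
  expression_set(X, meta)
}

#' Generate a complete synthetic benchmark dataset
#'
#' Bundles [generate_network()] and [simulate_expression()] into one call:
#' a known ground-truth network plus expression data simulated from it, with
#' the generator configuration kept as provenance.
#'
#' @inheritParams generate_network
#' @inheritParams simulate_expression
#' @return A list of class `synthetic_dataset` with elements `truth`
#'   (network), `expr` ([expression_set()]) and `config`.
#' @export
generate_dataset <- function(n_genes = 13, edge_density = 0.15,
                             activating_fraction = 0.5,
                             design = "multifactorial", n_samples = 60,
                             noise_sd = 0.25, perturb_sd = 1, seed = 1) {
  truth <- generate_network(n_genes, edge_density, activating_fraction,
                            seed = seed)
  expr <- simulate_expression(truth, design = design, n_samples = n_samples,
                              noise_sd = noise_sd, perturb_sd = perturb_sd,
                              seed = seed + 10000L)
  structure(list(
    truth = truth, expr = expr,
    config = list(n_genes = n_genes, edge_density = edge_density,
                  activating_fraction = activating_fraction, design = design,
                  n_samples = n_samples, noise_sd = noise_sd,
                  perturb_sd = perturb_sd, seed = seed)
  ), class = "synthetic_dataset")
}

#' Simulate a multi-study growth-plate compendium
#'
#' Emulates the layout of the published growth-plate microarray compendium:
#' five studies mixing treatment/control contrasts and zonal dissections
#' (12 + 8 + 15 + 12 + 18 samples), all simulated from the same ground-truth
#' network and concatenated with per-study metadata.
#'
#' @param truth A [regulatory_network()]; defaults to a 13-gene random
#'   network.
#' @param noise_sd,perturb_sd Generator noise levels.
#' @param seed Integer seed.
#' @return An [expression_set()] with 65 samples across 5 studies.
#' @export
simulate_growth_plate_study <- function(truth = generate_network(seed = seed),
                                        noise_sd = 0.25, perturb_sd = 1,
                                        seed = 1) {
  z3 <- c("resting/proliferating", "maturing/hypertrophic", "mineralising")
  parts <- list(
    simulate_expression(truth, "treatment", n_samples = 12, study = "S1",
                        noise_sd = noise_sd, perturb_sd = perturb_sd,
                        seed = seed + 1L),
    simulate_expression(truth, "zones", n_replicates = 2, study = "S2",
                        noise_sd = noise_sd, perturb_sd = perturb_sd,
                        seed = seed + 2L),
    simulate_expression(truth, "treatment", n_samples = 15, study = "S3",
                        noise_sd = noise_sd, perturb_sd = perturb_sd,
                        seed = seed + 3L),
    simulate_expression(truth, "zones", zones = z3, n_replicates = 4,
                        study = "S4", noise_sd = noise_sd,
                        perturb_sd = perturb_sd, seed = seed + 4L),
    simulate_expression(truth, "zones", zones = z3, n_replicates = 6,
                        study = "S5", noise_sd = noise_sd,
                        perturb_sd = perturb_sd, seed = seed + 5L)
  )
  values <- do.call(cbind, lapply(parts, function(p) p$values))
  meta <- bind_rows(lapply(parts, function(p) p$samples))
  expression_set(values, meta)
}

#' The packaged growth-plate inference fixture
#'
#' Returns the canonical 13-gene transcription-factor set used for
#' growth-plate network inference together with the curated prior sign
#' matrix: the nine known directed interactions
#' (MEF2C -> Runx2 +, Runx2 -> MEF2C +, Ets1 -> dEF1 +, ATF2 -> CCND1 +,
#' Sox9 -> Runx2 -, Runx2 -> Sox9 -, MEF2C -> Dlx5 +, NFkB -> Sox9 +,
#' NFkB -> HIF2a +); every other entry is 0.
#'
#' @return A list with elements `genes` (character vector of 13 canonical
#'   names) and `prior` (a 13 x 13 `prior_matrix`).
#' @export
#' @examples
#' fx <- growth_plate_fixture()
#' fx$genes
growth_plate_fixture <- function() {
  genes <- c("Gli2", "Tcf7", "Runx2", "Sox9", "MEF2C", "STAT1", "ATF2",
             "NFkB", "CCND1", "Dlx5", "Ets1", "dEF1", "HIF2a")
  m <- matrix(0L, 13, 13, dimnames = list(genes, genes))
  set_sign <- function(from, to, s) m[from, to] <<- as.integer(s)
  set_sign("MEF2C", "Runx2", +1)
  set_sign("Runx2", "MEF2C", +1)
  set_sign("Ets1", "dEF1", +1)
  set_sign("ATF2", "CCND1", +1)
  set_sign("Sox9", "Runx2", -1)
  set_sign("Runx2", "Sox9", -1)
  set_sign("MEF2C", "Dlx5", +1)
  set_sign("NFkB", "Sox9", +1)
  set_sign("NFkB", "HIF2a", +1)
  list(genes = genes, prior = new_prior_matrix(m))
}
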