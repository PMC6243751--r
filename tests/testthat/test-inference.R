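test_that("correlation confidences match hand-computed Pearson r", {
  A <- c(1, 2, 3, 4)
  B <- 2 * A
  C <- c(2, 1, 4, 3)
  m <- rbind(A = A, B = B, C = C)
  cm <- infer_correlation(m, "pearson")
  expect_symmetric_cm(cm)
  expect_equal(cm["A", "B"], 1)
  # hand arithmetic on the 4 points of (A, C)
  r_hand <- sum((A - mean(A)) * (C - mean(C))) /
    sqrt(sum((A - mean(A))^2) * sum((C - mean(C))^2))
  expect_equal(cm["A", "C"], abs(r_hand))
  # constructed zero-correlation pair
  D <- c(1, -1, -1, 1)
  E <- c(1, 1, -1, -1)
  cm0 <- infer_correlation(rbind(D = D, E = E, F = rnorm(4)), "pearson")
  expect_equal(cm0["D", "E"], 0)
  # zero-variance gene is refused by name
  expect_error(infer_correlation(rbind(A = A, Z = rep(1, 4))), "Z")
})

test_that("mutual information matches the plug-in formula and its limits", {
  # identical fair binary profiles carry exactly one bit
  x <- c(0, 0, 0, 1, 1, 1)
  cm <- infer_mutual_information(rbind(A = x, B = x), n_bins = 2)
  expect_equal(cm["A", "B"], 1)
  # hand computation from a printed 2x2 joint count table:
  # counts (a=0,b=0)=3, (0,1)=1, (1,0)=1, (1,1)=3
  a <- c(0, 0, 0, 0, 1, 1, 1, 1)
  b <- c(0, 0, 0, 1, 0, 1, 1, 1)
  p <- c(3, 1, 1, 3) / 8
  mi_hand <- sum(p * log2(p / c(0.5 * 0.5, 0.5 * 0.5, 0.5 * 0.5, 0.5 * 0.5)))
  cm2 <- infer_mutual_information(rbind(A = a, B = b), n_bins = 2)
  expect_equal(cm2["A", "B"], mi_hand)
  # MI is exactly symmetric
  set.seed(1)
  m <- matrix(rnorm(5 * 30), 5, dimnames = list(letters[1:5], NULL))
  cm3 <- infer_mutual_information(m, n_bins = 3)
  expect_symmetric_cm(cm3)
  # constant gene cannot be binned
  expect_error(infer_mutual_information(rbind(A = rep(1, 10), B = rnorm(10))),
               "degenerate binning.*A")
})

test_that("CLR matches an independent step-by-step recomputation", {
  set.seed(7)
  m <- matrix(rnorm(4 * 40), 4, dimnames = list(c("A", "B", "C", "D"), NULL))
  m["B", ] <- m["A", ] + 0.2 * rnorm(40)
  mi <- unclass(infer_mutual_information(m, n_bins = 4))
  clr <- unclass(infer_clr(m, n_bins = 4))
  for (i in 1:3) {
    for (j in (i + 1):4) {
      zi <- (mi[i, j] - mean(mi[i, -i])) / sd(mi[i, -i])
      zj <- (mi[i, j] - mean(mi[j, -j])) / sd(mi[j, -j])
      expect_equal(clr[i, j], sqrt(max(0, zi)^2 + max(0, zj)^2))
    }
  }
  # the uniquely strongest MI pair keeps the top CLR rank
  expect_equal(which.max(clr[upper.tri(clr)]), which.max(mi[upper.tri(mi)]))
})

test_that("ARACNE prunes exactly the weak triangle edges", {
  m <- chain_expression(n = 300, seed = 9, noise = 0.2)[1:3, ]
  mi <- cm_mat(infer_mutual_information(m))
  ar <- cm_mat(infer_aracne(m, dpi_tolerance = 0))
  # brute-force DPI over the single triple: (A, C) is the weakest edge
  expect_lt(mi["A", "C"], min(mi["A", "B"], mi["B", "C"]))
  expect_equal(ar["A", "C"], 0)
  expect_equal(ar["A", "B"], mi["A", "B"])
  expect_equal(ar["B", "C"], mi["B", "C"])
  # tolerance 1 disables pruning entirely
  expect_equal(cm_mat(infer_aracne(m, dpi_tolerance = 1)), mi)
  # ARACNE output never exceeds MI entrywise
  m4 <- chain_expression(n = 120, seed = 2)
  expect_true(all(unclass(infer_aracne(m4)) <= unclass(infer_mutual_information(m4))))
})

test_that("MRNETB reduces to MI for two genes and penalizes redundancy", {
  set.seed(3)
  two <- matrix(rnorm(2 * 40), 2, dimnames = list(c("A", "B"), NULL))
  expect_equal(cm_mat(infer_mrnetb(two, n_bins = 4)),
               cm_mat(infer_mutual_information(two, n_bins = 4)))
  # a duplicated regulator never outscores the original
  x <- rnorm(60)
  m <- rbind(T = x + 0.3 * rnorm(60), R = x, Rdup = x)
  sc <- unclass(infer_mrnetb(m, n_bins = 4))
  expect_lte(sc["Rdup", "T"], sc["R", "T"] + 1e-12)
  # 3-gene scores match step-by-step MRMR arithmetic
  m3 <- chain_expression(n = 100, seed = 5)[1:3, ]
  mi <- unclass(infer_mutual_information(m3, n_bins = 4))
  got <- cm_mat(infer_mrnetb(m3, n_bins = 4))
  hand <- matrix(0, 3, 3, dimnames = dimnames(mi))
  for (t in 1:3) {
    cand <- setdiff(1:3, t)
    first <- cand[which.max(mi[cand, t])]
    second <- setdiff(cand, first)
    hand[first, t] <- mi[first, t]
    hand[second, t] <- mi[second, t] - mi[second, first]
  }
  expect_equal(got, pmax(hand, t(hand), 0))
})

test_that("tree-ensemble importances find the dominant predictor reproducibly", {
  set.seed(11)
  x <- rnorm(60)
  m <- rbind(T = x, R = x, N1 = rnorm(60), N2 = rnorm(60))
  cm <- infer_tree_ensemble(m, n_trees = 100, seed = 4)
  expect_true(attr(cm, "directed"))
  expect_equal(unname(which.max(unclass(cm)[, "T"])), 2)
  expect_equal(sum(unclass(cm)[, "T"]), 1)
  # single candidate regressor takes all the importance
  cm2 <- infer_tree_ensemble(m[1:2, ], n_trees = 50, seed = 4)
  expect_equal(unclass(cm2)["R", "T"], 1)
  # bit-reproducible under the seed
  again <- infer_tree_ensemble(m, n_trees = 100, seed = 4)
  expect_identical(unclass(cm), unclass(again))
})

test_that("stability selection saturates on a duplicated profile and is seeded", {
  set.seed(21)
  x <- rnorm(40)
  m <- rbind(T = x, R = x, N1 = rnorm(40), N2 = rnorm(40), N3 = rnorm(40))
  cm <- infer_stability_regression(m, n_resamples = 20, seed = 8)
  expect_equal(unclass(cm)["R", "T"], 1)
  expect_identical(unclass(infer_stability_regression(m, n_resamples = 20, seed = 8)),
                   unclass(cm))
  # pure-noise regulators at stringent sparsity stay rarely selected: with
  # one path entry allowed per resample the selection mass spreads over the
  # nine candidate regulators
  set.seed(31)
  freqs <- vapply(1:20, function(s) {
    noise <- matrix(rnorm(10 * 40), 10,
                    dimnames = list(paste0("g", 1:10), NULL))
    cm <- infer_stability_regression(noise, n_resamples = 10,
                                     selection_fraction = 0.1, seed = s)
    mean(unclass(cm)[cbind(seq(2, 10), rep(1, 9))])
  }, numeric(1))
  expect_lt(mean(freqs), 0.2)
})

test_that("partial correlation removes the indirect chain edge", {
  m <- chain_expression(n = 200)[1:3, ]
  pc <- unclass(infer_partial_correlation(m))
  raw <- abs(cor(t(m)))
  expect_gt(raw["A", "C"], 0.3)
  expect_lt(pc["A", "C"], 0.1)
  # two genes: partial correlation equals |Pearson| exactly at zero shrinkage
  two <- m[1:2, 1:50]
  expect_equal(unclass(infer_partial_correlation(two, shrinkage = 0))["A", "B"],
               abs(cor(two["A", ], two["B", ])))
  # automatic shrinkage only attenuates it toward zero
  auto_ab <- unclass(infer_partial_correlation(two))["A", "B"]
  expect_lte(auto_ab, abs(cor(two["A", ], two["B", ])))
  expect_equal(auto_ab, abs(cor(two["A", ], two["B", ])), tolerance = 0.1)
  # uncorrelated data yield near-zero partial correlations
  set.seed(17)
  ind <- matrix(rnorm(4 * 500), 4, dimnames = list(letters[1:4], NULL))
  expect_lt(max(unclass(infer_partial_correlation(ind))), 0.15)
})

test_that("Bayesian scoring tracks dependence and respects its gates", {
  set.seed(13)
  x <- rnorm(100)
  dep <- rbind(A = x, B = x + 0.2 * rnorm(100))
  ind <- rbind(A = rnorm(100), B = rnorm(100))
  cd <- unclass(infer_bayesian_score(dep, n_bins = 3, max_parents = 1))
  ci <- unclass(infer_bayesian_score(ind, n_bins = 3, max_parents = 1))
  expect_gt(cd["A", "B"], ci["A", "B"])
  expect_gt(cd["B", "A"], ci["B", "A"])
  # independent genes at large n have near-zero confidences
  set.seed(14)
  big <- matrix(rnorm(3 * 500), 3, dimnames = list(letters[1:3], NULL))
  expect_lt(max(unclass(infer_bayesian_score(big, max_parents = 1))), 0.1)
  # no parents allowed -> all-zero matrix
  expect_true(all(unclass(infer_bayesian_score(dep, max_parents = 0)) == 0))
  too_big <- matrix(rnorm(16 * 20), 16,
                    dimnames = list(sprintf("g%02d", 1:16), NULL))
  expect_error(infer_bayesian_score(too_big), "15 genes")
})
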