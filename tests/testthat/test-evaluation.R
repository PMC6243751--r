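gold5 <- function() {
  regulatory_network(
    data.frame(name = LETTERS[1:5], category = "transcription_factor"),
    data.frame(from = c("A", "B", "C", "D"), to = c("B", "C", "D", "E"),
               sign = 1)
  )
}

test_that("label_predictions applies the either-direction rule and completes", {
  gold <- regulatory_network(data.frame(name = c("A", "B", "C")),
                             data.frame(from = "A", to = "B", sign = 1))
  pred <- tibble::tibble(from = "B", to = "A", score = 1)
  lab <- label_predictions(pred, gold, "undirected")
  expect_equal(nrow(lab), 3)  # all unordered pairs over {A,B,C}
  expect_true(lab$label[lab$from == "A" & lab$to == "B"])
  expect_equal(sum(is.infinite(lab$score)), 2)
  # symmetric in pair orientation
  lab2 <- label_predictions(tibble::tibble(from = "A", to = "B", score = 1),
                            gold, "undirected")
  expect_equal(lab, lab2)
  expect_error(label_predictions(tibble::tibble(from = "A", to = "Z", score = 1),
                                 gold, "undirected"), "Z")
})

test_that("perfect and inverted rankings bound the AUROC", {
  expect_equal(roc_auroc(c(TRUE, TRUE, FALSE, FALSE))$auroc, 1)
  expect_equal(roc_auroc(c(FALSE, FALSE, TRUE, TRUE))$auroc, 0)
  expect_error(roc_auroc(c(TRUE, TRUE)), "negative")
})

test_that("hand-worked 4-label curves give AUROC 0.75 and AUPR 5/6", {
  labels <- c(TRUE, FALSE, TRUE, FALSE)
  roc <- roc_auroc(labels)
  expect_equal(roc$auroc, 0.75)
  expect_equal(roc$roc_points$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(roc$roc_points$tpr, c(0, 0.5, 0.5, 1, 1))
  pr <- pr_aupr(labels)
  expect_equal(pr$aupr, 1 * 0.5 + (2 / 3) * 0.5)
  expect_true(all(c(1, 2 / 3) %in% pr$pr_points$precision[pr$pr_points$recall > 0]))
})

test_that("AUROC equals the Mann-Whitney oracle on random tied instances", {
  set.seed(123)
  for (i in 1:40) {
    n <- sample(10:40, 1)
    score <- sample(1:6, n, replace = TRUE)  # heavy ties
    label <- runif(n) < 0.4
    if (!any(label) || all(label)) next
    got <- roc_auroc(tibble::tibble(score = score, label = label))$auroc
    expect_equal(got, mw_auroc(score, label))
  }
})

test_that("random rankings average an AUROC of one half", {
  set.seed(99)
  vals <- replicate(150, {
    lab <- sample(c(rep(TRUE, 6), rep(FALSE, 14)))
    roc_auroc(lab)$auroc
  })
  expect_equal(mean(vals), 0.5, tolerance = 0.05)
})

test_that("prepending truths and appending falses move the metrics one way", {
  base <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
  better <- c(TRUE, base)
  worse_tail <- c(base, FALSE)
  expect_gte(roc_auroc(better)$auroc, roc_auroc(base)$auroc)
  expect_gte(pr_aupr(better)$aupr, pr_aupr(base)$aupr)
  # appending a false prediction leaves the average precision untouched
  # (the ROC area, by contrast, is a positive-negative pair average and can
  # only move toward its asymptote when negatives are appended)
  expect_lte(pr_aupr(worse_tail)$aupr, pr_aupr(base)$aupr)
})

test_that("AUPR matches the average-precision oracle and degenerate gates", {
  set.seed(7)
  for (i in 1:25) {
    lab <- runif(15) < 0.3
    if (!any(lab)) next
    expect_equal(pr_aupr(lab)$aupr, ap_oracle(lab))
  }
  expect_error(pr_aupr(c(FALSE, FALSE)), "positive")
  # empty gold network -> no positives -> error
  gold <- regulatory_network(data.frame(name = c("A", "B")))
  pred <- tibble::tibble(from = "A", to = "B", score = 1)
  expect_error(evaluate_ranking(pred, gold, "undirected"), "positive")
  # single true prediction hits precision 1 at recall 1/n_pos
  ev <- evaluate_ranking(tibble::tibble(from = "A", to = "B", score = 1),
                         gold5(), "undirected")
  expect_equal(ev$pr_points$precision[1], 1)
  expect_equal(ev$pr_points$recall[1], 1 / ev$n_positives)
  expect_equal(precision_at_k(ev, 1), 1)
})

test_that("evaluating the gold edges ranked first is perfect", {
  gold <- gold5()
  pred <- tibble::tibble(from = c("A", "B", "C", "D"),
                         to = c("B", "C", "D", "E"), score = 4:1)
  ev <- evaluate_ranking(pred, gold, "undirected")
  expect_equal(ev$auroc, 1)
  expect_equal(ev$aupr, 1)
  expect_equal(ev$n_positives, 4)
  expect_equal(ev$n_positives + ev$n_negatives, choose(5, 2))
  # directed mode distinguishes orientation
  rev_pred <- tibble::tibble(from = "B", to = "A", score = 1)
  lab_dir <- label_predictions(rev_pred, gold, "directed")
  expect_false(lab_dir$label[lab_dir$from == "B" & lab_dir$to == "A"])
  expect_true(lab_dir$label[lab_dir$from == "A" & lab_dir$to == "B"])
})
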