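test_that("regulatory_input computes the normalized signed weighted sum", {
  net <- regulatory_network(
    data.frame(name = c("A", "B", "T")),
    data.frame(from = c("A", "B"), to = c("T", "T"), sign = c(1, -1),
               weight = c(2, 1))
  )
  m <- additive_model(net)
  st <- initial_state(m, c(A = 0.5, B = 1, T = 0))
  # (2*0.5 - 1*1) / 3 = 0
  expect_equal(regulatory_input(m, st, "T", "slow"), 0)
  # single activator at weight 1, source total 1
  net1 <- regulatory_network(data.frame(name = c("A", "T")),
                             data.frame(from = "A", to = "T", sign = 1))
  m1 <- additive_model(net1)
  st1 <- initial_state(m1, c(A = 1, T = 0))
  expect_equal(regulatory_input(m1, st1, "T", "slow"), 1)
  # balanced activator/inhibitor cancel out
  net2 <- regulatory_network(
    data.frame(name = c("A", "B", "T")),
    data.frame(from = c("A", "B"), to = c("T", "T"), sign = c(1, -1)))
  m2 <- additive_model(net2)
  st2 <- initial_state(m2, c(A = 1, B = 1, T = 0.3))
  expect_equal(regulatory_input(m2, st2, "T", "slow"), 0)
  # a node without incoming slow edges holds its level
  expect_equal(regulatory_input(m2, st2, "A", "slow"), 1)
})

test_that("update_step is deterministic under a seed and fixes fixed points", {
  m <- toggle_model()
  st <- initial_state(m, c(X = 1, Y = 0))
  out <- update_step(m, st, seed = 5)
  expect_equal(out$total, st$total)
  # identical trajectory under identical seed, from a non-fixed state
  st2 <- initial_state(m, c(X = 1, Y = 1))
  a <- update_step(m, st2, seed = 11)
  b <- update_step(m, st2, seed = 11)
  expect_identical(a$slow, b$slow)
  # totals stay the product of fast and slow after stepping
  expect_equal(out$total, out$fast * out$slow)
  expect_equal(a$total, a$fast * a$slow)
})

test_that("toggle switch settles in the two asymmetric states from corners", {
  ss <- find_stable_states(toggle_model(), seed = 1)
  expect_true(all(vapply(attr(ss, "states"),
                         function(s) is_fixed_point(toggle_model(), s),
                         logical(1))))
  sig <- paste(ss$total_X, ss$total_Y)
  expect_true(all(c("1 0", "0 1") %in% sig))
  expect_true(any(ss$label == "X+") && any(ss$label == "Y+"))
  expect_lte(sum(ss$basin_fraction), 1)
})

test_that("a single self-activating node has off and on fixed points", {
  net <- regulatory_network(data.frame(name = "A"),
                            data.frame(from = "A", to = "A", sign = 1))
  m <- additive_model(net, activation = "step")
  ss <- find_stable_states(m, seed = 1)
  expect_setequal(ss$total_A, c(0, 1))
})

test_that("an all-clamped model has exactly one stable state with full basin", {
  m <- toggle_model(clamps = c(X = 1, Y = 0))
  ss <- find_stable_states(m, seed = 1)
  expect_equal(nrow(ss), 1)
  expect_equal(ss$basin_fraction, 1)
  expect_equal(ss$total_X, 1)
})

test_that("knockouts and over-activations clamp totals in every stable state", {
  ko <- apply_perturbation(toggle_model(), "X", "knockout")
  ss <- find_stable_states(ko, seed = 1)
  expect_true(all(ss$total_X == 0))
  oa <- apply_perturbation(toggle_model(), "Y", "overactivation")
  ss2 <- find_stable_states(oa, seed = 1)
  expect_true(all(ss2$total_Y == 1))
  # idempotence of repeated knockout
  ko2 <- apply_perturbation(ko, "X", "knockout")
  expect_identical(ko$clamps, ko2$clamps)
  expect_error(apply_perturbation(toggle_model(), "Z", "knockout"), "unknown node")
})

test_that("perturbation screen flags required factors and matches baseline", {
  scr <- perturbation_screen(toggle_model(), "X", seed = 3)
  base <- scr[scr$mode == "none", ]
  ss <- find_stable_states(toggle_model(), seed = 3)
  expect_equal(base$marker_basin, sum(ss$basin_fraction[ss$label == "X+"]))
  ko_x <- scr[scr$node == "X" & scr$mode == "knockout", ]
  expect_false(ko_x$reachable)
  expect_true(ko_x$required)
  # over-activating the rival reduces the X+ basin
  oa_y <- scr[scr$node == "Y" & scr$mode == "overactivation", ]
  expect_lt(oa_y$marker_basin, base$marker_basin)
})

test_that("dose response endpoints match knockout and over-activation clamps", {
  # toggle switch driven by an upstream activator of X
  net <- regulatory_network(
    data.frame(name = c("Z", "X", "Y"),
               category = c("growth_factor", rep("transcription_factor", 2))),
    data.frame(from = c("Z", "X", "X", "Y", "Y"),
               to = c("X", "X", "Y", "X", "Y"),
               sign = c(1, 1, -1, -1, 1))
  )
  m <- additive_model(net, activation = "step", markers = c("X", "Y"))
  dr <- dose_response(m, "Z", c(0, 1), seed = 2)
  ko <- find_stable_states(clamp_node(m, "Z", 0), seed = 2)
  expect_equal(sort(dr$total_X[dr$level == 0]), sort(ko$total_X))
  xp_basin <- function(lv) sum(dr$basin_fraction[dr$level == lv & dr$label == "X+"])
  expect_lte(xp_basin(0), xp_basin(1))
  expect_error(dose_response(m, "Z", numeric(0)), "empty level")
})

test_that("clamped totals never deviate along random trajectories", {
  m <- clamp_node(toggle_model(activation = "logistic"), "X", 0.6)
  st <- initial_state(m, c(X = 0.6, Y = 0.2))
  for (i in 1:20) {
    st <- update_step(m, st)
    expect_equal(unname(st$total[["X"]]), 0.6)
    expect_equal(st$total, st$fast * st$slow)
  }
})

test_that("logistic and step models agree with their JSON round trip", {
  m <- toggle_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  back <- read_model_json(f)
  expect_equal(back$nodes, m$nodes)
  expect_equal(back$activation, m$activation)
  expect_equal(as_tibble(find_stable_states(back, seed = 1)),
               as_tibble(find_stable_states(m, seed = 1)))
})
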