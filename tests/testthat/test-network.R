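test_that("SIF parsing builds the declared signed network", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("X\tactivates\tY", "Y\tinhibits\tX"), f)
  net <- read_network(f, "sif")
  expect_equal(nrow(net$nodes), 2)
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$edges$sign[net$edges$from == "X"], 1L)
  expect_equal(net$edges$sign[net$edges$from == "Y"], -1L)
})

test_that("network round trips through both file formats", {
  net <- generate_network(n_genes = 6, edge_density = 0.3, seed = 7)
  for (fmt in c("sif", "tsv")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_network(net, f, fmt)
    back <- read_network(f, fmt)
    key <- function(n) {
      e <- dplyr::arrange(n$edges, from, to)
      if (fmt == "sif") e$weight <- 1  # sif carries signs only
      e[, c("from", "to", "sign", "weight")]
    }
    exp_edges <- key(net)
    if (fmt == "sif") exp_edges$weight <- 1
    expect_equal(key(back), exp_edges)
    expect_setequal(back$nodes$name, net$nodes$name)
  }
})

test_that("self-loops parse and are flagged in the report", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines("A\tactivates\tA", f)
  net <- read_network(f, "sif")
  expect_equal(nrow(net$edges), 1)
  expect_equal(attr(net, "parse_report")$self_loops, "A->A")
})

test_that("malformed SIF records raise errors naming the problem", {
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("A\tactivates\tB", "A\tupregulates\tB"), f)
  expect_error(read_network(f, "sif"), "line 2")
  writeLines(c("A\tactivates\tB", "A\tactivates\tB"), f)
  expect_error(read_network(f, "sif"), "duplicate edge.*A, B")
})

test_that("canonicalization is alias-insensitive and idempotent", {
  aliases <- c("NF-κB", "NFκB", "NFkB")
  canon <- canonical_gene_names(aliases)
  expect_true(all(canon == "NFkB"))
  expect_identical(canonical_gene_names(canon), canon)
  # alias sets are pairwise disjoint
  tab <- gene_alias_table()
  expect_false(anyDuplicated(names(tab)) > 0)
  # reading either spelling yields the same node
  f <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("NF-κB\tactivates\tSox9", "NFκB\tactivates\tRunx2"), f)
  net <- read_network(f, "sif")
  expect_equal(sum(net$nodes$name == "NFkB"), 1)
})

test_that("inference node selection returns exactly the transcription factors", {
  net <- regulatory_network(
    data.frame(name = c("BMP2", "Sox9", "Runx2"),
               category = c("growth_factor", "transcription_factor",
                            "transcription_factor")),
    data.frame(from = "BMP2", to = "Sox9", sign = 1)
  )
  expect_equal(select_inference_nodes(net), c("Sox9", "Runx2"))
  gf_only <- regulatory_network(
    data.frame(name = c("BMP2", "FGF"), category = "growth_factor"))
  expect_error(select_inference_nodes(gf_only), "no transcription-factor")
  one_tf <- regulatory_network(
    data.frame(name = c("A", "B", "C"),
               category = c("other", "transcription_factor", "other")))
  expect_equal(select_inference_nodes(one_tf), "B")
})

test_that("prior_from_network encodes edge signs and zeros elsewhere", {
  fx <- growth_plate_fixture()
  net <- prior_to_network(fx$prior)
  pm <- prior_from_network(net, fx$genes)
  expect_equal(pm["MEF2C", "Runx2"], 1L)
  expect_equal(pm["Runx2", "MEF2C"], 1L)
  expect_equal(pm["Sox9", "Runx2"], -1L)
  expect_equal(pm["Runx2", "Sox9"], -1L)
  expect_equal(pm["MEF2C", "Tcf7"], 0L)
  expect_identical(unclass(pm), unclass(fx$prior))
  empty <- regulatory_network(data.frame(name = c("A", "B")))
  expect_true(all(prior_from_network(empty) == 0))
  expect_error(prior_from_network(empty, c("A", "Z")), "Z")
})

test_that("prior matrices survive a TSV round trip", {
  fx <- growth_plate_fixture()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_prior(fx$prior, f)
  expect_identical(unclass(read_prior(f)), unclass(fx$prior))
})

test_that("collapse_undirected keeps the stronger direction and is idempotent", {
  ranked <- tibble::tibble(from = c("A", "B"), to = c("B", "A"),
                           score = c(0.9, 0.4))
  out <- collapse_undirected(ranked)
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 0.9)
  expect_equal(out$direction, "undirected")
  expect_identical(collapse_undirected(out)[names(out)], out[names(out)])
  # hand-ranked three directed pairs over three nodes
  r3 <- tibble::tibble(from = c("A", "C", "B"), to = c("B", "A", "C"),
                       score = c(0.2, 0.8, 0.5))
  o3 <- collapse_undirected(r3)
  expect_equal(o3$from, c("A", "B", "A"))
  expect_equal(o3$to, c("C", "C", "B"))
  expect_equal(o3$score, c(0.8, 0.5, 0.2))
  expect_equal(o3$rank, c(1, 2, 3))
  expect_lte(nrow(o3), nrow(r3))
})
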