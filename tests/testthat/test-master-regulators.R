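star_graph <- function() {
  signaling_graph(tibble::tibble(
    from = c("R", "R"), to = c("T1", "T2"), sign = 1L, cost = 1
  ))
}

test_that("context discounting rescales exactly the adjacent edges", {
  g <- signaling_graph(tibble::tibble(
    from = c("A", "B", "C"), to = c("B", "C", "D"), sign = 1L,
    cost = c(2, 3, 4)
  ))
  same <- apply_context(g, "B", discount = 1.0)
  expect_equal(same$edges$cost, g$edges$cost)

  half <- apply_context(g, "B", discount = 0.5)
  expect_equal(half$edges$cost, c(1, 1.5, 4)) # both edges touching B
  expect_equal(g$edges$cost, c(2, 3, 4))      # original untouched

  # path cost A->D drops by exactly the two adjacent-edge reductions
  before <- sum(g$edges$cost)
  after <- sum(half$edges$cost)
  expect_equal(before - after, 0.5 * 2 + 0.5 * 3)

  expect_warning(apply_context(g, c("B", "ZZZ")), "not in graph")
  expect_error(apply_context(g, "B", discount = 0), "discount")
})

test_that("the star graph reproduces the hand-computed score exactly", {
  res <- keynode_search(star_graph(), c("T1", "T2"), radius = 1)
  expect_equal(res$node, "R")
  expect_equal(res$score, (1 / 2 + 1 / 2) / 2)
  expect_equal(res$n_reached, 2L)
  expect_equal(res$total_reachable, 2L)
})

test_that("nodes reaching no input are omitted; radius limits the search", {
  g <- signaling_graph(tibble::tibble(
    from = c("A", "B", "X"), to = c("B", "T1", "Y"), sign = 1L, cost = 1
  ))
  res <- keynode_search(g, "T1", radius = 10)
  expect_false("X" %in% res$node)
  expect_true(all(c("A", "B") %in% res$node))
  # radius 1: A (two steps away) cannot reach T1
  res1 <- keynode_search(g, "T1", radius = 1)
  expect_false("A" %in% res1$node)
  expect_error(keynode_search(g, "T1", radius = 0), "radius")
  expect_error(keynode_search(g, character(0)), "non-empty")
})

test_that("hop-bounded distances respect both cost and step limits", {
  # cheap long path vs expensive short path
  g <- signaling_graph(tibble::tibble(
    from = c("K", "a", "b", "K"),
    to = c("a", "b", "T1", "T1"),
    sign = 1L, cost = c(0.1, 0.1, 0.1, 5)
  ))
  # radius 3: the cheap 3-edge path wins
  r3 <- keynode_search(g, "T1", radius = 3)
  expect_equal(r3$reached[r3$node == "K"][[1]][["T1"]], 0.3,
               tolerance = 1e-12)
  # radius 1: only the direct expensive edge is allowed
  r1 <- keynode_search(g, "T1", radius = 1)
  expect_equal(r1$reached[r1$node == "K"][[1]][["T1"]], 5)
})

test_that("decreasing an on-path edge cost never decreases the score", {
  fx <- sim_network(n_nodes = 20, planted = TRUE, seed = 8)
  res <- keynode_search(fx$graph, fx$truth$inputs, radius = 3)
  s0 <- res$score[res$node == "REG"]
  e <- fx$graph$edges
  idx <- which(e$from == "REG")[1]
  e$cost[idx] <- e$cost[idx] / 2
  res2 <- keynode_search(signaling_graph(e, fx$graph$nodes),
                         fx$truth$inputs, radius = 3)
  expect_gte(res2$score[res2$node == "REG"], s0)
})

test_that("keynode scores are invariant under node relabelling", {
  fx <- sim_network(n_nodes = 15, planted = TRUE, seed = 12)
  res <- keynode_search(fx$graph, fx$truth$inputs, radius = 3)
  relabel <- function(x) paste0("zz_", x)
  e <- fx$graph$edges
  e$from <- relabel(e$from)
  e$to <- relabel(e$to)
  n <- fx$graph$nodes
  n$id <- relabel(n$id)
  res2 <- keynode_search(signaling_graph(e, n),
                         relabel(fx$truth$inputs), radius = 3)
  m <- match(relabel(res$node), res2$node)
  expect_equal(res2$score[m], res$score)
})

test_that("the planted regulator is recovered across random fixtures", {
  hits <- vapply(1:5, function(seed) {
    fx <- sim_network(n_nodes = 50, planted = TRUE, seed = seed)
    res <- keynode_search(fx$graph, fx$truth$inputs, radius = 3)
    res$node[1] == fx$truth$regulator
  }, TRUE)
  expect_gte(sum(hits), 4)
})

test_that("feedback loops through a node are enumerated with signs", {
  g <- signaling_graph(
    tibble::tibble(
      from = c("R", "TF", "gene_R"),
      to = c("TF", "gene_R", "R"),
      sign = c(1L, 1L, 1L), cost = 1,
      regulatory = c(FALSE, TRUE, FALSE)
    ),
    nodes = tibble::tibble(id = c("R", "TF", "gene_R"),
                           kind = c("protein", "TF", "gene"),
                           gene = NA_character_)
  )
  loops <- find_feedback_loops(g, "R", max_len = 5)
  expect_equal(nrow(loops), 1)
  expect_equal(loops$length, 3L)
  expect_true(loops$positive)
  expect_equal(loops$nodes[[1]], c("R", "TF", "gene_R", "R"))

  g$edges$sign[2] <- -1L
  loops_neg <- find_feedback_loops(g, "R", max_len = 5)
  expect_equal(nrow(loops_neg), 1)
  expect_false(loops_neg$positive)
  expect_equal(loops_neg$sign_product, -1)
  expect_error(find_feedback_loops(g, "R", max_len = 1), "max_len")
})

test_that("loop enumeration matches an independent igraph-based oracle", {
  set.seed(33)
  # dense random signed graph with gene nodes for regulatory closure
  ids <- c(paste0("n", 1:6), "gene_n1")
  e <- tidyr::expand_grid(from = ids, to = ids) |>
    dplyr::filter(from != to) |>
    dplyr::slice_sample(prop = 0.4)
  e$sign <- sample(c(-1L, 1L), nrow(e), replace = TRUE)
  e$cost <- 1
  nodes <- tibble::tibble(id = ids,
                          kind = ifelse(grepl("^gene", ids), "gene",
                                        "protein"),
                          gene = NA_character_)
  g <- signaling_graph(e, nodes)
  max_len <- 4
  loops <- find_feedback_loops(g, "n1", max_len = max_len)

  # oracle: all simple paths from each successor of n1 back to n1
  ig <- igraph::graph_from_data_frame(e[, c("from", "to")],
                                      vertices = ids)
  succ <- e$to[e$from == "n1"]
  oracle_cycles <- list()
  for (s in unique(succ)) {
    if (s == "n1") next
    ps <- igraph::all_simple_paths(ig, from = s, to = "n1",
                                   cutoff = max_len - 1)
    for (p in ps) {
      cyc <- c("n1", names(p))
      if (length(cyc) - 1 <= max_len) {
        oracle_cycles[[length(oracle_cycles) + 1L]] <- cyc
      }
    }
  }
  # keep oracle cycles traversing at least one edge into a gene node
  has_reg <- vapply(oracle_cycles, function(cyc) {
    any(grepl("^gene", cyc[-1]))
  }, TRUE)
  expect_equal(nrow(loops), sum(has_reg))
  key <- function(cyc) paste(cyc, collapse = ">")
  expect_setequal(vapply(loops$nodes, key, ""),
                  vapply(oracle_cycles[has_reg], key, ""))
})

test_that("context weighting lets the on-loop regulator overtake its twin", {
  fx <- sim_network(n_nodes = 30, planted = TRUE, feedback = TRUE, seed = 4)
  plain <- keynode_search(fx$graph, fx$truth$inputs, radius = 2)
  expect_lt(which(plain$node == fx$truth$twin),
            which(plain$node == fx$truth$regulator))
  ctx <- apply_context(fx$graph, fx$truth$loop_nodes, discount = 0.5)
  biased <- keynode_search(ctx, fx$truth$inputs, radius = 2)
  expect_lt(which(biased$node == fx$truth$regulator),
            which(biased$node == fx$truth$twin))
})

test_that("prioritisation filters and orders by the stated rule", {
  res <- structure(
    tibble::tibble(node = c("a", "b", "c"), score = c(0.9, 0.8, 0.7),
                   n_reached = c(3L, 2L, 2L),
                   total_reachable = c(5L, 4L, 4L),
                   reached = list(1, 1, 1), paths = list(1, 1, 1)),
    class = c("keynode_result", "tbl_df", "tbl", "data.frame")
  )
  expr <- tibble::tibble(feature = c("a", "b", "c"),
                         logFC = c(2, 0.5, -3))
  meth <- tibble::tibble(feature = c("a", "b", "c"),
                         logFC = c(1, 1, 1))
  out <- prioritize_regulators(res, expr, meth,
                               lfc_expression = 1,
                               lfc_methylation = 0.5)
  # b fails the expression filter despite its high score
  expect_equal(out$gene, c("a", "c"))
  # all pass: ordering identical to score ordering
  out_all <- prioritize_regulators(res, expr, meth,
                                   lfc_expression = 0,
                                   lfc_methylation = 0)
  expect_equal(out_all$gene, c("a", "b", "c"))
  # missing join keys are dropped with a warning
  expect_warning(
    out_miss <- prioritize_regulators(
      res, expr[1:2, ], meth, lfc_expression = 0, lfc_methylation = 0
    ),
    "dropped"
  )
  expect_equal(out_miss$gene, c("a", "b"))
})
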