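test_that("simple chains, skip edges and parallel branches solve exactly", {
  # S -> A -> T: one path covers everything
  g <- make_graph(3L, rbind(c(1, 2), c(2, 3)))
  sol <- solve_empc(g)
  expect_equal(sol$k, 1L)
  expect_equal(sol$paths[[1L]], 1:3)

  # add skip edge S -> T: edge coverage forces two paths
  g2 <- make_graph(3L, rbind(c(1, 2), c(2, 3), c(1, 3)))
  sol2 <- solve_empc(g2)
  expect_equal(sol2$k, 2L)
  expect_true(check_empc_conditions(g2, NULL, sol2))

  # four branch nodes in parallel: one path per branch
  g3 <- make_graph(6L, rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5),
                             c(2, 6), c(3, 6), c(4, 6), c(5, 6)))
  expect_equal(solve_empc(g3)$k, 4L)

  # single-node graph (single-exon circle)
  g4 <- make_graph(1L, NULL, src = 1L, snk = 1L)
  expect_equal(solve_empc(g4)$k, 1L)
})

test_that("subpath constraints are honoured and never decrease k", {
  # diamond: S->A->T, S->B->T; subpath (S, A, T)
  g <- make_graph(4L, rbind(c(1, 2), c(2, 4), c(1, 3), c(3, 4)))
  sp <- subpaths_of(c(1L, 2L, 4L))
  sol <- solve_empc(g, sp)
  expect_equal(sol$k, 2L)
  expect_true(any(vapply(sol$paths, function(p)
    circflow:::.contains_run(p, c(1L, 2L, 4L)), logical(1))))
  oracle <- enumerate_all_covers_bruteforce(g, sp)
  expect_equal(sol$k, oracle$k)

  # a subpath that is not a walk is dropped with a warning
  expect_warning(sol2 <- solve_empc(g, subpaths_of(c(2L, 3L, 4L))),
                 "dropped")
  expect_equal(sol2$k, 2L)
})

test_that("solver k matches the brute-force oracle on random DAGs", {
  n_ok <- 0L
  seed <- 0L
  while (n_ok < 200L && seed < 1000L) {
    seed <- seed + 1L
    inst <- random_dag_instance(seed)
    if (is.null(inst)) next
    oracle <- tryCatch(
      enumerate_all_covers_bruteforce(inst$graph, inst$subpaths),
      error = function(e) NULL)   # refused: beyond the oracle's budget
    if (is.null(oracle)) next
    sol <- suppressWarnings(solve_empc(inst$graph, inst$subpaths))
    expect_equal(sol$k, oracle$k, info = paste("instance seed", seed))
    expect_true(check_empc_conditions(inst$graph, inst$subpaths, sol),
                info = paste("conditions, seed", seed))
    # monotonicity: subpath constraints never reduce k
    base <- solve_empc(inst$graph, NULL)
    expect_lte(base$k, sol$k, label = paste("monotonicity, seed", seed))
    n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 200L)
})

test_that("no path of a proven-minimal solution is redundant", {
  for (seed in c(3, 17, 42, 99, 123)) {
    inst <- random_dag_instance(seed)
    if (is.null(inst)) next
    sol <- suppressWarnings(solve_empc(inst$graph, inst$subpaths))
    if (!sol$exact || sol$k < 2L) next
    for (drop in seq_len(sol$k)) {
      reduced <- list(paths = sol$paths[-drop], k = sol$k - 1L)
      expect_false(check_empc_conditions(inst$graph, inst$subpaths, reduced),
                   label = paste("redundant path, seed", seed))
    }
  }
})

test_that("flow primitive agrees with an independent max-flow implementation", {
  set.seed(5)
  for (rep in 1:20) {
    n <- 6L
    cap <- matrix(sample(0:4, n * n, replace = TRUE), n, n)
    cap[lower.tri(cap, diag = TRUE)] <- 0L
    edges <- which(cap > 0L, arr.ind = TRUE)
    if (nrow(edges) == 0L) next
    net <- list(n_nodes = n, from = edges[, 1L], to = edges[, 2L],
                lb = rep(0L, nrow(edges)), cap = cap[edges],
                f = rep(0L, nrow(edges)))
    got <- circflow:::.flow_augment(net, 1L, n)$pushed
    ig <- igraph::graph_from_edgelist(edges)
    want <- igraph::max_flow(ig, 1L, n, capacity = cap[edges])$value
    expect_equal(got, as.integer(want))
  }
})

test_that("locus assembly concatenates per-graph solutions with stable ids", {
  gA <- make_graph(3L, rbind(c(1, 2), c(2, 3), c(1, 3)))  # 2 isoforms
  gB <- make_graph(2L, rbind(c(1, 2)))                    # 1 isoform
  gB$bsj_start <- 1000L; gB$bsj_end <- 1300L
  txs <- assemble_locus(list(gA, gB))
  ids <- vapply(txs, `[[`, character(1), "transcript_id")
  expect_equal(ids, c("circT-1-1", "circT-1-2", "circT-2-1"))
  # transcript length is the sum of member exon lengths
  expect_equal(vapply(txs, `[[`, numeric(1), "length")[1L], 300)
})
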