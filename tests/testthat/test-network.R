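test_that("network construction thresholds similarity edges correctly", {
  toy <- toy_inputs(m = 4, n = 3, seed = 2, sim = 0.6)
  net <- build_network(toy$A, toy$SM, toy$SD, sim_threshold = 1)
  # all off-diagonal similarities are strictly below 1 -> no M-M/D-D edges
  expect_equal(sum(net$edges$class != "M-D"), 0L)
  # 2x2 identity association: exactly the two verified M-D edges
  t2 <- toy_inputs(m = 2, n = 2, sim = 0.3)
  A2 <- association_matrix(diag(2))
  net2 <- build_network(A2, t2$SM, t2$SD, sim_threshold = 1)
  expect_equal(nrow(net2$edges), 2L)
  expect_true(all(net2$edges$class == "M-D"))
  expect_error(build_network(toy$A, toy$SM, toy$SD, 1.5), "config error")
  expect_error(build_network(toy$A, toy$SM, toy$SD, -0.1), "config error")
})

test_that("network edges equal an elementwise filter oracle", {
  set.seed(17)
  for (rep in 1:5) {
    m <- sample(3:6, 1); n <- sample(3:6, 1)
    A <- matrix(as.integer(runif(m * n) < 0.4), m, n)
    if (!sum(A)) A[1, 1] <- 1L
    A <- association_matrix(A)
    SM <- matrix(runif(m * m), m, m); SM <- (SM + t(SM)) / 2; diag(SM) <- 1
    dimnames(SM) <- list(rownames(A), rownames(A))
    SD <- matrix(runif(n * n), n, n); SD <- (SD + t(SD)) / 2; diag(SD) <- 1
    dimnames(SD) <- list(colnames(A), colnames(A))
    thr <- runif(1, 0.3, 0.8)
    net <- build_network(A, SM, SD, thr)
    want <- character(0)
    for (i in seq_len(m)) for (j in seq_len(n))
      if (A[i, j] == 1) want <- c(want, paste(i, m + j))
    for (i in seq_len(m - 1)) for (j in (i + 1):m)
      if (SM[i, j] >= thr) want <- c(want, paste(i, j))
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
      if (SD[i, j] >= thr) want <- c(want, paste(m + i, m + j))
    expect_setequal(paste(net$edges$i, net$edges$j), want)
    # undirected adjacency is symmetric, no self loops
    for (u in seq_along(net$adj)) {
      expect_false(u %in% net$adj[[u]])
      for (v in net$adj[[u]]) expect_true(u %in% net$adj[[v]])
    }
  }
})

test_that("meta-path type enumeration is complete and ordered", {
  expect_equal(enumerate_types(1), c("MM", "DM", "MD", "DD"))
  expect_length(enumerate_types(3), 28)
  expect_true("MDMD" %in% enumerate_types(3))
  expect_equal(lengths(lapply(1:4, enumerate_types)),
               cumsum(2^(2:5)))
  expect_error(enumerate_types(0), "max_length")
})

test_that("instance extraction matches the exhaustive DFS oracle", {
  set.seed(23)
  for (rep in 1:8) {
    m <- sample(3:6, 1); n <- sample(3:6, 1)   # <= 12 nodes
    toy <- toy_inputs(m, n, seed = rep + 40, p = 0.4, sim = 0.9)
    SM <- toy$SM; SM[upper.tri(SM)] <- runif(sum(upper.tri(SM)))
    SM[lower.tri(SM)] <- t(SM)[lower.tri(SM)]
    net <- build_network(toy$A, SM, toy$SD, 0.5)
    for (L in 1:3) {
      inst <- extract_instances(net, L)
      got <- path_strings(inst$paths, inst$length)
      want <- vapply(oracle_all_paths(net$adj, L),
                     paste, character(1), collapse = "-")
      expect_identical(sort(got), sort(want))
      # types recorded from node classes along the path
      cls <- net$classes
      expect_identical(
        inst$types[inst$type_id],
        vapply(seq_len(nrow(inst$paths)), function(r)
          paste(cls[inst$paths[r, seq_len(inst$length[r] + 1L)]],
                collapse = ""), character(1)))
    }
  }
})

test_that("instance extraction agrees with igraph simple-path enumeration", {
  toy <- toy_inputs(m = 5, n = 4, seed = 77, p = 0.4, sim = 0.95)
  net <- build_network(toy$A, toy$SM, toy$SD, 0.5)
  inst <- extract_instances(net, 3)
  g <- igraph::graph_from_edgelist(as.matrix(net$edges[, c("i", "j")]),
                                   directed = FALSE)
  want <- unlist(lapply(seq_along(net$adj), function(s)
    vapply(igraph::all_simple_paths(g, from = s, cutoff = 3),
           function(p) paste(as.integer(p), collapse = "-"), character(1))),
    use.names = FALSE)
  want <- want[grepl("-", want, fixed = TRUE)]
  expect_identical(sort(path_strings(inst$paths, inst$length)), sort(want))
})

test_that("reversed instances are instances of the reversed type", {
  toy <- toy_inputs(m = 4, n = 4, seed = 3, p = 0.5, sim = 0.9)
  net <- build_network(toy$A, toy$SM, toy$SD, 0.5)
  inst <- extract_instances(net, 3)
  all_str <- path_strings(inst$paths, inst$length)
  rev_str <- vapply(seq_len(nrow(inst$paths)), function(r)
    paste(rev(inst$paths[r, seq_len(inst$length[r] + 1L)]), collapse = "-"),
    character(1))
  expect_true(all(rev_str %in% all_str))
})

test_that("instance counts are monotone in max_length and edge count", {
  toy <- toy_inputs(m = 4, n = 4, seed = 8, p = 0.4, sim = 0.9)
  net <- build_network(toy$A, toy$SM, toy$SD, 0.5)
  counts <- vapply(1:3, function(L)
    nrow(extract_instances(net, L)$paths), integer(1))
  expect_true(all(diff(counts) >= 0))
  # removing similarity edges cannot add instances
  net_sparse <- build_network(toy$A, toy$SM, toy$SD, 1)
  expect_lte(nrow(extract_instances(net_sparse, 3)$paths),
             nrow(extract_instances(net, 3)$paths))
})

test_that("non-simple walks are enumerated when requested", {
  A <- association_matrix(matrix(1, 1, 1))
  SM <- matrix(1, 1, 1, dimnames = list("r1", "r1"))
  SD <- matrix(1, 1, 1, dimnames = list("d1", "d1"))
  net <- build_network(A, SM, SD, 0.5)
  simple <- extract_instances(net, 3, simple_only = TRUE)
  walks <- extract_instances(net, 3, simple_only = FALSE)
  # one M-D edge: a single simple instance per endpoint, but bouncing
  # walks of lengths 1..3 when repeats are allowed
  expect_equal(nrow(simple$paths), 2L)
  expect_equal(nrow(walks$paths), 6L)
})

test_that("meta-path based neighbours are the instance endpoints", {
  # r2 - r5 - d3 - d2 built explicitly (plus required labels)
  A <- matrix(0L, 5, 3, dimnames = list(paste0("r", 1:5), paste0("d", 1:3)))
  A[5, 3] <- 1L
  SM <- diag(1, 5); dimnames(SM) <- list(rownames(A), rownames(A))
  SM[2, 5] <- SM[5, 2] <- 0.9
  SD <- diag(1, 3); dimnames(SD) <- list(colnames(A), colnames(A))
  SD[3, 2] <- SD[2, 3] <- 0.9
  net <- build_network(association_matrix(A), SM, SD, 0.5)
  inst <- extract_instances(net, 3)
  expect_equal(neighbours_by_type(inst, "r2", "MMDD"), "d2")
  expect_equal(neighbours_by_type(inst, "r1", "MMDD"), character(0))
  # multiplicities match the DFS oracle
  toy <- toy_inputs(m = 4, n = 3, seed = 12, p = 0.5, sim = 0.9)
  net2 <- build_network(toy$A, toy$SM, toy$SD, 0.5)
  inst2 <- extract_instances(net2, 2)
  oracle <- oracle_all_paths(net2$adj, 2)
  for (target in c(1L, 5L)) {
    for (tp in c("MM", "MDM", "MDD")) {
      want <- vapply(Filter(function(p) {
        p[1] == target &&
          paste(net2$classes[p], collapse = "") == tp
      }, oracle), function(p) net2$labels[p[length(p)]], character(1))
      expect_identical(sort(neighbours_by_type(inst2, target, tp)),
                       sort(want))
    }
  }
  expect_error(neighbours_by_type(inst2, "nope", "MM"), "unknown node")
  expect_error(neighbours_by_type(inst2, 1L, "ZZ"), "unknown meta-path type")
})

test_that("extraction is deterministic given the input ordering", {
  toy <- toy_inputs(m = 5, n = 4, seed = 4, p = 0.4, sim = 0.9)
  net <- build_network(toy$A, toy$SM, toy$SD, 0.5)
  i1 <- extract_instances(net, 3)
  i2 <- extract_instances(net, 3)
  expect_identical(i1$paths, i2$paths)
  expect_identical(i1$groups, i2$groups)
})
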