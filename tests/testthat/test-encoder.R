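test_that("linear transformation maps features into the latent space", {
  W <- cbind(diag(3), matrix(0, 3, 2))    # selects first 3 coordinates
  x <- matrix(c(0, 1, 0, 0, 0), 1)
  expect_equal(drop(transform_features(x, W)), c(0, 1, 0))
  expect_equal(drop(transform_features(matrix(0, 1, 5), W)), rep(0, 3))
  set.seed(2)
  X <- matrix(rnorm(12), 3, 4); W2 <- matrix(rnorm(8), 2, 4)
  want <- matrix(0, 3, 2)
  for (i in 1:3) for (a in 1:2) want[i, a] <- sum(W2[a, ] * X[i, ])
  expect_lt(max(abs(transform_features(X, W2) - want)), 1e-12)
  expect_error(transform_features(X, matrix(0, 2, 5)), "dimension mismatch")
})

test_that("mean encoder averages all node vectors of an instance", {
  expect_equal(mean_encode(rbind(c(0, 0), c(2, 4))), c(1, 2))
  v <- c(0.3, -1, 2)
  expect_equal(mean_encode(rbind(v, v, v)), v, ignore_attr = TRUE)
  set.seed(3)
  M <- matrix(rnorm(16), 4, 4)
  expect_equal(mean_encode(M), colSums(M) / 4)
  expect_error(mean_encode(matrix(0, 0, 3)), "empty")
})

test_that("instance attention matches the literal formula oracle", {
  set.seed(4)
  z <- 5
  h_u <- rnorm(z)
  inst <- matrix(rnorm(4 * z), 4, z)
  att <- rnorm(2 * z)
  got <- instance_attention(h_u, inst, att)
  want <- oracle_instance_attention(h_u, inst, att)
  expect_lt(max(abs(got$value - want$value)), 1e-10)
  expect_lt(max(abs(got$weights - want$weights)), 1e-10)
  expect_equal(sum(got$weights), 1, tolerance = 1e-9)
  # singleton: weight one, sigmoid of the instance vector
  one <- instance_attention(h_u, inst[1, , drop = FALSE], att)
  expect_equal(one$weights, 1)
  expect_equal(one$value, 1 / (1 + exp(-inst[1, ])))
  # identical instances share the weight equally
  same <- instance_attention(h_u, inst[c(2, 2), ], att)
  expect_equal(same$weights, c(0.5, 0.5))
})

test_that("type fusion matches the literal formula oracle", {
  set.seed(5)
  z <- 4
  tv <- matrix(rnorm(3 * z), 3, z)
  at <- matrix(rnorm(3 * z), 3, z)
  got <- type_fusion(tv, at)
  want <- oracle_type_fusion(tv, at)
  expect_lt(max(abs(got$value - want$value)), 1e-10)
  expect_lt(max(abs(got$weights - want$weights)), 1e-10)
  expect_equal(sum(got$weights), 1, tolerance = 1e-9)
  single <- type_fusion(tv[1, , drop = FALSE], at[1, , drop = FALSE])
  expect_equal(single$value, tv[1, ])
  # symmetric inputs -> equal weights
  sym <- type_fusion(tv[c(1, 1), ], at[c(1, 1), ])
  expect_equal(sym$weights, c(0.5, 0.5))
  expect_error(type_fusion(tv[0, , drop = FALSE], at[0, , drop = FALSE]),
               "no meta-path types")
})

test_that("Manhattan distance behaves like a metric", {
  expect_equal(manhattan(c(1, 2), c(3, 0)), 4)
  expect_equal(manhattan(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(6)
  for (rep in 1:20) {
    u <- rnorm(6); v <- rnorm(6); w <- rnorm(6)
    expect_lte(manhattan(u, w), manhattan(u, v) + manhattan(v, w) + 1e-12)
    expect_equal(manhattan(u, v), manhattan(v, u))
  }
  expect_error(manhattan(1:2, 1:3), "equal length")
})

test_that("contrastive loss follows the positive/negative split", {
  emb <- rbind(a = c(0, 0), b = c(0, 0), c = c(3, 4))
  expect_equal(contrastive_loss(cbind("a", "b"), NULL, emb), log(0.5))
  expect_equal(contrastive_loss(NULL, NULL, emb), 0)
  expect_error(contrastive_loss(NULL, cbind("a", "c"), emb),
               "empty positive")
  got <- contrastive_loss(cbind(1, 2), cbind(1, 3), emb)
  expect_equal(got, log(0.5) - log(1 / (1 + exp(-7))))
})

test_that("compiled encoder equals the composed reference operations", {
  toy <- toy_inputs(m = 4, n = 4, seed = 21, p = 0.5, sim = 0.9)
  net <- build_network(toy$A, toy$SM, toy$SD, 0.5)
  inst <- extract_instances(net, 3)
  g <- inst$groups
  set.seed(8)
  N <- 8; z <- 5; Tn <- length(inst$types)
  H <- matrix(rnorm(N * z), N, z)
  ai <- matrix(rnorm(2 * z * Tn), 2 * z, Tn)
  at <- matrix(rnorm(z * Tn), z, Tn)
  for (attn in c(TRUE, FALSE)) {
    got <- metamir:::cpp_embed(H, g$paths, g$length, g$grp_start, g$grp_end,
                               g$grp_type, g$node_g0, g$node_g1, ai, at,
                               1:N, attn)
    want <- metamir:::r_encode_targets(H, g, ai, at, 1:N, attention = attn)
    expect_lt(max(abs(got - want)), 1e-10)
    expect_true(all(is.finite(got)))
  }
})

test_that("encoder output is invariant to instance and type permutations", {
  toy <- toy_inputs(m = 4, n = 3, seed = 33, p = 0.5, sim = 0.9)
  net <- build_network(toy$A, toy$SM, toy$SD, 0.5)
  inst <- extract_instances(net, 2)
  g <- inst$groups
  set.seed(9)
  N <- 7; z <- 4; Tn <- length(inst$types)
  H <- matrix(rnorm(N * z), N, z)
  ai <- matrix(rnorm(2 * z * Tn), 2 * z, Tn)
  at <- matrix(rnorm(z * Tn), z, Tn)
  base <- metamir:::cpp_embed(H, g$paths, g$length, g$grp_start, g$grp_end,
                              g$grp_type, g$node_g0, g$node_g1, ai, at,
                              1:N, TRUE)
  # permute instance rows within every (target, type) group
  g2 <- g
  for (k in seq_along(g$grp_start)) {
    rows <- g$grp_start[k]:g$grp_end[k]
    perm <- sample(rows)
    g2$paths[rows, ] <- g$paths[perm, , drop = FALSE]
    g2$length[rows] <- g$length[perm]
  }
  perm_inst <- metamir:::cpp_embed(H, g2$paths, g2$length, g2$grp_start,
                                   g2$grp_end, g2$grp_type, g2$node_g0,
                                   g2$node_g1, ai, at, 1:N, TRUE)
  expect_lt(max(abs(base - perm_inst)), 1e-10)
  # permute the order of type groups within one target's span
  g3 <- g
  for (u in which(g$node_g0 > 0)) {
    span <- g$node_g0[u]:g$node_g1[u]
    perm <- sample(span)
    reorder_rows <- unlist(lapply(perm, function(k)
      g$grp_start[k]:g$grp_end[k]))
    rows <- g$grp_start[span[1]]:g$grp_end[span[length(span)]]
    g3$paths[rows, ] <- g$paths[reorder_rows, , drop = FALSE]
    g3$length[rows] <- g$length[reorder_rows]
    sizes <- g$grp_end[perm] - g$grp_start[perm] + 1L
    ends <- rows[1] - 1L + cumsum(sizes)
    g3$grp_start[span] <- ends - sizes + 1L
    g3$grp_end[span] <- ends
    g3$grp_type[span] <- g$grp_type[perm]
  }
  perm_type <- metamir:::cpp_embed(H, g3$paths, g3$length, g3$grp_start,
                                   g3$grp_end, g3$grp_type, g3$node_g0,
                                   g3$node_g1, ai, at, 1:N, TRUE)
  expect_lt(max(abs(base - perm_type)), 1e-10)
})

test_that("disabling attention reduces both stages to unweighted means", {
  toy <- toy_inputs(m = 3, n = 3, seed = 51, p = 0.6, sim = 0.9)
  net <- build_network(toy$A, toy$SM, toy$SD, 0.5)
  inst <- extract_instances(net, 2)
  g <- inst$groups
  set.seed(10)
  N <- 6; z <- 3; Tn <- length(inst$types)
  H <- matrix(rnorm(N * z), N, z)
  ai <- matrix(rnorm(2 * z * Tn), 2 * z, Tn)
  at <- matrix(rnorm(z * Tn), z, Tn)
  off <- metamir:::cpp_embed(H, g$paths, g$length, g$grp_start, g$grp_end,
                             g$grp_type, g$node_g0, g$node_g1, ai, at,
                             1:N, FALSE)
  # independent of the attention parameters
  off2 <- metamir:::cpp_embed(H, g$paths, g$length, g$grp_start, g$grp_end,
                              g$grp_type, g$node_g0, g$node_g1, ai * 5 + 1,
                              at * -2, 1:N, FALSE)
  expect_identical(off, off2)
  # equals hand-built unweighted means
  for (u in which(g$node_g0 > 0)) {
    span <- g$node_g0[u]:g$node_g1[u]
    tvecs <- t(vapply(span, function(k) {
      rows <- g$grp_start[k]:g$grp_end[k]
      msum <- rep(0, z)
      for (r in rows)
        msum <- msum + colMeans(H[g$paths[r, seq_len(g$length[r] + 1L)], ,
                                  drop = FALSE])
      1 / (1 + exp(-msum / length(rows)))
    }, numeric(z)))
    expect_lt(max(abs(off[u, ] - colMeans(tvecs))), 1e-10)
  }
})
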