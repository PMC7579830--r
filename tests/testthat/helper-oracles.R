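# Independent brute-force oracles used across the suite.  These are
# deliberately naive re-derivations (double loops, exhaustive recursion)
# kept separate from the package's implementation paths.

# GIP kernel by literal double loop
oracle_gip <- function(P, alpha0 = 1) {
  alpha <- alpha0 / mean(apply(P, 1L, function(r) sum(r^2)))
  k <- nrow(P)
  S <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    S[i, j] <- exp(-alpha * sum((P[i, ] - P[j, ])^2))
  S
}

# Wang contribution of term d equals delta^(shortest directed path from d
# down to the target disease), found by exhaustive path enumeration --
# a closed form independent of the package's memoised recursion.
oracle_wang_contrib <- function(dag, delta) {
  children <- split(dag$edges$child, factor(dag$edges$parent,
                                            levels = dag$nodes))
  depth_to_target <- function(d) {
    if (d == dag$disease) return(0L)
    ds <- unlist(lapply(children[[d]], depth_to_target))
    1L + min(ds)
  }
  vapply(dag$nodes, function(d) delta^depth_to_target(d), numeric(1))
}

# All paths of length 1..max_len from every node, by plain R recursion
oracle_all_paths <- function(adj, max_len, simple_only = TRUE) {
  out <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (length(path) - 1L >= max_len) return()
    for (v in adj[[u]]) {
      if (simple_only && v %in% path) next
      p2 <- c(path, v)
      out[[length(out) + 1L]] <<- p2
      walk(p2)
    }
  }
  for (s in seq_along(adj)) walk(s)
  out
}

# AUC by O(n^2) pairwise comparison with ties counted 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# random dense toy inputs for network/encoder tests
toy_inputs <- function(m = 3, n = 3, seed = 1, p = 0.6, sim = 0.9) {
  set.seed(seed)
  A <- matrix(as.integer(runif(m * n) < p), m, n)
  if (sum(A) == 0L) A[1L, 1L] <- 1L
  A <- association_matrix(A)
  SM <- matrix(sim, m, m); diag(SM) <- 1
  dimnames(SM) <- list(rownames(A), rownames(A))
  SD <- matrix(sim, n, n); diag(SD) <- 1
  dimnames(SD) <- list(colnames(A), colnames(A))
  list(A = A, SM = SM, SD = SD)
}

# literal evaluation of the two attention stages, written from the
# formulas rather than reusing the package helpers
oracle_instance_attention <- function(h_u, inst, att) {
  z <- length(h_u)
  e <- numeric(nrow(inst))
  for (i in seq_len(nrow(inst)))
    e[i] <- max(0, sum(att * c(h_u, inst[i, ])))
  ex <- exp(e - max(e))
  w <- ex / sum(ex)
  v <- rep(0, z)
  for (i in seq_len(nrow(inst))) v <- v + w[i] * inst[i, ]
  list(value = 1 / (1 + exp(-v)), weights = w)
}

oracle_type_fusion <- function(tvecs, att_rows) {
  s <- numeric(nrow(tvecs))
  for (i in seq_len(nrow(tvecs)))
    s[i] <- max(0, sum(att_rows[i, ] * tvecs[i, ]))
  ex <- exp(s - max(s))
  w <- ex / sum(ex)
  v <- rep(0, ncol(tvecs))
  for (i in seq_len(nrow(tvecs))) v <- v + w[i] * tvecs[i, ]
  list(value = v, weights = w)
}

# instances of a fit/extraction as sorted strings, for multiset equality
path_strings <- function(paths, lens) {
  vapply(seq_len(nrow(paths)), function(r)
    paste(paths[r, seq_len(lens[r] + 1L)], collapse = "-"), character(1))
}
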