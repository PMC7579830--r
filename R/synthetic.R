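#' Configuration for the block-structured synthetic generator
#'
#' The generator emulates the statistical premise of the method —
#' functionally related miRNAs associate with similar diseases — as
#' planted block structure: miRNAs and diseases are partitioned into
#' blocks, association probability is high within a block and low
#' between blocks, the functional-similarity matrix is a noisy block
#' indicator, and disease DAGs share their ancestor chain within a
#' block.
#'
#' @param n_mirnas,n_diseases Dataset dimensions (default 40 x 30).
#' @param n_blocks Number of planted blocks (default 2).
#' @param within_block_assoc_prob,between_block_assoc_prob Bernoulli
#'   association probabilities (defaults 0.3 and 0.02; the former must
#'   exceed the latter for a planted signal).
#' @param similarity_noise_sd Standard deviation of the Gaussian noise
#'   added to the block-indicator similarity before clipping to
#'   \[0, 1\] (default 0.1).
#' @param dag_depth Number of ancestor levels above each disease leaf
#'   (default 3).
#' @param seed Seed making the whole dataset reproducible.
#' @return Object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_mirnas = 40, n_diseases = 30, n_blocks = 2,
                             within_block_assoc_prob = 0.3,
                             between_block_assoc_prob = 0.02,
                             similarity_noise_sd = 0.1, dag_depth = 3,
                             seed = 1) {
  if (n_mirnas < 2 || n_diseases < 2 || n_blocks < 1)
    stop("dimensions must be >= 2 and n_blocks >= 1", call. = FALSE)
  for (p in c(within_block_assoc_prob, between_block_assoc_prob))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("association probabilities must lie in [0, 1]", call. = FALSE)
  if (within_block_assoc_prob <= between_block_assoc_prob)
    stop("within-block probability must exceed between-block probability",
         call. = FALSE)
  if (similarity_noise_sd <= 0) stop("similarity_noise_sd must be > 0",
                                     call. = FALSE)
  if (dag_depth < 1) stop("dag_depth must be >= 1", call. = FALSE)
  structure(list(n_mirnas = as.integer(n_mirnas),
                 n_diseases = as.integer(n_diseases),
                 n_blocks = as.integer(n_blocks),
                 within_block_assoc_prob = within_block_assoc_prob,
                 between_block_assoc_prob = between_block_assoc_prob,
                 similarity_noise_sd = similarity_noise_sd,
                 dag_depth = as.integer(dag_depth),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a seeded synthetic miRNA-disease dataset
#'
#' Produces the three inputs the prediction pipeline consumes: a binary
#' association matrix with planted blocks, an FS-like miRNA similarity
#' matrix (block indicator plus symmetric truncated Gaussian noise, unit
#' diagonal), and one ancestor DAG per disease in which same-block
#' diseases share their full ancestor chain and different blocks share
#' only the root term.
#'
#' @param config A [synthetic_config()].
#' @return List with `A` (an [association_matrix()]), `fs`, `dags`, the
#'   block assignments (`blocks`), and the `config`.
#' @examples
#' syn <- generate_synthetic(synthetic_config(n_mirnas = 10, n_diseases = 8))
#' syn$A
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  m <- config$n_mirnas; n <- config$n_diseases; B <- config$n_blocks
  mb <- sort(rep(seq_len(B), length.out = m))
  db <- sort(rep(seq_len(B), length.out = n))
  mirnas <- sprintf("mir-%03d", seq_len(m))
  diseases <- sprintf("disease-%03d", seq_len(n))

  same <- outer(mb, db, "==")
  p <- ifelse(same, config$within_block_assoc_prob,
              config$between_block_assoc_prob)
  A <- matrix(as.integer(runif(m * n) < p), m, n,
              dimnames = list(mirnas, diseases))
  if (sum(A) == 0L) A[1L, 1L] <- 1L  # kernel needs one interaction

  ind <- outer(mb, mb, "==") * 1
  noise <- matrix(rnorm(m * m, sd = config$similarity_noise_sd), m, m)
  noise <- (noise + t(noise)) / 2
  fs <- pmin(pmax(ind + noise, 0), 1)
  diag(fs) <- 1
  dimnames(fs) <- list(mirnas, mirnas)

  # block-shared ancestor chains of depth dag_depth under a common root
  edges <- data.frame(parent = character(), child = character(),
                      stringsAsFactors = FALSE)
  for (b in seq_len(B)) {
    chain <- c("root", sprintf("block%d-level%d", b,
                               seq_len(config$dag_depth - 1L)))
    if (length(chain) > 1L)
      edges <- rbind(edges, data.frame(parent = chain[-length(chain)],
                                       child = chain[-1L]))
    leaves <- diseases[db == b]
    edges <- rbind(edges, data.frame(parent = chain[length(chain)],
                                     child = leaves))
  }
  dags <- lapply(diseases, disease_dag, edges = edges)

  list(A = association_matrix(A), fs = fs, dags = dags,
       blocks = list(mirna = mb, disease = db), config = config)
}
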