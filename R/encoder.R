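#' Linear transformation of node features into the latent space
#'
#' Original features (rows of the similarity matrices, so dimension `m`
#' for miRNAs and `n` for diseases) are projected into one shared
#' `z`-dimensional latent space by a learnable linear map.
#'
#' @param features Numeric matrix, one node feature vector per row.
#' @param W `z x d` transformation matrix, with `d = ncol(features)`.
#' @return Matrix of transformed node vectors (`nrow(features) x z`).
#' @export
transform_features <- function(features, W) {
  features <- as.matrix(features)
  W <- as.matrix(W)
  if (ncol(W) != ncol(features))
    stop(sprintf("dimension mismatch: W is %dx%d but features have %d columns",
                 nrow(W), ncol(W), ncol(features)), call. = FALSE)
  out <- features %*% t(W)
  rownames(out) <- rownames(features)
  out
}

#' Mean encoder of a single meta-path instance
#'
#' The sequence information of one instance is collapsed into a single
#' latent vector: the arithmetic mean of the transformed vectors of all
#' nodes along the path, target and neighbour included.
#'
#' @param path_vectors Matrix with one transformed node vector per row,
#'   in path order (at least one row).
#' @return Numeric vector of length `z`.
#' @examples
#' mean_encode(rbind(c(0, 0), c(2, 4)))  # c(1, 2)
#' @export
mean_encode <- function(path_vectors) {
  path_vectors <- as.matrix(path_vectors)
  if (nrow(path_vectors) == 0L)
    stop("empty meta-path instance", call. = FALSE)
  colMeans(path_vectors)
}

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# softmax with max-subtraction for numerical stability
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Attention over the meta-path instances of one type
#'
#' Each instance vector is scored by `ReLU(att . [h_target || h_inst])`,
#' the scores are normalised with a softmax over all instances of the
#' type, and the instances are combined as a sigmoid-squashed weighted
#' sum, giving the target's per-type representation.
#'
#' @param h_target Transformed vector of the target node (length `z`).
#' @param instance_vecs Matrix of mean-encoded instance vectors, one per
#'   row (at least one).
#' @param att Attention parameter vector of length `2z` for this
#'   meta-path type.
#' @param attention If `FALSE`, uniform weights replace the attention
#'   scores (the ablated variant).
#' @return List with `value` (length-`z` representation) and `weights`
#'   (instance weights summing to 1).
#' @export
instance_attention <- function(h_target, instance_vecs, att,
                               attention = TRUE) {
  instance_vecs <- as.matrix(instance_vecs)
  k <- nrow(instance_vecs)
  if (k == 0L) stop("no meta-path instances for this type", call. = FALSE)
  z <- length(h_target)
  if (length(att) != 2L * z || ncol(instance_vecs) != z)
    stop("attention vector must have length 2z", call. = FALSE)
  if (attention) {
    pre <- relu(sum(att[seq_len(z)] * h_target) +
                  drop(instance_vecs %*% att[z + seq_len(z)]))
    w <- softmax(pre)
  } else {
    w <- rep(1 / k, k)
  }
  list(value = sigmoid(drop(crossprod(instance_vecs, w))), weights = w)
}

#' Attention fusion across meta-path types
#'
#' Each per-type representation is scored by `ReLU(att_type . h_type)`,
#' scores are softmax-normalised over the types present for the target,
#' and the final node representation is the weighted sum of the type
#' vectors under those normalised weights.
#'
#' @param type_vecs Matrix of per-type representations, one row per
#'   meta-path type present for the target (at least one).
#' @param att_type Matrix of type attention vectors (`z` columns), one
#'   row per type, aligned with `type_vecs`.
#' @param attention If `FALSE`, uniform weights replace the attention
#'   scores.
#' @return List with `value` (final representation) and `weights` (type
#'   weights summing to 1).
#' @export
type_fusion <- function(type_vecs, att_type, attention = TRUE) {
  type_vecs <- as.matrix(type_vecs)
  att_type <- as.matrix(att_type)
  k <- nrow(type_vecs)
  if (k == 0L)
    stop("target has no meta-path types; use its transformed feature vector",
         call. = FALSE)
  if (!identical(dim(att_type), dim(type_vecs)))
    stop("att_type must align with type_vecs", call. = FALSE)
  if (attention) {
    w <- softmax(relu(rowSums(att_type * type_vecs)))
  } else {
    w <- rep(1 / k, k)
  }
  list(value = drop(crossprod(type_vecs, w)), weights = w)
}

#' Manhattan distance between two latent vectors
#'
#' @param u,v Numeric vectors of equal length.
#' @return `sum(abs(u - v))`.
#' @export
manhattan <- function(u, v) {
  if (length(u) != length(v))
    stop("vectors must have equal length", call. = FALSE)
  sum(abs(u - v))
}

#' Contrastive training loss over node pairs
#'
#' `sum(log sigmoid(dist))` over positive pairs minus the same sum over
#' negative pairs, with `dist` the Manhattan distance between final
#' embeddings.  Minimising pulls connected nodes together and pushes
#' unrelated nodes apart.
#'
#' @param pos_pairs,neg_pairs Two-column matrices of node indices (or
#'   labels matching `rownames(embeddings)`).
#' @param embeddings Matrix of final node embeddings, one row per node.
#' @return The scalar loss (finite).
#' @export
contrastive_loss <- function(pos_pairs, neg_pairs, embeddings) {
  pair_sum <- function(pairs) {
    if (is.null(pairs) || NROW(pairs) == 0L) return(0)
    pairs <- as.matrix(pairs)
    if (is.character(pairs)) {
      pairs <- matrix(match(pairs, rownames(embeddings)), ncol = 2L)
      if (anyNA(pairs)) stop("pair member missing from embeddings",
                             call. = FALSE)
    }
    d <- rowSums(abs(embeddings[pairs[, 1L], , drop = FALSE] -
                       embeddings[pairs[, 2L], , drop = FALSE]))
    sum(-log1p(exp(-d)))  # log sigmoid(d) for d >= 0
  }
  if (NROW(pos_pairs) == 0L && NROW(neg_pairs) > 0L)
    stop("empty positive pair set", call. = FALSE)
  loss <- pair_sum(pos_pairs) - pair_sum(neg_pairs)
  if (!is.finite(loss)) stop("non-finite loss", call. = FALSE)
  loss
}

# Pure-R forward pass over a set of targets, composing the exported
# reference operations.  Used by tests as the slow cross-check of the
# compiled encoder and by the fit for tiny problems would be equivalent;
# the compiled path is always used for training.
r_encode_targets <- function(H, groups, att_inst, att_type, targets,
                             attention = TRUE) {
  z <- ncol(H)
  out <- matrix(0, length(targets), z)
  for (ti in seq_along(targets)) {
    u <- targets[[ti]]
    g0 <- groups$node_g0[u]
    if (g0 == 0L) {
      out[ti, ] <- H[u, ]
      next
    }
    g1 <- groups$node_g1[u]
    gsel <- g0:g1
    tvecs <- matrix(0, length(gsel), z)
    atype <- matrix(0, length(gsel), z)
    for (gi in seq_along(gsel)) {
      g <- gsel[[gi]]
      rows <- groups$grp_start[g]:groups$grp_end[g]
      inst <- matrix(vapply(rows, function(r) {
        nodes <- groups$paths[r, seq_len(groups$length[r] + 1L)]
        mean_encode(H[nodes, , drop = FALSE])
      }, numeric(z)), ncol = z, byrow = TRUE)
      tid <- groups$grp_type[g]
      tvecs[gi, ] <- instance_attention(H[u, ], inst, att_inst[, tid],
                                        attention = attention)$value
      atype[gi, ] <- att_type[, tid]
    }
    out[ti, ] <- type_fusion(tvecs, atype, attention = attention)$value
  }
  out
}
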