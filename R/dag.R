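#' Per-disease ancestor DAG
#'
#' A disease's semantic context is the directed acyclic graph spanned by
#' the disease itself and all of its ancestor terms in a MeSH-like
#' hierarchy.  The constructor takes a global `parent -> child` edge list
#' and derives the per-disease DAG by ancestor closure: starting from
#' `disease`, parents are added transitively, and only edges between
#' retained terms are kept.
#'
#' @param disease Disease term identifier (must appear as a term).
#' @param edges Two-column data frame or matrix of edges over terms with
#'   columns `parent`, `child` (a global hierarchy; only the ancestor
#'   closure of `disease` is retained).
#' @return An object of class `"disease_dag"`: a list with `disease`,
#'   `nodes`, `edges` (parent/child data frame) and slots for semantic
#'   contributions filled by [wang_contributions()] /
#'   [xuan_contributions()].
#' @examples
#' h <- data.frame(parent = c("neoplasms", "neoplasms"),
#'                 child  = c("lung neoplasms", "breast neoplasms"))
#' disease_dag("lung neoplasms", h)
#' @export
disease_dag <- function(disease, edges = NULL) {
  disease <- as.character(disease)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- data.frame(parent = character(), child = character(),
                        stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("parent", "child") %in% names(edges)))
      names(edges)[1:2] <- c("parent", "child")
    edges$parent <- as.character(edges$parent)
    edges$child <- as.character(edges$child)
  }
  # ancestor closure from the target disease
  nodes <- disease
  frontier <- disease
  while (length(frontier)) {
    parents <- unique(edges$parent[edges$child %in% frontier])
    frontier <- setdiff(parents, nodes)
    nodes <- c(nodes, frontier)
  }
  keep <- edges$parent %in% nodes & edges$child %in% nodes
  edges <- unique(edges[keep, c("parent", "child")])
  rownames(edges) <- NULL
  dag <- structure(list(disease = disease, nodes = nodes, edges = edges,
                        contributions1 = NULL, contributions2 = NULL,
                        semantic_value1 = NULL, semantic_value2 = NULL),
                   class = "disease_dag")
  assert_acyclic(dag)
  dag
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("disease DAG for %s: %d terms, %d edges\n",
              sQuote(x$disease), length(x$nodes), nrow(x$edges)))
  invisible(x)
}

assert_acyclic <- function(dag) {
  # Kahn's algorithm on the induced subgraph
  nodes <- dag$nodes
  edges <- dag$edges
  indeg <- table(factor(edges$child, levels = nodes))
  active <- stats::setNames(as.integer(indeg), nodes)
  queue <- names(active)[active == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    ch <- edges$child[edges$parent == v]
    for (c in ch) {
      active[[c]] <- active[[c]] - 1L
      if (active[[c]] == 0L) queue <- c(queue, c)
    }
  }
  if (seen != length(nodes))
    stop(sprintf("invalid disease DAG for %s: cycle detected",
                 sQuote(dag$disease)), call. = FALSE)
  invisible(dag)
}

#' Wang-style semantic contributions within a disease DAG
#'
#' The target disease contributes 1 to itself; every ancestor term `d`
#' contributes `delta` times the largest contribution among its children
#' inside the DAG, so contributions decay geometrically with distance
#' from the disease.  The disease's semantic value `DV1` is the sum of
#' all contributions.
#'
#' @param dag A [disease_dag()].
#' @param delta Semantic contribution decay factor in (0, 1], default 0.5.
#' @return The DAG with `contributions1` (named numeric vector over the
#'   DAG terms) and `semantic_value1` filled in.
#' @export
wang_contributions <- function(dag, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"))
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0 || delta > 1)
    stop("delta must be in (0, 1]", call. = FALSE)
  if (!length(dag$nodes)) stop("empty disease DAG", call. = FALSE)
  assert_acyclic(dag)
  nodes <- dag$nodes
  children <- split(dag$edges$child, factor(dag$edges$parent, levels = nodes))
  contrib <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
  contrib[[dag$disease]] <- 1
  compute <- function(d) {
    if (!is.na(contrib[[d]])) return(contrib[[d]])
    ch <- children[[d]]
    if (!length(ch))
      stop(sprintf("term %s has no path to disease %s in its DAG",
                   sQuote(d), sQuote(dag$disease)), call. = FALSE)
    val <- max(delta * vapply(ch, compute, numeric(1)))
    contrib[[d]] <<- val
    val
  }
  for (d in nodes) compute(d)
  dag$contributions1 <- contrib
  dag$semantic_value1 <- sum(contrib)
  dag$delta <- delta
  dag
}

#' Wang-style semantic similarity of two diseases
#'
#' Shared ancestor terms contribute their decayed semantic contributions
#' from both DAGs, normalised by the two semantic values, yielding a
#' similarity in \[0, 1\].
#'
#' @param dag_i,dag_j [disease_dag()] objects processed by
#'   [wang_contributions()].
#' @return Similarity score in \[0, 1\].
#' @export
wang_similarity <- function(dag_i, dag_j) {
  for (d in list(dag_i, dag_j)) {
    if (!inherits(d, "disease_dag") || is.null(d$contributions1))
      stop("both DAGs need wang_contributions() first", call. = FALSE)
    if (!length(d$nodes)) stop("empty disease DAG", call. = FALSE)
  }
  shared <- intersect(dag_i$nodes, dag_j$nodes)
  denom <- dag_i$semantic_value1 + dag_j$semantic_value1
  if (denom <= 0) stop("zero semantic value", call. = FALSE)
  sum(dag_i$contributions1[shared] + dag_j$contributions1[shared]) / denom
}

#' Xuan-style (information content) semantic contributions
#'
#' A term's contribution is `-log` of the fraction of disease DAGs in the
#' corpus that contain it: terms specific to few diseases carry more
#' information.  Contributions are corpus-level, so the whole DAG
#' collection is processed at once.
#'
#' @param dags List of [disease_dag()] objects — the full corpus.
#' @param n_diseases Denominator of the frequency ratio; defaults to the
#'   number of DAGs supplied.
#' @param log_base Base of the logarithm (cosmetic: the similarity in
#'   [xuan_similarity()] is invariant to it).  Default natural log.
#' @return The list of DAGs with `contributions2` and `semantic_value2`
#'   filled in.
#' @export
xuan_contributions <- function(dags, n_diseases = length(dags),
                               log_base = exp(1)) {
  stopifnot(length(dags) > 0, all(vapply(dags, inherits, TRUE, "disease_dag")))
  term_counts <- table(unlist(lapply(dags, `[[`, "nodes")))
  lapply(dags, function(dag) {
    cnt <- term_counts[dag$nodes]
    if (any(is.na(cnt)) || any(cnt == 0))
      stop("term appears in zero DAGs of the corpus", call. = FALSE)
    contrib <- -log(as.numeric(cnt) / n_diseases, base = log_base)
    names(contrib) <- dag$nodes
    dag$contributions2 <- contrib
    dag$semantic_value2 <- sum(contrib)
    dag
  })
}

#' Xuan-style semantic similarity of two diseases
#'
#' Shared terms contribute their information-content contributions from
#' both DAGs, normalised by the two semantic values.
#'
#' @param dag_i,dag_j [disease_dag()] objects processed by
#'   [xuan_contributions()].
#' @return Similarity score in \[0, 1\].
#' @export
xuan_similarity <- function(dag_i, dag_j) {
  for (d in list(dag_i, dag_j)) {
    if (!inherits(d, "disease_dag") || is.null(d$contributions2))
      stop("both DAGs need xuan_contributions() first", call. = FALSE)
  }
  denom <- dag_i$semantic_value2 + dag_j$semantic_value2
  if (denom <= 0)
    stop(sprintf("zero information content for pair (%s, %s): every term is shared by all diseases",
                 dag_i$disease, dag_j$disease), call. = FALSE)
  shared <- intersect(dag_i$nodes, dag_j$nodes)
  sum(dag_i$contributions2[shared] + dag_j$contributions2[shared]) / denom
}

#' Disease semantic similarity matrix over a DAG corpus
#'
#' Computes the Wang and Xuan similarities for every disease pair and
#' averages them into the combined semantic similarity used for the
#' disease similarity network.
#'
#' @param dags List of [disease_dag()] objects.
#' @param delta Decay factor for the Wang measure.
#' @param measure `"combined"` (default, mean of both), `"wang"`, or
#'   `"xuan"`.
#' @return Symmetric similarity matrix labelled by disease identifier.
#' @export
semantic_similarity <- function(dags, delta = 0.5,
                                measure = c("combined", "wang", "xuan")) {
  measure <- match.arg(measure)
  ids <- vapply(dags, `[[`, character(1), "disease")
  if (anyDuplicated(ids)) stop("duplicate disease DAGs", call. = FALSE)
  dags <- lapply(dags, wang_contributions, delta = delta)
  dags <- xuan_contributions(dags)
  n <- length(dags)
  pair_mat <- function(f) {
    S <- diag(1, n)
    if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
      S[i, j] <- S[j, i] <- f(dags[[i]], dags[[j]])
    dimnames(S) <- list(ids, ids)
    S
  }
  switch(measure,
         wang = pair_mat(wang_similarity),
         xuan = pair_mat(xuan_similarity),
         combined = combined_semantic(pair_mat(wang_similarity),
                                      pair_mat(xuan_similarity)))
}
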