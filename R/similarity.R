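#' Construct and validate a binary miRNA-disease association matrix
#'
#' The association matrix `A` is the package's central input: rows are
#' miRNAs, columns are diseases, and `A[i, j] == 1` records an
#' experimentally verified association between miRNA `i` and disease `j`.
#'
#' @param values Numeric matrix of 0/1 entries, miRNAs in rows and
#'   diseases in columns.
#' @param mirna_names Optional character vector of miRNA identifiers
#'   (defaults to `rownames(values)`).
#' @param disease_names Optional character vector of disease identifiers
#'   (defaults to `colnames(values)`).
#' @return An integer matrix of class `"association_matrix"` with unique
#'   row and column names.
#' @examples
#' A <- association_matrix(diag(2), c("mir-a", "mir-b"), c("lung", "breast"))
#' @export
association_matrix <- function(values, mirna_names = rownames(values),
                               disease_names = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(mirna_names))
    mirna_names <- paste0("r", seq_len(nrow(values)))
  if (is.null(disease_names))
    disease_names <- paste0("d", seq_len(ncol(values)))
  mirna_names <- as.character(mirna_names)
  disease_names <- as.character(disease_names)
  if (length(mirna_names) != nrow(values) ||
      length(disease_names) != ncol(values))
    stop("label lengths do not match matrix dimensions", call. = FALSE)
  if (anyDuplicated(mirna_names) || anyDuplicated(disease_names))
    stop("miRNA and disease identifiers must be unique", call. = FALSE)
  if (!all(values %in% c(0, 1)))
    stop("association matrix entries must be 0 or 1", call. = FALSE)
  storage.mode(values) <- "integer"
  dimnames(values) <- list(mirna_names, disease_names)
  class(values) <- c("association_matrix", class(values))
  values
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("miRNA-disease association matrix: %d miRNAs x %d diseases, %d associations\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

is_association_matrix <- function(A) {
  is.matrix(A) && all(A %in% c(0L, 1L)) && !is.null(rownames(A)) &&
    !is.null(colnames(A))
}

check_association <- function(A) {
  if (inherits(A, "association_matrix")) return(A)
  association_matrix(A)
}

#' Gaussian interaction profile kernel bandwidth
#'
#' Normalises an initial bandwidth `alpha0` by the mean squared Euclidean
#' norm of the interaction profiles, so the kernel adapts to the overall
#' density of the association data.
#'
#' @param profiles Numeric matrix whose rows are interaction profiles, or
#'   a list of equal-length numeric vectors.
#' @param alpha0 Initial kernel bandwidth (default 1).
#' @return A list of class `"kernel_bandwidth"` with elements `alpha0`
#'   and the normalised `alpha`.
#' @examples
#' gip_bandwidth(diag(2))$alpha  # == 1
#' @export
gip_bandwidth <- function(profiles, alpha0 = 1) {
  if (is.list(profiles)) {
    len <- unique(lengths(profiles))
    if (length(profiles) == 0L) stop("profiles must be nonempty", call. = FALSE)
    if (length(len) != 1L)
      stop("all profiles must have the same length", call. = FALSE)
    profiles <- do.call(rbind, profiles)
  }
  profiles <- as.matrix(profiles)
  if (nrow(profiles) == 0L) stop("profiles must be nonempty", call. = FALSE)
  if (!is.numeric(alpha0) || length(alpha0) != 1L || alpha0 <= 0)
    stop("alpha0 must be a single positive number", call. = FALSE)
  mean_norm <- mean(rowSums(profiles^2))
  if (mean_norm == 0)
    stop("degenerate input: all interaction profiles are zero, ",
         "kernel bandwidth is undefined for this matrix", call. = FALSE)
  structure(list(alpha0 = alpha0, alpha = alpha0 / mean_norm),
            class = "kernel_bandwidth")
}

#' Gaussian interaction profile (GIP) kernel similarity
#'
#' Computes `exp(-alpha * ||IV(u) - IV(v)||^2)` between all interaction
#' profiles on one side of the association matrix: rows (miRNAs) or
#' columns (diseases).  The bandwidth `alpha` is `alpha0` divided by the
#' mean squared profile norm (see [gip_bandwidth()]).
#'
#' @param A Binary association matrix (miRNAs x diseases).
#' @param axis `"mirna"` to compare rows, `"disease"` to compare columns.
#' @param alpha0 Initial kernel bandwidth, default 1.
#' @return Symmetric similarity matrix with unit diagonal and entries in
#'   (0, 1], labelled by the chosen axis.
#' @examples
#' A <- association_matrix(diag(2))
#' gip_similarity(A, "mirna")[1, 2]  # exp(-2)
#' @export
gip_similarity <- function(A, axis = c("mirna", "disease"), alpha0 = 1) {
  axis <- match.arg(axis)
  A <- check_association(A)
  profiles <- if (axis == "mirna") unclass(A) else t(unclass(A))
  bw <- tryCatch(gip_bandwidth(profiles, alpha0), error = function(e)
    stop(sprintf("GIP kernel on %s axis: %s", axis, conditionMessage(e)),
         call. = FALSE))
  d2 <- as.matrix(stats::dist(profiles))^2
  S <- exp(-bw$alpha * d2)
  diag(S) <- 1
  dimnames(S) <- list(rownames(profiles), rownames(profiles))
  S
}

check_similarity <- function(S, name = deparse(substitute(S)),
                             tol = 1e-9) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S))
    stop(sprintf("%s must be square", name), call. = FALSE)
  if (max(abs(S - t(S))) > tol)
    stop(sprintf("%s is asymmetric beyond tolerance %g", name, tol),
         call. = FALSE)
  if (any(S < -tol) || any(S > 1 + tol))
    stop(sprintf("%s has values outside [0, 1]", name), call. = FALSE)
  S[] <- pmin(pmax((S + t(S)) / 2, 0), 1)
  S
}

#' Combine two semantic similarity matrices by elementwise averaging
#'
#' @param ss1,ss2 Symmetric similarity matrices over the same labels.
#' @return Their elementwise mean.
#' @export
combined_semantic <- function(ss1, ss2) {
  if (!identical(dimnames(ss1), dimnames(ss2)) ||
      !identical(dim(ss1), dim(ss2)))
    stop("semantic similarity matrices must share labels", call. = FALSE)
  (ss1 + ss2) / 2
}

#' Integrate a primary similarity with a kernel fallback
#'
#' Where the primary similarity (miRNA functional similarity, or combined
#' disease semantic similarity) is defined, it is used; everywhere else
#' the GIP kernel similarity fills in.  The diagonal is forced to 1.
#'
#' @param primary Similarity matrix carrying the curated similarity.
#' @param fallback Similarity matrix (same labels) used where `primary`
#'   is undefined, typically from [gip_similarity()].
#' @param mask Logical matrix, `TRUE` where `primary` is defined.  By
#'   default taken from `attr(primary, "mask")`, else all `TRUE` where
#'   `primary` is non-`NA`.
#' @return Integrated similarity matrix with unit diagonal.
#' @export
integrate_similarity <- function(primary, fallback, mask = NULL) {
  if (!identical(dimnames(primary), dimnames(fallback)) ||
      !identical(dim(primary), dim(fallback)))
    stop("primary and fallback similarities must share labels",
         call. = FALSE)
  if (is.null(mask)) mask <- attr(primary, "mask")
  if (is.null(mask)) mask <- !is.na(unclass(primary))
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(primary)))
    stop("mask dimensions must match the similarity matrices", call. = FALSE)
  out <- unclass(fallback)
  p <- unclass(primary)
  out[mask] <- p[mask]
  diag(out) <- 1
  attr(out, "mask") <- NULL
  out
}

#' Integrated miRNA similarity (functional similarity with GIP fallback)
#'
#' Aligns a (possibly partial) miRNA functional-similarity matrix `fs` to
#' the miRNAs of `A` and fills undefined entries — pairs where either
#' miRNA is missing from `fs` — with GIP kernel similarity computed from
#' the rows of `A`.
#'
#' @param A Association matrix.
#' @param fs Functional-similarity matrix whose labels are a subset (or
#'   superset) of `rownames(A)`; `NULL` for pure GIP similarity.
#' @param alpha0 Initial GIP bandwidth.
#' @return `m x m` integrated miRNA similarity matrix `SM`.
#' @export
integrated_mirna_similarity <- function(A, fs = NULL, alpha0 = 1) {
  A <- check_association(A)
  gm <- gip_similarity(A, "mirna", alpha0)
  if (is.null(fs)) return(gm)
  fs <- check_similarity(fs, "functional similarity")
  ids <- rownames(A)
  present <- ids[ids %in% rownames(fs)]
  primary <- matrix(NA_real_, nrow(A), nrow(A), dimnames = dimnames(gm))
  primary[present, present] <- fs[present, present]
  mask <- !is.na(primary)
  primary[!mask] <- 0
  integrate_similarity(primary, gm, mask)
}

#' Integrated disease similarity (semantic similarity with GIP fallback)
#'
#' Builds combined semantic similarity from per-disease DAGs (mean of the
#' Wang and Xuan measures, see [semantic_similarity()]) for disease pairs
#' where both members have a DAG, and fills the remaining entries with
#' GIP kernel similarity computed from the columns of `A`.
#'
#' @param A Association matrix.
#' @param dags List of [disease_dag()] objects (names irrelevant; each
#'   carries its disease identifier), or `NULL` for pure GIP similarity.
#'   Alternatively a precomputed semantic similarity matrix.
#' @param delta Semantic contribution decay factor for the Wang measure.
#' @param alpha0 Initial GIP bandwidth.
#' @return `n x n` integrated disease similarity matrix `SD`.
#' @export
integrated_disease_similarity <- function(A, dags = NULL, delta = 0.5,
                                          alpha0 = 1) {
  A <- check_association(A)
  gd <- gip_similarity(A, "disease", alpha0)
  if (is.null(dags)) return(gd)
  if (is.matrix(dags)) {
    ss <- check_similarity(dags, "semantic similarity")
  } else {
    ss <- semantic_similarity(dags, delta = delta)
  }
  ids <- colnames(A)
  present <- ids[ids %in% rownames(ss)]
  primary <- matrix(NA_real_, ncol(A), ncol(A), dimnames = dimnames(gd))
  primary[present, present] <- ss[present, present]
  mask <- !is.na(primary)
  primary[!mask] <- 0
  integrate_similarity(primary, gd, mask)
}
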