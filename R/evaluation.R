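#' Area under the ROC curve (Mann-Whitney form)
#'
#' Computed as the Mann-Whitney rank statistic with midranks, so tied
#' scores contribute 1/2: `AUC = (sum of positive ranks - n1(n1+1)/2) /
#' (n1 n0)`.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical), same length.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' True/false positive rates at every distinct score threshold, from the
#' most permissive to the strictest; both rates are monotone along the
#' curve.
#'
#' @inheritParams auc_score
#' @return Data frame with columns `threshold`, `tpr`, `fpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l); fp <- cumsum(1L - l)
  last <- c(diff(s) != 0, TRUE)  # one point per distinct threshold
  data.frame(threshold = s[last],
             tpr = tp[last] / sum(l),
             fpr = fp[last] / sum(1L - l))
}

#' Cross-validation scheme descriptor
#'
#' @param kind `"kfold"` or `"loocv"` (global leave-one-out over the
#'   verified associations).
#' @param k Number of folds for k-fold (default 5).
#' @param repeats Number of repeated random partitions (k-fold only).
#' @param seed Seed controlling fold assignment and per-fold training.
#' @return Object of class `"cv_scheme"`.
#' @export
cv_scheme <- function(kind = c("kfold", "loocv"), k = 5, repeats = 1,
                      seed = 1) {
  kind <- match.arg(kind)
  if (kind == "kfold" && k < 2) stop("k must be >= 2", call. = FALSE)
  if (repeats < 1) stop("repeats must be >= 1", call. = FALSE)
  structure(list(kind = kind, k = as.integer(k),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "cv_scheme")
}

#' Cross-validated evaluation of the full prediction pipeline
#'
#' For each fold the held-out verified associations are zeroed in the
#' association matrix; the GIP similarities, heterogeneous network,
#' meta-path instances and model are then rebuilt and retrained on the
#' training portion only, so the held-out pairs leak into nothing.  The
#' held-out positives are scored against all unverified miRNA-disease
#' pairs and summarised as an AUC; k-fold AUCs are averaged per repeat
#' and across repeats.
#'
#' With `kind = "loocv"`, each verified association is held out in turn
#' and ranked against the unverified pairs of the same disease; the
#' per-holdout Mann-Whitney fractions are averaged.  This retrains once
#' per association and is only meant for small inputs.
#'
#' @param A Association matrix.
#' @param fs,dags Optional similarity inputs, as in [metamir()].
#' @param scheme A [cv_scheme()].
#' @param ... Further arguments passed to [metamir()] (embedding
#'   dimension, training hyperparameters, `attention`, ...).
#' @param reuse_similarity If `TRUE`, compute GIP similarities once from
#'   the full matrix instead of per fold.  Cheaper but leaks the test
#'   associations into the similarity kernels; kept only for studying
#'   that effect.
#' @param return_details Also return, per fold, the held-out cells and
#'   the trained network's edge table (for leakage audits).
#' @param verbose Progress messages.
#' @return Object of class `"roc_result"`: overall `auc`, per-fold and
#'   per-repeat AUCs, pooled ROC points for the first repeat, the
#'   scheme, and the configuration.
#' @export
run_cv <- function(A, fs = NULL, dags = NULL, scheme = cv_scheme(), ...,
                   reuse_similarity = FALSE, return_details = FALSE,
                   verbose = FALSE) {
  A <- check_association(A)
  stopifnot(inherits(scheme, "cv_scheme"))
  dots <- list(...)
  pos_cells <- which(unclass(A) == 1L)
  if (length(pos_cells) == 0L) stop("no verified associations", call. = FALSE)
  neg_cells <- which(unclass(A) == 0L)
  m <- nrow(A)

  SM_full <- SD_full <- NULL
  if (reuse_similarity) {
    SM_full <- integrated_mirna_similarity(A, fs,
                                           dots$alpha0 %||% 1)
    SD_full <- integrated_disease_similarity(A, dags,
                                             dots$delta %||% 0.5,
                                             dots$alpha0 %||% 1)
  }

  fit_fold <- function(A_train, fold_seed) {
    args <- c(list(A = A_train, seed = fold_seed), dots)
    if (reuse_similarity) {
      args$SM <- SM_full; args$SD <- SD_full
    } else {
      args$fs <- fs; args$dags <- dags
    }
    do.call(metamir, args)
  }

  if (scheme$kind == "loocv") {
    fracs <- numeric(length(pos_cells))
    details <- if (return_details) vector("list", length(pos_cells))
    for (i in seq_along(pos_cells)) {
      cell <- pos_cells[i]
      A_tr <- unclass(A); A_tr[cell] <- 0L
      fit <- fit_fold(association_matrix(A_tr), scheme$seed + i)
      S <- predict(fit)
      dj <- (cell - 1L) %/% m + 1L
      cand <- which(unclass(A)[, dj] == 0L)     # unverified, same disease
      s_hold <- S[(cell - 1L) %% m + 1L, dj]
      s_cand <- S[cand, dj]
      fracs[i] <- (sum(s_hold > s_cand) + 0.5 * sum(s_hold == s_cand)) /
        length(s_cand)
      if (return_details)
        details[[i]] <- list(test_cells = cell, net_edges = fit$network$edges)
      if (verbose) message(sprintf("loocv %d/%d", i, length(pos_cells)))
    }
    res <- structure(list(auc = mean(fracs), fold_aucs = fracs,
                          repeat_aucs = mean(fracs), roc = NULL,
                          scheme = scheme, config = dots,
                          seed = scheme$seed),
                     class = "roc_result")
    if (return_details) res$details <- details
    return(res)
  }

  k <- scheme$k
  if (length(pos_cells) < k)
    stop("fewer verified associations than folds", call. = FALSE)
  fold_aucs <- matrix(NA_real_, scheme$repeats, k)
  repeat_aucs <- numeric(scheme$repeats)
  details <- if (return_details) list()
  roc <- NULL
  for (rep_i in seq_len(scheme$repeats)) {
    set.seed(scheme$seed + 1000L * (rep_i - 1L))
    shuffled <- sample(pos_cells)
    fold_of <- rep(seq_len(k), length.out = length(shuffled))
    pooled_scores <- numeric(0); pooled_labels <- integer(0)
    for (fold in seq_len(k)) {
      test_cells <- shuffled[fold_of == fold]
      if (length(test_cells) == 0L)
        stop("fold with zero positives", call. = FALSE)
      A_tr <- unclass(A); A_tr[test_cells] <- 0L
      fit <- fit_fold(association_matrix(A_tr),
                      scheme$seed + 100L * rep_i + fold)
      S <- predict(fit)
      sc <- c(S[test_cells], S[neg_cells])
      lb <- c(rep(1L, length(test_cells)), rep(0L, length(neg_cells)))
      fold_aucs[rep_i, fold] <- auc_score(sc, lb)
      if (rep_i == 1L) {
        pooled_scores <- c(pooled_scores, sc)
        pooled_labels <- c(pooled_labels, lb)
      }
      if (return_details)
        details[[length(details) + 1L]] <-
          list(repeat_i = rep_i, fold = fold, test_cells = test_cells,
               net_edges = fit$network$edges)
      if (verbose)
        message(sprintf("repeat %d fold %d: AUC %.4f", rep_i, fold,
                        fold_aucs[rep_i, fold]))
    }
    repeat_aucs[rep_i] <- mean(fold_aucs[rep_i, ])
    if (rep_i == 1L) roc <- roc_points(pooled_scores, pooled_labels)
  }
  res <- structure(list(auc = mean(repeat_aucs), fold_aucs = fold_aucs,
                        repeat_aucs = repeat_aucs, roc = roc,
                        scheme = scheme, config = dots, seed = scheme$seed),
                   class = "roc_result")
  if (return_details) res$details <- details
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("%s cross-validation: AUC %.4f", x$scheme$kind, x$auc))
  if (x$scheme$kind == "kfold")
    cat(sprintf(" (%d-fold, %d repeat%s)", x$scheme$k, x$scheme$repeats,
                if (x$scheme$repeats > 1) "s" else ""))
  cat("\n")
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  if (is.null(x$roc)) stop("no ROC points stored", call. = FALSE)
  graphics::plot(c(0, x$roc$fpr, 1), c(0, x$roc$tpr, 1), type = "l",
                 xlab = "false positive rate", ylab = "true positive rate",
                 ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Attention-ablation comparison run
#'
#' Runs the cross-validated pipeline with the attention mechanism either
#' active or replaced by unweighted means (both the instance and the
#' type stage), holding everything else fixed.
#'
#' @inheritParams run_cv
#' @param mode `"attention"` or `"no_attention"`.
#' @return A `"roc_result"` (see [run_cv()]).
#' @export
ablation_run <- function(A, fs = NULL, dags = NULL,
                         mode = c("attention", "no_attention"),
                         scheme = cv_scheme(), ...) {
  mode <- match.arg(mode)
  run_cv(A, fs = fs, dags = dags, scheme = scheme,
         attention = (mode == "attention"), ...)
}

#' New-disease case study: rank candidates for a zeroed disease
#'
#' Emulates prediction for a disease with no verified miRNAs: all
#' associations of `disease` are set to zero, the model is retrained on
#' the remaining data, and every miRNA is ranked for the disease by its
#' association score.
#'
#' @inheritParams run_cv
#' @param disease Disease identifier (must be a column of `A`).
#' @param top_k Number of top candidates to return (default 50).
#' @return Data frame `rank`, `mirna`, `disease`, `score`, with the
#'   fitted model in `attr(, "fit")`.
#' @export
case_study <- function(A, fs = NULL, dags = NULL, disease, top_k = 50, ...) {
  A <- check_association(A)
  dj <- if (is.character(disease)) match(disease, colnames(A))
        else as.integer(disease)
  if (is.na(dj) || dj < 1 || dj > ncol(A))
    stop(sprintf("unknown disease %s", sQuote(disease)), call. = FALSE)
  A_tr <- unclass(A)
  A_tr[, dj] <- 0L
  fit <- metamir(association_matrix(A_tr), fs = fs, dags = dags, ...)
  ranked <- rank_candidates(fit, dj, top_k = top_k)
  attr(ranked, "fit") <- fit
  ranked
}
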