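test_that("AUC equals the pairwise-comparison oracle including ties", {
  set.seed(13)
  for (rep in 1:6) {
    n <- sample(20:200, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    scores <- sample(seq_len(8), n, replace = TRUE) / 8  # forces ties
    expect_equal(auc_score(scores, labels), oracle_auc(scores, labels))
  }
  expect_equal(auc_score(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc_score(c(4, 3, 2, 1), c(0, 0, 1, 1)), 0)
  expect_error(auc_score(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC of label-independent scores is near one half", {
  set.seed(14)
  n <- 1e4
  auc <- auc_score(rnorm(n), rbinom(n, 1, 0.5))
  expect_lt(abs(auc - 0.5), 0.03)  # ~5 sigma of the sampling error
})

test_that("ROC points are monotone along the curve", {
  set.seed(15)
  scores <- rnorm(200); labels <- rbinom(200, 1, 0.3)
  roc <- roc_points(scores, labels)
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_equal(roc$tpr[nrow(roc)], 1)
  expect_equal(roc$fpr[nrow(roc)], 1)
})

test_that("cross-validation scheme is validated", {
  expect_error(cv_scheme("kfold", k = 1), "k must be")
  expect_error(cv_scheme(repeats = 0), "repeats")
  expect_equal(cv_scheme("loocv")$kind, "loocv")
})

cv_data <- function(seed = 6)
  generate_synthetic(synthetic_config(n_mirnas = 10, n_diseases = 8,
                                      seed = seed))

fast <- list(embed_dim = 8, max_length = 2, epochs = 3, batch_size = 256)

test_that("k-fold partitions positives into near-equal folds and is seeded", {
  syn <- cv_data()
  r1 <- do.call(run_cv, c(list(A = syn$A, fs = syn$fs, dags = syn$dags,
                               scheme = cv_scheme("kfold", k = 5, seed = 2),
                               return_details = TRUE), fast))
  sizes <- vapply(r1$details, function(d) length(d$test_cells), integer(1))
  expect_lte(diff(range(sizes)), 1L)
  expect_equal(sum(sizes), sum(syn$A))
  r2 <- do.call(run_cv, c(list(A = syn$A, fs = syn$fs, dags = syn$dags,
                               scheme = cv_scheme("kfold", k = 5, seed = 2),
                               return_details = TRUE), fast))
  expect_identical(lapply(r1$details, `[[`, "test_cells"),
                   lapply(r2$details, `[[`, "test_cells"))
  expect_identical(r1$fold_aucs, r2$fold_aucs)
  expect_true(r1$auc >= 0 && r1$auc <= 1)
})

test_that("held-out positives leak into no fold network", {
  syn <- cv_data()
  res <- do.call(run_cv, c(list(A = syn$A, fs = syn$fs, dags = syn$dags,
                                scheme = cv_scheme("kfold", k = 4, seed = 3),
                                return_details = TRUE), fast))
  m <- nrow(syn$A)
  for (d in res$details) {
    held <- paste((d$test_cells - 1L) %% m + 1L,
                  m + (d$test_cells - 1L) %/% m + 1L)
    md <- d$net_edges[d$net_edges$class == "M-D", ]
    expect_length(intersect(held, paste(md$i, md$j)), 0)
  }
})

test_that("global LOOCV ranks each held-out pair against same-disease candidates", {
  syn <- generate_synthetic(synthetic_config(n_mirnas = 6, n_diseases = 4,
                                             seed = 8))
  res <- do.call(run_cv, c(list(A = syn$A, fs = syn$fs, dags = syn$dags,
                                scheme = cv_scheme("loocv", seed = 1)),
                           list(embed_dim = 6, max_length = 1, epochs = 2)))
  expect_length(res$fold_aucs, sum(syn$A))
  expect_true(all(res$fold_aucs >= 0 & res$fold_aucs <= 1))
  expect_equal(res$auc, mean(res$fold_aucs))
})

test_that("reusing full-data similarities is available as an explicit escape hatch", {
  syn <- cv_data()
  res <- do.call(run_cv, c(list(A = syn$A, fs = syn$fs, dags = syn$dags,
                                scheme = cv_scheme("kfold", k = 4, seed = 5),
                                reuse_similarity = TRUE), fast))
  expect_true(is.finite(res$auc))
})

test_that("the attention and mean-encoder variants coincide on singleton groups", {
  # single M-D edge: every (target, type) group and type set is a
  # singleton, so softmax weights are uniform and both variants agree
  A <- association_matrix(matrix(1, 1, 1))
  SM <- matrix(1, 1, 1, dimnames = list("r1", "r1"))
  SD <- matrix(1, 1, 1, dimnames = list("d1", "d1"))
  f_att <- metamir(A, SM = SM, SD = SD, embed_dim = 4, max_length = 1,
                   epochs = 3, seed = 2, attention = TRUE)
  f_mean <- metamir(A, SM = SM, SD = SD, embed_dim = 4, max_length = 1,
                    epochs = 3, seed = 2, attention = FALSE)
  expect_equal(f_att$embeddings, f_mean$embeddings, tolerance = 1e-10)
})

test_that("the new-disease case study zeroes the disease before training", {
  syn <- cv_data(seed = 9)
  target <- colnames(syn$A)[2]
  ranked <- do.call(case_study, c(list(A = syn$A, fs = syn$fs,
                                       dags = syn$dags, disease = target,
                                       top_k = 5, seed = 1), fast))
  expect_equal(nrow(ranked), 5L)
  expect_identical(ranked$disease, rep(target, 5))
  fit <- attr(ranked, "fit")
  m <- nrow(syn$A)
  md <- fit$network$edges[fit$network$edges$class == "M-D", ]
  expect_false((m + 2L) %in% c(md$j))  # no training edge touches the disease
  # ranking equals the sort-by-score oracle over all miRNAs
  S <- predict(fit)[, 2L]
  oracle <- order(-S, seq_along(S))[1:5]
  expect_identical(ranked$mirna, rownames(syn$A)[oracle])
  expect_equal(formals(case_study)$top_k, 50)  # shipped default
  expect_error(do.call(case_study,
                       c(list(A = syn$A, fs = syn$fs, dags = syn$dags,
                              disease = "nope"), fast)),
               "unknown disease")
})

test_that("ablation_run dispatches the attention mode", {
  syn <- cv_data(seed = 10)
  res <- do.call(ablation_run,
                 c(list(A = syn$A, fs = syn$fs, dags = syn$dags,
                        mode = "no_attention",
                        scheme = cv_scheme("kfold", k = 4, seed = 4)), fast))
  expect_false(res$config$attention)
  expect_true(is.finite(res$auc))
})
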