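#' Read a miRNA-disease association list
#'
#' Reads a two-column tab-separated file of `miRNA<TAB>disease` pairs
#' into a binary association matrix over the sorted unique labels.
#' Duplicated pairs are counted once (with a message); malformed lines
#' are reported with their line number.
#'
#' @param path File path.
#' @param header Does the file carry a header line? Default `FALSE`.
#' @return An [association_matrix()].
#' @export
read_associations <- function(path, header = FALSE) {
  lines <- readLines(path)
  if (header) lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("malformed association line %d in %s: expected 2 tab-separated fields",
                 bad[1L] + header, path), call. = FALSE)
  pairs <- do.call(rbind, parts)
  dup <- duplicated(pairs)
  if (any(dup))
    message(sprintf("%d duplicated association pair(s) counted once",
                    sum(dup)))
  pairs <- pairs[!dup, , drop = FALSE]
  mirnas <- sort(unique(pairs[, 1L]))
  diseases <- sort(unique(pairs[, 2L]))
  A <- matrix(0L, length(mirnas), length(diseases),
              dimnames = list(mirnas, diseases))
  A[cbind(match(pairs[, 1L], mirnas), match(pairs[, 2L], diseases))] <- 1L
  association_matrix(A)
}

#' Write an association matrix as a pair list
#'
#' @param A Association matrix.
#' @param path Output path (TSV, `miRNA<TAB>disease`, no header).
#' @export
write_associations <- function(A, path) {
  A <- check_association(A)
  cells <- which(unclass(A) == 1L, arr.ind = TRUE)
  cells <- cells[order(cells[, 1L], cells[, 2L]), , drop = FALSE]
  writeLines(paste(rownames(A)[cells[, 1L]], colnames(A)[cells[, 2L]],
                   sep = "\t"), path)
}

#' Read a labelled similarity matrix
#'
#' CSV dialect: header row of labels, first column of labels, decimal
#' values.  The matrix is validated on read: asymmetry beyond `1e-9` or
#' values outside \[0, 1\] are rejected.
#'
#' @param path File path.
#' @return Symmetric numeric matrix with row/column labels.
#' @export
read_similarity <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1L)
  S <- as.matrix(df)
  if (!identical(rownames(S), colnames(S)))
    stop(sprintf("similarity file %s: row and column labels differ", path),
         call. = FALSE)
  check_similarity(S, sprintf("similarity matrix %s", path))
}

#' Write a labelled similarity matrix
#'
#' Values are written with 17 significant digits so the
#' write-then-read round trip is lossless.
#'
#' @param S Similarity matrix with labels.
#' @param path Output CSV path.
#' @export
write_similarity <- function(S, path) {
  S <- as.matrix(S)
  lab <- rownames(S)
  body <- apply(S, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = ","))
  writeLines(c(paste(c("", lab), collapse = ","),
               paste(lab, body, sep = ",")), path)
}

#' Read disease DAGs from an edge list and a disease manifest
#'
#' The edge list is a two-column TSV `child<TAB>parent` over disease
#' terms (a global MeSH-like hierarchy); the manifest lists one target
#' disease per line.  Each disease's DAG is derived by ancestor closure.
#'
#' @param path Edge-list TSV path.
#' @param manifest Path of the disease manifest, or a character vector
#'   of disease terms.
#' @return List of [disease_dag()] objects.
#' @export
read_dags <- function(path, manifest) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("malformed DAG edge line %d in %s", bad[1L], path),
         call. = FALSE)
  tab <- do.call(rbind, parts)
  edges <- data.frame(parent = tab[, 2L], child = tab[, 1L],
                      stringsAsFactors = FALSE)
  diseases <- if (length(manifest) == 1L && file.exists(manifest))
    readLines(manifest) else as.character(manifest)
  diseases <- diseases[nzchar(diseases)]
  lapply(diseases, disease_dag, edges = edges)
}

#' Write disease DAGs as an edge list plus manifest
#'
#' @param dags List of [disease_dag()] objects.
#' @param path Edge-list TSV output (`child<TAB>parent`).
#' @param manifest Manifest output path (one disease per line).
#' @export
write_dags <- function(dags, path, manifest) {
  edges <- unique(do.call(rbind, lapply(dags, `[[`, "edges")))
  edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
  writeLines(paste(edges$child, edges$parent, sep = "\t"), path)
  writeLines(vapply(dags, `[[`, character(1), "disease"), manifest)
}

#' Write or read a heterogeneous network as a typed edge list
#'
#' TSV dialect `node1<TAB>node2<TAB>edge_class` with edge classes
#' `M-D`, `M-M`, `D-D`; for `M-D` rows, `node1` is the miRNA.  Isolated
#' nodes are not representable in an edge list, so reading back a
#' network with isolated nodes drops them.
#'
#' @param net A [build_network()] object.
#' @param path File path.
#' @return `read_network` returns a `"hetnet"` object.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "hetnet"))
  e <- net$edges
  writeLines(paste(net$labels[e$i], net$labels[e$j], e$class, sep = "\t"),
             path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop(sprintf("malformed network line %d in %s", bad[1L], path),
         call. = FALSE)
  tab <- do.call(rbind, parts)
  cls <- tab[, 3L]
  if (!all(cls %in% c("M-D", "M-M", "D-D")))
    stop("unknown edge class in network file", call. = FALSE)
  mirnas <- sort(unique(c(tab[cls == "M-D", 1L], tab[cls == "M-M", 1L],
                          tab[cls == "M-M", 2L])))
  diseases <- sort(unique(c(tab[cls == "M-D", 2L], tab[cls == "D-D", 1L],
                            tab[cls == "D-D", 2L])))
  overlap <- intersect(mirnas, diseases)
  if (length(overlap))
    stop(sprintf("node %s used as both miRNA and disease",
                 sQuote(overlap[1L])), call. = FALSE)
  A <- matrix(0L, length(mirnas), length(diseases),
              dimnames = list(mirnas, diseases))
  md <- tab[cls == "M-D", , drop = FALSE]
  A[cbind(match(md[, 1L], mirnas), match(md[, 2L], diseases))] <- 1L
  SM <- diag(1, length(mirnas)); dimnames(SM) <- list(mirnas, mirnas)
  mm <- tab[cls == "M-M", , drop = FALSE]
  SM[cbind(match(mm[, 1L], mirnas), match(mm[, 2L], mirnas))] <- 1
  SM[cbind(match(mm[, 2L], mirnas), match(mm[, 1L], mirnas))] <- 1
  SD <- diag(1, length(diseases)); dimnames(SD) <- list(diseases, diseases)
  dd <- tab[cls == "D-D", , drop = FALSE]
  SD[cbind(match(dd[, 1L], diseases), match(dd[, 2L], diseases))] <- 1
  SD[cbind(match(dd[, 2L], diseases), match(dd[, 1L], diseases))] <- 1
  build_network(association_matrix(A), SM, SD, sim_threshold = 1)
}

#' Write ranked predictions as TSV
#'
#' Columns `rank`, `miRNA`, `disease`, `score`.
#'
#' @param ranked Data frame from [rank_candidates()] or [case_study()].
#' @param path Output path.
#' @export
write_predictions <- function(ranked, path) {
  out <- data.frame(rank = ranked$rank, miRNA = ranked$mirna,
                    disease = ranked$disease,
                    score = formatC(ranked$score, digits = 17, format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write cross-validation metrics as JSON
#'
#' Emits the overall AUC, per-fold AUCs, the seed and a hash of the
#' configuration, so a run can be replayed.
#'
#' @param result A `"roc_result"` from [run_cv()].
#' @param path Output JSON path.
#' @export
write_metrics <- function(result, path) {
  stopifnot(inherits(result, "roc_result"))
  jsonlite::write_json(
    list(kind = result$scheme$kind, auc = result$auc,
         fold_aucs = as.vector(result$fold_aucs),
         repeat_aucs = result$repeat_aucs, seed = result$seed,
         config_hash = config_hash(result$config)),
    path, auto_unbox = TRUE, digits = NA)
}

# md5 of the canonical JSON serialisation of a configuration list
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Load and validate a run configuration file
#'
#' YAML (or JSON) configuration mirroring the arguments of [metamir()]
#' and [run_cv()]; unknown keys are rejected with an actionable message.
#'
#' @param path Config file path, or `NULL` for the shipped defaults.
#' @return Named list of validated settings merged over the defaults.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- if (is.null(path)) {
    list()
  } else if (grepl("[.]json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs", call. = FALSE)
    yaml::read_yaml(path)
  }
  defaults <- list(associations = NULL, fs = NULL, dag_edges = NULL,
                   dag_manifest = NULL, embed_dim = 64L, max_length = 3L,
                   sim_threshold = 0.5, delta = 0.5, alpha0 = 1,
                   attention = TRUE, epochs = 100L, batch_size = 64L,
                   learning_rate = 0.005, negative_ratio = 1,
                   cv_kind = "kfold", cv_k = 5L, cv_repeats = 100L,
                   seed = 1L, simple_only = TRUE, top_k = 50L)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s (known: %s)",
                 paste(unknown, collapse = ", "),
                 paste(names(defaults), collapse = ", ")), call. = FALSE)
  out <- utils::modifyList(defaults, cfg)
  num_keys <- c("embed_dim", "max_length", "sim_threshold", "delta",
                "alpha0", "epochs", "batch_size", "learning_rate",
                "negative_ratio", "cv_k", "cv_repeats", "seed", "top_k")
  for (key in num_keys)
    if (!is.numeric(out[[key]]) || length(out[[key]]) != 1L)
      stop(sprintf("config key %s must be a single number", sQuote(key)),
           call. = FALSE)
  if (out$sim_threshold < 0 || out$sim_threshold > 1)
    stop("config error: sim_threshold must be in [0, 1]", call. = FALSE)
  if (!out$cv_kind %in% c("kfold", "loocv"))
    stop("config error: cv_kind must be 'kfold' or 'loocv'", call. = FALSE)
  out
}
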