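#' Build the miRNA-disease heterogeneous network
#'
#' Combines three edge classes into one undirected graph: `M-D` edges for
#' every verified association, `M-M` edges between miRNAs whose
#' integrated similarity reaches `sim_threshold`, and `D-D` edges between
#' diseases likewise.  Nodes are the `m` miRNAs followed by the `n`
#' diseases.  The dense similarity matrices are only thresholded here;
#' their values are not carried as edge weights.
#'
#' @param A Binary association matrix.
#' @param SM `m x m` integrated miRNA similarity matrix.
#' @param SD `n x n` integrated disease similarity matrix.
#' @param sim_threshold Minimum off-diagonal similarity for an `M-M` or
#'   `D-D` edge, in \[0, 1\] (default 0.5).
#' @return Object of class `"hetnet"`: node labels and classes, an
#'   adjacency list, and the edge table.
#' @export
build_network <- function(A, SM, SD, sim_threshold = 0.5) {
  A <- check_association(A)
  if (!is.numeric(sim_threshold) || length(sim_threshold) != 1L ||
      is.na(sim_threshold) || sim_threshold < 0 || sim_threshold > 1)
    stop("config error: sim_threshold must be a number in [0, 1]",
         call. = FALSE)
  SM <- check_similarity(SM, "SM")
  SD <- check_similarity(SD, "SD")
  m <- nrow(A); n <- ncol(A)
  if (nrow(SM) != m || nrow(SD) != n ||
      (!is.null(rownames(SM)) && !identical(rownames(SM), rownames(A))) ||
      (!is.null(rownames(SD)) && !identical(rownames(SD), colnames(A))))
    stop("label sets of A, SM and SD are inconsistent", call. = FALSE)
  N <- m + n
  labels <- c(rownames(A), colnames(A))
  classes <- rep(c("M", "D"), c(m, n))

  md <- which(unclass(A) == 1L, arr.ind = TRUE)
  mm <- which(SM >= sim_threshold & upper.tri(SM), arr.ind = TRUE)
  dd <- which(SD >= sim_threshold & upper.tri(SD), arr.ind = TRUE)
  edges <- rbind(
    if (nrow(md)) cbind(md[, 1L], m + md[, 2L]),
    if (nrow(mm)) cbind(mm[, 1L], mm[, 2L]),
    if (nrow(dd)) cbind(m + dd[, 1L], m + dd[, 2L]))
  if (is.null(edges)) edges <- matrix(integer(), 0L, 2L)
  cls <- c(rep("M-D", nrow(md)), rep("M-M", nrow(mm)), rep("D-D", nrow(dd)))

  adj <- vector("list", N)
  both <- rbind(edges, edges[, 2:1, drop = FALSE])
  sp <- split(both[, 2L], factor(both[, 1L], levels = seq_len(N)))
  adj <- lapply(sp, function(v) as.integer(sort(v)))
  structure(list(labels = labels, classes = classes, m = m, n = n,
                 adj = adj,
                 edges = data.frame(i = as.integer(edges[, 1L]),
                                    j = as.integer(edges[, 2L]),
                                    class = cls, stringsAsFactors = FALSE),
                 sim_threshold = sim_threshold),
            class = "hetnet")
}

#' @export
print.hetnet <- function(x, ...) {
  tab <- table(factor(x$edges$class, levels = c("M-D", "M-M", "D-D")))
  cat(sprintf(
    "heterogeneous network: %d miRNAs + %d diseases; edges: %d M-D, %d M-M, %d D-D\n",
    x$m, x$n, tab[["M-D"]], tab[["M-M"]], tab[["D-D"]]))
  invisible(x)
}

#' Enumerate meta-path types
#'
#' A meta-path type of length `L` is a sequence of `L + 1` node classes
#' over \{M, D\}; because all three edge classes exist in the
#' heterogeneous network, every class sequence is realizable.  Types are
#' returned for all lengths `1..max_length`, in a fixed order that the
#' rest of the package (attention parameters, instance type ids) indexes
#' into.
#'
#' @param max_length Maximum meta-path length (edge count), >= 1.
#' @return Character vector of class sequences, e.g. `"MDMD"`; its
#'   length is `sum(2^(l+1))` over `l = 1..max_length` (28 for
#'   `max_length = 3`).
#' @examples
#' enumerate_types(1)  # "MM" "DM" "MD" "DD"
#' @export
enumerate_types <- function(max_length = 3) {
  if (!is.numeric(max_length) || length(max_length) != 1L || max_length < 1)
    stop("max_length must be >= 1", call. = FALSE)
  max_length <- as.integer(max_length)
  unlist(lapply(seq_len(max_length), function(l) {
    grid <- do.call(expand.grid,
                    c(rep(list(c("M", "D")), l + 1L),
                      list(stringsAsFactors = FALSE)))
    do.call(paste0, grid)
  }))
}

#' Extract all meta-path instances from a heterogeneous network
#'
#' Performs an exhaustive depth-first enumeration of every path of
#' length `1..max_length` starting at every node.  Each concrete path is
#' a meta-path instance; its type is the sequence of node classes along
#' it, its target the first node and its meta-path based neighbour the
#' last.  Instances are grouped by (target, type), the unit over which
#' instance attention later operates.
#'
#' @param net A [build_network()] object.
#' @param max_length Maximum path length in edges (default 3).
#' @param simple_only If `TRUE` (default) no node may repeat within an
#'   instance; cyclic walks mostly duplicate the information already in
#'   shorter paths.
#' @return Object of class `"metapath_instances"` with the instance
#'   table (`paths` node-index matrix, `length`, `type`, `target`,
#'   `neighbour`) and a (target, type) grouping index used by the
#'   encoder.
#' @export
extract_instances <- function(net, max_length = 3, simple_only = TRUE) {
  stopifnot(inherits(net, "hetnet"))
  if (!is.numeric(max_length) || length(max_length) != 1L || max_length < 1)
    stop("max_length must be >= 1", call. = FALSE)
  max_length <- as.integer(max_length)
  cls01 <- as.integer(net$classes == "D")
  res <- cpp_extract_paths(net$adj, cls01, max_length, isTRUE(simple_only))
  paths <- res$paths
  types <- enumerate_types(max_length)
  inst <- list(paths = paths, length = res$len, type_id = res$type,
               target = if (nrow(paths)) paths[, 1L] else integer(),
               max_length = max_length, simple_only = isTRUE(simple_only),
               types = types, labels = net$labels, classes = net$classes)
  inst$neighbour <- if (nrow(paths))
    paths[cbind(seq_len(nrow(paths)), inst$length + 1L)] else integer()
  inst$groups <- group_instances(inst, length(net$labels))
  class(inst) <- "metapath_instances"
  inst
}

# Sort instances by (target, type) and record contiguous group ranges,
# plus for every node the range of its groups.  This is the layout the
# C++ encoder consumes.
group_instances <- function(inst, n_nodes) {
  ni <- nrow(inst$paths)
  if (ni == 0L) {
    return(list(order = integer(), paths = inst$paths,
                length = integer(), type_id = integer(),
                grp_start = integer(), grp_end = integer(),
                grp_type = integer(), grp_target = integer(),
                node_g0 = integer(n_nodes), node_g1 = integer(n_nodes)))
  }
  o <- order(inst$target, inst$type_id, method = "radix")
  paths <- inst$paths[o, , drop = FALSE]
  len <- inst$length[o]
  type <- inst$type_id[o]
  tgt <- paths[, 1L]
  new_grp <- c(TRUE, diff(tgt) != 0L | diff(type) != 0L)
  grp_start <- which(new_grp)
  grp_end <- c(grp_start[-1L] - 1L, ni)
  grp_target <- tgt[grp_start]
  grp_type <- type[grp_start]
  node_g0 <- integer(n_nodes); node_g1 <- integer(n_nodes)
  new_node <- c(TRUE, diff(grp_target) != 0L)
  ng0 <- which(new_node)
  ng1 <- c(ng0[-1L] - 1L, length(grp_start))
  node_g0[grp_target[ng0]] <- ng0
  node_g1[grp_target[ng0]] <- ng1
  list(order = o, paths = paths, length = len, type_id = type,
       grp_start = grp_start, grp_end = grp_end, grp_type = grp_type,
       grp_target = grp_target, node_g0 = node_g0, node_g1 = node_g1)
}

#' @export
print.metapath_instances <- function(x, ...) {
  cat(sprintf("meta-path instances: %d instances, max length %d (%s paths)\n",
              nrow(x$paths), x$max_length,
              if (x$simple_only) "simple" else "non-simple"))
  tab <- instance_counts(x)
  print(utils::head(tab[order(-tab$instances), ], 10L), row.names = FALSE)
  invisible(x)
}

#' Per-type instance counts
#'
#' Diagnostic for the meta-path length / run-time trade-off: the number
#' of extracted instances of each meta-path type.
#'
#' @param instances A [extract_instances()] result.
#' @return Data frame with columns `type`, `length`, `instances`.
#' @export
instance_counts <- function(instances) {
  stopifnot(inherits(instances, "metapath_instances"))
  tid <- factor(instances$type_id, levels = seq_along(instances$types))
  data.frame(type = instances$types,
             length = nchar(instances$types) - 1L,
             instances = as.integer(table(tid)),
             stringsAsFactors = FALSE)
}

#' Meta-path based neighbours of a target node
#'
#' The neighbours of `target` under meta-path type `type`: the last
#' nodes of all matching instances, with multiplicity (one instance, one
#' neighbour).
#'
#' @param instances A [extract_instances()] result.
#' @param target Node label (or index) of the target.
#' @param type Meta-path type as a class string, e.g. `"MMDD"`.
#' @return Character vector of neighbour node labels (possibly empty).
#' @export
neighbours_by_type <- function(instances, target, type) {
  stopifnot(inherits(instances, "metapath_instances"))
  if (is.character(target)) {
    idx <- match(target, instances$labels)
    if (is.na(idx)) stop(sprintf("unknown node %s", sQuote(target)),
                         call. = FALSE)
  } else idx <- as.integer(target)
  tid <- match(type, instances$types)
  if (is.na(tid)) stop(sprintf("unknown meta-path type %s", sQuote(type)),
                       call. = FALSE)
  sel <- instances$target == idx & instances$type_id == tid
  instances$labels[instances$neighbour[sel]]
}
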