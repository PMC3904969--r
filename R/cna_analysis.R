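#' Call copy-number alterations per branch
#'
#' A CNA is any isoenzyme group whose (integer-resolved) gene count at a
#' node differs from the count at its direct ancestor.
#'
#' @param states a `node_state_matrix` from [reconstruct_all()].
#' @return data.frame of class `cna_events` with columns `parent`,
#'   `child`, `group`, `delta` (child minus parent, never 0), plus an
#'   attribute `branch_counts` (events per branch, named
#'   `parent->child`).
#' @export
cna_events <- function(states) {
  stopifnot(inherits(states, "node_state_matrix"))
  tix <- tree_index(states$tree)
  m <- states$integer_values
  ev <- list()
  labels <- branch_labels(tix)
  counts <- setNames(integer(length(labels)), labels)
  for (k in seq_along(tix$edge_parent)) {
    p <- tix$node_names[tix$edge_parent[k]]
    c_ <- tix$node_names[tix$edge_child[k]]
    d <- m[c_, ] - m[p, ]
    nz <- which(d != 0)
    counts[k] <- length(nz)
    if (length(nz)) {
      ev[[length(ev) + 1L]] <- data.frame(
        parent = p, child = c_, group = colnames(m)[nz],
        delta = as.integer(d[nz]), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(parent = character(), child = character(),
               group = character(), delta = integer())
  attr(out, "branch_counts") <- counts
  class(out) <- c("cna_events", "data.frame")
  out
}

#' Write CNA events as TSV
#' @param events a `cna_events` data.frame.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_cna_events <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Euclidean network distance between two copy-number vectors
#'
#' @param vA,vB numeric vectors over the same named group set (or
#'   `copy_number_vector` objects).
#' @return `sqrt(sum((vA - vB)^2))`.
#' @export
network_distance <- function(vA, vB) {
  if (inherits(vA, "copy_number_vector")) vA <- vA$counts
  if (inherits(vB, "copy_number_vector")) vB <- vB$counts
  if (length(vA) != length(vB)) stop("copy-number vectors differ in length")
  if (!is.null(names(vA)) && !is.null(names(vB))) {
    if (!setequal(names(vA), names(vB))) stop("copy-number vectors disagree on group sets")
    vB <- vB[names(vA)]
  }
  sqrt(sum((vA - vB)^2))
}

#' Power-law regression of network divergence on divergence time
#'
#' Fits `y = a * x^b` by least squares of `log y` on `log x`; `R` is the
#' Pearson correlation of the logs.  Non-positive pairs are excluded with
#' a warning.
#'
#' @param time numeric vector of divergence times (million years), or a
#'   two-column data.frame of (time, distance).
#' @param distance numeric vector of network distances.
#' @return An object of class `divergence_fit`: list `a`, `b`, `R`,
#'   `n_used`.
#' @export
divergence_regression <- function(time, distance = NULL) {
  if (is.null(distance)) { distance <- time[[2]]; time <- time[[1]] }
  keep <- is.finite(time) & is.finite(distance) & time > 0 & distance > 0
  if (any(!keep)) warning(sum(!keep), " non-positive or missing pairs excluded")
  time <- time[keep]; distance <- distance[keep]
  if (length(time) < 3) stop("need at least 3 positive (time, distance) pairs")
  lx <- log(time); ly <- log(distance)
  fit <- lm(ly ~ lx)
  structure(list(a = unname(exp(coef(fit)[1])), b = unname(coef(fit)[2]),
                 R = cor(lx, ly), n_used = length(time)),
            class = "divergence_fit")
}

#' @export
print.divergence_fit <- function(x, ...) {
  cat("y = ", signif(x$a, 4), " * x^", signif(x$b, 4),
      "   (log-log R = ", round(x$R, 3), ", n = ", x$n_used, ")\n", sep = "")
  invisible(x)
}

# fast weak-component statistics over an induced node subset, using a
# precomputed integer edge list; union-find.  Returns c(n_components,
# max_size, mean_size).
component_stats <- function(n_sel, sel_id, ef, et, member) {
  keep <- member[ef] & member[et]
  parent <- seq_len(n_sel)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (any(keep)) {
    a <- sel_id[ef[keep]]; b <- sel_id[et[keep]]
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(n_sel), find, integer(1))
  sizes <- tabulate(roots, nbins = n_sel)
  sizes <- sizes[sizes > 0]
  c(length(sizes), max(sizes), mean(sizes))
}

#' Permutation test for CNA clustering in the network
#'
#' Removes all nodes without CNAs and computes, on the induced subgraph
#' of CNA nodes, the number of (weak) connected components and their
#' maximum and mean size, plus the mean in- and out-degree of the CNA
#' nodes in the full network.  The null randomizes the position of the
#' CNAs: `|cna_nodes|` nodes are drawn uniformly without replacement and
#' the statistics recomputed, `n_perm` times (topology is never
#' randomized).  For each statistic two one-sided empirical p-values with
#' the +1 correction are reported, and a classification at `alpha` into
#' `"bigger"`, `"smaller"` or `"ns"`.
#'
#' @param net an `enzyme_orthology_network` or igraph graph.
#' @param cna_nodes character vector of node names (or integer indices)
#'   carrying CNAs.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed for reproducibility.
#' @param alpha classification level (default 0.05).
#' @return An object of class `cluster_test_result` with elements
#'   `observed`, `p_greater`, `p_smaller`, `classification`, `null`
#'   (matrix of null statistics), `n_perm`, `seed`, `degenerate`.
#' @export
cluster_test <- function(net, cna_nodes, n_perm = 1000, seed = NULL, alpha = 0.05) {
  g <- eon_graph(net)
  n <- igraph::vcount(g)
  vnames <- igraph::V(g)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(n))
  if (is.numeric(cna_nodes)) cna_nodes <- vnames[cna_nodes]
  cna_nodes <- unique(as.character(cna_nodes))
  bad <- setdiff(cna_nodes, vnames)
  if (length(bad)) stop("cna_nodes not in network: ", paste(head(bad, 5), collapse = ", "))
  m <- length(cna_nodes)

  el <- igraph::as_edgelist(g, names = FALSE)
  ef <- el[, 1]; et <- el[, 2]
  deg_in <- igraph::degree(g, mode = "in")
  deg_out <- igraph::degree(g, mode = "out")

  stat_names <- c("n_components", "max_component_size", "mean_component_size",
                  "mean_in_degree", "mean_out_degree")
  stats_for <- function(idx) {
    member <- logical(n); member[idx] <- TRUE
    sel_id <- integer(n); sel_id[idx] <- seq_along(idx)
    cs <- component_stats(length(idx), sel_id, ef, et, member)
    setNames(c(cs, mean(deg_in[idx]), mean(deg_out[idx])), stat_names)
  }

  obs_idx <- match(cna_nodes, vnames)
  observed <- if (m == 0) {
    setNames(c(0, 0, NA, NA, NA), stat_names)
  } else {
    stats_for(obs_idx)
  }

  degenerate <- m == 0 || m == n
  if (degenerate) {
    p_ge <- p_le <- setNames(rep(1, length(stat_names)), stat_names)
    null_mat <- matrix(numeric(), 0, length(stat_names),
                       dimnames = list(NULL, stat_names))
  } else {
    if (!is.null(seed)) set.seed(seed)
    null_mat <- matrix(NA_real_, n_perm, length(stat_names),
                       dimnames = list(NULL, stat_names))
    for (b in seq_len(n_perm)) {
      null_mat[b, ] <- stats_for(sample.int(n, m))
    }
    p_ge <- (1 + colSums(null_mat >= rep(observed, each = n_perm))) / (1 + n_perm)
    p_le <- (1 + colSums(null_mat <= rep(observed, each = n_perm))) / (1 + n_perm)
  }
  classification <- ifelse(p_ge <= alpha, "bigger",
                           ifelse(p_le <= alpha, "smaller", "ns"))
  names(classification) <- stat_names
  structure(list(observed = observed, p_greater = p_ge, p_smaller = p_le,
                 classification = classification, null = null_mat,
                 n_perm = n_perm, seed = seed, alpha = alpha,
                 degenerate = degenerate),
            class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat("CNA clustering permutation test (", x$n_perm, " permutations",
      if (x$degenerate) ", degenerate" else "", ")\n", sep = "")
  tab <- data.frame(observed = round(x$observed, 3),
                    p_greater = round(x$p_greater, 4),
                    p_smaller = round(x$p_smaller, 4),
                    class = x$classification)
  print(tab)
  invisible(x)
}
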