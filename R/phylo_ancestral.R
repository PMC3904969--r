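#' Ancestral reconstruction of a continuous character by parsimony
#'
#' Linear (Wagner) parsimony minimizes the sum over branches of
#' `|child - parent|`.  The implementation is the exact interval dynamic
#' program: an up-pass merges child state intervals (median interval of
#' the child interval endpoints, valid for multifurcations), a down-pass
#' resolves one optimal assignment by clamping each node's value to its
#' optimal interval, choosing the value closest to the resolved parent;
#' the root takes the midpoint of its interval.  Branch lengths play no
#' role in the cost.  Missing tip values impose no cost and are imputed
#' on the down-pass.
#'
#' `method = "squared"` instead minimizes the sum of squared changes
#' (quadratic dynamic program, unique optimum), offered as an
#' alternative; integer gene counts are better served by the default.
#'
#' @param tree rooted `phylo` tree (multifurcations allowed).
#' @param tip_values numeric vector, named by tip label (or in tip order);
#'   `NA` marks missing species.  At least 2 non-missing tips required.
#' @param method `"linear"` (default) or `"squared"`.
#' @return An object of class `parsimony_reconstruction`: list with
#'   `values` (named: tips then internal nodes), `cost` (total
#'   parsimony cost) and `root_interval` (for `"linear"`, the interval of
#'   optimal root states).
#' @export
linear_parsimony_reconstruct <- function(tree, tip_values,
                                         method = c("linear", "squared")) {
  method <- match.arg(method)
  tix <- tree_index(tree)
  v <- align_tip_values(tip_values, tix)
  if (sum(!is.na(v)) < 2) stop("need at least 2 non-missing tip values")
  if (method == "linear") {
    res <- cpp_wagner(tix$edge_parent, tix$edge_child, tix$n_tip, tix$n_node, v)
    values <- setNames(res$values, tix$node_names)
    out <- list(values = values, cost = res$cost,
                root_interval = res$root_interval, method = "linear")
  } else {
    res <- squared_parsimony(tix, v)
    out <- list(values = setNames(res$values, tix$node_names), cost = res$cost,
                root_interval = rep(res$values[tix$n_tip + 1L], 2), method = "squared")
  }
  class(out) <- "parsimony_reconstruction"
  out
}

# Squared-change parsimony (unweighted): each subtree's cost function is
# a quadratic a*(x - m)^2 + c; convolving across a branch maps
# a -> a/(a+1); summing children adds quadratics.  Exact, unique optimum.
squared_parsimony <- function(tix, v) {
  n_node <- tix$n_node
  a <- numeric(n_node); m <- numeric(n_node); cst <- numeric(n_node)
  inf <- logical(n_node)
  ca <- vector("list", n_node); cm <- vector("list", n_node); cc <- vector("list", n_node)
  for (i in seq_len(tix$n_tip)) {
    if (!is.na(v[i])) { inf[i] <- TRUE; a[i] <- Inf; m[i] <- v[i] }
  }
  conv <- function(ai, mi) if (is.infinite(ai)) 1 else ai / (ai + 1)
  done <- logical(n_node); done[seq_len(tix$n_tip)] <- TRUE
  finalize <- function(p) {
    as <- ca[[p]]; ms <- cm[[p]]; cs <- cc[[p]]
    if (is.null(as) || !length(as)) return(c(0, 0, 0, 0))
    A <- sum(as); M <- sum(as * ms) / A
    C <- sum(cs) + sum(as * ms^2) - A * M^2
    c(1, A, M, C)
  }
  ne <- length(tix$edge_parent)
  for (k in seq_len(ne)) {
    p <- tix$edge_parent[k]; c_ <- tix$edge_child[k]
    if (!done[c_]) {
      f <- finalize(c_)
      inf[c_] <- f[1] > 0; a[c_] <- f[2]; m[c_] <- f[3]; cst[c_] <- f[4]
      done[c_] <- TRUE
    }
    if (inf[c_]) {
      ca[[p]] <- c(ca[[p]], conv(a[c_], m[c_]))
      cm[[p]] <- c(cm[[p]], m[c_])
      cc[[p]] <- c(cc[[p]], cst[c_])
    }
  }
  root <- tix$edge_parent[ne]
  f <- finalize(root)
  values <- rep(NA_real_, n_node)
  values[root] <- f[3]
  for (k in rev(seq_len(ne))) {
    p <- tix$edge_parent[k]; c_ <- tix$edge_child[k]
    values[c_] <- if (!inf[c_]) values[p]
      else if (is.infinite(a[c_])) m[c_]
      else (a[c_] * m[c_] + values[p]) / (a[c_] + 1)
  }
  total <- sum((values[tix$edge_child] - values[tix$edge_parent])^2)
  list(values = values, cost = total)
}

#' @export
print.parsimony_reconstruction <- function(x, ...) {
  cat("<parsimony_reconstruction> method ", x$method, ", cost ", x$cost,
      ", root interval [", x$root_interval[1], ", ", x$root_interval[2], "]\n",
      sep = "")
  invisible(x)
}

#' Reconstruct ancestral copy numbers for every isoenzyme group
#'
#' Runs an independent linear-parsimony reconstruction per group
#' (character) over the same tree.  Raw real-valued resolutions are
#' retained; an integer-resolved copy (rounding exact halves down) is
#' provided for CNA calling.
#'
#' @param tree rooted `phylo` tree with tips matching the matrix rows.
#' @param tip_counts numeric matrix, rows = species (tips), columns =
#'   groups; or a list of named per-species vectors over a common group
#'   set.  `NA` allowed.
#' @param method passed to [linear_parsimony_reconstruct()].
#' @return An object of class `node_state_matrix`: list with `values`
#'   (nodes x groups, real), `integer_values`, per-group `cost` and
#'   `root_interval`s, the `tree` (postorder) and `node_names`.
#' @export
reconstruct_all <- function(tree, tip_counts, method = c("linear", "squared")) {
  method <- match.arg(method)
  tix <- tree_index(tree)
  if (is.list(tip_counts) && !is.data.frame(tip_counts) && !is.matrix(tip_counts)) {
    sets <- lapply(tip_counts, names)
    ref <- sets[[1]]
    for (i in seq_along(sets)) {
      if (!setequal(sets[[i]], ref)) {
        diff <- union(setdiff(sets[[i]], ref), setdiff(ref, sets[[i]]))
        stop("inconsistent group sets across tips; symmetric difference: ",
             paste(diff, collapse = ", "))
      }
    }
    tip_counts <- t(vapply(tip_counts, function(v) v[ref], numeric(length(ref))))
    colnames(tip_counts) <- ref
  }
  tip_counts <- as.matrix(tip_counts)
  if (is.null(rownames(tip_counts))) {
    if (nrow(tip_counts) != tix$n_tip) stop("rows of tip_counts must match tips")
    rownames(tip_counts) <- tix$tree$tip.label
  }
  miss <- setdiff(tix$tree$tip.label, rownames(tip_counts))
  if (length(miss)) stop("tip_counts lacks species: ", paste(miss, collapse = ", "))
  tip_counts <- tip_counts[tix$tree$tip.label, , drop = FALSE]

  if (method == "linear") {
    res <- cpp_wagner_matrix(tix$edge_parent, tix$edge_child, tix$n_tip,
                             tix$n_node, tip_counts)
    values <- res$values
    cost <- res$cost
    root_int <- cbind(lo = res$root_lo, hi = res$root_hi)
  } else {
    values <- matrix(NA_real_, tix$n_node, ncol(tip_counts))
    cost <- numeric(ncol(tip_counts))
    for (j in seq_len(ncol(tip_counts))) {
      r <- squared_parsimony(tix, tip_counts[, j])
      values[, j] <- r$values; cost[j] <- r$cost
    }
    root_int <- cbind(lo = values[tix$n_tip + 1L, ], hi = values[tix$n_tip + 1L, ])
  }
  dimnames(values) <- list(tix$node_names, colnames(tip_counts))
  names(cost) <- colnames(tip_counts)
  structure(list(values = values,
                 integer_values = round_half_down(values),
                 cost = cost, root_interval = root_int,
                 tree = tix$tree, node_names = tix$node_names,
                 method = method),
            class = "node_state_matrix")
}

#' @export
print.node_state_matrix <- function(x, ...) {
  cat("<node_state_matrix> ", nrow(x$values), " nodes x ", ncol(x$values),
      " characters, total parsimony cost ", sum(x$cost), "\n", sep = "")
  invisible(x)
}

#' Write a node-state matrix as CSV
#'
#' @param states a `node_state_matrix`.
#' @param path CSV path.
#' @param integer write the integer-resolved states (default) or raw.
#' @return `path`, invisibly.
#' @export
write_node_states <- function(states, path, integer = TRUE) {
  m <- if (integer) states$integer_values else states$values
  write.csv(data.frame(node = rownames(m), m, check.names = FALSE), path,
            row.names = FALSE)
  invisible(path)
}
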