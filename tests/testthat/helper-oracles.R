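# Independent oracles and small fixture builders shared across tests.

# --- tiny model builders -------------------------------------------------

make_model <- function(mets, rxns) {
  # mets: data.frame(id, name, compartment); rxns: list of lists with
  # id, reversible, reactants, products, genes
  rx <- data.frame(
    id = vapply(rxns, `[[`, character(1), "id"),
    reversible = vapply(rxns, function(r) isTRUE(r$reversible), logical(1)),
    stringsAsFactors = FALSE
  )
  rx$reactants <- lapply(rxns, function(r) as.character(r$reactants %||% character()))
  rx$products <- lapply(rxns, function(r) as.character(r$products %||% character()))
  rx$genes <- lapply(rxns, function(r) as.character(r$genes %||% character()))
  metacna::metabolic_model(mets, rx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

simple_mets <- function(ids, comp = "c") {
  data.frame(id = ids, name = ids, compartment = comp, stringsAsFactors = FALSE)
}

# canonical form of a gene partition: sorted list of sorted gene sets
partition_of <- function(groups) {
  unname(lapply(groups$genes, sort))[order(vapply(groups$genes, function(g) sort(g)[1], ""))]
}

# --- exhaustive Sankoff oracle for linear parsimony ---------------------

# Brute-force DP over an integer state grid; exact for integer tip values
# within the grid.  Returns minimal cost and the set of optimal root states.
sankoff_oracle <- function(tree, tip_values, states = 0:5) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  tip_values <- tip_values[tree$tip.label]
  cost <- matrix(0, n_node, length(states))
  for (i in seq_len(n_tip)) {
    v <- tip_values[i]
    if (!is.na(v)) cost[i, ] <- ifelse(states == v, 0, Inf)
  }
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]; ch <- tree$edge[k, 2]
    trans <- vapply(states, function(s) min(cost[ch, ] + abs(states - s)), numeric(1))
    cost[p, ] <- cost[p, ] + trans
  }
  root <- tree$edge[nrow(tree$edge), 1]
  mc <- min(cost[root, ])
  list(cost = mc, root_states = states[cost[root, ] <= mc + 1e-9])
}

# --- exhaustive elemental-subset LMS oracle -----------------------------

# R-median of squared residuals over all rows for the best exact fit on
# any (p+1)-point subset, enumerated with combn.
lms_oracle <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); m <- ncol(X) + 1
  A <- cbind(1, X)
  best <- list(crit = Inf, coef = NULL)
  for (s in asplit(combn(n, m), 2)) {
    b <- tryCatch(solve(A[s, , drop = FALSE], y[s]), error = function(e) NULL)
    if (is.null(b) || any(!is.finite(b))) next
    crit <- median((y - A %*% b)^2)
    if (crit < best$crit) best <- list(crit = crit, coef = b)
  }
  best
}

# --- CFS merit, direct formula ------------------------------------------

cfs_merit <- function(X, y, subset) {
  k <- length(subset)
  rcf <- abs(cor(X[, subset, drop = FALSE], y))
  num <- k * mean(rcf)
  rff <- 0
  if (k > 1) {
    cm <- abs(cor(X[, subset, drop = FALSE]))
    rff <- mean(cm[upper.tri(cm)])
  }
  num / sqrt(k + k * (k - 1) * rff)
}

# --- ANOSIM R, direct rank formula --------------------------------------

anosim_oracle <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  pairs <- t(combn(n, 2))
  dv <- d[pairs]
  rk <- rank(dv)
  between <- groups[pairs[, 1]] != groups[pairs[, 2]]
  M <- length(dv)
  (mean(rk[between]) - mean(rk[!between])) / (M / 2)
}

# --- exact cluster-test null on small graphs ----------------------------

# enumerate all node subsets of size m and return P(max component >= obs)
exact_max_component_tail <- function(graph, m, obs) {
  n <- igraph::vcount(graph)
  subsets <- combn(n, m)
  vals <- apply(subsets, 2, function(idx) {
    sub <- igraph::induced_subgraph(graph, idx)
    max(igraph::components(sub, mode = "weak")$csize)
  })
  mean(vals >= obs)
}

# --- small trees ---------------------------------------------------------

balanced8 <- function() {
  ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);")
}
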