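#' Collapse model genes into isoenzyme groups
#'
#' Two-step grouping of enzyme-coding genes by their reaction sets.
#' Step 1 places genes with identical reaction sets in one group.  Step 2
#' repeatedly merges any group whose reaction set is a strict subset of
#' another group's into that group (genes are pooled; the absorbing
#' group keeps its own reaction set) until no such pair remains.  Groups
#' with overlapping but non-identical, non-nested reaction sets are never
#' merged.  Genes with no reactions are excluded.
#'
#' When a group has several incomparable strict supersets the absorber is
#' the smallest one (ties broken on the sorted reaction-id key), which
#' makes the fixpoint deterministic and independent of processing order.
#'
#' @param model a [metabolic_model()].
#' @return A data.frame of class `isoenzyme_groups` with columns `id`,
#'   `genes` (list), `reactions` (list), `n_genes`, `n_reactions`.
#' @export
build_isoenzyme_groups <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  rx_genes <- model$reactions$genes
  rx_ids <- model$reactions$id
  pairs_gene <- unlist(rx_genes, use.names = FALSE)
  pairs_rxn <- rep(rx_ids, lengths(rx_genes))
  if (!length(pairs_gene)) {
    out <- data.frame(id = character(), n_genes = integer(), n_reactions = integer())
    out$genes <- list(); out$reactions <- list()
    class(out) <- c("isoenzyme_groups", "data.frame")
    return(out)
  }
  gene_rxns <- lapply(split(pairs_rxn, pairs_gene), function(r) sort(unique(r)))

  # step 1: identical reaction sets
  keys <- vapply(gene_rxns, paste, character(1), collapse = "\x1f")
  by_key <- split(names(gene_rxns), keys)
  grp_key <- names(by_key)
  grp_rxns <- lapply(by_key[grp_key], function(g) gene_rxns[[g[1]]])
  grp_genes <- unname(by_key[grp_key])
  sizes <- lengths(grp_rxns)
  n_grp <- length(grp_key)

  # step 2: subset merging to a deterministic fixpoint.  For each group,
  # its strict supersets are the groups whose reaction sets contain all
  # of its reactions; the absorber is the minimal one by (size, key).
  rxn_members <- split(rep(seq_len(n_grp), sizes), unlist(grp_rxns, use.names = FALSE))
  target <- integer(n_grp)
  for (i in seq_len(n_grp)) {
    cand <- Reduce(intersect, rxn_members[grp_rxns[[i]]])
    cand <- cand[cand != i]
    if (!length(cand)) { target[i] <- i; next }
    ord <- order(sizes[cand], grp_key[cand])
    target[i] <- cand[ord[1]]
  }
  sink <- seq_len(n_grp)
  for (i in seq_len(n_grp)) {
    s <- i
    while (target[s] != s) s <- target[s]
    sink[i] <- s
  }
  sinks <- sort(unique(sink))
  # deterministic ordering: by descending reaction-set size, then key
  sinks <- sinks[order(-sizes[sinks], grp_key[sinks])]
  genes_out <- lapply(sinks, function(s) sort(unique(unlist(grp_genes[sink == s]))))
  rxns_out <- grp_rxns[sinks]

  out <- data.frame(
    id = sprintf("ig%04d", seq_along(sinks)),
    n_genes = lengths(genes_out),
    n_reactions = lengths(rxns_out),
    stringsAsFactors = FALSE
  )
  out$genes <- genes_out
  out$reactions <- unname(rxns_out)
  class(out) <- c("isoenzyme_groups", "data.frame")
  out
}

#' Per-group gene counts of the reference genome
#'
#' @param groups an `isoenzyme_groups` data.frame (or an
#'   `enzyme_orthology_network`).
#' @return Named integer vector, one count per group.
#' @export
reference_copy_numbers <- function(groups) {
  if (inherits(groups, "enzyme_orthology_network")) groups <- groups$groups
  setNames(as.integer(groups$n_genes), groups$id)
}

#' Build the directed enzyme orthology network
#'
#' Nodes are isoenzyme groups.  A directed edge u -> v exists when some
#' directed orientation of a reaction in u produces a metabolite that a
#' directed orientation of a reaction in v consumes.  Reversible
#' reactions contribute both orientations, handled independently.
#' Metabolite identity is compartment-specific (the species id), so edges
#' never cross compartments unless a transport reaction shares the
#' species.  Currency metabolites should be stripped from the model first
#' (see [strip_currency_metabolites()]).
#'
#' @param groups output of [build_isoenzyme_groups()].
#' @param model the (currency-stripped) [metabolic_model()].
#' @return An object of class `enzyme_orthology_network`: a list with the
#'   igraph `graph`, the `groups` table and per-node `compartments`.
#' @export
build_edges <- function(groups, model) {
  stopifnot(inherits(groups, "isoenzyme_groups"), inherits(model, "metabolic_model"))
  unknown <- setdiff(unique(unlist(groups$reactions)), model$reactions$id)
  if (length(unknown)) {
    stop("groups reference unknown reactions: ", paste(head(unknown, 5), collapse = ", "))
  }
  rx <- model$reactions
  rxn_grp <- split(rep(groups$id, lengths(groups$reactions)),
                   unlist(groups$reactions, use.names = FALSE))

  # role tables: which groups produce / consume each species id
  prod_g <- character(); prod_m <- character()
  cons_g <- character(); cons_m <- character()
  for (i in seq_len(nrow(rx))) {
    gs <- rxn_grp[[rx$id[i]]]
    if (is.null(gs)) next
    rcts <- rx$reactants[[i]]; prds <- rx$products[[i]]
    produced <- if (rx$reversible[i]) union(prds, rcts) else prds
    consumed <- if (rx$reversible[i]) union(prds, rcts) else rcts
    if (length(produced)) {
      prod_g <- c(prod_g, rep(gs, each = length(produced)))
      prod_m <- c(prod_m, rep(produced, times = length(gs)))
    }
    if (length(consumed)) {
      cons_g <- c(cons_g, rep(gs, each = length(consumed)))
      cons_m <- c(cons_m, rep(consumed, times = length(gs)))
    }
  }
  producers <- lapply(split(prod_g, prod_m), unique)
  consumers <- lapply(split(cons_g, cons_m), unique)
  shared <- intersect(names(producers), names(consumers))
  edges <- vector("list", length(shared))
  for (k in seq_along(shared)) {
    m <- shared[k]
    edges[[k]] <- cbind(
      rep(producers[[m]], each = length(consumers[[m]])),
      rep(consumers[[m]], times = length(producers[[m]]))
    )
  }
  em <- if (length(edges)) unique(do.call(rbind, edges)) else matrix(character(), ncol = 2)
  if (nrow(em)) em <- em[em[, 1] != em[, 2], , drop = FALSE]

  g <- igraph::graph_from_data_frame(
    data.frame(from = em[, 1], to = em[, 2], stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = groups$id, n_genes = groups$n_genes,
                          stringsAsFactors = FALSE)
  )
  met_comp <- setNames(model$metabolites$compartment, model$metabolites$id)
  comps <- lapply(groups$reactions, function(rs) {
    idx <- match(rs, rx$id)
    sort(unique(unname(met_comp[unique(unlist(c(rx$reactants[idx], rx$products[idx])))])))
  })
  names(comps) <- groups$id
  structure(list(graph = g, groups = groups, compartments = comps),
            class = "enzyme_orthology_network")
}

#' @export
print.enzyme_orthology_network <- function(x, ...) {
  cat("<enzyme_orthology_network> ", igraph::vcount(x$graph), " isoenzyme groups, ",
      igraph::ecount(x$graph), " directed edges\n", sep = "")
  invisible(x)
}

eon_graph <- function(net) {
  if (inherits(net, "enzyme_orthology_network")) net$graph
  else if (inherits(net, "igraph")) net
  else stop("expected an enzyme_orthology_network or igraph object")
}

#' Network statistics
#'
#' Density is computed over all ordered node pairs
#' (`n_edges / (n_nodes * (n_nodes - 1))`).  Isolated nodes have total
#' degree zero.  Diameter and average shortest path are computed over the
#' reachable ordered pairs (excluding self-pairs) of the largest weakly
#' connected component, so that isolated nodes do not make them infinite.
#'
#' @param net an `enzyme_orthology_network` or igraph graph.
#' @return A list of class `network_stats`: `n_nodes`, `n_edges`,
#'   `n_isolated`, `diameter`, `avg_shortest_path`, `density`,
#'   `degenerate` (TRUE for single-node networks, where density is
#'   reported as 0).
#' @export
network_stats <- function(net) {
  g <- eon_graph(net)
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  degenerate <- n < 2
  density <- if (degenerate) 0 else e / (n * (n - 1))
  n_isolated <- sum(igraph::degree(g, mode = "all") == 0)
  diameter <- NA_real_; asp <- NA_real_
  if (n >= 2) {
    comp <- igraph::components(g, mode = "weak")
    big <- which.max(comp$csize)
    sub <- igraph::induced_subgraph(g, which(comp$membership == big))
    d <- igraph::distances(sub, mode = "out")
    d <- d[is.finite(d) & d > 0]
    if (length(d)) { diameter <- max(d); asp <- mean(d) }
  }
  structure(list(n_nodes = n, n_edges = e, n_isolated = n_isolated,
                 diameter = diameter, avg_shortest_path = asp,
                 density = density, degenerate = degenerate),
            class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat("nodes: ", x$n_nodes, "  directed edges: ", x$n_edges,
      "  isolated: ", x$n_isolated, "\n",
      "diameter: ", x$diameter, "  avg shortest path: ",
      round(x$avg_shortest_path, 3), "  density: ", signif(x$density, 3),
      "\n", sep = "")
  invisible(x)
}

#' Cross-network node overlap through gene orthology
#'
#' A node of network A is matched in network B when at least one of its
#' genes has an ortholog belonging to some node of B (and vice versa).
#'
#' @param netA,netB `enzyme_orthology_network` objects.
#' @param gene_orthology data.frame whose first two columns are gene-id
#'   pairs (A-side id, B-side id).
#' @return A list: `fraction_A_in_B`, `fraction_B_in_A`, and
#'   `correspondence`, the node-to-node pairs implied by the orthologs.
#' @export
map_between_networks <- function(netA, netB, gene_orthology) {
  ga <- netA$groups; gb <- netB$groups
  if (!nrow(gene_orthology)) {
    warning("empty orthology table: no nodes can be matched")
    return(list(fraction_A_in_B = 0, fraction_B_in_A = 0,
                correspondence = data.frame(node_a = character(), node_b = character())))
  }
  pa <- as.character(gene_orthology[[1]]); pb <- as.character(gene_orthology[[2]])
  gene2node_a <- setNames(rep(ga$id, lengths(ga$genes)), unlist(ga$genes))
  gene2node_b <- setNames(rep(gb$id, lengths(gb$genes)), unlist(gb$genes))
  na <- unname(gene2node_a[pa]); nb <- unname(gene2node_b[pb])
  ok <- !is.na(na) & !is.na(nb)
  corr <- unique(data.frame(node_a = na[ok], node_b = nb[ok], stringsAsFactors = FALSE))
  list(
    fraction_A_in_B = length(unique(corr$node_a)) / nrow(ga),
    fraction_B_in_A = length(unique(corr$node_b)) / nrow(gb),
    correspondence = corr
  )
}

#' Export the enzyme orthology network as GraphML
#'
#' @param net an `enzyme_orthology_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(eon_graph(net), path, format = "graphml")
  invisible(path)
}
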