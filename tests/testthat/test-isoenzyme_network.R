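gene_model <- function(gene_rxns, reversible = FALSE) {
  # build a model whose reactions r* exist with dummy metabolites and the
  # given gene -> reaction-set map
  rxn_ids <- sort(unique(unlist(gene_rxns)))
  mets <- simple_mets(c("s_c", "t_c"))
  rxns <- lapply(rxn_ids, function(r) {
    genes <- names(gene_rxns)[vapply(gene_rxns, function(x) r %in% x, logical(1))]
    list(id = r, reversible = reversible, reactants = "s_c", products = "t_c",
         genes = genes)
  })
  make_model(mets, rxns)
}

test_that("two-step grouping: identical sets merge, subsets merge, overlaps do not", {
  m <- gene_model(list(A = c("r1", "r2"), B = c("r1", "r2"), C = "r1",
                       D = c("r2", "r3")))
  g <- build_isoenzyme_groups(m)
  expect_equal(nrow(g), 2)
  part <- partition_of(g)
  expect_equal(part, list(c("A", "B", "C"), "D"))
  abc <- which(vapply(g$genes, function(x) "A" %in% x, logical(1)))
  expect_setequal(g$reactions[[abc]], c("r1", "r2"))
  d <- which(vapply(g$genes, function(x) "D" %in% x, logical(1)))
  expect_setequal(g$reactions[[d]], c("r2", "r3"))
})

test_that("all genes sharing one reaction give a single group", {
  m <- gene_model(list(A = "r1", B = "r1", C = "r1"))
  g <- build_isoenzyme_groups(m)
  expect_equal(nrow(g), 1)
  expect_setequal(g$genes[[1]], c("A", "B", "C"))
})

test_that("subset chains collapse and the fixpoint is input-order independent", {
  base <- list(A = "r1", B = c("r1", "r2"), C = c("r1", "r2", "r3"),
               D = c("r4", "r5"), E = "r4")
  ref <- partition_of(build_isoenzyme_groups(gene_model(base)))
  expect_equal(ref, list(c("A", "B", "C"), c("D", "E")))
  set.seed(7)
  for (i in 1:8) {
    g <- build_isoenzyme_groups(gene_model(base[sample(names(base))]))
    expect_equal(partition_of(g), ref)
  }
})

test_that("grouping partitions the gene set on random models", {
  set.seed(11)
  for (i in 1:5) {
    cfg <- simulation_config(seed = 100 + i, n_metabolites = 30,
                             n_reactions = 25, n_groups = 10, n_taxa = 4)
    gen <- generate_model(cfg)
    g <- build_isoenzyme_groups(gen$model)
    genes <- unlist(g$genes)
    expect_equal(sort(genes), sort(gen$model$genes))
    expect_false(anyDuplicated(genes) > 0)
    # every member gene's reaction list is a subset of the group's
    gene_rxns <- with(list(rx = gen$model$reactions), {
      pg <- unlist(rx$genes); pr <- rep(rx$id, lengths(rx$genes))
      lapply(split(pr, pg), unique)
    })
    for (k in seq_len(nrow(g))) {
      for (gene in g$genes[[k]]) {
        expect_true(all(gene_rxns[[gene]] %in% g$reactions[[k]]))
      }
    }
  }
})

edge_net <- function(rxns, mets = NULL) {
  ids <- unique(unlist(lapply(rxns, function(r) c(r$reactants, r$products))))
  if (is.null(mets)) {
    mets <- data.frame(id = ids, name = ids,
                       compartment = sub("^.*_", "", ids),
                       stringsAsFactors = FALSE)
  }
  m <- make_model(mets, rxns)
  build_edges(build_isoenzyme_groups(m), m)
}

test_that("irreversible product->reactant sharing gives one directed edge", {
  net <- edge_net(list(
    list(id = "r1", reactants = "a_c", products = "m_c", genes = "u"),
    list(id = "r2", reactants = "m_c", products = "b_c", genes = "v")))
  el <- igraph::as_edgelist(net$graph)
  gu <- net$groups$id[vapply(net$groups$genes, function(g) "u" %in% g, logical(1))]
  gv <- net$groups$id[vapply(net$groups$genes, function(g) "v" %in% g, logical(1))]
  expect_true(any(el[, 1] == gu & el[, 2] == gv))
  expect_false(any(el[, 1] == gv & el[, 2] == gu))
})

test_that("groups sharing no metabolites get no edge; reversible sharing gives both", {
  net0 <- edge_net(list(
    list(id = "r1", reactants = "a_c", products = "b_c", genes = "u"),
    list(id = "r2", reactants = "x_c", products = "y_c", genes = "v")))
  expect_equal(igraph::ecount(net0$graph), 0)
  net2 <- edge_net(list(
    list(id = "r1", reversible = TRUE, reactants = "a_c", products = "m_c", genes = "u"),
    list(id = "r2", reversible = TRUE, reactants = "m_c", products = "b_c", genes = "v")))
  expect_equal(igraph::ecount(net2$graph), 2)
})

test_that("metabolite identity is compartment-specific", {
  net <- edge_net(list(
    list(id = "r1", reactants = "a_c", products = "m_c", genes = "u"),
    list(id = "r2", reactants = "m_x", products = "b_x", genes = "v")))
  expect_equal(igraph::ecount(net$graph), 0)
})

test_that("removing a metabolite never adds an edge (monotone construction)", {
  set.seed(5)
  for (i in 1:4) {
    cfg <- simulation_config(seed = 300 + i, n_metabolites = 25,
                             n_reactions = 20, n_groups = 8, n_taxa = 4,
                             currency_frac = 0)
    gen <- generate_model(cfg)
    g <- build_isoenzyme_groups(gen$model)
    full <- build_edges(g, gen$model)
    victim <- gen$model$metabolites$name[1]
    reduced <- build_edges(g, strip_currency_metabolites(gen$model, victim))
    e_full <- apply(igraph::as_edgelist(full$graph), 1, paste, collapse = ">")
    e_red <- apply(igraph::as_edgelist(reduced$graph), 1, paste, collapse = ">")
    expect_true(all(e_red %in% e_full))
  }
})

test_that("network statistics on a directed 3-cycle match closed forms", {
  g <- igraph::make_graph(c("a", "b", "b", "c", "c", "a"), directed = TRUE)
  s <- network_stats(g)
  expect_equal(s$n_nodes, 3)
  expect_equal(s$n_edges, 3)
  expect_equal(s$density, 0.5)
  expect_equal(s$diameter, 2)
  expect_equal(s$avg_shortest_path, 1.5)
  expect_equal(s$n_isolated, 0)
})

test_that("density identity holds exactly and isolated nodes are counted", {
  set.seed(9)
  g <- igraph::sample_gnm(40, 120, directed = TRUE)
  g <- igraph::add_vertices(g, 2) # two isolated nodes
  s <- network_stats(g)
  expect_equal(s$density * s$n_nodes * (s$n_nodes - 1), s$n_edges)
  expect_equal(s$n_isolated, 2)
  s1 <- network_stats(igraph::make_empty_graph(1))
  expect_true(s1$degenerate)
  expect_equal(s1$density, 0)
})

test_that("cross-network overlap fractions follow the orthology links", {
  mA <- gene_model(list(g1 = "r1", g2 = "r2"))
  mB <- gene_model(list(h1 = "r1"))
  netA <- build_edges(build_isoenzyme_groups(mA), mA)
  netB <- build_edges(build_isoenzyme_groups(mB), mB)
  ov <- map_between_networks(netA, netB,
                             data.frame(gene_a = "g1", gene_b = "h1"))
  expect_equal(ov$fraction_A_in_B, 0.5)
  expect_equal(ov$fraction_B_in_A, 1)
  # identity orthology on the same network: full overlap both ways
  ident <- data.frame(gene_a = c("g1", "g2"), gene_b = c("g1", "g2"))
  ov2 <- map_between_networks(netA, netA, ident)
  expect_equal(ov2$fraction_A_in_B, 1)
  expect_equal(ov2$fraction_B_in_A, 1)
  expect_warning(ov0 <- map_between_networks(netA, netB,
                                             data.frame(gene_a = character(), gene_b = character())),
                 "empty")
  expect_equal(ov0$fraction_A_in_B, 0)
})

test_that("GraphML export round-trips through igraph", {
  m <- gene_model(list(A = "r1", B = "r2"))
  net <- edge_net(list(
    list(id = "r1", reactants = "a_c", products = "m_c", genes = "u"),
    list(id = "r2", reactants = "m_c", products = "b_c", genes = "v")))
  f <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, f)
  g2 <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g2), igraph::vcount(net$graph))
  expect_equal(igraph::ecount(g2), igraph::ecount(net$graph))
})
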