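#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator with defaults at
#' the scale of the mammalian study conditions: 16 taxa on a ~100-My
#' coalescent tree, a compartmentalized model yielding ~420 isoenzyme
#' groups, birth-death copy-number evolution at 0.02 gains and 0.02
#' losses per group per My, 17 traits of which one carries a planted
#' linear association (beta = 2 on one group) over Brownian noise.
#'
#' The default trait noise `trait_sigma2` = 0.018 per My puts the
#' per-branch signal fraction at
#' `beta^2 (gain + loss) / (beta^2 (gain + loss) + sigma2)` which is
#' approximately 0.9 (branch length cancels), i.e. a strong but noisy
#' planted association.
#'
#' @param seed integer RNG seed.
#' @param n_metabolites non-currency metabolites.
#' @param n_reactions total reactions (must exceed `n_groups`).
#' @param n_groups planted isoenzyme groups.
#' @param n_genes optional total gene budget; must be at least `n_groups`.
#' @param group_size_probs sampling weights for group sizes 1, 2, 3
#'   (ignored when `n_genes` is given).
#' @param n_compartments number of cellular compartments (>= 2).
#' @param reversible_frac fraction of reversible reactions.
#' @param currency_frac per-reaction probability of carrying currency
#'   metabolites on both sides.
#' @param n_taxa number of extant species.
#' @param tree_depth root age in million years.
#' @param gain_rate,loss_rate copy gains / losses per group per My.
#' @param planted data.frame with columns `trait`, `group` (index into
#'   the generated groups) and `beta`: the trait-generating effects.
#' @param n_traits total traits (non-planted traits are pure noise).
#' @param trait_sigma2 Brownian trait variance per My.
#' @param missing_frac per-tip, per-trait missingness probability.
#' @param root_trait trait value at the root.
#' @param orphan_frac fraction of target genes given only homology (not
#'   orthology) rows, exercising assignment step 2.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_metabolites = 300,
                              n_reactions = 620,
                              n_groups = 420,
                              n_genes = NULL,
                              group_size_probs = c(0.5, 0.3, 0.2),
                              n_compartments = 3,
                              reversible_frac = 0.3,
                              currency_frac = 0.15,
                              n_taxa = 16,
                              tree_depth = 100,
                              gain_rate = 0.02,
                              loss_rate = 0.02,
                              planted = data.frame(trait = "trait01",
                                                   group = 1L, beta = 2),
                              n_traits = 17,
                              trait_sigma2 = 0.018,
                              missing_frac = 0.05,
                              root_trait = 10,
                              orphan_frac = 0.1) {
  cfg <- as.list(environment())
  stopifnot(cfg$gain_rate >= 0, cfg$loss_rate >= 0, cfg$trait_sigma2 >= 0,
            cfg$n_compartments >= 2, cfg$n_reactions >= 1)
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate a random compartmentalized metabolic model
#'
#' Builds a bipartite reaction-metabolite structure over at least two
#' compartments and plants a known isoenzyme-group partition: every group
#' owns a unique signature reaction (so groups can never be merged across
#' the partition), at least one member gene carries the group's full
#' reaction set, and further members carry either the identical set
#' (exercising the identical-reaction merge) or a nested subset
#' (exercising the subset merge).  Currency metabolites from the standard
#' list are injected at configurable frequency.
#'
#' @param cfg a [simulation_config()].
#' @return List with `model` (a [metabolic_model()]) and `truth`:
#'   `gene_group` (named integer: planted group index per gene) and
#'   `group_reactions` (list of reaction-id sets).
#' @export
generate_model <- function(cfg) {
  if (cfg$n_reactions < cfg$n_groups + 1) {
    stop("infeasible config: need more reactions than groups (each group owns a signature reaction)")
  }
  if (!is.null(cfg$n_genes) && cfg$n_genes < cfg$n_groups) {
    stop("infeasible config: more groups demanded than genes")
  }
  comps <- c("c", "m", "e", "x", "r")[seq_len(cfg$n_compartments)]
  met_id <- sprintf("m%04d_%s", seq_len(cfg$n_metabolites),
                    sample(comps, cfg$n_metabolites, replace = TRUE))
  mets <- data.frame(id = met_id,
                     name = sprintf("met%04d", seq_len(cfg$n_metabolites)),
                     compartment = sub("^.*_", "", met_id),
                     stringsAsFactors = FALSE)

  currency_base <- c("atp", "adp", "h2o", "h", "pi", "nad", "nadh", "o2", "coa")
  cur_used <- character()
  rx_id <- sprintf("r%04d", seq_len(cfg$n_reactions))
  reactants <- products <- vector("list", cfg$n_reactions)
  for (i in seq_len(cfg$n_reactions)) {
    pool <- sample(mets$id, sample(2:6, 1))
    k <- sample(seq_len(length(pool) - 1), 1)
    r <- pool[seq_len(k)]; p <- pool[-seq_len(k)]
    if (runif(1) < cfg$currency_frac) {
      comp <- sample(comps, 1)
      pair <- sample(currency_base, 2)
      cur_r <- paste0(pair[1], "_", comp)
      cur_p <- paste0(pair[2], "_", comp)
      r <- c(r, cur_r); p <- c(p, cur_p)
      cur_used <- unique(c(cur_used, cur_r, cur_p))
    }
    reactants[[i]] <- r; products[[i]] <- p
  }
  if (length(cur_used)) {
    mets <- rbind(mets, data.frame(
      id = cur_used,
      name = toupper(sub("_[a-z]+$", "", cur_used)),
      compartment = sub("^.*_", "", cur_used),
      stringsAsFactors = FALSE))
  }

  # planted groups: signature reaction + shared extras
  sizes <- if (is.null(cfg$n_genes)) {
    sample(1:3, cfg$n_groups, replace = TRUE, prob = cfg$group_size_probs)
  } else {
    s <- rep(1L, cfg$n_groups)
    extra <- cfg$n_genes - cfg$n_groups
    while (extra > 0) {
      j <- sample.int(cfg$n_groups, 1)
      if (s[j] < 4) { s[j] <- s[j] + 1L; extra <- extra - 1 }
    }
    s
  }
  shared_pool <- rx_id[-seq_len(cfg$n_groups)]
  group_rxns <- vector("list", cfg$n_groups)
  gene_names <- character(); gene_sets <- list(); gene_group <- integer()
  for (g in seq_len(cfg$n_groups)) {
    extras <- sample(shared_pool, sample(0:3, 1))
    full <- sort(c(rx_id[g], extras))
    group_rxns[[g]] <- full
    for (j in seq_len(sizes[g])) {
      set <- if (j == 1 || runif(1) < 0.5 || length(extras) == 0) full
             else sort(c(rx_id[g], sample(extras, sample(0:(length(extras) - 1), 1))))
      gene_names <- c(gene_names, sprintf("g%04d", length(gene_names) + 1L))
      gene_sets[[length(gene_sets) + 1L]] <- set
      gene_group <- c(gene_group, g)
    }
  }
  rxn_genes <- setNames(vector("list", cfg$n_reactions), rx_id)
  for (k in seq_along(gene_names)) {
    for (r in gene_sets[[k]]) rxn_genes[[r]] <- c(rxn_genes[[r]], gene_names[k])
  }
  reactions <- data.frame(id = rx_id,
                          reversible = runif(cfg$n_reactions) < cfg$reversible_frac,
                          stringsAsFactors = FALSE)
  reactions$reactants <- reactants
  reactions$products <- products
  reactions$genes <- unname(rxn_genes)

  list(model = metabolic_model(mets, reactions),
       truth = list(gene_group = setNames(gene_group, gene_names),
                    group_reactions = group_rxns))
}

#' Simulate a dated phylogeny
#'
#' Random coalescent topology rescaled so the root sits at
#' `cfg$tree_depth` million years; tips `sp01..`, internal nodes
#' `anc1..`.
#'
#' @param cfg a [simulation_config()].
#' @return A rooted ultrametric `phylo` tree.
#' @export
simulate_tree <- function(cfg) {
  tree <- ape::rcoal(cfg$n_taxa, tip.label = sprintf("sp%02d", seq_len(cfg$n_taxa)))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth * cfg$tree_depth
  tree$node.label <- paste0("anc", seq_len(tree$Nnode))
  tree
}

#' Simulate copy-number evolution along a tree
#'
#' Root counts are drawn as 1 + Poisson(1) per group; along each branch
#' of length t, gains ~ Poisson(gain_rate * t) and losses ~
#' Poisson(loss_rate * t), with counts truncated at zero.  The full
#' ground truth (counts at every node, gains/losses per branch) is
#' recorded.
#'
#' @param tree a dated `phylo` tree (e.g. [simulate_tree()]).
#' @param groups an `isoenzyme_groups` table or character vector of group
#'   ids.
#' @param cfg a [simulation_config()].
#' @return List with `tip_counts` (species x group integer matrix) and
#'   `truth`: `node_counts` (all nodes x groups), `events` (per-branch
#'   data.frame with true gains, losses and net deltas).
#' @export
simulate_copy_evolution <- function(tree, groups, cfg) {
  ids <- if (inherits(groups, "isoenzyme_groups")) groups$id else as.character(groups)
  ng <- length(ids)
  tix <- tree_index(tree)
  counts <- matrix(NA_integer_, tix$n_node, ng,
                   dimnames = list(tix$node_names, ids))
  root <- tix$n_tip + 1L
  counts[root, ] <- 1L + rpois(ng, 1)
  ne <- length(tix$edge_parent)
  gains_b <- integer(ne); losses_b <- integer(ne)
  for (k in rev(seq_len(ne))) { # preorder
    p <- tix$edge_parent[k]; c_ <- tix$edge_child[k]
    t <- tix$edge_length[k]
    gains <- rpois(ng, cfg$gain_rate * t)
    losses <- rpois(ng, cfg$loss_rate * t)
    counts[c_, ] <- pmax(0L, counts[p, ] + gains - losses)
    gains_b[k] <- sum(gains); losses_b[k] <- sum(losses)
  }
  events <- data.frame(
    branch = branch_labels(tix),
    length = tix$edge_length,
    gains = gains_b, losses = losses_b,
    net_changes = vapply(seq_len(ne), function(k) {
      sum(abs(counts[tix$edge_child[k], ] - counts[tix$edge_parent[k], ]))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  list(tip_counts = counts[seq_len(tix$n_tip), , drop = FALSE],
       truth = list(node_counts = counts, events = events))
}

#' Simulate trait evolution from planted copy-number effects
#'
#' Per branch, each trait changes by the planted linear combination of
#' the group copy-number deltas plus Brownian noise
#' `Normal(0, sigma2 * t)`; tip values accumulate changes from the root.
#' A configurable fraction of tip values is set missing.
#'
#' @param tree the `phylo` tree used for the copy simulation.
#' @param copy_truth the `truth` element of [simulate_copy_evolution()].
#' @param cfg a [simulation_config()].
#' @return List with `traits` (species x trait data.frame, `NA` missing)
#'   and `truth`: `node_traits`, `betas` (trait x group effect matrix).
#' @export
simulate_traits <- function(tree, copy_truth, cfg) {
  tix <- tree_index(tree)
  counts <- copy_truth$node_counts
  ng <- ncol(counts)
  trait_names <- sprintf("trait%02d", seq_len(cfg$n_traits))
  betas <- matrix(0, cfg$n_traits, ng,
                  dimnames = list(trait_names, colnames(counts)))
  if (!is.null(cfg$planted) && nrow(cfg$planted)) {
    for (i in seq_len(nrow(cfg$planted))) {
      betas[cfg$planted$trait[i], cfg$planted$group[i]] <- cfg$planted$beta[i]
    }
  }
  node_traits <- matrix(NA_real_, tix$n_node, cfg$n_traits,
                        dimnames = list(tix$node_names, trait_names))
  node_traits[tix$n_tip + 1L, ] <- cfg$root_trait
  ne <- length(tix$edge_parent)
  for (k in rev(seq_len(ne))) { # preorder
    p <- tix$edge_parent[k]; c_ <- tix$edge_child[k]
    dcopy <- counts[c_, ] - counts[p, ]
    noise <- rnorm(cfg$n_traits, 0, sqrt(cfg$trait_sigma2 * tix$edge_length[k]))
    node_traits[c_, ] <- node_traits[p, ] + as.numeric(betas %*% dcopy) + noise
  }
  traits <- as.data.frame(node_traits[seq_len(tix$n_tip), , drop = FALSE])
  for (j in seq_len(ncol(traits))) {
    miss <- runif(nrow(traits)) < cfg$missing_frac
    traits[miss, j] <- NA_real_
  }
  list(traits = traits,
       truth = list(node_traits = node_traits, betas = betas))
}

#' Generate a complete synthetic dataset
#'
#' Orchestrates the generator end to end under one seed: model,
#' isoenzyme grouping, enzyme orthology network (on the
#' currency-stripped model), dated tree, copy-number evolution, traits,
#' and per-species orthology tables consistent with the simulated copy
#' numbers (a fraction of target genes get homology-only rows).  With a
#' `dir`, every input file the pipeline consumes is written
#' (SBML, GraphML, Newick, CSV/TSV) together with the ground truth;
#' outputs are byte-identical for a given seed.
#'
#' @param cfg a [simulation_config()].
#' @param dir optional output directory (created if needed).
#' @return List with `model`, `groups`, `net`, `tree`, `tip_counts`,
#'   `traits`, `orthology` (list per species) and `truth`.
#' @export
simulate_dataset <- function(cfg = simulation_config(), dir = NULL) {
  set.seed(cfg$seed)
  gen <- generate_model(cfg)
  model <- gen$model
  groups <- build_isoenzyme_groups(model)
  net <- build_edges(groups, strip_currency_metabolites(model))
  tree <- simulate_tree(cfg)
  cnv <- simulate_copy_evolution(tree, groups, cfg)
  tr <- simulate_traits(tree, cnv$truth, cfg)

  gene2grp <- setNames(rep(groups$id, lengths(groups$genes)), unlist(groups$genes))
  orthology <- list()
  for (s in rownames(cnv$tip_counts)) {
    rows <- list()
    for (gi in seq_len(nrow(groups))) {
      cnt <- cnv$tip_counts[s, groups$id[gi]]
      if (cnt == 0) next
      refs <- groups$genes[[gi]]
      for (i in seq_len(cnt)) {
        tg <- sprintf("%s_%s_%02d", s, groups$id[gi], i)
        if (runif(1) < cfg$orphan_frac) {
          rows[[length(rows) + 1L]] <- data.frame(
            reference_gene = refs, target_gene = tg, relation = "homolog",
            family = paste0("fam_", groups$id[gi]), stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            reference_gene = sample(refs, 1), target_gene = tg,
            relation = "ortholog", family = paste0("fam_", groups$id[gi]),
            stringsAsFactors = FALSE)
        }
      }
    }
    orthology[[s]] <- do.call(rbind, rows)
  }

  out <- list(model = model, groups = groups, net = net, tree = tree,
              tip_counts = cnv$tip_counts, traits = tr$traits,
              orthology = orthology,
              truth = list(model = gen$truth, copy = cnv$truth, trait = tr$truth),
              config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_sbml_model(model, file.path(dir, "model.xml"))
    write_network_graphml(net, file.path(dir, "network.graphml"))
    ape::write.tree(tree, file.path(dir, "tree.nwk"))
    write_copy_numbers(t(cnv$tip_counts), file.path(dir, "tip_counts.csv"))
    write_trait_table(tr$traits, file.path(dir, "traits.csv"))
    for (s in names(orthology)) {
      write.table(orthology[[s]], file.path(dir, paste0("orthology_", s, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.csv(data.frame(node = rownames(cnv$truth$node_counts),
                         cnv$truth$node_counts, check.names = FALSE),
              file.path(dir, "truth_node_counts.csv"), row.names = FALSE)
    write.table(cnv$truth$events, file.path(dir, "truth_events.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.csv(data.frame(trait = rownames(tr$truth$betas), tr$truth$betas,
                         check.names = FALSE),
              file.path(dir, "truth_betas.csv"), row.names = FALSE)
  }
  out
}
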