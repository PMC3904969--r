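test_that("boolean GPR strings are flattened to gene membership", {
  sbml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m"><listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies><species id="a" compartment="c"/><species id="b" compartment="c"/></listOfSpecies>',
    '<listOfReactions><reaction id="r1" reversible="false">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '<p>GENE_ASSOCIATION: (g1 or g2) and g3</p></body></notes>',
    '<listOfReactants><speciesReference species="a"/></listOfReactants>',
    '<listOfProducts><speciesReference species="b"/></listOfProducts>',
    '</reaction></listOfReactions></model></sbml>')
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, f)
  m <- read_sbml_model(f)
  expect_setequal(m$reactions$genes[[1]], c("g1", "g2", "g3"))
  expect_setequal(m$genes, c("g1", "g2", "g3"))
  expect_false(m$reactions$reversible[1])
})

test_that("SBML with zero reactions parses to an empty reaction list", {
  sbml <- c(
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m"><listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies><species id="a" compartment="c"/></listOfSpecies>',
    '<listOfReactions></listOfReactions></model></sbml>')
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, f)
  m <- read_sbml_model(f)
  expect_equal(nrow(m$reactions), 0)
  expect_equal(nrow(m$metabolites), 1)
  expect_equal(count_gene_associated_reactions(m), 0)
})

test_that("fbc gene-product associations are parsed via labels", {
  sbml <- c(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    ' xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    ' level="3" version="1" fbc:required="false">',
    '<model id="m" fbc:strict="false">',
    '<listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>',
    '<listOfSpecies><species id="a" compartment="c"/><species id="b" compartment="c"/></listOfSpecies>',
    '<fbc:listOfGeneProducts>',
    '<fbc:geneProduct fbc:id="gp1" fbc:label="GENE1"/>',
    '<fbc:geneProduct fbc:id="gp2" fbc:label="GENE2"/>',
    '</fbc:listOfGeneProducts>',
    '<listOfReactions><reaction id="r1" reversible="true">',
    '<fbc:geneProductAssociation><fbc:or>',
    '<fbc:geneProductRef fbc:geneProduct="gp1"/>',
    '<fbc:geneProductRef fbc:geneProduct="gp2"/>',
    '</fbc:or></fbc:geneProductAssociation>',
    '<listOfReactants><speciesReference species="a" stoichiometry="1" constant="true"/></listOfReactants>',
    '<listOfProducts><speciesReference species="b" stoichiometry="1" constant="true"/></listOfProducts>',
    '</reaction></listOfReactions></model></sbml>')
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, f)
  m <- read_sbml_model(f)
  expect_setequal(m$reactions$genes[[1]], c("GENE1", "GENE2"))
  expect_setequal(m$genes, c("GENE1", "GENE2"))
  expect_true(m$reactions$reversible[1])
})

test_that("reaction referencing an undeclared species is a validation error", {
  mets <- simple_mets(c("a"))
  expect_error(
    make_model(mets, list(list(id = "r1", reactants = "a", products = "zz"))),
    "undeclared species")
})

test_that("currency stripping removes every compartment instance and flags emptied reactions", {
  mets <- rbind(simple_mets(c("atp_c", "adp_c", "x_c", "y_c"), "c"),
                simple_mets("atp_m", "m"))
  mets$name <- c("ATP", "ADP", "met x", "met y", "ATP")
  m <- make_model(mets, list(
    list(id = "r1", reactants = c("atp_c", "x_c"), products = c("adp_c", "y_c"), genes = "g1"),
    list(id = "r2", reactants = "atp_m", products = "adp_c")
  ))
  s <- strip_currency_metabolites(m)
  expect_setequal(s$metabolites$id, c("x_c", "y_c"))
  expect_equal(s$reactions$reactants[[1]], "x_c")
  expect_equal(s$reactions$products[[1]], "y_c")
  # both compartment instances of ATP gone
  expect_setequal(attr(s, "removed_metabolites"), c("atp_c", "adp_c", "atp_m"))
  # reaction emptied on both sides retained and flagged
  expect_equal(nrow(s$reactions), 2)
  expect_true(s$reactions$empty_after_strip[2])
  expect_false(s$reactions$empty_after_strip[1])
  # metabolite count identity
  expect_equal(nrow(s$metabolites),
               nrow(m$metabolites) - length(attr(s, "removed_metabolites")))
})

test_that("currency stripping is idempotent and a no-op without currency names", {
  mets <- simple_mets(c("u_c", "v_c"))
  m <- make_model(mets, list(list(id = "r1", reactants = "u_c", products = "v_c")))
  s1 <- strip_currency_metabolites(m)
  expect_equal(s1$metabolites, m$metabolites)
  expect_equal(s1$reactions$reactants, m$reactions$reactants)
  m2 <- make_model(rbind(simple_mets(c("atp_c", "u_c", "v_c"))),
                   list(list(id = "r1", reactants = c("atp_c", "u_c"), products = "v_c")))
  once <- strip_currency_metabolites(m2)
  twice <- strip_currency_metabolites(once)
  expect_equal(twice$metabolites, once$metabolites)
  expect_equal(twice$reactions$reactants, once$reactions$reactants)
  expect_equal(twice$reactions$empty_after_strip, once$reactions$empty_after_strip)
})

test_that("gene-associated reaction count", {
  mets <- simple_mets(letters[1:2])
  rxns <- lapply(1:5, function(i)
    list(id = paste0("r", i), reactants = "a", products = "b",
         genes = if (i <= 3) paste0("g", i) else character()))
  m <- make_model(mets, rxns)
  expect_equal(count_gene_associated_reactions(m), 3)
  rxns0 <- lapply(rxns, function(r) { r$genes <- character(); r })
  expect_equal(count_gene_associated_reactions(make_model(mets, rxns0)), 0)
})

test_that("SBML round trip preserves metabolite, reaction and gene sets", {
  set.seed(42)
  cfg <- simulation_config(seed = 42, n_metabolites = 25, n_reactions = 20,
                           n_groups = 8, n_taxa = 4, n_traits = 2)
  gen <- generate_model(cfg)
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml_model(gen$model, f)
  m2 <- read_sbml_model(f)
  expect_setequal(m2$metabolites$id, gen$model$metabolites$id)
  expect_equal(m2$metabolites[order(m2$metabolites$id), ],
               gen$model$metabolites[order(gen$model$metabolites$id), ],
               ignore_attr = TRUE)
  expect_equal(m2$reactions$id, gen$model$reactions$id)
  expect_equal(m2$reactions$reversible, gen$model$reactions$reversible)
  expect_setequal(m2$genes, gen$model$genes)
  for (i in seq_len(nrow(m2$reactions))) {
    expect_setequal(m2$reactions$reactants[[i]], gen$model$reactions$reactants[[i]])
    expect_setequal(m2$reactions$products[[i]], gen$model$reactions$products[[i]])
    expect_setequal(m2$reactions$genes[[i]], gen$model$reactions$genes[[i]])
  }
})

test_that("gene id transforms collapse transcript suffixes", {
  sbml <- c(
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '<model id="m"><listOfCompartments><compartment id="c"/></listOfCompartments>',
    '<listOfSpecies><species id="a" compartment="c"/><species id="b" compartment="c"/></listOfSpecies>',
    '<listOfReactions><reaction id="r1">',
    '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '<p>GENE_ASSOCIATION: (8639.1) or (8639.2) or (26.1)</p></body></notes>',
    '<listOfReactants><speciesReference species="a"/></listOfReactants>',
    '<listOfProducts><speciesReference species="b"/></listOfProducts>',
    '</reaction></listOfReactions></model></sbml>')
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(sbml, f)
  m <- read_sbml_model(f, gene_id_transform = function(x) sub("\\.\\d+$", "", x))
  expect_setequal(m$reactions$genes[[1]], c("8639", "26"))
})
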