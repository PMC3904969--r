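#' Construct a metabolic model
#'
#' Container for a genome-scale metabolic model: compartmentalized
#' metabolites, reactions with reversibility and side membership, and
#' flattened gene-reaction associations.  Stoichiometric coefficients are
#' deliberately not represented: downstream analyses only use side
#' membership (which metabolites a reaction consumes and produces).
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id` (character), `reversible`
#'   (logical) and list-columns `reactants`, `products`, `genes` holding
#'   character vectors of metabolite/gene ids.
#' @param genes optional character vector of declared gene ids; the model
#'   gene set is the union of this and all reaction gene sets.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, genes = character()) {
  stopifnot(is.data.frame(metabolites), is.data.frame(reactions))
  metabolites$id <- as.character(metabolites$id)
  metabolites$name <- as.character(metabolites$name)
  metabolites$compartment <- as.character(metabolites$compartment)
  if (anyDuplicated(metabolites$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(metabolites$id[duplicated(metabolites$id)]), collapse = ", "))
  }
  if (any(!nzchar(metabolites$compartment))) {
    stop("every metabolite needs a non-empty compartment")
  }
  for (col in c("reactants", "products", "genes")) {
    if (is.null(reactions[[col]])) reactions[[col]] <- replicate(nrow(reactions), character(), simplify = FALSE)
    reactions[[col]] <- lapply(reactions[[col]], as.character)
  }
  if (is.null(reactions$empty_after_strip)) {
    reactions$empty_after_strip <- rep(FALSE, nrow(reactions))
  }
  known <- metabolites$id
  for (i in seq_len(nrow(reactions))) {
    bad <- setdiff(c(reactions$reactants[[i]], reactions$products[[i]]), known)
    if (length(bad)) {
      stop("reaction '", reactions$id[i], "' references undeclared species: ",
           paste(bad, collapse = ", "))
    }
  }
  all_genes <- sort(unique(c(as.character(genes), unlist(reactions$genes))))
  structure(
    list(metabolites = metabolites, reactions = reactions, genes = all_genes),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ",
      nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions, ",
      length(x$genes), " genes\n", sep = "")
  cat("  gene-associated reactions: ", count_gene_associated_reactions(x), "\n", sep = "")
  invisible(x)
}

# tokenize a boolean gene-protein-reaction string into the set of gene ids
# mentioned; AND/OR structure is discarded (copy counting needs membership
# only, never complex structure)
flatten_gpr <- function(gpr) {
  gpr <- gsub("\\b([Aa][Nn][Dd]|[Oo][Rr])\\b", " ", gpr)
  gpr <- gsub("[(),]", " ", gpr)
  toks <- strsplit(trimws(gpr), "\\s+")[[1]]
  unique(toks[nzchar(toks)])
}

#' Read a metabolic model from SBML
#'
#' Parses SBML Level 2 or 3.  Gene associations are taken from the `fbc`
#' package (gene product associations) when present, otherwise from
#' `GENE_ASSOCIATION:` (or `GENE ASSOCIATION:`) lines in reaction notes,
#' the dialect being auto-detected (override with `dialect`).  Boolean
#' AND/OR structure in the association is flattened to the set of gene
#' ids mentioned.
#'
#' @param path path to an SBML file.
#' @param gene_id_transform optional function applied to every parsed gene
#'   id, e.g. `function(x) sub("\\\\.\\\\d+$", "", x)` to collapse
#'   transcript-level ids (`8639.1`) to locus-level ids (`8639`).
#' @param dialect `"auto"` (default), `"fbc"` or `"notes"`.
#' @return A [metabolic_model()].
#' @export
read_sbml_model <- function(path, gene_id_transform = NULL,
                            dialect = c("auto", "fbc", "notes")) {
  dialect <- match.arg(dialect)
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("cannot parse SBML file '", path, "': ", conditionMessage(e))
  })
  xml2::xml_ns_strip(doc)

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  metabolites <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    name = xml2::xml_attr(sp_nodes, "name"),
    compartment = xml2::xml_attr(sp_nodes, "compartment"),
    stringsAsFactors = FALSE
  )
  metabolites$name <- ifelse(is.na(metabolites$name), metabolites$id, metabolites$name)
  metabolites$compartment[is.na(metabolites$compartment)] <- "default"

  # fbc gene products: id -> label (fbc elements keep their prefix even
  # after namespace stripping, hence local-name() matching)
  gp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  gp_map <- character()
  if (length(gp_nodes)) {
    attr_local <- function(nodes, local) {
      vapply(nodes, function(n) {
        a <- xml2::xml_attrs(n)
        hit <- grep(paste0("(^|:)", local, "$"), names(a))
        if (length(hit)) a[[hit[1]]] else NA_character_
      }, character(1))
    }
    ids <- attr_local(gp_nodes, "id")
    labels <- attr_local(gp_nodes, "label")
    gp_map <- ifelse(is.na(labels) | !nzchar(labels), ids, labels)
    names(gp_map) <- ids
  }
  use_fbc <- switch(dialect, fbc = TRUE, notes = FALSE,
                    auto = length(gp_nodes) > 0 ||
                      !inherits(xml2::xml_find_first(
                        doc, ".//*[local-name()='geneProductAssociation']"),
                        "xml_missing"))

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  n <- length(rx_nodes)
  ids <- xml2::xml_attr(rx_nodes, "id")
  rev_attr <- xml2::xml_attr(rx_nodes, "reversible")
  reversible <- ifelse(is.na(rev_attr), TRUE, tolower(rev_attr) == "true")
  side <- function(node, which) {
    refs <- xml2::xml_find_all(node, paste0("./", which, "/speciesReference"))
    unique(xml2::xml_attr(refs, "species"))
  }
  reactants <- vector("list", n); products <- vector("list", n); genes <- vector("list", n)
  for (i in seq_len(n)) {
    node <- rx_nodes[[i]]
    reactants[[i]] <- side(node, "listOfReactants")
    products[[i]] <- side(node, "listOfProducts")
    g <- character()
    if (use_fbc) {
      refs <- xml2::xml_find_all(node, ".//*[local-name()='geneProductRef']")
      if (length(refs)) {
        raw <- vapply(refs, function(r) {
          a <- xml2::xml_attrs(r)
          hit <- grep("(^|:)geneProduct$", names(a))
          if (length(hit)) a[[hit[1]]] else NA_character_
        }, character(1))
        raw <- raw[!is.na(raw)]
        g <- unique(ifelse(raw %in% names(gp_map), unname(gp_map[raw]), raw))
      }
    } else {
      notes <- xml2::xml_find_first(node, "./notes")
      if (!inherits(notes, "xml_missing")) {
        txt <- xml2::xml_text(notes)
        m <- regmatches(txt, regexec("GENE[ _]ASSOCIATION\\s*:\\s*([^\n\r]*)", txt))[[1]]
        if (length(m) == 2 && nzchar(trimws(m[2]))) g <- flatten_gpr(m[2])
      }
    }
    if (!is.null(gene_id_transform) && length(g)) g <- unique(gene_id_transform(g))
    genes[[i]] <- g
  }
  reactions <- data.frame(id = ids, reversible = reversible, stringsAsFactors = FALSE)
  reactions$reactants <- reactants
  reactions$products <- products
  reactions$genes <- genes

  declared <- character()
  if (length(gp_map)) {
    declared <- unique(unname(gp_map))
    if (!is.null(gene_id_transform)) declared <- unique(gene_id_transform(declared))
  }
  metabolic_model(metabolites, reactions, declared)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a metabolic model to SBML
#'
#' Emits SBML Level 2 Version 4 with gene associations stored as
#' `GENE_ASSOCIATION:` reaction notes (the notes dialect, which
#' [read_sbml_model()] parses back losslessly for the fields this package
#' uses).
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml_model <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  comps <- unique(model$metabolites$compartment)
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    '  <model id="metacna_model">',
    "    <listOfCompartments>",
    sprintf('      <compartment id="%s"/>', xml_escape(comps)),
    "    </listOfCompartments>",
    "    <listOfSpecies>",
    sprintf('      <species id="%s" name="%s" compartment="%s"/>',
            xml_escape(model$metabolites$id),
            xml_escape(model$metabolites$name),
            xml_escape(model$metabolites$compartment)),
    "    </listOfSpecies>",
    "    <listOfReactions>"
  )
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    out <- c(out, sprintf('      <reaction id="%s" reversible="%s">',
                          xml_escape(r$id), tolower(as.character(r$reversible))))
    g <- model$reactions$genes[[i]]
    if (length(g)) {
      out <- c(out,
               "        <notes>",
               '          <body xmlns="http://www.w3.org/1999/xhtml">',
               sprintf("            <p>GENE_ASSOCIATION: %s</p>",
                       xml_escape(paste(g, collapse = " or "))),
               "          </body>",
               "        </notes>")
    }
    rcts <- model$reactions$reactants[[i]]
    prds <- model$reactions$products[[i]]
    if (length(rcts)) {
      out <- c(out, "        <listOfReactants>",
               sprintf('          <speciesReference species="%s"/>', xml_escape(rcts)),
               "        </listOfReactants>")
    }
    if (length(prds)) {
      out <- c(out, "        <listOfProducts>",
               sprintf('          <speciesReference species="%s"/>', xml_escape(prds)),
               "        </listOfProducts>")
    }
    out <- c(out, "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}

#' The default currency metabolite list
#'
#' The thirteen ubiquitous cofactors removed before edge construction:
#' H+, H2O, ATP, ADP, Pi, PPi, Na+, coenzyme A, O2, NAD+, NADH, NADP+,
#' NADPH, plus common synonyms.  Matching is by compartment-stripped base
#' name, case-insensitively, with punctuation ignored.
#'
#' @return Character vector of normalized base names.
#' @export
currency_metabolites <- function() {
  c("h", "h+", "proton",
    "h2o", "water",
    "atp", "adp",
    "pi", "phosphate", "orthophosphate",
    "ppi", "diphosphate", "pyrophosphate",
    "na", "na+", "sodium",
    "coa", "coenzyme a", "co-enzyme a", "coenzymea",
    "o2", "oxygen",
    "nad", "nad+", "nadh", "nadp", "nadp+", "nadph")
}

normalize_met_name <- function(x) gsub("[^a-z0-9]", "", tolower(x))

# base name of a metabolite id: strip an M_/S_ prefix and a short
# trailing compartment suffix (SBML dialects suffix compartments
# differently, e.g. M_atp_c, atp_m, atp[c])
met_id_base <- function(id) {
  x <- sub("^[MSms]_", "", id)
  x <- sub("\\[[A-Za-z0-9]{1,3}\\]$", "", x)
  sub("_[A-Za-z0-9]{1,2}$", "", x)
}

#' Remove currency metabolites from a model
#'
#' Deletes every compartment instance of the given currency metabolites
#' from the metabolite list and from all reaction sides.  Reactions left
#' with empty reactant and product sets are retained but flagged
#' (`empty_after_strip`), so reaction counts stay stable; such reactions
#' simply contribute no network edges.  Idempotent; unknown names are
#' silently skipped.
#'
#' @param model a [metabolic_model()].
#' @param currency character vector of currency metabolite base names
#'   (compartment-independent); defaults to [currency_metabolites()].
#' @return The stripped [metabolic_model()], with attribute
#'   `removed_metabolites` listing the deleted metabolite ids.
#' @export
strip_currency_metabolites <- function(model, currency = currency_metabolites()) {
  stopifnot(inherits(model, "metabolic_model"))
  cur <- normalize_met_name(currency)
  hit <- normalize_met_name(model$metabolites$name) %in% cur |
    normalize_met_name(met_id_base(model$metabolites$id)) %in% cur
  removed <- model$metabolites$id[hit]
  mets <- model$metabolites[!hit, , drop = FALSE]
  rx <- model$reactions
  rx$reactants <- lapply(rx$reactants, setdiff, removed)
  rx$products <- lapply(rx$products, setdiff, removed)
  rx$empty_after_strip <- rx$empty_after_strip |
    (lengths(rx$reactants) == 0 & lengths(rx$products) == 0)
  out <- metabolic_model(mets, rx, model$genes)
  attr(out, "removed_metabolites") <- removed
  out
}

#' Count reactions associated with at least one gene
#'
#' @param model a [metabolic_model()].
#' @return Integer count of reactions with a non-empty gene set.
#' @export
count_gene_associated_reactions <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  sum(lengths(model$reactions$genes) > 0)
}

#' Summarize a metabolic model
#'
#' @param model a [metabolic_model()].
#' @return A list of basic counts, suitable for JSON export.
#' @export
model_summary <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  list(
    n_metabolites = nrow(model$metabolites),
    n_reactions = nrow(model$reactions),
    n_genes = length(model$genes),
    n_gene_associated_reactions = count_gene_associated_reactions(model),
    n_compartments = length(unique(model$metabolites$compartment)),
    n_reversible = sum(model$reactions$reversible)
  )
}
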