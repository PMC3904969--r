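#' Read an orthology/homology table
#'
#' Tab-separated table with columns `reference_gene`, `target_gene`,
#' `relation` (one of `ortholog`, `homolog`) and `family`.
#'
#' @param path TSV file path.
#' @return A validated data.frame.
#' @export
read_orthology_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  validate_orthology_table(tab)
}

validate_orthology_table <- function(tab) {
  need <- c("reference_gene", "target_gene", "relation", "family")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("orthology table lacks columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(tab$relation), c("ortholog", "homolog"))
  if (length(bad)) stop("unknown relation values: ", paste(bad, collapse = ", "))
  tab
}

#' Project a target genome onto the enzyme orthology network
#'
#' Three assignment steps produce a per-group gene copy-number vector for
#' the target genome:
#' \enumerate{
#'   \item Each target gene with orthologs among the reference genes of
#'     the network is counted in the group of its orthologs.  If its
#'     orthologs span several groups it is assigned to the group holding
#'     the plurality of them; exact ties go to the lexicographically
#'     smallest group id, with a warning.
#'   \item Remaining ("orphan") target genes homologous to members of
#'     exactly one group join that group; genes homologous to two or more
#'     groups stay unassigned.
#'   \item Remaining target genes from gene families of at least
#'     `family_min_size` members whose annotated reference members all
#'     lie in a single group are assigned to that group.
#' }
#' Target genes absent from the orthology table are ignored (most of a
#' genome is non-metabolic).  Each assigned gene is counted exactly once.
#'
#' @param net an `enzyme_orthology_network` built from the reference model.
#' @param orth orthology table (see [read_orthology_table()]) keyed to the
#'   reference gene ids used by the network.
#' @param target_genes character vector of target-genome gene ids.
#' @param species species label stored with the result.
#' @param family_min_size minimum family size for step 3 (default 2).
#' @return An object of class `copy_number_vector`: list with `counts`
#'   (named integer vector over groups), `species` and `audit` (one row
#'   per assigned gene: gene, step, group).
#' @export
map_genome_to_network <- function(net, orth, target_genes, species = "target",
                                  family_min_size = 2) {
  stopifnot(inherits(net, "enzyme_orthology_network"))
  orth <- validate_orthology_table(orth)
  groups <- net$groups
  gene2grp <- setNames(rep(groups$id, lengths(groups$genes)), unlist(groups$genes))
  counts <- setNames(integer(nrow(groups)), groups$id)
  target_genes <- unique(as.character(target_genes))

  orth <- orth[orth$target_gene %in% target_genes, , drop = FALSE]
  orth$ref_group <- unname(gene2grp[orth$reference_gene])

  audit <- list()
  assigned <- character()

  # step 1: orthologs
  o <- orth[orth$relation == "ortholog" & !is.na(orth$ref_group), , drop = FALSE]
  if (nrow(o)) {
    for (tg in unique(o$target_gene)) {
      grps <- o$ref_group[o$target_gene == tg]
      tab <- sort(table(grps), decreasing = TRUE)
      top <- names(tab)[tab == tab[1]]
      if (length(top) > 1) {
        warning("target gene '", tg, "' has orthologs tied across groups ",
                paste(sort(top), collapse = ", "), "; assigned to the smallest id")
      }
      g <- sort(top)[1]
      counts[g] <- counts[g] + 1L
      assigned <- c(assigned, tg)
      audit[[length(audit) + 1L]] <- data.frame(target_gene = tg, step = 1L, group = g,
                                                stringsAsFactors = FALSE)
    }
  }

  # step 2: orphans homologous to exactly one group
  h <- orth[orth$relation == "homolog" & !is.na(orth$ref_group) &
              !(orth$target_gene %in% assigned), , drop = FALSE]
  if (nrow(h)) {
    for (tg in unique(h$target_gene)) {
      grps <- unique(h$ref_group[h$target_gene == tg])
      if (length(grps) != 1) next
      counts[grps] <- counts[grps] + 1L
      assigned <- c(assigned, tg)
      audit[[length(audit) + 1L]] <- data.frame(target_gene = tg, step = 2L, group = grps,
                                                stringsAsFactors = FALSE)
    }
  }

  # step 3: single-group gene families
  fam_size <- tapply(c(orth$reference_gene, orth$target_gene),
                     c(orth$family, orth$family),
                     function(g) length(unique(g)))
  rest <- orth[!(orth$target_gene %in% assigned), , drop = FALSE]
  if (nrow(rest)) {
    for (tg in unique(rest$target_gene)) {
      fams <- unique(rest$family[rest$target_gene == tg])
      grps <- unique(unlist(lapply(fams, function(f) {
        refs <- unique(orth$reference_gene[orth$family == f])
        ann <- gene2grp[refs]
        unique(ann[!is.na(ann)])
      })))
      grps <- grps[!is.na(grps)]
      if (length(grps) != 1) next
      if (max(fam_size[fams]) < family_min_size) next
      counts[grps] <- counts[grps] + 1L
      assigned <- c(assigned, tg)
      audit[[length(audit) + 1L]] <- data.frame(target_gene = tg, step = 3L, group = grps,
                                                stringsAsFactors = FALSE)
    }
  }

  audit <- if (length(audit)) do.call(rbind, audit) else
    data.frame(target_gene = character(), step = integer(), group = character())
  structure(list(counts = counts, species = species, audit = audit),
            class = "copy_number_vector")
}

#' @export
print.copy_number_vector <- function(x, ...) {
  cat("<copy_number_vector> species '", x$species, "': ",
      sum(x$counts), " genes over ", length(x$counts), " groups (",
      sum(x$counts > 0), " non-empty)\n", sep = "")
  invisible(x)
}

#' Assemble a group-by-species copy-number matrix
#'
#' @param vectors list of `copy_number_vector` objects over the same group
#'   set (or a single one).
#' @return Integer matrix, rows = groups, columns = species.
#' @export
copy_number_matrix <- function(vectors) {
  if (inherits(vectors, "copy_number_vector")) vectors <- list(vectors)
  ids <- names(vectors[[1]]$counts)
  for (v in vectors) {
    if (!identical(names(v$counts), ids)) stop("copy-number vectors disagree on group sets")
  }
  m <- vapply(vectors, function(v) v$counts, integer(length(ids)))
  colnames(m) <- vapply(vectors, function(v) v$species, character(1))
  rownames(m) <- ids
  m
}

#' Write / read copy-number matrices as CSV (groups x species)
#'
#' @param m integer matrix, rows = groups, columns = species.
#' @param path CSV file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_copy_numbers <- function(m, path) {
  write.csv(data.frame(group = rownames(m), m, check.names = FALSE), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_copy_numbers
#' @export
read_copy_numbers <- function(path) {
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$group
  storage.mode(m) <- "integer"
  m
}
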