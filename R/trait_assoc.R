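#' Branch-wise change matrix
#'
#' One row per tree branch (postorder edge order), one column per
#' isoenzyme group holding the integer copy-number delta (child minus
#' parent) on that branch; optionally one additional column per trait
#' with the branch-wise trait change from that trait's own parsimony
#' reconstruction.
#'
#' @param states a `node_state_matrix` from [reconstruct_all()].
#' @param traits optional species x trait data.frame/matrix (rownames =
#'   species, `NA` = missing); each trait is reconstructed by linear
#'   parsimony and its per-branch delta appended as column
#'   `trait.<name>`.
#' @param predictors `"delta"` (default, signed per-branch changes) or
#'   `"absolute"` (the child node's absolute copy numbers).
#' @return Numeric matrix with rownames `parent->child`; attribute
#'   `trait_columns` names any appended trait columns.
#' @export
branch_change_matrix <- function(states, traits = NULL,
                                 predictors = c("delta", "absolute")) {
  stopifnot(inherits(states, "node_state_matrix"))
  predictors <- match.arg(predictors)
  tix <- tree_index(states$tree)
  m <- states$integer_values
  D <- if (predictors == "delta") {
    m[tix$edge_child, , drop = FALSE] - m[tix$edge_parent, , drop = FALSE]
  } else {
    m[tix$edge_child, , drop = FALSE]
  }
  rownames(D) <- branch_labels(tix)
  tcols <- character()
  if (!is.null(traits)) {
    traits <- as.data.frame(traits)
    for (tr in colnames(traits)) {
      y <- setNames(as.numeric(traits[[tr]]), rownames(traits))
      rec <- linear_parsimony_reconstruct(states$tree, y)
      td <- rec$values[tix$edge_child] - rec$values[tix$edge_parent]
      D <- cbind(D, setNames(data.frame(td), paste0("trait.", tr)))
      tcols <- c(tcols, paste0("trait.", tr))
    }
    D <- as.matrix(D)
    rownames(D) <- branch_labels(tix)
  }
  attr(D, "trait_columns") <- tcols
  D
}

#' Correlation-based feature subset selection (CFS)
#'
#' Greedy best-first forward search maximizing
#' `merit(S) = k * mean|r_cf| / sqrt(k + k (k - 1) * mean|r_ff|)`
#' where `r_cf` are feature-target and `r_ff` pairwise feature Pearson
#' correlations: subsets highly correlated with the target but mutually
#' uncorrelated are preferred.  The search keeps expanding past
#' non-improving additions and stops after two consecutive failures to
#' improve, returning the best subset seen.  Constant features are never
#' selected.
#'
#' @param features numeric matrix (rows = branches, columns = features).
#' @param target numeric vector.
#' @return Character vector of selected feature names (column indices if
#'   unnamed); empty, with a warning, when no feature varies.
#' @export
cfs_select <- function(features, target) {
  features <- as.matrix(features)
  stopifnot(length(target) == nrow(features))
  idx <- cpp_cfs(features, as.numeric(target))
  if (!length(idx)) {
    warning("no usable (non-constant) features; empty selection")
    return(character())
  }
  if (!is.null(colnames(features))) colnames(features)[idx] else as.character(idx)
}

#' Least-median-of-squares (LMS) regression
#'
#' Robust linear regression minimizing the median of the squared
#' residuals.  Exact fits are computed on (p+1)-point subsamples and the
#' fit with the smallest median squared residual over all rows is kept;
#' all subsamples are enumerated when their number does not exceed
#' `n_subsamples`, otherwise seeded random subsamples are drawn
#' (degenerate subsamples are skipped and redrawn).  Missing predictor
#' values are imputed with column medians; columns are re-centered
#' internally (coefficients are reported on the original scale).
#'
#' @param X numeric matrix or data.frame of predictors.
#' @param y numeric response (no missing values).
#' @param n_subsamples subsample budget; default `min(2000, all subsets)`.
#' @param seed RNG seed.
#' @return Object of class `lms_fit`: `coefficients` (intercept first)
#'   and `crit` (the minimized median squared residual).
#' @export
lms_regress <- function(X, y, n_subsamples = NULL, seed = 1) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (anyNA(y)) stop("missing values in the response are not allowed")
  if (nrow(X) < ncol(X) + 1) stop("need at least p + 1 rows")
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- median(X[!nas, j])
  }
  if (is.null(n_subsamples)) {
    n_subsamples <- min(2000, choose(nrow(X), ncol(X) + 1))
  }
  fit <- cpp_lms(X, y, as.integer(n_subsamples), as.double(seed))
  cf <- fit$coefficients
  names(cf) <- c("(Intercept)", colnames(X) %||% paste0("x", seq_len(ncol(X))))[
    seq_along(cf)]
  structure(list(coefficients = cf, crit = fit$crit,
                 n_subsamples = n_subsamples),
            class = "lms_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lms_fit <- function(x, ...) {
  cat("LMS fit (median squared residual ", signif(x$crit, 4), ")\n", sep = "")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
predict.lms_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  cf <- object$coefficients
  drop(cf[1] + newdata %*% cf[-1])
}

# shared setup for the association engine: postorder arrays + predictor
# delta matrix from a copy-number reconstruction
assoc_setup <- function(tree, tip_counts, predictors = "delta") {
  states <- if (inherits(tip_counts, "node_state_matrix")) tip_counts
            else reconstruct_all(tree, tip_counts)
  tix <- tree_index(states$tree)
  m <- states$integer_values
  D <- if (predictors == "absolute") {
    m[tix$edge_child, , drop = FALSE]
  } else {
    m[tix$edge_child, , drop = FALSE] - m[tix$edge_parent, , drop = FALSE]
  }
  storage.mode(D) <- "double"
  list(tix = tix, D = D, states = states)
}

#' Leave-one-species-out trait prediction
#'
#' For each species with an observed trait value: its terminal branch is
#' dropped, the trait is re-reconstructed on the tree without that tip,
#' predictors are re-selected by CFS among the per-branch copy-number
#' deltas and an LMS model re-fitted; the species' trait is then
#' predicted as (reconstructed trait value of its parent node) +
#' (predicted trait change along its terminal branch).  The reported `r`
#' is the Pearson correlation between these predictions and the observed
#' values.  Copy-number reconstructions are kept fixed throughout (genome
#' data is never missing in this scheme).
#'
#' @param tree rooted `phylo` tree.
#' @param tip_counts species x group copy-number matrix (or a
#'   `node_state_matrix` already reconstructed on `tree`).
#' @param trait named numeric vector of tip trait values (`NA` missing);
#'   at least 4 observed species required.
#' @param predictors `"delta"` (default) or `"absolute"`.
#' @param n_subsamples LMS subsample budget inside the pipeline
#'   (default 200).
#' @param seed RNG seed.
#' @return Object of class `association_result`: `trait` (name), `r`,
#'   `predictions` (named by species), `selected` (groups selected on the
#'   full data), `trait_values` (reconstructed node values), and the
#'   internal inputs needed by [permutation_significance()].
#' @export
loo_species_predict <- function(tree, tip_counts, trait,
                                predictors = c("delta", "absolute"),
                                n_subsamples = 200, seed = 1) {
  predictors <- match.arg(predictors)
  setup <- assoc_setup(tree, tip_counts, predictors)
  tix <- setup$tix
  y <- align_tip_values(trait, tix)
  if (sum(!is.na(y)) < 4) stop("need at least 4 species with observed trait values")
  res <- cpp_assoc_loo(tix$edge_parent, tix$edge_child, tix$n_tip, tix$n_node,
                       setup$D, y, as.integer(n_subsamples), as.double(seed))
  structure(list(
    trait = attr(trait, "trait_name") %||% deparse(substitute(trait)),
    r = res$r,
    predictions = setNames(res$predictions, tix$tree$tip.label),
    observed = setNames(y, tix$tree$tip.label),
    selected = colnames(setup$D)[res$selected],
    trait_values = setNames(res$trait_values, tix$node_names),
    trait_cost = res$trait_cost,
    p = NA_real_, n_perm = 0L,
    .tix = tix, .D = setup$D, .y = y,
    n_subsamples = n_subsamples, seed = seed
  ), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat("<association_result> trait '", x$trait, "': LOO r = ",
      round(x$r, 3), sep = "")
  if (x$n_perm > 0) cat(", empirical p = ", signif(x$p, 3),
                        " (", x$n_perm, " permutations)", sep = "")
  cat("\n  selected groups: ",
      if (length(x$selected)) paste(x$selected, collapse = ", ") else "(none)",
      "\n", sep = "")
  invisible(x)
}

#' Permutation significance of a trait association
#'
#' Observed trait values are reshuffled among the observed taxa and the
#' whole pipeline (trait reconstruction, branch deltas, CFS selection,
#' LMS fit, leave-one-species-out correlation) is re-run for each
#' reshuffle.  One-tailed empirical p:
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n)`.
#'
#' @param result an `association_result` from [loo_species_predict()].
#' @param n number of reshuffles (default 1000).
#' @param seed RNG seed.
#' @return The `association_result` updated with `p`, `n_perm` and
#'   `r_perm` (the null correlations).
#' @export
permutation_significance <- function(result, n = 1000, seed = 1) {
  stopifnot(inherits(result, "association_result"))
  tix <- result$.tix
  res <- cpp_assoc_perm(tix$edge_parent, tix$edge_child, tix$n_tip, tix$n_node,
                        result$.D, result$.y, as.integer(n),
                        as.integer(result$n_subsamples), as.double(seed))
  result$r_perm <- res$r_perm
  result$p <- (1 + sum(res$r_perm >= result$r)) / (1 + n)
  result$n_perm <- as.integer(n)
  result
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up false-discovery-rate control at level `alpha`.
#'
#' @param pvalues numeric vector of p-values.
#' @param alpha FDR level (default 0.05).
#' @return Logical vector: which hypotheses are rejected.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (!length(pvalues)) return(logical())
  p.adjust(pvalues, method = "BH") <= alpha
}

#' Trait association over a full trait table
#'
#' Runs [loo_species_predict()] and [permutation_significance()] for
#' every trait column and applies [bh_fdr()] across traits, mirroring a
#' trait / prediction-correlation / p-value / FDR-flag results table.
#'
#' @param tree rooted `phylo` tree.
#' @param tip_counts species x group copy-number matrix (or
#'   `node_state_matrix`).
#' @param traits species x trait data.frame (rownames = species, `NA`
#'   missing; see [read_trait_table()]).
#' @param n_perm permutations per trait (default 1000).
#' @param seed base seed; trait i uses `seed + i`.
#' @param n_subsamples LMS subsample budget (default 200).
#' @param alpha FDR level.
#' @param predictors `"delta"` or `"absolute"`.
#' @return data.frame of class `trait_association`: columns `trait`, `r`,
#'   `p`, `fdr_significant`, `selected`; per-trait `association_result`s
#'   in attribute `results`.
#' @export
trait_association <- function(tree, tip_counts, traits, n_perm = 1000, seed = 1,
                              n_subsamples = 200, alpha = 0.05,
                              predictors = c("delta", "absolute")) {
  predictors <- match.arg(predictors)
  setup <- assoc_setup(tree, tip_counts, predictors)
  traits <- as.data.frame(traits)
  results <- vector("list", ncol(traits))
  names(results) <- colnames(traits)
  for (i in seq_along(traits)) {
    y <- setNames(as.numeric(traits[[i]]), rownames(traits))
    attr(y, "trait_name") <- colnames(traits)[i]
    res <- loo_species_predict(tree, setup$states, y, predictors = predictors,
                               n_subsamples = n_subsamples, seed = seed + i)
    res$trait <- colnames(traits)[i]
    res <- permutation_significance(res, n = n_perm, seed = seed + i)
    results[[i]] <- res
  }
  out <- data.frame(
    trait = names(results),
    r = vapply(results, `[[`, numeric(1), "r"),
    p = vapply(results, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE
  )
  out$fdr_significant <- bh_fdr(out$p, alpha)
  out$selected <- vapply(results, function(r) paste(r$selected, collapse = ","),
                         character(1))
  rownames(out) <- NULL
  attr(out, "results") <- results
  class(out) <- c("trait_association", "data.frame")
  out
}

#' Write association results as TSV
#' @param assoc a `trait_association` data.frame.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_association_results <- function(assoc, path) {
  write.table(assoc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation comparison of between-group versus within-group
#' distances (statistic R in [-1, 1]); computed via \pkg{vegan}.  Groups
#' of size one are excluded with a warning.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @param groups factor of group labels, one per object.
#' @param n_perm number of label permutations (default 999).
#' @param seed RNG seed.
#' @return List with elements `R` and `p`.
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = NULL) {
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (any(sizes < 2)) {
    drop <- names(sizes)[sizes < 2]
    warning("excluding singleton groups: ", paste(drop, collapse = ", "))
    keep <- !(groups %in% drop)
    d <- stats::as.dist(as.matrix(d)[keep, keep])
    groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2) stop("need at least 2 groups of size >= 2")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::anosim(d, groups, permutations = n_perm)
  list(R = unname(fit$statistic), p = fit$signif)
}

#' PCA variance summary
#'
#' Principal component analysis on the covariance matrix (centered, not
#' scaled); returns the fraction of variance explained per component.
#'
#' @param m numeric matrix (rows = observations).
#' @return List with `variance_fraction` (sums to 1), `sdev`, and
#'   `constant` (TRUE when the matrix has no variance at all, in which
#'   case the fractions are all zero).
#' @export
pca_summary <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least 2 rows and 2 columns")
  v <- apply(m, 2, sd)
  if (all(v < .Machine$double.eps^0.5)) {
    return(list(variance_fraction = rep(0, ncol(m)), sdev = rep(0, ncol(m)),
                constant = TRUE))
  }
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  list(variance_fraction = vf, sdev = fit$sdev, constant = FALSE,
       scores = fit$x)
}

#' Read / write a species x trait table
#'
#' CSV with a `species` first column; missing values are written and read
#' as `?`.
#'
#' @param path CSV file path.
#' @return data.frame with species rownames (read); `path` (write).
#' @export
read_trait_table <- function(path) {
  d <- read.csv(path, na.strings = c("?", "NA"), check.names = FALSE,
                stringsAsFactors = FALSE)
  rownames(d) <- d[[1]]
  d[[1]] <- NULL
  d
}

#' @rdname read_trait_table
#' @param traits species x trait data.frame with species rownames.
#' @export
write_trait_table <- function(traits, path) {
  out <- data.frame(species = rownames(traits), traits, check.names = FALSE)
  write.csv(out, path, row.names = FALSE, na = "?")
  invisible(path)
}
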