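# orthonormal design for exact CFS correlations
orthonormal_features <- function(n = 40) {
  set.seed(101)
  raw <- matrix(rnorm(n * 3), n, 3)
  q <- qr.Q(qr(cbind(1, raw)))[, 2:4]  # orthogonal to the intercept
  sweep(q, 2, sqrt(colSums(q^2)), "/")
}

test_that("CFS merit: single feature merit is |r_cf| and the formula matches", {
  z <- orthonormal_features()
  y <- 0.8 * z[, 1] + sqrt(1 - 0.64) * z[, 3]
  X <- cbind(f1 = z[, 1], f2 = z[, 2])
  expect_equal(cfs_merit(X, y, 1), abs(cor(z[, 1], y)))
  expect_equal(cfs_select(X, y), "f1")
})

test_that("CFS never keeps an exact duplicate when a complementary feature exists", {
  z <- orthonormal_features()
  # r_cf exactly (0.7, 0.7, 0.55): all 7 subset merits, enumerated with the
  # formula, peak at {f1, f3}; the duplicate f2 only ever hurts
  y <- 0.7 * z[, 1] + 0.55 * z[, 2] + sqrt(1 - 0.7^2 - 0.55^2) * z[, 3]
  X <- cbind(f1 = z[, 1], f2 = z[, 1], f3 = z[, 2])
  merits <- sapply(list(1, 2, 3, c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3)),
                   function(s) cfs_merit(X, y, s))
  expect_equal(which.max(merits), 5) # {f1, f3}
  expect_equal(cfs_select(X, y), c("f1", "f3"))
})

test_that("CFS warns and returns empty on all-constant features", {
  X <- cbind(a = rep(1, 10), b = rep(2, 10))
  expect_warning(sel <- cfs_select(X, rnorm(10)), "non-constant")
  expect_equal(sel, character())
})

test_that("LMS reproduces exact linear data", {
  X <- matrix(seq(-3, 6, length.out = 12), ncol = 1)
  f <- lms_regress(X, 3 * X[, 1] - 2)
  expect_equal(unname(f$coefficients), c(-2, 3), tolerance = 1e-10)
  expect_equal(f$crit, 0)
})

test_that("LMS resists gross outliers where OLS breaks", {
  x <- 1:13
  y <- 2 * x + 1
  y[c(2, 6, 11)] <- y[c(2, 6, 11)] + 100
  f <- lms_regress(matrix(x, ncol = 1), y) # exhaustive: choose(13,2)=78 subsets
  expect_lt(abs(f$coefficients[2] - 2), 0.05)
  ols <- lm(y ~ x)
  expect_gt(abs(coef(ols)[2] - 2), 0.5)
  # matches the exhaustive elemental oracle exactly
  orc <- lms_oracle(matrix(x, ncol = 1), y)
  expect_equal(f$crit, orc$crit)
  expect_equal(unname(f$coefficients), as.numeric(orc$coef))
})

test_that("LMS criterion never exceeds the OLS median squared residual", {
  set.seed(5)
  for (i in 1:8) {
    n <- sample(12:20, 1)
    X <- matrix(rnorm(2 * n), ncol = 2)
    y <- X %*% c(1, -2) + rnorm(n) + ifelse(runif(n) < 0.2, 30, 0)
    f <- lms_regress(X, y, seed = i)
    ols <- lm(y ~ X)
    expect_lte(f$crit, median(resid(ols)^2) + 1e-9)
  }
})

test_that("LMS agrees with MASS::lqs on heavily contaminated data", {
  skip_if_not_installed("MASS")
  set.seed(31)
  x <- c(1:20)
  y <- 0.5 * x + 3 + rnorm(20, 0, 0.2)
  y[1:6] <- y[1:6] + 50
  f <- lms_regress(matrix(x, ncol = 1), y)
  lq <- MASS::lqs(y ~ x, method = "lms", nsamp = "exact")
  expect_lt(abs(f$coefficients[2] - coef(lq)[2]), 0.15)
})

test_that("LMS slope survives up to 40% outlier contamination", {
  set.seed(41)
  x <- seq(1, 15, length.out = 15)
  y <- 2 * x + 1 + rnorm(15, 0, 0.05)
  contaminated <- y
  contaminated[1:6] <- contaminated[1:6] + 80  # 40% of rows
  f_clean <- lms_regress(matrix(x, ncol = 1), y)
  f_bad <- lms_regress(matrix(x, ncol = 1), contaminated)
  expect_lt(abs(f_bad$coefficients[2] - f_clean$coefficients[2]), 0.1)
})

test_that("LMS fits are reproducible under a fixed seed when sampling", {
  set.seed(2)
  X <- matrix(rnorm(120), ncol = 4)
  y <- rnorm(30)
  f1 <- lms_regress(X, y, n_subsamples = 60, seed = 9)
  f2 <- lms_regress(X, y, n_subsamples = 60, seed = 9)
  expect_identical(f1$coefficients, f2$coefficients)
})

planted_noiseless <- function() {
  tr <- balanced8()
  counts <- cbind(gA = c(0, 0, 0, 0, 2, 2, 2, 2), gB = rep(1, 8), gC = rep(3, 8))
  rownames(counts) <- tr$tip.label
  trait <- setNames(5 + 2 * counts[, "gA"], rownames(counts))
  list(tree = tr, counts = counts, trait = trait)
}

test_that("noiseless planted signal is predicted exactly (r = 1)", {
  p <- planted_noiseless()
  res <- loo_species_predict(p$tree, p$counts, p$trait)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(unname(res$predictions[names(p$trait)]), unname(p$trait),
               tolerance = 1e-10)
  expect_equal(res$selected, "gA")
})

test_that("permutation count arithmetic: unbeatable signal gives p = 1/(n+1)", {
  # equal-valued cherry pairs keep the leave-one-out reconstruction exact
  # (r_obs = 1); distinct values across cherries make a tying reshuffle
  # very unlikely (only within-pair swaps reproduce the value vector)
  tr <- balanced8()
  counts <- cbind(gA = c(0, 0, 4, 4, 8, 8, 12, 12), gB = rep(1, 8))
  rownames(counts) <- tr$tip.label
  trait <- setNames(5 + 2 * counts[, "gA"], rownames(counts))
  res <- loo_species_predict(tr, counts, trait)
  expect_equal(res$r, 1, tolerance = 1e-12)
  res <- permutation_significance(res, n = 99, seed = 11)
  expect_equal(res$p, 1 / 100)
  expect_true(all(res$r_perm < res$r))
})

test_that("a trait independent of all groups yields correlations centered on zero", {
  set.seed(55)
  cfg <- simulation_config(seed = 55, n_taxa = 10)
  tree <- simulate_tree(cfg)
  sim <- simulate_copy_evolution(tree, paste0("g", 1:40), cfg)
  rs <- replicate(25, {
    y <- setNames(rnorm(10), tree$tip.label)
    loo_species_predict(tree, sim$tip_counts, y, n_subsamples = 50)$r
  })
  expect_lt(abs(mean(rs)), 0.25)
})

test_that("BH step-up flags match hand-computed thresholds", {
  expect_equal(bh_fdr(c(0.001, 0.01, 0.03, 0.2)), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh_fdr(rep(1, 5)), rep(FALSE, 5))
  expect_equal(bh_fdr(0.04), TRUE)
  expect_equal(bh_fdr(numeric()), logical())
})

test_that("ANOSIM statistic matches the direct rank formula", {
  set.seed(19)
  pts <- rbind(matrix(rnorm(8, 0), 4), matrix(rnorm(8, 6), 4))
  d <- dist(pts)
  grp <- rep(c("a", "b"), each = 4)
  res <- anosim_test(d, grp, n_perm = 199, seed = 3)
  expect_equal(res$R, 1) # complete separation
  expect_lt(res$p, 0.05)
  # random configuration: vegan equals the rank formula
  pts2 <- matrix(rnorm(12), 6)
  d2 <- dist(pts2)
  grp2 <- rep(c("a", "b"), 3)
  res2 <- anosim_test(d2, grp2, n_perm = 99, seed = 3)
  expect_equal(res2$R, anosim_oracle(d2, grp2), tolerance = 1e-12)
  # 4-point case: R enumerated for all 3 distinct balanced labelings
  d4 <- as.dist(matrix(c(0, 1, 4, 5,
                         1, 0, 6, 7,
                         4, 6, 0, 2,
                         5, 7, 2, 0), 4))
  labelings <- list(c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 2, 2, 1))
  Rs <- vapply(labelings, function(l) anosim_oracle(d4, l), numeric(1))
  expect_equal(which.max(Rs), 1) # the planted split separates best
  for (i in seq_along(labelings)) {
    ri <- anosim_test(d4, labelings[[i]], n_perm = 23, seed = 1)
    expect_equal(ri$R, Rs[i], tolerance = 1e-12)
  }
  expect_warning(anosim_test(d, c("a", "a", "a", "a", "b", "b", "b", "c"),
                             n_perm = 49, seed = 1), "singleton")
})

test_that("PCA variance fractions behave spectrally", {
  u <- rnorm(20)
  rank1 <- cbind(u, 2 * u, -u)
  p <- pca_summary(rank1)
  expect_equal(p$variance_fraction[1], 1)
  set.seed(12)
  m <- matrix(rnorm(40), 20, 2) %*% matrix(c(2, 1, 0, 1), 2)
  p2 <- pca_summary(m)
  S <- cov(m)
  tr <- S[1, 1] + S[2, 2]; det2 <- S[1, 1] * S[2, 2] - S[1, 2]^2
  lam1 <- (tr + sqrt(tr^2 - 4 * det2)) / 2 # closed-form 2x2 eigenvalue
  expect_equal(p2$variance_fraction[1], lam1 / tr, tolerance = 1e-10)
  expect_true(all(diff(p2$variance_fraction) <= 1e-12))
  expect_equal(sum(p2$variance_fraction), 1)
  pc <- pca_summary(matrix(1, 5, 3))
  expect_true(pc$constant)
  expect_equal(pc$variance_fraction, c(0, 0, 0))
})

test_that("branch change matrix rows align with CNA events and trait deltas", {
  p <- planted_noiseless()
  st <- reconstruct_all(p$tree, p$counts)
  D <- branch_change_matrix(st, traits = data.frame(t1 = p$trait))
  expect_equal(nrow(D), nrow(st$tree$edge))
  expect_equal(attr(D, "trait_columns"), "trait.t1")
  # trait deltas are exactly twice the gA deltas (affine equivariance)
  expect_equal(unname(D[, "trait.t1"]), unname(2 * D[, "gA"]), tolerance = 1e-10)
  ev <- cna_events(st)
  for (i in seq_len(nrow(ev))) {
    b <- paste0(ev$parent[i], "->", ev$child[i])
    expect_equal(unname(D[b, ev$group[i]]), as.numeric(ev$delta[i]))
  }
})

test_that("trait_association tables combine LOO, permutations and FDR", {
  p <- planted_noiseless()
  traits <- data.frame(planted = p$trait + seq(0, 0.007, length.out = 8),
                       noise = c(3, 1, 4, 1, 5, 9, 2, 6))
  rownames(traits) <- names(p$trait)
  res <- trait_association(p$tree, p$counts, traits, n_perm = 99, seed = 2)
  expect_equal(res$trait, c("planted", "noise"))
  expect_gt(res$r[1], 0.99)
  expect_equal(res$p[1], 0.01)
  expect_gt(res$p[2], 0.05)
  expect_true(res$fdr_significant[1])
  expect_false(res$fdr_significant[2])
  expect_match(res$selected[1], "gA")
})

test_that("full association pipeline is bit-reproducible under fixed seeds", {
  p <- planted_noiseless()
  y <- p$trait + c(0.01, -0.02, 0.03, 0, 0.01, -0.01, 0.02, 0)
  r1 <- permutation_significance(loo_species_predict(p$tree, p$counts, y, seed = 4),
                                 n = 50, seed = 4)
  r2 <- permutation_significance(loo_species_predict(p$tree, p$counts, y, seed = 4),
                                 n = 50, seed = 4)
  expect_identical(r1$r, r2$r)
  expect_identical(r1$r_perm, r2$r_perm)
  expect_identical(r1$p, r2$p)
})

test_that("missing trait species are skipped in the LOO correlation", {
  p <- planted_noiseless()
  y <- p$trait
  y["H"] <- NA
  res <- loo_species_predict(p$tree, p$counts, y)
  expect_true(is.na(res$predictions["H"]))
  expect_equal(sum(!is.na(res$predictions)), 7)
  expect_error(loo_species_predict(p$tree, p$counts,
                                   setNames(c(1, 2, 3, rep(NA, 5)), names(y))),
               "at least 4")
})
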