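test_that("OLS fits exact lines and matches a pseudo-inverse oracle", {
  fit <- hover_lm(y ~ x, data.frame(x = c(0, 1, 2), y = c(1, 3, 5)))
  expect_equal(unname(coef(fit)), c(1, 2))
  expect_equal(fit$r2, 1)
  for (seed in 1:5) {
    set.seed(seed)
    d <- data.frame(matrix(rnorm(60), 20, 3))
    names(d) <- c("a", "b", "c")
    d$y <- rnorm(20)
    fit <- hover_lm(y ~ a + b + c, d)
    expect_equal(unname(coef(fit)),
                 unname(ols_oracle(d[, c("a", "b", "c")], d$y)),
                 tolerance = 1e-8)
    expect_equal(fit$fitted + fit$residuals, d$y)
  }
})

test_that("zero-noise reference-coefficient designs refit to machine precision", {
  tab <- gen_species_table(noiseless_plan(seed = 1))
  fit <- hover_lm(mo2_formula("mo2net"), tab)
  expect_equal(coef(fit), hover_reference_coefs("mo2net"),
               tolerance = 1e-10)
  expect_equal(coef(fit)[["fineness_depth"]], 201.28, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  fit2 <- hover_lm(mo2_formula("ratio"), tab)
  expect_equal(coef(fit2), hover_reference_coefs("ratio"),
               tolerance = 1e-10)
})

test_that("rank-deficient designs fail naming the collinear column", {
  d <- data.frame(x1 = 1:6, y = rnorm(6))
  d$x2 <- 2 * d$x1
  expect_error(hover_lm(y ~ x1 + x2, d), "x2")
})

test_that("refitting on fitted values is idempotent with R2 = 1", {
  tab <- gen_species_table(synth_plan(seed = 2, noise_sd = 120))
  fit <- hover_lm(mo2_formula("mo2net"), tab)
  tab2 <- tab
  tab2$mo2net <- fit$fitted
  fit2 <- hover_lm(mo2_formula("mo2net"), tab2)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-8)
  expect_equal(fit2$r2, 1, tolerance = 1e-12)
})

test_that("importance is zero for irrelevant variables and equals nested dR2", {
  set.seed(1)
  n <- 40
  x1 <- rnorm(n); x1 <- x1 - mean(x1)
  x2 <- rnorm(n); x2 <- x2 - mean(x2)
  x2 <- x2 - x1 * sum(x1 * x2) / sum(x1^2)  # orthogonalize (centered)
  d <- data.frame(x1 = x1, x2 = x2, y = 2 * x1)
  fit <- hover_lm(y ~ x1 + x2, d)
  imp <- importance(fit, method = "drop")
  expect_equal(imp$dr2_drop[imp$predictor == "x2"], 0, tolerance = 1e-10)
  # dropping x1 loses everything x2 cannot explain; x2 orthogonal to y
  r2_without_x1 <- hover_lm(y ~ x2, d)$r2
  expect_equal(imp$dr2_drop[imp$predictor == "x1"],
               fit$r2 - r2_without_x1, tolerance = 1e-12)
  expect_equal(imp$dr2_drop[imp$predictor == "x1"], fit$r2,
               tolerance = 1e-6)
  expect_error(importance(fit, method = "permute", n_perm = 0), "n_perm")
})

test_that("drop and permute importance agree on well-separated effects", {
  set.seed(3)
  n <- 60
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  d$y <- 5 * d$x1 + 1.5 * d$x2 + rnorm(n, 0, 0.3)
  fit <- hover_lm(y ~ x1 + x2 + x3, d)
  imp <- importance(fit, method = "both", n_perm = 99, seed = 2)
  expect_equal(order(-imp$dr2_drop), order(-imp$dr2_permute))
  expect_equal(imp$predictor[order(-imp$dr2_drop)], c("x1", "x2", "x3"))
})

test_that("a pure-noise column does not reorder importance ranks", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 50
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    d$y <- 4 * d$x1 + 1 * d$x2 + rnorm(n, 0, 0.3)
    base_rank <- order(-importance(hover_lm(y ~ x1 + x2, d),
                                   method = "drop")$dr2_drop)
    d$junk <- rnorm(n)
    imp <- importance(hover_lm(y ~ x1 + x2 + junk, d), method = "drop")
    keep <- imp$predictor != "junk"
    expect_equal(order(-imp$dr2_drop[keep]), base_rank)
  }
})

test_that("dropping one fineness ratio keeps R2 high when they are correlated", {
  plan <- synth_plan(seed = 4, n_species = 100, fineness_cor = 0.95,
                     noise_sd = 170, ratio_noise_sd = 0)
  tab <- gen_species_table(plan)
  full <- hover_lm(mo2_formula("mo2net"), tab)
  reduced <- hover_lm(mo2net ~ mass + fineness_depth + comcob_ap +
                        comcob_dv + pect_fin_ap + caud_fin_ap, tab)
  expect_gt(full$r2, 0.7)
  expect_gt(reduced$r2, full$r2 - 0.15)
})

test_that("species land in G2 when above average on either metric", {
  g <- assign_groups(c(1, 2, 3, 10), c(1, 1, 1, 1))
  expect_equal(as.vector(g), c("G1", "G1", "G1", "G2"))
  # above the mean on the ratio alone is enough for the high group
  g2 <- assign_groups(c(1, 1, 1, 1), c(0.5, 0.5, 0.5, 2))
  expect_equal(as.vector(g2), c("G1", "G1", "G1", "G2"))
  # exactly at the mean stays in the low group
  g3 <- assign_groups(c(2, 2, 2, 2), c(1, 1, 1, 3))
  expect_equal(as.vector(g3)[1], "G1")
  expect_warning(assign_groups(c(1, 1), c(2, 2)), "G1")
})

test_that("species ANOVA matches a sum-of-squares oracle", {
  # identical groups: no between-species signal
  st <- species_tests(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(st$anova$F, 0)
  expect_equal(st$anova$p, 1)
  # zero within-group variance flagged degenerate
  st2 <- species_tests(c(0, 0, 0, 1, 1, 1), rep(c("a", "b"), each = 3))
  expect_true(st2$degenerate)
  expect_lt(st2$anova$p, 1e-10)
  # random 3-group instances against the from-scratch decomposition
  for (seed in 1:5) {
    set.seed(seed)
    sp <- rep(c("a", "b", "c"), times = c(5, 7, 6))
    y <- rnorm(length(sp)) + rep(c(0, 0.5, 1.2), times = c(5, 7, 6))
    st3 <- species_tests(y, sp)
    oracle <- anova_oracle(y, sp)
    expect_equal(st3$anova$F, oracle$F, tolerance = 1e-10)
    expect_equal(st3$anova$df, c(oracle$df1, oracle$df2))
  }
  expect_warning(species_tests(c(1, 2, 3, 4, 9),
                               c("a", "a", "b", "b", "c")),
                 "single replicate")
})

test_that("hover-rest and group contrasts are reported", {
  set.seed(9)
  sp <- rep(c("a", "b"), each = 8)
  cond <- rep(rep(c("hover", "rest"), each = 4), 2)
  mo2 <- c(rnorm(4, 300, 10), rnorm(4, 150, 10),
           rnorm(4, 200, 10), rnorm(4, 150, 10))
  st <- species_tests(mo2, sp, condition = cond,
                      groups = c(a = "G2", b = "G1"))
  expect_lt(st$within_species$a$p, 0.01)
  expect_gt(st$within_species$a$mean_hover, st$within_species$a$mean_rest)
  expect_true(is.numeric(st$group_test$t))
})

test_that("Abouheif C equals the hand-built proximity and exhaustive p", {
  a4 <- abouheif_a4()
  x <- c(A = 1, B = 1, C = -1, D = -1)
  c_obs <- moran_oracle(x, a4)
  expect_equal(c_obs, 1 / 3)
  # exhaustive enumeration over all 4! assignments
  perms <- all_perms(4)
  cs <- vapply(perms, function(ix) moran_oracle(unname(x)[ix], a4),
               numeric(1))
  expect_equal(mean(cs >= c_obs - 1e-12), 1 / 3)
  # the package agrees: same statistic, permutation p near 1/3
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(abouheif_proximity(tr)[names(x), names(x)], a4)
  ab <- abouheif(tr, x, n_perm = 4999, seed = 1)
  expect_equal(ab$c_stat, 1 / 3, tolerance = 1e-12)
  expect_equal(ab$p, 1 / 3, tolerance = 0.02)
})

test_that("Abouheif p is invariant to relabeling and affine trait transforms", {
  plan <- synth_plan(seed = 5, tree_params = list(n_taxa = 12,
                                                  signal = "none",
                                                  brownian_sd = 1))
  tt <- gen_tree_with_trait(plan)
  ab <- abouheif(tt$tree, tt$trait, n_perm = 199, seed = 3)
  # permuting tips and trait identically leaves C unchanged
  ord <- sample(length(tt$trait))
  tr2 <- tt$tree
  tr2$tip.label <- tt$tree$tip.label  # same tree, trait given shuffled
  ab2 <- abouheif(tr2, tt$trait[ord], n_perm = 199, seed = 3)
  expect_equal(ab2$c_stat, ab$c_stat, tolerance = 1e-12)
  # affine transform of the trait
  ab3 <- abouheif(tt$tree, 3 * tt$trait - 7, n_perm = 199, seed = 3)
  expect_equal(ab3$c_stat, ab$c_stat, tolerance = 1e-10)
  expect_equal(ab3$p, ab$p)
  expect_error(abouheif(tt$tree, rep(1, 12), n_perm = 199), "constant")
  expect_error(abouheif(tt$tree, tt$trait, n_perm = 50), "99")
})
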