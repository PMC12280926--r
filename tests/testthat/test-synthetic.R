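test_that("noiseless species tables are exactly linear in the coefficients", {
  for (seed in c(1, 7, 42)) {
    plan <- noiseless_plan(seed = seed)
    tab <- gen_species_table(plan)
    x <- as.matrix(tab[, hover_predictors()])
    expect_equal(tab$mo2net,
                 unname(plan$coeffs[1] + drop(x %*% plan$coeffs[-1])))
    expect_equal(tab$mo2net, tab$mo2net_true)
    expect_equal(tab$ratio, tab$ratio_true)
  }
})

test_that("generators are deterministic under a fixed plan", {
  plan <- synth_plan(seed = 5, noise_sd = 50)
  expect_identical(gen_species_table(plan), gen_species_table(plan))
  tr1 <- gen_o2_trace(200, 0.01, 0.615, plan = plan)
  tr2 <- gen_o2_trace(200, 0.01, 0.615, plan = plan)
  expect_identical(tr1, tr2)
  expect_identical(gen_landmark_series(plan)$points,
                   gen_landmark_series(plan)$points)
  tt1 <- gen_tree_with_trait(plan)
  tt2 <- gen_tree_with_trait(plan)
  expect_identical(ape::write.tree(tt1$tree), ape::write.tree(tt2$tree))
  expect_identical(tt1$trait, tt2$trait)
})

test_that("coefficient recovery error shrinks with sample size", {
  rmse_at_n <- function(n) {
    errs <- vapply(1:60, function(k) {
      plan <- synth_plan(seed = k, n_species = n, noise_sd = 170,
                         ratio_noise_sd = 0)
      tab <- gen_species_table(plan)
      fit <- hover_lm(mo2_formula("mo2net"), tab)
      sqrt(mean((coef(fit) - plan$coeffs)^2))
    }, numeric(1))
    mean(errs)
  }
  rmse <- vapply(c(20, 80, 320), rmse_at_n, numeric(1))
  expect_true(all(diff(rmse) < 0))
})

test_that("degenerate designs and bad coefficient vectors are caught", {
  rng <- default_predictor_ranges()
  rng["comcob_ap", ] <- c(0.02, 0.02)
  rng["caud_fin_ap", ] <- c(0.9, 0.9)
  expect_warning(
    gen_species_table(synth_plan(seed = 1, predictor_ranges = rng)),
    "collinear")
  plan <- synth_plan(seed = 1)
  plan$coeffs <- plan$coeffs[1:5]
  expect_error(gen_species_table(plan), "length")
})

test_that("oxygen traces invert the metabolic-rate formula", {
  plan <- synth_plan(seed = 1,
                     trace_params = list(duration_min = 60,
                                         interval_min = 1,
                                         o2_noise_sd = 0, o2_init = 8))
  tr <- gen_o2_trace(113.57, mass = 0.01, chamber_vol = 0.61,
                     fish_vol = 0.01, plan = plan)
  expect_equal(attr(tr, "true_slope"), 0.05, tolerance = 1e-4)
  tr2 <- gen_o2_trace(200, mass = 0.005, chamber_vol = 0.6, fish_vol = 0,
                      plan = plan)
  expect_equal(attr(tr2, "true_slope"),
               200 / (0.6 * 0.005^-0.9 * 60), tolerance = 1e-12)
  expect_equal(attr(tr2, "true_slope"), 0.0472, tolerance = 1e-3)
  # noiseless round trip is exact
  expect_equal(as.numeric(mo2_from_trace(tr2)), 200, tolerance = 1e-9)
  # unphysical traces refuse to generate
  expect_error(gen_o2_trace(5000, mass = 0.02, chamber_vol = 0.615,
                            plan = plan), "unphysical")
})

test_that("landmark series carry the commanded motion", {
  plan <- synth_plan(seed = 2)
  s <- gen_landmark_series(plan)
  expect_equal(dim(s$points)[2], 15)
  rp <- roll_pitch(s)
  expect_equal(rp$roll_max_excursion, 4, tolerance = 0.05)
  expect_equal(rp$pitch_max_excursion, 2, tolerance = 0.05)
  ab <- abduction_signals(s)
  expect_equal(phase_lag(ab$left, ab$right, s$fps)$phase_deg, 180,
               tolerance = 0.1)
  # roll-only motion shows no pitch
  mp <- modifyList(plan$motion_params,
                   list(roll_amp_deg = 4, pitch_amp_deg = 0))
  s2 <- gen_landmark_series(synth_plan(seed = 2, motion_params = mp))
  rp2 <- roll_pitch(s2)
  expect_equal(rp2$roll_max_excursion, 4, tolerance = 0.05)
  expect_lt(rp2$pitch_max_excursion, 1e-6)
  # circular stroke: distance 2*pi*r*f/bl = pi for r = 0.5, f = 3, bl = 3
  mp3 <- modifyList(plan$motion_params,
                    list(roll_amp_deg = 0, pitch_amp_deg = 0))
  s3 <- gen_landmark_series(synth_plan(seed = 2, motion_params = mp3))
  fd <- fin_distance(s3$points[, "pect_tip_l", ], s3$fps, s3$bl)
  expect_equal(fd, pi, tolerance = 0.005 * pi)
  expect_error(
    gen_landmark_series(synth_plan(
      seed = 1, motion_params = modifyList(plan$motion_params,
                                           list(roll_amp_deg = 95)))),
    "gimbal")
})

test_that("random trees have the right shape and traits respond to signal", {
  plan4 <- synth_plan(seed = 3, tree_params = list(n_taxa = 4,
                                                   signal = "none",
                                                   brownian_sd = 1))
  tt <- gen_tree_with_trait(plan4)
  expect_equal(length(tt$tree$tip.label), 4)
  expect_equal(tt$tree$Nnode, 3)  # fully bifurcating rooted tree
  expect_error(gen_tree_with_trait(
    synth_plan(seed = 1, tree_params = list(n_taxa = 3, signal = "none",
                                            brownian_sd = 1))),
    "n_taxa")
  # Brownian traits carry phylogenetic signal, i.i.d. traits do not:
  # paired replicates on the same topologies
  p_null <- vapply(1:30, function(k) {
    tt <- gen_tree_with_trait(synth_plan(
      seed = k, tree_params = list(n_taxa = 20, signal = "none",
                                   brownian_sd = 1)))
    abouheif(tt$tree, tt$trait, n_perm = 199, seed = k)$p
  }, numeric(1))
  p_bm <- vapply(1:30, function(k) {
    tt <- gen_tree_with_trait(synth_plan(
      seed = k, tree_params = list(n_taxa = 20, signal = "brownian",
                                   brownian_sd = 2)))
    abouheif(tt$tree, tt$trait, n_perm = 199, seed = k)$p
  }, numeric(1))
  expect_lt(median(p_bm), median(p_null))
})

test_that("landmark TSV round-trips through write and read", {
  plan <- synth_plan(seed = 9)
  s <- gen_landmark_series(plan)
  f <- tempfile(fileext = ".tsv")
  write_landmarks(s, f)
  s2 <- read_landmarks(f)
  expect_equal(s2$fps, s$fps)
  expect_equal(s2$bl, s$bl)
  expect_equal(s2$points, s$points, tolerance = 1e-6)
})
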