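test_that("zero-noise landing datasets reproduce the regression curves", {
  d <- gen_landing_dataset(c(20, 40, 60), n_per_height = 2,
                           noise_sd_fraction = 0, seed = 11)
  models <- default_landing_models()
  for (v in names(models)) {
    expect_equal(d[[v]], evaluate_regression(models[[v]], d$height),
                 tolerance = 1e-12)
  }
  # hand-evaluated spot values of the printed coefficient pairs
  expect_equal(d$knee_flex_angle[d$height == 20][1],
               14.769 * log(20) - 15.237, tolerance = 1e-12)
  expect_equal(d$vgrf[d$height == 60][1], 0.4468 * 60^0.542,
               tolerance = 1e-12)
})

test_that("landing generator is a pure function of its seed", {
  a <- gen_landing_dataset(c(30, 50), 5, 0.15, seed = 42)
  b <- gen_landing_dataset(c(30, 50), 5, 0.15, seed = 42)
  c2 <- gen_landing_dataset(c(30, 50), 5, 0.15, seed = 43)
  expect_identical(a, b)
  expect_false(identical(a, c2))
  expect_true(all(is.finite(as.matrix(a))))
  expect_true(all(a$height > 0) && all(a$vgrf > 0))
})

test_that("landing generator rejects invalid heights", {
  expect_error(gen_landing_dataset(-5, 1, 0, 1), "positive")
  expect_error(gen_landing_dataset(500, 1, 0, 1), "\\[10, 200\\]")
})

test_that("toy musculoskeleton fixtures are feasible by construction", {
  msk <- gen_toy_musculoskeleton(3, 34, seed = 5, with_ground_truth = TRUE)
  expect_length(msk$muscle_names, 34)
  expect_true(all(msk$pcsa > 0))
  expect_true(all(msk$x_passive <= msk$x_max))
  # optimizer-independent feasibility: R x* = M exactly
  expect_equal(as.vector(msk$lever_arms %*% msk$ground_truth_forces),
               msk$targets, tolerance = 1e-12)
  # every DoF actuated in both directions
  expect_true(all(apply(msk$lever_arms, 1, function(r) any(r > 0))))
  expect_true(all(apply(msk$lever_arms, 1, function(r) any(r < 0))))
  # single muscle / single DoF: unique feasible force is M / r
  m1 <- gen_toy_musculoskeleton(1, 1, seed = 2, with_ground_truth = TRUE)
  expect_equal(m1$ground_truth_forces,
               m1$targets / m1$lever_arms[1, 1], tolerance = 1e-12)
})

test_that("synthetic fibril curves follow the softened law exactly at zero noise", {
  cv <- gen_synthetic_fibril_curve(10, 4000, 50, 8, noise_sd = 0,
                                   n_points = 25, seed = 1)
  e <- cv$strain
  W <- 10 * e^2 / 2 + 4000 * e^3 / 3
  expect_equal(cv$stress, (10 * e + 4000 * e^2) * exp(-(W / 50)^8),
               tolerance = 1e-12)
  # enormous limiter -> intact law
  cvi <- gen_synthetic_fibril_curve(10, 4000, 1e9, 8, 0, 25, 1)
  expect_equal(cvi$stress, 10 * cvi$strain + 4000 * cvi$strain^2,
               tolerance = 1e-9)
  # reproducible serialisation
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_stress_strain_csv(gen_synthetic_fibril_curve(seed = 9), f1)
  write_stress_strain_csv(gen_synthetic_fibril_curve(seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("toy articular geometry honours its invariants", {
  g <- gen_toy_articular_geometry(grid_n = 4, thickness_mm = 2)
  expect_equal(nrow(g$nodes), 2 * 16)
  expect_setequal(unique(g$nodes$compartment), c("medial", "lateral"))
  expect_true(all(g$nodes$thickness_mm == 2))
  expect_true(all(g$nodes$gap_mm >= 0))
  g0 <- gen_toy_articular_geometry(grid_n = 6, uncovered_fraction = 0)
  expect_true(all(g0$nodes$region == "covered"))
  gu <- gen_toy_articular_geometry(grid_n = 20, uncovered_fraction = 0.39)
  frac <- mean(gu$nodes$region == "uncovered")
  expect_lt(abs(frac - 0.39), 0.05)
})
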