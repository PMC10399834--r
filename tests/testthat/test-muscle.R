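test_that("single-muscle problems solve in closed form", {
  p1 <- optimization_problem(matrix(0.05, 1, 1), 10, 10, 0, 500)
  s <- solve_muscle_forces(p1)
  expect_equal(s$forces, 200, tolerance = 1e-9)
  expect_true(s$converged)
  expect_lt(s$kkt_residual, 1e-6)
})

test_that("identical muscles share the load equally", {
  p2 <- optimization_problem(matrix(c(0.05, 0.05), 1), 10, c(10, 10),
                             c(0, 0), c(500, 500))
  s <- solve_muscle_forces(p2)
  expect_equal(s$forces[1], s$forces[2], tolerance = 1e-8)
  expect_equal(sum(0.05 * s$forces), 10, tolerance = 1e-8)
})

test_that("asymmetric splits match a dense grid-search oracle", {
  p3 <- optimization_problem(matrix(c(0.05, 0.05), 1), 10, c(20, 10),
                             c(0, 0), c(2000, 2000))
  s <- solve_muscle_forces(p3)
  x1 <- seq(0, 200, length.out = 100001)
  x2 <- (10 - 0.05 * x1) / 0.05
  ok <- x2 >= 0 & x2 <= 2000
  obj <- (x1 / 20)^3 + (x2 / 10)^3
  expect_lt(abs(s$objective - min(obj[ok])) / min(obj[ok]), 0.005)
})

test_that("solutions satisfy KKT and dominate random feasible points", {
  set.seed(12)
  for (sd in c(3, 8)) {
    msk <- gen_toy_musculoskeleton(3, 12, seed = sd, with_ground_truth = TRUE)
    prob <- as_optimization_problem(msk)
    s <- solve_muscle_forces(prob)
    expect_lt(s$kkt_residual, 1e-6)
    expect_lt(s$equality_residual, 1)
    # random feasible points: perturb the known interior solution within
    # the null space of R, clip to bounds, keep the ones still feasible
    R <- prob$lever_arms
    N <- diag(ncol(R)) - t(R) %*% solve(tcrossprod(R), R)
    n_checked <- 0
    for (k in 1:1000) {
      x <- msk$ground_truth_forces +
        as.vector(N %*% rnorm(ncol(R), 0, 50))
      if (any(x < prob$x_passive | x > prob$x_max)) next
      n_checked <- n_checked + 1
      expect_gte(sum((x / prob$pcsa)^3), s$objective - 1e-6)
    }
    expect_gt(n_checked, 100)
  }
})

test_that("scaling every PCSA leaves the optimal forces unchanged", {
  msk <- gen_toy_musculoskeleton(2, 10, seed = 4, with_ground_truth = TRUE)
  prob <- as_optimization_problem(msk)
  s1 <- solve_muscle_forces(prob)
  prob2 <- prob
  prob2$pcsa <- 3 * prob$pcsa
  s2 <- solve_muscle_forces(prob2)
  expect_equal(s1$forces, s2$forces, tolerance = 1e-6)
})

test_that("infeasible moment targets are rejected with a certificate", {
  p_inf <- optimization_problem(matrix(0.05, 1, 1), 1000, 10, 0, 500)
  expect_error(solve_muscle_forces(p_inf), "infeasible")
})

test_that("genetic and NLP solvers agree on the toy 34-muscle fixture", {
  msk <- gen_toy_musculoskeleton(3, 34, seed = 7, with_ground_truth = TRUE)
  prob <- as_optimization_problem(msk)
  sn <- solve_muscle_forces(prob, method = "nlp")
  sg <- solve_muscle_forces(prob, method = "genetic", seed = 2)
  expect_lt(abs(sg$objective - sn$objective) / sn$objective, 0.01)
  expect_lt(sg$equality_residual, 1)
  # and on a small problem
  p3 <- optimization_problem(matrix(c(0.05, 0.04), 1), 8, c(15, 10),
                             c(0, 0), c(900, 900))
  sn3 <- solve_muscle_forces(p3, method = "nlp")
  sg3 <- solve_muscle_forces(p3, method = "genetic", seed = 5)
  expect_lt(abs(sg3$objective - sn3$objective) / sn3$objective, 0.01)
})

test_that("coupling loop converges as the passive surrogate demands", {
  msk <- gen_toy_musculoskeleton(3, 20, seed = 6, with_ground_truth = TRUE)
  prob <- as_optimization_problem(msk)
  # zero passive resistance: fixed point after one solve
  j0 <- surrogate_joint(prob)
  c0 <- iterative_coupling(j0, tol = 1)
  expect_equal(c0$iterations, 1)
  expect_true(c0$converged)
  # linear passive stiffness: residual decreases and ends below 1 N.m
  P <- matrix(5e-4, 3, 20)
  jl <- surrogate_joint(prob, passive_gain = P)
  cl <- iterative_coupling(jl, tol = 1)
  expect_true(cl$converged)
  expect_lt(cl$trace[length(cl$trace)], 1)
  if (length(cl$trace) > 1) expect_true(all(diff(cl$trace) < 0))
  # infinite tolerance: a single solve is returned
  ci <- iterative_coupling(jl, tol = Inf)
  expect_equal(ci$iterations, 1)
})
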