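p <- ligament_params()

test_that("pre-strain tensor follows the configured convention", {
  expect_equal(prestrain_gradient(1), diag(3))
  F0 <- prestrain_gradient(1.05)
  expect_equal(F0[3, 3], 1.05)
  expect_equal(det(F0), 1, tolerance = 1e-12)
  Fr <- prestrain_gradient(1.05, "reciprocal")
  expect_equal(diag(Fr), c(1 / 1.05, 1 / 1.05, 1.05))
})

test_that("kinematic invariants at identity and under uniaxial stretch", {
  iv <- kinematic_invariants(diag(3))
  expect_equal(iv$I1e_bar, 3)
  expect_equal(iv$I4e_bar, 1)
  expect_equal(iv$I1ef_bar, 3) # 1 + 2 * 1 = 3
  lam <- 1.08
  F <- diag(c(lam^(-1 / 2), lam^(-1 / 2), lam))
  iv2 <- kinematic_invariants(F)
  expect_equal(iv2$I4e_bar, lam^2, tolerance = 1e-12)
  expect_error(kinematic_invariants(diag(3), Fp = matrix(0, 3, 3)),
               "singular")
})

test_that("fibril energy is zero at reference and increasing in stretch", {
  expect_equal(lig_fibril_energy(3, 1, p), 0)
  i4 <- seq(1.001, 1.2, length.out = 30)
  en <- vapply(i4, function(x) lig_fibril_energy(x + 2 / sqrt(x), x, p),
               numeric(1))
  expect_true(all(diff(en) > 0))
})

test_that("mixture degeneracies reduce the tissue energy correctly", {
  expect_equal(lig_tissue_energy(diag(3), p = p), 0)
  # no fibrous phase at either level: pure matrix response
  pm <- ligament_params(v_f = 1e-12, v_fb = 1e-12, kappa_t = 0, kappa_f = 0)
  F <- diag(c(0.99, 0.98, 1.05))
  iv <- kinematic_invariants(F)
  matrix_only <- pm$v_m * pm$mu_m / 2 * (iv$I1_bar - 3) +
    pm$Ek / 2 * (iv$J - 1)^2
  # remaining fibre-level matrix term
  fibre_matrix <- pm$v_f * pm$v_mb * pm$mu_fm / 2 * (iv$I1e_bar - 3)
  expect_equal(lig_tissue_energy(F, p = pm), matrix_only + fibre_matrix,
               tolerance = 1e-9)
  # term-by-term assembly at one tensile state with the default mixture
  F2 <- diag(c(0.985, 0.985, 1.06))
  iv2 <- kinematic_invariants(F2)
  psi_fb <- lig_fibril_energy(iv2$I1ef_bar, iv2$I4e_bar, p)
  psi_fi <- p$v_fb * psi_fb + p$v_mb * p$mu_fm / 2 * (iv2$I1e_bar - 3) +
    p$kappa_f * p$mu_fm / 2 * (iv2$I1e_bar - iv2$I1ef_bar)
  psi_t <- p$v_f * psi_fi + p$v_m * p$mu_m / 2 * (iv2$I1_bar - 3) +
    p$kappa_t * p$mu_m / 2 * (iv2$I1_bar - iv2$I1e_bar) +
    p$Ek / 2 * (iv2$J - 1)^2
  expect_equal(lig_tissue_energy(F2, p = p), psi_t, tolerance = 1e-12)
})

test_that("ligament stress is the derivative of the energy at tensile states", {
  set.seed(17)
  n_ok <- 0
  for (k in 1:100) {
    lam <- runif(1, 1.01, 1.08)
    F <- random_F(diag(c(lam^(-1 / 2), lam^(-1 / 2), lam)), 0.004)
    iv <- kinematic_invariants(F)
    if (iv$I4_bar < 1.005) next # stay clear of the tension switch
    fd <- fd_cauchy_stress(function(FF) lig_tissue_energy(FF, p = p), F)
    expect_lt(rel_stress_err(lig_total_stress(F, p = p), fd), 1e-5)
    n_ok <- n_ok + 1
  }
  expect_gt(n_ok, 60)
})

test_that("tension switch removes all fibrillar stress in fibre compression", {
  pm <- ligament_params()
  pnofib <- ligament_params(v_fb = 1e-12, kappa_f = 0)
  set.seed(5)
  for (k in 1:20) {
    lam <- runif(1, 0.9, 0.999)
    F <- diag(c(runif(1, 0.98, 1.05), runif(1, 0.98, 1.05), lam))
    iv <- kinematic_invariants(F)
    if (iv$I4_bar > 1) next
    s_full <- lig_total_stress(F, p = pm)
    # with the switch active, the energy has no fibril terms: stresses of
    # the full model and a fibril-free model differ only via kappa_f I1ef
    # bookkeeping, which the switch also freezes
    d <- landingmech:::.lig_denergy(iv, pm)
    expect_equal(d$d_I4, 0)
    expect_equal(d$d_I4e, 0)
    expect_true(is.finite(max(abs(s_full))))
  }
})

test_that("identity and pre-strain behave consistently", {
  expect_equal(lig_total_stress(diag(3), p = p), matrix(0, 3, 3),
               tolerance = 1e-12)
  # pre-strain at F = identity produces tensile fibre stress
  s <- lig_total_stress(diag(3), p = p, pre = 1.05)
  expect_gt(s[3, 3], 0)
  # pre-strain composition: response to F with alpha0 equals response to
  # F F0 with no pre-strain
  F <- diag(c(0.99, 1.0, 1.03))
  F0 <- prestrain_gradient(1.04)
  expect_equal(lig_total_stress(F, p = p, pre = 1.04),
               lig_total_stress(F %*% F0, p = p), tolerance = 1e-12)
})

test_that("near-incompressibility holds under the default penalty", {
  for (lam in seq(1.01, 1.10, 0.03)) {
    ax <- 3
    f <- function(lt) {
      s <- lig_total_stress(diag(c(lt, lt, lam)), p = p)
      s[1, 1]
    }
    lt <- uniroot(f, c(0.8 * lam^(-0.5), 1.2), tol = 1e-12)$root
    J <- lt^2 * lam
    expect_gt(J, 0.99)
    expect_lt(J, 1.01)
  }
})

test_that("plastic return mapping honours KKT and leaves elastic steps alone", {
  yield <- stress_strain_curve(c(0, 0.05, 0.2), c(12, 20, 60))
  st0 <- plastic_state()
  # elastic: trial below yield
  st1 <- lig_plastic_update(st0, 1.01, yield, p)
  expect_equal(st1$lambda_p, 1)
  expect_false(st1$yielding)
  expect_equal(attr(st1, "slip_increment"), 0)
  # loading past yield: slip grows, consistency satisfied
  st2 <- lig_plastic_update(st0, 1.12, yield, p, tol = 1e-8)
  expect_true(st2$yielding)
  expect_gt(attr(st2, "slip_increment"), 0)
  expect_lt(abs(attr(st2, "f_residual")), 1e-7)
  expect_equal(det(st2$Fp), 1, tolerance = 1e-12)
  # KKT: slip >= 0, f <= tol, complementarity
  expect_gte(attr(st2, "slip_increment"), 0)
  expect_lte(attr(st2, "f_residual"), 1e-7)
  # unloading to zero stress leaves residual (plastic) stretch
  expect_gt(st2$lambda_p, 1)
  s_unloaded <- lig_total_stress(diag(3), st2, p)
  # with Fp != I the reference state is now stressed in compression along
  # the fibre (elastic part is compressed): the permanent set is real
  expect_gt(st2$accumulated_slip, 0)
  expect_true(is.finite(max(abs(s_unloaded))))
})

test_that("load-unload cycles dissipate energy through plastic flow", {
  yield <- stress_strain_curve(c(0, 0.05, 0.2), c(12, 18, 45))
  lams <- c(seq(1, 1.15, length.out = 25), seq(1.15, 1, length.out = 25))
  st <- plastic_state()
  stress <- numeric(length(lams))
  for (i in seq_along(lams)) {
    st <- lig_plastic_update(st, lams[i], yield, p)
    lam_e <- lams[i] / st$lambda_p
    stress[i] <- landingmech:::.lig_axial_fibril_stress(lam_e, p)
  }
  # dissipation: closed-cycle work integral (trapezoid in log strain) >= 0
  eps <- log(lams)
  W <- sum(diff(eps) * (stress[-1] + stress[-length(stress)]) / 2)
  expect_gte(W, 0)
  expect_gt(st$lambda_p, 1) # permanent set after the cycle
  # slip never decreased
  expect_gte(st$accumulated_slip, 0)
})

test_that("aggregate calibration recovers generating parameters", {
  p_true <- ligament_params(mu_fm = 1.4)
  lam <- seq(1.005, 1.09, length.out = 12)
  target <- stress_strain_curve(lam - 1, lig_uniaxial_stress(lam, p = p_true))
  p_start <- ligament_params(mu_fm = 0.8)
  fit <- calibrate_aggregate(target, p_start, free = "mu_fm")
  expect_lt(abs(fit$params$mu_fm - 1.4) / 1.4, 0.01)
  expect_lt(fit$residual, 1e-4 * max(target$stress))
  # empty free subset returns the inputs unchanged
  same <- calibrate_aggregate(target, p_start, free = character(0))
  expect_identical(same$params, p_start)
  # the best objective seen never increases across the returned trace
  expect_true(all(diff(cummin(fit$trace)) <= 0))
})

test_that("calibration warns when the free subset is unidentifiable", {
  # under uniaxial stretch the two matrix moduli act through a single
  # effective combination (the shear-interaction invariant difference
  # vanishes), so fitting both from a uniaxial target is ill-posed
  p_true <- ligament_params(mu_m = 0.6, mu_fm = 1.4)
  lam <- seq(1.01, 1.08, length.out = 8)
  target <- stress_strain_curve(lam - 1, lig_uniaxial_stress(lam, p = p_true))
  p_start <- ligament_params(mu_m = 0.3, mu_fm = 0.8)
  expect_warning(
    fit <- calibrate_aggregate(target, p_start, free = c("mu_m", "mu_fm")),
    "unidentifiable")
  # the identifiable combination v_m mu_m + v_f v_mb mu_fm is recovered
  comb <- function(q) q$v_m * q$mu_m + q$v_f * q$v_mb * q$mu_fm
  expect_lt(abs(comb(fit$params) - comb(p_true)) / comb(p_true), 0.01)
})
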