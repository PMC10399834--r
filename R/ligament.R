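#' Ligament / tendon material parameters
#'
#' Hierarchical fibre-and-fibril hyper-elastoplastic soft-tissue model:
#' collagen fibrils reinforce fibres, fibres reinforce the tissue, each
#' level mixing the reinforcement with a neo-Hookean matrix and an
#' effective shear-interaction term, plus a volumetric penalty.
#'
#' The fibril strain energy is
#' \code{psi_fb = 1/2 mu_o tanh(a1 (I4e - 1)) + a2 exp(a3 (I4e - I_o)) (I1ef - 3)}
#' with \code{I1ef = I4 + 2 I4^(-1/2)}. None of the fibril or matrix
#' constants are universal; the shipped defaults are package fixtures that
#' produce a toe-then-linear tensile response, and every value can be
#' overridden or calibrated (see \code{\link{calibrate_aggregate}}).
#'
#' @param mu_o fibril shear modulus, MPa.
#' @param I_o secondary-stiffening onset (value of \code{I4e}).
#' @param a1,a2,a3 dimensionless fibril coefficients (\code{a2} in MPa).
#' @param mu_m,mu_fm tissue- and fibre-level matrix shear moduli, MPa.
#' @param v_f,v_m fibre / tissue-matrix volume fractions (sum to 1).
#' @param v_fb,v_mb fibril / fibre-matrix volume fractions (sum to 1).
#' @param kappa_t,kappa_f effective shear-interaction coefficients at the
#'   tissue and fibre level (single-coefficient reduction of the two-phase
#'   shear coupling).
#' @param Ek volumetric penalty modulus, MPa.
#' @param n0 initial fibril direction (unit 3-vector).
#' @return object of class \code{ligament_params}.
#' @export
ligament_params <- function(mu_o = 12, I_o = 1.10, a1 = 1.5, a2 = 1.2,
                            a3 = 20, mu_m = 0.4, mu_fm = 1.0,
                            v_f = 0.8, v_m = 1 - v_f,
                            v_fb = 0.7, v_mb = 1 - v_fb,
                            kappa_t = 0.5, kappa_f = 0.5,
                            Ek = 2000, n0 = c(0, 0, 1)) {
  stopifnot(mu_o > 0, mu_m > 0, mu_fm > 0, Ek > 0,
            abs(v_f + v_m - 1) < 1e-12, abs(v_fb + v_mb - 1) < 1e-12,
            abs(sum(n0^2) - 1) < 1e-8)
  structure(list(mu_o = mu_o, I_o = I_o, a1 = a1, a2 = a2, a3 = a3,
                 mu_m = mu_m, mu_fm = mu_fm, v_f = v_f, v_m = v_m,
                 v_fb = v_fb, v_mb = v_mb, kappa_t = kappa_t,
                 kappa_f = kappa_f, Ek = Ek, n0 = n0),
            class = "ligament_params")
}

#' Pre-strain deformation gradient
#'
#' Ligament in-situ tension as an initial stretch \code{alpha0} along the
#' fibre axis. The default convention is isochoric,
#' \code{diag(a0, a0^-1/2, a0^-1/2)}; the variant
#' \code{diag(a0, a0^-1, a0^-1)} is selectable but not volume preserving.
#' Composes with the motion as \code{F_total = F \%*\% F0}.
#'
#' @param alpha0 initial stretch (> 0).
#' @param convention \code{"isochoric"} or \code{"reciprocal"}.
#' @param n0 fibre axis (the tensor is built in the frame where \code{n0}
#'   is the third axis; only axis-aligned \code{n0} of the form
#'   c(0,0,1)/c(1,0,0)/c(0,1,0) are supported here).
#' @return 3 x 3 diagonal tensor.
#' @export
prestrain_gradient <- function(alpha0, convention = c("isochoric", "reciprocal"),
                               n0 = c(0, 0, 1)) {
  stopifnot(alpha0 > 0)
  convention <- match.arg(convention)
  tv <- if (convention == "isochoric") alpha0^(-1 / 2) else alpha0^(-1)
  ax <- which(abs(n0) > 0.999)
  if (length(ax) != 1) stop("n0 must be axis aligned for prestrain_gradient")
  d <- rep(tv, 3)
  d[ax] <- alpha0
  diag(d)
}

#' Plastic state of the fibril slip system
#'
#' One fibre-aligned mechanism: \code{Fp} is an isochoric stretch
#' \code{lambda_p} along \code{n0}; \code{accumulated_slip} is the
#' logarithmic plastic stretch, non-decreasing.
#'
#' @param lambda_p plastic stretch along the fibre (>= 1 under tension).
#' @param accumulated_slip accumulated slip (log plastic stretch).
#' @param n0 fibre axis.
#' @return object of class \code{plastic_state} with \code{Fp}
#'   (det = 1), \code{lambda_p}, \code{accumulated_slip}, \code{yielding}.
#' @export
plastic_state <- function(lambda_p = 1, accumulated_slip = log(lambda_p),
                          n0 = c(0, 0, 1)) {
  stopifnot(lambda_p > 0)
  N <- tcrossprod(n0)
  Fp <- lambda_p * N + lambda_p^(-1 / 2) * (diag(3) - N)
  structure(list(Fp = Fp, lambda_p = lambda_p,
                 accumulated_slip = accumulated_slip,
                 yielding = FALSE, n0 = n0),
            class = "plastic_state")
}

#' Kinematic invariants of the ligament model
#'
#' Elastic split \code{Fe = F Fp^-1}; isochoric elastic Cauchy-Green
#' \code{Cbar_e = J^(-2/3) Fe' Fe}. Returns \code{I1e_bar = tr(Cbar_e)},
#' \code{I4e_bar = n0 . Cbar_e n0} and
#' \code{I1ef_bar = I4_bar + 2 I4_bar^(-1/2)} (a function of the total
#' fibre invariant), together with the total invariants used by the energy.
#'
#' @param F deformation gradient.
#' @param Fp plastic deformation gradient (det = 1).
#' @param n0 fibre axis, unit 3-vector.
#' @return list with I1_bar, I4_bar, I1e_bar, I4e_bar, I1ef_bar, J.
#' @export
kinematic_invariants <- function(F, Fp = diag(3), n0 = c(0, 0, 1)) {
  J <- det(F)
  if (J <= 0) stop("det(F) must be positive")
  dp <- det(Fp)
  if (abs(dp) < 1e-12) stop("singular Fp")
  Fe <- F %*% solve(Fp)
  I1 <- J^(-2 / 3) * sum(F^2)
  a <- as.vector(F %*% n0)
  I4 <- J^(-2 / 3) * sum(a^2)
  I1e <- J^(-2 / 3) * sum(Fe^2)
  ae <- as.vector(Fe %*% n0)
  I4e <- J^(-2 / 3) * sum(ae^2)
  list(I1_bar = I1, I4_bar = I4, I1e_bar = I1e, I4e_bar = I4e,
       I1ef_bar = I4 + 2 / sqrt(I4), J = J)
}

#' Fibril strain energy
#'
#' \code{1/2 mu_o tanh(a1 (I4e - 1)) + a2 exp(a3 (I4e - I_o)) (I1ef - 3)};
#' zero at the reference state (\code{I4e = 1}, \code{I1ef = 3}). The
#' tension switch (no fibril contribution for \code{I4 <= 1}) is applied by
#' the callers.
#'
#' @param I1ef_bar fibre pseudo-invariant \code{I4 + 2 I4^(-1/2)}.
#' @param I4e_bar elastic fibre invariant (> 0).
#' @param p a \code{\link{ligament_params}}.
#' @return energy density, MPa.
#' @export
lig_fibril_energy <- function(I1ef_bar, I4e_bar, p = ligament_params()) {
  stopifnot(I4e_bar > 0)
  0.5 * p$mu_o * tanh(p$a1 * (I4e_bar - 1)) +
    p$a2 * exp(p$a3 * (I4e_bar - p$I_o)) * (I1ef_bar - 3)
}

#' Total tissue strain energy density
#'
#' Two-level rule of mixtures. Fibre level:
#' \code{psi_fi = v_fb psi_fb + v_mb mu_fm/2 (I1e - 3)
#'   + kappa_f mu_fm/2 (I1e - I1ef)}.
#' Tissue level:
#' \code{psi_t = v_f psi_fi + v_m mu_m/2 (I1 - 3)
#'   + kappa_t mu_m/2 (I1 - I1e) + Ek/2 (J - 1)^2}.
#' Fibril terms are dropped when \code{I4_bar <= 1} (tension switch).
#'
#' @param F deformation gradient.
#' @param state a \code{\link{plastic_state}} (or NULL for virgin material).
#' @param p a \code{\link{ligament_params}}.
#' @param pre optional pre-strain stretch \code{alpha0}; the energy is
#'   evaluated at \code{F \%*\% F0}.
#' @param prestrain_convention see \code{\link{prestrain_gradient}}.
#' @return energy density, MPa.
#' @export
lig_tissue_energy <- function(F, state = NULL, p = ligament_params(),
                              pre = 1, prestrain_convention = "isochoric") {
  if (pre != 1)
    F <- F %*% prestrain_gradient(pre, prestrain_convention, p$n0)
  Fp <- if (is.null(state)) diag(3) else state$Fp
  iv <- kinematic_invariants(F, Fp, p$n0)
  tension <- iv$I4_bar > 1
  psi_fb <- if (tension)
    lig_fibril_energy(iv$I1ef_bar, iv$I4e_bar, p) else 0
  I1ef <- if (tension) iv$I1ef_bar else 3
  psi_fi <- p$v_fb * psi_fb + p$v_mb * p$mu_fm / 2 * (iv$I1e_bar - 3) +
    p$kappa_f * p$mu_fm / 2 * (iv$I1e_bar - I1ef)
  p$v_f * psi_fi + p$v_m * p$mu_m / 2 * (iv$I1_bar - 3) +
    p$kappa_t * p$mu_m / 2 * (iv$I1_bar - iv$I1e_bar) +
    p$Ek / 2 * (iv$J - 1)^2
}

# partial derivatives of the tissue energy w.r.t. its invariants
.lig_denergy <- function(iv, p) {
  tension <- iv$I4_bar > 1
  d_I1 <- p$v_m * p$mu_m / 2 + p$kappa_t * p$mu_m / 2
  d_I1e <- p$v_f * (p$v_mb * p$mu_fm / 2 + p$kappa_f * p$mu_fm / 2) -
    p$kappa_t * p$mu_m / 2
  if (tension) {
    dfb_dI4e <- 0.5 * p$mu_o * p$a1 / cosh(p$a1 * (iv$I4e_bar - 1))^2 +
      p$a2 * p$a3 * exp(p$a3 * (iv$I4e_bar - p$I_o)) * (iv$I1ef_bar - 3)
    dfb_dI1ef <- p$a2 * exp(p$a3 * (iv$I4e_bar - p$I_o))
    d_I1ef <- p$v_f * (p$v_fb * dfb_dI1ef - p$kappa_f * p$mu_fm / 2)
    d_I4 <- d_I1ef * (1 - iv$I4_bar^(-3 / 2)) # chain rule I1ef(I4)
    d_I4e <- p$v_f * p$v_fb * dfb_dI4e
  } else {
    d_I4 <- 0
    d_I4e <- 0
  }
  list(d_I1 = d_I1, d_I1e = d_I1e, d_I4 = d_I4, d_I4e = d_I4e)
}

#' Total Cauchy stress of the ligament model
#'
#' Analytic push-forward of the invariant derivatives of
#' \code{\link{lig_tissue_energy}}: deviatoric contributions from
#' \code{I1_bar}, \code{I1e_bar}, \code{I4_bar} (through \code{I1ef_bar})
#' and \code{I4e_bar}, plus the volumetric term \code{Ek (J - 1) I}. The
#' fibrillar part vanishes when \code{I4_bar <= 1}.
#'
#' @inheritParams lig_tissue_energy
#' @return 3 x 3 Cauchy stress, MPa.
#' @export
lig_total_stress <- function(F, state = NULL, p = ligament_params(),
                             pre = 1, prestrain_convention = "isochoric") {
  if (pre != 1)
    F <- F %*% prestrain_gradient(pre, prestrain_convention, p$n0)
  Fp <- if (is.null(state)) diag(3) else state$Fp
  iv <- kinematic_invariants(F, Fp, p$n0)
  d <- .lig_denergy(iv, p)
  J <- iv$J
  dev3 <- function(A) A - diag(3) * sum(diag(A)) / 3
  Fe <- F %*% solve(Fp)
  Bbar <- J^(-2 / 3) * tcrossprod(F)
  Bebar <- J^(-2 / 3) * tcrossprod(Fe)
  a <- J^(-1 / 3) * as.vector(F %*% p$n0)
  ae <- J^(-1 / 3) * as.vector(Fe %*% p$n0)
  sig <- (2 / J) * (d$d_I1 * dev3(Bbar) + d$d_I1e * dev3(Bebar) +
                      d$d_I4 * dev3(tcrossprod(a)) +
                      d$d_I4e * dev3(tcrossprod(ae))) +
    p$Ek * (J - 1) * diag(3)
  (sig + t(sig)) / 2
}

# axial fibrillar Cauchy stress under isochoric uniaxial elastic stretch
# lambda_e along n0 (used as the resolved stress of the slip system)
.lig_axial_fibril_stress <- function(lambda_e, p) {
  if (lambda_e <= 1) return(0)
  F <- prestrain_gradient(lambda_e, "isochoric", p$n0)
  iv <- kinematic_invariants(F, diag(3), p$n0)
  d <- .lig_denergy(iv, p)
  a2 <- iv$I4_bar
  # axial deviatoric component of the fibril dyad terms: dev(a x a) has
  # axial entry 2/3 I4; the difference axial-lateral is I4
  2 * ((d$d_I4 * a2 + d$d_I4e * a2)) * (2 / 3) -
    2 * ((d$d_I4 * a2 + d$d_I4e * a2)) * (-1 / 3)
}

#' Plastic return mapping along the fibril slip system
#'
#' Single-mechanism crystal-plasticity update under the
#' Karush-Kuhn-Tucker loading/unloading conditions. The resolved (axial)
#' fibril stress of the elastic trial state is compared with the current
#' yield stress read from an MD-derived stress-strain curve (linearly
#' interpolated in accumulated slip). If the trial stress exceeds the
#' yield stress, plastic stretch grows until consistency
#' \code{|f| <= tol}; slip never decreases and \code{det(Fp) = 1}.
#'
#' @param state a \code{\link{plastic_state}}.
#' @param lambda total (elastic trial producing) fibre stretch imposed on
#'   the tissue, so the trial elastic stretch is
#'   \code{lambda / state$lambda_p}.
#' @param yield_curve a \code{\link{stress_strain_curve}} giving yield
#'   stress (MPa) versus accumulated slip; typically a scaled fibril MD
#'   curve.
#' @param p a \code{\link{ligament_params}}.
#' @param tol consistency tolerance, MPa.
#' @param max_iter iteration cap for the consistency solve.
#' @return updated \code{plastic_state}; attributes \code{f_residual} and
#'   \code{slip_increment} expose the KKT quantities.
#' @export
lig_plastic_update <- function(state, lambda, yield_curve, p = ligament_params(),
                               tol = 1e-8, max_iter = 100) {
  yfun <- function(slip) {
    stats::approx(yield_curve$strain, yield_curve$stress, xout = slip,
                  rule = 2)$y
  }
  lam_e_trial <- lambda / state$lambda_p
  s_trial <- .lig_axial_fibril_stress(lam_e_trial, p)
  f_trial <- s_trial - yfun(state$accumulated_slip)
  if (f_trial <= tol) {
    state$yielding <- FALSE
    attr(state, "f_residual") <- f_trial
    attr(state, "slip_increment") <- 0
    return(state)
  }
  g <- function(dg) {
    .lig_axial_fibril_stress(lam_e_trial * exp(-dg), p) -
      yfun(state$accumulated_slip + dg)
  }
  # the elastic stress is only defined down to the recruitment level
  # sigma(1+): the tanh term of the fibril energy carries a finite stress
  # offset at the tension switch, so a consistent return requires the
  # yield curve to cross above that level
  upper <- log(max(lam_e_trial, 1 + 1e-12)) * (1 - 1e-12)
  if (g(upper) > 0)
    stop(paste("yield curve saturates below the fibril recruitment",
               "stress: no consistent plastic return exists"))
  sol <- stats::uniroot(g, c(0, upper), tol = tol / max(1, abs(s_trial)),
                        maxiter = max_iter)
  dg <- sol$root
  res <- g(dg)
  if (abs(res) > tol * 10)
    stop(sprintf("plastic return mapping did not converge: residual %.3e", res))
  new <- plastic_state(state$lambda_p * exp(dg),
                       state$accumulated_slip + dg, p$n0)
  new$yielding <- TRUE
  attr(new, "f_residual") <- res
  attr(new, "slip_increment") <- dg
  new
}

#' Uniaxial stress response of the ligament model
#'
#' Axial Cauchy stress under stretch \code{lambda} along the fibre with
#' traction-free lateral faces (lateral stretch solved so the lateral
#' stress vanishes).
#'
#' @param lambda axial stretch (vector accepted).
#' @param state optional \code{\link{plastic_state}}.
#' @param p a \code{\link{ligament_params}}.
#' @param pre pre-strain stretch \code{alpha0}.
#' @return axial Cauchy stress, MPa (vector).
#' @export
lig_uniaxial_stress <- function(lambda, state = NULL, p = ligament_params(),
                                pre = 1) {
  ax <- which(abs(p$n0) > 0.999)
  vapply(lambda, function(l) {
    f <- function(lt) {
      d <- rep(lt, 3)
      d[ax] <- l
      s <- lig_total_stress(diag(d), state, p, pre)
      lat <- setdiff(1:3, ax)[1]
      s[lat, lat]
    }
    lt <- stats::uniroot(f, c(0.5 * l^(-1 / 2), 2 * max(1, l^(-1 / 2))),
                         tol = 1e-10, extendInt = "yes")$root
    d <- rep(lt, 3)
    d[ax] <- l
    lig_total_stress(diag(d), state, p, pre)[ax, ax]
  }, numeric(1))
}

#' Calibrate aggregate ligament parameters to a target curve
#'
#' Least-squares fit of the uniaxial model response over a free parameter
#' subset, holding the MD-informed fibril parameters fixed. The optimiser
#' trace (residual per iteration) is returned; a warning with a condition
#' diagnostic is issued when the subset is unidentifiable (flat residual).
#'
#' @param target_curve a \code{\link{stress_strain_curve}} of axial stress
#'   versus stretch-minus-one (engineering strain) covering toe and linear
#'   regions.
#' @param p_init starting \code{\link{ligament_params}}.
#' @param free character vector of parameter names to fit (subset of
#'   mu_m, mu_fm, mu_o, a1, a2, a3).
#' @param lower,upper optional named bounds.
#' @return list with \code{params} (fitted \code{ligament_params}),
#'   \code{residual} (RMS, MPa) and \code{trace} (objective per evaluation).
#' @export
calibrate_aggregate <- function(target_curve, p_init = ligament_params(),
                                free = c("mu_m", "mu_fm"),
                                lower = NULL, upper = NULL) {
  if (length(free) == 0)
    return(list(params = p_init, residual = NA_real_, trace = numeric(0)))
  lam <- 1 + target_curve$strain
  y <- target_curve$stress
  trace <- numeric(0)
  # mean-squared objective (smooth at the optimum); the reported residual
  # is its square root (RMS)
  obj <- function(th) {
    pp <- p_init
    pp[free] <- as.list(exp(th))
    val <- tryCatch(
      mean((lig_uniaxial_stress(lam, p = pp) - y)^2),
      error = function(e) 1e12)
    trace <<- c(trace, sqrt(val))
    val
  }
  th0 <- log(unlist(p_init[free]))
  fit <- if (length(free) == 1) {
    stats::optim(th0, obj, method = "Brent", lower = th0 - log(1e3),
                 upper = th0 + log(1e3))
  } else {
    stats::optim(th0, obj, method = "Nelder-Mead",
                 control = list(maxit = 800, reltol = 1e-12))
  }
  if (length(free) > 1) {
    # identifiability: smallest-eigenvalue curvature of the objective at
    # the optimum; a flat ridge means a combination of the free parameters
    # is not constrained by the target protocol
    h <- 1e-3
    np <- length(fit$par)
    H <- matrix(0, np, np)
    f0 <- obj(fit$par)
    for (i in seq_len(np)) {
      for (j in i:np) {
        ei <- ej <- rep(0, np)
        ei[i] <- h
        ej[j] <- h
        H[i, j] <- H[j, i] <-
          (obj(fit$par + ei + ej) - obj(fit$par + ei - ej) -
             obj(fit$par - ei + ej) + obj(fit$par - ei - ej)) / (4 * h^2)
      }
    }
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-6 * max(abs(ev), 1e-12))
      warning(sprintf(
        "flat residual ridge over {%s}: condition %.2e; subset may be unidentifiable",
        paste(free, collapse = ", "),
        max(abs(ev)) / max(abs(min(ev)), 1e-300)))
  }
  pf <- unclass(p_init)
  pf[free] <- as.list(exp(fit$par))
  pf <- do.call(ligament_params, pf)
  list(params = pf, residual = sqrt(fit$value), trace = trace)
}
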