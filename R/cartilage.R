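#' Articular cartilage material parameters
#'
#' Fibril-reinforced incompressible hyperelastic cartilage with
#' depth-dependent composition and energy-limiter softening of the collagen
#' fibrils. Defaults are the fitted/literature values shipped with the
#' model: collagen coefficients \code{E0} and \code{Ee} (initial and
#' strain-dependent), energy limiter \code{phi} with sharpness \code{m},
#' non-fibrillar shear modulus \code{Gm} and incompressibility penalty
#' \code{D}. The depth profiles are fixed polynomials of the normalised
#' depth z (0 at the cartilage-bone junction, 1 at the articular surface):
#' total collagen fraction \code{v_t(z) = 1.4 z^2 - 1.1 z + 0.59} and
#' elastic parameter \code{eta0s(z) = 0.1 z + 0.1}; each primary fibril
#' bundle carries \code{3/13 v_t}, each secondary bundle \code{1/13 v_t}.
#'
#' @param E0 initial collagen coefficient, MPa.
#' @param Ee strain-dependent collagen coefficient, MPa.
#' @param phi energy limiter (energy-density units of \code{W_fl}).
#' @param m dimensionless sharpness of the softening transition.
#' @param Gm non-fibrillar shear modulus, MPa.
#' @param D incompressibility penalty parameter.
#' @param damage_threshold indicator level above which a material point is
#'   flagged damaged.
#' @return object of class \code{cartilage_params}.
#' @export
cartilage_params <- function(E0 = 8.121, Ee = 5326.32, phi = 82.326,
                             m = 12, Gm = 0.723, D = 1e-4,
                             damage_threshold = 0.05) {
  stopifnot(E0 > 0, Ee > 0, phi > 0, m >= 1, Gm > 0, D > 0)
  structure(list(E0 = E0, Ee = Ee, phi = phi, m = m, Gm = Gm, D = D,
                 damage_threshold = damage_threshold),
            class = "cartilage_params")
}

#' Depth-dependent composition profiles
#'
#' @param z normalised depth in [0, 1] (0 = bone junction, 1 = surface).
#' @return list with \code{vt}, \code{eta0s}, \code{vf_primary},
#'   \code{vf_secondary} (per-bundle fibril volume fractions).
#' @export
depth_profiles <- function(z) {
  if (any(z < 0 | z > 1)) stop("z must lie in [0, 1]")
  vt <- 1.4 * z^2 - 1.1 * z + 0.59
  eta0s <- 0.1 * z + 0.1
  list(vt = vt, eta0s = eta0s,
       vf_primary = vt * 3 / 13, vf_secondary = vt * 1 / 13)
}

#' Fibril bundle directions at a depth
#'
#' Two primary bundles rotate with depth from perpendicular to the bone
#' junction (z = 0) to parallel to the articular surface (z = 1), splayed
#' symmetrically in the x-z plane; seven secondary bundles form a fixed
#' quasi-uniform set. Per-bundle volume fractions are \code{3/13 v_t}
#' (primary) and \code{1/13 v_t} (secondary), so the nine bundles sum to
#' \code{v_t}.
#'
#' @param z normalised depth in [0, 1].
#' @return list with \code{directions} (9 x 3, unit rows), \code{kind},
#'   \code{vf} (per-bundle volume fraction).
#' @export
fibril_bundles <- function(z) {
  if (z < 0 || z > 1) stop("z must lie in [0, 1]")
  prof <- depth_profiles(z)
  ang <- (pi / 2) * (1 - z) # from surface plane: pi/2 at bone, 0 at surface
  p1 <- c(cos(ang), 0, sin(ang))
  p2 <- c(-cos(ang), 0, sin(ang))
  sec <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               c(1, 1, 1), c(-1, 1, 1), c(1, -1, 1), c(1, 1, -1))
  sec <- sec / sqrt(rowSums(sec^2))
  dirs <- rbind(p1, p2, sec)
  rownames(dirs) <- NULL
  list(directions = dirs,
       kind = c("primary", "primary", rep("secondary", 7)),
       vf = c(rep(prof$vf_primary, 2), rep(prof$vf_secondary, 7)))
}

#' Intact fibril stress
#'
#' Tension-only fibril Cauchy stress
#' \code{(eta0s(z)/J) (E0 ef + Ee ef^2) (n x n)} where \code{ef} is the
#' logarithmic fibril strain; zero in compression.
#'
#' @param eps_f logarithmic fibril strain.
#' @param z normalised depth.
#' @param dirn current fibril direction (unit 3-vector).
#' @param J volume ratio.
#' @param p a \code{\link{cartilage_params}}.
#' @return 3 x 3 stress tensor, MPa.
#' @export
cart_fibril_stress <- function(eps_f, z, dirn, J = 1, p = cartilage_params()) {
  stopifnot(abs(sum(dirn^2) - 1) < 1e-8)
  if (eps_f <= 0) return(matrix(0, 3, 3))
  eta <- depth_profiles(z)$eta0s
  (eta / J) * (p$E0 * eps_f + p$Ee * eps_f^2) * tcrossprod(dirn)
}

#' Intact fibril strain energy density
#'
#' Closed-form integral of the axial fibril law at J = 1:
#' \code{W_fl = eta0s(z) (E0 ef^2/2 + Ee ef^3/3)}.
#'
#' @inheritParams cart_fibril_stress
#' @return energy density (same units as stress).
#' @export
cart_fibril_energy <- function(eps_f, z, p = cartilage_params()) {
  stopifnot(all(eps_f >= 0))
  depth_profiles(z)$eta0s * (p$E0 * eps_f^2 / 2 + p$Ee * eps_f^3 / 3)
}

#' Energy-limiter attenuation factor
#'
#' @param W_fl intact fibril energy density.
#' @param p a \code{\link{cartilage_params}}.
#' @return \code{exp(-(W_fl/phi)^m)}.
#' @export
softening_factor <- function(W_fl, p = cartilage_params()) {
  exp(-(W_fl / p$phi)^p$m)
}

#' Softened fibril stress
#'
#' Intact fibril stress attenuated by the energy limiter,
#' \code{sigma_f exp(-(W_fl/phi)^m)}; zero in compression.
#'
#' @inheritParams cart_fibril_stress
#' @return 3 x 3 stress tensor, MPa.
#' @export
cart_softened_stress <- function(eps_f, z, dirn, J = 1, p = cartilage_params()) {
  if (eps_f <= 0) return(matrix(0, 3, 3))
  W <- cart_fibril_energy(eps_f, z, p)
  cart_fibril_stress(eps_f, z, dirn, J, p) * softening_factor(W, p)
}

#' Softened (limited) strain energy
#'
#' \code{psi = (phi/m) [Gamma(1/m, 0) - Gamma(1/m, (W_fl/phi)^m)]} with
#' \code{Gamma} the upper incomplete gamma function; monotone in
#' \code{W_fl}, saturating at \code{(phi/m) Gamma(1/m)}.
#'
#' @param W_fl intact fibril energy density (>= 0).
#' @param p a \code{\link{cartilage_params}}.
#' @return limited energy density.
#' @export
cart_softened_energy <- function(W_fl, p = cartilage_params()) {
  stopifnot(all(W_fl >= 0))
  s <- 1 / p$m
  u <- (W_fl / p$phi)^p$m
  (p$phi / p$m) * (gamma(s) - vapply(u, function(ui)
    if (ui == 0) gamma(s) else pracma::incgam(ui, s), numeric(1)))
}

#' Non-fibrillar (matrix) stress
#'
#' Compressible neo-Hookean ground matrix scaled by the depth profile:
#' declared energy
#' \code{W_nf = eta0s(z) Gm/2 (Ibar1 - 3) + (1/D)(J - 1)^2}, whose Cauchy
#' stress is \code{eta0s Gm/J dev(Bbar) + (2/D)(J - 1) I}.
#'
#' @param F deformation gradient (3 x 3) with \code{det(F) > 0}.
#' @param z normalised depth.
#' @param p a \code{\link{cartilage_params}}.
#' @return 3 x 3 Cauchy stress, MPa.
#' @export
cart_nonfibrillar_stress <- function(F, z, p = cartilage_params()) {
  J <- det(F)
  if (J <= 0) stop("J must be positive")
  eta <- depth_profiles(z)$eta0s
  Bbar <- J^(-2 / 3) * tcrossprod(F)
  devB <- Bbar - diag(3) * sum(diag(Bbar)) / 3
  eta * p$Gm / J * devB + (2 / p$D) * (J - 1) * diag(3)
}

#' Non-fibrillar strain energy density
#'
#' @inheritParams cart_nonfibrillar_stress
#' @return energy density consistent with
#'   \code{\link{cart_nonfibrillar_stress}}.
#' @export
cart_nonfibrillar_energy <- function(F, z, p = cartilage_params()) {
  J <- det(F)
  if (J <= 0) stop("J must be positive")
  eta <- depth_profiles(z)$eta0s
  I1bar <- J^(-2 / 3) * sum(F^2)
  eta * p$Gm / 2 * (I1bar - 3) + (1 / p$D) * (J - 1)^2
}

#' Total cartilage Cauchy stress
#'
#' \code{sigma_c = sum_bundles v_f sigma_fl + (1 - v_t) sigma_nf}: softened
#' tension-only fibril stresses over all bundles plus the matrix share.
#'
#' @param F deformation gradient (3 x 3).
#' @param z normalised depth.
#' @param p a \code{\link{cartilage_params}}.
#' @param bundles optional \code{\link{fibril_bundles}} result for depth z.
#' @return 3 x 3 Cauchy stress, MPa.
#' @export
cart_total_stress <- function(F, z, p = cartilage_params(),
                              bundles = fibril_bundles(z)) {
  J <- det(F)
  prof <- depth_profiles(z)
  sig <- (1 - prof$vt) * cart_nonfibrillar_stress(F, z, p)
  for (b in seq_along(bundles$vf)) {
    n0 <- bundles$directions[b, ]
    a <- as.vector(F %*% n0)
    lam <- sqrt(sum(a^2))
    eps_f <- log(lam)
    if (eps_f > 0) {
      # per-bundle stress uses eta0s through the axial law; the bundle
      # volume fraction multiplies it per the mixture rule
      sig <- sig + bundles$vf[b] *
        cart_softened_stress(eps_f, z, a / lam, J, p)
    }
  }
  sig
}

#' Fit fibril coefficients to an MD stress-strain curve
#'
#' Least-squares fit of the intact axial fibril law
#' \code{sigma = E0 e + Ee e^2} to \code{scale} times the pre-peak portion
#' of a fibril tensile curve. The default \code{scale = 0.7} encodes the
#' 30 percent stiffness reduction of collagen II relative to the collagen I
#' fibrils the tensile test simulates. The fit is linear in the
#' coefficients, so scaling the stresses scales the recovered coefficients.
#'
#' @param curve a \code{\link{stress_strain_curve}}.
#' @param scale stress scale factor in (0, 1], default 0.7.
#' @return list with \code{E0}, \code{Ee} (MPa), \code{residual} (RMS, MPa)
#'   and the number of points used.
#' @export
fit_fibril_params_to_md <- function(curve, scale = 0.7) {
  stopifnot(scale > 0, scale <= 1)
  ipeak <- which.max(curve$stress)
  keep <- seq_len(ipeak)
  keep <- keep[curve$strain[keep] > 0]
  if (length(keep) < 3) stop("fewer than 3 pre-peak points")
  e <- curve$strain[keep]
  s <- scale * curve$stress[keep]
  X <- cbind(e, e^2)
  coefs <- qr.solve(X, s)
  list(E0 = coefs[[1]], Ee = coefs[[2]],
       residual = sqrt(mean((X %*% coefs - s)^2)), n_used = length(keep))
}

#' Damage indicator from a fibril strain history
#'
#' The energy-limiter attenuation reached at the historical peak:
#' \code{1 - exp(-(max W_fl / phi)^m)}. A point is flagged damaged when the
#' indicator exceeds \code{p$damage_threshold}.
#'
#' @param eps_f_history vector (one bundle) or matrix (bundles in columns)
#'   of logarithmic fibril strains over the loading history.
#' @param z normalised depth.
#' @param p a \code{\link{cartilage_params}}.
#' @return per-bundle indicator in [0, 1).
#' @export
damage_indicator <- function(eps_f_history, z, p = cartilage_params()) {
  h <- as.matrix(eps_f_history)
  if (nrow(h) == 0) stop("empty strain history")
  apply(h, 2, function(col) {
    emax <- max(c(0, col))
    1 - softening_factor(cart_fibril_energy(emax, z, p), p)
  })
}

#' Total cartilage strain energy density
#'
#' Reference-volume energy whose derivative reproduces
#' \code{\link{cart_total_stress}}: limited fibril energies over the bundles
#' (tension only) plus the non-fibrillar share.
#'
#' @inheritParams cart_total_stress
#' @return energy density.
#' @export
cart_total_energy <- function(F, z, p = cartilage_params(),
                              bundles = fibril_bundles(z)) {
  prof <- depth_profiles(z)
  W <- (1 - prof$vt) * cart_nonfibrillar_energy(F, z, p)
  for (b in seq_along(bundles$vf)) {
    lam <- sqrt(sum((F %*% bundles$directions[b, ])^2))
    eps_f <- log(lam)
    if (eps_f > 0) {
      W <- W + bundles$vf[b] *
        cart_softened_energy(cart_fibril_energy(eps_f, z, p), p)
    }
  }
  W
}
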