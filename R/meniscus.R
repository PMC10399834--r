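#' Meniscus material parameters (transverse isotropy)
#'
#' Linear-elastic transversely isotropic meniscus in local
#' circumferential / transverse / axial axes; the circumferential direction
#' is the stiff fibre direction. Defaults are the shipped aggregate values
#' (circumferential modulus 120 MPa, transverse/axial modulus 20 MPa,
#' Poisson ratios 0.3 and 0.2, shear modulus 47 MPa). The single shear
#' modulus fills all three shear slots of the compliance.
#'
#' @param Ec circumferential modulus, MPa.
#' @param Et transverse (= axial) modulus, MPa.
#' @param nu_ct Poisson ratio: transverse contraction per circumferential
#'   tension (= nu_ca).
#' @param nu_ta Poisson ratio within the transverse-axial plane.
#' @param G shear modulus, MPa.
#' @param local_axes 3 x 3 orthonormal matrix with columns = local axes
#'   (third column circumferential).
#' @return object of class \code{meniscus_params}.
#' @export
meniscus_params <- function(Ec = 120, Et = 20, nu_ct = 0.3, nu_ta = 0.2,
                            G = 47, local_axes = diag(3)) {
  stopifnot(Ec > 0, Et > 0, G > 0,
            max(abs(crossprod(local_axes) - diag(3))) < 1e-8)
  structure(list(Ec = Ec, Et = Et, Ea = Et, nu_ct = nu_ct, nu_ca = nu_ct,
                 nu_ta = nu_ta, G = G, local_axes = local_axes),
            class = "meniscus_params")
}

#' Meniscus compliance matrix
#'
#' 6 x 6 compliance in Voigt order (11, 22, 33, 12, 13, 23) with
#' engineering shear strains; axes 1, 2 transverse/axial, axis 3
#' circumferential. In-plane coupling uses \code{nu_ta/Et}; the
#' circumferential coupling uses \code{nu_ct/Ec}, which elastic reciprocity
#' (\code{nu_ct/Ec = nu_tc/Et}) makes symmetric. The shear block is
#' diagonal \code{1/G}.
#'
#' @param p a \code{\link{meniscus_params}}.
#' @return symmetric positive-definite 6 x 6 matrix (1/MPa).
#' @export
compliance_matrix <- function(p = meniscus_params()) {
  S <- matrix(0, 6, 6)
  S[1, 1] <- S[2, 2] <- 1 / p$Et
  S[3, 3] <- 1 / p$Ec
  S[1, 2] <- S[2, 1] <- -p$nu_ta / p$Et
  S[1, 3] <- S[3, 1] <- S[2, 3] <- S[3, 2] <- -p$nu_ct / p$Ec
  S[4, 4] <- S[5, 5] <- S[6, 6] <- 1 / p$G
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    # name the violating leading principal minor for the error message
    k <- which(vapply(1:6, function(i) det(S[1:i, 1:i, drop = FALSE]) <= 0,
                      logical(1)))[1]
    stop(sprintf("compliance not positive definite (leading minor %d)", k))
  }
  S
}

#' Strain from stress (meniscus)
#'
#' Applies the compliance to a stress 6-vector given in the local material
#' axes; with \code{global = TRUE} the input is a 3 x 3 stress tensor in
#' global axes, rotated through \code{local_axes} and returned as a local
#' strain 6-vector.
#'
#' @param sigma stress: 6-vector (local Voigt) or 3 x 3 tensor
#'   (if \code{global}).
#' @param p a \code{\link{meniscus_params}}.
#' @param global interpret \code{sigma} as a global-frame tensor.
#' @return strain 6-vector (engineering shear), local axes.
#' @export
stress_to_strain <- function(sigma, p = meniscus_params(), global = FALSE) {
  if (global) {
    stopifnot(is.matrix(sigma), all(dim(sigma) == c(3, 3)))
    Q <- p$local_axes
    sl <- t(Q) %*% sigma %*% Q
    sigma <- c(sl[1, 1], sl[2, 2], sl[3, 3], sl[1, 2], sl[1, 3], sl[2, 3])
  }
  stopifnot(length(sigma) == 6)
  as.vector(compliance_matrix(p) %*% sigma)
}
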