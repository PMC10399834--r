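#' Generate a literature-style drop-landing dataset
#'
#' Draws landing records around the shipped height-regression curves:
#' sagittal variables are the regression means times multiplicative
#' Gaussian noise (the spread of pooled literature data is roughly
#' symmetric about the mean), coupled-plane variables are height-independent
#' means plus additive Gaussian noise. With
#' \code{noise_sd_fraction = 0} the sagittal columns reproduce the
#' regression curves exactly.
#'
#' @param heights landing heights, cm, each within [10, 200].
#' @param n_per_height records per height (>= 1).
#' @param noise_sd_fraction multiplicative noise standard deviation as a
#'   fraction of the mean (sagittal variables).
#' @param seed RNG seed; the generator is a pure function of it.
#' @param coupled_means coupled-plane means,
#'   see \code{\link{default_coupled_means}}.
#' @param coupled_noise_sd additive noise SD for coupled-plane variables,
#'   as a fraction of each mean's magnitude.
#' @return data.frame, one row per record: \code{height}, the seven
#'   sagittal columns and \code{coupled_*} columns.
#' @export
gen_landing_dataset <- function(heights, n_per_height = 1,
                                noise_sd_fraction = 0.1, seed = 1L,
                                coupled_means = default_coupled_means(),
                                coupled_noise_sd = 0.1) {
  if (any(heights <= 0)) stop("heights must be positive")
  if (any(heights < 10 | heights > 200))
    stop("heights must lie within [10, 200] cm")
  stopifnot(n_per_height >= 1)
  set.seed(seed)
  models <- default_landing_models()
  h <- rep(heights, each = n_per_height)
  n <- length(h)
  out <- data.frame(height = h)
  for (v in names(models)) {
    mu <- evaluate_regression(models[[v]], h)
    out[[v]] <- mu * (1 + stats::rnorm(n, 0, noise_sd_fraction))
  }
  for (v in names(coupled_means)) {
    out[[paste0("coupled_", v)]] <- coupled_means[[v]] +
      stats::rnorm(n, 0, coupled_noise_sd * abs(coupled_means[[v]]))
  }
  stopifnot(all(is.finite(as.matrix(out))))
  out
}

#' Names of the 34 lower-extremity muscle actuators
#'
#' Actuator list of the toy musculoskeletal fixture (quadriceps,
#' hamstrings, gastrocnemius and the remaining hip/ankle muscles split
#' into their commonly used compartments).
#'
#' @return character vector of length 34.
#' @export
default_muscle_names <- function() {
  c("vastus_intermedius", "vastus_medialis", "vastus_lateralis",
    "rectus_femoris", "semimembranosus", "semitendinosus",
    "biceps_femoris_long", "biceps_femoris_short",
    "gastrocnemius_medialis", "gastrocnemius_lateralis",
    "soleus_medial", "soleus_lateral", "tibialis_anterior",
    "tibialis_posterior", "peroneus_longus", "peroneus_brevis",
    "flexor_digitorum_longus", "extensor_digitorum_longus",
    "gluteus_maximus_sup", "gluteus_maximus_mid", "gluteus_maximus_inf",
    "gluteus_medius_ant", "gluteus_medius_post",
    "gluteus_minimus_ant", "gluteus_minimus_post",
    "iliacus", "psoas_major", "sartorius", "gracilis",
    "adductor_longus", "adductor_magnus", "adductor_brevis",
    "tensor_fasciae_latae", "piriformis")
}

#' Generate a toy musculoskeletal optimisation fixture
#'
#' Random feasible static-optimisation problem: lever-arm matrix R
#' (DoF x muscles), physiological cross-sectional areas, and passive /
#' maximum force bounds. When \code{with_ground_truth} the target moments
#' are constructed as \code{M = R x*} for a known interior \code{x*}, so
#' feasibility is guaranteed independent of any solver.
#'
#' @param n_dof number of degrees of freedom (>= 1).
#' @param n_muscles number of muscles (>= n_dof); default the 34-actuator
#'   fixture.
#' @param seed RNG seed.
#' @param with_ground_truth construct target moments from a known interior
#'   solution.
#' @param max_stress active muscle strength per unit PCSA, N/cm^2.
#' @return object of class \code{toy_musculoskeleton}: \code{muscle_names},
#'   \code{pcsa} (cm^2), \code{lever_arms} (DoF x muscles, m),
#'   \code{x_passive}, \code{x_max} (N), \code{targets} (N.m) and
#'   optionally \code{ground_truth_forces}.
#' @export
gen_toy_musculoskeleton <- function(n_dof = 3, n_muscles = 34, seed = 1L,
                                    with_ground_truth = FALSE,
                                    max_stress = 61) {
  stopifnot(n_dof >= 1, n_muscles >= n_dof)
  set.seed(seed)
  names <- if (n_muscles == 34) default_muscle_names() else
    paste0("muscle_", seq_len(n_muscles))
  pcsa <- stats::runif(n_muscles, 4, 40)
  # each muscle spans 1-2 DoF with moment arms of a few cm, signs mixed;
  # every DoF guaranteed at least one actuator on each side
  R <- matrix(0, n_dof, n_muscles)
  for (j in seq_len(n_muscles)) {
    k <- sample(n_dof, sample(1:min(2, n_dof), 1))
    R[k, j] <- stats::runif(length(k), 0.02, 0.06) *
      sample(c(-1, 1), length(k), replace = TRUE)
  }
  for (i in seq_len(n_dof)) {
    if (all(R[i, ] <= 0)) R[i, sample(n_muscles, 1)] <- stats::runif(1, 0.02, 0.06)
    if (all(R[i, ] >= 0)) R[i, sample(n_muscles, 1)] <- -stats::runif(1, 0.02, 0.06)
  }
  x_passive <- stats::runif(n_muscles, 0, 5)
  x_max <- x_passive + max_stress * pcsa
  if (any(x_passive > x_max)) stop("infeasible bounds requested")
  obj <- structure(list(muscle_names = names, pcsa = pcsa, lever_arms = R,
                        x_passive = x_passive, x_max = x_max,
                        ground_truth_forces = NULL, targets = NULL,
                        seed = seed),
                   class = "toy_musculoskeleton")
  if (with_ground_truth) {
    u <- stats::runif(n_muscles, 0.2, 0.8)
    xstar <- x_passive + u * (x_max - x_passive)
    obj$ground_truth_forces <- xstar
    obj$targets <- as.vector(R %*% xstar)
  }
  obj
}

#' Generate a synthetic fibril stress-strain curve
#'
#' Samples the softened axial fibril law
#' \code{sigma = (E0 e + Ee e^2) exp(-(W/phi)^m)} with
#' \code{W = E0 e^2/2 + Ee e^3/3}, plus additive Gaussian noise. Used as a
#' fit-recovery fixture for the cartilage coefficient fitting; with a very
#' large \code{phi_true} the curve follows the intact law.
#'
#' @param E0_true,Ee_true generating coefficients, MPa.
#' @param phi_true energy limiter of the generator.
#' @param m_true sharpness of the generator.
#' @param noise_sd additive stress noise SD, MPa.
#' @param n_points number of strain samples (>= 10).
#' @param seed RNG seed.
#' @param max_strain largest strain sampled.
#' @return a \code{\link{stress_strain_curve}}.
#' @export
gen_synthetic_fibril_curve <- function(E0_true = 8.121, Ee_true = 5326.32,
                                       phi_true = 82.326, m_true = 12,
                                       noise_sd = 0, n_points = 40,
                                       seed = 1L, max_strain = 0.2) {
  stopifnot(n_points >= 10)
  set.seed(seed)
  e <- seq(max_strain / n_points, max_strain, length.out = n_points)
  W <- E0_true * e^2 / 2 + Ee_true * e^3 / 3
  s <- (E0_true * e + Ee_true * e^2) * exp(-(W / phi_true)^m_true) +
    stats::rnorm(n_points, 0, noise_sd)
  stress_strain_curve(e, s, meta = list(E0_true = E0_true, Ee_true = Ee_true,
                                        phi_true = phi_true, m_true = m_true,
                                        noise_sd = noise_sd, seed = seed))
}

#' Generate toy articular geometry
#'
#' Two tibial-plateau-like compartments (medial, lateral), each a square
#' grid of surface nodes under a spherical femoral condyle: the initial
#' gap to the indenter is parabolic in the radial distance. Nodes beyond a
#' radius chosen to enclose \code{1 - uncovered_fraction} of the grid area
#' are labelled \code{uncovered} (meniscus-covered periphery); the rest are
#' \code{covered} (direct cartilage-cartilage contact). Cartilage thickness
#' is uniform; the normalised depth coordinate z runs from 0 at the bone
#' junction to 1 at the surface.
#'
#' @param grid_n nodes per side (>= 4).
#' @param thickness_mm cartilage thickness, mm.
#' @param condyle_radius_mm indenting condyle radius, mm.
#' @param seed RNG seed (reserved for optional jitter; the default
#'   geometry is deterministic).
#' @param uncovered_fraction area fraction labelled uncovered.
#' @param patch_halfwidth_mm half-width of each compartment patch, mm.
#' @return object of class \code{toy_articular_geometry}: \code{nodes}
#'   data.frame (compartment, x, y, gap_mm, thickness_mm, region,
#'   area_mm2) plus the generating parameters.
#' @export
gen_toy_articular_geometry <- function(grid_n = 25, thickness_mm = 2,
                                       condyle_radius_mm = 30, seed = 1L,
                                       uncovered_fraction = 0.39,
                                       patch_halfwidth_mm = 10) {
  stopifnot(grid_n >= 4, thickness_mm > 0, condyle_radius_mm > 0,
            uncovered_fraction >= 0, uncovered_fraction <= 1)
  xs <- seq(-patch_halfwidth_mm, patch_halfwidth_mm, length.out = grid_n)
  cell <- if (grid_n > 1) (xs[2] - xs[1])^2 else (2 * patch_halfwidth_mm)^2
  one <- expand.grid(x = xs, y = xs)
  r <- sqrt(one$x^2 + one$y^2)
  rcut <- stats::quantile(r, probs = 1 - uncovered_fraction, names = FALSE)
  region <- ifelse(r <= rcut, "covered", "uncovered")
  if (uncovered_fraction == 0) region[] <- "covered"
  gap <- r^2 / (2 * condyle_radius_mm)
  nodes <- rbind(
    data.frame(compartment = "medial", x = one$x, y = one$y, gap_mm = gap,
               thickness_mm = thickness_mm, region = region,
               area_mm2 = cell),
    data.frame(compartment = "lateral", x = one$x, y = one$y, gap_mm = gap,
               thickness_mm = thickness_mm, region = region,
               area_mm2 = cell))
  structure(list(nodes = nodes, grid_n = grid_n,
                 thickness_mm = thickness_mm,
                 condyle_radius_mm = condyle_radius_mm,
                 uncovered_fraction = uncovered_fraction,
                 patch_halfwidth_mm = patch_halfwidth_mm, seed = seed),
            class = "toy_articular_geometry")
}
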