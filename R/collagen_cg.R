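#' Coarse-grained collagen force field
#'
#' Bead-spring force field for mesoscopic collagen: a piecewise-harmonic
#' breakable bond potential (hyperelastic stiffening beyond \code{r1},
#' rupture at \code{rb}), a harmonic bending term, and 12-6 Lennard-Jones
#' interactions between non-bonded beads.
#'
#' Internal units are angstrom / kcal/mol / amu; the derived time unit is
#' \code{sqrt(amu A^2 / (kcal/mol))} (about 48.9 fs). Stresses are converted
#' to MPa with 1 kcal/mol/A^3 = 6947.7 MPa.
#'
#' The shipped numeric defaults follow the magnitudes used by mesoscopic
#' bead-spring collagen models in the literature; they are package defaults,
#' editable per call, and can be stored in a YAML parameter file (see
#' \code{\link{write_config}}).
#'
#' \code{c1} and \code{c2} are never free: they are computed from energy
#' continuity at \code{r1} and zero energy at \code{rb}. By default
#' \code{r1_bar} is placed so that the bond force is also continuous at
#' \code{r1} (it is described as the continuity point of the force field).
#'
#' @param eps_lj Lennard-Jones well depth (kcal/mol).
#' @param sigma_lj Lennard-Jones characteristic distance (A).
#' @param kT0,kT1 bond spring constants below/above \code{r1} (kcal/mol/A^2).
#' @param r0 bond rest length (A).
#' @param r1 onset of the stiffened (hyperelastic) bond regime (A).
#' @param r1_bar centre of the stiffened branch (A); default enforces force
#'   continuity at \code{r1}.
#' @param rb bond breaking distance (A); at \code{r >= rb} the bond is
#'   permanently broken.
#' @param k_theta bending strength (kcal/mol/rad^2).
#' @param theta0 equilibrium bead-triple angle (rad); straight chain = pi.
#' @param bead_mass bead mass (amu).
#' @param lj_cutoff Lennard-Jones cutoff (A).
#' @return An object of class \code{collagen_ff} (a named list).
#' @export
collagen_ff <- function(eps_lj = 10.6, sigma_lj = 14.72,
                        kT0 = 15.41, kT1 = 47.0,
                        r0 = 14.0, r1 = 18.2, r1_bar = NULL, rb = 21.0,
                        k_theta = 14.98, theta0 = pi,
                        bead_mass = 1358, lj_cutoff = 2.5 * sigma_lj) {
  stopifnot(r0 < r1, r1 < rb, eps_lj > 0, kT0 > 0, kT1 > 0, k_theta > 0)
  if (is.null(r1_bar)) r1_bar <- r1 - kT0 * (r1 - r0) / kT1
  # E(rb-) = 0 and energy continuity at r1 fix c2 then c1
  c2 <- -0.5 * kT1 * (rb - r1_bar)^2
  c1 <- 0.5 * kT1 * (r1 - r1_bar)^2 + c2 - 0.5 * kT0 * (r1 - r0)^2
  structure(list(eps_lj = eps_lj, sigma_lj = sigma_lj, kT0 = kT0, kT1 = kT1,
                 r0 = r0, r1 = r1, r1_bar = r1_bar, rb = rb, c1 = c1,
                 c2 = c2, k_theta = k_theta, theta0 = theta0,
                 bead_mass = bead_mass, lj_cutoff = lj_cutoff),
            class = "collagen_ff")
}

#' Bond energy and force of the breakable piecewise-harmonic potential
#'
#' @param r bond length(s), A.
#' @param p a \code{\link{collagen_ff}}.
#' @return list with \code{energy} (kcal/mol), \code{force} (-dE/dr,
#'   kcal/mol/A) and \code{broken} (TRUE where \code{r >= rb}).
#' @export
bond_energy_force <- function(r, p) {
  stopifnot(all(r > 0))
  e <- ifelse(r < p$r1, 0.5 * p$kT0 * (r - p$r0)^2 + p$c1,
              0.5 * p$kT1 * (r - p$r1_bar)^2 + p$c2)
  f <- ifelse(r < p$r1, -p$kT0 * (r - p$r0), -p$kT1 * (r - p$r1_bar))
  broken <- r >= p$rb
  e[broken] <- 0
  f[broken] <- 0
  list(energy = e, force = f, broken = broken)
}

#' Lennard-Jones energy and force (truncated and shifted)
#'
#' @inheritParams bond_energy_force
#' @return list with \code{energy} and \code{force} (-dE/dr). The energy is
#'   shifted so that it vanishes at the cutoff; beyond the cutoff both are 0.
#' @export
lj_energy_force <- function(r, p) {
  stopifnot(all(r > 0))
  sr6 <- (p$sigma_lj / r)^6
  shift <- local({ s6 <- (p$sigma_lj / p$lj_cutoff)^6; 4 * p$eps_lj * (s6^2 - s6) })
  e <- 4 * p$eps_lj * (sr6^2 - sr6) - shift
  f <- 4 * p$eps_lj * (12 * sr6^2 - 6 * sr6) / r
  out <- r >= p$lj_cutoff
  e[out] <- 0
  f[out] <- 0
  list(energy = e, force = f)
}

#' Harmonic bending energy
#'
#' @param theta angle(s) between consecutive bead triples, rad.
#' @param p a \code{\link{collagen_ff}}.
#' @return energy \code{k_theta * (theta - theta0)^2}, kcal/mol.
#' @export
angle_energy <- function(theta, p) {
  stopifnot(all(theta >= 0), all(theta <= pi + 1e-12))
  p$k_theta * (theta - p$theta0)^2
}

#' Build a straight bead-chain collagen molecule
#'
#' The tropocollagen molecule (about 300 nm long, 1.6 nm thick) is idealised
#' as a straight chain of beads along the z axis; the mesoscale response is
#' carried by the force field, not by atomistic coordinates.
#'
#' @param length_nm target contour length, nm (default the 300 nm molecule).
#' @param bead_spacing_nm equilibrium bead spacing, nm.
#' @return object of class \code{cg_molecule}: positions (A), bonds (pairs),
#'   angles (triples), spacing (A).
#' @export
build_molecule <- function(length_nm = 300, bead_spacing_nm = 1.4) {
  stopifnot(length_nm > bead_spacing_nm, bead_spacing_nm > 0)
  spacing <- bead_spacing_nm * 10 # A
  n <- round(length_nm / bead_spacing_nm) + 1L
  pos <- cbind(0, 0, (seq_len(n) - 1) * spacing)
  bonds <- cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  angles <- if (n >= 3L) cbind(seq_len(n - 2L), seq_len(n - 2L) + 1L,
                               seq_len(n - 2L) + 2L) else
    matrix(integer(0), ncol = 3)
  structure(list(positions = pos, bonds = bonds, angles = angles,
                 spacing = spacing, n_beads = n,
                 contour_length_nm = (n - 1L) * bead_spacing_nm),
            class = "cg_molecule")
}

# Hexagonal lattice sites within a clip radius (units of the pitch).
hex_sites <- function(clip_radius, pitch) {
  nmax <- ceiling(clip_radius / pitch) + 2L
  g <- expand.grid(i = -nmax:nmax, j = -nmax:nmax)
  x <- pitch * (g$i + 0.5 * g$j)
  y <- pitch * (sqrt(3) / 2) * g$j
  keep <- sqrt(x^2 + y^2) <= clip_radius + 1e-9
  cbind(x = x[keep], y = y[keep])
}

#' Build a crosslinked collagen fibril
#'
#' Molecules are packed on a quasi-hexagonal lattice clipped to the circular
#' fibril cross-section, with an axial stagger between neighbours; each group
#' of five molecules is recorded as a microfibril. Enzymatic crosslinks bond
#' molecule ends (telopeptide beads) to the nearest helical bead of an
#' adjacent molecule; the density parameter \code{beta} is the fraction of
#' molecule ends so connected (\code{beta = 1} gives 2 connected ends per
#' molecule).
#'
#' The default packing pitch (1.55 nm) is slightly tighter than the nominal
#' 1.6 nm molecule diameter; with molecule axes clipped to
#' \code{diameter/2 - molecule_diameter/2} this calibration makes the
#' 21.5 nm fibril hold exactly 151 molecules.
#'
#' @param diameter_nm fibril diameter, nm.
#' @param beta crosslink density, fraction of molecule ends in [0, 1].
#' @param stagger_nm axial stagger between consecutive stagger groups, nm
#'   (D-period-like offset).
#' @param seed RNG seed for sampling which ends are crosslinked.
#' @param length_nm,bead_spacing_nm molecule geometry,
#'   see \code{\link{build_molecule}}.
#' @param pitch_nm lattice pitch of the quasi-hexagonal packing, nm.
#' @param molecule_diameter_nm nominal molecule thickness, nm.
#' @return object of class \code{cg_fibril}: positions (A), molecule ids,
#'   bonds (with a type column: 1 backbone, 2 crosslink), angles,
#'   microfibril assignment and bookkeeping fields.
#' @export
build_fibril <- function(diameter_nm = 21.5, beta = 1, stagger_nm = 67,
                         seed = 1L, length_nm = 300, bead_spacing_nm = 1.4,
                         pitch_nm = 1.55, molecule_diameter_nm = 1.6) {
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  stopifnot(diameter_nm >= molecule_diameter_nm)
  clip <- (diameter_nm - molecule_diameter_nm) / 2
  sites <- hex_sites(clip * 10, pitch_nm * 10) # in A
  nmol <- nrow(sites)
  if (nmol < 1L) stop("fibril diameter too small to hold a molecule")
  mol <- build_molecule(length_nm, bead_spacing_nm)
  nb <- mol$n_beads

  # axial stagger: five offset classes, like the D-period staggering of
  # neighbouring molecules; class from lattice position
  ij <- round(cbind(sites[, 1] / (pitch_nm * 10) -
                      0.5 * sites[, 2] / (pitch_nm * 10 * sqrt(3) / 2),
                    sites[, 2] / (pitch_nm * 10 * sqrt(3) / 2)))
  cls <- ((ij[, 1] + 2 * ij[, 2]) %% 5 + 5) %% 5
  zoff <- cls * stagger_nm * 10 / 5

  pos <- matrix(0, nmol * nb, 3)
  molecule_id <- rep(seq_len(nmol), each = nb)
  for (m in seq_len(nmol)) {
    idx <- (m - 1L) * nb + seq_len(nb)
    pos[idx, 1] <- sites[m, 1]
    pos[idx, 2] <- sites[m, 2]
    pos[idx, 3] <- mol$positions[, 3] + zoff[m]
  }
  off <- rep((seq_len(nmol) - 1L) * nb, each = nrow(mol$bonds))
  bonds <- cbind(rep(mol$bonds[, 1], nmol) + off,
                 rep(mol$bonds[, 2], nmol) + off)
  bond_type <- rep(1L, nrow(bonds))
  aoff <- rep((seq_len(nmol) - 1L) * nb, each = nrow(mol$angles))
  angles <- cbind(rep(mol$angles[, 1], nmol) + aoff,
                  rep(mol$angles[, 2], nmol) + aoff,
                  rep(mol$angles[, 3], nmol) + aoff)

  # microfibril grouping of 5: chunk lattice sites by distance-sorted order
  ord <- order(sites[, 1]^2 + sites[, 2]^2, atan2(sites[, 2], sites[, 1]))
  microfibril <- integer(nmol)
  microfibril[ord] <- (seq_len(nmol) - 1L) %/% 5L + 1L

  # crosslinks: sample round(beta * 2 * nmol) molecule ends; bond each end
  # bead to the nearest non-end bead of a different molecule
  end_beads <- c((seq_len(nmol) - 1L) * nb + 1L, seq_len(nmol) * nb)
  n_cl <- round(beta * 2 * nmol)
  xl <- matrix(integer(0), 0, 2)
  if (n_cl > 0) {
    set.seed(seed)
    chosen <- if (n_cl >= length(end_beads)) end_beads else
      sample(end_beads, n_cl)
    is_end <- rep(FALSE, nmol * nb)
    is_end[end_beads] <- TRUE
    for (e in chosen) {
      m <- molecule_id[e]
      cand <- which(molecule_id != m & !is_end)
      d2 <- (pos[cand, 1] - pos[e, 1])^2 + (pos[cand, 2] - pos[e, 2])^2 +
        (pos[cand, 3] - pos[e, 3])^2
      xl <- rbind(xl, c(e, cand[which.min(d2)]))
    }
    bonds <- rbind(bonds, xl)
    bond_type <- c(bond_type, rep(2L, nrow(xl)))
  }

  structure(list(positions = pos, molecule_id = molecule_id, bonds = bonds,
                 bond_type = bond_type, angles = angles,
                 n_molecules = nmol, n_beads = nmol * nb,
                 beads_per_molecule = nb, microfibril = microfibril,
                 beta = beta, diameter_nm = diameter_nm,
                 length_nm = mol$contour_length_nm,
                 spacing = mol$spacing, crosslinks = xl, seed = seed),
            class = "cg_fibril")
}

#' Average number of crosslink-connected ends per molecule
#'
#' Counts, for each molecule, how many of its two terminal beads carry a
#' crosslink bond to a bead of another molecule, and averages over molecules.
#'
#' @param fibril a \code{\link{build_fibril}} result.
#' @return average connected ends per molecule (0 to 2).
#' @export
connected_ends_per_molecule <- function(fibril) {
  nb <- fibril$beads_per_molecule
  nmol <- fibril$n_molecules
  end_beads <- c((seq_len(nmol) - 1L) * nb + 1L, seq_len(nmol) * nb)
  if (nrow(fibril$crosslinks) == 0) return(0)
  linked <- unique(fibril$crosslinks[, 1])
  counts <- table(factor(fibril$molecule_id[linked], levels = seq_len(nmol)))
  mean(as.numeric(counts))
}

#' Create a simulation state from a fibril or molecule
#'
#' @param topology a \code{cg_fibril} or \code{cg_molecule}.
#' @param ff a \code{\link{collagen_ff}} (stored for bookkeeping).
#' @return object of class \code{cg_state} with positions, velocities,
#'   bonds, angles, per-bond broken flags and elapsed time.
#' @export
simulation_state <- function(topology, ff = collagen_ff()) {
  if (inherits(topology, "cg_molecule")) {
    bonds <- topology$bonds
    bond_type <- rep(1L, nrow(bonds))
  } else {
    bonds <- topology$bonds
    bond_type <- topology$bond_type
  }
  structure(list(positions = topology$positions,
                 velocities = matrix(0, nrow(topology$positions), 3),
                 bonds = bonds, bond_type = bond_type,
                 angles = topology$angles,
                 broken = rep(0L, nrow(bonds)),
                 mass = rep(ff$bead_mass, nrow(topology$positions)),
                 time = 0),
            class = "cg_state")
}

#' Maximum stable timestep heuristic
#'
#' @param ff a \code{\link{collagen_ff}}.
#' @return \code{0.05 * sqrt(bead_mass / kT0)} in internal time units.
#' @export
stable_dt <- function(ff) 0.05 * sqrt(ff$bead_mass / ff$kT0)

#' Total potential energy and forces of a configuration
#'
#' Thin wrapper over the compiled kernel; used by the force-consistency
#' oracles and available for custom drivers.
#'
#' @param state a \code{cg_state}.
#' @param ff a \code{\link{collagen_ff}}.
#' @return list with \code{potential}, \code{forces} (n x 3) and updated
#'   \code{broken} flags.
#' @export
energy_forces <- function(state, ff) {
  md_energy_forces(state$positions, state$bonds, state$angles,
                   state$broken, unclass(ff))
}

#' Integrate the equations of motion
#'
#' Velocity-Verlet with an optional Langevin thermostat. Bonds that reach
#' the breaking distance are flagged broken and excluded from all later
#' force evaluations.
#'
#' @param state a \code{cg_state}.
#' @param ff a \code{\link{collagen_ff}}.
#' @param dt timestep (internal units); see \code{\link{stable_dt}}.
#' @param n_steps number of steps.
#' @param thermostat \code{"none"} (NVE) or \code{"langevin"}.
#' @param seed RNG seed (Langevin noise).
#' @param gamma Langevin friction (1/time unit).
#' @param temperature thermostat target (K).
#' @param mode per-bead constraint: 0 free, 1 frozen, 2 moving grip.
#' @param grip_vel velocity (3-vector, A/time unit) of mode-2 beads.
#' @param sample_every record energies every this many steps.
#' @return the updated \code{cg_state}, with a \code{trace} element holding
#'   sampled time, potential/kinetic energies, grip reaction force and grip
#'   position.
#' @export
integrate_md <- function(state, ff, dt = stable_dt(ff), n_steps = 1000,
                         thermostat = c("none", "langevin"), seed = 1L,
                         gamma = 0.05, temperature = 300,
                         mode = rep(0L, nrow(state$positions)),
                         grip_vel = c(0, 0, 0), sample_every = 10L) {
  thermostat <- match.arg(thermostat)
  if (dt > stable_dt(ff) * (1 + 1e-9))
    warning("dt exceeds the documented stability heuristic")
  kB <- 0.0019872041 # kcal/mol/K
  set.seed(seed)
  out <- md_run(state$positions, state$velocities, state$mass,
                state$bonds, state$angles, state$broken, unclass(ff),
                dt, as.integer(n_steps),
                as.integer(thermostat == "langevin"), gamma,
                kB * temperature, as.integer(mode), grip_vel,
                as.integer(sample_every), 10L, 0.3 * ff$sigma_lj)
  if (any(!is.finite(out$pos)))
    stop("numerical blow-up: non-finite positions")
  state$positions <- out$pos
  state$velocities <- out$vel
  state$broken <- out$broken
  state$time <- state$time + dt * n_steps
  state$trace <- data.frame(time = out$time, epot = out$epot,
                            ekin = out$ekin, grip_fz = out$grip_fz,
                            grip_z = out$grip_z, virial_zz = out$virial_zz)
  state
}

# MPa per kcal/mol/A^3
.kcalmolA3_to_MPa <- 6947.695

#' Stress-strain curve container
#'
#' @param strain dimensionless strain samples (strictly increasing).
#' @param stress stress samples, MPa.
#' @param meta optional protocol descriptor list.
#' @export
stress_strain_curve <- function(strain, stress, meta = list()) {
  stopifnot(length(strain) == length(stress), all(diff(strain) > 0))
  structure(list(strain = strain, stress = stress, meta = meta),
            class = "stress_strain_curve")
}

#' Constant-rate tensile test of a fibril
#'
#' One axial end of the fibril is restrained, the other is displaced at a
#' constant engineering strain rate; the engineering stress is the axial
#' reaction force on the moving grip divided by the initial cross-section
#' area \code{pi (d/2)^2}. Beads within \code{grip_frac} of the axial
#' extremes form the grips. The configurational virial stress is reported
#' as an alternative column in \code{meta$virial_stress}.
#'
#' @param fibril a \code{\link{build_fibril}} result.
#' @param ff a \code{\link{collagen_ff}}.
#' @param strain_rate engineering strain per internal time unit.
#' @param max_strain final engineering strain (<= 1).
#' @param dt timestep.
#' @param seed RNG seed (thermostat).
#' @param thermostat,temperature,gamma passed to \code{\link{integrate_md}}.
#' @param grip_frac axial fraction of the fibril length clamped at each end.
#' @param n_samples number of uniformly spaced strain samples reported.
#' @param equilibrate_steps thermostatted steps with both grips fixed before
#'   loading starts.
#' @return a \code{\link{stress_strain_curve}}; \code{meta} carries the
#'   broken-bond count and the virial stress column.
#' @export
tensile_test <- function(fibril, ff, strain_rate = 5e-5, max_strain = 0.3,
                         dt = stable_dt(ff), seed = 1L,
                         thermostat = "langevin", temperature = 300,
                         gamma = 0.1, grip_frac = 0.05, n_samples = 60L,
                         equilibrate_steps = 500L) {
  stopifnot(max_strain <= 1, max_strain > 0, strain_rate > 0)
  state <- simulation_state(fibril, ff)
  z <- state$positions[, 3]
  L0 <- max(z) - min(z)
  lo <- z <= min(z) + grip_frac * L0
  hi <- z >= max(z) - grip_frac * L0
  mode <- integer(length(z))
  mode[lo] <- 1L
  mode[hi] <- 2L
  if (equilibrate_steps > 0) {
    st0 <- integrate_md(state, ff, dt, equilibrate_steps, "langevin",
                        seed = seed, gamma = gamma,
                        temperature = temperature, mode = replace(mode, mode == 2L, 1L),
                        sample_every = max(1L, equilibrate_steps))
    state$positions <- st0$positions
    state$velocities <- st0$velocities
    state$broken <- st0$broken
  }
  vz <- strain_rate * L0
  n_steps <- ceiling(max_strain / (strain_rate * dt))
  sample_every <- max(1L, floor(n_steps / n_samples))
  out <- tryCatch(
    integrate_md(state, ff, dt, n_steps, thermostat, seed = seed + 1L,
                 gamma = gamma, temperature = temperature, mode = mode,
                 grip_vel = c(0, 0, vz), sample_every = sample_every),
    error = function(e) NULL)
  if (is.null(out)) stop("tensile test aborted: numerical blow-up")
  area <- pi * (fibril$diameter_nm * 10 / 2)^2 # A^2
  strain <- out$trace$time * strain_rate
  # reaction force exerted ON the grip by the rest of the fibril acts
  # downward (-z) under tension; engineering stress is its magnitude
  stress <- -out$trace$grip_fz / area * .kcalmolA3_to_MPa
  vol <- area * L0
  vir <- -out$trace$virial_zz / vol * .kcalmolA3_to_MPa
  keep <- diff(c(-Inf, strain)) > 0
  stress_strain_curve(strain[keep], stress[keep],
                      meta = list(protocol = "constant-rate tensile",
                                  strain_rate = strain_rate,
                                  n_broken = sum(out$broken),
                                  virial_stress = vir[keep],
                                  diameter_nm = fibril$diameter_nm,
                                  beta = fibril$beta))
}
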