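#' Deterministic 34-muscle fixture for the knee pipeline
#'
#' Three sagittal degrees of freedom (hip flexion, knee flexion, ankle
#' dorsiflexion), each actuated by a fixed muscle group with plausible
#' lever arms and PCSAs. Unlike \code{\link{gen_toy_musculoskeleton}} this
#' fixture is deterministic: it is the musculoskeletal stand-in used by the
#' landing pipeline.
#'
#' @param max_stress active strength per unit PCSA, N/cm^2.
#' @return a \code{toy_musculoskeleton} (targets unset).
#' @export
pipeline_musculoskeleton <- function(max_stress = 61) {
  names <- default_muscle_names()
  n <- length(names)
  pcsa <- c(28, 24, 35, 14, 17, 5, 11, 6, # quads + hams
            26, 12, 42, 24, 11, 15, 12, 6, 5, 6, # shank
            30, 30, 28, 17, 17, 8, 8, # glutes
            10, 12, 3, 3, 12, 22, 7, 4, 8)[seq_len(n)]
  R <- matrix(0, 3, n, dimnames = list(c("hip", "knee", "ankle"), names))
  knee_grp <- c("vastus_intermedius", "vastus_medialis", "vastus_lateralis",
                "rectus_femoris", "biceps_femoris_short")
  ankle_grp <- c("gastrocnemius_medialis", "gastrocnemius_lateralis",
                 "soleus_medial", "soleus_lateral", "tibialis_anterior",
                 "tibialis_posterior", "peroneus_longus", "peroneus_brevis",
                 "flexor_digitorum_longus", "extensor_digitorum_longus")
  hip_grp <- setdiff(names, c(knee_grp, ankle_grp))
  arm <- stats::setNames(numeric(n), names)
  arm[knee_grp] <- c(0.045, 0.042, 0.048, 0.050, 0.035)
  arm[ankle_grp] <- c(0.050, 0.048, 0.045, 0.045, 0.040, 0.038, 0.035,
                      0.035, 0.030, 0.040)
  arm[hip_grp] <- seq(0.050, 0.070, length.out = length(hip_grp))
  R["knee", knee_grp] <- arm[knee_grp]
  R["ankle", ankle_grp] <- arm[ankle_grp]
  R["hip", hip_grp] <- arm[hip_grp]
  structure(list(muscle_names = names, pcsa = pcsa, lever_arms = R,
                 x_passive = rep(0, n), x_max = max_stress * pcsa,
                 ground_truth_forces = NULL, targets = NULL, seed = NA),
            class = "toy_musculoskeleton")
}

#' Pipeline configuration
#'
#' Bundles every knob of the reduced knee pipeline: the articular-surface
#' fixture, material parameters, the musculoskeletal fixture with its
#' muscle line-of-action table, load-sharing rules and the damage
#' threshold. All compartment-share and line-of-action defaults are
#' qualitative surrogates, configurable per call.
#'
#' @param body_mass_kg subject mass (drives the body-weight unit).
#' @param geometry a \code{\link{gen_toy_articular_geometry}} result.
#' @param cartilage a \code{\link{cartilage_params}}.
#' @param msk a musculoskeletal fixture
#'   (default \code{\link{pipeline_musculoskeleton}}).
#' @param axial_fraction per-muscle axial line-of-action components
#'   (fraction of muscle force compressing the joint).
#' @param foundation_modulus elastic-foundation modulus, MPa; nodal
#'   pressure is \code{k * penetration / thickness}.
#' @param medial_share function of height (cm) giving the medial
#'   compartment share of the tibiofemoral load; the default increases
#'   with height and crosses 50 percent above 40 cm.
#' @param wrap_ratio fraction of the summed quadriceps force loading the
#'   patellofemoral contact.
#' @param passive_gain passive-resistance moment per unit muscle force
#'   (DoF x muscles), N.m/N; the default is a small uniform coupling.
#' @param coupling_tol convergence tolerance of the muscle coupling loop,
#'   N.m.
#' @param z_samples normalised cartilage depths evaluated per node.
#' @param max_height_cm upper bound of the critical-height search.
#' @return a list of class \code{knee_config}.
#' @export
knee_config <- function(body_mass_kg = 66.2,
                        geometry = gen_toy_articular_geometry(),
                        cartilage = cartilage_params(),
                        msk = pipeline_musculoskeleton(),
                        axial_fraction = NULL,
                        foundation_modulus = 40,
                        medial_share = function(h)
                          pmin(0.75, pmax(0.40, 0.5 + 0.0025 * (h - 40))),
                        wrap_ratio = 0.7,
                        passive_gain = NULL,
                        coupling_tol = 1,
                        z_samples = c(0, 0.25, 0.5, 0.75, 1),
                        max_height_cm = 300) {
  n <- length(msk$muscle_names)
  if (is.null(axial_fraction))
    axial_fraction <- stats::setNames(rep(0.85, n), msk$muscle_names)
  if (is.null(passive_gain))
    passive_gain <- matrix(1e-4, 3, n) # mild passive resistance, N.m/N
  structure(list(body_mass_kg = body_mass_kg, geometry = geometry,
                 cartilage = cartilage, msk = msk,
                 axial_fraction = axial_fraction,
                 foundation_modulus = foundation_modulus,
                 medial_share = medial_share, wrap_ratio = wrap_ratio,
                 passive_gain = passive_gain, coupling_tol = coupling_tol,
                 z_samples = z_samples, max_height_cm = max_height_cm),
            class = "knee_config")
}

#' Muscle forces at a landing height
#'
#' Builds the moment targets from the landing profile (normalised moments
#' times body mass), then runs the iterative coupling loop against the
#' linear passive surrogate.
#'
#' @param height landing height, cm.
#' @param config a \code{\link{knee_config}}.
#' @return list with \code{profile}, \code{solution}, \code{coupling}.
#' @export
pipeline_muscle_forces <- function(height, config = knee_config()) {
  profile <- suppressWarnings(
    predict_profile(height, validity = c(10, config$max_height_cm)))
  M <- config$body_mass_kg *
    profile$sagittal[c("hip_flex_moment", "knee_flex_moment",
                       "ankle_dorsi_moment")]
  prob <- optimization_problem(config$msk$lever_arms, M, config$msk$pcsa,
                               config$msk$x_passive, config$msk$x_max)
  joint <- surrogate_joint(prob, passive_gain = config$passive_gain)
  coup <- iterative_coupling(joint, tol = config$coupling_tol)
  list(profile = profile, solution = coup$solution, coupling = coup)
}

#' Axial joint load from muscle forces and ground reaction
#'
#' Joint compression in body weights: the vertical ground reaction plus
#' the axial components of every muscle force from the line-of-action
#' table.
#'
#' @param solution a \code{muscle_solution}.
#' @param profile a \code{landing_profile}.
#' @param axial_fraction per-muscle axial components (fractions).
#' @param body_mass_kg subject mass, kg.
#' @return axial load, body weights.
#' @export
joint_axial_load <- function(solution, profile, axial_fraction,
                             body_mass_kg = 66.2) {
  bw <- body_mass_kg * 9.80665
  unname(profile$sagittal["vgrf"] +
           sum(axial_fraction * solution$forces) / bw)
}

#' Elastic-foundation contact solve
#'
#' Rigid spherical indenter on an elastic foundation per compartment:
#' nodal pressure \code{k (delta - gap)/thickness} with the approach
#' \code{delta} solved so the integrated pressure balances that
#' compartment's share of the load. Penetration saturates at 95 percent of
#' the thickness; a load beyond the grid capacity raises an error.
#'
#' @param load_bw total axial load, body weights.
#' @param geometry a \code{\link{gen_toy_articular_geometry}} result.
#' @param foundation_modulus foundation modulus k, MPa.
#' @param shares named compartment shares (must sum to 1), e.g.
#'   \code{c(medial = 0.55, lateral = 0.45)}.
#' @param body_mass_kg subject mass, kg.
#' @return object of class \code{contact_result}: per-node pressures and a
#'   summary (per-compartment and covered/uncovered forces in BW, contact
#'   area, peak pressure and its node).
#' @export
contact_solve <- function(load_bw, geometry, foundation_modulus = 40,
                          shares = c(medial = 0.55, lateral = 0.45),
                          body_mass_kg = 66.2) {
  stopifnot(load_bw >= 0, abs(sum(shares) - 1) < 1e-9)
  bw <- body_mass_kg * 9.80665
  nodes <- geometry$nodes
  nodes$pressure <- 0
  k <- foundation_modulus
  for (comp in names(shares)) {
    idx <- nodes$compartment == comp
    Fc <- shares[[comp]] * load_bw * bw
    if (Fc <= 0) next
    g <- nodes$gap_mm[idx]
    t <- nodes$thickness_mm[idx]
    A <- nodes$area_mm2[idx]
    press <- function(delta) k * pmin(pmax(delta - g, 0), 0.95 * t) / t
    total <- function(delta) sum(press(delta) * A)
    cap <- total(max(g) + 0.95 * max(t))
    if (Fc > cap)
      stop(paste("load exceeds foundation capacity on the grid;",
                 "use a finer/larger grid or stiffer foundation"))
    delta <- stats::uniroot(function(d) total(d) - Fc,
                            c(0, max(g) + 0.95 * max(t)),
                            tol = 1e-12 * (max(g) + max(t)))$root
    nodes$pressure[idx] <- press(delta)
  }
  in_contact <- nodes$pressure > 0
  nodal_force_bw <- nodes$pressure * nodes$area_mm2 / bw
  comp_force <- tapply(nodal_force_bw, nodes$compartment, sum)
  region_force <- tapply(nodal_force_bw, nodes$region, sum)
  ipk <- which.max(nodes$pressure)
  structure(list(
    nodes = nodes,
    load_bw = load_bw,
    compartment_force_bw = comp_force,
    region_force_bw = region_force,
    contact_area_mm2 = sum(nodes$area_mm2[in_contact]),
    peak_pressure = nodes$pressure[ipk],
    peak_node = ipk), class = "contact_result")
}

#' Depth-resolved cartilage stress and damage under a contact field
#'
#' Each contacting node's pressure is mapped to the local foundation
#' kinematics: compressive through-thickness stretch
#' \code{lambda_z = 1 - p/k} with isochoric lateral expansion
#' \code{lambda_z^(-1/2)}. The cartilage law is evaluated at the requested
#' depths; per-bundle logarithmic fibril strains feed the energy-limiter
#' damage indicator.
#'
#' @param contact a \code{\link{contact_solve}} result.
#' @param cartilage a \code{\link{cartilage_params}}.
#' @param z_samples normalised depths.
#' @param foundation_modulus the modulus used in the contact solve, MPa.
#' @return data.frame: node, compartment, region, z, pressure,
#'   axial_stress (MPa, compression negative), damage (max bundle
#'   indicator), damaged (indicator above threshold).
#' @export
tissue_stress_field <- function(contact, cartilage = cartilage_params(),
                                z_samples = c(0, 0.25, 0.5, 0.75, 1),
                                foundation_modulus = 40) {
  nodes <- contact$nodes
  act <- which(nodes$pressure > 0)
  out <- expand.grid(node = seq_len(nrow(nodes)), z = z_samples)
  out$compartment <- nodes$compartment[out$node]
  out$region <- nodes$region[out$node]
  out$pressure <- nodes$pressure[out$node]
  out$axial_stress <- 0
  out$damage <- 0
  if (length(act) > 0) {
    bundles_by_z <- lapply(z_samples, fibril_bundles)
    names(bundles_by_z) <- as.character(z_samples)
    # evaluate per unique pressure level (grids share symmetric values)
    for (i in which(out$pressure > 0)) {
      e <- min(out$pressure[i] / foundation_modulus, 0.95)
      lz <- 1 - e
      F <- diag(c(lz^(-1 / 2), lz^(-1 / 2), lz))
      z <- out$z[i]
      b <- bundles_by_z[[as.character(z)]]
      sig <- cart_total_stress(F, z, cartilage, b)
      out$axial_stress[i] <- sig[3, 3] - sig[1, 1]
      eps <- apply(b$directions, 1, function(n0) log(sqrt(sum((F %*% n0)^2))))
      out$damage[i] <- max(damage_indicator(matrix(pmax(eps, 0), nrow = 1),
                                            z, cartilage))
    }
  }
  out$damaged <- out$damage > cartilage$damage_threshold
  out
}

#' Full-pipeline damage scan at one height
#'
#' Runs height -> profile -> muscle forces -> axial load -> tibiofemoral
#' and patellofemoral contact -> depth-resolved damage, and reports whether
#' any node/depth exceeds the damage threshold.
#'
#' @param height landing height, cm.
#' @param config a \code{\link{knee_config}}.
#' @param detail return the intermediate results as attributes.
#' @return logical; attributes \code{load_bw}, \code{peak_pressure},
#'   \code{max_damage} (and with \code{detail} the full field and contact).
#' @export
damage_scan <- function(height, config = knee_config(), detail = FALSE) {
  mf <- pipeline_muscle_forces(height, config)
  load_bw <- joint_axial_load(mf$solution, mf$profile,
                              config$axial_fraction, config$body_mass_kg)
  ms <- config$medial_share(height)
  tf <- contact_solve(load_bw, config$geometry, config$foundation_modulus,
                      c(medial = ms, lateral = 1 - ms),
                      config$body_mass_kg)
  quad <- grepl("vastus|rectus", config$msk$muscle_names)
  pf_load <- config$wrap_ratio * sum(mf$solution$forces[quad]) /
    (config$body_mass_kg * 9.80665)
  pf <- contact_solve(pf_load, config$geometry, config$foundation_modulus,
                      c(medial = 0.45, lateral = 0.55),
                      config$body_mass_kg)
  field_tf <- tissue_stress_field(tf, config$cartilage, config$z_samples,
                                  config$foundation_modulus)
  field_pf <- tissue_stress_field(pf, config$cartilage, config$z_samples,
                                  config$foundation_modulus)
  md <- max(field_tf$damage, field_pf$damage)
  res <- md > config$cartilage$damage_threshold
  attr(res, "load_bw") <- load_bw
  attr(res, "pf_load_bw") <- pf_load
  attr(res, "peak_pressure") <- max(tf$peak_pressure, pf$peak_pressure)
  attr(res, "max_damage") <- md
  if (detail) {
    attr(res, "contact_tf") <- tf
    attr(res, "contact_pf") <- pf
    attr(res, "field_tf") <- field_tf
    attr(res, "field_pf") <- field_pf
    attr(res, "muscle") <- mf
  }
  res
}

#' Critical landing-height search
#'
#' Bracketing walk with a shrinking-increment schedule: starting from
#' \code{start_cm}, step upward by the current increment until damage
#' flips on, restart from the last undamaged height with the next smaller
#' increment, and return the first damaged height at the final (1 cm)
#' resolution. Damage evaluations are memoised.
#'
#' @param start_cm initial height, cm (default 100, i.e. 1 m).
#' @param schedule strictly decreasing increments ending at 1 cm.
#' @param config a \code{\link{knee_config}}.
#' @param damage_fun optional replacement damage predicate
#'   \code{function(height) logical}; defaults to the full
#'   \code{\link{damage_scan}} pipeline.
#' @return object of class \code{critical_height_result}:
#'   \code{critical_height} (cm), \code{search_trace} (data.frame of
#'   evaluated heights and outcomes) and \code{n_evaluations}.
#' @export
critical_height_search <- function(start_cm = 100,
                                   schedule = c(20, 10, 5, 1),
                                   config = knee_config(),
                                   damage_fun = NULL) {
  stopifnot(all(diff(schedule) < 0), schedule[length(schedule)] == 1,
            start_cm >= 1)
  if (is.null(damage_fun))
    damage_fun <- function(h) as.logical(damage_scan(h, config))
  cache <- new.env(parent = emptyenv())
  trace <- data.frame(height = numeric(0), damaged = logical(0))
  eval_h <- function(h) {
    key <- as.character(h)
    if (!is.null(cache[[key]])) return(cache[[key]])
    d <- isTRUE(damage_fun(h))
    cache[[key]] <- d
    trace <<- rbind(trace, data.frame(height = h, damaged = d))
    d
  }
  max_h <- config$max_height_cm
  if (eval_h(start_cm)) {
    return(structure(list(critical_height = start_cm, search_trace = trace,
                          n_evaluations = nrow(trace)),
                     class = "critical_height_result"))
  }
  base <- start_cm
  for (inc in schedule) {
    h <- base + inc
    while (!eval_h(h)) {
      base <- h
      h <- base + inc
      if (h > max_h)
        stop(sprintf("no damage found up to %g cm", max_h))
    }
  }
  structure(list(critical_height = base + 1, search_trace = trace,
                 n_evaluations = nrow(trace)),
            class = "critical_height_result")
}
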