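#' Write / read a landing-record table
#'
#' Plain CSV, one row per record; a comment header line documents the
#' units (heights cm, angles degrees, moments N.m/kg, vGRF body weights).
#'
#' @param records data.frame from \code{\link{gen_landing_dataset}}.
#' @param path file path.
#' @return (write) the path invisibly; (read) the data.frame.
#' @export
write_landing_csv <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# landing records: height cm, angles deg,",
                   "moments N.m/kg, vgrf BW"), con)
  utils::write.csv(records, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landing_csv
#' @export
read_landing_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Write / read a stress-strain curve as CSV
#'
#' Columns \code{strain} and \code{stress_MPa}; a \code{stress_virial_MPa}
#' column is added when the curve carries a virial alternative.
#'
#' @param curve a \code{\link{stress_strain_curve}}.
#' @param path file path.
#' @export
write_stress_strain_csv <- function(curve, path) {
  df <- data.frame(strain = curve$strain, stress_MPa = curve$stress)
  if (!is.null(curve$meta$virial_stress))
    df$stress_virial_MPa <- curve$meta$virial_stress
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stress_strain_csv
#' @export
read_stress_strain_csv <- function(path) {
  df <- utils::read.csv(path)
  stress_strain_curve(df$strain, df$stress_MPa)
}

#' Write a LAMMPS-style data file for a fibril topology
#'
#' Atoms (molecular style), Bonds and Angles sections with two bond types
#' (1 backbone, 2 crosslink), for cross-checking topologies in external MD
#' codes. Lengths in angstrom.
#'
#' @param fibril a \code{\link{build_fibril}} result (or
#'   \code{\link{build_molecule}}).
#' @param path file path.
#' @export
write_lammps_data <- function(fibril, path) {
  pos <- fibril$positions
  if (inherits(fibril, "cg_molecule")) {
    bonds <- cbind(fibril$bonds, 1L)
    mol_id <- rep(1L, nrow(pos))
  } else {
    bonds <- cbind(fibril$bonds, fibril$bond_type)
    mol_id <- fibril$molecule_id
  }
  angles <- fibril$angles
  pad <- 50
  lines <- c(
    "LAMMPS data file: coarse-grained collagen topology",
    "",
    sprintf("%d atoms", nrow(pos)),
    sprintf("%d bonds", nrow(bonds)),
    sprintf("%d angles", nrow(angles)),
    "",
    "1 atom types",
    "2 bond types",
    "1 angle types",
    "",
    sprintf("%.4f %.4f xlo xhi", min(pos[, 1]) - pad, max(pos[, 1]) + pad),
    sprintf("%.4f %.4f ylo yhi", min(pos[, 2]) - pad, max(pos[, 2]) + pad),
    sprintf("%.4f %.4f zlo zhi", min(pos[, 3]) - pad, max(pos[, 3]) + pad),
    "",
    "Atoms # molecular",
    "",
    sprintf("%d %d 1 %.6f %.6f %.6f", seq_len(nrow(pos)), mol_id,
            pos[, 1], pos[, 2], pos[, 3]),
    "",
    "Bonds",
    "",
    sprintf("%d %d %d %d", seq_len(nrow(bonds)), bonds[, 3],
            bonds[, 1], bonds[, 2]))
  if (nrow(angles) > 0) {
    lines <- c(lines, "", "Angles", "",
               sprintf("%d 1 %d %d %d", seq_len(nrow(angles)),
                       angles[, 1], angles[, 2], angles[, 3]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a declarative configuration document
#'
#' YAML serialisation of generator / run parameters (force-field values,
#' geometry knobs, seeds, search schedules).
#'
#' @param config a named list.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}
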