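# Shared oracles: independent finite-difference and brute-force references
# used across the constitutive and MD tests.

# Cauchy stress by central difference of an energy density W(F):
# sigma = (1/J) dW/dF F', symmetrised.
fd_cauchy_stress <- function(energy_fun, F, h = 1e-6) {
  P <- matrix(0, 3, 3)
  for (i in 1:3) {
    for (j in 1:3) {
      Fp <- F
      Fp[i, j] <- Fp[i, j] + h
      Fm <- F
      Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (energy_fun(Fp) - energy_fun(Fm)) / (2 * h)
    }
  }
  S <- P %*% t(F) / det(F)
  (S + t(S)) / 2
}

# relative difference between two stress tensors, scaled sensibly
rel_stress_err <- function(a, b) {
  max(abs(a - b)) / max(1, max(abs(a)), max(abs(b)))
}

# brute-force O(N^2) pair energy of the truncated-shifted LJ over all
# non-excluded pairs (exclusions: chain distance <= 2 within a molecule)
brute_lj_energy <- function(pos, molecule_id, chain_index, ff) {
  n <- nrow(pos)
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (molecule_id[i] == molecule_id[j] &&
          abs(chain_index[i] - chain_index[j]) <= 2) next
      r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (r < ff$lj_cutoff) e <- e + lj_energy_force(r, ff)$energy
    }
  }
  e
}

# random rotation matrix (for frame-objectivity tests)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# small random deformation gradient around a base stretch
random_F <- function(base = diag(3), mag = 0.01) {
  base + matrix(stats::rnorm(9, 0, mag), 3, 3)
}
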