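#!/usr/bin/env Rscript
# Tissue constitutive models parameterised from the fibril MD output.
#
# Fits the cartilage collagen coefficients to 70% of the beta = 1 MD curve
# (the stiffness reduction of collagen II relative to the simulated
# collagen I fibrils), then sweeps the cartilage, ligament and meniscus
# laws and writes the curves under results/.

library(landingmech)

dir.create("results/tissue", recursive = TRUE, showWarnings = FALSE)

# --- cartilage fibril coefficients from the MD curve -----------------------
cv <- read_stress_strain_csv("results/fibril/tensile_beta100_seed1.csv")
fit <- fit_fibril_params_to_md(cv, scale = 0.7)
cat(sprintf("MD fit (70%% rule): E0 = %.3f MPa, Ee = %.1f MPa (RMS %.2f MPa, %d pts)\n",
            fit$E0, fit$Ee, fit$residual, fit$n_used))
cat(sprintf("shipped defaults:   E0 = 8.121 MPa, Ee = 5326.32 MPa\n"))
write.csv(data.frame(source = c("md_fit_70pct", "shipped_default"),
                     E0_MPa = c(fit$E0, 8.121),
                     Ee_MPa = c(fit$Ee, 5326.32)),
          "results/tissue/cartilage_fibril_coefficients.csv",
          row.names = FALSE)

# --- cartilage sweeps: softened axial fibril law and depth profiles --------
p <- cartilage_params()
es <- seq(0, 1, 0.01)
soft <- vapply(es, function(e)
  if (e > 0) cart_softened_stress(e, 1, c(1, 0, 0), 1, p)[1, 1] else 0,
  numeric(1))
intact <- vapply(es, function(e)
  if (e > 0) cart_fibril_stress(e, 1, c(1, 0, 0), 1, p)[1, 1] else 0,
  numeric(1))
write.csv(data.frame(strain = es, stress_intact_MPa = intact,
                     stress_softened_MPa = soft),
          "results/tissue/cartilage_fibril_softening.csv", row.names = FALSE)
cat(sprintf("softened fibril peak: %.1f MPa at strain %.2f (limiter phi = %.1f)\n",
            max(soft), es[which.max(soft)], p$phi))

zs <- seq(0, 1, 0.05)
pr <- depth_profiles(zs)
write.csv(data.frame(z = zs, vt = pr$vt, eta0s = pr$eta0s,
                     vf_primary = pr$vf_primary,
                     vf_secondary = pr$vf_secondary),
          "results/tissue/cartilage_depth_profiles.csv", row.names = FALSE)

# --- ligament: uniaxial response and an elastoplastic cycle ----------------
pl <- ligament_params()
lam_up <- seq(1, 1.15, length.out = 25)
lams <- c(lam_up, rev(lam_up)[-1])
yield <- stress_strain_curve(c(0, 0.05, 0.2),
                             0.05 * approx(cv$strain, cv$stress,
                                           c(0.02, 0.05, 0.08))$y + 12)
st <- plastic_state()
cyc <- data.frame(stretch = lams, stress_MPa = NA, lambda_p = NA)
for (i in seq_along(lams)) {
  st <- lig_plastic_update(st, lams[i], yield, pl)
  cyc$stress_MPa[i] <-
    landingmech:::.lig_axial_fibril_stress(lams[i] / st$lambda_p, pl)
  cyc$lambda_p[i] <- st$lambda_p
}
write.csv(cyc, "results/tissue/ligament_plastic_cycle.csv", row.names = FALSE)
cat(sprintf("ligament cycle: permanent plastic stretch %.4f after loading to 1.15\n",
            st$lambda_p))

elastic <- data.frame(stretch = lam_up[-1],
                      stress_MPa = lig_uniaxial_stress(lam_up[-1], p = pl),
                      prestrained_MPa = lig_uniaxial_stress(lam_up[-1],
                                                            p = pl, pre = 1.03))
write.csv(elastic, "results/tissue/ligament_uniaxial.csv", row.names = FALSE)

# --- meniscus compliance ---------------------------------------------------
S <- compliance_matrix(meniscus_params())
write.csv(as.data.frame(S), "results/tissue/meniscus_compliance.csv",
          row.names = FALSE)
cat(sprintf("meniscus: circumferential strain under 12 MPa hoop stress = %.3f\n",
            stress_to_strain(c(0, 0, 12, 0, 0, 0))[3]))
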