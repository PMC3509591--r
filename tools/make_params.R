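# Builds the packaged default parameter set and the synthetic homopair PMF
# fixtures under inst/extdata/. Run from the repository root after
# installing the package:
#   Rscript tools/make_params.R
# Regeneration is deterministic (seed 20121108).

library(cgff)

seed <- 20121108

# --- synthetic homopair PMF fixtures for the well-depth fits --------------
# The force field's adopted zero-crossings fix c_ii; the well depths below
# were chosen once on physical grounds (deeper for hydrophobic/aromatic
# side chains, all bracketed by the water bead's 6 kJ/mol) and encode the
# "true" depths the synthetic curves are built from. Each curve is the
# 12-6 form plus a short-range (r < c) perturbation emulating the
# non-transferable contact region of an umbrella-sampled PMF, plus small
# noise.
TRUE_EPS <- c(
  B_ALA = 3.2, B_ASN = 3.4, B_ASP = 3.0, B_CYS = 3.8, B_GLY = 2.8,
  B_LEU = 4.4, B_PRO = 3.6, B_SER = 3.0, B_THR = 3.2, B_VAL = 4.0,
  S_ARG = 3.0, S_GLN = 3.2, S_GLU = 3.0, S_HIS = 3.5, S_ILE = 4.5,
  S_LYS = 3.0, S_MET = 4.2, S_PHE = 4.8, S_TRP = 5.0, S_TYR = 4.2)

specs <- bead_specs()
dir.create("inst/extdata/pmf_synthetic", recursive = TRUE,
           showWarnings = FALSE)

set.seed(seed)
lj <- data.frame(bead = character(), eps = numeric(), c = numeric())
for (bd in names(TRUE_EPS)) {
  cii <- specs$c_ii[specs$bead == bd]
  r <- seq(0.30, 1.50, by = 0.005)
  r <- r[r > 0.82 * cii]          # US windows start near contact
  u <- 4 * TRUE_EPS[[bd]] * ((cii / r)^12 - (cii / r)^6)
  u <- u + 1.5 * exp(-((r - 0.88 * cii) / 0.04)^2)   # contact artefact
  u <- u + rnorm(length(r), 0, 0.03)
  pmf <- pmf_curve(r, u, temperature = 300)
  f <- file.path("inst/extdata/pmf_synthetic", paste0(bd, ".txt"))
  write_pmf(pmf, f)
  fit <- fit_lj_depth(read_pmf(f), c_fixed = cii)
  lj <- rbind(lj, data.frame(bead = bd, eps = fit$eps, c = cii))
}
lj <- rbind(lj, data.frame(bead = "W", eps = 6, c = 0.51))

# --- bonded Gaussian-sum parameters from the calibration ensemble ---------
structures <- calibration_structures(n_helix = 80, n_strand = 80,
                                     n_coil = 120, n_res = 30,
                                     jitter_sd = 6,
                                     seed = seed %% 1000000L)
bonded <- parameterize_bonded(structures, temperature = 300, n_max = 6)

angles <- lapply(bonded$angles, `[[`, "param")
torsions <- lapply(bonded$torsions, `[[`, "param")
cat("angle fits:\n")
for (nm in names(bonded$angles))
  cat(sprintf("  %-6s N=%d rms=%.3f\n", nm, bonded$angles[[nm]]$n_terms,
              bonded$angles[[nm]]$rms))
cat("torsion fits:\n")
for (nm in names(bonded$torsions))
  cat(sprintf("  %-8s N=%d rms=%.3f\n", nm, bonded$torsions[[nm]]$n_terms,
              bonded$torsions[[nm]]$rms))

# --- adopted bond constants ----------------------------------------------
bonds <- list(`B-B` = list(K = 1e5, L = 0.38))
for (r in cgff:::TWO_BEAD_RESIDUES)
  bonds[[paste0("B-S_", r)]] <- list(K = 5e3,
                                     L = cgff:::BS_BOND_LENGTH[[r]])

params <- parameter_set(bonds, angles, torsions, lj, er = 1, cutoff = 1.2)
write_parameters(params, "inst/extdata/cg_parameters.json")
cat("wrote inst/extdata/cg_parameters.json\n")
print(params)
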