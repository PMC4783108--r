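#!/usr/bin/env Rscript
# Stage 1: generate the synthetic osmotic-pressure isotherms that stand in
# for the experimental crystallin data.  Four generating models on the same
# 16-point grid over 25-400 mg/mL: the ideal law, pure hard spheres, the
# TPM at its reference attraction depth (13.9 kT), and the CBM at two
# binding sites with K = 10.6.  Noisy replicas carry 5% multiplicative
# Gaussian noise under a fixed seed.

library(sptcrowd)

seed <- 20160308
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

sys <- crystallin_system()   # sigma = 3.6 nm, T = 298.15 K, M = 21 kDa
cat("System:\n"); print(sys)

models <- list(ideal = "ideal", hard_sphere = NULL,
               tpm_eps13.9 = tpm_model(13.9),
               cbm_ns2_K10.6 = cbm_model(2, 10.6))

for (nm in names(models)) {
  exact <- simulate_isotherm(sys, models[[nm]], noise_sd = 0)
  write_isotherm(exact, file.path(out_dir, sprintf("isotherm_%s.csv", nm)))
  noisy <- simulate_isotherm(sys, models[[nm]], noise_sd = 0.05, seed = seed)
  write_isotherm(noisy,
                 file.path(out_dir, sprintf("isotherm_%s_noisy.csv", nm)))
  cat(sprintf("%-14s Pi(400 mg/mL) = %8.2f kPa (ideal: %.2f kPa)\n", nm,
              exact$Pi_kPa[nrow(exact)],
              ideal_pressure(concentration_to_density(400))))
}

cat("\nAll attractive-model curves lie below the ideal law, as expected\n")
cat("for crystallin solutions; files written under", out_dir, "\n")
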