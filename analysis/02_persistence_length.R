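#!/usr/bin/env Rscript
# Persistence length of the flexible vs stiff synthetic strands via the
# 2D worm-like-chain tangent-correlation fit:
#   <cos(phi(s) - phi(0))> = exp(-s / (2 l_p)),
# ln C regressed on s over the longest prefix with R^2 >= 0.95 (>= 3 lags),
# l_p = -1 / (2 slope).
suppressMessages(library(strandmech))
dir.create("results", showWarnings = FALSE)

fits <- c()
for (nm in c(flexible = "flexible", stiff = "stiff")) {
  lp <- c(flexible = 150, stiff = 590)[[nm]]
  ens <- generate_wlc_ensemble(wlc_params(n_points = 44, ds = 3.0, lp = lp,
                                          n_frames = 2000, seed = lp))
  res <- persistence_pipeline(ens, k_max = 15, r2_cutoff = 0.95)
  write_persistence(res,
                    file.path("results", paste0("correlation_", nm, ".csv")),
                    file.path("results", paste0("persistence_", nm, ".json")))
  cat(sprintf("%-8s: true l_p %3d nm -> fitted %6.1f nm  (delta_s %.2f nm, R2 %.4f, %d lags)\n",
              nm, lp, res$estimate$lp_nm, res$ds_nm, res$estimate$r2,
              res$estimate$lags_used))
  fits[nm] <- res$estimate$lp_nm
}
cat(sprintf("The stiff strand's %.1fx larger l_p mirrors the flexible-vs-rigid\n",
            fits["stiff"] / fits["flexible"]))
cat("contrast the estimator is built to resolve.\n")
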