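#!/usr/bin/env Rscript
# Local curvature along the synthetic strands: sliding-window (i-5..i+5)
# algebraic circle fits, curvature = 1/radius in um^-1, window positions
# i = 6..39 on a 44-point trace (ends excluded by the window margin).
suppressMessages(library(strandmech))
dir.create("results", showWarnings = FALSE)

out <- NULL
for (nm in c("flexible", "stiff")) {
  lp <- c(flexible = 150, stiff = 590)[[nm]]
  ens <- generate_wlc_ensemble(wlc_params(n_points = 44, ds = 3.0, lp = lp,
                                          n_frames = 500, seed = lp))
  cp <- curvature_pipeline(ens, half_width = 5)
  # per-position table capped at 50 frames to keep outputs small; the
  # pooled summary below uses all frames
  write_curvature(cp$profiles[1:50],
                  file.path("results", paste0("curvature_", nm, ".csv")))
  utils::write.csv(cp$summary$histogram,
                   file.path("results",
                             paste0("curvature_hist_", nm, ".csv")),
                   row.names = FALSE)
  cat(sprintf("%-8s (l_p %3d nm): mean curvature %6.2f um^-1, sd %6.2f um^-1 (n = %d)\n",
              nm, lp, cp$summary$mean, cp$summary$sd, cp$summary$n))
  out <- c(out, cp$summary$mean)
}
cat(sprintf("Curvature ratio flexible/stiff: %.2f — stiffer strands bend less,\n",
            out[1] / out[2]))
cat("the same qualitative contrast seen between curvy and straight strand\n")
cat("morphologies in membranes.\n")
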