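#!/usr/bin/env Rscript
# TM3-like helix geometry: tilt of the helical axis against the membrane
# normal (HELANAL-style local axes from 4-Calpha windows) and the bend angle
# at the apex residue — the chord angle at Calpha(134) toward the two helix
# ends. A straight helix with the literature end residues (123/141) reads
# below 180 deg because the chords carry a radial offset on fractional
# turns; the imposed-kink recovery therefore uses full-turn arms.
suppressMessages(library(strandmech))
dir.create("results", showWarnings = FALSE)

# straight (alanine-like) vs kinked (proline-like) helix, 0.2 A noise
summary <- list()
for (nm in c("straight", "kinked")) {
  kink <- c(straight = 0, kinked = 15)[[nm]]
  p <- kinked_helix_params(n_residues = 37, kink_residue = 134,
                           kink_angle = kink, resid_start = 116,
                           noise_sd = 0.2, seed = 134)
  frames <- generate_kinked_helix(p, n_frames = 200)
  bends <- vapply(frames, bend_angle, 1.0, apex_residue = 134,
                  end_residues = c(116, 152))
  tilts <- vapply(frames, function(h) tilt_angle(local_helix_axes(h)$axis),
                  1.0)
  cat(sprintf("%-8s helix (kink %2d deg): bend %6.2f +/- %4.2f deg, tilt %5.2f +/- %4.2f deg\n",
              nm, kink, mean(bends), sd(bends), mean(tilts), sd(tilts)))
  summary[[nm]] <- list(kink_deg = kink, bend_mean_deg = mean(bends),
                        bend_sd_deg = sd(bends),
                        tilt_mean_deg = mean(tilts),
                        tilt_sd_deg = sd(tilts), n_frames = length(frames),
                        sd_convention = "sample (n-1)")
}
jsonlite::write_json(summary, "results/helix_angles.json",
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("Kink shifts the mean bend by %.1f deg — the scale of the\n",
            summary$straight$bend_mean_deg - summary$kinked$bend_mean_deg))
cat("proline-induced transmembrane-helix bending this analysis resolves.\n")
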