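#!/usr/bin/env Rscript
# Build MFA profiles for every simulated track: normalize against the
# stationary-phase control, smooth with the circular loess (span 0.1) and
# render figure-style plots. Reads the tracks written by 01_simulate.R.

suppressPackageStartupMessages(library(termfa))

map <- default_map()
dir.create("results/profiles", showWarnings = FALSE, recursive = TRUE)
dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

control <- read_counts_tsv("results/tracks/stationary_control.tsv",
                           condition = "stationary_control",
                           sample_id = "stationary_control")

tracks <- setdiff(list.files("results/tracks", pattern = "\\.tsv$"),
                  "stationary_control.tsv")
for (f in tracks) {
  tag <- sub("\\.tsv$", "", f)
  spc <- grepl("_spc$", tag)
  track <- read_counts_tsv(file.path("results/tracks", f),
                           condition = if (spc) "spc" else "log",
                           sample_id = tag)
  prof <- assemble_profile(track, control, span = 0.1)
  write_profile_tsv(prof, file.path("results/profiles",
                                    paste0(tag, "_profile.tsv")))
  eff_map <- if (grepl("_inv_", paste0(tag, "_"))) {
    apply_inversion(map, 1520000, 1840000)
  } else map
  plot_profile(prof, eff_map,
               file.path("results/figures", paste0(tag, ".png")))
  amax <- prof$window_centers[which.max(prof$loess)] / 1e6
  cat(sprintf("%-22s loess range [%+.2f, %+.2f], maximum at %.2f Mb\n",
              tag, min(prof$loess), max(prof$loess), amax))
}
cat("profiles in results/profiles/, figures in results/figures/\n")
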