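#!/usr/bin/env Rscript
# Simulate expected copy-number profiles and Poisson read counts for every
# strain scenario the study contrasts (wild type, topA, topA topB,
# topA topB tus, topA topB with the TerB-repositioning inversion), each in
# log phase and after the spectinomycin run-off, plus the shared
# stationary-phase control. Writes per-window count tables under
# results/tracks/ and the scenario configurations under results/configs/.

suppressPackageStartupMessages(library(termfa))

seed <- 20260918L
grid_n <- 10000L
depth <- 100
n_cells <- 5000L

map <- default_map()
grid <- build_grid(map$length, grid_n)
dir.create("results/tracks", showWarnings = FALSE, recursive = TRUE)
dir.create("results/configs", showWarnings = FALSE, recursive = TRUE)

control <- sample_counts(rep(1, grid_n), depth, grid, seed = seed,
                         condition = "stationary_control",
                         sample_id = "stationary_control")
write_counts_tsv(control, "results/tracks/stationary_control.tsv")

scenarios <- c("wild_type", "topA", "topA_topB", "topA_topB_tus",
               "topA_topB_inv")
for (i in seq_along(scenarios)) {
  sc <- scenarios[i]
  for (spc in c(FALSE, TRUE)) {
    cfg <- make_scenario(sc, spc = spc, seed = seed + 10L * i + spc,
                         n_cells = n_cells, depth = depth)
    tag <- paste0(sc, if (spc) "_spc" else "_log")
    expected <- expected_copy_profile(cfg, map, grid_n)
    track <- sample_counts(expected, depth, grid,
                           seed = seed + 1000L + 10L * i + spc,
                           condition = if (spc) "spc" else "log",
                           sample_id = tag)
    write_counts_tsv(track, file.path("results/tracks",
                                      paste0(tag, ".tsv")))
    write_config_json(cfg, file.path("results/configs",
                                     paste0(tag, ".json")))
    cat(sprintf("%-22s total reads %s, expected copy range [%.2f, %.2f]\n",
                tag, format(sum(track$counts), big.mark = ","),
                min(expected), max(expected)))
  }
}
cat("tracks written to results/tracks/\n")
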