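#' Pipeline run configuration
#'
#' Bundles the parameters of a full simulate -> coverage -> profile -> peaks
#' run. Defaults are the published analysis parameters: 10,000 genome
#' windows, loess span 0.1, minimum mapping quality 10.
#'
#' @param scenario Scenario name for [make_scenario()].
#' @param outdir Output directory (created if missing).
#' @param seed Master seed; all stage seeds derive from it.
#' @param map A `chromosome_map` (default [default_map()]).
#' @param grid_n Number of windows.
#' @param span Loess span.
#' @param min_mapq MAPQ threshold (recorded in the manifest; applied on the
#'   SAM ingest path).
#' @param region Optional [peak_region()]; default: the innermost Ter/Tus
#'   interval of the (possibly inverted) map.
#' @param depth Mean reads per window.
#' @param n_cells Monte-Carlo cells per profile.
#' @param flank_width Flank windows for the peak statistic.
#' @param plots Write Fig-style profile plots (PNG)?
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenario = "topA_topB", outdir = "termfa_run",
                       seed = 1L, map = default_map(), grid_n = 10000,
                       span = 0.1, min_mapq = 10, region = NULL, depth = 100,
                       n_cells = 2000, flank_width = 200, plots = FALSE) {
  structure(list(scenario = scenario, outdir = outdir, seed = as.integer(seed),
                 map = map, grid_n = grid_n, span = span, min_mapq = min_mapq,
                 region = region, depth = depth, n_cells = n_cells,
                 flank_width = flank_width, plots = plots),
            class = "run_config")
}

#' Run the full MFA pipeline on a simulated scenario
#'
#' Simulates the scenario's log-phase sample, its spectinomycin run-off
#' counterpart and a flat stationary-phase control; bins, normalizes and
#' smooths them; computes the Ter peak report; and writes deterministic TSV
#' outputs plus a JSON run manifest (all parameters and derived seeds) under
#' `config$outdir`. Outputs are byte-identical across runs with the same
#' config.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `report` (the [peak_report()] row),
#'   `profile_pre`, `profile_post`, `region` and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  map <- config$map
  grid <- build_grid(map$length, config$grid_n)

  cfg_pre <- make_scenario(config$scenario, spc = FALSE, seed = config$seed,
                           n_cells = config$n_cells, depth = config$depth)
  cfg_post <- make_scenario(config$scenario, spc = TRUE,
                            seed = config$seed + 1L,
                            n_cells = config$n_cells, depth = config$depth)
  eff_map <- if (is.null(cfg_pre$inversion)) map else
    apply_inversion(map, cfg_pre$inversion[1], cfg_pre$inversion[2])

  exp_pre <- expected_copy_profile(cfg_pre, map, config$grid_n)
  exp_post <- expected_copy_profile(cfg_post, map, config$grid_n)
  control <- sample_counts(rep(1, config$grid_n), config$depth, grid,
                           seed = config$seed + 2L,
                           condition = "stationary_control",
                           sample_id = "stationary_control")
  pre <- sample_counts(exp_pre, config$depth, grid, seed = config$seed + 3L,
                       condition = "log",
                       sample_id = paste0(config$scenario, "_log"))
  post <- sample_counts(exp_post, config$depth, grid,
                        seed = config$seed + 4L, condition = "spc",
                        sample_id = paste0(config$scenario, "_spc"))

  prof_pre <- assemble_profile(pre, control, span = config$span)
  prof_post <- assemble_profile(post, control, span = config$span)

  region <- config$region
  if (is.null(region)) {
    iv <- innermost_ter_interval(eff_map)
    region <- peak_region(iv["left"], iv["right"],
                          flank_width = config$flank_width)
  }
  report <- peak_report(prof_pre, prof_post, region, eff_map)

  out <- function(f) file.path(config$outdir, f)
  write_counts_tsv(control, out("control_stationary.tsv"))
  write_counts_tsv(pre, out(paste0(config$scenario, "_log.tsv")))
  write_counts_tsv(post, out(paste0(config$scenario, "_spc.tsv")))
  write_profile_tsv(prof_pre, out(paste0(config$scenario, "_log_profile.tsv")),
                    bedgraph = out(paste0(config$scenario, "_log.bedgraph")))
  write_profile_tsv(prof_post, out(paste0(config$scenario, "_spc_profile.tsv")),
                    bedgraph = out(paste0(config$scenario, "_spc.bedgraph")))
  utils::write.table(report, out("peak_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    scenario = config$scenario, seed = config$seed,
    stage_seeds = list(sim_pre = config$seed, sim_post = config$seed + 1L,
                       control = config$seed + 2L, sample_pre = config$seed + 3L,
                       sample_post = config$seed + 4L),
    grid_n = config$grid_n, span = config$span, min_mapq = config$min_mapq,
    depth = config$depth, n_cells = config$n_cells,
    flank_width = config$flank_width,
    region = c(region$left, region$right),
    genome_length = map$length
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (isTRUE(config$plots)) {
    plot_profile(prof_pre, eff_map,
                 out(paste0(config$scenario, "_log.png")))
    plot_profile(prof_post, eff_map,
                 out(paste0(config$scenario, "_spc.png")))
  }
  invisible(list(report = report, profile_pre = prof_pre,
                 profile_post = prof_post, region = region,
                 manifest = manifest))
}

#' Plot an MFA profile
#'
#' Scatter of per-window log2 ratios against chromosomal position (Mb) with
#' the loess curve overlaid in gray and oriC / Ter annotations, in the style
#' of published MFA figures.
#'
#' @param profile An `mfa_profile`.
#' @param map Optional `chromosome_map` supplying annotations.
#' @param path Optional output path (`.png`/`.svg`/`.pdf`); if `NULL` the
#'   ggplot object is returned unsaved.
#' @param point_alpha Scatter transparency.
#' @return The ggplot object, invisibly when saved.
#' @export
plot_profile <- function(profile, map = NULL, path = NULL, point_alpha = 0.25) {
  stopifnot(inherits(profile, "mfa_profile"))
  df <- data.frame(mb = profile$window_centers / 1e6,
                   log2_ratio = profile$log2_ratio, loess = profile$loess)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mb)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$log2_ratio),
                        size = 0.3, alpha = point_alpha, colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$loess),
                       colour = "gray40", linewidth = 0.8) +
    ggplot2::labs(x = "Genomic position (Mb)",
                  y = expression(Log[2] ~ "normalized read count"),
                  title = profile$sample_id) +
    ggplot2::theme_bw()
  if (!is.null(map) && inherits(map, "chromosome_map")) {
    ann <- data.frame(
      mb = c(map$oriC, vapply(map$ter_sites, `[[`, numeric(1),
                              "position")) / 1e6,
      label = c("oriC", vapply(map$ter_sites, `[[`, character(1), "name"))
    )
    if (nrow(ann)) {
      p <- p +
        ggplot2::geom_vline(data = ann,
                            ggplot2::aes(xintercept = .data$mb),
                            linetype = "dashed", colour = "gray60",
                            linewidth = 0.3) +
        ggplot2::geom_text(data = ann,
                           ggplot2::aes(x = .data$mb, label = .data$label),
                           y = Inf, vjust = 1.2, size = 2.8,
                           colour = "gray30")
    }
  }
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = 8, height = 3.2, dpi = 150)
    return(invisible(p))
  }
  p
}
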