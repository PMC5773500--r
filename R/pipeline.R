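# Pipeline orchestration: one YAML/list config drives simulate -> correlate
# -> fit -> N&B -> zones -> report, or the 3D-segmentation and image-pCF
# chains, with a machine-readable manifest for reproducibility.

child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 777771 * k) %% 2147483629)
}

#' Build a [simulation_config()] from a plain list (YAML block)
#'
#' @param x Named list mirroring the [simulation_config()] arguments, with
#'   `species` a list of lists and optional `barrier` / `lamina` lists.
#' @return A `simulation_config`.
#' @export
simulation_config_from_list <- function(x) {
  species <- lapply(x$species, function(s) do.call(species_spec, s))
  barrier <- if (!is.null(x$barrier)) do.call(barrier_spec, x$barrier)
  lamina <- if (!is.null(x$lamina)) do.call(lamina_spec, x$lamina)
  args <- x[setdiff(names(x), c("species", "barrier", "lamina"))]
  do.call(simulation_config,
          c(list(species = species, barrier = barrier, lamina = lamina),
            args))
}

validate_pipeline_config <- function(config) {
  problems <- character(0)
  modes <- c("simulate", "carpet", "seg3d", "imagepcf")
  if (is.null(config$mode) || !config$mode %in% modes)
    problems <- c(problems, sprintf("mode must be one of: %s",
                                    paste(modes, collapse = ", ")))
  if (is.null(config$outdir))
    problems <- c(problems, "outdir is required")
  for (f in c("carpet", "stack", "nucleus_mask")) {
    p <- config$input[[f]]
    if (!is.null(p) && !file.exists(p))
      problems <- c(problems, sprintf("input file not found: %s (%s)", p, f))
  }
  if (identical(config$mode, "carpet") &&
      is.null(config$input$carpet) && is.null(config$simulation))
    problems <- c(problems, "carpet mode needs input$carpet or a simulation block")
  if (identical(config$mode, "simulate") && is.null(config$simulation))
    problems <- c(problems, "simulate mode needs a simulation block")
  if (identical(config$mode, "imagepcf") &&
      is.null(config$input$stack) && is.null(config$simulation))
    problems <- c(problems, "imagepcf mode needs input$stack or a simulation block")
  problems
}

#' Run an analysis pipeline from a config
#'
#' Validates the whole config up front (all problems reported at once),
#' then executes one of the modes:
#' \describe{
#'   \item{simulate}{generate a line-scan carpet and write TIFF + sidecar}
#'   \item{carpet}{lamina detection, zone assignment, ACF + pCF carpets,
#'     per-column FCS fits, fast/slow N&B, joint partition, zone summary,
#'     brightness-vs-distance histogram}
#'   \item{seg3d}{3D watershed segmentation, distances to the nucleus,
#'     distance-binned summary}
#'   \item{imagepcf}{per-channel and cross-channel pCF amplitude maps,
#'     overlay colocalization, NE profile}
#' }
#' A `manifest.json` is written with the config, seed, package version and
#' the unit/interpretation decisions in force. With a fixed seed, rerunning
#' reproduces all numeric outputs.
#'
#' @param config Path to a YAML file or an equivalent named list.
#' @param outdir Output directory (overrides `config$outdir`).
#' @param seed Integer seed (overrides `config$seed`).
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config, outdir = NULL, seed = NULL) {
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- yaml::read_yaml(config)
  }
  if (!is.null(outdir)) config$outdir <- outdir
  if (!is.null(seed)) config$seed <- seed
  problems <- validate_pipeline_config(config)
  if (length(problems))
    stop("pipeline config invalid:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  params <- config$params
  decisions <- c(
    "distance bins interpreted in micrometres (0.5 um default)",
    "NE zone width primary unit is pixels; nm conversion reported from pixel_size_nm")

  get_carpet <- function() {
    if (!is.null(config$input$carpet)) {
      read_carpet(config$input$carpet, config$input$carpet_sidecar)
    } else {
      sim <- simulation_config_from_list(config$simulation)
      sim$seed <- child_seed(seed, 1)
      carp <- simulate_carpet(sim)
      write_carpet(carp, file.path(out, "carpet.tif"))
      carp
    }
  }

  if (config$mode == "simulate") {
    sim <- simulation_config_from_list(config$simulation)
    sim$seed <- child_seed(seed, 1)
    carp <- simulate_carpet(sim)
    write_carpet(carp, file.path(out, "carpet.tif"))
  } else if (config$mode == "carpet") {
    carp <- get_carpet()
    lamin_ch <- params$lamin_channel %||% 1
    part_ch <- params$particle_channel %||% 2
    lam <- detect_lamina(carp, lamin_channel = lamin_ch)
    orient <- params$orientation %||%
      infer_orientation(carp, lam$lamina_px, part_ch)$orientation
    zm <- assign_zones(lam, ne_half_width_px = params$ne_half_width_px %||% 11,
                       orientation = orient,
                       n_pixels = dim(carp$data)[2],
                       pixel_size_nm = carp$pixel_size_nm)
    model <- do.call(fcs_model_config, as.list(params$fcs %||% list()))
    fits <- fit_carpet_acf(carp, model, channel = part_ch)
    write_results_table(fits, file.path(out, "fcs_fits.csv"))
    write_correlation_carpet(attr(fits, "acf"), file.path(out, "acf_carpet.tif"))
    pcf_d <- params$pcf_d %||% 20
    pc <- pcf_carpet(carp, d = pcf_d, channel_a = part_ch)
    write_correlation_carpet(pc, file.path(out, "pcf_carpet.tif"))
    # canonical schemes (300-line fast segments, 100-line slow averaging),
    # shrunk proportionally for short carpets
    nl <- dim(carp$data)[1]
    fast_bl <- min(300L, max(2L, floor(nl / 10)))
    slow_aw <- min(100L, max(1L, floor(nl / 200)))
    slow_bl <- min(100L, floor(nl / slow_aw))
    nb_f <- nb_compute(carp, nb_scheme("fast", block_lines = fast_bl),
                       channel = part_ch)
    nb_s <- nb_compute(carp, nb_scheme("slow", average_window = slow_aw,
                                       block_lines = slow_bl),
                       channel = part_ch)
    write_results_table(nb_aggregate(nb_f), file.path(out, "nb_fast.csv"))
    write_results_table(nb_aggregate(nb_s), file.path(out, "nb_slow.csv"))
    joint <- joint_speed_partition(nb_f, nb_s, fits)
    write_results_table(joint, file.path(out, "nb_joint.csv"))
    zs <- zone_statistics(fits, zm)
    write_results_table(zs, file.path(out, "zone_summary.csv"))
    zsc <- zone_statistics(fits, zm, by_class = TRUE)
    write_results_table(zsc, file.path(out, "zone_summary_by_class.csv"))
    bh <- brightness_vs_distance(nb_s, zm, carp$pixel_size_nm,
                                 bin_width_um = params$bin_width_um %||% 0.25)
    write_results_table(bh, file.path(out, "brightness_vs_distance.csv"))
    jsonlite::write_json(
      list(lamina_px = lam$lamina_px, subpixel = lam$subpixel,
           orientation = orient, labels = zm$labels,
           ne_half_width_px = zm$ne_half_width_px,
           ne_width_nm = zm$ne_width_nm),
      file.path(out, "zones.json"), auto_unbox = TRUE, digits = NA)
  } else if (config$mode == "seg3d") {
    if (!is.null(config$input$stack)) {
      st <- read_stack3d(config$input$stack, config$input$stack_sidecar)
      stack <- st$stack; vs <- st$voxel_size_nm
      nmask <- if (!is.null(config$input$nucleus_mask))
        read_stack3d(config$input$nucleus_mask)$stack > 0.5
    } else {
      simp <- config$simulation
      field <- do.call(simulate_sphere_field,
                       c(simp, list(seed = child_seed(seed, 2))))
      stack <- field$stack; vs <- field$voxel_size_nm
      nmask <- field$nucleus_mask
      write_results_table(field$truth, file.path(out, "sphere_truth.csv"))
    }
    seg <- segment_particles(stack, voxel_size_nm = vs,
                             threshold = params$threshold,
                             min_voxels = params$min_voxels %||% 5)
    objs <- seg$objects
    if (!is.null(nmask) && nrow(objs) > 0) {
      objs <- distance_to_nucleus(objs, nmask, vs)
      bins <- bin_by_distance(objs, params$bin_width_um %||% 0.5)
      write_results_table(bins, file.path(out, "distance_bins.csv"))
    }
    write_results_table(objs, file.path(out, "objects.csv"))
    write_stack3d(seg$labels, vs, file.path(out, "labels.tif"))
  } else if (config$mode == "imagepcf") {
    if (!is.null(config$input$stack)) {
      stk <- read_image_stack(config$input$stack, config$input$stack_sidecar)
    } else {
      sim <- simulation_config_from_list(config$simulation)
      sim$seed <- child_seed(seed, 3)
      stk <- simulate_cotransport_stack(
        sim, n_frames = config$n_frames %||% 512,
        cotransport_fraction = config$cotransport_fraction %||% 0)
    }
    d_px <- params$d_px %||% 4
    m1 <- pcf_image_map(stk, d_px = d_px, channel_pair = c(1, 1))
    m2 <- pcf_image_map(stk, d_px = d_px, channel_pair = c(2, 2))
    mx <- cross_pcf_map(stk, d_px = d_px)
    for (nm in c("pcf_ch1", "pcf_ch2", "pcf_cross")) {
      mm <- switch(nm, pcf_ch1 = m1, pcf_ch2 = m2, pcf_cross = mx)
      v <- mm$values; v[!is.finite(v)] <- 0
      utils::write.csv(v, file.path(out, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    ov <- overlay_pcf_maps(m1, m2, apply(stk$data[, , , 1], c(2, 3), mean))
    ne_col <- params$ne_col %||% floor(ncol(m1$values) / 2)
    prof <- profile_across_ne(m1, m2, ne_col = ne_col)
    write_results_table(prof, file.path(out, "ne_profile.csv"))
    jsonlite::write_json(
      list(colocalization_score = ov$score,
           cross_map_mean = mean(mx$values, na.rm = TRUE),
           separation_nm = mx$separation_nm),
      file.path(out, "imagepcf_summary.json"), auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    mode = config$mode, seed = seed,
    package_version = as.character(utils::packageVersion("carpetFCS")),
    config = config[setdiff(names(config), "outdir")],
    config_md5 = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NULL,
    decisions = decisions)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render standard report figures from a pipeline run directory
#'
#' Produces (where the underlying artifacts exist): a pseudocolor ACF/pCF
#' carpet with logarithmic time axis, zone boxplots of fitted D, the
#' brightness-vs-distance histogram, and N&B column maps. Missing
#' artifacts yield a partial report with warnings rather than an error.
#'
#' @param run_dir Directory written by [run_pipeline()].
#' @param format `"png"` or `"pdf"`.
#' @return Invisibly, character vector of figure paths written.
#' @export
report_run <- function(run_dir, format = c("png", "pdf")) {
  format <- match.arg(format)
  figs <- character(0)
  save_fig <- function(p, name, width = 6, height = 4) {
    path <- file.path(run_dir, paste0(name, ".", format))
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 120)
    figs <<- c(figs, path)
  }
  fits_path <- file.path(run_dir, "fcs_fits.csv")
  zones_path <- file.path(run_dir, "zones.json")
  if (file.exists(fits_path) && file.exists(zones_path)) {
    fits <- read_results_table(fits_path)
    zj <- jsonlite::read_json(zones_path, simplifyVector = TRUE)
    df <- fits[fits$valid, , drop = FALSE]
    df$zone <- factor(zj$labels[df$column + 1],
                      levels = c("cytoplasm", "NE", "nucleoplasm"))
    if (nrow(df) > 0) {
      p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$zone,
                                            y = .data$D_um2_s)) +
        ggplot2::geom_boxplot(outlier.size = 0.6) +
        ggplot2::stat_summary(fun = mean, geom = "point", shape = 4,
                              size = 2) +
        ggplot2::labs(y = expression(D ~ (mu * m^2 / s)), x = NULL) +
        ggplot2::theme_bw()
      save_fig(p, "zone_boxplot")
    } else warning("no valid fits: zone boxplot skipped")
  } else warning("fit table or zones missing: boxplot skipped")
  for (nm in c("acf_carpet", "pcf_carpet")) {
    tp <- file.path(run_dir, paste0(nm, ".tif"))
    if (!file.exists(tp)) { warning(nm, " missing: carpet figure skipped"); next }
    cc <- read_correlation_carpet(tp)
    df <- expand.grid(column = seq_len(nrow(cc$values)) - 1,
                      lag_i = seq_along(cc$lag_times_s))
    df$lag_s <- cc$lag_times_s[df$lag_i]
    df$value <- as.numeric(cc$values)[(df$lag_i - 1) * nrow(cc$values) +
                                        df$column + 1]
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$lag_s,
                                          fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_y_log10() +
      ggplot2::scale_fill_viridis_c(na.value = "grey80") +
      ggplot2::labs(x = "pixel along scan", y = "lag time (s)",
                    fill = "G") +
      ggplot2::theme_bw()
    save_fig(p, nm)
  }
  bh_path <- file.path(run_dir, "brightness_vs_distance.csv")
  if (file.exists(bh_path)) {
    bh <- read_results_table(bh_path)
    if (nrow(bh) > 0) {
      p <- ggplot2::ggplot(bh, ggplot2::aes(x = .data$bin_mid_um,
                                            y = .data$mean_B)) +
        ggplot2::geom_col() +
        ggplot2::geom_errorbar(ggplot2::aes(
          ymin = .data$mean_B - .data$sem_B,
          ymax = .data$mean_B + .data$sem_B), width = 0.05) +
        ggplot2::labs(x = "distance from lamina (um, cytoplasm < 0)",
                      y = "mean brightness B") +
        ggplot2::theme_bw()
      save_fig(p, "brightness_vs_distance")
    }
  }
  invisible(figs)
}

#' Read a correlation carpet written by [write_correlation_carpet()]
#' @param path TIFF path.
#' @param sidecar_path JSON sidecar path.
#' @return A `correlation_carpet`.
#' @export
read_correlation_carpet <- function(path, sidecar_path = NULL) {
  if (is.null(sidecar_path)) sidecar_path <- paste0(path, ".json")
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  scale <- required_field(meta, "value_scale")
  v <- (tiff::readTIFF(path) - 0.5) * 2 * scale
  structure(list(values = v, lag_times_s = meta$lag_times_s,
                 lags = meta$lags, valid = meta$valid,
                 distance_px = meta$distance_px, mode = meta$mode,
                 direction = meta$direction,
                 pixel_size_nm = meta$pixel_size_nm,
                 separation_nm = meta$separation_nm),
            class = "correlation_carpet")
}
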