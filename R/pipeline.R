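#' Pipeline configuration
#'
#' Nested configuration for the end-to-end analysis, with defaults that
#' reproduce the reference device: 100 um core diameter, 37.5 um AlN
#' shell, 293 mT bias, 126/188 MHz drive tones from a 100 mA coil pair
#' separated by 800 um, structural losses 1e-4.  Serializable to YAML.
#'
#' @param ... Named overrides merged over the defaults, e.g.
#'   `drive = list(f1 = 100e6)`.
#' @return Object of class `pipeline_config` (nested named list).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    geometry = list(core_radius = 50e-6, shell_thickness = 37.5e-6,
                    coil_separation = 800e-6, coil_radius = 400e-6,
                    coil_current = 0.1),
    drive = list(f1 = 126e6, f2 = 188e6, bias_B = 0.293,
                 duration = NULL, sample_rate = NULL,
                 amplitude_override = NULL),
    bias_sweep = list(B_min = -1, B_max = 1, n = 201),
    modes = list(f_min = 30e6, f_max = 240e6, l_max = 6,
                 min_separation = 40e6),
    resonator = list(enabled = FALSE, mode_frequency = 62e6,
                     quality_factor = 5000),
    hh = list(interface_resistance = 0.45e6, effective_area = 1e-8,
              lowpass_cutoff = 100e6, time_scale_factor = 1e6,
              electrode_separation = 3e-6,
              peaks = seq(1, 20, by = 1), duration_ms = 1000,
              stimulus_beats = 93),
    output = list(directory = NULL),
    random_seed = 1L)
  over <- list(...)
  cfg <- defaults
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], over[[nm]], keep.null = TRUE)
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

.drive_from_config <- function(cfg) {
  d <- cfg$drive; g <- cfg$geometry
  drive_spec(f1 = d$f1, f2 = d$f2,
             coil_current = g$coil_current, coil_radius = g$coil_radius,
             coil_separation = g$coil_separation, bias_B = d$bias_B,
             duration = d$duration, sample_rate = d$sample_rate,
             amplitude_override = d$amplitude_override)
}

#' Run the full analysis pipeline
#'
#' Executes the three-step methodology end to end: (1) DC bias sweep of
#' the magnetostriction and optimal-bias identification; (2) eigenmode
#' search of the core sphere and drive-pair selection; (3) two-tone
#' demodulation with the air-medium control; then the coupling
#' coefficient at the operating bias and the membrane amplitude sweep of
#' the demodulated stimulus.  Any stage failure halts with an error
#' naming the stage.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for the JSON report and CSV
#'   tables.
#' @return Object of class `pipeline_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  core_mat <- metglas_material()
  shell_mat <- aln_material()
  geom <- core_shell_geometry(
    core_radius = config$geometry$core_radius,
    shell_thickness = config$geometry$shell_thickness,
    coil_separation = config$geometry$coil_separation,
    coil_radius = config$geometry$coil_radius,
    coil_current = config$geometry$coil_current)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  bias <- stage("bias_sweep", {
    bs <- config$bias_sweep
    bias_sweep(seq(bs$B_min, bs$B_max, length.out = bs$n), core_mat)
  })

  modes <- stage("eigenmodes", {
    sphere_mode_frequencies(core_mat, geom$core_radius,
                            c(config$modes$f_min, config$modes$f_max),
                            l_max = config$modes$l_max)
  })
  pair <- stage("mode_selection", {
    select_mti_pair(modes, config$modes$min_separation)
  })

  spec <- stage("drive", .drive_from_config(config))
  resonator <- resonator_spec(config$resonator$mode_frequency,
                              config$resonator$quality_factor,
                              config$resonator$enabled)
  demod <- stage("demodulation", {
    demodulation_report(spec, core_mat,
                        if (resonator$enabled) resonator else NULL)
  })

  alpha <- stage("coupling", {
    me_coefficient_at_bias(config$drive$bias_B, core_mat, shell_mat, geom)
  })

  hh_cfg <- config$hh
  stim_spec <- stimulus_spec(
    interface_resistance = hh_cfg$interface_resistance,
    effective_area = hh_cfg$effective_area,
    lowpass_cutoff = hh_cfg$lowpass_cutoff,
    time_scale_factor = hh_cfg$time_scale_factor)
  sweep <- stage("stimulation", {
    dfr <- abs(spec$f2 - spec$f1)
    long_spec <- drive_spec(
      f1 = spec$f1, f2 = spec$f2, coil_current = spec$coil_current,
      coil_radius = spec$coil_radius,
      coil_separation = spec$coil_separation, bias_B = spec$bias_B,
      duration = hh_cfg$stimulus_beats / dfr,
      amplitude_override = spec$amplitude_override)
    i_base <- stimulation_current(
      long_spec, core_mat, shell_mat, geom, stim_spec,
      resonator = if (resonator$enabled) resonator else NULL,
      electrode_separation = hh_cfg$electrode_separation)
    amplitude_sweep(i_base, peaks = hh_cfg$peaks,
                    duration_ms = hh_cfg$duration_ms)
  })

  report <- structure(list(
    bias_optimum_T = attr(bias, "optimum_bias"),
    bias_window_T = attr(bias, "optimum_window"),
    bias_curve = as.data.frame(bias),
    n_modes = nrow(modes),
    selected_pair_Hz = pair,
    configured_pair_Hz = c(f1 = spec$f1, f2 = spec$f2),
    demodulation = list(
      contrast = demod$contrast,
      core_peak_Hz = demod$core_peak$frequency,
      core_prominence_dB = demod$core_peak$prominence_db,
      air_prominence_dB = demod$air_peak$prominence_db),
    alpha_me_V_per_m_Oe = alpha,
    spike_sweep = sweep,
    spike_breakpoints = list(
      max_silent_peak_uA_cm2 = max_silent_peak(sweep),
      plateau_onset_uA_cm2 = plateau_onset(sweep)),
    provenance = list(
      config_hash = .config_hash(config),
      package_version = as.character(packageVersion("memti")),
      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    payload <- unclass(report)
    payload$bias_curve <- NULL
    payload$spike_sweep <- NULL
    jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.csv(report$bias_curve, file.path(out_dir, "bias_curve.csv"),
              row.names = FALSE)
    write.csv(report$spike_sweep, file.path(out_dir, "spike_sweep.csv"),
              row.names = FALSE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  optimum bias %.3f T (window %.3f-%.3f T)\n",
              x$bias_optimum_T, x$bias_window_T[1], x$bias_window_T[2]))
  cat(sprintf("  %d eigenmodes; selected pair %.4g / %.4g MHz\n",
              x$n_modes, x$selected_pair_Hz[1] / 1e6,
              x$selected_pair_Hz[2] / 1e6))
  cat(sprintf("  demodulation contrast: %s (core %.1f dB, air %.1f dB)\n",
              x$demodulation$contrast, x$demodulation$core_prominence_dB,
              x$demodulation$air_prominence_dB))
  cat(sprintf("  alpha_ME at bias: %.4g V/(m Oe)\n", x$alpha_me_V_per_m_Oe))
  cat(sprintf("  spike sweep: silent below %.3g uA/cm2, plateau from %.3g uA/cm2\n",
              x$spike_breakpoints$max_silent_peak_uA_cm2,
              x$spike_breakpoints$plateau_onset_uA_cm2))
  invisible(x)
}

#' Command-line entry point
#'
#' Thin wrapper over the package functions with subcommands
#' `bias-sweep`, `modes`, `demodulate`, `couple`, `stimulate`, and
#' `pipeline`.  Flags: `--config PATH` (YAML), `--out DIR`, `--f1`,
#' `--f2`, `--bias-mT`, `--shell-um`, `--scale`.
#'
#' @param args Character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status (0 on success), invisibly.
#' @export
memti_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: memti-cli <bias-sweep|modes|demodulate|couple|stimulate|pipeline>",
    "[--config PATH] [--out DIR] [--f1 HZ] [--f2 HZ] [--bias-mT X]",
    "[--shell-um X] [--scale X]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[[1]]
  rest <- args[-1]
  opt <- list(config = NULL, out = NULL, f1 = NULL, f2 = NULL,
              bias_mT = NULL, shell_um = NULL, scale = NULL)
  i <- 1
  while (i <= length(rest)) {
    key <- rest[i]
    if (!startsWith(key, "--") || i == length(rest)) {
      message("unknown or incomplete flag: ", key, "\n", usage)
      return(invisible(2L))
    }
    val <- rest[i + 1]
    nm <- gsub("-", "_", sub("^--", "", key))
    if (!nm %in% names(opt)) {
      message("unknown flag: ", key, "\n", usage)
      return(invisible(2L))
    }
    opt[[nm]] <- val
    i <- i + 2
  }
  cfg <- if (!is.null(opt$config)) {
    if (!file.exists(opt$config)) {
      message("config file not found: ", opt$config, "\n", usage)
      return(invisible(2L))
    }
    read_pipeline_config(opt$config)
  } else pipeline_config()
  if (!is.null(opt$f1)) cfg$drive$f1 <- as.numeric(opt$f1)
  if (!is.null(opt$f2)) cfg$drive$f2 <- as.numeric(opt$f2)
  if (!is.null(opt$bias_mT)) cfg$drive$bias_B <- as.numeric(opt$bias_mT) / 1e3
  if (!is.null(opt$shell_um))
    cfg$geometry$shell_thickness <- as.numeric(opt$shell_um) * 1e-6
  out <- opt$out

  status <- tryCatch({
    switch(cmd,
      "bias-sweep" = {
        bs <- cfg$bias_sweep
        curve <- bias_sweep(seq(bs$B_min, bs$B_max, length.out = bs$n))
        print(curve)
        if (!is.null(out)) {
          dir.create(out, recursive = TRUE, showWarnings = FALSE)
          write_bias_curve(curve, file.path(out, "bias_curve.csv"))
        }
        0L
      },
      "modes" = {
        m <- sphere_mode_frequencies(
          radius = cfg$geometry$core_radius,
          f_range = c(cfg$modes$f_min, cfg$modes$f_max),
          l_max = cfg$modes$l_max)
        print(m)
        if (!is.null(out)) {
          dir.create(out, recursive = TRUE, showWarnings = FALSE)
          write_mode_list(m, file.path(out, "modes.csv"))
        }
        0L
      },
      "demodulate" = {
        rep <- demodulation_report(.drive_from_config(cfg))
        print(rep)
        if (!is.null(out)) {
          dir.create(out, recursive = TRUE, showWarnings = FALSE)
          write_spectrum_csv(rep$core_spectrum,
                             file.path(out, "core_spectrum.csv"))
          write_spectrum_csv(rep$air_spectrum,
                             file.path(out, "air_spectrum.csv"))
        }
        0L
      },
      "couple" = {
        a <- me_coefficient_at_bias(
          cfg$drive$bias_B,
          geom = core_shell_geometry(
            core_radius = cfg$geometry$core_radius,
            shell_thickness = cfg$geometry$shell_thickness,
            coil_separation = cfg$geometry$coil_separation,
            coil_radius = cfg$geometry$coil_radius,
            coil_current = cfg$geometry$coil_current))
        cat(sprintf("alpha_ME = %.6g V/(m Oe) at %.3f T\n",
                    a, cfg$drive$bias_B))
        0L
      },
      "stimulate" = {
        if (!is.null(opt$scale))
          cfg$hh$peaks <- max(cfg$hh$peaks) / as.numeric(opt$scale)
        rep <- run_pipeline(cfg, out_dir = out)
        print(rep$spike_sweep)
        0L
      },
      "pipeline" = {
        rep <- run_pipeline(cfg, out_dir = out)
        print(rep)
        0L
      },
      {
        message("unknown subcommand: ", cmd, "\n", usage)
        2L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
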