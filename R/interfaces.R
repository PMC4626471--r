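# Configuration files, reproducible experiment orchestration, and report
# generation. Config files are YAML; all internal quantities are SI, and
# scalar values may carry nm / um / mm / cm / m suffixes which are converted
# on load.

.default_config_list <- function() {
  list(
    particle = list(core_material = "Fe3O4", core_radius = "50 nm",
                    shell_material = NULL, shell_thickness = "0 nm"),
    channel = list(width = "0.4 cm", length = "5.6 cm",
                   magnet_footprint = c("0.4 cm", "5.2 cm"),
                   rho_b = 1060),
    flow = list(mean_velocity = 0.10, period = 1.0,
                profile_mode = "mixed", pulsatility = 1),
    viscosity = list(eta_inf = 0.0035, d_eta = 0.025, a = 50, b = 3,
                     n_inf = 1, d_n = 0.45, c = 50, d = 4, gdot_min = 1e-3),
    magnet = list(b_rem = NULL, center = NULL, size = c("0.4 cm", "2 cm"),
                  axis = c(0, 1), assembly = NULL,
                  calibrate = list(b = 0.5, grad_b = 180)),
    blood = list(chi_b = -6.6e-7),
    sim = list(n_particles = 6000, injection_times = seq(0, 0.05, by = 0.01),
               dt = 1e-4, t_max = 5, temperature = 310, eta_drag = 0.0035,
               seed = 1, brownian = TRUE, integrator = "overdamped"))
}

#' Parse a physical quantity with an optional length-unit suffix
#'
#' Accepts numerics (returned unchanged, SI assumed) or strings such as
#' `"50 nm"`, `"2um"`, `"0.4 cm"`, `"1 mm"`, `"0.04 m"`.
#'
#' @param x numeric or character scalar/vector.
#' @return numeric value(s) in meters (or the original numeric).
#' @export
parse_quantity <- function(x) {
  if (is.numeric(x)) return(x)
  units <- c(nm = 1e-9, um = 1e-6, mm = 1e-3, cm = 1e-2, m = 1)
  vapply(x, function(s) {
    s <- trimws(s)
    m <- regmatches(s, regexec("^([-+0-9.eE]+)\\s*(nm|um|µm|mm|cm|m)?$", s))[[1]]
    if (length(m) == 0 || m[2] == "")
      stop("cannot parse quantity '", s, "'")
    v <- as.numeric(m[2])
    if (is.na(v)) stop("cannot parse quantity '", s, "'")
    u <- m[3]
    if (u == "" || is.na(u)) return(v)
    if (u == "µm") u <- "um"
    v * units[[u]]
  }, numeric(1), USE.NAMES = FALSE)
}

.check_keys <- function(user, template, path = "") {
  bad <- setdiff(names(user), names(template))
  if (length(bad))
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", bad)), collapse = ", "))
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(template[[k]]) &&
        !is.null(names(template[[k]])) && k != "injection_times")
      .check_keys(user[[k]], template[[k]], paste0(path, ".", k))
  }
}

#' Load a simulation configuration from a YAML file
#'
#' Unspecified keys fall back to the study defaults (4 mm channel, 0.10 m/s
#' mean pulsatile flow, bare 50 nm Fe3O4 core, 6000 particles, 5 s window,
#' magnet calibrated to 0.5 T / 180 T/m at the vessel center). Unknown keys
#' are rejected; all range violations found are reported together.
#'
#' @param path YAML file path, or `NULL` for the pure defaults.
#' @return a [simulation_config()].
#' @export
load_config <- function(path = NULL) {
  tpl <- .default_config_list()
  usr <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(usr)) usr <- list()
  .check_keys(usr, tpl)
  cfg <- modifyList(tpl, usr)

  errs <- character(0)
  note <- function(cond, msg) if (cond) errs <<- c(errs, msg)

  core_r <- parse_quantity(cfg$particle$core_radius)
  note(core_r <= 0, "particle.core_radius must be positive")
  sh_th <- parse_quantity(cfg$particle$shell_thickness)
  note(sh_th < 0, "particle.shell_thickness must be >= 0")
  width <- parse_quantity(cfg$channel$width)
  note(width <= 0, "channel.width must be positive")
  len <- parse_quantity(cfg$channel$length)
  note(len <= 0, "channel.length must be positive")
  fp <- parse_quantity(unlist(cfg$channel$magnet_footprint))
  note(length(fp) != 2 || fp[1] >= fp[2] || fp[1] < 0 || fp[2] > len,
       "channel.magnet_footprint must be an increasing interval within [0, channel.length]")
  note(cfg$sim$n_particles <= 0, "sim.n_particles must be positive")
  note(cfg$sim$dt <= 0, "sim.dt must be positive")
  note(cfg$sim$t_max <= 0, "sim.t_max must be positive")
  note(cfg$sim$temperature <= 0, "sim.temperature must be positive")
  if (length(errs)) stop(paste(errs, collapse = "; "))

  particle <- particle_spec(
    core = cfg$particle$core_material, core_radius = core_r,
    shell = cfg$particle$shell_material, shell_thickness = sh_th)
  geometry <- channel_geometry(width = width, length = len, footprint = fp,
                               rho_b = cfg$channel$rho_b)
  waveform <- make_waveform(mean = cfg$flow$mean_velocity,
                            period = cfg$flow$period,
                            pulsatility = cfg$flow$pulsatility)
  viscosity <- do.call(viscosity_params, cfg$viscosity)
  magnet <- NULL
  if (!is.null(cfg$magnet$assembly)) {
    magnet <- lapply(cfg$magnet$assembly, function(m) {
      sz <- parse_quantity(unlist(m[c("width", "height")]))
      magnet_spec(b_rem = m$b_rem, center = parse_quantity(unlist(m$center)),
                  width = sz[1], height = sz[2], axis = unlist(m$axis))
    })
    class(magnet) <- c("magnet_assembly", "list")
  } else if (!is.null(cfg$magnet$b_rem) && !is.null(cfg$magnet$center)) {
    sz <- parse_quantity(unlist(cfg$magnet$size))
    magnet <- magnet_spec(b_rem = cfg$magnet$b_rem,
                          center = parse_quantity(unlist(cfg$magnet$center)),
                          width = sz[1], height = sz[2],
                          axis = unlist(cfg$magnet$axis))
  }
  simulation_config(
    particle = particle, geometry = geometry, waveform = waveform,
    viscosity = viscosity, magnet = magnet,
    blood = blood_magnetics(chi_b = cfg$blood$chi_b),
    b_target = cfg$magnet$calibrate$b,
    grad_target = cfg$magnet$calibrate$grad_b,
    n_particles = cfg$sim$n_particles,
    injection_times = unlist(cfg$sim$injection_times),
    dt = cfg$sim$dt, t_max = cfg$sim$t_max,
    temperature = cfg$sim$temperature, eta_drag = cfg$sim$eta_drag,
    seed = cfg$sim$seed,
    brownian = cfg$sim$brownian, integrator = cfg$sim$integrator,
    profile_mode = cfg$flow$profile_mode)
}

.magnet_fields <- function(magnet) {
  if (inherits(magnet, "magnet_spec"))
    list(b_rem = magnet$b_rem, center = magnet$center,
         size = c(magnet$width, magnet$height), axis = magnet$axis)
  else
    list(assembly = lapply(magnet, function(m)
      m[c("b_rem", "center", "width", "height", "axis")]))
}

#' Write a normalized configuration file
#'
#' Serializes a resolved [simulation_config()] back to YAML in SI units.
#' `load_config(dump_config(cfg, f))` reproduces an equivalent configuration.
#'
#' @param config a [simulation_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  out <- list(
    particle = list(core_material = config$particle$core,
                    core_radius = config$particle$core_radius,
                    shell_material = config$particle$shell,
                    shell_thickness = config$particle$shell_thickness),
    channel = list(width = config$geometry$width,
                   length = config$geometry$length,
                   magnet_footprint = config$geometry$footprint,
                   rho_b = config$geometry$rho_b),
    flow = list(mean_velocity = config$waveform$mean,
                period = config$waveform$period,
                profile_mode = config$profile_mode,
                pulsatility = config$waveform$pulsatility),
    viscosity = unclass(config$viscosity),
    magnet = .magnet_fields(config$magnet),
    blood = list(chi_b = config$blood$chi_b),
    sim = list(n_particles = config$n_particles,
               injection_times = config$injection_times,
               dt = config$dt, t_max = config$t_max,
               temperature = config$temperature, eta_drag = config$eta_drag,
               seed = config$seed,
               brownian = config$brownian, integrator = config$integrator))
  yaml::write_yaml(out, path, precision = 12)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record of the fully resolved configuration, seed, and package
#' version; together with the package version it suffices to regenerate
#' every output bit-exactly.
#'
#' @param config a [simulation_config()].
#' @param path output JSON path.
#' @param outputs named list/vector of result file paths to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, outputs = list()) {
  man <- list(
    tool = "mdtsim",
    version = as.character(utils::packageVersion("mdtsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    outputs = outputs,
    config = list(
      particle = config$particle[c("core", "core_radius", "shell",
                                   "shell_thickness")],
      magnet = .magnet_fields(config$magnet),
      channel = config$geometry[c("width", "length", "footprint", "rho_b")],
      flow = list(mean = config$waveform$mean,
                  period = config$waveform$period,
                  coefficients = config$waveform$coef,
                  profile_mode = config$profile_mode),
      viscosity = unclass(config$viscosity),
      sim = config[c("n_particles", "injection_times", "dt", "t_max",
                     "temperature", "eta_drag", "brownian", "integrator")]))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Reproduce the size- and coating-dependence figures
#'
#' Runs the core-size sweep over a log-spaced radius grid (10 nm to 2 um)
#' and the coating sweep (Au, SiO2, PEG shells of 5 to 50 nm on 50 nm and
#' 500 nm cores), writing CSV tables, PNG figures with binomial error bars,
#' and a JSON manifest to `out_dir`. `scale = "desk"` uses reduced particle
#' counts and grids; `scale = "full"` uses the complete study conditions.
#'
#' @param out_dir output directory (created if needed).
#' @param scale `"desk"` or `"full"`.
#' @param config base [simulation_config()]; defaults to the study
#'   conditions.
#' @param radii,thicknesses,core_sizes optional overrides (m) of the
#'   scale-determined sweep grids.
#' @param n_particles optional override of the scale-determined particle
#'   count.
#' @return named list of output file paths, invisibly.
#' @export
reproduce_figures <- function(out_dir, scale = c("desk", "full"),
                              config = NULL, radii = NULL,
                              thicknesses = NULL, core_sizes = NULL,
                              n_particles = NULL) {
  scale <- match.arg(scale)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config)) config <- simulation_config()
  if (scale == "desk") {
    config$n_particles <- 600L
    if (is.null(radii))
      radii <- 10^seq(log10(10e-9), log10(2e-6), length.out = 7)
    if (is.null(thicknesses)) thicknesses <- c(5e-9, 25e-9, 50e-9)
    if (is.null(core_sizes)) core_sizes <- c(50e-9, 500e-9)
  } else {
    if (is.null(radii))
      radii <- 10^seq(log10(10e-9), log10(2e-6), length.out = 15)
    if (is.null(thicknesses)) thicknesses <- seq(5e-9, 50e-9, by = 5e-9)
    if (is.null(core_sizes)) core_sizes <- c(50e-9, 500e-9)
  }
  if (!is.null(n_particles)) config$n_particles <- as.integer(n_particles)

  size_tab <- sweep_core_size(config, radii)
  f_size_csv <- file.path(out_dir, "capture_vs_core_size.csv")
  write.csv(size_tab, f_size_csv, row.names = FALSE)

  coat_tabs <- lapply(core_sizes, function(rc) {
    cfg <- config
    cfg$particle <- particle_spec(core = config$particle$core,
                                  core_radius = rc)
    tab <- sweep_coating(cfg, thicknesses = thicknesses)
    tab$core_radius_m <- rc
    tab
  })
  coat_tab <- do.call(rbind, coat_tabs)
  f_coat_csv <- file.path(out_dir, "capture_vs_coating.csv")
  write.csv(coat_tab, f_coat_csv, row.names = FALSE)

  f_size_png <- file.path(out_dir, "capture_vs_core_size.png")
  grDevices::png(f_size_png, width = 900, height = 600)
  with(size_tab, {
    plot(radius_m * 1e9, efficiency_pct, log = "x", type = "b", pch = 19,
         xlab = "core radius (nm)", ylab = "capture efficiency (%)",
         main = "Capture efficiency vs core size", ylim = c(0, 100))
    arrows(radius_m * 1e9, pmax(efficiency_pct - 2 * stderr_pct, 0),
           radius_m * 1e9, pmin(efficiency_pct + 2 * stderr_pct, 100),
           angle = 90, code = 3, length = 0.04)
  })
  grDevices::dev.off()

  f_coat_png <- file.path(out_dir, "capture_vs_coating.png")
  grDevices::png(f_coat_png, width = 900, height = 600)
  coated <- coat_tab[coat_tab$material != "none", ]
  cols <- c(Au = "goldenrod", SiO2 = "steelblue", PEG = "forestgreen")
  pchs <- c(1, 19)
  plot(range(coated$thickness_m * 1e9), range(coated$efficiency_pct),
       type = "n", xlab = "coating thickness (nm)",
       ylab = "capture efficiency (%)",
       main = "Capture efficiency vs coating (Au, SiO2, PEG)")
  for (i in seq_along(core_sizes)) {
    sub <- coated[coated$core_radius_m == core_sizes[i], ]
    for (m in unique(sub$material)) {
      s2 <- sub[sub$material == m, ]
      graphics::lines(s2$thickness_m * 1e9, s2$efficiency_pct,
                      col = cols[[m]], type = "b", pch = pchs[i])
    }
  }
  graphics::legend("topright",
                   legend = c(names(cols), paste0("core ",
                              round(core_sizes * 1e9), " nm")),
                   col = c(cols, rep("black", length(core_sizes))),
                   pch = c(19, 19, 19, pchs[seq_along(core_sizes)]),
                   bty = "n")
  grDevices::dev.off()

  f_man <- file.path(out_dir, "manifest.json")
  write_manifest(config, f_man,
                 outputs = list(size_csv = f_size_csv, coating_csv = f_coat_csv,
                                size_png = f_size_png, coating_png = f_coat_png))
  invisible(list(size_csv = f_size_csv, coating_csv = f_coat_csv,
                 size_png = f_size_png, coating_png = f_coat_png,
                 manifest = f_man, size_table = size_tab,
                 coating_table = coat_tab))
}

#' Export or import a waveform as CSV (t, v) samples
#'
#' @param w a [make_waveform()] object.
#' @param path CSV path.
#' @param n number of samples over one period.
#' @return `path` invisibly (export); data.frame (import).
#' @export
write_waveform_csv <- function(w, path, n = 201) {
  t <- seq(0, w$period, length.out = n)
  write.csv(data.frame(t = t, v = mean_velocity(t, w)), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path) read.csv(path)
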