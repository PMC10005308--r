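# Run configuration, the analysis pipeline, and the provenance manifest.

#' Build and validate a run configuration
#'
#' @param trajectory path to a trajectory file readable by
#'   [load_trajectory()] (optional when `traj` is passed to
#'   [run_pipeline()] directly).
#' @param analyses character vector of stages to run; any of `"area"`,
#'   `"thickness"`, `"tilt"`, `"proximity_tilt"`, `"transverse"`,
#'   `"density"`, `"scd"`, `"rdf"`, `"msd"`, `"acf"`, `"pmf"`.
#' @param outdir output directory.
#' @param discard equilibration discard in ns; frames with `time < discard`
#'   are excluded.
#' @param temperature temperature in K.
#' @param seed integer seed recorded in the manifest and used by any
#'   stochastic stage.
#' @param params named list of per-stage parameter lists (e.g.
#'   `params$area$n_lipids_per_leaflet`, `params$rdf$r_max`,
#'   `params$pmf$window_files`).
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(trajectory = NULL, analyses, outdir,
                       discard = 0, temperature = 298.15, seed = 1L,
                       params = list()) {
  known <- c("area", "thickness", "tilt", "proximity_tilt", "transverse",
             "density", "scd", "rdf", "msd", "acf", "pmf")
  bad <- setdiff(analyses, known)
  if (length(bad)) stop("unknown analyses: ", paste(bad, collapse = ", "))
  stopifnot_scalar(discard, "discard", nonneg = TRUE)
  stopifnot_scalar(temperature, "temperature", positive = TRUE)
  if (!is.numeric(seed) || seed != as.integer(seed)) stop("seed must be an integer")
  if (!is.null(trajectory) && !file.exists(trajectory))
    stop("trajectory path not resolvable: ", trajectory)
  structure(list(trajectory = trajectory, analyses = analyses,
                 outdir = outdir, discard = discard,
                 temperature = temperature, seed = as.integer(seed),
                 params = params),
            class = "run_config")
}

write_tidy_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages on one trajectory (and, for the PMF stage,
#' on umbrella window files), writing tidy CSV outputs, a JSON summary and a
#' provenance manifest (config hash, package version, seed) to
#' `config$outdir`. Outputs are deterministic given the configuration and
#' seed. Stage failures are re-raised with the stage name.
#'
#' @param config a [run_config()] object.
#' @param traj optional pre-loaded `"traj"` object (overrides
#'   `config$trajectory`).
#' @return Named list of stage results plus `files` (written paths),
#'   invisibly.
#' @export
run_pipeline <- function(config, traj = NULL) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  needs_traj <- length(setdiff(config$analyses, "pmf")) > 0
  if (needs_traj) {
    if (is.null(traj)) {
      if (is.null(config$trajectory)) stop("no trajectory provided")
      traj <- load_trajectory(config$trajectory)
    }
    if (config$discard >= max(traj$time))
      stop("equilibration discard (", config$discard,
           " ns) is not shorter than the trajectory duration")
    traj <- subset_time(traj, config$discard)
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  P <- config$params
  results <- list(); files <- character(0); summary <- list()

  stage <- function(name, fn) {
    message(sprintf("[%s] running", name))
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done in %.2f s", name, proc.time()[["elapsed"]] - t0))
    r
  }

  for (an in config$analyses) {
    res <- switch(an,
      area = stage("area", function() {
        nl <- P$area$n_lipids_per_leaflet
        if (is.null(nl)) stop("params$area$n_lipids_per_leaflet required")
        s <- compute_area_per_lipid(traj, nl)
        files <<- c(files, write_tidy_csv(
          data.frame(frame = seq_along(s$series), time = traj$time,
                     area_per_lipid_nm2 = s$series),
          file.path(config$outdir, "area_per_lipid.csv")))
        summary$area <<- list(mean_nm2 = s$mean, ci95_nm2 = s$ci)
        s
      }),
      thickness = stage("thickness", function() {
        s <- compute_thickness_dPP(traj,
                                   atom = P$thickness$atom %||% "P")
        files <<- c(files, write_tidy_csv(
          data.frame(frame = seq_along(s$series), time = traj$time,
                     d_PP_nm = s$series),
          file.path(config$outdir, "thickness_dpp.csv")))
        summary$thickness <<- list(mean_nm = s$mean, ci95_nm = s$ci)
        s
      }),
      tilt = stage("tilt", function() {
        d <- compute_tilt_distribution(traj,
               species = P$tilt$species %||% "LIP",
               bin_width = P$tilt$bin_width %||% 1)
        mid <- (d$edges[-1] + d$edges[-length(d$edges)]) / 2
        files <<- c(files, write_tidy_csv(
          data.frame(bin_center_deg = mid, density = d$density,
                     group = d$label),
          file.path(config$outdir, "tilt_distribution.csv")))
        summary$tilt <<- list(mean_deg = d$mean, variance_deg2 = d$variance,
                              n = d$n)
        d
      }),
      proximity_tilt = stage("proximity_tilt", function() {
        r <- compute_proximity_binned_tilts(traj,
               lipid_species = P$proximity_tilt$lipid_species %||% "LIP",
               probe_species = P$proximity_tilt$probe_species %||% "PRB",
               R_edges = P$proximity_tilt$R_edges %||% c(0.7, 1.2))
        rows <- do.call(rbind, lapply(c("near", "mid", "far"), function(b) {
          d <- r[[b]]
          mid <- (d$edges[-1] + d$edges[-length(d$edges)]) / 2
          data.frame(bin_center_deg = mid, density = d$density, group = b)
        }))
        files <<- c(files, write_tidy_csv(rows,
          file.path(config$outdir, "proximity_tilt.csv")))
        summary$proximity_tilt <<- list(
          variance_near = r$near$variance, variance_mid = r$mid$variance,
          variance_far = r$far$variance,
          sd_increase_percent = if (isTRUE(r$far$variance > 0))
            sd_increase_percent(r$far$variance, r$near$variance) else NA)
        r
      }),
      transverse = stage("transverse", function() {
        g <- P$transverse$groups
        if (is.null(g)) stop("params$transverse$groups required")
        d <- compute_transverse_positions(traj, g)
        files <<- c(files, write_tidy_csv(d,
          file.path(config$outdir, "transverse_positions.csv")))
        summary$transverse <<- d
        d
      }),
      density = stage("density", function() {
        d <- compute_density_profile(traj,
               species = P$density$species,
               bin_width = P$density$bin_width %||% 0.1)
        files <<- c(files, write_tidy_csv(as.data.frame(d),
          file.path(config$outdir, "density_profile.csv")))
        d
      }),
      scd = stage("scd", function() {
        d <- compute_scd_profile(traj, species = P$scd$species %||% "LIP")
        files <<- c(files, write_tidy_csv(as.data.frame(d),
          file.path(config$outdir, "scd_profile.csv")))
        d
      }),
      rdf = stage("rdf", function() {
        pr <- P$rdf
        if (is.null(pr$ref_sel) || is.null(pr$sel) || is.null(pr$r_max))
          stop("params$rdf needs ref_sel, sel and r_max")
        d <- compute_rdf(traj, pr$ref_sel, pr$sel, pr$r_max,
                         bin_width = pr$bin_width %||% 0.01)
        files <<- c(files, write_tidy_csv(as.data.frame(d),
          file.path(config$outdir, "rdf.csv")))
        d
      }),
      msd = stage("msd", function() {
        pr <- P$msd
        if (is.null(pr$sel)) stop("params$msd$sel required")
        d <- compute_msd(traj, sel = pr$sel,
                         leaflet_com_removal = pr$leaflet_com_removal %||% TRUE)
        files <<- c(files, write_tidy_csv(as.data.frame(d),
          file.path(config$outdir, "msd.csv")))
        est <- estimate_dlat(d)
        summary$msd <<- list(D_lat_cm2_s = est$D_lat,
                             r_squared = est$r_squared)
        list(msd = d, dlat = est)
      }),
      acf = stage("acf", function() {
        pr <- P$acf
        if (is.null(pr$axis_spec)) stop("params$acf$axis_spec required")
        curve <- compute_rotational_acf(traj, axis_spec = pr$axis_spec)
        fit <- fit_acf(curve)
        files <<- c(files, write_tidy_csv(
          data.frame(t_ns = curve$t, C = curve$C,
                     n_origins = curve$n_origins),
          file.path(config$outdir, "acf.csv")))
        summary$acf <<- list(a = fit$a, phi_ns = fit$phi, a_inf = fit$a_inf,
                             mean_time_ns = fit$mean_time, r_inf = fit$r_inf,
                             ssr = fit$ssr)
        list(curve = curve, fit = fit)
      }),
      pmf = stage("pmf", function() {
        pr <- P$pmf
        if (is.null(pr$window_files)) stop("params$pmf$window_files required")
        wins <- read_umbrella_windows(pr$window_files)
        prof <- wham(wins, bin_width = pr$bin_width %||% 0.05,
                     reference = pr$reference %||% "plateau",
                     water_region = pr$water_region)
        files <<- c(files, write_tidy_csv(
          data.frame(z_nm = prof$z, G_kJ_mol = prof$G, counts = prof$counts),
          file.path(config$outdir, "pmf.csv")))
        bars <- extract_barriers(prof, water_region = pr$water_region)
        kp <- partition_coefficient(bars, T = config$temperature)
        summary$pmf <<- list(dG_insert = bars$dG_insert,
                             dG_desorb = bars$dG_desorb,
                             dG_transloc = bars$dG_transloc,
                             z_min = bars$z_min, Kp = kp$Kp,
                             dG_wl = kp$dG_wl)
        list(profile = prof, barriers = bars, partition = kp)
      }))
    results[[an]] <- res
  }

  sum_path <- file.path(config$outdir, "summary.json")
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, sum_path)

  cfg_path <- file.path(config$outdir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  manifest <- list(config_hash = unname(tools::md5sum(cfg_path)),
                   package = "memprobe",
                   version = as.character(utils::packageVersion("memprobe")),
                   seed = config$seed,
                   files = basename(files))
  man_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE)
  results$files <- c(files, cfg_path, man_path)
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
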