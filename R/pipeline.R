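# Pipeline surface: validated run configuration, composable stages
# (simulate -> correlate -> frames -> detectors -> landscape), attribute
# export for molecular viewers, and the command-line entry point.

#' Run configuration
#'
#' Validates and normalizes a pipeline configuration before any
#' computation. The configuration (or the relevant subset) is serialized
#' into the output directory together with a log of package version, seed
#' and all tunable parameter values, so every run is reproducible.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed funneling all randomness.
#' @param simulate,correlate,frames,detectors,landscape Per-stage parameter
#'   lists (see the pipeline vignette); stages set to \code{NULL} are
#'   skipped.
#' @return A validated \code{run_config} object.
#' @export
run_config <- function(out_dir, seed = 1L, simulate = NULL, correlate = NULL,
                       frames = NULL, detectors = NULL, landscape = NULL) {
  stopifnot(is.character(out_dir), length(out_dir) == 1)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  if (!is.null(simulate)) {
    stopifnot(!is.null(simulate$model), !is.null(simulate$n_steps),
              !is.null(simulate$dt))
  }
  structure(list(out_dir = out_dir, seed = seed, simulate = simulate,
                 correlate = correlate, frames = frames,
                 detectors = detectors, landscape = landscape),
            class = "run_config")
}

config_model <- function(m) {
  switch(m$kind,
    static = motion_static(),
    isotropic_diffusion = motion_isotropic_diffusion(m$D),
    axial_diffusion = motion_axial_diffusion(m$D, m$beta),
    wobble_cone = motion_wobble_cone(m$D, m$theta0),
    power_law_distribution = motion_power_law(m$d, unlist(m$zrange)),
    n_site_jump = {
      k <- m$n_sites %||% 3
      rate <- m$rate
      Q <- matrix(rate / (k - 1), k, k); diag(Q) <- -rate
      sites <- lapply(seq_len(k) - 1,
                      function(j) rot_zyz(euler_angles(2 * pi * j / k, 0, 0)))
      motion_n_site_jump(Q, sites, bond_beta = m$bond_beta %||% acos(-1/3))
    },
    stop("unknown model kind in config: ", m$kind))
}

write_run_log <- function(cfg, stage, extra = list()) {
  log <- c(sprintf("stage: %s", stage),
           sprintf("dynland version: %s",
                   as.character(utils::packageVersion("dynland"))),
           sprintf("seed: %d", cfg$seed),
           sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           vapply(names(extra), function(n) {
             sprintf("%s: %s", n, paste(format(extra[[n]]), collapse = " "))
           }, character(1)))
  cat(log, file = file.path(cfg$out_dir, sprintf("%s.log", stage)),
      sep = "\n")
}

stage_path <- function(cfg, name) file.path(cfg$out_dir, name)

require_stage_file <- function(cfg, name, needed_by, produced_by) {
  p <- stage_path(cfg, name)
  if (!file.exists(p)) {
    stop(sprintf("stage `%s` needs %s; run `%s` first", needed_by, name,
                 produced_by), call. = FALSE)
  }
  p
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order. Each stage reads its inputs
#' from the previous stage's serialized outputs in \code{out_dir}, so any
#' stage can be re-run on its own. Numeric outputs are reproducible
#' bit-for-bit under a fixed seed and configuration.
#'
#' @param cfg A [run_config()] (or a list accepted by it).
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- do.call(run_config, cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(cfg, stage_path(cfg, "config.rds"))
  yaml::write_yaml(lapply(unclass(cfg), function(x) x),
                   stage_path(cfg, "config.yaml"))
  res <- list()
  if (!is.null(cfg$simulate)) {
    sc <- cfg$simulate
    inner <- config_model(sc$model)
    traj <- if (!is.null(sc$outer)) {
      compose_hierarchy(inner, config_model(sc$outer), sc$n_steps, sc$dt,
                        seed = cfg$seed, n_copies = sc$n_copies %||% 1L)
    } else {
      simulate_motion(inner, sc$n_steps, sc$dt, seed = cfg$seed,
                      n_copies = sc$n_copies %||% 1L)
    }
    saveRDS(traj, stage_path(cfg, "trajectory.rds"))
    export_trajectory(traj, stage_path(cfg, "trajectory"))
    write_run_log(cfg, "simulate",
                  list(n_steps = sc$n_steps, dt = sc$dt,
                       model = sc$model$kind,
                       outer = sc$outer$kind %||% "none"))
    res$trajectory <- traj
  }
  if (!is.null(cfg$correlate)) {
    traj <- res$trajectory %||% readRDS(
      require_stage_file(cfg, "trajectory.rds", "correlate", "simulate"))
    cc <- cfg$correlate
    grid <- lag_grid(dim(traj$vectors)[2], traj$dt,
                     scheme = cc$scheme %||% "log_spaced",
                     per_decade = cc$per_decade %||% 50L,
                     max_frac = cc$max_frac %||% 0.1)
    cs <- autocorrelation_fft(traj, grid, error = isTRUE(cc$error))
    if (dim(traj$vectors)[3] > 1) cs <- average_equivalent(cs)
    write_correlation(cs, stage_path(cfg, "correlation.tsv"))
    saveRDS(cs, stage_path(cfg, "correlation.rds"))
    write_run_log(cfg, "correlate", list(n_lags = length(grid$lags)))
    res$correlation <- cs
  }
  if (!is.null(cfg$frames)) {
    traj <- res$trajectory %||% readRDS(
      require_stage_file(cfg, "trajectory.rds", "frames", "simulate"))
    if (is.null(traj$frames)) {
      stop("frames stage needs a trajectory with recorded frame axes")
    }
    fc <- cfg$frames
    grid <- lag_grid(dim(traj$vectors)[2], traj$dt,
                     per_decade = fc$per_decade %||% 20L,
                     max_frac = fc$max_frac %||% 0.1)
    dec <- decompose_hierarchy(traj, frame_axes(traj$frames), grid)
    saveRDS(dec, stage_path(cfg, "decomposition.rds"))
    for (m in dec$motions) {
      write_correlation(m$correlation,
                        stage_path(cfg, sprintf("motion_%s.tsv", m$name)))
    }
    rt <- do.call(rbind, lapply(dec$motions, function(m) {
      data.frame(motion = m$name,
                 delta_ratio = m$residual$delta_ratio,
                 eta = m$residual$eta,
                 D2_00 = Re(m$residual$components[3]))
    }))
    utils::write.table(rt, stage_path(cfg, "residual_tensors.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_run_log(cfg, "frames",
                  list(max_product_deviation = dec$max_deviation))
    res$decomposition <- dec
  }
  if (!is.null(cfg$detectors)) {
    dc <- cfg$detectors
    n <- dc$n %||% 6L
    specs <- if (!is.null(dc$experiment_table)) {
      read_experiments(dc$experiment_table)
    } else {
      popc_experiment_set()
    }
    grid <- z_grid(dc$zmin %||% -14, dc$zmax %||% -3, dc$nz %||% 200L)
    S <- build_rate_sensitivities(specs, grid)
    dset <- optimize_detectors(S, n)
    utils::write.table(
      data.frame(z = grid$z, t(dset$rho)),
      stage_path(cfg, "detector_sensitivities.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(dset$r, stage_path(cfg, "detector_r_matrix.tsv"),
                       sep = "\t", row.names = TRUE, quote = FALSE,
                       col.names = NA)
    saveRDS(dset, stage_path(cfg, "detectors.rds"))
    write_run_log(cfg, "detectors",
                  list(n = n, centers_z = round(dset$centers, 3),
                       widths = round(dset$widths, 3)))
    res$detectors <- dset
  }
  if (!is.null(cfg$landscape)) {
    dset <- res$detectors %||% readRDS(
      require_stage_file(cfg, "detectors.rds", "landscape", "detectors"))
    dec <- res$decomposition %||% readRDS(
      require_stage_file(cfg, "decomposition.rds", "landscape", "frames"))
    lc <- cfg$landscape
    md <- build_md_sensitivities(md_lag_subset(dec$grid), dset$grid)
    mdet <- match_detectors(md, dset)
    sites <- list()
    motions <- list()
    for (m in dec$motions) {
      resp <- fit_responses(m$correlation, mdet)
      kind <- if (m$name == "overall") "gaussian" else "skewed_gaussian"
      motions[[m$name]] <- fit_motion_distribution(resp, mdet, model = kind)
    }
    sl <- site_landscape(lc$site %||% "site1", motions,
                         internal = setdiff(names(motions), "overall"),
                         grid = dset$grid)
    write_landscape(list(sl), stage_path(cfg, "landscape"))
    saveRDS(sl, stage_path(cfg, "landscape.rds"))
    write_run_log(cfg, "landscape", list(site = sl$site))
    res$landscape <- sl
  }
  invisible(res)
}

# log-spaced subset of positive lags suitable for detector matching
md_lag_subset <- function(grid, per_decade = 10) {
  tt <- grid$times[grid$times > 0]
  lo <- log10(min(tt)); hi <- log10(max(tt))
  want <- 10^seq(lo, hi, by = 1 / per_decade)
  unique(vapply(want, function(w) tt[which.min(abs(tt - w))], numeric(1)))
}

#' Write per-atom attributes for molecular viewers
#'
#' Writes a "defattr"-style text attribute file assigning one detector
#' response (or any scalar) to each mapped atom, loadable by common
#' molecular viewers.
#'
#' @param values Named numeric vector (names = site labels).
#' @param atom_map Data frame with columns \code{site}, \code{resno},
#'   \code{name} mapping sites to atoms.
#' @param path Output path.
#' @param attribute Attribute name.
#' @return Invisibly, the path; unmapped sites are reported and skipped.
#' @export
write_attributes <- function(values, atom_map, path, attribute = "rho") {
  hdr <- c(sprintf("attribute: %s", attribute),
           "match mode: 1-to-1",
           "recipient: atoms")
  rows <- character(0)
  for (site in names(values)) {
    hit <- atom_map[atom_map$site == site, , drop = FALSE]
    if (!nrow(hit)) {
      message("site ", site, " has no mapped atom; skipped")
      next
    }
    rows <- c(rows, sprintf("\t:%d@%s\t%.6g", hit$resno, hit$name,
                            values[[site]]))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Command-line entry point
#'
#' Thin argument parser behind the \code{dynland} script
#' (\code{system.file("scripts", "dynland", package = "dynland")}):
#' subcommands \code{simulate}, \code{correlate}, \code{frames},
#' \code{detectors}, \code{landscape} and \code{pipeline} run the matching
#' stage(s) of [run_pipeline()] from a YAML config.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: dynland <simulate|correlate|frames|detectors|landscape|pipeline> --config <yaml> [--out <dir>] [--seed <int>]"
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  sub <- args[1]
  stages <- c("simulate", "correlate", "frames", "detectors", "landscape")
  if (!sub %in% c(stages, "pipeline")) {
    message("unknown subcommand: ", sub, "\n", usage)
    return(invisible(1L))
  }
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = list(
      optparse::make_option("--config", type = "character"),
      optparse::make_option("--out", type = "character", default = NULL),
      optparse::make_option("--seed", type = "integer", default = NULL))),
    args = args[-1])
  if (is.null(opts$config)) {
    message("--config is required\n", usage)
    return(invisible(1L))
  }
  raw <- yaml::read_yaml(opts$config)
  if (!is.null(opts$out)) raw$out_dir <- opts$out
  if (!is.null(opts$seed)) raw$seed <- opts$seed
  if (sub != "pipeline") {
    keep <- c("out_dir", "seed", sub)
    raw <- raw[intersect(names(raw), keep)]
  }
  status <- tryCatch({
    cfg <- do.call(run_config, raw)
    run_pipeline(cfg)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
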