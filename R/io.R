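# Canonical CSV schemas: required columns per table kind. CSV is the
# interchange format; images are one possible source feeding the same
# tables.
.gq_schemas <- list(
  cells = c("x", "y", "z", "radius", "intensity"),
  sections = c("section_id", "t_um", "BA_um"),
  points = c("section_id", "roi", "P"),
  frames = c("section_id", "roi", "frame_id", "corner_in_roi", "Q_minus"),
  soma_planes = c("soma_id", "plane_idx", "area_um2"),
  traces = c("cell_id", "t_s", "F"),
  trials = c("trial_idx", "t_s", "peak_pA"),
  qc = c("synapse_id", "t_s")
)

#' Read and write the package's CSV tables
#'
#' Thin wrappers over [utils::read.csv()] / [utils::write.csv()] that
#' validate the schema for each table kind, so errors carry row/column
#' context instead of surfacing downstream. Writers and readers round-trip
#' losslessly.
#'
#' @param path file path.
#' @param kind one of `"cells"`, `"sections"`, `"points"`, `"frames"`,
#'   `"soma_planes"`, `"traces"`, `"trials"`, `"qc"`.
#' @return `read_gq_csv`: the validated data.frame.
#' @export
read_gq_csv <- function(path, kind) {
  kind <- match.arg(kind, names(.gq_schemas))
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  if (file.size(path) == 0) stop(sprintf("input file is empty: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop(sprintf("input file has no rows: %s", path))
  missing_cols <- setdiff(.gq_schemas[[kind]], names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("%s: missing required column(s) %s for '%s' table",
                 path, paste(missing_cols, collapse = ", "), kind))
  }
  num_cols <- setdiff(.gq_schemas[[kind]],
                      c("roi", "synapse_id", "soma_id", "cell_id"))
  for (cc in num_cols) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[cc]]))))
    if (length(bad) > 0) {
      stop(sprintf("%s: non-numeric value in column '%s', row %d",
                   path, cc, bad[1]))
    }
    df[[cc]] <- as.numeric(df[[cc]])
  }
  df
}

#' @rdname read_gq_csv
#' @param df data.frame to write.
#' @export
write_gq_csv <- function(df, path, kind) {
  kind <- match.arg(kind, names(.gq_schemas))
  missing_cols <- setdiff(.gq_schemas[[kind]], names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf("cannot write '%s' table: missing column(s) %s",
                 kind, paste(missing_cols, collapse = ", ")))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Per-plane areas from a multi-page TIFF of binary masks
#'
#' Converts a z-stack of binary masks (e.g. thresholded S100B somas) into
#' the per-plane area table feeding [soma_volume()]. Pages must be binary
#' (only two levels, foreground and background); anything else is an error.
#'
#' @param path TIFF file, or a list of matrices (in-memory pages).
#' @param pixel_size_um physical pixel edge length, um.
#' @param z_spacing_um plane spacing, um (recorded on the output).
#' @return data.frame `plane_idx, area_um2` with attribute `z_spacing_um`.
#' @export
read_image_stack <- function(path, pixel_size_um = 1, z_spacing_um = 1) {
  pages <- if (is.character(path)) {
    if (!file.exists(path)) stop(sprintf("TIFF not found: %s", path))
    tiff::readTIFF(path, all = TRUE)
  } else path
  stopifnot(is.list(pages))
  areas <- vapply(seq_along(pages), function(i) {
    pg <- pages[[i]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1] # collapse identical channels
    vals <- unique(as.vector(pg))
    if (length(vals) > 2) {
      stop(sprintf("page %d is not a binary mask (%d distinct levels)",
                   i, length(vals)))
    }
    sum(pg > min(vals)) * pixel_size_um^2
  }, numeric(1))
  out <- data.frame(plane_idx = seq_along(pages), area_um2 = areas)
  attr(out, "z_spacing_um") <- z_spacing_um
  attr(out, "pixel_size_um") <- pixel_size_um
  out
}

write_metadata <- function(out_dir, config, seed) {
  meta <- list(
    package = "gliaquant",
    version = as.character(utils::packageVersion("gliaquant")),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = seed,
    config = config
  )
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(meta)
}

scrub_config <- function(cfg) {
  # drop function-valued entries (distributions) for JSON metadata
  rapply(cfg, function(x) if (is.function(x)) "<function>" else x,
         how = "replace")
}

#' Run a pipeline stage end to end
#'
#' Drives the three analysis arms from CSV inputs to CSV/JSON outputs.
#' Stages: `"simulate"` writes synthetic tables for all arms; `"stereology"`
#' consumes `sections.csv`, `points.csv`, `frames.csv` (and optionally
#' `soma_planes.csv`) and writes `estimates.csv`; `"calcium"` consumes
#' `traces.csv` and writes `events.csv` and `cell_summary.csv`; `"ephys"`
#' consumes `trials.csv` (optionally `qc.csv`) and writes
#' `synaptic_params.csv`, `outcomes.csv` and `timecourse.csv`; `"report"`
#' chains simulate and the three arms in one run directory. Every run
#' writes a `metadata.json` capturing config, seed and package version;
#' stage seeds derive deterministically from the global seed, so identical
#' seed and config reproduce simulation outputs bit-identically.
#'
#' @param stage stage name.
#' @param config named list of stage parameters (see Details in the
#'   vignette), or a YAML file path.
#' @param seed global integer seed.
#' @param out_dir output directory (created if needed).
#' @param in_dir input directory for analysis stages (defaults to
#'   `out_dir`).
#' @return Invisibly, a list of the stage's main results.
#' @export
run_pipeline <- function(stage = c("simulate", "stereology", "calcium",
                                   "ephys", "report"),
                         config = list(), seed = 1, out_dir = ".",
                         in_dir = NULL) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- yaml::read_yaml(config) %||% list()
  in_dir <- in_dir %||% out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(seed, 8L)
  res <- switch(stage,
    simulate = .stage_simulate(config, seeds, out_dir),
    stereology = .stage_stereology(config, seeds, in_dir, out_dir),
    calcium = .stage_calcium(config, seeds, in_dir, out_dir),
    ephys = .stage_ephys(config, seeds, in_dir, out_dir),
    report = {
      sim <- .stage_simulate(config, seeds, out_dir)
      st <- .stage_stereology(config, seeds, out_dir, out_dir)
      ca <- .stage_calcium(config, seeds, out_dir, out_dir)
      ep <- .stage_ephys(config, seeds, out_dir, out_dir)
      list(simulate = sim, stereology = st, calcium = ca, ephys = ep)
    }
  )
  write_metadata(out_dir, c(list(stage = stage), scrub_config(config)), seed)
  invisible(res)
}

.stage_simulate <- function(config, seeds, out_dir) {
  density <- config$density %||% 1e-4
  bounds <- config$bounds %||% c(500, 500, 240)
  field <- simulate_cell_field(density, bounds = unlist(bounds),
                               seed = seeds[1])
  tissue <- section_field(field, BA = config$BA %||% 40,
                          shrinkage = config$shrinkage %||% 0.75,
                          sampling_interval = config$sampling_interval %||% 6,
                          seed = seeds[2])
  write_gq_csv(field$cells, file.path(out_dir, "cells.csv"), "cells")
  sec <- tissue$sections
  write_gq_csv(data.frame(section_id = sec$section_id, t_um = sec$t,
                          BA_um = sec$BA, z_top_um = sec$z_top,
                          sampled = sec$sampled),
               file.path(out_dir, "sections.csv"), "sections")

  ca_cfg <- ca_sim_config(n_cells = config$n_cells %||% 30, seed = seeds[3])
  ca <- simulate_ca_traces(ca_cfg)
  write_gq_csv(ca$traces, file.path(out_dir, "traces.csv"), "traces")
  utils::write.csv(ca$events, file.path(out_dir, "truth_events.csv"),
                   row.names = FALSE)

  ep_cfg <- ephys_sim_config(pr_basal = config$pr_basal %||% 0.5,
                             pr_post = config$pr_post %||% 0.5,
                             seed = seeds[4])
  ep <- simulate_minimal_stim(ep_cfg)
  tr <- ep$trials
  tr$truth_success <- as.integer(tr$truth_success)
  write_gq_csv(tr, file.path(out_dir, "trials.csv"), "trials")
  list(field = field, tissue = tissue, ca = ca, ephys = ep)
}

.stage_stereology <- function(config, seeds, in_dir, out_dir) {
  sections <- read_gq_csv(file.path(in_dir, "sections.csv"), "sections")
  a_p <- config$a_p %||% 2704
  T_spacing <- config$T %||% ((config$sampling_interval %||% 6) *
                                stats::median(sections$BA_um))
  points_path <- file.path(in_dir, "points.csv")
  frames_path <- file.path(in_dir, "frames.csv")
  est <- NULL
  if (file.exists(points_path) && file.exists(frames_path)) {
    pts <- read_gq_csv(points_path, "points")
    frm <- read_gq_csv(frames_path, "frames")
    rois <- unique(pts$roi)
    est <- do.call(rbind, lapply(rois, function(rr) {
      P <- pts$P[pts$roi == rr]
      cav <- cavalieri_volume(P, a_p = a_p, T = T_spacing)
      fr <- frm[frm$roi == rr, , drop = FALSE]
      Qsec <- tapply(fr$Q_minus, fr$section_id, sum)
      tsec <- sections$t_um[match(as.numeric(names(Qsec)),
                                  sections$section_id)]
      tQ <- number_weighted_mean_thickness(tsec, as.numeric(Qsec))
      nv <- nv_estimate(sum(fr$Q_minus), sum(fr$corner_in_roi != 0), tQ,
                        BA = stats::median(sections$BA_um),
                        h = config$h %||% 10,
                        a_p_frame = config$a_p_frame %||% 400)
      data.frame(roi = rr, Vref_um3 = cav$volume, Nv_per_um3 = nv$Nv,
                 N_total = total_number(nv, cav))
    }))
  } else {
    # no tally tables: recover them from the simulated cells (report mode)
    cells <- read_gq_csv(file.path(in_dir, "cells.csv"), "cells")
    field <- structure(
      list(region_label = "ROI",
           bounds = unlist(config$bounds %||% c(500, 500, 240)),
           cells = cells, density_true = NA, seed = NULL),
      class = "cell_field")
    tissue <- section_field(field, BA = stats::median(sections$BA_um),
                            shrinkage = stats::median(sections$t_um /
                                                        sections$BA_um),
                            sampling_interval = config$sampling_interval %||% 6,
                            seed = seeds[5])
    se <- estimate_region(tissue, a_p_grid = a_p, seed = seeds[6])
    est <- data.frame(roi = "ROI", Vref_um3 = se$cavalieri$volume,
                      Nv_per_um3 = se$nv$Nv, N_total = se$N_total)
  }
  soma_path <- file.path(in_dir, "soma_planes.csv")
  if (file.exists(soma_path)) {
    sp <- read_gq_csv(soma_path, "soma_planes")
    vols <- do.call(rbind, lapply(split(sp, sp$soma_id), function(d) {
      data.frame(soma_id = d$soma_id[1],
                 volume_um3 = soma_volume(d$area_um2,
                                          T = config$plane_T %||% 1)$volume)
    }))
    utils::write.csv(vols, file.path(out_dir, "soma_volumes.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(est, file.path(out_dir, "estimates.csv"),
                   row.names = FALSE)
  est
}

.stage_calcium <- function(config, seeds, in_dir, out_dir) {
  traces <- read_gq_csv(file.path(in_dir, "traces.csv"), "traces")
  res <- analyze_traces(traces, k = config$k %||% 2,
                        steady_window_s = config$steady_window_s %||% 20,
                        stim_time_s = config$stim_time_s %||% 120)
  utils::write.csv(res$events, file.path(out_dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(res$summary, file.path(out_dir, "cell_summary.csv"),
                   row.names = FALSE)
  res
}

.stage_ephys <- function(config, seeds, in_dir, out_dir) {
  trials <- read_gq_csv(file.path(in_dir, "trials.csv"), "trials")
  if ("truth_success" %in% names(trials)) {
    trials$truth_success <- trials$truth_success != 0
  }
  qc_path <- file.path(in_dir, "qc.csv")
  qc <- NULL
  if (file.exists(qc_path)) {
    qtab <- read_gq_csv(qc_path, "qc")
    chans <- setdiff(names(qtab), c("synapse_id", "t_s"))
    qc <- stability_qc(as.list(qtab[chans]))
  }
  oc <- classify_outcome(trials, qc = qc,
                         alpha = config$alpha %||% 0.05,
                         noise_sd = config$noise_sd,
                         threshold_k = config$threshold_k %||% 3)
  utils::write.csv(
    data.frame(synapse_id = oc$synapse_id, call = oc$call,
               p_value = oc$p_value),
    file.path(out_dir, "outcomes.csv"), row.names = FALSE)
  if (oc$call == "excluded") return(list(outcome = oc))
  tc <- efficacy_timecourse(trials)
  params <- rbind(
    cbind(phase = "basal", as.data.frame(
      oc$basal_params[c("efficacy_pA", "potency_pA", "Pr")])),
    cbind(phase = "post_stim", as.data.frame(
      oc$post_params[c("efficacy_pA", "potency_pA", "Pr")]))
  )
  utils::write.csv(params, file.path(out_dir, "synaptic_params.csv"),
                   row.names = FALSE)
  utils::write.csv(tc, file.path(out_dir, "timecourse.csv"),
                   row.names = FALSE)
  list(outcome = oc, timecourse = tc)
}
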