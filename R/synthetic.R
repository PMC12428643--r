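#' Simulate a 3D field of cell somas
#'
#' Draws a Poisson number of cells (`density * volume` expected) uniformly
#' inside a rectangular tissue block, the ground truth against which the
#' stereological estimators are validated. Each cell carries a soma radius
#' and a marker intensity (arbitrary units, e.g. S100B immunofluorescence).
#'
#' The unique counting point of a cell -- the point the optical disector
#' counts once and only once -- is the top of its nucleus, modelled as a
#' point at the soma centre. Counting points are therefore uniform in the
#' block and the true numerical density is exactly `count / volume`.
#'
#' @param density expected cells per um^3 (>= 0; 0 gives an empty field).
#' @param bounds numeric length-3, box edge lengths in um (x, y, z); the
#'   block occupies `[0, bounds]` in each axis with z increasing downward
#'   from the preparation top.
#' @param region_label label for the region of interest (e.g. "CA1_SR").
#' @param radius_dist function of `n` returning soma radii in um.
#' @param intensity_dist function of `n` returning marker intensities (a.u.).
#' @param seed integer seed; fixed seed gives a bit-identical field.
#' @return A `cell_field`: list with `region_label`, `bounds`, `cells`
#'   (data.frame `x, y, z, radius, intensity`), `density_true`, `seed`.
#' @examples
#' f <- simulate_cell_field(1e-4, bounds = c(500, 500, 240), seed = 1)
#' f$density_true
#' @export
simulate_cell_field <- function(density,
                                bounds = c(500, 500, 240),
                                region_label = "ROI",
                                radius_dist = function(n) stats::runif(n, 3, 6),
                                intensity_dist = function(n)
                                  stats::rlnorm(n, log(800), 0.2),
                                seed = NULL) {
  assert_scalar_num(density, "density", nonneg = TRUE)
  if (!is.numeric(bounds) || length(bounds) != 3L || any(bounds <= 0)) {
    stop("`bounds` must be three positive box edge lengths (um)")
  }
  vol <- prod(bounds)
  cells <- with_seed(seed, {
    n <- stats::rpois(1L, density * vol)
    data.frame(
      x = stats::runif(n, 0, bounds[1]),
      y = stats::runif(n, 0, bounds[2]),
      z = stats::runif(n, 0, bounds[3]),
      radius = radius_dist(n),
      intensity = intensity_dist(n)
    )
  })
  stopifnot(all(cells$radius > 0))
  structure(
    list(region_label = region_label, bounds = bounds, cells = cells,
         density_true = nrow(cells) / vol, seed = seed),
    class = "cell_field"
  )
}

#' @export
print.cell_field <- function(x, ...) {
  cat(sprintf(
    "<cell_field> %s: %d cells in %g x %g x %g um (density %.3g /um^3)\n",
    x$region_label, nrow(x$cells), x$bounds[1], x$bounds[2], x$bounds[3],
    x$density_true))
  invisible(x)
}

#' Section a simulated cell field into slabs
#'
#' Cuts the block into consecutive sections of nominal thickness `BA` (the
#' block advance set on the cutting device) starting at the preparation top
#' (z = 0), then keeps every `sampling_interval`-th section by systematic
#' uniform random sampling (random start within the first period). Measured
#' post-processing thickness is `t = BA * shrinkage` per section, optionally
#' jittered; shrinkage acts along z only. Each cell's counting point is
#' assigned to exactly one section and re-expressed in measured (shrunken)
#' within-section coordinates.
#'
#' @param field a [simulate_cell_field()] result.
#' @param BA block advance in um (> 0).
#' @param shrinkage z shrinkage factor in (0, 1].
#' @param sampling_interval keep every k-th section (integer >= 1).
#' @param thickness_jitter_sd SD of multiplicative jitter on measured
#'   thickness (0 = none); jittered thickness is clamped to (0, BA].
#' @param seed integer seed for the random sampling start (and jitter).
#' @return A `sectioned_tissue`: `sections` data.frame (`section_id, z_top,
#'   BA, t, sampled`), `cells` (field cells plus `section_id` and `z_rel`,
#'   the measured depth of the counting point within its section),
#'   `sampling_interval`, `start_index`, and `T` (spacing between sampled
#'   sections, `sampling_interval * BA`).
#' @export
section_field <- function(field, BA = 40, shrinkage = 0.75,
                          sampling_interval = 6, thickness_jitter_sd = 0,
                          seed = NULL) {
  stopifnot(inherits(field, "cell_field"))
  assert_scalar_num(BA, "BA", positive = TRUE)
  assert_scalar_num(shrinkage, "shrinkage", positive = TRUE)
  if (shrinkage > 1) stop("`shrinkage` must be in (0, 1]")
  sampling_interval <- as.integer(sampling_interval)
  stopifnot(sampling_interval >= 1L)

  depth <- field$bounds[3]
  n_sec <- max(1L, as.integer(ceiling(depth / BA)))
  with_seed(seed, {
    start <- sample.int(sampling_interval, 1L)
    t_meas <- rep(BA * shrinkage, n_sec)
    if (thickness_jitter_sd > 0) {
      t_meas <- t_meas * exp(stats::rnorm(n_sec, 0, thickness_jitter_sd))
      t_meas <- pmin(pmax(t_meas, .Machine$double.eps), BA)
    }
    sections <- data.frame(
      section_id = seq_len(n_sec),
      z_top = (seq_len(n_sec) - 1L) * BA,
      BA = BA,
      t = t_meas,
      sampled = ((seq_len(n_sec) - start) %% sampling_interval) == 0
    )
    cells <- field$cells
    # counting point = nucleus top (a point at the soma centre); half-open
    # sections [z_top, z_top + BA) give each point exactly one section
    sec_id <- pmin(n_sec, as.integer(floor(cells$z / BA)) + 1L)
    cells$section_id <- sec_id
    cells$z_rel <- (cells$z - sections$z_top[sec_id]) *
      (sections$t[sec_id] / BA)
    structure(
      list(sections = sections, cells = cells,
           sampling_interval = sampling_interval, start_index = start,
           T = sampling_interval * BA, bounds = field$bounds,
           region_label = field$region_label, seed = seed),
      class = "sectioned_tissue"
    )
  })
}

#' @export
print.sectioned_tissue <- function(x, ...) {
  cat(sprintf(
    "<sectioned_tissue> %d sections (BA %g um, t %g um), every %dth sampled (%d), T = %g um\n",
    nrow(x$sections), x$sections$BA[1], mean(x$sections$t),
    x$sampling_interval, sum(x$sections$sampled), x$T))
  invisible(x)
}

#' Configuration for the calcium-trace simulator
#'
#' Emulates somatic GCaMP recordings at 1 Hz over 150 s with a chemogenetic
#' (CNO) stimulus at 118 s: spontaneous transients at `rate_basal` before the
#' stimulus and `rate_post` after it, riding multiplicatively on a noisy
#' baseline. Rates and amplitudes are free parameters of the generator, not
#' literature values.
#'
#' @param n_cells number of astrocytes in the field of view.
#' @param duration_s recording length in s (1 Hz sampling).
#' @param rate_basal,rate_post spontaneous / post-stimulus event rates, /s.
#' @param stim_time_s stimulus application time in s.
#' @param amp_dist function of `n` returning peak dF/F0 amplitudes.
#' @param decay_tau_s transient exponential decay constant, s.
#' @param noise_sd additive Gaussian noise SD in dF/F0 units.
#' @param baseline_F0 baseline fluorescence above background, a.u.
#' @param background camera/neuropil background, a.u.
#' @param frac_silent fraction of cells carrying no events.
#' @param min_separation_s minimum spacing between kept events of one cell
#'   (0 = pure Poisson); later events violating it are thinned.
#' @param seed integer seed.
#' @return A `ca_sim_config` list.
#' @export
ca_sim_config <- function(n_cells = 30, duration_s = 150, rate_basal = 0.02,
                          rate_post = 0.1, stim_time_s = 118,
                          amp_dist = function(n) stats::rlnorm(n, log(0.8), 0.4),
                          decay_tau_s = 6, noise_sd = 0.05,
                          baseline_F0 = 500, background = 50,
                          frac_silent = 0.1, min_separation_s = 0,
                          seed = NULL) {
  assert_scalar_num(rate_basal, "rate_basal", nonneg = TRUE)
  assert_scalar_num(rate_post, "rate_post", nonneg = TRUE)
  assert_scalar_num(duration_s, "duration_s", positive = TRUE)
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  assert_scalar_num(baseline_F0, "baseline_F0", positive = TRUE)
  if (frac_silent < 0 || frac_silent > 1) stop("`frac_silent` must be in [0, 1]")
  if (stim_time_s > duration_s) stop("`duration_s` must cover `stim_time_s`")
  structure(
    list(n_cells = as.integer(n_cells), duration_s = duration_s,
         rate_basal = rate_basal, rate_post = rate_post,
         stim_time_s = stim_time_s, amp_dist = amp_dist,
         decay_tau_s = decay_tau_s, noise_sd = noise_sd,
         baseline_F0 = baseline_F0, background = background,
         frac_silent = frac_silent, min_separation_s = min_separation_s,
         seed = seed),
    class = "ca_sim_config"
  )
}

#' Simulate somatic calcium traces with ground-truth events
#'
#' Per cell, event onsets follow a Poisson process (`rate_basal` on
#' `[0, stim_time_s)`, `rate_post` after), snapped to the 1 Hz acquisition
#' grid so the recorded frame maximum equals the true amplitude. Each
#' transient rises instantaneously and decays exponentially; overlapping
#' transients sum linearly. The sampled fluorescence is
#' `F(t) = background + F0 * (1 + sum of transients + noise)`.
#'
#' @param config a [ca_sim_config()].
#' @return A `ca_sim`: `traces` (long data.frame `cell_id, t_s, F, masked,
#'   background`), `events` (ground truth `cell_id, t0_s, amplitude,
#'   window`), and `config`.
#' @export
simulate_ca_traces <- function(config = ca_sim_config()) {
  stopifnot(inherits(config, "ca_sim_config"))
  cfg <- config
  t_s <- seq(0, cfg$duration_s - 1)
  frames_basal <- t_s[t_s < cfg$stim_time_s]
  frames_post <- t_s[t_s >= cfg$stim_time_s]
  with_seed(cfg$seed, {
    n_silent <- round(cfg$frac_silent * cfg$n_cells)
    silent <- logical(cfg$n_cells)
    if (n_silent > 0) silent[sample.int(cfg$n_cells, n_silent)] <- TRUE
    traces <- vector("list", cfg$n_cells)
    events <- vector("list", cfg$n_cells)
    for (i in seq_len(cfg$n_cells)) {
      ev_t <- numeric(0)
      if (!silent[i]) {
        nb <- stats::rpois(1L, cfg$rate_basal * cfg$stim_time_s)
        np <- stats::rpois(1L, cfg$rate_post * (cfg$duration_s - cfg$stim_time_s))
        tb <- if (nb > 0) sample(frames_basal, nb, replace = TRUE) else numeric(0)
        tp <- if (np > 0) sample(frames_post, np, replace = TRUE) else numeric(0)
        ev_t <- sort(c(tb, tp))
        if (cfg$min_separation_s > 0 && length(ev_t) > 1) {
          keep <- ev_t[1]
          for (tt in ev_t[-1]) {
            if (tt - keep[length(keep)] >= cfg$min_separation_s) keep <- c(keep, tt)
          }
          ev_t <- keep
        }
      }
      amp <- if (length(ev_t) > 0) cfg$amp_dist(length(ev_t)) else numeric(0)
      sig <- numeric(length(t_s))
      for (j in seq_along(ev_t)) {
        on <- t_s >= ev_t[j]
        sig[on] <- sig[on] + amp[j] * exp(-(t_s[on] - ev_t[j]) / cfg$decay_tau_s)
      }
      noise <- if (cfg$noise_sd > 0) stats::rnorm(length(t_s), 0, cfg$noise_sd) else 0
      traces[[i]] <- data.frame(
        cell_id = i, t_s = t_s,
        F = cfg$background + cfg$baseline_F0 * (1 + sig + noise),
        masked = FALSE, background = cfg$background
      )
      events[[i]] <- if (length(ev_t) > 0) {
        data.frame(cell_id = i, t0_s = ev_t, amplitude = amp,
                   window = ifelse(ev_t < 120, "basal", "post_stim"))
      } else NULL
    }
    structure(
      list(traces = do.call(rbind, traces),
           events = do.call(rbind, events) %||%
             data.frame(cell_id = integer(0), t0_s = numeric(0),
                        amplitude = numeric(0), window = character(0)),
           config = cfg),
      class = "ca_sim"
    )
  })
}

#' Reconstruct noise-free fluorescence traces from a ground-truth event list
#'
#' Builds the deterministic part of the generative model,
#' `F(t) = background + F0 * (1 + sum of transients)`, for an arbitrary
#' event list. On noise-free simulations the reconstruction reproduces the
#' generated traces exactly; it is also the natural way to craft traces
#' with prescribed event times for detector benchmarks.
#'
#' @param events data.frame `cell_id, t0_s, amplitude`.
#' @param config a [ca_sim_config()] supplying the kernel and baseline
#'   parameters (its noise and rates are ignored).
#' @param cell_ids cells to render (default: those present in `events`).
#' @return Long data.frame `cell_id, t_s, F, masked, background`.
#' @export
reconstruct_trace <- function(events, config = ca_sim_config(),
                              cell_ids = NULL) {
  stopifnot(inherits(config, "ca_sim_config"))
  cell_ids <- cell_ids %||% unique(events$cell_id)
  t_s <- seq(0, config$duration_s - 1)
  out <- lapply(cell_ids, function(cid) {
    ev <- events[events$cell_id == cid, , drop = FALSE]
    sig <- numeric(length(t_s))
    for (j in seq_len(nrow(ev))) {
      on <- t_s >= ev$t0_s[j]
      sig[on] <- sig[on] +
        ev$amplitude[j] * exp(-(t_s[on] - ev$t0_s[j]) / config$decay_tau_s)
    }
    data.frame(cell_id = cid, t_s = t_s,
               F = config$background + config$baseline_F0 * (1 + sig),
               masked = FALSE, background = config$background)
  })
  do.call(rbind, out)
}

#' Configuration for the minimal-stimulation simulator
#'
#' Emulates a minimal-stimulation session: 0.5 Hz stimuli, 5 min of basal
#' trials calibrated near 50% successes / 50% failures, a mid-session
#' astrocyte (CNO) stimulation, then 10 min of post trials at a possibly
#' different release probability.
#'
#' @param pr_basal,pr_post per-trial success probabilities in `[0, 1]`.
#' @param potency_dist function of `n` returning success peak amplitudes (pA).
#' @param noise_sd measurement noise SD on every trial peak, pA.
#' @param stim_rate_hz stimulation rate, Hz.
#' @param basal_duration_min,post_duration_min window lengths, min.
#' @param drift_spec optional `list(slope_per_min = ...)` multiplicative
#'   drift on true peaks, for stability-QC testing.
#' @param seed integer seed.
#' @return An `ephys_sim_config` list. An identifiability warning is raised
#'   when mean potency is not clearly above `3 * noise_sd`.
#' @export
ephys_sim_config <- function(pr_basal = 0.5, pr_post = 0.5,
                             potency_dist = function(n)
                               stats::rlnorm(n, log(20), 0.25),
                             noise_sd = 2, stim_rate_hz = 0.5,
                             basal_duration_min = 5, post_duration_min = 10,
                             drift_spec = NULL, seed = NULL) {
  for (p in c(pr_basal, pr_post)) {
    if (p < 0 || p > 1) stop("release probabilities must be in [0, 1]")
  }
  assert_scalar_num(noise_sd, "noise_sd", nonneg = TRUE)
  assert_scalar_num(stim_rate_hz, "stim_rate_hz", positive = TRUE)
  structure(
    list(pr_basal = pr_basal, pr_post = pr_post, potency_dist = potency_dist,
         noise_sd = noise_sd, stim_rate_hz = stim_rate_hz,
         basal_duration_min = basal_duration_min,
         post_duration_min = post_duration_min, drift_spec = drift_spec,
         seed = seed),
    class = "ephys_sim_config"
  )
}

#' Simulate a minimal-stimulation session with ground truth
#'
#' Each trial succeeds with the phase's release probability; a success draws
#' its true peak from `potency_dist`, a failure has true peak 0 pA. Gaussian
#' measurement noise is added to every peak (clamped at 0, peaks being
#' positive EPSC magnitudes) and per-trial ground-truth labels are retained.
#'
#' @param config an [ephys_sim_config()].
#' @param synapse_id identifier stored on the session.
#' @return A `synapse_session`: `trials` data.frame (`trial_idx, t_s, phase,
#'   peak_pA, truth_success, true_peak_pA`), `stim_time_s`, `holding_mV`
#'   (-70), and `config`.
#' @export
simulate_minimal_stim <- function(config = ephys_sim_config(),
                                  synapse_id = "syn1") {
  stopifnot(inherits(config, "ephys_sim_config"))
  cfg <- config
  n_basal <- round(cfg$stim_rate_hz * cfg$basal_duration_min * 60)
  n_post <- round(cfg$stim_rate_hz * cfg$post_duration_min * 60)
  n <- n_basal + n_post
  with_seed(cfg$seed, {
    phase <- rep(c("basal", "post_stim"), c(n_basal, n_post))
    pr <- ifelse(phase == "basal", cfg$pr_basal, cfg$pr_post)
    success <- stats::rbinom(n, 1L, pr) == 1L
    true_peak <- numeric(n)
    if (any(success)) {
      pot <- cfg$potency_dist(sum(success))
      if (mean(pot) <= 3 * cfg$noise_sd) {
        warning("mean potency <= 3 * noise_sd: successes and failures ",
                "may not be identifiable", call. = FALSE)
      }
      true_peak[success] <- pot
    }
    t_s <- (seq_len(n) - 1L) / cfg$stim_rate_hz
    if (!is.null(cfg$drift_spec)) {
      slope <- cfg$drift_spec$slope_per_min %||% 0
      true_peak <- true_peak * (1 + slope * t_s / 60)
    }
    peak <- pmax(0, true_peak + stats::rnorm(n, 0, cfg$noise_sd))
    structure(
      list(synapse_id = synapse_id,
           trials = data.frame(trial_idx = seq_len(n), t_s = t_s,
                               phase = phase, peak_pA = peak,
                               truth_success = success,
                               true_peak_pA = true_peak),
           stim_time_s = cfg$basal_duration_min * 60,
           holding_mV = -70, config = cfg),
      class = "synapse_session"
    )
  })
}

#' @export
print.synapse_session <- function(x, ...) {
  cat(sprintf(
    "<synapse_session> %s: %d trials (%d basal / %d post), stim at %g s\n",
    x$synapse_id, nrow(x$trials), sum(x$trials$phase == "basal"),
    sum(x$trials$phase == "post_stim"), x$stim_time_s))
  invisible(x)
}
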