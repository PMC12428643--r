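# Match ground-truth events to detected events (nearest detected peak in
# the same cell within `tol` seconds); returns one row per truth event with
# the detected amplitude (NA when unmatched).
match_events <- function(truth, detected, tol = 3) {
  out <- truth
  out$det_amplitude <- NA_real_
  out$det_peak_s <- NA_real_
  for (i in seq_len(nrow(truth))) {
    de <- detected[detected$cell_id == truth$cell_id[i], , drop = FALSE]
    if (nrow(de) == 0) next
    j <- which.min(abs(de$peak_s - truth$t0_s[i]))
    if (abs(de$peak_s[j] - truth$t0_s[i]) <= tol) {
      out$det_amplitude[i] <- de$amplitude[j]
      out$det_peak_s[i] <- de$peak_s[j]
    }
  }
  out
}

# Independent brute-force oracle for the unbiased counting-frame rule:
# per-cell if/else chain, deliberately written differently from the
# vectorised implementation.
brute_force_disector <- function(frame, cells, guard_top = 0) {
  q <- 0L
  for (i in seq_len(nrow(cells))) {
    x <- cells$x[i]; y <- cells$y[i]; z <- cells$z_rel[i]
    if (x <= frame$x0) next                        # left exclusion line
    if (x > frame$x0 + frame$width) next
    if (y <= frame$y0) next                        # lower exclusion line
    if (y > frame$y0 + frame$height) next
    if (z <= guard_top) next
    if (z > guard_top + frame$disector_height) next
    q <- q + 1L
  }
  q
}

# Noise-free trace builder with prescribed, well-separated event times,
# for detector benchmarks where every event is in the detector's domain.
make_benchmark_traces <- function(n_cells, noise_sd, seed,
                                  first_onset = 25, spacing = 30,
                                  amp_range = c(0.3, 0.6)) {
  cfg <- ca_sim_config(noise_sd = 0, seed = NULL)
  withr::with_seed(seed, {
    ev <- do.call(rbind, lapply(seq_len(n_cells), function(cid) {
      t0 <- seq(first_onset, cfg$duration_s - 5, by = spacing) +
        sample(0:4, 1)
      t0 <- t0[t0 <= cfg$duration_s - 2]
      data.frame(cell_id = cid, t0_s = t0,
                 amplitude = stats::runif(length(t0), amp_range[1],
                                          amp_range[2]))
    }))
    tr <- reconstruct_trace(ev, cfg, cell_ids = seq_len(n_cells))
    if (noise_sd > 0) {
      tr$F <- tr$F + cfg$baseline_F0 * stats::rnorm(nrow(tr), 0, noise_sd)
    }
    list(traces = tr, events = ev, config = cfg)
  })
}
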