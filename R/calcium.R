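#' Compute dF/F0 from a raw fluorescence trace
#'
#' Subtracts the per-cell background, estimates the baseline `F0` from the
#' unmasked samples of the baseline window (a robust mean that drops samples
#' more than 2 MAD above the window median, so transients inside the window
#' do not inflate the baseline), and returns
#' `dff = (F - background - F0) / F0`.
#'
#' @param trace data.frame with columns `t_s`, `F` and optionally `masked`
#'   (logical), `background` and `cell_id`.
#' @param f0_window numeric length-2, baseline window in s (default 0-20 s,
#'   the earliest artifact-free epoch).
#' @param background background level, a.u.; defaults to the trace's
#'   `background` column, else 0.
#' @return A `dff_trace` data.frame (`cell_id, t_s, dff, masked`) with
#'   attributes `F0` and `background`. An error is raised when the
#'   background-subtracted baseline is not positive (uninterpretable trace).
#' @export
compute_dff <- function(trace, f0_window = c(0, 20), background = NULL) {
  stopifnot(is.data.frame(trace), all(c("t_s", "F") %in% names(trace)))
  masked <- if ("masked" %in% names(trace)) as.logical(trace$masked) else
    rep(FALSE, nrow(trace))
  bg <- background %||%
    (if ("background" %in% names(trace)) trace$background[1] else 0)
  if (bg < 0) stop("`background` must be >= 0")
  Fsub <- trace$F - bg
  in_win <- !masked & trace$t_s >= f0_window[1] & trace$t_s < f0_window[2]
  if (!any(in_win)) stop("no unmasked samples in the F0 window")
  Fw <- Fsub[in_win]
  # robust clip: samples above median + 2 MAD belong to transients, not
  # baseline (MAD, unlike SD, is not inflated by the transients themselves)
  s <- stats::mad(Fw)
  keep <- if (is.finite(s) && s > 0) Fw <= stats::median(Fw) + 2 * s else
    rep(TRUE, length(Fw))
  F0 <- mean(Fw[keep])
  if (!is.finite(F0) || F0 <= 0) {
    stop("baseline F0 <= 0 after background subtraction: trace uninterpretable")
  }
  out <- data.frame(
    cell_id = if ("cell_id" %in% names(trace)) trace$cell_id else 1L,
    t_s = trace$t_s,
    dff = Fsub / F0 - 1,
    masked = masked
  )
  attr(out, "F0") <- F0
  attr(out, "background") <- bg
  class(out) <- c("dff_trace", "data.frame")
  out
}

#' Detect calcium transients in a dF/F0 trace
#'
#' An event is a signal maximum rising more than `k` standard deviations of
#' the previous steady signal above the steady level. Candidate peaks are
#' the local maxima of the trace; neighbouring maxima whose intervening
#' valley stays above half the smaller peak are merged into one event
#' (wiggles on a transient's decay are not new events). Each candidate is
#' then accepted when its peak exceeds `median + k * SD` of the trailing
#' steady window before its onset, with the steady SD estimated robustly
#' (median absolute deviation of first differences / sqrt(2)) so sparse
#' transients inside the window do not inflate it. Because the candidate
#' set and grouping do not depend on `k`, the event count is non-increasing
#' in `k` on every trace. Masked samples split the trace into independent
#' runs: statistics never cross a gap and gaps never spawn events. An onset
#' needs at least 5 preceding unmasked samples in its run.
#'
#' @param dff a [compute_dff()] result (or data.frame `t_s, dff, masked`).
#' @param k threshold multiplier (> 0; default 2).
#' @param steady_window_s trailing steady-window length, s.
#' @param stim_time_s basal / post-stimulus boundary, s; events are assigned
#'   to windows by peak time, half-open `[0, stim_time_s)`.
#' @return data.frame of events ordered by time: `cell_id, onset_s, peak_s,
#'   amplitude` (peak dF/F0), `window_label`. Entirely masked traces return
#'   an empty result with a warning.
#' @export
detect_events <- function(dff, k = 2, steady_window_s = 20,
                          stim_time_s = 120) {
  assert_scalar_num(k, "k", positive = TRUE)
  stopifnot(is.data.frame(dff), all(c("t_s", "dff") %in% names(dff)))
  masked <- if ("masked" %in% names(dff)) as.logical(dff$masked) else
    rep(FALSE, nrow(dff))
  cell <- if ("cell_id" %in% names(dff)) dff$cell_id[1] else 1L
  empty <- data.frame(cell_id = rep(cell, 0), onset_s = numeric(0),
                      peak_s = numeric(0), amplitude = numeric(0),
                      window_label = character(0))
  if (all(masked)) {
    warning("entire trace is masked; no events detectable", call. = FALSE)
    return(empty)
  }
  ord <- order(dff$t_s)
  t_all <- dff$t_s[ord]
  x_all <- dff$dff[ord]
  masked <- masked[ord]
  dt <- if (length(t_all) > 1) stats::median(diff(t_all)) else 1
  w <- max(5L, round(steady_window_s / dt))

  run_id <- cumsum(c(TRUE, diff(masked) != 0) | FALSE)
  out <- list()
  for (rid in unique(run_id[!masked])) {
    sel <- run_id == rid & !masked
    x <- x_all[sel]
    tt <- t_all[sel]
    n <- length(x)
    if (n < 7L) next
    # candidate peaks: strict rise then non-increase (plateaus keep their
    # first sample); run-initial samples never qualify. A peak must also
    # persist (one of the next two frames above half the peak): a genuine
    # transient decaying with a multi-second time constant stays elevated
    # at 1 Hz, a single-frame noise spike does not.
    cand <- which(vapply(2:(n - 1), function(i) {
      after <- x[(i + 1):min(n, i + 2)]
      x[i] > x[i - 1] && x[i] >= x[i + 1] && max(after) > 0.5 * x[i]
    }, logical(1))) + 1L
    if (n >= 2 && x[n] > x[n - 1]) cand <- c(cand, n)
    if (length(cand) == 0) next
    # merge neighbouring maxima separated by shallow valleys (k-independent)
    groups <- list()
    gpeak <- cand[1]
    for (cc in cand[-1]) {
      valley <- min(x[gpeak:cc])
      if (valley > 0.5 * min(x[gpeak], x[cc])) {
        if (x[cc] > x[gpeak]) gpeak <- cc
      } else {
        groups[[length(groups) + 1L]] <- gpeak
        gpeak <- cc
      }
    }
    groups[[length(groups) + 1L]] <- gpeak
    peaks <- unlist(groups)
    prev <- 1L
    for (p in peaks) {
      # onset = foot of the rising edge (nearest local valley before peak)
      onset <- p
      while (onset > prev && x[onset - 1L] < x[onset]) onset <- onset - 1L
      prev <- p
      if (onset < 6L) next # needs >= 5 preceding steady samples
      buf <- x[max(1L, onset - w):(onset - 1L)]
      mu <- stats::median(buf)
      sigma <- if (length(buf) >= 2)
        stats::mad(diff(buf)) / sqrt(2) else 0
      if (x[p] > mu + k * sigma) {
        out[[length(out) + 1L]] <- data.frame(
          cell_id = cell, onset_s = tt[onset], peak_s = tt[p],
          amplitude = x[p],
          window_label = if (tt[p] < stim_time_s) "basal" else "post_stim"
        )
      }
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[order(res$peak_s), , drop = FALSE]
}

#' Per-cell event summary by analysis window
#'
#' Event frequencies (events/min and Hz) and mean amplitudes for the basal
#' (`[0, stim_time_s)`) and post-stimulus windows, using effective window
#' durations with masked time subtracted. A cell with no events anywhere in
#' the recording is flagged non-oscillating and should be excluded from
#' group means.
#'
#' @param events event table for one cell (from [detect_events()]).
#' @param trace the cell's trace (or dff trace) supplying `t_s` and `masked`.
#' @param stim_time_s window boundary, s.
#' @return A one-row data.frame: `cell_id, n_basal, n_post, freq_basal,
#'   freq_post` (events/min), `freq_basal_hz, freq_post_hz, amp_mean_basal,
#'   amp_mean_post, oscillating`.
#' @export
summarize_cell <- function(events, trace, stim_time_s = 120) {
  stopifnot(is.data.frame(trace), "t_s" %in% names(trace))
  masked <- if ("masked" %in% names(trace)) as.logical(trace$masked) else
    rep(FALSE, nrow(trace))
  t_s <- trace$t_s
  dt <- if (length(t_s) > 1) stats::median(diff(t_s)) else 1
  dur_basal <- sum(!masked & t_s < stim_time_s) * dt
  dur_post <- sum(!masked & t_s >= stim_time_s) * dt
  cell <- if (nrow(events) > 0) events$cell_id[1] else
    if ("cell_id" %in% names(trace)) trace$cell_id[1] else 1L
  basal <- events[events$window_label == "basal", , drop = FALSE]
  post <- events[events$window_label == "post_stim", , drop = FALSE]
  oscillating <- nrow(events) > 0
  if (!oscillating) {
    log_exclusion("non_oscillating", sprintf("cell_id=%s", cell))
  }
  data.frame(
    cell_id = cell,
    n_basal = nrow(basal), n_post = nrow(post),
    freq_basal = if (dur_basal > 0) nrow(basal) / dur_basal * 60 else NA_real_,
    freq_post = if (dur_post > 0) nrow(post) / dur_post * 60 else NA_real_,
    freq_basal_hz = if (dur_basal > 0) nrow(basal) / dur_basal else NA_real_,
    freq_post_hz = if (dur_post > 0) nrow(post) / dur_post else NA_real_,
    amp_mean_basal = if (nrow(basal) > 0) mean(basal$amplitude) else NA_real_,
    amp_mean_post = if (nrow(post) > 0) mean(post$amplitude) else NA_real_,
    oscillating = oscillating
  )
}

#' Run dF/F0, detection and summaries over a multi-cell trace table
#'
#' @param traces long data.frame `cell_id, t_s, F[, masked][, background]`.
#' @param k,steady_window_s,f0_window,stim_time_s passed to the per-cell
#'   steps.
#' @return List with `events` (all cells) and `summary` (one row per cell).
#' @export
analyze_traces <- function(traces, k = 2, steady_window_s = 20,
                           f0_window = c(0, 20), stim_time_s = 120) {
  stopifnot(all(c("cell_id", "t_s", "F") %in% names(traces)))
  cells <- unique(traces$cell_id)
  ev <- list()
  sm <- list()
  for (cid in cells) {
    tr <- traces[traces$cell_id == cid, , drop = FALSE]
    d <- compute_dff(tr, f0_window = f0_window)
    e <- detect_events(d, k = k, steady_window_s = steady_window_s,
                       stim_time_s = stim_time_s)
    ev[[length(ev) + 1L]] <- e
    sm[[length(sm) + 1L]] <- summarize_cell(e, d, stim_time_s = stim_time_s)
  }
  list(events = do.call(rbind, ev), summary = do.call(rbind, sm))
}

#' Factorial comparison of per-cell measures across groups
#'
#' Two-factor (genotype x treatment) analysis of a per-cell measure with
#' all-pairs Tukey-adjusted comparisons, preceded by normality
#' (Shapiro-Wilk on residuals) and variance-homogeneity (Bartlett) gates.
#' When either gate fails the rank-based fallback (Kruskal-Wallis plus
#' pairwise Wilcoxon with Holm adjustment) is reported as the primary
#' result. With a single-level second factor the analysis degrades to a
#' one-way comparison.
#'
#' @param x numeric response, one value per cell (e.g. mean amplitude).
#' @param genotype,treatment factors (or coercible) of the same length.
#' @param alpha gate significance level.
#' @return A `group_comparison`: `anova` table, `tukey`, `gates`
#'   (`shapiro_p`, `bartlett_p`), `parametric` flag, and `nonparametric`
#'   (`kruskal`, `pairwise`) results.
#' @export
group_compare <- function(x, genotype, treatment = NULL, alpha = 0.05) {
  genotype <- factor(genotype)
  if (is.null(treatment)) treatment <- rep("all", length(x))
  treatment <- factor(treatment)
  stopifnot(length(x) == length(genotype), length(x) == length(treatment))
  grp <- interaction(genotype, treatment, drop = TRUE)
  if (nlevels(grp) < 2) stop("need at least two groups")
  tab <- table(grp)
  if (any(tab < 2)) stop("every group needs at least 2 observations")

  two_way <- nlevels(genotype) > 1 && nlevels(treatment) > 1
  fml <- if (two_way) x ~ genotype * treatment else
    if (nlevels(genotype) > 1) x ~ genotype else x ~ treatment
  dat <- data.frame(x = x, genotype = genotype, treatment = treatment)
  fit <- stats::aov(fml, data = dat)

  res <- stats::residuals(fit)
  shapiro_p <- if (length(res) >= 3 && length(res) <= 5000 &&
                   stats::sd(res) > 0) {
    stats::shapiro.test(res)$p.value
  } else NA_real_
  bartlett_p <- if (all(tapply(x, grp, stats::sd) > 0)) {
    stats::bartlett.test(x, grp)$p.value
  } else NA_real_
  parametric <- (is.na(shapiro_p) || shapiro_p > alpha) &&
    (is.na(bartlett_p) || bartlett_p > alpha)

  kw <- stats::kruskal.test(x, grp)
  pw <- suppressWarnings(
    stats::pairwise.wilcox.test(x, grp, p.adjust.method = "holm"))
  structure(
    list(anova = summary(fit), tukey = stats::TukeyHSD(fit),
         gates = c(shapiro_p = shapiro_p, bartlett_p = bartlett_p),
         parametric = parametric,
         nonparametric = list(kruskal = kw, pairwise = pw),
         formula = fml),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>",
      if (x$parametric) "parametric (ANOVA + Tukey HSD)" else
        "non-parametric fallback (Kruskal-Wallis + pairwise Wilcoxon)", "\n")
  cat(sprintf("  gates: Shapiro p = %.3g, Bartlett p = %.3g\n",
              x$gates["shapiro_p"], x$gates["bartlett_p"]))
  if (x$parametric) print(x$anova) else print(x$nonparametric$kruskal)
  invisible(x)
}
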