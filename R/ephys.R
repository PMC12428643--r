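#' Call success or failure for trial peaks
#'
#' Minimal stimulation resolves single-synapse release statistics as
#' successes versus failures. A trial is a success when its response-window
#' peak exceeds `threshold_k` times the baseline noise SD (default 3, the
#' conventional detection limit).
#'
#' @param peak_pA trial peak amplitudes, pA (positive EPSC magnitudes).
#' @param noise_sd baseline noise SD, pA (> 0, estimated from the
#'   pre-stimulus baseline).
#' @param threshold_k threshold multiplier.
#' @return Logical vector of success calls.
#' @export
call_success <- function(peak_pA, noise_sd, threshold_k = 3) {
  assert_scalar_num(noise_sd, "noise_sd", positive = TRUE)
  assert_scalar_num(threshold_k, "threshold_k", positive = TRUE)
  if (any(peak_pA < 0)) stop("`peak_pA` must be positive EPSC magnitudes")
  peak_pA > threshold_k * noise_sd
}

#' Synaptic efficacy, potency and probability of release
#'
#' The three minimal-stimulation parameters: efficacy = mean peak amplitude
#' of all responses including failures; potency = mean peak amplitude of
#' the successes; Pr = successes / total stimuli. With failure peaks set
#' exactly to zero (`failure_mode = "zero"`), efficacy equals
#' `Pr * potency` identically; with `"measured"` (default for real data)
#' failures contribute their recorded noise peak.
#'
#' @param peak_pA trial peak amplitudes, pA.
#' @param success logical success calls (same length).
#' @param failure_mode `"measured"` or `"zero"`.
#' @return A `synaptic_params`: `efficacy_pA`, `potency_pA` (NA and flagged
#'   `potency_defined = FALSE` with zero successes), `Pr`, `n_trials`,
#'   `n_successes`, `failure_mode`.
#' @examples
#' synaptic_params(c(10, 0, 10, 0), c(TRUE, FALSE, TRUE, FALSE))
#' @export
synaptic_params <- function(peak_pA, success,
                            failure_mode = c("measured", "zero")) {
  failure_mode <- match.arg(failure_mode)
  if (length(peak_pA) == 0) stop("need at least one trial")
  stopifnot(length(peak_pA) == length(success))
  success <- as.logical(success)
  eff_peaks <- if (failure_mode == "zero")
    ifelse(success, peak_pA, 0) else peak_pA
  n_succ <- sum(success)
  structure(
    list(efficacy_pA = mean(eff_peaks),
         potency_pA = if (n_succ > 0) mean(peak_pA[success]) else NA_real_,
         potency_defined = n_succ > 0,
         Pr = n_succ / length(success),
         n_trials = length(success), n_successes = n_succ,
         failure_mode = failure_mode),
    class = "synaptic_params"
  )
}

#' @export
print.synaptic_params <- function(x, ...) {
  cat(sprintf(
    "<synaptic_params> efficacy = %.2f pA, potency = %s pA, Pr = %.3f (%d/%d trials)\n",
    x$efficacy_pA,
    if (x$potency_defined) sprintf("%.2f", x$potency_pA) else "undefined",
    x$Pr, x$n_successes, x$n_trials))
  invisible(x)
}

#' Recording stability check
#'
#' A recording is stable when none of the monitored channels (series
#' resistance, input resistance, resting potential, stimulus artifact
#' duration) fluctuates by more than the tolerance relative to its initial
#' value; exactly the tolerance is still stable ("more than 20%" fails).
#' Channels starting at zero cannot be assessed and are skipped with a
#' warning.
#'
#' @param monitor_series named list of numeric time series.
#' @param tolerance allowed fractional fluctuation (default 0.20).
#' @return A `stability_qc`: per-channel `max_fluctuation_fraction`,
#'   `channel_stable`, overall `stable`, `tolerance`.
#' @export
stability_qc <- function(monitor_series, tolerance = 0.20) {
  stopifnot(is.list(monitor_series), length(monitor_series) > 0)
  assert_scalar_num(tolerance, "tolerance", positive = TRUE)
  frac <- vapply(names(monitor_series), function(nm) {
    s <- monitor_series[[nm]]
    if (length(s) == 0) stop(sprintf("channel '%s' is empty", nm))
    if (s[1] == 0) {
      warning(sprintf("channel '%s' starts at 0; skipped", nm), call. = FALSE)
      return(NA_real_)
    }
    max(abs(s - s[1])) / abs(s[1])
  }, numeric(1))
  ok <- frac <= tolerance
  structure(
    list(max_fluctuation_fraction = frac,
         channel_stable = ok,
         stable = all(ok, na.rm = TRUE),
         tolerance = tolerance),
    class = "stability_qc"
  )
}

#' @export
print.stability_qc <- function(x, ...) {
  cat(sprintf("<stability_qc> %s (tolerance %.0f%%)\n",
              if (x$stable) "stable" else "UNSTABLE", 100 * x$tolerance))
  for (nm in names(x$max_fluctuation_fraction)) {
    cat(sprintf("  %s: max fluctuation %.1f%%\n", nm,
                100 * x$max_fluctuation_fraction[nm]))
  }
  invisible(x)
}

session_trials <- function(session) {
  if (inherits(session, "synapse_session")) session$trials else session
}

#' Classify a synapse's response to astrocyte stimulation
#'
#' Paired comparison of per-minute synaptic efficacy between the basal
#' window (five 1-min bins) and the first five post-stimulus minutes:
#' minute m of the basal window is paired with minute m after stimulation.
#' A significant increase is called `potentiated`, a significant decrease
#' `depressed`, otherwise `unchanged`. Sessions failing stability QC are
#' excluded with a reason.
#'
#' @param session a `synapse_session` (or its trials data.frame).
#' @param basal_window,post_window analysis windows in s (defaults: 0-300
#'   and 300-600, i.e. basal 5 min and first 5 min after stimulation).
#' @param alpha significance level for the paired test.
#' @param bin_s bin width, s (half-open bins).
#' @param qc optional [stability_qc()] result gating the session.
#' @param failure_mode passed to the efficacy computation.
#' @param noise_sd,threshold_k success-calling parameters used when the
#'   trials carry no ground-truth labels (see [call_success()]).
#' @return An `outcome_call`: `call` (potentiated / depressed / unchanged /
#'   excluded), `p_value`, `basal_params`, `post_params`, per-bin
#'   efficacies, `reason` when excluded.
#' @export
classify_outcome <- function(session, basal_window = c(0, 300),
                             post_window = c(300, 600), alpha = 0.05,
                             bin_s = 60, qc = NULL,
                             failure_mode = c("measured", "zero"),
                             noise_sd = NULL, threshold_k = 3) {
  failure_mode <- match.arg(failure_mode)
  trials <- session_trials(session)
  synapse_id <- if (inherits(session, "synapse_session"))
    session$synapse_id else "synapse"
  if (!is.null(qc) && !qc$stable) {
    log_exclusion("unstable_session", sprintf("synapse_id=%s", synapse_id))
    return(structure(
      list(synapse_id = synapse_id, call = "excluded",
           reason = "unstable recording (QC fluctuation > tolerance)",
           p_value = NA_real_, basal_params = NULL, post_params = NULL),
      class = "outcome_call"
    ))
  }
  in_b <- trials$t_s >= basal_window[1] & trials$t_s < basal_window[2]
  in_p <- trials$t_s >= post_window[1] & trials$t_s < post_window[2]
  if (sum(in_b) < 30 || sum(in_p) < 30) {
    stop("both analysis windows need at least 30 trials")
  }
  eff_peak <- function(tr) {
    if (failure_mode == "zero" && "truth_success" %in% names(tr))
      ifelse(tr$truth_success, tr$peak_pA, 0) else tr$peak_pA
  }
  bin_eff <- function(tr, win) {
    edges <- seq(win[1], win[2], by = bin_s)
    idx <- findInterval(tr$t_s, edges, rightmost.closed = FALSE)
    keep <- idx >= 1 & idx <= length(edges) - 1
    tapply(eff_peak(tr)[keep], factor(idx[keep], levels = seq_len(length(edges) - 1)),
           mean)
  }
  b <- bin_eff(trials[in_b, , drop = FALSE], basal_window)
  p <- bin_eff(trials[in_p, , drop = FALSE], post_window)
  nb <- min(length(b), length(p))
  b <- as.numeric(b[seq_len(nb)])
  p <- as.numeric(p[seq_len(nb)])
  d <- p - b
  if (all(is.finite(d)) && all(d == 0)) {
    pval <- 1
  } else {
    pval <- stats::t.test(p, b, paired = TRUE)$p.value
  }
  if ("truth_success" %in% names(trials)) {
    succ_b <- trials$truth_success[in_b]
    succ_p <- trials$truth_success[in_p]
  } else {
    if (is.null(noise_sd)) {
      stop("trials carry no ground-truth labels; supply `noise_sd` for success calling")
    }
    succ_b <- call_success(trials$peak_pA[in_b], noise_sd, threshold_k)
    succ_p <- call_success(trials$peak_pA[in_p], noise_sd, threshold_k)
  }
  basal_params <- synaptic_params(trials$peak_pA[in_b], succ_b, failure_mode)
  post_params <- synaptic_params(trials$peak_pA[in_p], succ_p, failure_mode)
  call <- if (is.finite(pval) && pval < alpha) {
    if (mean(p) > mean(b)) "potentiated" else "depressed"
  } else "unchanged"
  structure(
    list(synapse_id = synapse_id, call = call, p_value = pval,
         basal_bin_efficacy = b, post_bin_efficacy = p,
         basal_params = basal_params, post_params = post_params,
         alpha = alpha, reason = NULL),
    class = "outcome_call"
  )
}

#' @export
print.outcome_call <- function(x, ...) {
  cat(sprintf("<outcome_call> %s: %s (p = %s)\n", x$synapse_id, x$call,
              format.pval(x$p_value, digits = 3)))
  if (!is.null(x$reason)) cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Normalized synaptic efficacy time course
#'
#' Per-bin mean efficacy over the whole session, normalized by the
#' basal-window mean efficacy so that the basal level maps to 1. Bins are
#' half-open `[b, b + bin_s)`: a trial at exactly 60 s belongs to the
#' second 60-s bin.
#'
#' @param session a `synapse_session` or trials data.frame.
#' @param bin_s bin width, s.
#' @param basal_window basal window in s used as the normalization anchor.
#' @param failure_mode passed to the efficacy computation.
#' @return data.frame `bin, t_mid_s, n_trials, efficacy_pA, efficacy_norm`.
#' @export
efficacy_timecourse <- function(session, bin_s = 60, basal_window = c(0, 300),
                                failure_mode = c("measured", "zero")) {
  failure_mode <- match.arg(failure_mode)
  trials <- session_trials(session)
  if (diff(range(trials$t_s)) < bin_s) stop("session must span at least 2 bins")
  peaks <- if (failure_mode == "zero" && "truth_success" %in% names(trials))
    ifelse(trials$truth_success, trials$peak_pA, 0) else trials$peak_pA
  in_b <- trials$t_s >= basal_window[1] & trials$t_s < basal_window[2]
  basal_mean <- mean(peaks[in_b])
  if (!is.finite(basal_mean) || basal_mean <= 0) {
    stop("basal-window efficacy is zero; cannot normalize")
  }
  bin <- floor(trials$t_s / bin_s) + 1L
  eff <- tapply(peaks, bin, mean)
  n <- tapply(peaks, bin, length)
  bins <- as.integer(names(eff))
  data.frame(
    bin = bins,
    t_mid_s = (bins - 0.5) * bin_s,
    n_trials = as.integer(n),
    efficacy_pA = as.numeric(eff),
    efficacy_norm = as.numeric(eff) / basal_mean
  )
}

#' Cohort proportions of synaptic outcomes
#'
#' Counts and percentages of potentiated / depressed / unchanged calls
#' (excluded sessions are tallied separately and not part of the
#' denominator). Percentages are exact fractions rounded to two decimals
#' and sum to 100 within rounding.
#'
#' @param outcome_calls list of [classify_outcome()] results, or a
#'   character vector of calls.
#' @return A `cohort_summary` data.frame: `call, n, percent`, with
#'   attributes `n_total` and `n_excluded`.
#' @examples
#' cohort_summary(c(rep("potentiated", 7), rep("unchanged", 6)))
#' @export
cohort_summary <- function(outcome_calls) {
  calls <- if (is.character(outcome_calls)) outcome_calls else
    vapply(outcome_calls, function(x) x$call, character(1))
  if (length(calls) == 0) stop("need at least one outcome call")
  excluded <- sum(calls == "excluded")
  calls <- calls[calls != "excluded"]
  lev <- c("potentiated", "depressed", "unchanged")
  if (!all(calls %in% lev)) stop("unknown outcome call")
  n <- table(factor(calls, levels = lev))
  out <- data.frame(
    call = lev,
    n = as.integer(n),
    percent = round(100 * as.integer(n) / length(calls), 2)
  )
  attr(out, "n_total") <- length(calls)
  attr(out, "n_excluded") <- excluded
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d synapses (%d excluded)\n",
              attr(x, "n_total"), attr(x, "n_excluded")))
  print.data.frame(x)
  invisible(x)
}
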