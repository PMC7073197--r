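#' Pulsatile force regime of a magnetic-tweezers assay
#'
#' The standard mechanosensing protocol: a train of constant-force pulses
#' separated by rest periods; by default 12 pulses of 1 nN, 3 s on and 4 s
#' rest. The commanded force is metadata (the statistic uses displacements
#' only).
#'
#' @param n_pulses number of pulses (>= 2).
#' @param force_nN commanded force amplitude per pulse, nN.
#' @param on_s pulse duration, s.
#' @param rest_s rest between pulses, s.
#' @return An object of class `pulse_regime`.
#' @export
pulse_regime <- function(n_pulses = 12L, force_nN = 1, on_s = 3, rest_s = 4) {
  n_pulses <- as.integer(n_pulses)
  stopifnot(n_pulses >= 2L, force_nN > 0, on_s > 0, rest_s > 0)
  structure(list(n_pulses = n_pulses, force_nN = force_nN,
                 on_s = on_s, rest_s = rest_s),
            class = "pulse_regime")
}

#' Bead-displacement trace
#'
#' Validates and wraps a magnetic-tweezers bead displacement time series:
#' strictly increasing, uniformly sampled time (within 1% jitter).
#'
#' @param time_s time, s.
#' @param displacement_nm bead displacement, nm.
#' @param onset_s optional known start time of the first pulse.
#' @return A `bead_trace` (data.frame with `sample_rate_hz` and `onset_s`
#'   attributes).
#' @export
bead_trace <- function(time_s, displacement_nm, onset_s = NA_real_) {
  stopifnot(length(time_s) == length(displacement_nm), length(time_s) >= 2L)
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("'time_s' must be strictly increasing")
  if ((max(dt) - min(dt)) > 0.01 * stats::median(dt))
    stop("sampling is not uniform (jitter exceeds 1%)")
  structure(data.frame(time_s = time_s, displacement_nm = displacement_nm),
            sample_rate_hz = 1 / stats::median(dt), onset_s = onset_s,
            class = c("bead_trace", "data.frame"))
}

#' Segment a bead trace into pulse windows
#'
#' Splits a trace into one window per force pulse. With a known onset the
#' windows are placed arithmetically (pulse i occupies
#' `[onset + (i-1)(on+rest), onset + (i-1)(on+rest) + on)`). Otherwise the
#' onset is estimated by maximising the correlation of the trace derivative
#' with the regime's on/off template (+1 during pulses, -1 during rests).
#'
#' @param trace a [bead_trace()].
#' @param regime a [pulse_regime()].
#' @param onset_s start time of pulse 1, s; `NULL` to use the trace's
#'   `onset_s` attribute or, failing that, to estimate it.
#' @return integer matrix `[pulse, c(start, end)]` of sample indices
#'   (on-phase windows), with the onset used stored as attribute `onset_s`.
#' @export
segment_pulses <- function(trace, regime = pulse_regime(), onset_s = NULL) {
  stopifnot(inherits(trace, "bead_trace"), inherits(regime, "pulse_regime"))
  rate <- attr(trace, "sample_rate_hz")
  if (rate * regime$on_s < 2)
    stop("sample rate too low: fewer than 2 samples per on-phase")
  period <- regime$on_s + regime$rest_s
  need <- regime$n_pulses * period
  t <- trace$time_s
  if (is.null(onset_s)) {
    onset_s <- attr(trace, "onset_s")
    if (is.null(onset_s) || is.na(onset_s))
      onset_s <- .estimate_onset(trace, regime)
  }
  if (onset_s < t[1L] || onset_s + need - regime$rest_s > t[length(t)] + 1e-9)
    stop(sprintf("trace (%.3g s) too short for a %.3g s regime from onset %.3g s",
                 diff(range(t)), need - regime$rest_s, onset_s))
  win <- matrix(0L, regime$n_pulses, 2L,
                dimnames = list(NULL, c("start", "end")))
  for (i in seq_len(regime$n_pulses)) {
    t0 <- onset_s + (i - 1) * period
    idx <- which(t >= t0 - 1e-9 & t < t0 + regime$on_s - 1e-9)
    if (length(idx) < 2L) stop("pulse ", i, " window has < 2 samples")
    win[i, ] <- c(idx[1L], idx[length(idx)])
  }
  attr(win, "onset_s") <- onset_s
  win
}

# onset estimation: correlate the displacement derivative with the regime's
# +1 (on) / -1 (off) square template over all feasible shifts
.estimate_onset <- function(trace, regime) {
  rate <- attr(trace, "sample_rate_hz")
  dt <- 1 / rate
  period <- regime$on_s + regime$rest_s
  len <- round((regime$n_pulses * period - regime$rest_s) / dt)
  tmpl <- rep(rep(c(1, -1), regime$n_pulses),
              times = rep(c(round(regime$on_s / dt),
                            round(regime$rest_s / dt)), regime$n_pulses)
              )[seq_len(len)]
  d <- diff(trace$displacement_nm)
  if (len > length(d)) stop("trace too short for the pulse regime")
  nshift <- length(d) - len + 1L
  score <- vapply(seq_len(nshift), function(s)
    sum(d[s:(s + len - 1L)] * tmpl), numeric(1L))
  trace$time_s[which.max(score)]
}

#' Per-pulse displacement amplitudes
#'
#' The amplitude of pulse i is the maximum displacement inside its window
#' minus the displacement at the window start. Subtracting the per-pulse
#' start absorbs slow bead drift without any detrending, so adding a constant
#' offset (or linear drift between pulses) to the trace leaves amplitudes
#' essentially unchanged.
#'
#' @param trace a [bead_trace()].
#' @param windows pulse windows from [segment_pulses()].
#' @return An object of class `pulse_metrics`: data.frame with `pulse`,
#'   `start_nm`, `max_nm`, `amplitude_nm`, `relative` (amplitude / pulse-1
#'   amplitude); attribute `baseline_mad_nm` holds the MAD of the pre-onset
#'   baseline (used as the no-response noise threshold).
#' @export
pulse_amplitudes <- function(trace, windows) {
  stopifnot(inherits(trace, "bead_trace"), is.matrix(windows))
  if (any(windows[, 2L] - windows[, 1L] < 1L))
    stop("a pulse window has fewer than 2 samples")
  y <- trace$displacement_nm
  start <- y[windows[, 1L]]
  mx <- vapply(seq_len(nrow(windows)), function(i)
    max(y[windows[i, 1L]:windows[i, 2L]]), numeric(1L))
  amp <- mx - start
  pre <- seq_len(max(windows[1L, 1L] - 1L, 0L))
  bmad <- if (length(pre) >= 5L) stats::mad(y[pre]) else NA_real_
  structure(data.frame(pulse = seq_len(nrow(windows)), start_nm = start,
                       max_nm = mx, amplitude_nm = amp,
                       relative = amp / amp[1L]),
            baseline_mad_nm = bmad,
            class = c("pulse_metrics", "data.frame"))
}

#' Mechanosensing statistic of one bead
#'
#' Quantifies cell stiffening under repeated force as the relative decrease
#' in bead displacement amplitude from pulse 1 to pulse 12 (or the last
#' pulse): `r12 = A12/A1`, percent decrease `100 (1 - r12)`. A bead is
#' *included* in a cohort only when its 12th-pulse amplitude is smaller than
#' its 1st (`A12 < A1`); beads with a negative amplitude are excluded with a
#' reason code. If the first-pulse amplitude does not exceed the noise
#' threshold (3 x the pre-onset baseline MAD by default) the bead shows no
#' initial response and an error is raised.
#'
#' @param metrics a [pulse_amplitudes()] result.
#' @param noise_threshold_nm minimum A1; default `3 * baseline MAD` when the
#'   baseline was available, else 0.
#' @return list: `r12`, `decrease_pct`, `included` (logical), `reason`
#'   (`""`, `"A12 >= A1"` or `"negative amplitude"`).
#' @export
mechanosensing_metric <- function(metrics, noise_threshold_nm = NULL) {
  stopifnot(inherits(metrics, "pulse_metrics"))
  A <- metrics$amplitude_nm
  n <- length(A)
  if (is.null(noise_threshold_nm)) {
    bm <- attr(metrics, "baseline_mad_nm")
    noise_threshold_nm <- if (is.na(bm)) 0 else 3 * bm
  }
  if (A[1L] <= noise_threshold_nm)
    stop(sprintf("no initial response: A1 = %.3g nm <= threshold %.3g nm",
                 A[1L], noise_threshold_nm))
  r12 <- A[n] / A[1L]
  included <- A[n] < A[1L]
  reason <- if (any(A < 0)) "negative amplitude"
            else if (!included) "A12 >= A1" else ""
  if (reason == "negative amplitude") included <- FALSE
  list(r12 = r12, decrease_pct = 100 * (1 - r12),
       included = included, reason = reason)
}

#' Mechanosensing summary over a cohort of bead traces
#'
#' Runs pulse segmentation, amplitude extraction and the stiffening statistic
#' on each trace, applies the inclusion filter (`A12 < A1`, positive
#' amplitudes, detectable first response) and reports the per-bead table plus
#' the cohort mean percent decrease over included beads. Per-bead ratios are
#' averaged (rather than taking the ratio of averaged amplitudes).
#'
#' @param traces list of [bead_trace()] objects.
#' @param regime a [pulse_regime()].
#' @return list with `beads` (data.frame: bead, A1_nm, A12_nm, r12,
#'   decrease_pct, included, exclusion_reason) and `cohort` (named vector:
#'   mean_decrease_pct over included beads, n_included, n_total).
#' @export
mechanosensing_cohort <- function(traces, regime = pulse_regime()) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    win <- segment_pulses(tr, regime)
    pm <- pulse_amplitudes(tr, win)
    met <- tryCatch(mechanosensing_metric(pm), error = function(e) NULL)
    n <- nrow(pm)
    if (is.null(met))
      return(data.frame(bead = i, A1_nm = pm$amplitude_nm[1L],
                        A12_nm = pm$amplitude_nm[n], r12 = NA_real_,
                        decrease_pct = NA_real_, included = FALSE,
                        exclusion_reason = "no initial response"))
    data.frame(bead = i, A1_nm = pm$amplitude_nm[1L],
               A12_nm = pm$amplitude_nm[n], r12 = met$r12,
               decrease_pct = met$decrease_pct, included = met$included,
               exclusion_reason = met$reason)
  })
  beads <- do.call(rbind, rows)
  inc <- beads$included
  list(beads = beads,
       cohort = c(mean_decrease_pct = mean(beads$decrease_pct[inc]),
                  n_included = sum(inc), n_total = nrow(beads)))
}
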