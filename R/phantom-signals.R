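#' Specification of a synthetic magnetic-tweezers bead trace
#'
#' Describes a bead-displacement time series under the pulsatile force regime
#' used for mechanosensing assays: by default 12 pulses of 3 s on / 4 s rest.
#' During each pulse the bead displaces toward a programmed amplitude with a
#' fast exponential rise; during rest it relaxes but retains a residual
#' fraction, so the start displacement of successive pulses creeps upward
#' (bead drift), as seen in real traces. A linear baseline drift and Gaussian
#' noise are added on top.
#'
#' @param amplitudes programmed pulse amplitudes in nm: scalar (recycled) or
#'   length `n_pulses`. A decaying schedule models a stiffening
#'   (mechanosensing) cell.
#' @param n_pulses number of force pulses (default 12).
#' @param on_s pulse duration, s (default 3).
#' @param rest_s rest between pulses, s (default 4).
#' @param sample_rate_hz sampling rate (default 50 Hz).
#' @param pre_s quiet baseline recorded before the first pulse, s.
#' @param post_s extra time recorded after the last pulse, s.
#' @param drift_nm_s linear baseline drift rate, nm/s.
#' @param noise_sd additive Gaussian noise SD, nm.
#' @param tau_on_s rise time constant during a pulse, s.
#' @param tau_off_s relaxation time constant during rest, s.
#' @param residual_frac fraction of each pulse's amplitude retained
#'   permanently after relaxation (bead drift between pulses).
#' @param seed integer RNG seed.
#' @return An object of class `trace_phantom_spec`.
#' @seealso [generate_bead_trace()]
#' @export
trace_phantom_spec <- function(amplitudes = 100, n_pulses = 12L, on_s = 3,
                               rest_s = 4, sample_rate_hz = 50, pre_s = 5,
                               post_s = 2, drift_nm_s = 1, noise_sd = 2,
                               tau_on_s = 0.3, tau_off_s = 0.5,
                               residual_frac = 0.2, seed = 1L) {
  n_pulses <- as.integer(n_pulses)
  stopifnot(n_pulses >= 2L, on_s > 0, rest_s > 0, sample_rate_hz > 0,
            pre_s >= 0, post_s >= 0, noise_sd >= 0, tau_on_s > 0,
            tau_off_s > 0, residual_frac >= 0, residual_frac < 1)
  amplitudes <- rep_len(as.numeric(amplitudes), n_pulses)
  if (any(amplitudes <= 0)) stop("pulse amplitudes must be > 0")
  if (sample_rate_hz * on_s < 2)
    stop("sample rate too low: fewer than 2 samples per ", on_s, " s pulse")
  structure(list(amplitudes = amplitudes, n_pulses = n_pulses, on_s = on_s,
                 rest_s = rest_s, sample_rate_hz = sample_rate_hz,
                 pre_s = pre_s, post_s = post_s, drift_nm_s = drift_nm_s,
                 noise_sd = noise_sd, tau_on_s = tau_on_s,
                 tau_off_s = tau_off_s, residual_frac = residual_frac,
                 seed = as.integer(seed)),
            class = "trace_phantom_spec")
}

# noiseless bead response of a trace phantom at times t (s)
.trace_response <- function(spec, t) {
  y <- spec$drift_nm_s * t
  for (i in seq_len(spec$n_pulses)) {
    t0 <- spec$pre_s + (i - 1) * (spec$on_s + spec$rest_s)
    A <- spec$amplitudes[i]
    res <- spec$residual_frac * A
    on <- t >= t0 & t < t0 + spec$on_s
    t1 <- t0 + spec$on_s
    relax <- t >= t1 & t < t1 + spec$rest_s
    after <- t >= t1 + spec$rest_s
    y[on] <- y[on] + A * (1 - exp(-(t[on] - t0) / spec$tau_on_s))
    v_end <- A * (1 - exp(-spec$on_s / spec$tau_on_s))
    # normalised exponential relaxation: reaches the residual exactly when
    # the rest period ends, so pulses do not bleed into each other's windows
    ef <- exp(-spec$rest_s / spec$tau_off_s)
    y[relax] <- y[relax] + res + (v_end - res) *
      (exp(-(t[relax] - t1) / spec$tau_off_s) - ef) / (1 - ef)
    y[after] <- y[after] + res
  }
  y
}

#' Generate a synthetic bead trace with ground-truth pulse amplitudes
#'
#' Samples the noiseless response of a [trace_phantom_spec()] on a uniform
#' time grid, adds noise, and returns the trace together with the analytic
#' per-pulse amplitudes (max minus start displacement of the noiseless trace
#' within each pulse window — the same convention the analysis uses).
#'
#' @param spec a [trace_phantom_spec()].
#' @return list with `trace` (a `bead_trace`: data.frame `time_s`,
#'   `displacement_nm` with attributes `sample_rate_hz` and `onset_s`) and
#'   `truth` (list: `amplitudes_nm`, `r12`, `decrease_pct`).
#' @export
generate_bead_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_phantom_spec"))
  total <- spec$pre_s + spec$n_pulses * (spec$on_s + spec$rest_s) + spec$post_s
  t <- seq(0, total, by = 1 / spec$sample_rate_hz)
  clean <- .trace_response(spec, t)
  y <- if (spec$noise_sd > 0)
    .with_seed(spec$seed, clean + stats::rnorm(length(t), 0, spec$noise_sd))
  else clean
  trace <- structure(data.frame(time_s = t, displacement_nm = y),
                     sample_rate_hz = spec$sample_rate_hz,
                     onset_s = spec$pre_s,
                     class = c("bead_trace", "data.frame"))
  amp <- vapply(seq_len(spec$n_pulses), function(i) {
    t0 <- spec$pre_s + (i - 1) * (spec$on_s + spec$rest_s)
    w <- t >= t0 & t < t0 + spec$on_s
    max(clean[w]) - clean[w][1L]
  }, numeric(1L))
  r12 <- amp[spec$n_pulses] / amp[1L]
  list(trace = trace,
       truth = list(amplitudes_nm = amp, r12 = r12,
                    decrease_pct = 100 * (1 - r12)))
}

#' Specification of a synthetic AFM approach curve
#'
#' Describes a force-distance approach curve for a spherical indenter on an
#' elastic half-space: flat (zero-force) baseline before the contact point,
#' then a Hertzian force rise. The generated force accounts for cantilever
#' deflection (indentation = piezo travel past contact minus deflection
#' force/k), matching how the fitting routine computes indentation.
#'
#' @param E_pa true Young's modulus, Pa.
#' @param nu Poisson ratio (default 0.5, incompressible).
#' @param radius_um indenter (bead) radius, um; default 7.5 (15 um bead).
#' @param k_n_m cantilever spring constant, N/m; default 0.03.
#' @param contact_um piezo position of the contact point, um.
#' @param max_force_nN maximum set force, nN; default 1. The curve extends
#'   just past the position where this force is reached.
#' @param speed_um_s approach speed, um/s (recorded metadata).
#' @param sample_spacing_um piezo position sampling interval, um.
#' @param z_max_um optional hard end of the sampled range; an error is raised
#'   if the set force cannot be reached within it.
#' @param noise_sd_pn additive Gaussian force noise SD, pN.
#' @param seed integer RNG seed.
#' @return An object of class `curve_phantom_spec`.
#' @seealso [generate_force_curve()], [hertz_force()]
#' @export
curve_phantom_spec <- function(E_pa, nu = 0.5, radius_um = 7.5, k_n_m = 0.03,
                               contact_um = 2, max_force_nN = 1,
                               speed_um_s = 5, sample_spacing_um = 0.005,
                               z_max_um = NULL, noise_sd_pn = 20, seed = 1L) {
  stopifnot(E_pa > 0, nu >= 0, nu <= 0.5, radius_um > 0, k_n_m > 0,
            contact_um > 0, max_force_nN > 0, speed_um_s > 0,
            sample_spacing_um > 0, noise_sd_pn >= 0)
  structure(list(E_pa = E_pa, nu = nu, radius_um = radius_um, k_n_m = k_n_m,
                 contact_um = contact_um, max_force_nN = max_force_nN,
                 speed_um_s = speed_um_s,
                 sample_spacing_um = sample_spacing_um,
                 z_max_um = z_max_um, noise_sd_pn = noise_sd_pn,
                 seed = as.integer(seed)),
            class = "curve_phantom_spec")
}

#' Generate a synthetic AFM approach curve with known modulus
#'
#' Solves, at every sampled piezo position past contact, the implicit
#' force balance `F = (4/3) E/(1-nu^2) sqrt(R) delta^(3/2)` with
#' `delta = (z - z_contact) - F/k` (deflection-corrected indentation), then
#' adds Gaussian force noise. The pre-contact baseline is exactly zero force
#' plus noise.
#'
#' @param spec a [curve_phantom_spec()].
#' @return list with `curve` (a `force_curve`: data.frame `position_um`,
#'   `force_nN` with attributes `k_n_m`, `radius_um`, `speed_um_s`) and
#'   `truth` (list: `E_pa`, `contact_um`).
#' @export
generate_force_curve <- function(spec) {
  stopifnot(inherits(spec, "curve_phantom_spec"))
  k_nN_um <- spec$k_n_m * 1000            # 1 N/m = 1000 nN/um
  B <- (4 / 3) * spec$E_pa / (1 - spec$nu^2) * sqrt(spec$radius_um) * 1e-3
  # piezo travel needed to reach the set force (delta + deflection)
  d_max <- (spec$max_force_nN / B)^(2 / 3)
  z_need <- spec$contact_um + d_max + spec$max_force_nN / k_nN_um
  if (!is.null(spec$z_max_um)) {
    if (spec$z_max_um < z_need)
      stop(sprintf(
        "max force %.3g nN unreachable within z_max = %.3g um (needs %.3g um)",
        spec$max_force_nN, spec$z_max_um, z_need))
    z_end <- spec$z_max_um
  } else {
    z_end <- z_need * 1.02
  }
  z <- seq(0, z_end, by = spec$sample_spacing_um)
  F <- numeric(length(z))
  past <- z > spec$contact_um
  if (any(past)) {
    z0 <- z[past] - spec$contact_um
    Fi <- B * z0^1.5                      # start from uncorrected Hertz
    for (it in 1:60) Fi <- B * pmax(z0 - Fi / k_nN_um, 0)^1.5
    F[past] <- Fi
  }
  if (spec$noise_sd_pn > 0)
    F <- .with_seed(spec$seed,
                    F + stats::rnorm(length(F), 0, spec$noise_sd_pn / 1000))
  curve <- force_curve(position_um = z, force_nN = F, k_n_m = spec$k_n_m,
                       radius_um = spec$radius_um,
                       speed_um_s = spec$speed_um_s)
  list(curve = curve,
       truth = list(E_pa = spec$E_pa, contact_um = spec$contact_um))
}
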