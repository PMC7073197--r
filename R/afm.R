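#' AFM approach force curve
#'
#' Container for a force-distance approach curve: piezo position (increasing
#' toward the sample) versus cantilever force, plus the probe metadata needed
#' for Hertz analysis.
#'
#' @param position_um piezo position, um, strictly increasing along the
#'   approach.
#' @param force_nN measured force, nN (same length).
#' @param k_n_m cantilever spring constant, N/m.
#' @param radius_um spherical indenter radius, um.
#' @param speed_um_s approach speed, um/s (metadata only).
#' @return An object of class `force_curve` (a data.frame with attributes).
#' @export
force_curve <- function(position_um, force_nN, k_n_m, radius_um,
                        speed_um_s = NA_real_) {
  stopifnot(length(position_um) == length(force_nN),
            k_n_m > 0, radius_um > 0)
  if (any(diff(position_um) <= 0))
    stop("'position_um' must be strictly increasing (approach direction)")
  structure(data.frame(position_um = position_um, force_nN = force_nN),
            k_n_m = k_n_m, radius_um = radius_um, speed_um_s = speed_um_s,
            class = c("force_curve", "data.frame"))
}

#' Hertz force for a spherical indenter
#'
#' Force-indentation law of a rigid sphere indenting an elastic half-space:
#' `F = (4/3) * E / (1 - nu^2) * sqrt(R) * delta^(3/2)`.
#'
#' @param delta_um indentation depth, um (>= 0); vectorised.
#' @param E_pa Young's modulus, Pa.
#' @param radius_um indenter radius, um.
#' @param nu Poisson ratio in `[0, 0.5]` (0.5 = incompressible).
#' @return force in nN.
#' @examples
#' hertz_force(1, E_pa = 300, radius_um = 7.5, nu = 0.5)  # 1.461 nN
#' @export
hertz_force <- function(delta_um, E_pa, radius_um, nu = 0.5) {
  stopifnot(E_pa > 0, radius_um > 0, nu >= 0, nu <= 0.5)
  if (any(delta_um < 0)) stop("indentation must be >= 0")
  (4 / 3) * E_pa / (1 - nu^2) * sqrt(radius_um) * delta_um^1.5 * 1e-3
}

# joint baseline + Hertz least squares at a fixed candidate contact point.
# Returns the profiled E, baseline offset and total RSS. Indentation is
# deflection-corrected: delta = (z - zc) - (F - b0)/k.
.hertz_profile <- function(curve, zc, nu, max_force_nN) {
  z <- curve$position_um; F <- curve$force_nN
  k_nN_um <- attr(curve, "k_n_m") * 1000
  pre <- z <= zc
  if (sum(pre) < 2L) return(list(rss = Inf))
  b0 <- mean(F[pre])
  post <- z > zc
  delta <- pmax((z[post] - zc) - (F[post] - b0) / k_nN_um, 0)
  C <- (4 / 3) / (1 - nu^2) * sqrt(attr(curve, "radius_um")) * delta^1.5 * 1e-3
  use <- (F[post] - b0) <= max_force_nN
  C <- C[use]; Fd <- F[post][use] - b0
  if (length(Fd) < 2L || sum(C^2) == 0)
    return(list(rss = Inf, n_post = length(Fd)))
  E <- sum(C * Fd) / sum(C^2)
  if (E <= 0) E <- .Machine$double.eps
  rss <- sum((F[pre] - b0)^2) + sum((Fd - C * E)^2)
  list(rss = rss, E = E, b0 = b0, n_post = length(Fd))
}

#' Estimate the contact point of an approach curve
#'
#' Finds the piezo position where the probe first touches the sample by
#' minimising the joint residual of a two-piece model: flat baseline before
#' the candidate contact point, Hertz force law after it. A coarse grid scan
#' brackets the optimum, which is then refined by golden-section search.
#'
#' @param curve a [force_curve()].
#' @param nu Poisson ratio used for the Hertz branch.
#' @param max_force_nN only data up to this force above baseline enter the
#'   Hertz branch.
#' @return contact point, um.
#' @export
estimate_contact_point <- function(curve, nu = 0.5, max_force_nN = Inf) {
  stopifnot(inherits(curve, "force_curve"))
  z <- curve$position_um
  n <- length(z)
  if (n < 20L) stop("curve too short to estimate a contact point")
  # require a contact region: force must rise well above baseline noise
  head_f <- curve$force_nN[seq_len(max(5L, n %/% 10L))]
  rise <- max(curve$force_nN) - stats::median(head_f)
  noise <- max(stats::mad(head_f), 1e-6)
  if (rise < 5 * noise)
    stop("no contact region found: force never rises above the baseline")
  cand <- z[seq(3L, n - 10L, length.out = min(60L, n - 12L))]
  rss <- vapply(cand, function(c0)
    .hertz_profile(curve, c0, nu, max_force_nN)$rss, numeric(1L))
  i <- which.min(rss)
  lo <- cand[max(1L, i - 1L)]; hi <- cand[min(length(cand), i + 1L)]
  opt <- stats::optimize(function(c0)
    .hertz_profile(curve, c0, nu, max_force_nN)$rss, c(lo, hi),
    tol = diff(range(z)) * 1e-6)
  opt$minimum
}

#' Fit the Hertz model to an AFM approach curve
#'
#' Estimates the sample's Young's modulus by least squares over the contact
#' region of the approach curve, up to a maximum force above baseline
#' (default 1 nN, the usual set force). The contact point is estimated with
#' [estimate_contact_point()] unless supplied; the baseline force offset is
#' re-estimated from the pre-contact segment, which makes the fitted modulus
#' invariant under a constant force offset. Indentation is corrected for
#' cantilever deflection, `delta = (z - z_c) - F/k`.
#'
#' @param curve a [force_curve()].
#' @param nu Poisson ratio (default 0.5, incompressible cell).
#' @param max_force_nN upper force bound of the fitted region, nN.
#' @param contact_um optional known contact point, um (skips estimation).
#' @return An object of class `hertz_fit`: Young's modulus `E_pa`, contact
#'   point `contact_um`, baseline offset `baseline_nN`, `nu`, RMS residual
#'   `residual_rms_pN`, number of fitted contact-region samples `n_post`, and
#'   the input curve. Has `print`, `coef`, `predict`, `residuals` and `plot`
#'   methods.
#' @examples
#' ph <- generate_force_curve(curve_phantom_spec(E_pa = 300, noise_sd_pn = 0))
#' fit <- fit_hertz(ph$curve)
#' coef(fit)["E_pa"]  # ~300
#' @export
fit_hertz <- function(curve, nu = 0.5, max_force_nN = 1, contact_um = NULL) {
  stopifnot(inherits(curve, "force_curve"), nu >= 0, nu <= 0.5,
            max_force_nN > 0)
  if (is.null(contact_um))
    contact_um <- estimate_contact_point(curve, nu, max_force_nN)
  sol <- .hertz_profile(curve, contact_um, nu, max_force_nN)
  if (is.null(sol$n_post) || sol$n_post < 10L)
    stop("fewer than 10 contact-region samples below the force bound")
  if (!is.finite(sol$rss)) stop("Hertz fit failed at the contact point")
  fit <- structure(list(E_pa = sol$E, contact_um = contact_um,
                        baseline_nN = sol$b0, nu = nu,
                        max_force_nN = max_force_nN,
                        residual_rms_pN = sqrt(sol$rss /
                          length(curve$position_um)) * 1000,
                        n_post = sol$n_post, curve = curve),
                   class = "hertz_fit")
  fit
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat("Hertz spherical-indenter fit\n")
  cat(sprintf("  Young's modulus: %.4g Pa (nu = %.2f)\n", x$E_pa, x$nu))
  cat(sprintf("  contact point:   %.4g um\n", x$contact_um))
  cat(sprintf("  baseline offset: %.4g nN; RMS residual %.3g pN over %d contact samples\n",
              x$baseline_nN, x$residual_rms_pN, x$n_post))
  invisible(x)
}

#' @export
coef.hertz_fit <- function(object, ...) {
  c(E_pa = object$E_pa, contact_um = object$contact_um,
    baseline_nN = object$baseline_nN)
}

#' @rdname fit_hertz
#' @param object,x a `hertz_fit`.
#' @param position_um piezo positions at which to predict force; defaults to
#'   the fitted curve's positions.
#' @param ... unused.
#' @export
predict.hertz_fit <- function(object, position_um = NULL, ...) {
  if (is.null(position_um)) position_um <- object$curve$position_um
  k_nN_um <- attr(object$curve, "k_n_m") * 1000
  R <- attr(object$curve, "radius_um")
  B <- (4 / 3) * object$E_pa / (1 - object$nu^2) * sqrt(R) * 1e-3
  F <- numeric(length(position_um))
  past <- position_um > object$contact_um
  if (any(past)) {
    z0 <- position_um[past] - object$contact_um
    Fi <- B * z0^1.5
    for (it in 1:60) Fi <- B * pmax(z0 - Fi / k_nN_um, 0)^1.5
    F[past] <- Fi
  }
  F + object$baseline_nN
}

#' @export
residuals.hertz_fit <- function(object, ...) {
  object$curve$force_nN - predict(object)
}

#' @rdname fit_hertz
#' @export
plot.hertz_fit <- function(x, ...) {
  graphics::plot(x$curve$position_um, x$curve$force_nN, pch = 16, cex = 0.3,
                 xlab = "piezo position (um)", ylab = "force (nN)",
                 main = sprintf("Hertz fit: E = %.3g Pa", x$E_pa), ...)
  graphics::lines(x$curve$position_um, predict(x), col = 2, lwd = 2)
  graphics::abline(v = x$contact_um, lty = 2, col = 4)
  invisible(x)
}

#' Fit a batch of approach curves and summarise the cohort
#'
#' Applies [fit_hertz()] to each curve; reports per-curve moduli plus the
#' cohort mean and median (both are reported because cohort statistics of
#' AFM moduli are variously summarised either way).
#'
#' @param curves list of [force_curve()] objects.
#' @param ... passed to [fit_hertz()].
#' @return list with `fits` (data.frame: curve, E_pa, contact_um,
#'   residual_rms_pN) and `cohort` (named vector: mean_E_pa, median_E_pa, n).
#' @export
fit_hertz_batch <- function(curves, ...) {
  fits <- lapply(curves, fit_hertz, ...)
  tab <- data.frame(curve = seq_along(fits),
                    E_pa = vapply(fits, `[[`, 0, "E_pa"),
                    contact_um = vapply(fits, `[[`, 0, "contact_um"),
                    residual_rms_pN = vapply(fits, `[[`, 0, "residual_rms_pN"))
  list(fits = tab,
       cohort = c(mean_E_pa = mean(tab$E_pa),
                  median_E_pa = stats::median(tab$E_pa),
                  n = nrow(tab)))
}
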