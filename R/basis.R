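# Exponential convolution of a piecewise-linear curve and the basis set used
# by the linearised (basis-function) reference-tissue fitters.

# Analytic convolution of a piecewise-linear curve with exp(-theta*t).
# t: strictly increasing sample times (min), y: values at t; the curve is
# anchored at (0, 0) if t[1] > 0. Returns the convolution at the same t.
# Exact for the interpolant: each segment integral is closed-form, so no
# quadrature grid is involved.
.conv_exp_pl <- function(t, y, theta) {
  if (t[1L] > 0) {
    t <- c(0, t)
    y <- c(0, y)
    drop_first <- TRUE
  } else drop_first <- FALSE
  n <- length(t)
  out <- numeric(n)
  for (i in 2:n) {
    dt <- t[i] - t[i - 1L]
    E <- exp(-theta * dt)
    one_mE <- -expm1(-theta * dt)
    m <- (y[i] - y[i - 1L]) / dt
    seg <- y[i - 1L] * one_mE / theta + m * (dt / theta - one_mE / theta^2)
    out[i] <- out[i - 1L] * E + seg
  }
  if (drop_first) out[-1L] else out
}

#' Convolve a reference TAC with a decaying exponential
#'
#' Computes `(C_R (*) exp(-theta * t))` at the frame midpoints, treating the
#' reference curve as piecewise-linear between midpoints with `C_R(0) = 0`.
#' Segment integrals are analytic, so the result is exact for the
#' interpolant. This is the impulse-response kernel of the simplified
#' reference tissue model; `theta` plays the role of the apparent efflux
#' rate k2a.
#'
#' @param ref A [tac()] (the reference-tissue curve).
#' @param theta Exponential rate (min^-1), > 0.
#' @return Numeric vector of per-frame values (same units as `ref` times
#'   minutes).
#' @examples
#' sch <- parse_frame_scheme("1x60,4x60")
#' flat <- tac(sch, rep(1, 5))
#' # constant input from t=0: closed form c * (1 - exp(-theta*t)) / theta
#' convolve_exp(flat, 0.3)
#' @export
convolve_exp <- function(ref, theta) {
  stopifnot(inherits(ref, "tac"))
  if (!is.finite(theta) || theta <= 0)
    stop("'theta' must be a positive rate (min^-1)")
  if (n_frames(ref$schedule) < 2L)
    stop("reference TAC needs at least 2 frames")
  .conv_exp_pl(.midpoints_min(ref$schedule), ref$values, theta)
}

#' Build a basis set for reference-tissue fitting
#'
#' Precomputes, for a logarithmically spaced grid of candidate apparent
#' efflux rates theta, the convolution of the reference TAC with
#' `exp(-theta*t)`. The default grid (0.006-0.6 min^-1, 100 points)
#' brackets plausible apparent efflux rates for reversible tracers.
#'
#' @param ref A [tac()].
#' @param theta_min,theta_max Grid bounds (min^-1), `0 < theta_min <
#'   theta_max`.
#' @param n_theta Number of grid points, >= 2.
#' @return An object of class `srtm_basis`: `thetas`, `curves` (frames x
#'   n_theta matrix), `ref`.
#' @export
srtm_basis <- function(ref, theta_min = 0.006, theta_max = 0.6,
                       n_theta = 100) {
  stopifnot(inherits(ref, "tac"))
  if (!is.finite(theta_min) || !is.finite(theta_max) ||
      theta_min <= 0 || theta_min >= theta_max)
    stop("need 0 < theta_min < theta_max")
  if (n_theta < 2) stop("'n_theta' must be >= 2")
  thetas <- exp(seq(log(theta_min), log(theta_max), length.out = n_theta))
  curves <- vapply(thetas, function(th) convolve_exp(ref, th),
                   numeric(n_frames(ref$schedule)))
  structure(list(thetas = thetas, curves = curves, ref = ref),
            class = "srtm_basis")
}

#' @export
print.srtm_basis <- function(x, ...) {
  cat(sprintf("SRTM basis: %d log-spaced thetas in [%.4g, %.4g] min^-1, %d frames\n",
              length(x$thetas), min(x$thetas), max(x$thetas),
              nrow(x$curves)))
  invisible(x)
}
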