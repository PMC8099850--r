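#' SRTM forward model
#'
#' Generates a target-tissue TAC from the simplified reference tissue model,
#' `C_T(t) = R1 * C_R(t) + (k2 - R1 * k2a) * (C_R (*) exp(-k2a * t))`,
#' with apparent efflux `k2a = k2 / (1 + BP_ND)`. Setting `R1 = 1`,
#' `BP_ND = 0` and `k2 = k2a` reproduces the reference curve exactly.
#'
#' @param ref A [tac()] reference curve.
#' @param R1 Relative delivery K1/K1' (unitless).
#' @param k2 Target efflux rate (min^-1).
#' @param bp_nd Non-displaceable binding potential (unitless), > -1.
#' @return A [tac()] of the target tissue on the reference schedule.
#' @export
srtm_forward <- function(ref, R1, k2, bp_nd) {
  stopifnot(inherits(ref, "tac"))
  if (!all(is.finite(c(R1, k2, bp_nd))))
    stop("model parameters must be finite")
  if (bp_nd <= -1) stop("'bp_nd' must be > -1")
  k2a <- k2 / (1 + bp_nd)
  if (k2a <= 0) stop("apparent efflux k2a = k2/(1+BP_ND) must be > 0")
  vals <- R1 * ref$values + (k2 - R1 * k2a) * convolve_exp(ref, k2a)
  tac(ref$schedule, vals, label = "srtm")
}

# Vectorised basis-function fit over a frames x n matrix of target TACs.
# k2_prime = NULL -> two-coefficient RPM fit; otherwise one-coefficient
# SRTM2 fit with k2' fixed. Ties in RSS resolve to the smallest theta
# (thetas ascend and improvement must be strict). Returns per-column
# parameter vectors and validity flags; implausible fits (R1 outside
# [0, 3], BP_ND outside [-0.5, 10]) are flagged, never clamped.
.fit_basis <- function(Y, basis, weights = NULL, k2_prime = NULL) {
  stopifnot(inherits(basis, "srtm_basis"))
  refv <- basis$ref$values
  nf <- length(refv)
  if (nrow(Y) != nf)
    stop("data and basis do not share a schedule (frame count mismatch)")
  w <- if (is.null(weights)) rep(1, nf) else as.numeric(weights)
  if (length(w) != nf || any(!is.finite(w)) || any(w < 0))
    stop("'weights' must be ", nf, " non-negative finite values")
  nv <- ncol(Y)
  thetas <- basis$thetas
  ywy <- colSums(w * Y * Y)
  best_rss <- rep(Inf, nv)
  best_th <- rep(NA_real_, nv)
  R1 <- k2 <- rep(NA_real_, nv)
  rw <- refv * w
  a11 <- sum(rw * refv)
  b1 <- as.vector(crossprod(rw, Y))
  degenerate <- a11 <= 0
  for (j in seq_along(thetas)) {
    th <- thetas[j]
    Bj <- basis$curves[, j]
    if (is.null(k2_prime)) {
      bw <- Bj * w
      a12 <- sum(rw * Bj)
      a22 <- sum(bw * Bj)
      det <- a11 * a22 - a12 * a12
      if (degenerate || det <= .Machine$double.eps * a11 * a22) next
      b2 <- as.vector(crossprod(bw, Y))
      ca <- (a22 * b1 - a12 * b2) / det
      cb <- (a11 * b2 - a12 * b1) / det
      rss <- ywy - (ca * b1 + cb * b2)
      better <- is.finite(rss) & rss < best_rss
      if (any(better)) {
        best_rss[better] <- rss[better]
        best_th[better] <- th
        R1[better] <- ca[better]
        k2[better] <- cb[better] + ca[better] * th
      }
    } else {
      B2 <- refv + (k2_prime - th) * Bj
      g <- sum(w * B2 * B2)
      if (g <= 0) next
      b2 <- as.vector(crossprod(B2 * w, Y))
      r1 <- b2 / g
      rss <- ywy - r1 * b2
      better <- is.finite(rss) & rss < best_rss
      if (any(better)) {
        best_rss[better] <- rss[better]
        best_th[better] <- th
        R1[better] <- r1[better]
        k2[better] <- r1[better] * k2_prime
      }
    }
  }
  bp <- k2 / best_th - 1
  valid <- is.finite(R1) & is.finite(best_th) & is.finite(bp) &
    R1 >= 0 & R1 <= 3 & bp >= -0.5 & bp <= 10
  list(R1 = R1, k2 = k2, k2a = best_th, bp_nd = bp,
       rss = best_rss, valid = valid)
}

#' Fit the simplified reference tissue model to a single TAC
#'
#' Basis-function fit: for every candidate apparent efflux rate theta in the
#' basis grid the model is linear in its remaining coefficients and solved in
#' closed form; the theta with the smallest (weighted) residual sum of
#' squares wins. `method = "rpm"` is the two-coefficient receptor parametric
#' mapping fit estimating R1, k2 and BP_ND freely; `method = "srtm2"` fixes
#' the reference efflux `k2'` (from a first RPM pass, see
#' [estimate_k2_prime()]) and estimates R1 alone per theta, which stabilises
#' voxel-level fits.
#'
#' @param target A [tac()] to fit.
#' @param basis An [srtm_basis()] built from the reference TAC, or a [tac()]
#'   reference from which a default basis is built.
#' @param method `"srtm2"` or `"rpm"`.
#' @param k2_prime Reference efflux rate (min^-1); required for `"srtm2"`.
#' @param weights Optional per-frame weights (e.g. frame durations);
#'   uniform by default.
#' @return An object of class `srtm_fit` with components `coefficients`
#'   (R1, k2, k2a, BP_ND), `k2_prime`, `method`, `rss`, `valid`,
#'   `fitted.values`, `target`, `basis`.
#' @examples
#' sch <- parse_frame_scheme("1x15,3x5,3x10,2x30,3x60,2x150,2x300,7x600")
#' ref <- generate_reference_tac(sch)
#' tgt <- srtm_forward(ref, R1 = 0.85, k2 = 0.1275, bp_nd = 0.4)
#' fit <- srtm_fit(tgt, srtm_basis(ref), method = "rpm")
#' coef(fit)
#' @export
srtm_fit <- function(target, basis, method = c("srtm2", "rpm"),
                     k2_prime = NULL, weights = NULL) {
  stopifnot(inherits(target, "tac"))
  method <- match.arg(method)
  if (inherits(basis, "tac")) basis <- srtm_basis(basis)
  stopifnot(inherits(basis, "srtm_basis"))
  if (method == "srtm2") {
    if (is.null(k2_prime) || !is.finite(k2_prime) || k2_prime <= 0)
      stop("'k2_prime' (min^-1, > 0) is required for method = 'srtm2'")
  } else k2_prime <- NULL
  res <- .fit_basis(matrix(target$values, ncol = 1L), basis,
                    weights = weights, k2_prime = k2_prime)
  cf <- c(R1 = res$R1, k2 = res$k2, k2a = res$k2a, BP_ND = res$bp_nd)
  fitted <- if (is.finite(res$R1) && is.finite(res$k2a) && res$k2a > 0 &&
                is.finite(res$bp_nd) && res$bp_nd > -1)
    srtm_forward(basis$ref, res$R1, res$k2, res$bp_nd)$values
  else rep(NA_real_, n_frames(target$schedule))
  structure(list(coefficients = cf,
                 k2_prime = if (is.null(k2_prime)) NA_real_ else k2_prime,
                 method = method, rss = res$rss, valid = res$valid,
                 fitted.values = fitted, target = target, basis = basis,
                 weights = weights),
            class = "srtm_fit")
}

#' @export
print.srtm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s basis-function fit%s\n",
              toupper(x$method),
              if (x$valid) "" else "  [flagged implausible]"))
  print(round(x$coefficients, digits))
  if (is.finite(x$k2_prime))
    cat(sprintf("k2' (fixed): %.*g min^-1\n", digits, x$k2_prime))
  cat(sprintf("RSS: %.*g\n", digits, x$rss))
  invisible(x)
}

#' @export
coef.srtm_fit <- function(object, ...) object$coefficients

#' @export
summary.srtm_fit <- function(object, ...) {
  n <- n_frames(object$target$schedule)
  out <- list(coefficients = object$coefficients, method = object$method,
              k2_prime = object$k2_prime, rss = object$rss,
              valid = object$valid, n_frames = n,
              sigma = sqrt(object$rss / max(1L, n - if (object$method == "rpm") 3L else 2L)))
  class(out) <- "summary.srtm_fit"
  out
}

#' @export
print.summary.srtm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s fit over %d frames\n", toupper(x$method), x$n_frames))
  print(round(x$coefficients, digits))
  cat(sprintf("residual sigma %.3g; fit %s\n", x$sigma,
              if (x$valid) "valid" else "flagged implausible"))
  invisible(x)
}

#' @export
fitted.srtm_fit <- function(object, ...) object$fitted.values

#' @export
residuals.srtm_fit <- function(object, ...) {
  object$target$values - object$fitted.values
}

#' @export
predict.srtm_fit <- function(object, ref = NULL, ...) {
  if (is.null(ref)) return(object$fitted.values)
  stopifnot(inherits(ref, "tac"))
  cf <- object$coefficients
  srtm_forward(ref, cf[["R1"]], cf[["k2"]], cf[["BP_ND"]])$values
}

#' @export
plot.srtm_fit <- function(x, ..., xlab = "Time (min)",
                          ylab = "Activity (kBq/mL)") {
  tmin <- .midpoints_min(x$target$schedule)
  graphics::plot(tmin, x$target$values, pch = 16, xlab = xlab, ylab = ylab,
                 main = sprintf("%s fit: R1 = %.3f", toupper(x$method),
                                x$coefficients[["R1"]]), ...)
  graphics::lines(tmin, x$fitted.values, col = "firebrick", lwd = 2)
  graphics::lines(tmin, x$basis$ref$values, col = "grey50", lty = 2)
  graphics::legend("topright", bty = "n", lwd = c(NA, 2, 1),
                   pch = c(16, NA, NA), lty = c(NA, 1, 2),
                   col = c("black", "firebrick", "grey50"),
                   legend = c("target", "fit", "reference"))
  invisible(x)
}

#' Simulate noisy replicates of a fitted TAC
#'
#' Draws per-frame Gaussian noise with standard deviation
#' `noise_level * value * sqrt(mean(durations) / duration)`, the
#' count-statistics shape in which short early frames are noisier.
#'
#' @param object An `srtm_fit`.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param noise_level Proportional noise level (SD at a frame of mean
#'   duration).
#' @param ... Unused.
#' @return A frames x `nsim` matrix of simulated TAC values.
#' @export
simulate.srtm_fit <- function(object, nsim = 1, seed = NULL,
                              noise_level = 0.05, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  sd <- .frame_noise_sd(mu, object$target$schedule, noise_level)
  matrix(stats::rnorm(length(mu) * nsim, mean = mu, sd = sd),
         ncol = nsim)
}

# SD = noise_level * |value| * sqrt(mean duration / duration)
.frame_noise_sd <- function(values, schedule, noise_level) {
  d <- schedule$durations
  noise_level * abs(values) * sqrt(mean(d) / d)
}
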