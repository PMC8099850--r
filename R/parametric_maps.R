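# Voxel-wise parametric imaging: RPM first pass, coupled k2', SRTM2 maps.

.maps_from_fit <- function(res, shape, idx, voxel_size, basis, k2_prime,
                           method) {
  blank <- function() array(NA_real_, shape)
  R1 <- blank(); k2a <- blank(); bp <- blank(); k2 <- blank()
  validity <- array(FALSE, shape)
  keep <- res$valid
  # invalid voxels carry NaN in every parameter volume
  put <- function(vol, v) {
    v[!keep] <- NaN
    vol[idx] <- v
    vol
  }
  R1 <- put(R1, res$R1); k2a <- put(k2a, res$k2a)
  bp <- put(bp, res$bp_nd); k2 <- put(k2, res$k2)
  validity[idx] <- keep
  structure(list(R1 = R1, k2a = k2a, bp_nd = bp, k2 = k2,
                 validity = validity,
                 k2_prime = if (is.null(k2_prime)) NA_real_ else k2_prime,
                 method = method, voxel_size = voxel_size,
                 thetas = basis$thetas,
                 n_fitted = length(idx),
                 invalid_fraction = mean(!keep)),
            class = "parametric_maps")
}

#' @export
print.parametric_maps <- function(x, ...) {
  cat(sprintf("Parametric maps (%s): %s grid, %d voxels fitted, %.1f%% flagged invalid\n",
              toupper(x$method), paste(dim(x$R1), collapse = "x"),
              x$n_fitted, 100 * x$invalid_fraction))
  if (is.finite(x$k2_prime))
    cat(sprintf("  coupled k2' = %.4g min^-1\n", x$k2_prime))
  invisible(x)
}

.image_fit <- function(img, basis, mask, weights, k2_prime, method) {
  stopifnot(inherits(img, "dynamic_image"))
  if (inherits(basis, "tac")) basis <- srtm_basis(basis)
  stopifnot(inherits(basis, "srtm_basis"))
  shape <- dim(img$voxels)[1:3]
  nf <- dim(img$voxels)[4L]
  if (nf != nrow(basis$curves))
    stop("image and basis do not share a schedule (frame count mismatch)")
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "voi_mask"))
    if (!identical(dim(mask$labels), shape))
      stop("mask grid does not match image grid")
    idx <- which(mask$labels != 0L)
    if (length(idx) == 0L) stop("mask selects no voxels")
  } else idx <- seq_len(prod(shape))
  Y <- t(matrix(img$voxels, ncol = nf)[idx, , drop = FALSE])
  res <- .fit_basis(Y, basis, weights = weights, k2_prime = k2_prime)
  .maps_from_fit(res, shape, idx, img$voxel_size, basis, k2_prime, method)
}

#' First-pass receptor parametric mapping (RPM)
#'
#' Voxel-wise two-coefficient basis-function fit of the simplified reference
#' tissue model, producing R1, k2, k2a and BP_ND maps. Used as the first run
#' from which the coupled reference efflux `k2'` is taken (see
#' [estimate_k2_prime()]) before the one-coefficient [fit_srtm2()] pass.
#'
#' @param x A [dynamic_image()] or a single [tac()].
#' @param basis An [srtm_basis()] (or reference [tac()] from which a default
#'   basis is built) sharing the data's schedule.
#' @param mask Optional [voi_mask()]; only voxels with a non-zero label are
#'   fitted, all others are marked not fitted.
#' @param weights Optional per-frame weights.
#' @return For an image, a `parametric_maps` object; for a TAC, an
#'   [srtm_fit()] object.
#' @export
fit_rpm <- function(x, basis, mask = NULL, weights = NULL) {
  if (inherits(x, "tac"))
    return(srtm_fit(x, basis, method = "rpm", weights = weights))
  .image_fit(x, basis, mask, weights, k2_prime = NULL, method = "rpm")
}

#' Coupled reference efflux rate from an RPM first pass
#'
#' The reference efflux `k2' = k2 / R1` is computed per voxel from the RPM
#' maps and its median is taken across all valid voxels with `BP_ND`
#' strictly greater than `bp_threshold`, restricting to voxels with
#' appreciable specific binding where `k2'` is well identified.
#'
#' @param maps A `parametric_maps` object from [fit_rpm()].
#' @param bp_threshold BP_ND cutoff (strict inequality); default 0.05.
#' @return Scalar `k2'` (min^-1).
#' @export
estimate_k2_prime <- function(maps, bp_threshold = 0.05) {
  stopifnot(inherits(maps, "parametric_maps"))
  if (!is.finite(bp_threshold) || bp_threshold < 0)
    stop("'bp_threshold' must be >= 0")
  sel <- maps$validity & is.finite(maps$bp_nd) &
    maps$bp_nd > bp_threshold & is.finite(maps$R1) & maps$R1 > 0
  if (!any(sel))
    stop("no valid voxel has BP_ND > ", bp_threshold,
         "; lower the threshold deliberately if appropriate")
  stats::median(maps$k2[sel] / maps$R1[sel])
}

#' Second-pass SRTM2 parametric maps with fixed k2'
#'
#' Voxel-wise one-coefficient basis-function fit with the reference efflux
#' fixed to the coupled `k2'`, yielding R1, k2a and `BP_ND = R1 * k2' / k2a
#' - 1` maps. Fixing `k2'` removes one degree of freedom per voxel and
#' stabilises the R1 estimate.
#'
#' @inheritParams fit_rpm
#' @param k2_prime Reference efflux rate (min^-1), > 0; typically from
#'   [estimate_k2_prime()].
#' @return For an image, a `parametric_maps` object (with `k2_prime`
#'   recorded); for a TAC, an [srtm_fit()] object.
#' @export
fit_srtm2 <- function(x, basis, k2_prime, mask = NULL, weights = NULL) {
  if (!is.finite(k2_prime) || k2_prime <= 0)
    stop("'k2_prime' must be a positive rate (min^-1)")
  if (inherits(x, "tac"))
    return(srtm_fit(x, basis, method = "srtm2", k2_prime = k2_prime,
                    weights = weights))
  .image_fit(x, basis, mask, weights, k2_prime = k2_prime,
             method = "srtm2")
}

#' Write parametric maps as NIfTI volumes plus a JSON fit report
#'
#' Writes `r1.nii.gz`, `k2a.nii.gz`, `bpnd.nii.gz`, `validity.nii.gz` and
#' `fit.json` (k2', theta grid, invalid-voxel fraction) into `dir`.
#'
#' @param maps A `parametric_maps` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_parametric_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "parametric_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wv <- function(arr, name, datatype = "float") {
    nii <- RNifti::asNifti(arr)
    RNifti::pixdim(nii) <- maps$voxel_size
    RNifti::writeNifti(nii, file.path(dir, name), datatype = datatype)
  }
  wv(maps$R1, "r1.nii.gz")
  wv(maps$k2a, "k2a.nii.gz")
  wv(maps$bp_nd, "bpnd.nii.gz")
  wv(maps$validity + 0L, "validity.nii.gz", datatype = "int16")
  jsonlite::write_json(list(method = maps$method,
                            k2_prime = maps$k2_prime,
                            theta_min = min(maps$thetas),
                            theta_max = max(maps$thetas),
                            n_theta = length(maps$thetas),
                            n_fitted = maps$n_fitted,
                            invalid_fraction = maps$invalid_fraction),
                       file.path(dir, "fit.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
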