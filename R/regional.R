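# Regional extraction: VOI means on parametric maps and the volume-weighted
# global cortical composite.

#' Default grey-matter VOI catalog
#'
#' The ordered list of cortical target-region names used for reporting and by
#' the synthetic atlas. The cerebellar grey matter is the reference tissue
#' and is deliberately not part of the catalog; the global cortical composite
#' is a volume-weighted average across all of these targets, not a catalog
#' entry.
#'
#' @return Character vector of region names, in report order.
#' @export
default_voi_catalog <- function() {
  c("Anterior temporal lobe medial part",
    "Anterior temporal lobe lateral part",
    "Parahippocampal and ambient gyri",
    "Superior temporal gyrus",
    "Middle and inferior temporal gyri",
    "Fusiform gyrus",
    "Insula",
    "Lateral remainder of occipital lobe",
    "Gyrus cinguli anterior part",
    "Gyrus cinguli posterior part",
    "Middle frontal gyrus",
    "Posterior temporal lobe",
    "Inferolateral remainder of parietal lobe",
    "Precentral gyrus",
    "Gyrus rectus",
    "Orbitofrontal gyri",
    "Inferior frontal gyrus",
    "Superior frontal gyrus",
    "Postcentral gyrus",
    "Superior parietal gyrus",
    "Lingual gyrus",
    "Cuneus")
}

#' Name of the global cortical composite row
#' @export
composite_region_name <- function() "Global Cortex"

#' Regional means of an R1 parametric map
#'
#' Superimposes the VOI mask on the R1 map and reports, per target region,
#' the mean over valid voxels, the valid-voxel count and volume, plus a
#' volume-weighted global composite row across all target regions (the
#' reference region is excluded from the composite). Regions without any
#' valid voxel are reported as missing (`NA`), never as zero, with a
#' warning.
#'
#' @param maps A `parametric_maps` object.
#' @param mask A [voi_mask()] on the same grid.
#' @return A data.frame with columns `region`, `label`, `n_voxels`,
#'   `volume_mm3`, `mean_r1`; the first row is the composite (label `NA`).
#' @export
regional_means <- function(maps, mask) {
  stopifnot(inherits(maps, "parametric_maps"), inherits(mask, "voi_mask"))
  if (!identical(dim(maps$R1), dim(mask$labels)))
    stop("mask grid does not match parametric-map grid")
  vox_vol <- prod(maps$voxel_size)
  labs <- target_labels(mask)
  rows <- lapply(labs, function(lb) {
    sel <- mask$labels == lb & maps$validity & is.finite(maps$R1)
    n <- sum(sel)
    data.frame(region = mask$names[[as.character(lb)]], label = lb,
               n_voxels = n, volume_mm3 = n * vox_vol,
               mean_r1 = if (n > 0) mean(maps$R1[sel]) else NA_real_)
  })
  tab <- do.call(rbind, rows)
  empty <- is.na(tab$mean_r1)
  if (any(empty))
    warning("regions with no valid voxel reported as missing: ",
            paste(tab$region[empty], collapse = ", "))
  ok <- !empty
  comp <- if (any(ok))
    sum(tab$volume_mm3[ok] * tab$mean_r1[ok]) / sum(tab$volume_mm3[ok])
  else NA_real_
  out <- rbind(data.frame(region = composite_region_name(), label = NA_integer_,
                          n_voxels = sum(tab$n_voxels[ok]),
                          volume_mm3 = sum(tab$volume_mm3[ok]),
                          mean_r1 = comp),
               tab)
  rownames(out) <- NULL
  out
}
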