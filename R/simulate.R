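# Synthetic dynamic-PET phantoms with known ground truth: a plasma-like
# input, reference-tissue kinetics, block-structured atlas, paired
# test/retest cohorts.

# Plasma-like input: linear rise to the peak, then a tri-exponential
# washout. t in minutes; amplitudes in kBq/mL.
.input_curve <- function(t, peak_time, amplitudes, lambdas) {
  A0 <- sum(amplitudes)
  out <- ifelse(t <= peak_time, A0 * t / peak_time, 0)
  late <- t > peak_time
  if (any(late)) {
    u <- t[late] - peak_time
    out[late] <- colSums(amplitudes * exp(-outer(lambdas, u)))
  }
  out
}

#' Generate a noise-free reference-tissue TAC
#'
#' Emulates a measured reference-region (cerebellar grey matter) curve: a
#' plasma-like input with a linear rise to a peak at about one minute and a
#' tri-exponential washout is passed through one-tissue kinetics with influx
#' `K1_ref` and efflux `k2_prime`. The convolution is evaluated analytically
#' on a fine time grid and sampled at the frame midpoints.
#'
#' @param schedule A [frame_schedule()].
#' @param k2_prime Reference efflux rate (min^-1), > 0.
#' @param K1_ref Reference influx scale (mL cm^-3 min^-1), > 0.
#' @param peak_time Input peak time (min), > 0.
#' @param amplitudes Three non-negative exponential amplitudes (kBq/mL);
#'   their sum is the input peak height.
#' @param lambdas Three positive washout rates (min^-1).
#' @return A [tac()] labelled "reference"; non-negative, rising to a single
#'   peak then decaying.
#' @export
generate_reference_tac <- function(schedule, k2_prime = 0.15,
                                   K1_ref = 0.35, peak_time = 1,
                                   amplitudes = c(25, 8, 3),
                                   lambdas = c(3.5, 0.35, 0.015)) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (!is.finite(k2_prime) || k2_prime <= 0) stop("'k2_prime' must be > 0")
  if (!is.finite(K1_ref) || K1_ref <= 0) stop("'K1_ref' must be > 0")
  if (!is.finite(peak_time) || peak_time <= 0)
    stop("'peak_time' must be > 0")
  if (length(amplitudes) != length(lambdas))
    stop("'amplitudes' and 'lambdas' must have equal length")
  if (any(amplitudes < 0)) stop("'amplitudes' must be >= 0")
  if (any(lambdas <= 0)) stop("'lambdas' must be > 0")
  mid <- .midpoints_min(schedule)
  grid <- sort(unique(c(seq(0, max(mid), by = 0.02), mid)))
  cp <- .input_curve(grid, peak_time, amplitudes, lambdas)
  cr <- K1_ref * .conv_exp_pl(grid, cp, k2_prime)
  tac(schedule, stats::approx(grid, cr, xout = mid)$y,
      label = "reference")
}

#' Ground truth for a synthetic test-retest cohort
#'
#' Defines the study conditions the phantoms emulate: per-subject diagnostic
#' group and amyloid status, per-subject global R1 level drawn around the
#' group mean, a fixed regional R1 pattern (volume-weighted to zero mean so
#' the composite matches the group level), regional binding potentials
#' (high in amyloid-positive subjects, low otherwise), a global reference
#' efflux `k2'`, a proportional TAC noise level, and a between-scan
#' per-region R1 jitter.
#'
#' @param n_cu,n_mci,n_ad Subjects per diagnostic group.
#' @param group_means Named true composite R1 means per group.
#' @param between_subject_sd SD of the per-subject global R1 level.
#' @param k2_prime True reference efflux (min^-1).
#' @param noise_level Proportional TAC noise SD at a frame of mean duration.
#' @param jitter_sd SD of the per-region between-scan R1 jitter
#'   (retest = truth + jitter).
#' @param seed Integer seed; the generator is deterministic given it.
#' @return Object of class `ground_truth`: `subjects` (id, group,
#'   amyloid_status, r1_level), `regions` (region, label, r1_offset,
#'   bp_positive, bp_negative), plus the scalar conditions.
#' @export
ground_truth <- function(n_cu = 5, n_mci = 1, n_ad = 6,
                         group_means = c(CU = 0.93, MCI = 0.91, AD = 0.82),
                         between_subject_sd = 0.04,
                         k2_prime = 0.15, noise_level = 0.05,
                         jitter_sd = 0.01, seed = 20210421) {
  if (n_cu < 0 || n_mci < 0 || n_ad < 0) stop("group counts must be >= 0")
  n <- n_cu + n_mci + n_ad
  if (n == 0) stop("cohort must contain at least one subject")
  if (noise_level < 0 || jitter_sd < 0)
    stop("noise and jitter levels must be >= 0")
  if (k2_prime <= 0) stop("'k2_prime' must be > 0")
  regions <- default_voi_catalog()
  nr <- length(regions)
  dims <- .atlas_dims()
  vols <- dims[, 1] * dims[, 2] * dims[, 3]
  offset <- seq(-0.06, 0.06, length.out = nr)
  offset <- offset - sum(vols * offset) / sum(vols)  # composite-neutral
  # specific binding pattern: spread over plausible cortical ranges
  bp_pos <- seq(0.6, 1.5, length.out = nr)
  bp_neg <- seq(0.05, 0.4, length.out = nr)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  group <- c(rep("CU", n_cu), rep("MCI", n_mci), rep("AD", n_ad))
  # visual-read amyloid status: all AD positive, 20% of CU, MCI negative
  amyloid <- ifelse(group == "AD", "positive", "negative")
  if (n_cu > 0) {
    n_pos <- round(0.2 * n_cu)
    if (n_pos > 0) amyloid[seq_len(n_pos)] <- "positive"
  }
  r1_level <- stats::rnorm(n, mean = group_means[group],
                           sd = between_subject_sd)
  subjects <- data.frame(
    id = sprintf("sub-%02d", seq_len(n)),
    group = group, amyloid_status = amyloid, r1_level = r1_level,
    stringsAsFactors = FALSE)
  structure(list(subjects = subjects,
                 regions = data.frame(region = regions,
                                      label = seq_len(nr),
                                      r1_offset = offset,
                                      bp_positive = bp_pos,
                                      bp_negative = bp_neg,
                                      stringsAsFactors = FALSE),
                 k2_prime = k2_prime, noise_level = noise_level,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "Ground truth: %d subjects (%s), k2' = %.3g min^-1, noise %.1f%%, jitter SD %.3g, seed %d\n",
    nrow(x$subjects),
    paste(names(table(x$subjects$group)), table(x$subjects$group),
          sep = "=", collapse = ", "),
    x$k2_prime, 100 * x$noise_level, x$jitter_sd, x$seed))
  invisible(x)
}

#' True regional R1 values for one subject
#'
#' The subject's global R1 level plus the fixed composite-neutral regional
#' pattern, clipped to the plausible (0.5, 1.2) range.
#'
#' @param truth A [ground_truth()].
#' @param subject_id Subject id as in `truth$subjects$id`.
#' @return Numeric vector, one true R1 per catalog region (label order).
#' @export
true_regional_r1 <- function(truth, subject_id) {
  s <- truth$subjects[truth$subjects$id == subject_id, ]
  if (nrow(s) != 1) stop("unknown subject: ", subject_id)
  pmin(pmax(s$r1_level + truth$regions$r1_offset, 0.5), 1.2)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# block dims (wx, wy, wz) per catalog region; volumes span 8..240 voxels
# (a ~30-fold range) so the volume-vs-TRT trend is exercisable
.atlas_dims <- function() {
  matrix(c(3, 3, 3,   4, 3, 3,   3, 3, 2,   5, 4, 3,   6, 5, 4,
           4, 4, 3,   4, 3, 3,   6, 5, 4,   4, 3, 2,   3, 3, 2,
           7, 5, 4,   6, 4, 4,   6, 5, 4,   6, 5, 4,   2, 2, 2,
           4, 3, 2,   5, 4, 3,   8, 6, 5,   6, 4, 4,   5, 4, 4,
           4, 3, 3,   3, 3, 2),
         ncol = 3, byrow = TRUE)
}

#' Synthetic block atlas
#'
#' Axis-aligned blocks, one per catalog region plus a cerebellar reference
#' slab, on a regular grid. No anatomical realism is claimed; volumes span a
#' ~30-fold range so size-dependent precision is exercisable.
#'
#' @param shape Grid dimensions (x, y, z); minimum 46 x 46 x 20.
#' @return A [voi_mask()]; the reference carries the highest label.
#' @export
synthetic_atlas <- function(shape = c(48, 48, 24)) {
  min_shape <- c(46, 46, 20)
  if (length(shape) != 3 || any(shape < min_shape))
    stop("atlas shape too small; minimum is ",
         paste(min_shape, collapse = "x"))
  labels <- array(0L, shape)
  dims <- .atlas_dims()
  regions <- default_voi_catalog()
  for (i in seq_along(regions)) {
    cell <- c((i - 1) %% 5, (i - 1) %/% 5)  # 5x5 grid of 9-voxel cells
    x0 <- 1 + cell[1] * 9
    y0 <- 1 + cell[2] * 9
    labels[x0:(x0 + dims[i, 1] - 1),
           y0:(y0 + dims[i, 2] - 1),
           2:(1 + dims[i, 3])] <- i
  }
  ref_label <- length(regions) + 1L
  labels[6:17, 6:17, 14:19] <- ref_label  # 12x12x6 reference slab
  nm <- as.list(c(regions, "Cerebellar grey matter"))
  names(nm) <- as.character(seq_len(ref_label))
  voi_mask(labels, nm, reference_label = ref_label)
}

# fill one scan: per-region SRTM kinetics + count-statistics noise
.fill_scan <- function(mask, ref_true, r1_by_region, bp_by_region,
                       k2_prime, noise_level) {
  shape <- dim(mask$labels)
  nf <- n_frames(ref_true$schedule)
  vox <- array(0, c(shape, nf))
  flat <- matrix(vox, ncol = nf)
  for (lb in sort(as.integer(names(mask$names)))) {
    idx <- which(mask$labels == lb)
    if (lb == mask$reference_label) {
      mu <- ref_true$values
    } else {
      r1 <- r1_by_region[lb]
      mu <- srtm_forward(ref_true, r1, k2 = r1 * k2_prime,
                         bp_nd = bp_by_region[lb])$values
    }
    sd <- .frame_noise_sd(mu, ref_true$schedule, noise_level)
    nv <- length(idx)
    flat[idx, ] <- rep(mu, each = nv) +
      stats::rnorm(nv * nf, sd = rep(sd, each = nv))
  }
  array(flat, c(shape, nf))
}

#' Generate a paired test/retest phantom for one subject
#'
#' Builds the block atlas, evaluates the SRTM forward model with the
#' subject's true regional parameters on the noise-free reference curve, and
#' adds per-frame Gaussian noise with SD
#' `noise_level * value * sqrt(mean frame duration / frame duration)` (the
#' count-statistics shape: short early frames are noisier). The retest scan
#' is regenerated with independent noise and a per-region R1 jitter drawn
#' from `Normal(0, jitter_sd)`; the reference-region truth is scan-stable.
#' Deterministic given the truth's seed and the subject id.
#'
#' @param truth A [ground_truth()].
#' @param subject_id Subject id as in `truth$subjects$id`.
#' @param shape Atlas grid dimensions.
#' @param schedule Frame schedule; default the 23-frame 90-min protocol.
#' @param voxel_size Voxel edge lengths (mm).
#' @return List with `test` and `retest` ([dynamic_image()]), `mask`
#'   ([voi_mask()]), and `meta` (subject row, true regional R1 for both
#'   scans, k2').
#' @export
generate_subject_pair <- function(truth, subject_id,
                                  shape = c(48, 48, 24),
                                  schedule = default_schedule(),
                                  voxel_size = c(2, 2, 2)) {
  stopifnot(inherits(truth, "ground_truth"))
  srow <- which(truth$subjects$id == subject_id)
  if (length(srow) != 1) stop("unknown subject: ", subject_id)
  mask <- synthetic_atlas(shape)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed((truth$seed + 7919L * srow) %% .Machine$integer.max)
  ref_true <- generate_reference_tac(schedule, k2_prime = truth$k2_prime)
  r1_true <- true_regional_r1(truth, subject_id)
  amy <- truth$subjects$amyloid_status[srow]
  bp_true <- if (amy == "positive") truth$regions$bp_positive
             else truth$regions$bp_negative
  test_arr <- .fill_scan(mask, ref_true, r1_true, bp_true,
                         truth$k2_prime, truth$noise_level)
  jitter <- stats::rnorm(length(r1_true), sd = truth$jitter_sd)
  r1_retest <- pmin(pmax(r1_true + jitter, 0.5), 1.2)
  retest_arr <- .fill_scan(mask, ref_true, r1_retest, bp_true,
                           truth$k2_prime, truth$noise_level)
  list(test = dynamic_image(test_arr, schedule, voxel_size),
       retest = dynamic_image(retest_arr, schedule, voxel_size),
       mask = mask,
       meta = list(subject = truth$subjects[srow, ],
                   r1_true_test = r1_true, r1_true_retest = r1_retest,
                   bp_true = bp_true, k2_prime = truth$k2_prime))
}

#' The default 23-frame, 90-minute acquisition protocol
#' @return A [frame_schedule()] of 23 frames totalling 5400 s.
#' @export
default_schedule <- function() {
  parse_frame_scheme("1x15,3x5,3x10,2x30,3x60,2x150,2x300,7x600")
}

#' Generate a full synthetic test-retest cohort on disk
#'
#' Writes, per subject, test and retest dynamic images (NIfTI + timing
#' sidecar), one shared atlas (NIfTI + JSON label map), and a cohort
#' manifest TSV (`subject`, `group`, `amyloid_status`, image/mask paths)
#' the pipeline reader round-trips.
#'
#' @param dir Output directory.
#' @param truth A [ground_truth()]; defaults to the standard cohort of
#'   5 CU + 1 MCI + 6 AD subjects.
#' @param shape Atlas grid dimensions.
#' @param schedule Frame schedule.
#' @return Path of the manifest TSV, invisibly; also writes
#'   `ground_truth.json`.
#' @export
generate_cohort <- function(dir, truth = ground_truth(),
                            shape = c(48, 48, 24),
                            schedule = default_schedule()) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mask_path <- file.path(dir, "atlas.nii.gz")
  rows <- list()
  for (i in seq_len(nrow(truth$subjects))) {
    sid <- truth$subjects$id[i]
    pair <- generate_subject_pair(truth, sid, shape = shape,
                                  schedule = schedule)
    if (i == 1) write_mask(pair$mask, mask_path)
    tp <- file.path(dir, paste0(sid, "_test.nii.gz"))
    rp <- file.path(dir, paste0(sid, "_retest.nii.gz"))
    write_dynamic_image(pair$test, tp)
    write_dynamic_image(pair$retest, rp)
    rows[[i]] <- data.frame(subject = sid,
                            group = truth$subjects$group[i],
                            amyloid_status = truth$subjects$amyloid_status[i],
                            test_image = basename(tp),
                            retest_image = basename(rp),
                            mask = basename(mask_path),
                            stringsAsFactors = FALSE)
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(seed = truth$seed, k2_prime = truth$k2_prime,
         noise_level = truth$noise_level, jitter_sd = truth$jitter_sd,
         subjects = truth$subjects, regions = truth$regions),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort manifest
#' @param path Manifest TSV path.
#' @return Data.frame with absolute image/mask paths resolved against the
#'   manifest directory.
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("subject", "group", "amyloid_status", "test_image",
            "retest_image", "mask")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  for (col in c("test_image", "retest_image", "mask"))
    tab[[col]] <- file.path(base, tab[[col]])
  tab
}
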