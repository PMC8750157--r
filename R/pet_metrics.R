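# FDG-PET lesion metrics: SUV scaling, SUVpeak (1 mL sphere), local
# background estimation, and threshold-based metabolically active tumor
# volume (MATV) segmentation with SUVmean and total lesion glycolysis
# (TLG = SUVmean x MATV).

#' Scale an activity-concentration volume to SUV
#'
#' `SUV = C / (injected activity / body weight)` assuming unit tissue
#' density, with the activity concentration decay-corrected to injection
#' time. A voxel whose concentration equals dose/weight maps to SUV 1.
#'
#' @param volume `image_volume` in Bq/mL (decay-corrected).
#' @param injected_dose_MBq Injected activity, MBq.
#' @param body_weight_kg Body weight, kg.
#' @return `image_volume` in SUV (dimensionless).
#' @export
suv_scale <- function(volume, injected_dose_MBq, body_weight_kg) {
  if (injected_dose_MBq <= 0 || body_weight_kg <= 0)
    stop("dose and weight must be positive")
  # dose/weight in Bq/g == Bq/mL at unit density
  denom <- injected_dose_MBq * 1e6 / (body_weight_kg * 1e3)
  image_volume(volume$voxels / denom, spacing = volume$spacing,
               origin = volume$origin, timepoint = volume$timepoint)
}

# Integer voxel offsets whose centers lie within radius_mm of the center
# voxel, for a given spacing. Radius 6.2035 mm encloses exactly 1 mL.
sphere_offsets <- function(spacing, radius_mm = (3 * 1000 / (4 * pi))^(1 / 3)) {
  r <- ceiling(radius_mm / spacing)
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2
  off <- as.matrix(g[d2 <= radius_mm^2, , drop = FALSE])
  if (nrow(off) == 0) stop("sphere of radius ", radius_mm,
                           " mm contains no voxel centers at this spacing")
  off
}

#' SUVpeak: maximum mean over a 1 mL spherical VOI
#'
#' For every candidate center in the search region, the mean SUV over the
#' voxels whose centers lie within the 1 mL-sphere radius (6.204 mm) of the
#' center is computed; SUVpeak is the maximum of those means. Ties are broken
#' by lexicographic (column-major) center index. Sphere voxels falling
#' outside the grid are dropped from the mean.
#'
#' @param volume `image_volume` in SUV.
#' @param search_mask Logical array or `roi_mask` of candidate centers
#'   (default: whole grid).
#' @return List with `suv_peak`, `center` (voxel index, length 3).
#' @export
suv_peak <- function(volume, search_mask = NULL) {
  dims <- dim(volume$voxels)
  m <- if (is.null(search_mask)) array(TRUE, dims) else
    if (inherits(search_mask, "roi_mask")) search_mask$mask else search_mask
  if (!any(m)) stop("empty search region")
  off <- sphere_offsets(volume$spacing)
  centers <- which(m, arr.ind = TRUE)
  best <- -Inf; best_center <- NULL
  for (i in seq_len(nrow(centers))) {
    c0 <- centers[i, ]
    pts <- sweep(off, 2, c0, "+")
    keep <- pts[, 1] >= 1 & pts[, 1] <= dims[1] &
            pts[, 2] >= 1 & pts[, 2] <= dims[2] &
            pts[, 3] >= 1 & pts[, 3] <= dims[3]
    pts <- pts[keep, , drop = FALSE]
    v <- mean(volume$voxels[pts])
    if (v > best + 1e-15) { best <- v; best_center <- c0 }
  }
  list(suv_peak = best, center = unname(best_center))
}

#' Binary 26-neighborhood dilation / erosion
#'
#' Iterated 3x3x3-box morphological dilation (erosion) of a 3-D logical
#' mask, used for background shells, peak search regions and observer
#' perturbation.
#'
#' @param mask Logical 3-D array.
#' @param steps Number of one-voxel steps.
#' @return Logical 3-D array.
#' @export
dilate_mask <- function(mask, steps = 1L) {
  m <- mask
  dims <- dim(m)
  for (s in seq_len(steps)) {
    out <- m
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xs <- pmin(pmax(1:dims[1] + dx, 1), dims[1])
      ys <- pmin(pmax(1:dims[2] + dy, 1), dims[2])
      zs <- pmin(pmax(1:dims[3] + dz, 1), dims[3])
      out <- out | m[xs, ys, zs]
    }
    m <- out
  }
  m
}

#' @rdname dilate_mask
#' @export
erode_mask <- function(mask, steps = 1L) {
  !dilate_mask(!mask, steps)
}

#' Local background SUV around a lesion
#'
#' Mean SUV over a shell of configurable thickness starting a configurable
#' margin outside the lesion boundary (defaults: 1-voxel margin, 2-voxel
#' shell), which never intersects the lesion itself.
#'
#' @param volume `image_volume` in SUV.
#' @param lesion_mask Logical array or `roi_mask`.
#' @param margin_voxels Gap between lesion and shell, voxels (default 1).
#' @param shell_voxels Shell thickness, voxels (default 2).
#' @return Mean background SUV.
#' @export
local_background <- function(volume, lesion_mask, margin_voxels = 1L,
                             shell_voxels = 2L) {
  m <- if (inherits(lesion_mask, "roi_mask")) lesion_mask$mask else lesion_mask
  stopifnot(identical(dim(volume$voxels), dim(m)))
  inner <- dilate_mask(m, margin_voxels)
  outer <- dilate_mask(inner, shell_voxels)
  shell <- outer & !inner
  if (!any(shell)) stop("background shell is empty (lesion fills the grid)")
  mean(volume$voxels[shell])
}

# 26-connected component of `candidate` containing `seed_idx` (arr.ind).
connected_component <- function(candidate, seed_idx) {
  dims <- dim(candidate)
  lin <- function(p) p[1] + (p[2] - 1L) * dims[1] +
    (p[3] - 1L) * dims[1] * dims[2]
  comp <- array(FALSE, dims)
  seed <- as.integer(seed_idx)
  if (!candidate[seed[1], seed[2], seed[3]]) return(comp)
  queue <- matrix(seed, ncol = 3)
  comp[lin(seed)] <- TRUE
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(off == 0) != 3, ]
  while (nrow(queue) > 0) {
    p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
    nb <- sweep(off, 2, p, "+")
    keep <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
            nb[, 2] >= 1 & nb[, 2] <= dims[2] &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb <- nb[keep, , drop = FALSE]
    for (j in seq_len(nrow(nb))) {
      q <- nb[j, ]
      li <- lin(q)
      if (!comp[li] && candidate[li]) {
        comp[li] <- TRUE
        queue <- rbind(queue, q)
      }
    }
  }
  comp
}

#' Segment the metabolically active tumor volume (MATV)
#'
#' Background-adapted 50%-of-SUVpeak threshold segmentation:
#' `T = 0.5 * (SUVpeak - BG) + BG`, where SUVpeak is searched inside the
#' seed region and BG is the local background. The lesion is the
#' 26-connected component of above-threshold voxels containing the peak
#' sphere center. MATV is the component volume in mL, SUVmean its mean,
#' and TLG = SUVmean x MATV.
#'
#' @param volume `image_volume` in SUV.
#' @param seed_mask Logical array or `roi_mask` indicating the lesion
#'   neighborhood (peak search region).
#' @param background Optional precomputed background SUV; default computed by
#'   [local_background()] on the seed mask.
#' @param peak_fraction Threshold fraction of the background-corrected peak
#'   (default 0.5).
#' @return List with `mask` (logical array), `MATV_ml`, `SUV_mean`,
#'   `SUV_peak`, `TLG`, `background`, `threshold`.
#' @export
matv_segment <- function(volume, seed_mask, background = NULL,
                         peak_fraction = 0.5) {
  m <- if (inherits(seed_mask, "roi_mask")) seed_mask$mask else seed_mask
  pk <- suv_peak(volume, m)
  bg <- if (is.null(background)) local_background(volume, m) else background
  if (pk$suv_peak <= bg)
    stop("SUVpeak (", signif(pk$suv_peak, 4), ") must exceed background (",
         signif(bg, 4), ")")
  thr <- peak_fraction * (pk$suv_peak - bg) + bg
  candidate <- volume$voxels >= thr
  comp <- connected_component(candidate, pk$center)
  if (!any(comp)) stop("nothing above threshold at the peak center")
  matv <- sum(comp) * voxel_volume_ml(volume)
  suv_mean <- mean(volume$voxels[comp])
  list(mask = comp, MATV_ml = matv, SUV_mean = suv_mean,
       SUV_peak = pk$suv_peak, TLG = suv_mean * matv,
       background = bg, threshold = thr)
}
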