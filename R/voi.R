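# linear <-> 3-D index helpers (1-based, column-major)
lin_to_ijk <- function(lin, dm) {
  lin0 <- lin - 1L
  k <- lin0 %/% (dm[1] * dm[2])
  r <- lin0 - k * dm[1] * dm[2]
  cbind(r %% dm[1] + 1L, r %/% dm[1] + 1L, k + 1L)
}

ijk_to_lin <- function(ijk, dm) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1)
  (ijk[, 1] - 1L) + dm[1] * ((ijk[, 2] - 1L) + dm[2] * (ijk[, 3] - 1L)) + 1L
}

# logical box region of half-width radius_mm around a grid index
box_region <- function(dm, voxel_size, center_ijk, radius_mm) {
  reg <- array(FALSE, dim = dm)
  lo <- pmax(1L, floor(center_ijk - radius_mm / voxel_size))
  hi <- pmin(dm, ceiling(center_ijk + radius_mm / voxel_size))
  reg[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  reg
}

region_values <- function(search_region, dm) {
  if (is.null(search_region)) return(NULL)
  reg <- if (inherits(search_region, "reference_mask")) search_region$values
         else search_region
  stopifnot(is.array(reg), is.logical(reg), all(dim(reg) == dm))
  reg
}

new_voi <- function(voxels, threshold_fraction, seed_point, dim, voxel_size,
                    connectivity, ref_max, image_id = NULL) {
  stopifnot(length(voxels) > 0)
  structure(list(voxels = as.integer(voxels),
                 threshold_fraction = threshold_fraction,
                 seed_point = as.integer(seed_point),
                 dim = as.integer(dim), voxel_size = as.numeric(voxel_size),
                 connectivity = as.integer(connectivity),
                 ref_max = ref_max, image_id = image_id),
            class = "voi")
}

#' Isocontour-threshold volume of interest
#'
#' Extracts the VOI defined by an isocontour at a fraction of the reference
#' maximum: every voxel whose value reaches or exceeds
#' `threshold_fraction * max` (ties included) is eligible, and the VOI is the
#' connected component of eligible voxels that contains the seed point. The
#' reference maximum is taken over `search_region` when given, otherwise over
#' the whole image.
#'
#' @param image An [activity_image()].
#' @param threshold_fraction Fraction of the reference maximum, in (0, 1].
#' @param seed_point Integer length-3 grid index (1-based) inside the VOI.
#' @param search_region Optional [reference_mask()] or logical array
#'   restricting both the reference maximum and the VOI.
#' @param connectivity Voxel adjacency, 6 or 26 (default 26).
#' @return An object of class `voi` holding the member voxel set (linear
#'   indices), the threshold, the seed and the grid geometry.
#' @seealso [measure_volume()], [measure_counts()], [fit_threshold_anatomical()]
#' @export
isocontour_voi <- function(image, threshold_fraction, seed_point,
                           search_region = NULL, connectivity = 26L) {
  stopifnot(inherits(image, "activity_image"),
            length(threshold_fraction) == 1,
            threshold_fraction > 0, threshold_fraction <= 1,
            length(seed_point) == 3)
  dm <- dim(image$values)
  seed_point <- as.integer(seed_point)
  if (any(seed_point < 1) || any(seed_point > dm))
    stop("seed_point outside the image grid")
  reg <- region_values(search_region, dm)
  seed_lin <- ijk_to_lin(seed_point, dm)
  if (!is.null(reg) && !reg[seed_lin])
    stop("seed_point lies outside the search region")
  ref_max <- if (is.null(reg)) max(image$values) else max(image$values[reg])
  if (ref_max <= 0) stop("search region has no positive activity")
  cutoff <- threshold_fraction * ref_max
  if (image$values[seed_lin] < cutoff)
    stop(sprintf("empty VOI: seed voxel below the %.0f%% isocontour",
                 100 * threshold_fraction))
  member <- image$values >= cutoff
  if (!is.null(reg)) member <- member & reg
  comp <- flood_component(member, dm, seed_lin, as.integer(connectivity))
  new_voi(comp, threshold_fraction, seed_point, dm, image$voxel_size,
          connectivity, ref_max, image$metadata$source)
}

#' Measure the volume of a VOI
#'
#' @param voi A [isocontour_voi()] result.
#' @param image Optional [activity_image()]; when given, its grid must match
#'   the VOI's.
#' @return Volume in mL (member count times voxel volume).
#' @export
measure_volume <- function(voi, image = NULL) {
  stopifnot(inherits(voi, "voi"))
  if (!is.null(image)) check_same_grid(voi, image)
  length(voi$voxels) * voxel_volume_mL(voi$voxel_size)
}

#' Total counts within a VOI
#'
#' @param voi A [isocontour_voi()] result.
#' @param image The [activity_image()] to integrate over (same grid).
#' @return Sum of voxel values over the VOI members.
#' @export
measure_counts <- function(voi, image) {
  stopifnot(inherits(voi, "voi"), inherits(image, "activity_image"))
  check_same_grid(voi, image)
  sum(image$values[voi$voxels])
}

check_same_grid <- function(voi, image) {
  if (!all(voi$dim == dim(image$values)) ||
      !isTRUE(all.equal(voi$voxel_size, image$voxel_size)))
    stop("VOI and image are not on the same grid")
  invisible(TRUE)
}

#' Dice overlap between a VOI and a reference mask
#'
#' @param voi A `voi` object (or integer linear indices).
#' @param reference A [reference_mask()] (or logical array).
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(voi, reference) {
  idx <- if (inherits(voi, "voi")) voi$voxels else as.integer(voi)
  ref <- if (inherits(reference, "reference_mask")) reference$values
         else reference
  n_ref <- sum(ref)
  if (length(idx) + n_ref == 0) return(NA_real_)
  2 * sum(ref[idx]) / (length(idx) + n_ref)
}

# Scan a threshold grid over the seed's connected component.
#
# Exploits threshold nestedness: the component at any threshold t >= tmin is
# contained in the component at tmin, so a single full-grid flood fill at
# tmin bounds a crop window inside which every other threshold is evaluated.
# Returns the trace (volume and, when a reference is given, Dice per
# threshold) and a closure mapping a threshold to full-grid member indices.
scan_thresholds <- function(values, voxel_size, reg, seed_lin, thresholds,
                            ref_max, connectivity, reference = NULL) {
  dm <- dim(values)
  thresholds <- sort(unique(thresholds))
  stopifnot(all(thresholds > 0), all(thresholds <= 1))
  vox_mL <- voxel_volume_mL(voxel_size)
  n_ref <- if (is.null(reference)) NA_integer_ else sum(reference)
  empty_trace <- data.frame(threshold = thresholds, volume_mL = 0,
                            dice = if (is.null(reference)) NA_real_ else 0)
  tmin <- thresholds[1]
  member_low <- values >= tmin * ref_max
  if (!is.null(reg)) member_low <- member_low & reg
  if (!member_low[seed_lin])
    return(list(trace = empty_trace, all_empty = TRUE, voi_at = NULL))
  comp_low <- flood_component(member_low, dm, seed_lin,
                              as.integer(connectivity))
  ijk <- lin_to_ijk(comp_low, dm)
  if (!is.null(reference)) ijk <- rbind(ijk, lin_to_ijk(which(reference), dm))
  lo <- pmax(1L, apply(ijk, 2, min) - 1L)
  hi <- pmin(dm, apply(ijk, 2, max) + 1L)
  dc <- hi - lo + 1L
  crop <- function(full_lin) {
    x <- lin_to_ijk(full_lin, dm)
    ijk_to_lin(cbind(x[, 1] - lo[1] + 1L, x[, 2] - lo[2] + 1L,
                     x[, 3] - lo[3] + 1L), dc)
  }
  uncrop <- function(crop_lin) {
    x <- lin_to_ijk(crop_lin, dc)
    ijk_to_lin(cbind(x[, 1] + lo[1] - 1L, x[, 2] + lo[2] - 1L,
                     x[, 3] + lo[3] - 1L), dm)
  }
  vals_c <- values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  low_c <- array(FALSE, dim = dc)
  low_c[crop(comp_low)] <- TRUE
  ref_c <- if (is.null(reference)) NULL
           else reference[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  seed_c <- crop(seed_lin)
  comp_at <- function(t) {
    if (vals_c[seed_c] < t * ref_max) return(integer(0))
    member_t <- low_c & (vals_c >= t * ref_max)
    flood_component(member_t, dc, seed_c, as.integer(connectivity))
  }
  vol <- numeric(length(thresholds))
  dce <- rep(if (is.null(reference)) NA_real_ else 0, length(thresholds))
  for (i in seq_along(thresholds)) {
    comp <- comp_at(thresholds[i])
    vol[i] <- length(comp) * vox_mL
    if (!is.null(reference) && length(comp) > 0)
      dce[i] <- 2 * sum(ref_c[comp]) / (length(comp) + n_ref)
  }
  list(trace = data.frame(threshold = thresholds, volume_mL = vol, dice = dce),
       all_empty = all(vol == 0),
       voi_at = function(t) uncrop(comp_at(t)))
}

new_threshold_fit <- function(best_threshold, objective, trace, voi,
                              method) {
  structure(list(best_threshold = best_threshold, objective = objective,
                 trace = trace, voi = voi, method = method),
            class = "threshold_fit")
}

#' Anatomically guided isocontour threshold fitting
#'
#' Emulates SPECT/CT delineation: the isocontour threshold is adjusted until
#' the VOI best matches the anatomical truth, here a reference mask standing
#' in for the object wall seen on the fused CT. The candidate threshold
#' maximizing the Dice overlap with the reference is returned; ties resolve
#' to the smallest threshold (largest VOI).
#'
#' @param image An [activity_image()].
#' @param reference A [reference_mask()] of the true object boundary.
#' @param seed_point Optional grid index inside the object; defaults to the
#'   hottest voxel within the reference mask.
#' @param thresholds Candidate threshold fractions; default integer percent
#'   grid 0.01 ... 0.99.
#' @param search_region Optional region restricting the reference maximum;
#'   defaults to the reference bounding box dilated by `margin_mm`. The
#'   margin defaults to one PSF FWHM so that neighbouring hot objects cannot
#'   capture the reference maximum.
#' @param margin_mm Dilation margin for the default search region, mm.
#' @param connectivity Voxel adjacency, 6 or 26.
#' @return A `threshold_fit` with fields `best_threshold`, `objective` (best
#'   Dice), `trace` (threshold, volume_mL, dice) and `voi`.
#' @export
fit_threshold_anatomical <- function(image, reference, seed_point = NULL,
                                     thresholds = seq(0.01, 0.99, by = 0.01),
                                     search_region = NULL, margin_mm = 15,
                                     connectivity = 26L) {
  stopifnot(inherits(image, "activity_image"),
            inherits(reference, "reference_mask"))
  dm <- dim(image$values)
  stopifnot(all(dim(reference$values) == dm))
  ref_idx <- which(reference$values)
  if (is.null(seed_point)) {
    seed_lin <- ref_idx[which.max(image$values[ref_idx])]
    seed_point <- drop(lin_to_ijk(seed_lin, dm))
  } else {
    seed_lin <- ijk_to_lin(as.integer(seed_point), dm)
  }
  reg <- region_values(search_region, dm)
  if (is.null(reg)) {
    ijk <- lin_to_ijk(ref_idx, dm)
    lo <- pmax(1L, apply(ijk, 2, min) -
                 as.integer(ceiling(margin_mm / image$voxel_size)))
    hi <- pmin(dm, apply(ijk, 2, max) +
                 as.integer(ceiling(margin_mm / image$voxel_size)))
    reg <- array(FALSE, dim = dm)
    reg[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  }
  ref_max <- max(image$values[reg])
  if (ref_max <= 0) stop("search region has no positive activity")
  scan <- scan_thresholds(image$values, image$voxel_size, reg, seed_lin,
                          thresholds, ref_max, connectivity,
                          reference = reference$values)
  if (scan$all_empty)
    stop("threshold fitting failure: every candidate VOI is empty")
  best_i <- which.max(scan$trace$dice)  # ascending grid: first max = smallest
  best_t <- scan$trace$threshold[best_i]
  voi <- new_voi(scan$voi_at(best_t), best_t, seed_point, dm,
                 image$voxel_size, connectivity, ref_max,
                 image$metadata$source)
  new_threshold_fit(best_t, scan$trace$dice[best_i], scan$trace, voi,
                    "anatomical")
}

# quasi-uniform ray directions on the unit sphere (Fibonacci lattice)
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Hot-spot-only isocontour threshold fitting
#'
#' Emulates visual delineation of a hot spot on emission images alone, with
#' no anatomical truth available. The image is display-transformed with a
#' gamma curve (`display ~ (value / max)^gamma`), rays are cast from the
#' hottest voxel, and the apparent edge on each ray is the point of maximum
#' falling gradient of the displayed intensity. The fitted threshold is the
#' median underlying image fraction at those apparent edges, snapped to the
#' candidate grid. `display_gamma` parametrizes observer/display variability:
#' different gamma settings displace the apparent edge on blurred objects and
#' so change the recovered volume, which is exactly how window settings drive
#' interobserver spread in visual contouring.
#'
#' @param image An [activity_image()].
#' @param seed_point Grid index near the hot spot; the ray origin is the
#'   hottest voxel of the search region.
#' @param thresholds Candidate threshold fractions (snap grid).
#' @param display_gamma Positive display-curve exponent; 1 is linear.
#' @param search_region Optional region; defaults to a box of half-width
#'   `region_radius_mm` around the seed.
#' @param region_radius_mm Half-width of the default search box, mm.
#' @param n_rays Number of ray directions.
#' @param connectivity Voxel adjacency, 6 or 26.
#' @param ray_origin `"peak"` (default) casts rays from the hottest voxel
#'   within `peak_radius_mm` of the seed and normalizes thresholds to that
#'   peak — the natural reading of an isocontour as a percentage of the hot
#'   spot's own highest activity. `"seed"` casts rays from `seed_point` and
#'   normalizes to the search-region maximum, which suits a large warm
#'   compartment whose brightest voxel is an interior hot lesion rather than
#'   the structure being outlined.
#' @param peak_radius_mm Radius of the peak search around the seed, mm
#'   (`"peak"` mode only).
#' @return A `threshold_fit`; `objective` is the fraction of rays with a
#'   detectable edge.
#' @export
fit_threshold_hotspot <- function(image, seed_point,
                                  thresholds = seq(0.01, 0.99, by = 0.01),
                                  display_gamma = 1, search_region = NULL,
                                  region_radius_mm = 45, n_rays = 42L,
                                  connectivity = 26L,
                                  ray_origin = c("peak", "seed"),
                                  peak_radius_mm = 15) {
  stopifnot(inherits(image, "activity_image"), display_gamma > 0,
            length(seed_point) == 3)
  ray_origin <- match.arg(ray_origin)
  dm <- dim(image$values)
  seed_point <- as.integer(seed_point)
  reg <- region_values(search_region, dm)
  if (is.null(reg))
    reg <- box_region(dm, image$voxel_size, seed_point, region_radius_mm)
  if (ray_origin == "peak") {
    near <- box_region(dm, image$voxel_size, seed_point, peak_radius_mm) & reg
    near_idx <- which(near)
    peak_lin <- near_idx[which.max(image$values[near_idx])]
    ref_max <- image$values[peak_lin]
  } else {
    peak_lin <- ijk_to_lin(seed_point, dm)
    ref_max <- max(image$values[reg])
  }
  if (ref_max <= 0) stop("search region has no positive activity")
  peak <- drop(lin_to_ijk(peak_lin, dm))

  dirs <- fibonacci_directions(n_rays)
  step <- min(image$voxel_size) / 2
  radii <- seq(step, region_radius_mm, by = step)
  origin <- (peak - 0.5) * image$voxel_size
  edge_frac <- rep(NA_real_, n_rays)
  for (k in seq_len(n_rays)) {
    pts <- sweep(outer(radii, dirs[k, ]), 2, origin, "+")  # world mm
    ijk <- sweep(pts, 2, image$voxel_size, "/")
    ijk <- floor(ijk) + 1L
    keep <- ijk[, 1] >= 1 & ijk[, 1] <= dm[1] &
            ijk[, 2] >= 1 & ijk[, 2] <= dm[2] &
            ijk[, 3] >= 1 & ijk[, 3] <= dm[3]
    if (sum(keep) < 4) next
    lin <- ijk_to_lin(ijk[keep, , drop = FALSE], dm)
    inreg <- reg[lin]
    if (any(!inreg)) lin <- lin[seq_len(which.min(inreg) - 1)]
    if (length(lin) < 4) next
    prof <- image$values[lin] / ref_max
    disp <- pmin(prof, 1)^display_gamma
    disp <- stats::filter(disp, rep(1 / 3, 3), sides = 2)  # light smoothing
    g <- -diff(as.numeric(disp))
    g[is.na(g)] <- 0
    if (max(g) <= 1e-9) next  # no falling edge on this ray
    # outermost substantial falling edge: the apparent outer boundary, not
    # an interior structure or a noise ripple
    j <- max(which(g >= 0.5 * max(g)))
    edge_frac[k] <- (prof[j] + prof[j + 1]) / 2
  }
  detected <- !is.na(edge_frac)
  if (!any(detected))
    stop("threshold fitting failure: no detectable hot-spot edge")
  thr_raw <- stats::median(edge_frac[detected])
  thresholds <- sort(unique(thresholds))
  best_t <- thresholds[which.min(abs(thresholds - thr_raw))]
  # the outlined contour must contain the ray origin
  origin_frac <- image$values[peak_lin] / ref_max
  if (best_t > origin_frac) {
    ok <- thresholds[thresholds <= origin_frac]
    if (!length(ok))
      stop("threshold fitting failure: no candidate isocontour contains the ray origin")
    best_t <- max(ok)
  }
  scan <- scan_thresholds(image$values, image$voxel_size, reg, peak_lin,
                          thresholds, ref_max, connectivity)
  if (scan$all_empty || length(scan$voi_at(best_t)) == 0)
    stop("threshold fitting failure: fitted isocontour excludes the ray origin")
  voi <- new_voi(scan$voi_at(best_t), best_t, peak, dm, image$voxel_size,
                 connectivity, ref_max, image$metadata$source)
  fit <- new_threshold_fit(best_t, mean(detected), scan$trace, voi, "hotspot")
  fit$display_gamma <- display_gamma
  fit
}

#' @export
print.voi <- function(x, ...) {
  cat(sprintf("<voi> %d voxels (%.1f mL) at %.0f%% isocontour, seed (%d,%d,%d)\n",
              length(x$voxels), measure_volume(x), 100 * x$threshold_fraction,
              x$seed_point[1], x$seed_point[2], x$seed_point[3]))
  invisible(x)
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("<threshold_fit:%s> best %.0f%% (objective %.3f), VOI %.1f mL\n",
              x$method, 100 * x$best_threshold, x$objective,
              measure_volume(x$voi)))
  invisible(x)
}
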