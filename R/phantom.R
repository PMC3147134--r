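#' @useDynLib maadose, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rpois sd median
#' @importFrom utils read.csv write.csv
NULL

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))

#' Geometric object of a digital phantom
#'
#' Describes one analytic solid (sphere, axis-aligned cylinder along z, or
#' ellipsoid) with a uniform activity concentration. All coordinates and
#' dimensions are in millimetres (world coordinates); concentrations are in
#' arbitrary activity units per mL.
#'
#' @param shape `"sphere"`, `"cylinder"` or `"ellipsoid"`.
#' @param center Numeric length-3 world coordinate of the object centre, mm.
#' @param dimensions For a sphere, the radius; for a cylinder, `c(radius,
#'   height)` (axis along z); for an ellipsoid, the three semi-axes. mm.
#' @param concentration Activity concentration, arbitrary units per mL.
#' @param label Character identifier, unique within a phantom.
#' @return An object of class `geometric_object`.
#' @examples
#' sph <- geometric_object("sphere", c(0, 0, 0), 23.58, 2.8, "sphere1")
#' analytic_volume(sph)  # about 55 mL
#' @export
geometric_object <- function(shape = c("sphere", "cylinder", "ellipsoid"),
                             center, dimensions, concentration, label) {
  shape <- match.arg(shape)
  ndim <- switch(shape, sphere = 1L, cylinder = 2L, ellipsoid = 3L)
  stopifnot(length(center) == 3, is.numeric(center),
            length(dimensions) == ndim, is.numeric(dimensions),
            length(concentration) == 1, concentration >= 0,
            is.character(label), length(label) == 1, nzchar(label))
  if (any(dimensions <= 0))
    stop("dimensions of '", label, "' must be strictly positive")
  structure(list(shape = shape, center = as.numeric(center),
                 dimensions = as.numeric(dimensions),
                 concentration = as.numeric(concentration), label = label),
            class = "geometric_object")
}

#' Analytic volume of a geometric object
#'
#' @param object A [geometric_object()].
#' @return Volume in mL.
#' @export
analytic_volume <- function(object) {
  stopifnot(inherits(object, "geometric_object"))
  d <- object$dimensions
  mm3 <- switch(object$shape,
                sphere = 4 / 3 * pi * d[1]^3,
                cylinder = pi * d[1]^2 * d[2],
                ellipsoid = 4 / 3 * pi * d[1] * d[2] * d[3])
  mm3 / 1000
}

#' Phantom specification
#'
#' A voxel grid plus a list of analytic objects to be rasterized onto it.
#' Voxels inside no object receive `background` (use 0 for air). Nested
#' objects are resolved innermost-first: the smallest object containing a
#' voxel centre supplies its concentration.
#'
#' @param objects List of [geometric_object()]s.
#' @param background Concentration outside all objects, units per mL.
#' @param grid_shape Integer length-3, voxels per axis.
#' @param voxel_size Numeric length-3, mm per axis.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(objects, background = 0,
                         grid_shape = c(128L, 128L, 128L),
                         voxel_size = c(4, 4, 4)) {
  stopifnot(is.list(objects),
            all(vapply(objects, inherits, TRUE, "geometric_object")),
            length(grid_shape) == 3, all(grid_shape >= 1),
            length(voxel_size) == 3, all(voxel_size > 0),
            length(background) == 1, background >= 0)
  labels <- vapply(objects, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("duplicate object labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  spec <- structure(list(objects = objects, background = as.numeric(background),
                         grid_shape = as.integer(grid_shape),
                         voxel_size = as.numeric(voxel_size)),
                    class = "phantom_spec")
  for (ob in objects) check_inside_grid(ob, spec)
  spec
}

# Bounding half-widths of an object along x/y/z, mm
object_halfwidths <- function(object) {
  d <- object$dimensions
  switch(object$shape,
         sphere = rep(d[1], 3),
         cylinder = c(d[1], d[1], d[2] / 2),
         ellipsoid = d)
}

check_inside_grid <- function(object, spec) {
  extent <- spec$grid_shape * spec$voxel_size
  hw <- object_halfwidths(object)
  if (any(object$center - hw < 0) || any(object$center + hw > extent))
    stop("object '", object$label, "' does not lie fully inside the grid")
  invisible(TRUE)
}

#' Acquisition (image degradation) model
#'
#' Image-domain surrogate for a reconstructed SPECT acquisition: an isotropic
#' Gaussian point-spread function, a global rescaling to an expected total
#' count sum, and optional Poisson counting noise.
#'
#' @param psf_fwhm Full width at half maximum of the Gaussian PSF, mm (>= 0).
#' @param total_counts Expected whole-image count sum (> 0).
#' @param noise Logical; draw voxel-wise Poisson counts?
#' @param seed Integer seed used for the Poisson draw (recorded in image
#'   metadata for provenance).
#' @return An object of class `acquisition_model`.
#' @export
acquisition_model <- function(psf_fwhm = 15, total_counts = 5e6,
                              noise = TRUE, seed = 1L) {
  stopifnot(length(psf_fwhm) == 1, psf_fwhm >= 0,
            length(total_counts) == 1, total_counts > 0,
            is.logical(noise), length(noise) == 1,
            length(seed) == 1)
  structure(list(psf_fwhm = as.numeric(psf_fwhm),
                 total_counts = as.numeric(total_counts),
                 noise = noise, seed = as.integer(seed)),
            class = "acquisition_model")
}

#' Activity image constructor
#'
#' @param values Non-negative 3-D numeric array of counts.
#' @param voxel_size Numeric length-3 voxel spacing, mm.
#' @param metadata Named list of provenance fields.
#' @return An object of class `activity_image`.
#' @export
activity_image <- function(values, voxel_size, metadata = list()) {
  stopifnot(is.array(values), length(dim(values)) == 3,
            length(voxel_size) == 3, all(voxel_size > 0))
  if (any(values < 0)) stop("activity values must be non-negative")
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 metadata = metadata),
            class = "activity_image")
}

#' Reference mask constructor
#'
#' A binary mask of true object boundaries on the same grid as an activity
#' image; it plays the role of the anatomical (CT) truth in SPECT/CT fusion.
#'
#' @param values Logical 3-D array; must be non-empty.
#' @param voxel_size Numeric length-3 voxel spacing, mm.
#' @param label Object label.
#' @return An object of class `reference_mask`.
#' @export
reference_mask <- function(values, voxel_size, label) {
  stopifnot(is.array(values), length(dim(values)) == 3, is.logical(values))
  if (!any(values)) stop("reference mask '", label, "' is empty")
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 label = label),
            class = "reference_mask")
}

#' Voxel volume in mL
#'
#' @param x An `activity_image`, `reference_mask`, `phantom_spec`, or numeric
#'   length-3 voxel size in mm.
#' @return Volume of one voxel, mL.
#' @export
voxel_volume_mL <- function(x) {
  vs <- if (is.numeric(x)) x else x$voxel_size
  stopifnot(length(vs) == 3, all(vs > 0))
  prod(vs) / 1000
}

# voxel-centre coordinates along one axis (1-based indices, world mm)
axis_centers <- function(n, v) (seq_len(n) - 0.5) * v

# logical membership array for one object on the full grid
rasterize_object <- function(object, grid_shape, voxel_size) {
  xc <- axis_centers(grid_shape[1], voxel_size[1])
  yc <- axis_centers(grid_shape[2], voxel_size[2])
  zc <- axis_centers(grid_shape[3], voxel_size[3])
  ctr <- object$center
  d <- object$dimensions
  if (object$shape == "cylinder") {
    inplane <- outer((xc - ctr[1])^2, (yc - ctr[2])^2, "+") <= d[1]^2
    inz <- abs(zc - ctr[3]) <= d[2] / 2
    return(outer(inplane, inz, "&"))
  }
  semi <- if (object$shape == "sphere") rep(d[1], 3) else d
  q <- outer(outer(((xc - ctr[1]) / semi[1])^2,
                   ((yc - ctr[2]) / semi[2])^2, "+"),
             ((zc - ctr[3]) / semi[3])^2, "+")
  q <= 1
}

#' Rasterize a phantom specification
#'
#' Paints each voxel with the concentration of the innermost (smallest
#' analytic volume) object whose analytic surface contains the voxel centre;
#' voxels outside all objects receive the background concentration. Voxel
#' membership is decided purely by centre inclusion, so rasterized volumes
#' converge to the analytic ones as the voxel size shrinks.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (noise-free, unblurred [activity_image()]) and
#'   `masks` (named list of [reference_mask()], one per object).
#' @examples
#' sph <- geometric_object("sphere", c(32, 32, 32), 23.58, 1, "s55")
#' ph <- rasterize(phantom_spec(list(sph), grid_shape = c(64, 64, 64),
#'                              voxel_size = c(1, 1, 1)))
#' sum(ph$masks$s55$values) / 1000  # close to 55 mL
#' @export
rasterize <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vals <- array(spec$background, dim = spec$grid_shape)
  masks <- list()
  vols <- vapply(spec$objects, analytic_volume, 0)
  for (i in order(vols, decreasing = TRUE)) {  # paint outermost first
    ob <- spec$objects[[i]]
    m <- rasterize_object(ob, spec$grid_shape, spec$voxel_size)
    vals[m] <- ob$concentration
    masks[[ob$label]] <- reference_mask(m, spec$voxel_size, ob$label)
  }
  img <- activity_image(vals, spec$voxel_size,
                        metadata = list(source = "rasterize",
                                        background = spec$background))
  list(image = img, masks = masks)
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Isotropic Gaussian blur by Fourier multiplication; the transfer function is
# the analytic Gaussian characteristic function, so the DC gain is exactly 1
# and the total count sum is conserved.
gaussian_blur <- function(values, voxel_size, fwhm) {
  if (fwhm == 0) return(values)
  sigma <- fwhm * FWHM_TO_SIGMA
  dm <- dim(values)
  freq2 <- lapply(1:3, function(a) {
    f <- c(0:(dm[a] %/% 2), -((dm[a] - dm[a] %/% 2 - 1):1)) / (dm[a] * voxel_size[a])
    f[seq_len(dm[a])]^2
  })
  g <- exp(-2 * pi^2 * sigma^2 *
             outer(outer(freq2[[1]], freq2[[2]], "+"), freq2[[3]], "+"))
  out <- Re(stats::fft(stats::fft(values) * g, inverse = TRUE)) / length(values)
  out[out < 0] <- 0  # clip FFT ringing at machine-precision level
  out
}

#' Degrade an activity image
#'
#' Applies the acquisition model: Gaussian PSF blur, rescaling of the image
#' sum to the expected total counts, then (optionally) voxel-wise Poisson
#' draws under the model's seed. Without noise the operation is linear and
#' conserves total counts exactly; with noise it conserves them in
#' expectation, and identical seeds give bit-identical images.
#'
#' @param image An [activity_image()].
#' @param acq An [acquisition_model()].
#' @return A degraded [activity_image()]; metadata records the model
#'   parameters and seed.
#' @export
degrade <- function(image, acq) {
  stopifnot(inherits(image, "activity_image"),
            inherits(acq, "acquisition_model"))
  s <- sum(image$values)
  if (s <= 0) stop("cannot degrade an image with zero total activity")
  vals <- gaussian_blur(image$values, image$voxel_size, acq$psf_fwhm)
  vals <- vals * (acq$total_counts / sum(vals))
  if (acq$noise) {
    vals <- with_seed(acq$seed, {
      array(rpois(length(vals), lambda = vals), dim = dim(vals))
    })
    vals <- vals * 1.0  # store as double for downstream arithmetic
  }
  activity_image(vals, image$voxel_size,
                 metadata = c(image$metadata,
                              list(psf_fwhm = acq$psf_fwhm,
                                   total_counts = acq$total_counts,
                                   noise = acq$noise, seed = acq$seed)))
}

#' Jaszczak-style phantom specification
#'
#' A warm cylinder (6,716 mL by default) holding four hot spheres of 55,
#' 20.5, 16 and 8 mL mounted in one transaxial plane. Sphere concentrations
#' are expressed as sphere-to-background ratios, the contrast actually
#' realized when equal sphere activities are imaged over a fixed background.
#'
#' @param sphere_ratios Sphere-to-background concentration ratios for the
#'   55/20.5/16/8 mL spheres (one value each, or `NULL` to omit spheres).
#' @param background Background (cylinder) concentration, units per mL.
#' @param cylinder_volume_mL Volume of the main cylinder.
#' @param cylinder_radius_mm Radius of the main cylinder (height follows from
#'   the volume).
#' @param sphere_volumes_mL True sphere volumes, mL.
#' @param grid_shape,voxel_size Grid geometry; defaults 128^3 at 4 mm.
#' @return A [phantom_spec()]; the cylinder is labelled `cylinder1`, spheres
#'   `sphere1` ... `sphere4` in decreasing volume.
#' @export
jaszczak_phantom <- function(sphere_ratios = c(2.8, 7.6, 9.6, 19.6),
                             background = 1,
                             cylinder_volume_mL = 6716,
                             cylinder_radius_mm = 108,
                             sphere_volumes_mL = c(55, 20.5, 16, 8),
                             grid_shape = c(128L, 128L, 128L),
                             voxel_size = c(4, 4, 4)) {
  stopifnot(background > 0,
            is.null(sphere_ratios) ||
              length(sphere_ratios) == length(sphere_volumes_mL))
  extent <- grid_shape * voxel_size
  ctr <- extent / 2
  height <- cylinder_volume_mL * 1000 / (pi * cylinder_radius_mm^2)
  objects <- list(geometric_object("cylinder", ctr,
                                   c(cylinder_radius_mm, height),
                                   background, "cylinder1"))
  if (!is.null(sphere_ratios)) {
    radii <- (3 * sphere_volumes_mL * 1000 / (4 * pi))^(1 / 3)
    mount_r <- 58  # radial mounting distance from the cylinder axis, mm
    ang <- (seq_along(radii) - 1) * 2 * pi / length(radii)
    # snap sphere centres onto voxel centres: keeps the discretized volume
    # close to the analytic one instead of maximally lattice-misaligned
    snap <- function(x) (round(x / voxel_size + 0.5) - 0.5) * voxel_size
    for (i in seq_along(radii)) {
      objects[[i + 1]] <- geometric_object(
        "sphere",
        snap(ctr + c(mount_r * cos(ang[i]), mount_r * sin(ang[i]), 0)),
        radii[i], sphere_ratios[i] * background, paste0("sphere", i))
    }
  }
  phantom_spec(objects, background = 0, grid_shape = grid_shape,
               voxel_size = voxel_size)
}

#' Standalone cylinder phantom specification
#'
#' A single uniform cylinder in air, used for the large liver-like volumes
#' (774 and 473 mL).
#'
#' @param volume_mL Cylinder volume.
#' @param radius_mm Cylinder radius (height follows from the volume).
#' @param concentration Activity concentration, units per mL.
#' @param label Object label.
#' @param grid_shape,voxel_size Grid geometry.
#' @return A [phantom_spec()].
#' @export
cylinder_phantom <- function(volume_mL, radius_mm = 45, concentration = 1,
                             label = "cylinder",
                             grid_shape = c(128L, 128L, 128L),
                             voxel_size = c(4, 4, 4)) {
  extent <- grid_shape * voxel_size
  height <- volume_mL * 1000 / (pi * radius_mm^2)
  ob <- geometric_object("cylinder", extent / 2, c(radius_mm, height),
                         concentration, label)
  phantom_spec(list(ob), background = 0, grid_shape = grid_shape,
               voxel_size = voxel_size)
}

#' Clinical-like liver/tumor phantom
#'
#' An ellipsoidal liver containing an internal tumor ellipsoid, with
#' compartment concentrations chosen so that the tumor holds a stated
#' fraction of the total hepatic counts. The fraction is enforced on the
#' rasterized (voxel) compartments, so the noise-free count integrals satisfy
#' it exactly before any degradation.
#'
#' @param liver_volume_mL Total liver volume (default 1829 mL, a whole-liver
#'   distribution volume).
#' @param tumor_volume_mL Tumor volume, strictly less than the liver volume.
#'   The 610 mL default is a back-calculated convenience value consistent
#'   with a large infiltrative tumor; it is not a measured ground truth.
#' @param tumor_count_fraction Fraction of hepatic counts in the tumor,
#'   in (0, 1); default 0.691.
#' @param acq Optional [acquisition_model()]; when supplied the returned
#'   image is degraded with it.
#' @param grid_shape,voxel_size Grid geometry.
#' @return List with `image` ([activity_image()]), `liver_mask` (whole liver,
#'   tumor included) and `tumor_mask` ([reference_mask()]s).
#' @export
make_clinical_phantom <- function(liver_volume_mL = 1829,
                                  tumor_volume_mL = 610,
                                  tumor_count_fraction = 0.691,
                                  acq = NULL,
                                  grid_shape = c(128L, 128L, 128L),
                                  voxel_size = c(4, 4, 4)) {
  stopifnot(liver_volume_mL > 0, tumor_volume_mL > 0,
            tumor_volume_mL < liver_volume_mL,
            tumor_count_fraction > 0, tumor_count_fraction < 1)
  extent <- grid_shape * voxel_size
  ctr <- extent / 2
  # liver ellipsoid with 1.4 : 1 : 0.8 axis proportions
  prop <- c(1.4, 1, 0.8)
  s <- (liver_volume_mL * 1000 * 3 / (4 * pi * prod(prop)))^(1 / 3)
  liver_ax <- prop * s
  k <- (tumor_volume_mL / liver_volume_mL)^(1 / 3)
  tumor_ax <- liver_ax * k
  # offset the tumor along x, keeping it strictly inside the liver surface
  off <- min(0.25, 0.9 * (1 - k)) * liver_ax[1]
  liver <- geometric_object("ellipsoid", ctr, liver_ax, 1, "liver")
  tumor <- geometric_object("ellipsoid", ctr + c(off, 0, 0), tumor_ax, 1,
                            "tumor")
  spec <- phantom_spec(list(liver, tumor), background = 0,
                       grid_shape = grid_shape, voxel_size = voxel_size)
  liver_m <- rasterize_object(liver, spec$grid_shape, spec$voxel_size)
  tumor_m <- rasterize_object(tumor, spec$grid_shape, spec$voxel_size)
  if (!all(liver_m[tumor_m]))
    stop("tumor ellipsoid is not contained in the liver ellipsoid")
  n_t <- sum(tumor_m)
  n_h <- sum(liver_m) - n_t
  if (n_t == 0 || n_h == 0)
    stop("degenerate compartments at this grid resolution")
  f <- tumor_count_fraction
  conc_t <- f * n_h / ((1 - f) * n_t)  # healthy concentration fixed at 1
  if (!is.finite(conc_t) || conc_t < 0)
    stop("infeasible tumor count fraction: negative compartment concentration")
  vals <- array(0, dim = spec$grid_shape)
  vals[liver_m] <- 1
  vals[tumor_m] <- conc_t
  img <- activity_image(vals, spec$voxel_size,
                        metadata = list(source = "make_clinical_phantom",
                                        tumor_count_fraction = f))
  if (!is.null(acq)) img <- degrade(img, acq)
  list(image = img,
       liver_mask = reference_mask(liver_m, spec$voxel_size, "liver"),
       tumor_mask = reference_mask(tumor_m, spec$voxel_size, "tumor"))
}
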