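FIXTURE_MD5 <- c(table1_operator1.csv = "df14e61334603c6b91f6e9572ac09a01",
                 table2_operator2.csv = "9cc4a19793ac3600c3971fa1ad6b9ad5")

#' Load the packaged phantom measurement tables
#'
#' Reads the two packaged operator tables (23 test objects per operator and
#' method: the Jaszczak cylinder and four hot spheres at four activity
#' levels, plus two standalone cylinders) into one long measurement-record
#' data frame. Decimal separators are already normalized to dots; missing
#' measurements are `NA`. File checksums are verified so that silent fixture
#' corruption fails hard.
#'
#' Columns: `object`, `config` (activity level), `ratio` (true
#' sphere-to-background ratio, `NA` for cylinders), `method` (`spect` or
#' `spect_ct`), `operator` (1 or 2), `isocontour_pct`, `true_mL`,
#' `true_mL_alt` (alternative candidate truth for sphere 2, whose printed
#' errors are only consistent with 21.0 mL), `measured_mL`, `error_pct`.
#'
#' @param check Verify file checksums (default `TRUE`).
#' @return Data frame of measurement records (92 rows: 23 objects x 2
#'   operators x 2 methods).
#' @export
load_fixture_tables <- function(check = TRUE) {
  files <- names(FIXTURE_MD5)
  paths <- vapply(files, function(f)
    system.file("extdata", f, package = "maadose", mustWork = TRUE), "")
  if (check) {
    got <- tools::md5sum(paths)
    bad <- files[got != FIXTURE_MD5]
    if (length(bad))
      stop("fixture checksum mismatch: ", paste(bad, collapse = ", "))
  }
  recs <- do.call(rbind, lapply(paths, read_measurement_csv))
  rownames(recs) <- NULL
  recs
}

#' Read a measurement-record CSV
#'
#' Expects the declared header `object, config, ratio, method, operator,
#' isocontour_pct, true_mL, true_mL_alt, measured_mL, error_pct` (extra
#' columns are allowed). Cells mixing comma and dot separators are rejected.
#'
#' @param path CSV path.
#' @return Data frame of measurement records.
#' @export
read_measurement_csv <- function(path) {
  need <- c("object", "config", "method", "operator", "isocontour_pct",
            "true_mL", "measured_mL", "error_pct")
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing columns in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  num_cols <- intersect(c("ratio", "isocontour_pct", "true_mL", "true_mL_alt",
                          "measured_mL", "error_pct"), names(raw))
  for (cl in num_cols) {
    x <- raw[[cl]]
    if (any(grepl(",", x) & grepl("\\.", x), na.rm = TRUE))
      stop("mixed decimal separators in column '", cl, "' of ", path)
    x <- sub(",", ".", x, fixed = TRUE)
    x[x %in% c("", "NA")] <- NA
    raw[[cl]] <- as.numeric(x)
  }
  raw$operator <- as.integer(raw$operator)
  alt <- if ("true_mL_alt" %in% names(raw)) raw$true_mL_alt
         else rep(NA_real_, nrow(raw))
  for (i in seq_len(nrow(raw))) {
    r <- raw[i, ]
    if (!is.na(r$error_pct) && !is.na(r$measured_mL)) {
      recomputed <- percent_error(r$measured_mL,
                                  if (!is.na(alt[i])) alt[i] else r$true_mL)
      if (abs(recomputed - r$error_pct) > 0.5)
        warning("row ", i, " of ", basename(path),
                ": printed error deviates from recomputation by ",
                sprintf("%.2f", abs(recomputed - r$error_pct)), " points")
    }
  }
  raw
}

#' Write measurement records to CSV
#'
#' @param records Measurement-record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurement_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write an activity image or mask as NIfTI
#'
#' @param x An [activity_image()] or [reference_mask()] (masks are written
#'   as 0/1 labels).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_image <- function(x, path) {
  stopifnot(inherits(x, "activity_image") || inherits(x, "reference_mask"))
  vals <- if (is.logical(x$values)) array(as.integer(x$values),
                                          dim = dim(x$values)) else x$values
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- x$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as an activity image
#'
#' @param path NIfTI path.
#' @return An [activity_image()] with voxel sizes taken from the header.
#' @export
read_nifti_image <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  activity_image(array(as.numeric(img), dim = dim(img)[1:3]), vs,
                 metadata = list(source = path))
}

#' Export a VOI as a NIfTI label mask
#'
#' @param voi A `voi` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_voi_nifti <- function(voi, path) {
  stopifnot(inherits(voi, "voi"))
  lab <- array(0L, dim = voi$dim)
  lab[voi$voxels] <- 1L
  write_nifti_image(reference_mask(lab > 0, voi$voxel_size, "voi"), path)
}

#' Write a threshold-fit search trace as CSV
#'
#' @param fit A `threshold_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_trace_csv <- function(fit, path) {
  stopifnot(inherits(fit, "threshold_fit"))
  write.csv(fit$trace, path, row.names = FALSE)
  invisible(path)
}

#' Read a phantom-study run configuration
#'
#' Reads a YAML configuration describing a phantom study: the acquisition
#' model, sphere-to-background ratio sets, segmentation settings, seeds and
#' pseudo-operator display gammas. Missing fields fall back to the defaults
#' of [run_phantom_study()].
#'
#' @param path YAML path.
#' @return A named list suitable for `do.call(run_phantom_study, ...)`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg))
  cfg
}
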