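DOSE_CONSTANT_GY_KG_PER_GBQ <- 50    # Y-90 local-deposition MIRD constant
TISSUE_DENSITY_KG_PER_L <- 1.03      # liver tissue density (mass factor)

#' Compartment mass from volume
#'
#' Converts a measured distribution volume to tissue mass with the standard
#' liver density factor of 1.03 kg/L.
#'
#' @param volume_mL Volume(s), mL; must be non-negative.
#' @return Mass in kg (`volume / 1000 * 1.03`).
#' @examples
#' mass_from_volume(1829)  # 1.88387 kg
#' @export
mass_from_volume <- function(volume_mL) {
  if (any(volume_mL < 0)) stop("volume must be non-negative")
  volume_mL / 1000 * TISSUE_DENSITY_KG_PER_L
}

#' Absorbed dose delivered by an injected Y-90 activity
#'
#' MIRD-based dose to a vascularized volume:
#' `D[Gy] = A_inj[GBq] * (1 - S) * 50 / M[kg]`, where `S` is the lung shunt
#' fraction and `M` the compartment mass from [mass_from_volume()].
#'
#' @param activity_GBq Injected activity, GBq (>= 0).
#' @param shunt Lung shunt fraction `S`, in \[0, 1).
#' @param volume_mL Vascularized volume, mL (> 0).
#' @return Absorbed dose in Gy.
#' @examples
#' dose_from_activity(5, 0, 1829)  # about 132.7 Gy
#' @export
dose_from_activity <- function(activity_GBq, shunt, volume_mL) {
  check_shunt(shunt)
  if (any(activity_GBq < 0)) stop("activity must be non-negative")
  if (any(volume_mL <= 0)) stop("volume must be strictly positive")
  activity_GBq * (1 - shunt) * DOSE_CONSTANT_GY_KG_PER_GBQ /
    mass_from_volume(volume_mL)
}

#' Injected activity needed for a prescribed dose
#'
#' Exact inverse of [dose_from_activity()]:
#' `A[GBq] = D[Gy] * M[kg] / (50 * (1 - S))`. The usual prescription is
#' 120 +/- 20 Gy to the volume to be treated.
#'
#' @param dose_Gy Target absorbed dose, Gy (> 0).
#' @param shunt Lung shunt fraction, in \[0, 1).
#' @param volume_mL Vascularized volume, mL (> 0).
#' @return Activity in GBq.
#' @examples
#' activity_for_dose(120, 0, 346)   # about 0.855 GBq
#' activity_for_dose(120, 0, 1829)  # about 4.52 GBq
#' @export
activity_for_dose <- function(dose_Gy, shunt, volume_mL) {
  check_shunt(shunt)
  if (any(dose_Gy <= 0)) stop("target dose must be strictly positive")
  if (any(volume_mL <= 0)) stop("volume must be strictly positive")
  dose_Gy * mass_from_volume(volume_mL) /
    (DOSE_CONSTANT_GY_KG_PER_GBQ * (1 - shunt))
}

check_shunt <- function(shunt) {
  if (any(shunt < 0) || any(shunt >= 1))
    stop("lung shunt fraction must lie in [0, 1)")
  invisible(TRUE)
}

#' Compartment quantities (volume and counts)
#'
#' @param label One of `"liver"`, `"tumor"`, `"healthy_liver"`, `"lungs"`.
#' @param volume_mL Compartment volume, mL (>= 0).
#' @param counts Total VOI counts (>= 0).
#' @return An object of class `compartment`.
#' @export
compartment <- function(label = c("liver", "tumor", "healthy_liver", "lungs"),
                        volume_mL, counts) {
  label <- match.arg(label)
  stopifnot(length(volume_mL) == 1, volume_mL >= 0,
            length(counts) == 1, counts >= 0)
  structure(list(label = label, volume_mL = as.numeric(volume_mL),
                 counts = as.numeric(counts)),
            class = "compartment")
}

#' Compartment from a VOI measurement
#'
#' @param label Compartment label.
#' @param voi A `voi` object.
#' @param image The [activity_image()] the VOI was drawn on.
#' @return A [compartment()] with the VOI's volume and count integral.
#' @export
compartment_from_voi <- function(label, voi, image) {
  compartment(label, measure_volume(voi, image), measure_counts(voi, image))
}

#' Lung shunt fraction from planar or SPECT count integrals
#'
#' `S = lung counts / (lung counts + liver counts)` — the standard shunt
#' definition (the fraction of extracted activity bypassing the liver).
#'
#' @param lungs,liver [compartment()]s (or anything with a `counts` field).
#' @return Shunt fraction in \[0, 1\].
#' @export
lung_shunt_fraction <- function(lungs, liver) {
  cl <- lungs$counts; ch <- liver$counts
  stopifnot(cl >= 0, ch >= 0)
  if (cl + ch == 0) stop("no counts in lungs or liver")
  cl / (cl + ch)
}

#' Partition a liver VOI into tumor and healthy-liver compartments
#'
#' Healthy-liver volume and counts are obtained by subtraction
#' (`CP_HL = CP_L - CP_tum`; same for volumes); the tumor uptake fraction is
#' `CP_tum / (CP_tum + CP_HL)`.
#'
#' @param liver,tumor [compartment()]s, with the tumor contained in the
#'   liver (counts and volume not exceeding the liver's).
#' @return List with `healthy_liver` (a [compartment()]) and
#'   `tumor_uptake_fraction`.
#' @examples
#' partition(compartment("liver", 1829, 1000), compartment("tumor", 610, 691))
#' @export
partition <- function(liver, tumor) {
  if (tumor$volume_mL > liver$volume_mL)
    stop("tumor volume exceeds liver volume")
  if (tumor$counts > liver$counts)
    stop("tumor counts exceed liver counts")
  hl <- compartment("healthy_liver", liver$volume_mL - tumor$volume_mL,
                    liver$counts - tumor$counts)
  frac <- if (liver$counts == 0) 0 else tumor$counts / liver$counts
  list(healthy_liver = hl, tumor_uptake_fraction = frac)
}

#' Dose plan
#'
#' @param activity_GBq Injected activity `A_inj`, GBq (>= 0).
#' @param shunt Lung shunt fraction, in \[0, 1).
#' @param prescription_Gy Prescribed dose to the treated volume, Gy.
#' @return An object of class `dose_plan`.
#' @export
dose_plan <- function(activity_GBq, shunt = 0, prescription_Gy = 120) {
  check_shunt(shunt)
  stopifnot(activity_GBq >= 0, prescription_Gy > 0)
  structure(list(activity_GBq = activity_GBq, shunt = shunt,
                 prescription_Gy = prescription_Gy,
                 mass_factor_kg_per_L = TISSUE_DENSITY_KG_PER_L,
                 dose_constant = DOSE_CONSTANT_GY_KG_PER_GBQ),
            class = "dose_plan")
}

#' Partition-model dose report
#'
#' Splits the hepatic activity `A_inj * (1 - S)` between tumor and healthy
#' liver in proportion to their count integrals, and converts each to an
#' absorbed dose with the 50 Gy.kg/GBq constant and per-compartment masses:
#' `D_tum = 50 * A_tum / W_tum`, `D_HL = 50 * A_HL / W_HL`, with
#' `A_tum = A_inj (1 - S) CP_tum / (CP_tum + CP_HL)` and the complementary
#' expression for the healthy liver. The whole treated-volume dose uses the
#' full liver volume.
#'
#' @param plan A [dose_plan()].
#' @param liver [compartment()] for the whole injected liver.
#' @param tumor [compartment()] for the tumor.
#' @return An object of class `dose_report`: treated-volume dose, tumor and
#'   healthy-liver activities (GBq), masses (kg) and doses (Gy), and the
#'   tumor uptake fraction. Activities satisfy
#'   `A_tum + A_HL = A_inj * (1 - S)` to floating precision.
#' @examples
#' rep <- dose_report(dose_plan(5, 0), compartment("liver", 1829, 1000),
#'                    compartment("tumor", 610, 691))
#' rep$D_treated_Gy  # about 132.7
#' @export
dose_report <- function(plan, liver, tumor) {
  stopifnot(inherits(plan, "dose_plan"))
  part <- partition(liver, tumor)
  hl <- part$healthy_liver
  f <- part$tumor_uptake_fraction
  hepatic <- plan$activity_GBq * (1 - plan$shunt)
  A_tum <- hepatic * f
  A_HL <- hepatic * (1 - f)
  W_tum <- mass_from_volume(tumor$volume_mL)
  W_HL <- mass_from_volume(hl$volume_mL)
  if (W_tum == 0 && A_tum > 0)
    stop("nonzero tumor activity in a zero-mass compartment")
  if (W_HL == 0 && A_HL > 0)
    stop("nonzero healthy-liver activity in a zero-mass compartment")
  D_tum <- if (A_tum == 0) 0 else plan$dose_constant * A_tum / W_tum
  D_HL <- if (A_HL == 0) 0 else plan$dose_constant * A_HL / W_HL
  stopifnot(isTRUE(all.equal(A_tum + A_HL, hepatic, tolerance = 1e-9)))
  structure(list(plan = plan,
                 D_treated_Gy = dose_from_activity(plan$activity_GBq,
                                                   plan$shunt,
                                                   liver$volume_mL),
                 A_tum_GBq = A_tum, A_HL_GBq = A_HL,
                 W_tum_kg = W_tum, W_HL_kg = W_HL,
                 D_tum_Gy = D_tum, D_HL_Gy = D_HL,
                 tumor_uptake_fraction = f,
                 liver = liver, tumor = tumor, healthy_liver = hl),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<dose_report> A_inj %.3f GBq, shunt %.1f%%\n",
    "  treated volume %.0f mL -> %.0f Gy\n",
    "  tumor:         %.0f mL, A %.3f GBq, W %.3f kg -> %.0f Gy\n",
    "  healthy liver: %.0f mL, A %.3f GBq, W %.3f kg -> %.0f Gy\n",
    "  tumor uptake fraction %.1f%%\n"),
    x$plan$activity_GBq, 100 * x$plan$shunt,
    x$liver$volume_mL, x$D_treated_Gy,
    x$tumor$volume_mL, x$A_tum_GBq, x$W_tum_kg, x$D_tum_Gy,
    x$healthy_liver$volume_mL, x$A_HL_GBq, x$W_HL_kg, x$D_HL_Gy,
    100 * x$tumor_uptake_fraction))
  invisible(x)
}

#' Serialize a dose report to JSON
#'
#' @param report A [dose_report()].
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
dose_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "dose_report"))
  x <- report[c("D_treated_Gy", "A_tum_GBq", "A_HL_GBq", "W_tum_kg",
                "W_HL_kg", "D_tum_Gy", "D_HL_Gy", "tumor_uptake_fraction")]
  x$activity_GBq <- report$plan$activity_GBq
  x$shunt <- report$plan$shunt
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
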