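#' Signed percent error of a volume measurement
#'
#' @param measured_mL Measured volume(s), mL.
#' @param true_mL True volume(s), mL; must be strictly positive.
#' @return `100 * (measured - true) / true`, signed.
#' @examples
#' percent_error(6521, 6716)   # -2.90
#' percent_error(57.22, 55)    #  4.04
#' @export
percent_error <- function(measured_mL, true_mL) {
  if (any(!is.na(true_mL) & true_mL <= 0))
    stop("true volume must be strictly positive")
  100 * (measured_mL - true_mL) / true_mL
}

#' Stratified summary of absolute volume-measurement errors
#'
#' For each operator, method and true-volume stratum, reports the number of
#' usable records and the mean and sample standard deviation (n - 1
#' denominator) of the absolute percent errors. Records with a missing error
#' are dropped from the statistics (and counted in `n_dropped`); strata with
#' no usable record are kept in the output with `n = 0` rather than silently
#' omitted. With a single record the SD is reported as missing.
#'
#' @param records Data frame of measurement records with columns `operator`,
#'   `method`, `true_mL` and `error_pct` (see [load_fixture_tables()]).
#' @param strata Named numeric vector of lower true-volume bounds (mL,
#'   inclusive) defining the strata.
#' @return Data frame with columns `operator`, `method`, `stratum`, `n`,
#'   `n_dropped`, `mean_abs_error_pct`, `sd_abs_error_pct`.
#' @examples
#' recs <- load_fixture_tables()
#' summarize_errors(recs)
#' @export
summarize_errors <- function(records,
                             strata = c(all = 0, ">=16mL" = 16,
                                        ">=473mL" = 473)) {
  stopifnot(is.data.frame(records),
            all(c("operator", "method", "true_mL", "error_pct") %in%
                  names(records)),
            length(strata) >= 1, !is.null(names(strata)))
  combos <- expand.grid(operator = sort(unique(records$operator)),
                        method = sort(unique(records$method)),
                        stratum = names(strata),
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cm <- combos[i, ]
    sel <- records$operator == cm$operator & records$method == cm$method &
      !is.na(records$true_mL) & records$true_mL >= strata[[cm$stratum]]
    err <- records$error_pct[sel]
    ok <- abs(err[!is.na(err)])
    data.frame(operator = cm$operator, method = cm$method,
               stratum = cm$stratum, n = length(ok),
               n_dropped = sum(is.na(err)),
               mean_abs_error_pct = if (length(ok)) mean(ok) else NA_real_,
               sd_abs_error_pct = if (length(ok) > 1) sd(ok) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bland-Altman interobserver agreement with Lin's concordance
#'
#' Computes the Bland-Altman bias (mean of operator-1 minus operator-2
#' differences) and 95% limits of agreement (bias +/- 1.96 SD of the
#' differences), together with Lin's concordance correlation coefficient of
#' the paired measurements. Lin's coefficient is reported because agreement
#' is often graded on a single number in \[-1, 1\] (>= 0.8 excellent,
#' 0.6-0.8 good, 0.4-0.6 poor, < 0.4 very poor), which the two-number
#' Bland-Altman limits do not directly provide.
#'
#' @param op1,op2 Numeric vectors of paired measurements of the same objects
#'   by two operators. Pairs with a missing value are dropped; at least 3
#'   complete pairs are required.
#' @param labels Optional object labels, used to report unpaired objects.
#' @return An object of class `agreement`: a list with `n`, `bias`,
#'   `loa_lower`, `loa_upper`, `sd_diff`, and `concordance`.
#' @examples
#' bland_altman(c(10, 20, 30, 40), c(12, 18, 33, 37))
#' @export
bland_altman <- function(op1, op2, labels = NULL) {
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(op1) || length(labels) == length(op2))
    bad <- labels[xor(is.na(op1), is.na(op2))]
    if (length(bad))
      stop("unpaired objects: ", paste(bad, collapse = ", "))
  }
  if (length(op1) != length(op2))
    stop("operators measured different numbers of objects")
  keep <- !is.na(op1) & !is.na(op2)
  x <- op1[keep]; y <- op2[keep]
  n <- length(x)
  if (n < 3) stop("at least 3 complete measurement pairs are required")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  # Lin's concordance correlation coefficient (1/n moment estimators)
  mx <- mean(x); my <- mean(y)
  sxx <- mean((x - mx)^2); syy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  denom <- sxx + syy + (mx - my)^2
  ccc <- if (denom == 0) 1 else 2 * sxy / denom
  structure(list(n = n, bias = bias, sd_diff = s,
                 loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
                 concordance = ccc),
            class = "agreement")
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf(paste0("<agreement> n = %d pairs\n",
                     "  bias %.3f, 95%% limits of agreement [%.3f, %.3f]\n",
                     "  Lin's concordance %.3f\n"),
              x$n, x$bias, x$loa_lower, x$loa_upper, x$concordance))
  invisible(x)
}

#' Qualitative agreement band for a concordance value
#'
#' @param concordance Value in \[-1, 1\] (e.g. from [bland_altman()]).
#' @return `"excellent"` (>= 0.8), `"good"` (0.6-0.8), `"poor"` (0.4-0.6) or
#'   `"very poor"` (< 0.4).
#' @export
agreement_band <- function(concordance) {
  stopifnot(is.numeric(concordance), concordance >= -1, concordance <= 1)
  cut(concordance, breaks = c(-1, 0.4, 0.6, 0.8, 1),
      labels = c("very poor", "poor", "good", "excellent"),
      include.lowest = TRUE, right = FALSE) |> as.character()
}
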