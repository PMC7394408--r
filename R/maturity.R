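#' FlAsH:Cerulean intensity ratio
#'
#' Per-inclusion ratio of mean FlAsH to mean Cerulean fluorescence inside
#' the inclusion ROI. High ratios indicate disordered, biarsenical-reactive
#' (recently formed) inclusions; low ratios indicate amyloid-converted,
#' poorly reactive (mature) inclusions.
#'
#' @param flash_mean mean FlAsH intensity (a.u.), `>= 0`. Vectorized.
#' @param cerulean_mean mean Cerulean intensity (a.u.), must be `> 0`
#'   (a non-positive value means the cell did not express the fusion).
#' @return dimensionless ratio(s).
#' @export
flash_cerulean_ratio <- function(flash_mean, cerulean_mean) {
  if (any(!is.finite(cerulean_mean)) || any(cerulean_mean <= 0)) {
    stop("cerulean mean must be positive (unexpressed cell?)")
  }
  if (any(flash_mean < 0)) stop("FlAsH mean must be non-negative")
  flash_mean / cerulean_mean
}

#' Population thresholds for maturity classification
#'
#' The classification band is calibrated per experiment: the population
#' mean of the FlAsH:Cerulean ratios plus/minus one standard error of the
#' mean (SEM, sample SD with `n - 1` denominator divided by `sqrt(n)`).
#' Because absolute ratios vary between experiments, thresholds are always
#' reported alongside labels.
#'
#' @param ratios numeric vector of per-inclusion ratios, `n >= 2`.
#' @return object of class `maturity_thresholds` with fields `mean`,
#'   `sem`, `lower`, `upper`, `n`.
#' @export
population_thresholds <- function(ratios) {
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) < 2L) {
    stop("at least two ratios are required to estimate thresholds")
  }
  m <- mean(ratios)
  sem <- stats::sd(ratios) / sqrt(length(ratios))
  maturity_thresholds(m, sem, n = length(ratios))
}

#' @rdname population_thresholds
#' @param mean,sem known population mean and SEM (e.g. values reported for
#'   a published experiment).
#' @param n sample size behind the estimate, if known.
#' @export
maturity_thresholds <- function(mean, sem, n = NA_integer_) {
  stopifnot(is.numeric(mean), is.numeric(sem), sem >= 0)
  structure(list(mean = mean, sem = sem,
                 lower = mean - sem, upper = mean + sem, n = n),
            class = "maturity_thresholds")
}

#' @export
print.maturity_thresholds <- function(x, ...) {
  cat(sprintf("<maturity_thresholds> mean %.4g, SEM %.4g, band [%.4g, %.4g], n = %s\n",
              x$mean, x$sem, x$lower, x$upper, x$n))
  invisible(x)
}

#' Classify inclusion maturity
#'
#' An inclusion with ratio strictly greater than `mean + sem` is `HBR`
#' (Highly Biarsenical-Reactive, recently formed); strictly below
#' `mean - sem` is `PBR` (Poorly Biarsenical-Reactive, mature). Ratios
#' inside the band — including exact ties with either threshold — get an
#' explicit `INTERMEDIATE` label rather than being dropped, so downstream
#' summaries can report all three counts.
#'
#' @param ratio numeric vector of FlAsH:Cerulean ratios.
#' @param thresholds a `maturity_thresholds`.
#' @return factor with levels `PBR`, `INTERMEDIATE`, `HBR` (ordered by
#'   increasing reactivity).
#' @export
classify_maturity <- function(ratio, thresholds) {
  if (!inherits(thresholds, "maturity_thresholds")) {
    stop("expected `maturity_thresholds`")
  }
  lab <- ifelse(ratio > thresholds$upper, "HBR",
                ifelse(ratio < thresholds$lower, "PBR", "INTERMEDIATE"))
  factor(lab, levels = c("PBR", "INTERMEDIATE", "HBR"), ordered = TRUE)
}

#' Per-inclusion maturity table
#'
#' Computes ratios from per-inclusion FlAsH / Cerulean mean intensities,
#' calibrates thresholds on this population (unless supplied), and labels
#' every inclusion. This is the tidy per-inclusion export.
#'
#' @param flash_means,cerulean_means numeric vectors of per-inclusion mean
#'   intensities.
#' @param inclusion_ids optional identifiers (default `1..n`).
#' @param thresholds optional pre-computed `maturity_thresholds`; default
#'   is to calibrate on this population.
#' @return `data.frame` with columns `inclusion_id`, `flash_mean`,
#'   `cerulean_mean`, `ratio`, `population_mean`, `population_sem`,
#'   `label`.
#' @export
maturity_table <- function(flash_means, cerulean_means,
                           inclusion_ids = seq_along(flash_means),
                           thresholds = NULL) {
  ratio <- flash_cerulean_ratio(flash_means, cerulean_means)
  if (is.null(thresholds)) thresholds <- population_thresholds(ratio)
  data.frame(
    inclusion_id = inclusion_ids,
    flash_mean = flash_means,
    cerulean_mean = cerulean_means,
    ratio = ratio,
    population_mean = thresholds$mean,
    population_sem = thresholds$sem,
    label = as.character(classify_maturity(ratio, thresholds)),
    stringsAsFactors = FALSE
  )
}
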