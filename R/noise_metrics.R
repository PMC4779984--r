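#' Combine step variances into total technical noise
#'
#' The technical noise introduced by the three processing steps is assumed
#' independent, so the total variance of a single Cq measurement is the sum
#' of the step variances, sigma2_Cq = sigma2_sampling + sigma2_rt +
#' sigma2_qpcr, and the total noise is its square root. Per-step
#' contributions are the shares of each variance in that total, in percent.
#'
#' @param vc A `variance_components` object, or a named numeric vector of
#'   variances with names `sampling`, `rt`, `qpcr` (cycles^2).
#' @return An object of class `noise_summary`: list with `total_sd` (cycles),
#'   `total_var` (cycles^2), `contributions` (named percent vector, `NA` when
#'   all components are zero), and `fold_equiv` (`2^total_sd`, the
#'   fold-change magnitude a single-measurement deviation of one total-noise
#'   SD corresponds to).
#' @export
#' @examples
#' total_noise(c(sampling = 0.45^2, rt = 0.73^2, qpcr = 0.32^2))
total_noise <- function(vc) {
  if (inherits(vc, "variance_components")) {
    v <- c(sampling = vc$var_sampling, rt = vc$var_rt, qpcr = vc$var_qpcr)
  } else {
    stopifnot(is.numeric(vc), all(c("sampling", "rt", "qpcr") %in% names(vc)))
    v <- vc[c("sampling", "rt", "qpcr")]
  }
  if (anyNA(v)) stop("variance components contain NA", call. = FALSE)
  if (any(v < 0)) stop("variance components must be non-negative", call. = FALSE)
  total_var <- sum(v)
  contributions <- if (total_var > 0) 100 * v / total_var
                   else stats::setNames(rep(NA_real_, 3), names(v))
  structure(list(
    total_sd = sqrt(total_var),
    total_var = total_var,
    contributions = contributions,
    fold_equiv = 2^sqrt(total_var)
  ), class = "noise_summary")
}

#' @export
print.noise_summary <- function(x, ...) {
  cat(sprintf("Total noise: %.2f cycles (variance %.4f; ~%.1f-fold)\n",
              x$total_sd, x$total_var, x$fold_equiv))
  if (anyNA(x$contributions)) {
    cat("Contributions: undefined (all components zero)\n")
  } else {
    cat(sprintf("Contributions: sampling %.1f%%, RT %.1f%%, qPCR %.1f%%\n",
                x$contributions[["sampling"]], x$contributions[["rt"]],
                x$contributions[["qpcr"]]))
  }
  invisible(x)
}

#' Standard error of a replicate mean
#'
#' Averaging n replicates of one processing step reduces that step's noise
#' contribution from sigma to sigma/sqrt(n): the SD of a mean is its
#' standard error.
#'
#' @param sd Step SD, cycles (>= 0).
#' @param n Replicate count (>= 1); need not be an integer mid-calculation,
#'   but a sampling plan would use integers.
#' @return `sd / sqrt(n)`, cycles.
#' @export
#' @examples
#' se_of_mean(0.32, 2)  # duplicate qPCR: 0.32 -> 0.23
se_of_mean <- function(sd, n) {
  stopifnot(is.numeric(sd), is.numeric(n))
  if (any(sd < 0)) stop("sd must be >= 0", call. = FALSE)
  if (any(n < 1)) stop("n must be >= 1", call. = FALSE)
  sd / sqrt(n)
}

#' Convert a Cq difference to a fold change
#'
#' With amplification efficiency E (fraction of templates duplicated per
#' cycle), a Cq difference of delta corresponds to a (1+E)^delta fold
#' difference in starting template. The default E = 1 (perfect doubling,
#' base 2) matches the usual reporting convention.
#'
#' @param delta_cq Cq difference, cycles.
#' @param efficiency Amplification efficiency in `[0, 1]`; default 1.
#' @return Fold change, `(1 + efficiency)^delta_cq`.
#' @export
#' @examples
#' cq_to_fold(8.47)  # ~355-fold
cq_to_fold <- function(delta_cq, efficiency = 1) {
  stopifnot(is.numeric(delta_cq), is.numeric(efficiency))
  if (any(efficiency < 0 | efficiency > 1)) {
    stop("efficiency must be in [0, 1]", call. = FALSE)
  }
  (1 + efficiency)^delta_cq
}

#' 3':5' integrity ratio from comparative Cq
#'
#' RNA-integrity / RT-processivity QC: amplicons near the 3' and 5' ends of
#' the same transcript are quantified from the same cDNA, and the ratio
#' 2^(Cq_5' - Cq_3') measures how much less of the 5' end was reverse
#' transcribed. Oligo-dT priming starts at the 3' end, so degraded RNA or a
#' poorly processive RT inflates the ratio; samples above the threshold are
#' flagged inadequate.
#'
#' @param cq_5prime Cq of the 5' amplicon, cycles.
#' @param cq_3prime Cq of the 3' amplicon, cycles.
#' @param threshold Fold ratio above which RNA quality is deemed inadequate;
#'   default 4.5.
#' @return A list with `ratio` (fold) and `adequate` (logical,
#'   `ratio <= threshold`).
#' @export
#' @examples
#' three_five_ratio(26.0, 25.0)  # ratio 2, adequate
three_five_ratio <- function(cq_5prime, cq_3prime, threshold = 4.5) {
  if (anyNA(cq_5prime) || anyNA(cq_3prime)) {
    stop("both Cq values must be present", call. = FALSE)
  }
  stopifnot(is.numeric(cq_5prime), is.numeric(cq_3prime))
  ratio <- 2^(cq_5prime - cq_3prime)
  list(ratio = ratio, adequate = ratio <= threshold)
}
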