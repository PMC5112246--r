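# Quality control of array methylation values: beta computation from raw
# intensities, detection p-value masking, and the probe missingness filter.

#' Compute beta values from methylated/unmethylated intensities
#'
#' beta = M / (M + U + 100), the Illumina summary with a +100 stabilising
#' offset in the denominator; values lie in `[0, 1)`.
#'
#' @param M Matrix of methylated signal intensities, >= 0.
#' @param U Matrix of unmethylated signal intensities, same shape as `M`.
#' @param offset Denominator offset (default 100).
#' @return Beta matrix with the dimnames of `M`.
#' @export
compute_beta <- function(M, U, offset = 100) {
  if (!identical(dim(M), dim(U)))
    stop("M and U must have identical dimensions", call. = FALSE)
  if (any(M < 0, na.rm = TRUE) || any(U < 0, na.rm = TRUE))
    stop("negative intensity", call. = FALSE)
  beta <- M / (M + U + offset)
  dimnames(beta) <- dimnames(M)
  beta
}

#' Mask beta values with failed detection
#'
#' Entries whose detection p-value exceeds the threshold (strictly: the rule
#' is `detp > threshold`, so a value at exactly the threshold is kept) are
#' set to `NA`.
#'
#' @param betas Beta matrix.
#' @param detp Detection p-value matrix, same shape as `betas`.
#' @param threshold Masking threshold (default 0.01).
#' @return Beta matrix with failed entries set missing.
#' @export
mask_by_detection <- function(betas, detp, threshold = 0.01) {
  if (!identical(dim(betas), dim(detp)))
    stop("detection p-value matrix shape differs from beta matrix",
         call. = FALSE)
  betas[!is.na(detp) & detp > threshold] <- NA_real_
  betas
}

#' Drop probes with a high fraction of missing values
#'
#' Probes whose missing fraction strictly exceeds `max_missing_frac`
#' (default 5%) are removed; exactly 5% missing is retained.
#'
#' @param betas Beta matrix.
#' @param max_missing_frac Maximum tolerated missing fraction per probe.
#' @return List with `betas` (filtered matrix) and `dropped` (character
#'   vector of removed probe ids).
#' @export
filter_high_missing <- function(betas, max_missing_frac = 0.05) {
  frac <- rowMeans(is.na(betas))
  drop <- frac > max_missing_frac
  list(betas = betas[!drop, , drop = FALSE],
       dropped = rownames(betas)[drop])
}

#' Clip beta values away from 0 and 1
#'
#' Ratio-scale summaries (fold changes) divide by control methylation;
#' values are clipped to `[eps, 1 - eps]` beforehand so the ratio is always
#' finite and positive.
#'
#' @param betas Beta matrix.
#' @param eps Clipping margin (default 1e-6).
#' @return Clipped matrix; the number of clipped cells is reported via
#'   `message` when positive.
#' @export
clip_betas <- function(betas, eps = 1e-6) {
  n <- sum(betas < eps | betas > 1 - eps, na.rm = TRUE)
  if (n > 0)
    message(sprintf("clip_betas: %d value(s) clipped to [%g, %g]",
                    n, eps, 1 - eps))
  pmin(pmax(betas, eps), 1 - eps)
}
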