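# Reference-based cell-type deconvolution and removal of composition
# effects. Whole blood is a mixture of leukocyte populations with distinct
# methylation signatures; per-sample mixing proportions are estimated by
# constrained projection onto reference profiles, then regressed out of
# every CpG so that downstream co-twin contrasts are not driven by
# composition differences between co-twins.

# Minimise ||R w - b||^2 subject to w >= 0, sum(w) = 1. Exact for small
# numbers of cell types by enumerating candidate supports: the optimal
# active set's equality-constrained solution is feasible and attains the
# global minimum, so the best feasible support solution is the optimum.
# Ties in the objective prefer the larger support (the interior solution).
.simplex_lsq <- function(R, b) {
  K <- ncol(R)
  best_w <- NULL
  best_obj <- Inf
  best_size <- 0L
  for (mask in seq_len(2^K - 1L)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(K) - 1L)) != 0L)
    RS <- R[, S, drop = FALSE]
    k <- length(S)
    # KKT system of least squares with the sum-to-one equality constraint
    A <- rbind(cbind(2 * crossprod(RS), rep(1, k)),
               c(rep(1, k), 0))
    rhs <- c(2 * crossprod(RS, b), 1)
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) sol <- MASS::ginv(A) %*% rhs
    w <- sol[seq_len(k)]
    if (any(w < -1e-9)) next
    w <- pmax(w, 0)
    w <- w / sum(w)
    obj <- sum((RS %*% w - b)^2)
    if (obj < best_obj - 1e-12 ||
        (obj < best_obj + 1e-12 && k > best_size)) {
      best_obj <- obj
      best_size <- k
      best_w <- numeric(K)
      best_w[S] <- w
    }
  }
  best_w
}

#' Validate a cell-type reference profile matrix
#'
#' @param profiles Numeric matrix of mean beta per probe (rows, named) and
#'   cell type (columns, named), values in `[0, 1]`.
#' @return The validated matrix.
#' @export
celltype_reference <- function(profiles) {
  if (!is.matrix(profiles) || ncol(profiles) < 2L)
    stop("reference needs at least 2 cell types", call. = FALSE)
  if (nrow(profiles) < ncol(profiles))
    stop("reference needs at least as many probes as cell types",
         call. = FALSE)
  if (any(profiles < 0 | profiles > 1, na.rm = TRUE))
    stop("reference profiles must lie in [0,1]", call. = FALSE)
  profiles
}

#' Estimate cell-type proportions per sample
#'
#' For each sample, finds nonnegative weights summing to one that minimise
#' the sum of squared deviations between the sample's beta values at the
#' reference probes and the weighted combination of reference profiles
#' (simplex-constrained least squares).
#'
#' @param betas Beta matrix containing the reference probes.
#' @param ref Reference matrix from [celltype_reference()].
#' @return Matrix of proportions, samples x cell types; rows sum to 1.
#' @export
estimate_proportions <- function(betas, ref) {
  ref <- celltype_reference(ref)
  common <- intersect(rownames(ref), rownames(betas))
  lost <- setdiff(rownames(ref), common)
  if (length(lost))
    warning(sprintf("%d reference probe(s) absent from beta matrix, dropped",
                    length(lost)), call. = FALSE)
  if (length(common) < ncol(ref))
    stop("fewer usable reference probes than cell types", call. = FALSE)
  R <- ref[common, , drop = FALSE]
  B <- betas[common, , drop = FALSE]
  out <- matrix(NA_real_, ncol(B), ncol(R),
                dimnames = list(colnames(B), colnames(R)))
  for (j in seq_len(ncol(B))) {
    ok <- !is.na(B[, j])
    if (sum(ok) < ncol(R))
      stop(sprintf("sample '%s': fewer usable probes than cell types",
                   colnames(B)[j]), call. = FALSE)
    out[j, ] <- .simplex_lsq(R[ok, , drop = FALSE], B[ok, j])
  }
  out
}

#' Remove cell-type composition effects from a beta matrix
#'
#' Per CpG, beta values are replaced by the residuals of an ordinary
#' least-squares fit on the proportion covariates (one cell-type column is
#' dropped, since proportions sum to one) plus the CpG's grand mean,
#' clipped back to `[0, 1]`. Constant proportion columns are dropped with a
#' warning. Re-adjusting the output changes nothing (up to numerical
#' tolerance), so the operation can safely appear once per pipeline run.
#'
#' @param betas Beta matrix.
#' @param proportions Matrix from [estimate_proportions()]; rows must cover
#'   all samples of `betas`.
#' @return Adjusted beta matrix, same shape and dimnames.
#' @export
adjust_for_celltype <- function(betas, proportions) {
  if (!all(colnames(betas) %in% rownames(proportions)))
    stop("proportions missing for some samples", call. = FALSE)
  W <- proportions[colnames(betas), , drop = FALSE]
  # drop one column (sum-to-one collinearity), then any constant column
  W <- W[, -ncol(W), drop = FALSE]
  keep <- apply(W, 2L, function(x) stats::sd(x) > 1e-12)
  if (!all(keep))
    warning("constant proportion column(s) dropped: ",
            paste(colnames(W)[!keep], collapse = ", "), call. = FALSE)
  W <- W[, keep, drop = FALSE]
  if (ncol(W) == 0L) return(betas)
  X <- cbind(1, W)
  complete <- !rowSums(is.na(betas)) > 0
  out <- betas
  if (any(complete)) {
    B <- betas[complete, , drop = FALSE]
    # residuals + grand mean, all probes at once
    coef <- t(qr.coef(qr(X), t(B)))
    fitted <- coef %*% t(X)
    out[complete, ] <- B - fitted + rowMeans(B)
  }
  for (i in which(!complete)) {
    ok <- !is.na(betas[i, ])
    if (sum(ok) <= ncol(X)) next
    fit <- stats::lm.fit(X[ok, , drop = FALSE], betas[i, ok])
    out[i, ok] <- fit$residuals + mean(betas[i, ok])
  }
  pmin(pmax(out, 0), 1)
}
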