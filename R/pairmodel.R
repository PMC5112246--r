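# Per-CpG co-twin regression. In a disease-discordant monozygotic pair the
# within-pair beta difference (affected minus unaffected) cancels genetic
# and shared-environment effects; regressing that difference on centered
# pair-level covariates gives an intercept alpha measuring the disease
# effect (alpha > 0: hypermethylation in the affected twin) and slopes
# measuring exposure-linked modulation (smoking, anti-CCP, DMARD), with
# age and sex as adjustment covariates.

#' Compute within-pair methylation differences
#'
#' Per probe and pair: `delta` = beta(case) - beta(control), and the
#' ratio-scale fold change beta(case)/beta(control) after clipping both
#' values away from 0 and 1. A pair missing either value at a probe is
#' `NA` at that probe.
#'
#' @param betas Beta matrix.
#' @param design `pair_design` whose samples all resolve in `betas`.
#' @param eps Clipping margin for the ratio denominator.
#' @return List with matrices `delta`, `ratio`, `case`, `control`
#'   (probes x pairs, columns named by pair id).
#' @export
compute_pair_differences <- function(betas, design, eps = 1e-6) {
  check_design_samples(design, betas)
  case <- betas[, design$case_sample, drop = FALSE]
  control <- betas[, design$control_sample, drop = FALSE]
  colnames(case) <- colnames(control) <- design$pair_id
  cc <- pmin(pmax(case, eps), 1 - eps)
  kk <- pmin(pmax(control, eps), 1 - eps)
  list(delta = case - control, ratio = cc / kk,
       case = case, control = control)
}

# Numeric covariate matrix (pairs x covariates) from a design sheet.
.covariate_matrix <- function(design, covariates) {
  if (length(covariates) == 0L)
    return(matrix(numeric(0), nrow(design), 0,
                  dimnames = list(design$pair_id, NULL)))
  Z <- sapply(covariates, function(v) as.numeric(design[[v]]))
  Z <- matrix(Z, nrow = nrow(design),
              dimnames = list(design$pair_id, covariates))
  Z
}

# Precompute, per missingness pattern, the OLS machinery shared by the
# observed fit and every permutation: design matrix (intercept + exposure
# covariates as 0/1, adjustment covariates centered), its pseudo-inverse
# H = (X'X)^-1 X', residual df and which covariate columns survived rank
# checks. Binary exposures stay uncentered so the intercept is the disease
# effect in unexposed pairs and an exposure-driven signal loads on its
# slope surface only, not on the intercept. Pairs with a missing covariate
# are excluded from every probe's fit; probes then group by the NA pattern
# of their delta row.
.ols_precompute <- function(delta, Z, min_pairs,
                            center = c("age", "sex")) {
  usable <- if (ncol(Z)) !rowSums(is.na(Z)) > 0 else rep(TRUE, ncol(delta))
  pat <- apply(!is.na(delta[, usable, drop = FALSE]), 1L, function(r)
    paste(which(r), collapse = ","))
  groups <- list()
  for (key in unique(pat)) {
    rows <- which(pat == key)
    pairs <- which(usable)[as.integer(strsplit(key, ",")[[1L]])]
    n <- length(pairs)
    if (n < min_pairs) {
      groups[[length(groups) + 1L]] <-
        list(rows = rows, pairs = pairs, skipped = TRUE)
      next
    }
    Zs <- Z[pairs, , drop = FALSE]
    keep <- if (ncol(Zs)) apply(Zs, 2L, function(x) stats::sd(x) > 1e-12)
            else logical(0)
    center_cols <- function(M) {
      cc <- intersect(colnames(M), center)
      M[, cc] <- scale(M[, cc, drop = FALSE], center = TRUE, scale = FALSE)
      M
    }
    X <- cbind(intercept = 1, center_cols(Zs[, keep, drop = FALSE]))
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      # drop collinear covariate columns (never the intercept)
      drop_idx <- qx$pivot[seq(qx$rank + 1L, ncol(X))]
      keep_names <- setdiff(colnames(X)[-drop_idx], "intercept")
      keep[!(names(keep) %in% keep_names) & keep] <- FALSE
      X <- cbind(intercept = 1, center_cols(Zs[, keep, drop = FALSE]))
      qx <- qr(X)
    }
    XtXinv <- chol2inv(qr.R(qx))
    H <- XtXinv %*% t(X)
    df <- n - ncol(X)
    groups[[length(groups) + 1L]] <- list(
      rows = rows, pairs = pairs, skipped = FALSE, X = X, H = H,
      XtXinv = XtXinv, df = df, keep = names(keep)[keep])
  }
  groups
}

#' Fit the per-CpG co-twin regression
#'
#' Ordinary least squares of the within-pair delta on pair-level
#' covariates, probe by probe. Binary exposures (smoking, anti-CCP,
#' DMARD) enter as 0/1, so the intercept is the disease effect on the
#' delta scale in unexposed pairs and exposure-driven signal loads on the
#' matching slope; adjustment covariates (age, sex) are centered across
#' the pairs used at each probe so the intercept is never extrapolated
#' beyond the cohort. Two-sided t tests use
#' residual df = n_pairs_used - (1 + retained covariates). Pairs with a
#' missing covariate value (e.g. unknown smoking status) are excluded, not
#' imputed; probes with fewer complete pairs than `min_pairs` are skipped.
#' Covariate columns constant (or collinear) across the pairs used are
#' dropped with a warning and reported as `NA`.
#'
#' @param delta Probes x pairs matrix of within-pair differences.
#' @param design `pair_design` aligned to the columns of `delta`.
#' @param covariates Character vector of design columns to adjust for.
#' @param min_pairs Minimum complete pairs per probe (default 10).
#' @param center Covariates to center before fitting. The default centers
#'   only age and sex, leaving binary exposures at 0/1 so the intercept
#'   is orthogonal to every exposure slope (an exposure-driven signal
#'   cannot surface as a disease effect). Passing all covariate names
#'   instead makes the intercept the disease effect at cohort-average
#'   exposures — a much more precise estimate of a uniform disease
#'   effect, at the cost of absorbing a fraction of any exposure-driven
#'   signal.
#' @return `data.frame` with probe_id, n_pairs_used, df, alpha, alpha_se,
#'   alpha_p and `<cov>_slope`, `<cov>_se`, `<cov>_p` per covariate.
#' @export
fit_cpg_models <- function(delta, design,
                           covariates = c("smoking", "accp", "dmard",
                                          "age", "sex"),
                           min_pairs = 10, center = c("age", "sex")) {
  covariates <- intersect(covariates, names(design))
  Z <- .covariate_matrix(design, covariates)
  groups <- .ols_precompute(delta, Z, min_pairs, center = center)
  P <- nrow(delta)
  out <- data.frame(probe_id = rownames(delta),
                    n_pairs_used = NA_integer_, df = NA_integer_,
                    alpha = NA_real_, alpha_se = NA_real_,
                    alpha_p = NA_real_, stringsAsFactors = FALSE)
  for (v in covariates)
    out[paste0(v, c("_slope", "_se", "_p"))] <-
      list(rep(NA_real_, P), rep(NA_real_, P), rep(NA_real_, P))
  dropped_any <- character(0)
  for (g in groups) {
    out$n_pairs_used[g$rows] <- length(g$pairs)
    if (g$skipped) next
    Y <- delta[g$rows, g$pairs, drop = FALSE]
    coefs <- Y %*% t(g$H)                       # probes x (1 + k)
    res <- Y - coefs %*% t(g$X)
    sigma2 <- rowSums(res^2) / g$df
    se <- sqrt(outer(sigma2, diag(g$XtXinv)))
    tval <- coefs / se
    pval <- 2 * stats::pt(-abs(tval), df = g$df)
    out$df[g$rows] <- g$df
    out$alpha[g$rows] <- coefs[, 1L]
    out$alpha_se[g$rows] <- se[, 1L]
    out$alpha_p[g$rows] <- pval[, 1L]
    for (v in g$keep) {
      j <- match(v, colnames(g$X))
      out[[paste0(v, "_slope")]][g$rows] <- coefs[, j]
      out[[paste0(v, "_se")]][g$rows] <- se[, j]
      out[[paste0(v, "_p")]][g$rows] <- pval[, j]
    }
    dropped_any <- union(dropped_any, setdiff(covariates, g$keep))
  }
  if (length(dropped_any))
    warning("covariate column(s) dropped (constant or collinear) in some ",
            "fits: ", paste(dropped_any, collapse = ", "), call. = FALSE)
  out
}

#' Fit the co-twin model from a beta matrix and attach fold changes
#'
#' Convenience wrapper: computes pair differences, fits [fit_cpg_models()]
#' and appends the Table-style fold change, mean(case beta)/mean(control
#' beta) per probe over the pairs with both twins measured (values below
#' one: relative hypomethylation in the affected twin).
#'
#' @inheritParams fit_cpg_models
#' @param betas Beta matrix.
#' @param eps Clipping margin for the fold-change denominator.
#' @return The [fit_cpg_models()] table plus a `fold_change` column.
#' @export
fit_pair_model <- function(betas, design,
                           covariates = c("smoking", "accp", "dmard",
                                          "age", "sex"),
                           min_pairs = 10, center = c("age", "sex"),
                           eps = 1e-6) {
  diffs <- compute_pair_differences(betas, design, eps = eps)
  stats <- fit_cpg_models(diffs$delta, design, covariates = covariates,
                          min_pairs = min_pairs, center = center)
  both <- !is.na(diffs$case) & !is.na(diffs$control)
  cs <- diffs$case; cs[!both] <- NA
  ct <- diffs$control; ct[!both] <- NA
  mc <- pmax(rowMeans(cs, na.rm = TRUE), eps)
  mk <- pmax(rowMeans(ct, na.rm = TRUE), eps)
  stats$fold_change <- mc / mk
  stats
}

#' Call differentially methylated positions
#'
#' Benjamini-Hochberg FDR over the disease-intercept p-values (and,
#' separately, over each covariate's slope p-values); genome-wide
#' significant means FDR < `fdr_threshold`, suggestive means uncorrected
#' p < `suggestive_p`.
#'
#' @param stats Table from [fit_cpg_models()] / [fit_pair_model()].
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param suggestive_p Uncorrected suggestive cutoff (default 5e-5).
#' @return `stats` with added columns `fdr`, `significant`, `suggestive`
#'   and `<cov>_fdr` for each covariate present.
#' @export
call_dmps <- function(stats, fdr_threshold = 0.05, suggestive_p = 5e-5) {
  stats$fdr <- stats::p.adjust(stats$alpha_p, method = "BH")
  stats$significant <- !is.na(stats$fdr) & stats$fdr < fdr_threshold
  stats$suggestive <- !is.na(stats$alpha_p) & stats$alpha_p < suggestive_p
  for (v in sub("_p$", "", grep("_p$", names(stats), value = TRUE))) {
    pc <- paste0(v, "_p")
    if (pc %in% names(stats) && v != "alpha")
      stats[[paste0(v, "_fdr")]] <- stats::p.adjust(stats[[pc]],
                                                    method = "BH")
  }
  stats
}
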