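# Bump hunting on per-CpG coefficient surfaces. Probes are grouped into
# clusters (runs with inter-probe gaps <= maxgap), the chosen coefficient
# surface (disease intercept or an exposure slope) is smoothed within
# clusters, symmetric thresholds are taken at the 99th percentile of the
# absolute smoothed values, and maximal runs beyond a threshold become
# candidate DMRs scored by the area statistic (sum of absolute smoothed
# values). Inference flips case/control labels independently per pair
# (equivalently, flips the sign of each pair's delta column), re-runs the
# fit -> smooth -> detect chain with the observed thresholds held fixed,
# and summarises the null areas as FWER, suggestive, empirical-p and FDR.
#
# The smoother depends only on probe positions, so it is precomputed once
# as a sparse linear operator; each permutation then costs two matrix
# products and a run scan.

#' Cluster probes by genomic proximity
#'
#' Maximal runs of manifest probes whose consecutive gaps are at most
#' `maxgap` base pairs, per chromosome (a gap of exactly `maxgap` stays in
#' the same cluster).
#'
#' @param manifest Sorted probe manifest ([manifest()]).
#' @param maxgap Maximum intra-cluster gap in bp (default 500).
#' @return Integer vector of cluster ids aligned to manifest rows.
#' @export
cluster_probes <- function(manifest, maxgap = 500) {
  n <- nrow(manifest)
  if (n == 0L) return(integer(0))
  new_chrom <- c(TRUE, manifest$chrom[-1L] != manifest$chrom[-n])
  gap <- c(0L, diff(manifest$pos))
  breaks <- new_chrom | gap > maxgap
  cumsum(breaks)
}

# Row of the local-linear tricube smoother: fitted value at x0 from
# responses at positions x with window half-width h. Falls back to a
# weighted mean when the window holds fewer than two distinct positions.
.local_linear_row <- function(x, x0, h) {
  w <- numeric(length(x))
  d <- abs(x - x0)
  inside <- d < h
  w[inside] <- (1 - (d[inside] / h)^3)^3
  if (sum(w > 0) < 2L || length(unique(x[w > 0])) < 2L) {
    if (sum(w) == 0) w[which.min(d)] <- 1
    return(w / sum(w))
  }
  z <- x - x0
  sw <- sum(w); swz <- sum(w * z); swz2 <- sum(w * z^2)
  det <- sw * swz2 - swz^2
  if (abs(det) < 1e-300) return(w / sum(w))
  # e1' (Z'WZ)^-1 Z'W  with Z = [1, z]
  (swz2 * w - swz * (w * z)) / det
}

#' Build the within-cluster smoother operator
#'
#' Returns a sparse matrix `S` such that `S %*% coef` smooths a per-probe
#' coefficient vector within clusters: clusters with at least
#' `min_probes_loess` probes get a local linear (tricube-weighted) fit over
#' a +/- `bandwidth` bp window evaluated at each probe; smaller clusters a
#' running mean of window 3; clusters of size <= 2 pass through unchanged.
#' The smoother reproduces constants exactly and, on large clusters, is
#' exact on linear trends.
#'
#' @param manifest Sorted probe manifest.
#' @param clusters Cluster ids from [cluster_probes()].
#' @param bandwidth Window half-width in bp (default 1000).
#' @param min_probes_loess Minimum cluster size for the local linear fit.
#' @return `dgCMatrix` of dimension n_probes x n_probes.
#' @export
build_smoother <- function(manifest, clusters, bandwidth = 1000,
                           min_probes_loess = 7) {
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (idx in split(seq_len(nrow(manifest)), clusters)) {
    m <- length(idx)
    pos <- manifest$pos[idx]
    if (m <= 2L) {
      ii <- c(ii, idx); jj <- c(jj, idx); xx <- c(xx, rep(1, m))
    } else if (m < min_probes_loess) {
      for (k in seq_len(m)) {
        nb <- idx[max(1L, k - 1L):min(m, k + 1L)]
        ii <- c(ii, rep(idx[k], length(nb)))
        jj <- c(jj, nb)
        xx <- c(xx, rep(1 / length(nb), length(nb)))
      }
    } else {
      for (k in seq_len(m)) {
        r <- .local_linear_row(pos, pos[k], bandwidth)
        nz <- which(r != 0)
        ii <- c(ii, rep(idx[k], length(nz)))
        jj <- c(jj, idx[nz])
        xx <- c(xx, r[nz])
      }
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(nrow(manifest), nrow(manifest)))
}

#' Smooth a coefficient surface within probe clusters
#'
#' @param coef Numeric vector, one coefficient per manifest probe (`NA`
#'   entries are treated as 0 before smoothing).
#' @param manifest Sorted probe manifest.
#' @param clusters Cluster ids from [cluster_probes()].
#' @param smoother Optional precomputed operator from [build_smoother()].
#' @param bandwidth,min_probes_loess Passed to [build_smoother()] when
#'   `smoother` is `NULL`.
#' @return Numeric vector of smoothed values.
#' @export
smooth_within_clusters <- function(coef, manifest, clusters,
                                   smoother = NULL, bandwidth = 1000,
                                   min_probes_loess = 7) {
  if (is.null(smoother))
    smoother <- build_smoother(manifest, clusters, bandwidth,
                               min_probes_loess)
  coef[is.na(coef)] <- 0
  as.numeric(smoother %*% coef)
}

#' Compute symmetric bump thresholds
#'
#' Upper threshold = the `quantile_level` (default 99th percentile,
#' linear-interpolation quantile) of the absolute smoothed values; lower
#' threshold its negative. With `signed = TRUE` the upper/lower thresholds
#' are instead the `quantile_level` and `1 - quantile_level` quantiles of
#' the signed values.
#'
#' @param smoothed Genome-wide smoothed values.
#' @param quantile_level Quantile (default 0.99).
#' @param signed Use signed quantiles instead of the symmetric absolute
#'   rule.
#' @return List with `upper` and `lower`.
#' @export
compute_thresholds <- function(smoothed, quantile_level = 0.99,
                               signed = FALSE) {
  smoothed <- smoothed[!is.na(smoothed)]
  if (max(smoothed) - min(smoothed) < 1e-300)
    warning("degenerate thresholds: all smoothed values identical",
            call. = FALSE)
  if (signed) {
    list(upper = unname(stats::quantile(smoothed, quantile_level)),
         lower = unname(stats::quantile(smoothed, 1 - quantile_level)))
  } else {
    q <- unname(stats::quantile(abs(smoothed), quantile_level))
    list(upper = q, lower = -q)
  }
}

# Fast run scan: maximal runs of smoothed > upper (state +1) or < lower
# (state -1) that do not cross cluster boundaries. Returns start/end probe
# indices, direction and area per run.
.scan_bumps <- function(smoothed, clusters, upper, lower) {
  state <- integer(length(smoothed))
  state[smoothed > upper] <- 1L
  state[smoothed < lower] <- -1L
  code <- clusters * 3L + state      # distinct per (cluster, state)
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  st <- state[starts]
  keep <- st != 0L
  if (!any(keep))
    return(list(start = integer(0), end = integer(0),
                direction = integer(0), area = numeric(0)))
  cs <- c(0, cumsum(abs(smoothed)))
  s <- starts[keep]; e <- ends[keep]
  list(start = s, end = e, direction = st[keep],
       area = cs[e + 1L] - cs[s])
}

#' Detect candidate bumps on a smoothed surface
#'
#' Within each cluster, maximal runs of consecutive probes strictly beyond
#' a threshold (above `upper`: hypermethylated bump; below `lower`:
#' hypomethylated) become candidate regions. Each bump's area is the sum
#' of absolute smoothed values over its probes; bumps are ranked by area
#' descending with ties broken by genomic position.
#'
#' @param smoothed Smoothed coefficient vector.
#' @param manifest Sorted probe manifest.
#' @param clusters Cluster ids.
#' @param thresholds List from [compute_thresholds()].
#' @return `data.frame`: chrom, start, end, n_probes, direction, area,
#'   peak, index_start, index_end, rank.
#' @export
detect_bumps <- function(smoothed, manifest, clusters, thresholds) {
  sc <- .scan_bumps(smoothed, clusters, thresholds$upper, thresholds$lower)
  n <- length(sc$start)
  out <- data.frame(
    chrom = manifest$chrom[sc$start],
    start = manifest$pos[sc$start],
    end = manifest$pos[sc$end],
    n_probes = sc$end - sc$start + 1L,
    direction = ifelse(sc$direction > 0L, "hyper", "hypo"),
    area = sc$area,
    peak = vapply(seq_len(n), function(i)
      max(abs(smoothed[sc$start[i]:sc$end[i]])), numeric(1)),
    index_start = sc$start,
    index_end = sc$end,
    stringsAsFactors = FALSE)
  out <- out[order(-out$area, out$chrom, out$start), , drop = FALSE]
  out$rank <- seq_len(n)
  rownames(out) <- NULL
  out
}

# Per-surface hat vectors: for each precomputed OLS group, the linear
# functional h such that coef_surface = delta[rows, pairs] %*% h. Surface
# "alpha" is the intercept; covariate surfaces use that slope's row of H.
.surface_hat <- function(groups, surface) {
  lapply(groups, function(g) {
    if (g$skipped) return(NULL)
    j <- if (surface == "alpha") 1L else match(surface, colnames(g$X))
    if (is.na(j)) return(NULL)
    g$H[j, ]
  })
}

# Coefficient vector for one surface given per-pair signs (+1 observed,
# -1 swapped case/control). Probes in skipped groups get NA (observed) /
# 0 (permutations: absent from smoothing anyway since NA -> 0).
.surface_coef <- function(delta, groups, hats, signs) {
  coef <- rep(NA_real_, nrow(delta))
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    h <- hats[[k]]
    if (is.null(h)) next
    coef[g$rows] <- delta[g$rows, g$pairs, drop = FALSE] %*%
      (signs[g$pairs] * h)
  }
  coef
}

#' Permutation inference for bumps on one coefficient surface
#'
#' Runs the full chain on the observed data (fit, smooth, 99th-percentile
#' thresholds, bump detection), then for each permutation swaps
#' case/control labels independently per pair with probability 1/2
#' (equivalently flips the sign of that pair's delta column; covariates
#' stay attached to their pair), re-runs fit -> smooth -> detect with the
#' observed thresholds held fixed, and records every null bump area and
#' the per-permutation maximum area. Summaries per observed bump, all with
#' strict ">" tail counts:
#'
#' * `fwer_p`: proportion of permutation maximum areas larger than the
#'   observed area (a permutation with no bumps contributes maximum 0);
#' * `suggestive`: observed area larger than the smallest of the
#'   per-permutation maximum areas;
#' * `emp_p`: proportion of all null bump areas larger than the observed
#'   area;
#' * `fdr`: ratio of the mean per-permutation count of null areas >= the
#'   observed area to the count of observed areas >= it, monotonised by a
#'   running minimum from the smallest area upward and capped at 1.
#'
#' A `fwer_p` or `emp_p` of exactly 0 is a resolution boundary: the column
#' `at_boundary` flags it and the value is to be read as "< 1/n_perm"
#' (resp. "< 1/number of null bumps").
#'
#' @param delta Probes x pairs matrix of within-pair differences, rows
#'   aligned to `manifest`.
#' @param design `pair_design` aligned to the columns of `delta`.
#' @param manifest Sorted probe manifest (same probes, same order).
#' @param surface `"alpha"` or one of the covariate names.
#' @param covariates Covariates entering every fit.
#' @param n_perm Number of permutations (default 1000).
#' @param seed RNG seed for the permutation signs.
#' @param maxgap,bandwidth,quantile_level,min_probes_loess,signed_thresholds
#'   Bump-hunting knobs, see [cluster_probes()], [build_smoother()] and
#'   [compute_thresholds()].
#' @param min_pairs Minimum complete pairs per probe.
#' @param center Covariates centered before fitting; see
#'   [fit_cpg_models()].
#' @param perm_signs Optional matrix of per-pair signs (+1/-1), one row per
#'   permutation, overriding random sampling (e.g. the exhaustive set of
#'   sign assignments for small designs).
#' @param fold_change Optional per-probe fold changes; bumps then report
#'   the mean over member probes.
#' @return `data.frame` of observed bumps with columns of
#'   [detect_bumps()] plus fwer_p, suggestive, emp_p, fdr, at_boundary;
#'   attributes `max_areas` (per-permutation maxima), `null_areas`,
#'   `thresholds` and `n_perm`.
#' @export
permutation_inference <- function(delta, design, manifest,
                                  surface = "alpha",
                                  covariates = c("smoking", "accp",
                                                 "dmard", "age", "sex"),
                                  n_perm = 1000, seed = 1,
                                  maxgap = 500, bandwidth = 1000,
                                  quantile_level = 0.99,
                                  min_probes_loess = 7,
                                  signed_thresholds = FALSE,
                                  min_pairs = 10, center = c("age", "sex"),
                                  perm_signs = NULL,
                                  fold_change = NULL) {
  stopifnot(nrow(delta) == nrow(manifest))
  if (is.null(perm_signs) && n_perm < 1)
    stop("n_perm must be >= 1", call. = FALSE)
  covariates <- intersect(covariates, names(design))
  Z <- .covariate_matrix(design, covariates)
  groups <- .ols_precompute(delta, Z, min_pairs, center = center)
  hats <- .surface_hat(groups, surface)
  if (all(vapply(hats, is.null, logical(1))))
    stop(sprintf("surface '%s' unavailable (constant or always dropped)",
                 surface), call. = FALSE)
  clusters <- cluster_probes(manifest, maxgap)
  S <- build_smoother(manifest, clusters, bandwidth, min_probes_loess)
  d0 <- delta
  d0[is.na(d0)] <- 0   # NA-safe matrix products; NA probes sit in skipped groups
  ones <- rep(1, ncol(delta))
  coef_obs <- .surface_coef(d0, groups, hats, ones)
  coef_obs[rowSums(!is.na(delta)) == 0L] <- NA
  smoothed <- smooth_within_clusters(coef_obs, manifest, clusters, S)
  thr <- compute_thresholds(smoothed, quantile_level, signed_thresholds)
  bumps <- detect_bumps(smoothed, manifest, clusters, thr)

  if (is.null(perm_signs)) {
    set.seed(seed)
    perm_signs <- matrix(sample(c(-1, 1), n_perm * ncol(delta),
                                replace = TRUE), nrow = n_perm)
  }
  n_perm <- nrow(perm_signs)
  max_areas <- numeric(n_perm)
  null_areas <- vector("list", n_perm)
  for (p in seq_len(n_perm)) {
    cf <- .surface_coef(d0, groups, hats, perm_signs[p, ])
    cf[is.na(cf)] <- 0
    sm <- as.numeric(S %*% cf)
    sc <- .scan_bumps(sm, clusters, thr$upper, thr$lower)
    null_areas[[p]] <- sc$area
    max_areas[p] <- if (length(sc$area)) max(sc$area) else 0
  }
  null_all <- sort(unlist(null_areas))
  n_null <- length(null_all)

  if (nrow(bumps)) {
    a <- bumps$area
    bumps$fwer_p <- vapply(a, function(x) mean(max_areas > x), numeric(1))
    bumps$suggestive <- a > min(max_areas)
    bumps$emp_p <- if (n_null)
      vapply(a, function(x) sum(null_all > x) / n_null, numeric(1))
      else rep(0, length(a))
    # expected null count with area >= a_i over observed count >= a_i
    e_cnt <- vapply(a, function(x) sum(null_all >= x), numeric(1)) / n_perm
    o_cnt <- vapply(a, function(x) sum(a >= x), numeric(1))
    raw <- pmin(1, e_cnt / o_cnt)
    ord <- order(-a)
    raw_sorted <- raw[ord]
    fdr_sorted <- rev(cummin(rev(raw_sorted)))
    bumps$fdr <- raw
    bumps$fdr[ord] <- fdr_sorted
    bumps$at_boundary <- bumps$fwer_p == 0 | (n_null > 0 & bumps$emp_p == 0)
    if (!is.null(fold_change))
      bumps$fold_change <- vapply(seq_len(nrow(bumps)), function(i)
        mean(fold_change[bumps$index_start[i]:bumps$index_end[i]],
             na.rm = TRUE), numeric(1))
  } else {
    bumps$fwer_p <- numeric(0); bumps$suggestive <- logical(0)
    bumps$emp_p <- numeric(0); bumps$fdr <- numeric(0)
    bumps$at_boundary <- logical(0)
    if (!is.null(fold_change)) bumps$fold_change <- numeric(0)
  }
  attr(bumps, "max_areas") <- max_areas
  attr(bumps, "null_areas") <- null_all
  attr(bumps, "thresholds") <- thr
  attr(bumps, "n_perm") <- n_perm
  bumps
}

#' Bump hunting on every coefficient surface
#'
#' Applies the full DMR procedure — cluster, fit, smooth, threshold,
#' detect, permutation inference — to the disease intercept surface and to
#' each requested covariate slope surface. A covariate constant across the
#' usable pairs is skipped with a warning.
#'
#' @param betas Beta matrix, rows aligned to `manifest`.
#' @param design `pair_design`.
#' @param manifest Sorted probe manifest covering the rows of `betas`.
#' @param surfaces Surfaces to scan (default the disease intercept plus
#'   the three exposure slopes).
#' @param ... Passed on to [permutation_inference()].
#' @return Named list of DMR tables, one per surface run.
#' @export
find_dmrs <- function(betas, design, manifest,
                      surfaces = c("alpha", "smoking", "accp", "dmard"),
                      ...) {
  stopifnot(identical(rownames(betas), manifest$probe_id))
  diffs <- compute_pair_differences(betas, design)
  fc <- rowMeans(diffs$case, na.rm = TRUE) /
    pmax(rowMeans(diffs$control, na.rm = TRUE), 1e-6)
  out <- list()
  for (s in surfaces) {
    if (s != "alpha") {
      vals <- design[[s]]
      if (is.null(vals) || length(unique(vals[!is.na(vals)])) < 2L) {
        warning(sprintf("surface '%s' skipped: covariate constant or absent",
                        s), call. = FALSE)
        next
      }
    }
    out[[s]] <- permutation_inference(diffs$delta, design, manifest,
                                      surface = s, fold_change = fc, ...)
  }
  out
}
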