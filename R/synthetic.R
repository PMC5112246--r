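# Synthetic paired-methylation data with known ground truth. The generator
# emulates the statistical structure the analysis assumes: probes grouped
# in clusters along chromosomes, a bimodal beta-value baseline (most CpGs
# near fully unmethylated or fully methylated), strong within-pair
# correlation (a shared pair-level latent value per probe with independent
# twin-level noise on top), optional cell-type mixture structure, spiked
# disease- and exposure-linked regions, and detection-p failures.
# Everything is deterministic given the seed.

#' Generate a probe manifest with known cluster structure
#'
#' Probes are laid down cluster by cluster: gaps inside a cluster are drawn
#' from `gap_within`, gaps between clusters from `gap_between`, so the
#' cluster structure is exactly recoverable with any maxgap between the
#' two ranges.
#'
#' @param n_chrom Number of chromosomes.
#' @param n_clusters Clusters per chromosome.
#' @param probes_per_cluster Integer range (min, max) of cluster sizes.
#' @param gap_within Range (bp) of intra-cluster gaps.
#' @param gap_between Range (bp) of inter-cluster gaps; must exceed the
#'   clustering maxgap in use.
#' @param seed RNG seed.
#' @return Manifest `data.frame` with an extra `cluster` column recording
#'   the true cluster id.
#' @export
generate_manifest <- function(n_chrom = 1, n_clusters = 500,
                              probes_per_cluster = c(5, 15),
                              gap_within = c(20, 400),
                              gap_between = c(2000, 10000),
                              seed = 1) {
  set.seed(seed)
  rint <- function(r, n = 1L)    # uniform integer draw, safe for lo == hi
    if (r[1] == r[2]) rep(r[1], n) else sample(r[1]:r[2], n, replace = TRUE)
  rows <- list()
  cl_id <- 0L
  for (ch in seq_len(n_chrom)) {
    pos <- 0L
    for (cl in seq_len(n_clusters)) {
      cl_id <- cl_id + 1L
      m <- rint(probes_per_cluster)
      pos <- pos + rint(gap_between)
      p <- pos
      for (k in seq_len(m - 1L))
        p <- c(p, p[length(p)] + rint(gap_within))
      pos <- p[length(p)]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = sprintf("chr%d", ch), pos = p, cluster = cl_id,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$probe_id <- sprintf("cg%07d", seq_len(nrow(tab)))
  tab$gene <- NA_character_
  manifest(tab[, c("probe_id", "chrom", "pos", "gene", "cluster")])
}

#' Generate a cohort of discordant twin pairs
#'
#' Pair-level exposures are Bernoulli draws at the given prevalences
#' (defaults follow a rheumatoid-arthritis discordant-twin cohort: ever
#' smoking 69%, anti-CCP positivity 61%, current DMARD treatment 68%,
#' smoking status missing for 14% of pairs, 78% female); age is normal.
#'
#' @param n_pairs Number of pairs (default 28).
#' @param p_smoking,p_accp,p_dmard Exposure prevalences.
#' @param p_smoking_missing Fraction of pairs with unknown smoking status.
#' @param p_female Probability sex = 1.
#' @param age_mean,age_sd Age distribution (years).
#' @param seed RNG seed.
#' @return Validated `pair_design`.
#' @export
generate_pairs <- function(n_pairs = 28, p_smoking = 0.69, p_accp = 0.61,
                           p_dmard = 0.68, p_smoking_missing = 0.14,
                           p_female = 0.78, age_mean = 56, age_sd = 10,
                           seed = 1) {
  set.seed(seed)
  smoking <- stats::rbinom(n_pairs, 1, p_smoking)
  smoking[stats::runif(n_pairs) < p_smoking_missing] <- NA
  pair_design(data.frame(
    pair_id = sprintf("pair%02d", seq_len(n_pairs)),
    case_sample = sprintf("pair%02d_case", seq_len(n_pairs)),
    control_sample = sprintf("pair%02d_ctrl", seq_len(n_pairs)),
    smoking = smoking,
    accp = stats::rbinom(n_pairs, 1, p_accp),
    dmard = stats::rbinom(n_pairs, 1, p_dmard),
    age = round(stats::rnorm(n_pairs, age_mean, age_sd), 1),
    sex = stats::rbinom(n_pairs, 1, p_female),
    stringsAsFactors = FALSE))
}

#' Choose spike-in regions inside generated clusters
#'
#' Picks clusters with at least `n_probes` members (without reuse) and
#' marks their first `n_probes` probes as a spiked region for the given
#' surface.
#'
#' @param manifest Manifest from [generate_manifest()] (needs the
#'   `cluster` column).
#' @param surface `"alpha"`, `"smoking"`, `"accp"` or `"dmard"`.
#' @param effect Per-probe effect size on the delta (case - control) scale;
#'   negative for hypomethylation in the affected twin.
#' @param n_spikes Number of regions.
#' @param n_probes Probes per region.
#' @param exclude_clusters Cluster ids not to use (e.g. already spiked).
#' @param seed RNG seed.
#' @return `data.frame`: surface, effect, chrom, start, end, n_probes,
#'   cluster.
#' @export
spike_regions <- function(manifest, surface = "alpha", effect = 0.15,
                          n_spikes = 1, n_probes = 10,
                          exclude_clusters = integer(0), seed = 1) {
  set.seed(seed)
  sizes <- table(manifest$cluster)
  ok <- setdiff(as.integer(names(sizes)[sizes >= n_probes]),
                exclude_clusters)
  if (length(ok) < n_spikes)
    stop("not enough clusters large enough for the requested spikes",
         call. = FALSE)
  chosen <- ok[sample.int(length(ok), n_spikes)]
  do.call(rbind, lapply(chosen, function(cl) {
    idx <- which(manifest$cluster == cl)[seq_len(n_probes)]
    data.frame(surface = surface, effect = effect,
               chrom = manifest$chrom[idx[1]],
               start = manifest$pos[idx[1]],
               end = manifest$pos[idx[length(idx)]],
               n_probes = n_probes, cluster = cl,
               stringsAsFactors = FALSE)
  }))
}

#' Generate a paired beta-value dataset with ground truth
#'
#' Per probe, a bimodal baseline mean (Beta-distributed modes near 0.1 and
#' 0.9 with a minor intermediate component) plus, per pair, a shared
#' latent deviation (sd `pair_sd`) and independent twin-level noise (sd
#' `noise_sd`). Spiked effects are added to the affected twin only: on the
#' alpha surface in every pair, on a covariate surface only in pairs
#' exposed to that covariate — which is what makes exposure-linked regions
#' detectable on the matching slope surface but not on the disease
#' surface. Optional cell-type mixture structure replaces the baseline at
#' the reference probes by the reference-weighted mixture for per-sample
#' weights. Values are clipped to `[0, 1]`.
#'
#' @param manifest Manifest (rows define probes; `cluster` column required
#'   when `spikes` given).
#' @param design `pair_design`.
#' @param spikes Optional spike table from [spike_regions()] (rows may mix
#'   surfaces).
#' @param pair_sd Sd of the shared within-pair latent deviation.
#' @param noise_sd Sd of twin-level measurement noise.
#' @param baseline_weights Mixture weights of the (low, high, mid)
#'   baseline components.
#' @param celltype_spec Optional list with `reference` (probe x cell-type
#'   matrix, rownames in the manifest) and `weights` (sample x cell-type
#'   matrix, rownames = sample ids; `NULL` for symmetric Dirichlet draws).
#' @param detp_frac Fraction of measurements flagged as failed in the
#'   generated detection-p matrix (0 disables the matrix).
#' @param seed RNG seed.
#' @return List: `betas` (probes x samples), `detp` (or `NULL`), `truth`
#'   (spike table, parameters, cell-type weights).
#' @export
generate_dataset <- function(manifest, design, spikes = NULL,
                             pair_sd = 0.05, noise_sd = 0.05,
                             baseline_weights = c(0.45, 0.45, 0.10),
                             celltype_spec = NULL, detp_frac = 0,
                             seed = 1) {
  set.seed(seed)
  P <- nrow(manifest)
  n <- nrow(design)
  comp <- sample.int(3L, P, replace = TRUE, prob = baseline_weights)
  mu <- numeric(P)
  mu[comp == 1L] <- stats::rbeta(sum(comp == 1L), 2, 18)   # ~0.10
  mu[comp == 2L] <- stats::rbeta(sum(comp == 2L), 18, 2)   # ~0.90
  mu[comp == 3L] <- stats::rbeta(sum(comp == 3L), 5, 5)
  if (!is.null(spikes)) {
    # spiked regions sit at intermediate-methylation CpGs, where
    # methylation is actually variable, so the configured delta-scale
    # effect is realized instead of truncated at the [0,1] boundary
    for (i in seq_len(nrow(spikes))) {
      idx <- which(manifest$chrom == spikes$chrom[i] &
                     manifest$pos >= spikes$start[i] &
                     manifest$pos <= spikes$end[i])
      mu[idx] <- stats::rbeta(length(idx), 8, 8)
    }
  }
  latent <- mu + matrix(stats::rnorm(P * n, 0, pair_sd), P, n)
  case <- latent + matrix(stats::rnorm(P * n, 0, noise_sd), P, n)
  control <- latent + matrix(stats::rnorm(P * n, 0, noise_sd), P, n)

  weights <- NULL
  if (!is.null(celltype_spec)) {
    ref <- celltype_spec$reference
    ridx <- match(rownames(ref), manifest$probe_id)
    if (any(is.na(ridx)))
      stop("cell-type reference probes absent from manifest", call. = FALSE)
    weights <- celltype_spec$weights
    if (is.null(weights)) {
      g <- matrix(stats::rgamma(2 * n * ncol(ref), shape = 5), 2 * n)
      weights <- g / rowSums(g)
      rownames(weights) <- c(design$case_sample, design$control_sample)
      colnames(weights) <- colnames(ref)
    }
    wc <- weights[design$case_sample, , drop = FALSE]
    wk <- weights[design$control_sample, , drop = FALSE]
    case[ridx, ] <- ref %*% t(wc) +
      matrix(stats::rnorm(length(ridx) * n, 0, noise_sd), length(ridx), n)
    control[ridx, ] <- ref %*% t(wk) +
      matrix(stats::rnorm(length(ridx) * n, 0, noise_sd), length(ridx), n)
  }

  if (!is.null(spikes)) {
    for (i in seq_len(nrow(spikes))) {
      sp <- spikes[i, ]
      idx <- which(manifest$chrom == sp$chrom & manifest$pos >= sp$start &
                     manifest$pos <= sp$end)
      if ("cluster" %in% names(manifest) &&
          length(unique(manifest$cluster[idx])) != 1L)
        stop("spike region spans more than one cluster", call. = FALSE)
      exposed <- if (sp$surface == "alpha") rep(TRUE, n)
                 else !is.na(design[[sp$surface]]) & design[[sp$surface]] == 1
      case[idx, exposed] <- case[idx, exposed] + sp$effect
    }
  }

  betas <- cbind(pmin(pmax(case, 0), 1), pmin(pmax(control, 0), 1))
  colnames(betas) <- c(design$case_sample, design$control_sample)
  rownames(betas) <- manifest$probe_id

  detp <- NULL
  if (detp_frac > 0) {
    fail <- matrix(stats::runif(length(betas)) < detp_frac,
                   nrow(betas), ncol(betas))
    detp <- matrix(stats::runif(length(betas), 0, 0.005),
                   nrow(betas), ncol(betas), dimnames = dimnames(betas))
    detp[fail] <- stats::runif(sum(fail), 0.011, 0.5)
  }

  list(betas = beta_matrix(betas), detp = detp,
       truth = list(spikes = spikes, seed = seed, pair_sd = pair_sd,
                    noise_sd = noise_sd, celltype_weights = weights))
}

#' Build a synthetic cell-type reference panel
#'
#' A small panel of distinguishing probes for testing the deconvolution
#' step: each cell type gets its own block of probes that are highly
#' methylated in that type and lowly methylated in the others.
#'
#' @param probe_ids Probe ids to use (length divisible decisions are not
#'   required; probes are assigned round-robin).
#' @param cell_types Cell-type labels (default 6 synthetic blood types).
#' @param high,low Methylation levels of distinguishing vs background
#'   probes.
#' @param seed RNG seed for small jitter that breaks exact symmetry.
#' @return Probe x cell-type reference matrix.
#' @export
synthetic_reference <- function(probe_ids,
                                cell_types = c("CD4T", "CD8T", "NK",
                                               "Bcell", "Mono", "Gran"),
                                high = 0.85, low = 0.1, seed = 1) {
  set.seed(seed)
  K <- length(cell_types)
  P <- length(probe_ids)
  prof <- matrix(low, P, K, dimnames = list(probe_ids, cell_types))
  block <- rep_len(seq_len(K), P)
  for (k in seq_len(K)) prof[block == k, k] <- high
  jitter <- matrix(stats::runif(P * K, -0.02, 0.02), P, K)
  pmin(pmax(prof + jitter, 0), 1)
}
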