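# Region-to-gene annotation for enrichment export, and the probes-per-gene
# bias diagnostic for pathway results: pathways made of large, probe-dense
# genes can look significant merely because they carry more measurements,
# so the diagnostic checks whether pathway significance tracks mean probes
# per gene.

#' Annotate regions with overlapping or nearest genes
#'
#' Per region, reports every gene whose span overlaps the region (distance
#' 0); if none overlaps, the nearest gene with its distance; and
#' `"no nearby gene"` when the nearest gene is farther than `max_distance`
#' (or the chromosome is absent from the gene set).
#'
#' @param regions `data.frame` with chrom, start, end (1-based inclusive).
#' @param genes `data.frame` with chrom, start, end, name (e.g. from
#'   [read_bed()]).
#' @param max_distance Distance cutoff in bp (default 100 kb).
#' @return `data.frame`: one row per input region (in input order) with
#'   `genes` (comma-separated) and `distance` (`NA` when no nearby gene).
#' @export
nearest_gene <- function(regions, genes, max_distance = 1e5) {
  n <- nrow(regions)
  out <- data.frame(regions, genes = rep("no nearby gene", n),
                    distance = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  if (n == 0L || nrow(genes) == 0L) return(out)
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  ov <- GenomicRanges::findOverlaps(rg, gg)
  if (length(ov)) {
    hit <- split(genes$name[S4Vectors::subjectHits(ov)],
                 S4Vectors::queryHits(ov))
    idx <- as.integer(names(hit))
    out$genes[idx] <- vapply(hit, function(g)
      paste(unique(g), collapse = ","), character(1))
    out$distance[idx] <- 0
  }
  todo <- which(is.na(out$distance))
  if (length(todo)) {
    nr <- GenomicRanges::distanceToNearest(rg[todo], gg)
    qh <- S4Vectors::queryHits(nr)
    d <- S4Vectors::mcols(nr)$distance
    ok <- d <= max_distance
    tgt <- todo[qh[ok]]
    out$genes[tgt] <- genes$name[S4Vectors::subjectHits(nr)[ok]]
    out$distance[tgt] <- d[ok]
  }
  out
}

#' Probes-per-gene bias diagnostic for pathway results
#'
#' Spearman correlation between pathway significance (on the
#' -log10 scale; rank-based, so any monotone transform of the significance
#' column gives the same answer) and the mean number of manifest probes
#' per member gene, with a permutation p-value from shuffling the
#' significance column across pathways. A strong positive correlation
#' indicates probe-count-driven enrichment.
#'
#' @param pathways `data.frame` with columns `pathway_id`, `significance`
#'   (p-value or FDR) and `genes` (comma-separated gene symbols).
#' @param manifest Probe manifest with a `gene` column.
#' @param n_perm Label shuffles for the permutation p (default 10000).
#' @param seed RNG seed.
#' @return List: `rho` (0 by convention when either column has zero
#'   variance), `p_perm`, and `table` (per-pathway mean probes per gene;
#'   pathways with no resolvable gene dropped).
#' @export
probes_per_gene_bias <- function(pathways, manifest, n_perm = 10000,
                                 seed = 1) {
  counts <- table(manifest$gene[!is.na(manifest$gene) &
                                  nzchar(manifest$gene)])
  ppg <- vapply(strsplit(pathways$genes, ","), function(gs) {
    gs <- trimws(gs)
    hit <- counts[gs[gs %in% names(counts)]]
    if (!length(hit)) return(NA_real_)
    mean(as.numeric(hit))
  }, numeric(1))
  keep <- !is.na(ppg)
  if (any(!keep))
    message(sprintf("probes_per_gene_bias: %d pathway(s) with no ",
                    sum(!keep)), "resolvable gene dropped")
  tab <- data.frame(pathway_id = pathways$pathway_id[keep],
                    significance = pathways$significance[keep],
                    mean_probes_per_gene = ppg[keep],
                    stringsAsFactors = FALSE)
  x <- -log10(pmax(tab$significance, .Machine$double.xmin))
  y <- tab$mean_probes_per_gene
  if (nrow(tab) < 3L || stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12)
    return(list(rho = 0, p_perm = 1, table = tab))
  rho <- stats::cor(x, y, method = "spearman")
  set.seed(seed)
  null_rho <- replicate(n_perm,
                        stats::cor(sample(x), y, method = "spearman"))
  p_perm <- (sum(abs(null_rho) >= abs(rho)) + 1) / (n_perm + 1)
  list(rho = rho, p_perm = p_perm, table = tab)
}

#' Post-filter an external enrichment table
#'
#' Keeps pathways with fold enrichment of at least `min_fold` by either
#' test and FDR below `max_fdr` by both tests, the convention for
#' reporting region-based enrichment output.
#'
#' @param tab `data.frame` with columns `binom_fold`, `hyper_fold`,
#'   `binom_fdr`, `hyper_fdr`.
#' @param min_fold Fold-enrichment cutoff (default 2).
#' @param max_fdr FDR cutoff (default 0.05).
#' @return Filtered `data.frame`.
#' @export
filter_enrichment <- function(tab, min_fold = 2, max_fdr = 0.05) {
  keep <- (tab$binom_fold >= min_fold | tab$hyper_fold >= min_fold) &
    tab$binom_fdr < max_fdr & tab$hyper_fdr < max_fdr
  tab[keep, , drop = FALSE]
}
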