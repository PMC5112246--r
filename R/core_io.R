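# Domain containers and tabular/BED readers and writers shared by all stages.
#
# Conventions: genomic coordinates are 1-based inclusive everywhere inside the
# package; the only 0-based half-open representation is on-disk BED. Sample and
# probe order follow file order; all joins are by identifier, never position.

#' Validate a beta-value matrix
#'
#' A beta matrix is a plain numeric matrix of methylation fractions with CpG
#' probes in rows (unique rownames) and samples in columns (unique colnames).
#' Missing measurements are `NA`. Every finite entry must lie in `[0, 1]`.
#'
#' @param values Numeric matrix with rownames (probe ids) and colnames
#'   (sample ids).
#' @return The validated matrix, invisibly usable as-is.
#' @export
beta_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("beta matrix must be a numeric matrix", call. = FALSE)
  if (nrow(values) == 0L)
    stop("no probes", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("beta matrix requires probe rownames and sample colnames",
         call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids in beta matrix", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in beta matrix", call. = FALSE)
  bad <- which(!is.na(values) & (values < 0 | values > 1))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(values))
    stop(sprintf(
      "beta value out of [0,1] at probe '%s', sample '%s' (%.4g)",
      rownames(values)[i[1L]], colnames(values)[i[2L]], values[bad[1L]]),
      call. = FALSE)
  }
  values
}

#' Read a beta-value matrix from tab-delimited text
#'
#' First column holds probe ids, header row holds sample ids. Cells are
#' numeric or the missing-value token.
#'
#' @param path Path to a tab-delimited text file.
#' @param na_token Token encoding a missing value (default `"NA"`).
#' @return Validated numeric matrix (probes x samples).
#' @export
read_beta_matrix <- function(path, na_token = "NA") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           row.names = NULL, na.strings = na_token,
                           check.names = FALSE, colClasses = NA,
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L)
    stop("no probes", call. = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate probe ids in beta matrix file", call. = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(values))
    stop("non-numeric cell in beta matrix file", call. = FALSE)
  rownames(values) <- ids
  beta_matrix(values)
}

#' Write a beta-value matrix as tab-delimited text
#'
#' Inverse of [read_beta_matrix()]: finite values round-trip bit-exactly
#' (17 significant digits) and the missingness mask is preserved.
#'
#' @param values Beta matrix (probes x samples).
#' @param path Output path.
#' @param na_token Token used for missing values.
#' @export
write_beta_matrix <- function(values, path, na_token = "NA") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(values)), collapse = "\t"), con)
  body <- apply(values, 1L, function(r) {
    cells <- ifelse(is.na(r), na_token, sprintf("%.17g", r))
    paste(cells, collapse = "\t")
  })
  writeLines(paste(rownames(values), body, sep = "\t"), con)
  invisible(path)
}

#' Read a probe manifest
#'
#' Tab-delimited with columns `probe_id`, `chrom`, `pos` (1-based) and
#' optionally `gene`. Rows are sorted by chromosome then position on load.
#'
#' @param path Path to the manifest file.
#' @return `data.frame` with columns probe_id, chrom, pos, gene.
#' @export
read_manifest <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("probe_id", "chrom", "pos")
  if (!all(need %in% names(tab)))
    stop("manifest requires columns probe_id, chrom, pos", call. = FALSE)
  if (!"gene" %in% names(tab)) tab$gene <- NA_character_
  manifest(tab[, c("probe_id", "chrom", "pos", "gene")])
}

#' Validate and sort a probe manifest
#'
#' @param tab `data.frame` with probe_id, chrom, pos and optional gene.
#' @return The manifest sorted by (chrom, pos), probe ids unique.
#' @export
manifest <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  if (!"gene" %in% names(tab)) tab$gene <- NA_character_
  if (anyDuplicated(tab$probe_id))
    stop("duplicate probe ids in manifest", call. = FALSE)
  if (any(is.na(tab$pos)) || any(tab$pos < 1))
    stop("manifest positions must be 1-based positive integers",
         call. = FALSE)
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Construct and validate a pair design sheet
#'
#' One row per monozygotic pair: identifiers of the affected (case) and
#' unaffected (control) co-twin, pair-level exposure covariates of the
#' affected twin (smoking ever/never, anti-CCP antibody status, current
#' DMARD treatment; each 0/1, smoking possibly missing), plus age and sex.
#'
#' @param tab `data.frame` with columns pair_id, case_sample,
#'   control_sample, smoking, accp, dmard, age, sex.
#' @return Validated design `data.frame` of class `pair_design`.
#' @export
pair_design <- function(tab) {
  tab <- as.data.frame(tab, stringsAsFactors = FALSE)
  need <- c("pair_id", "case_sample", "control_sample",
            "smoking", "accp", "dmard", "age", "sex")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("pair design missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$pair_id))
    stop("duplicate pair ids", call. = FALSE)
  if (any(tab$case_sample == tab$control_sample))
    stop("case and control sample identical within a pair", call. = FALSE)
  all_samples <- c(tab$case_sample, tab$control_sample)
  if (anyDuplicated(all_samples))
    stop("a sample appears in more than one pair slot", call. = FALSE)
  for (v in c("smoking", "accp", "dmard", "sex")) {
    x <- tab[[v]]
    if (!all(is.na(x) | x %in% c(0, 1)))
      stop(sprintf("non-binary code in column '%s'", v), call. = FALSE)
  }
  class(tab) <- c("pair_design", "data.frame")
  tab
}

#' Read a pair design sheet from tab-delimited text
#'
#' @inheritParams read_beta_matrix
#' @return Validated `pair_design` data.frame; missing smoking stays `NA`,
#'   never imputed.
#' @export
read_pair_design <- function(path, na_token = "NA") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           na.strings = na_token, stringsAsFactors = FALSE,
                           check.names = FALSE)
  pair_design(tab)
}

#' Check that a design's samples resolve in a beta matrix
#'
#' @param design `pair_design`.
#' @param betas Beta matrix.
#' @return The design, invisibly; error if any sample id is absent.
#' @export
check_design_samples <- function(design, betas) {
  missing <- setdiff(c(design$case_sample, design$control_sample),
                     colnames(betas))
  if (length(missing))
    stop("design samples absent from beta matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  invisible(design)
}

#' Write genomic regions as BED
#'
#' Internal coordinates are 1-based inclusive; BED lines are written 0-based
#' half-open (`start - 1`, `end`). Column 4 is a region name, column 5 the
#' score. A header comment records the column layout; an empty region set
#' yields a header-only file.
#'
#' @param regions `data.frame` with columns chrom, start, end; optional name.
#' @param path Output path.
#' @param score Numeric score per region (default 0).
#' @export
write_bed <- function(regions, path, score = NULL) {
  if (is.null(score)) score <- rep(0, nrow(regions))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chrom\tstart\tend\tname\tscore (0-based half-open)", con)
  if (nrow(regions) == 0L) return(invisible(path))
  if (any(regions$end < regions$start))
    stop("region with end < start", call. = FALSE)
  name <- if ("name" %in% names(regions)) regions$name else
    sprintf("region_%d", seq_len(nrow(regions)))
  writeLines(sprintf("%s\t%d\t%d\t%s\t%.6g",
                     regions$chrom,
                     as.integer(regions$start) - 1L,
                     as.integer(regions$end),
                     name, score), con)
  invisible(path)
}

#' Read a BED file into 1-based inclusive regions
#'
#' Accepts 3+ column BED (comment lines starting with `#` or `track`
#' skipped); converts to the package's internal 1-based inclusive
#' convention.
#'
#' @param path Path to a BED file.
#' @return `data.frame` with chrom, start, end and, when present, name and
#'   score.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  tab <- utils::read.table(text = lines, sep = "\t",
                           stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(tab[[1L]]),
                    start = as.integer(tab[[2L]]) + 1L,
                    end = as.integer(tab[[3L]]),
                    stringsAsFactors = FALSE)
  if (ncol(tab) >= 4L) out$name <- as.character(tab[[4L]])
  if (ncol(tab) >= 5L) out$score <- as.numeric(tab[[5L]])
  out
}
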