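# End-to-end orchestration: (simulate or load) -> QC -> cell-type
# adjustment -> per-CpG model/DMP table -> DMR tables per surface -> BED
# export, with a run log, a config snapshot and its hash stamped into
# every output table. Outputs are pure functions of (inputs, config,
# seed).

.default_config <- function() {
  list(
    seed = NULL,
    out_dir = NULL,
    simulate = NULL,     # list of generate_* parameters, or NULL to load
    beta_path = NULL, manifest_path = NULL, design_path = NULL,
    detp_path = NULL, celltype_reference_path = NULL, genes_bed = NULL,
    na_token = "NA",
    qc = list(detection_threshold = 0.01, max_missing_frac = 0.05),
    skip_celltype = FALSE,
    model = list(covariates = c("smoking", "accp", "dmard", "age", "sex"),
                 min_pairs = 10, fdr_threshold = 0.05,
                 suggestive_p = 5e-5),
    dmr = list(n_perm = 1000, maxgap = 500, bandwidth = 1000,
               quantile_level = 0.99, min_probes_loess = 7,
               surfaces = c("alpha", "smoking", "accp", "dmard"))
  )
}

.merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) &&
        !is.null(names(user[[k]])))
      base[[k]] <- .merge_config(base[[k]], user[[k]])
    else base[[k]] <- user[[k]]
  }
  base
}

#' Assemble and validate a pipeline configuration
#'
#' Merges user settings (a list, or a path to a YAML file) over the
#' defaults and validates them before any compute: the seed is mandatory,
#' `n_perm` must be positive, and in load mode every referenced input file
#' must exist.
#'
#' @param config Named list or path to a YAML config file.
#' @return Validated config list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .merge_config(.default_config(), config)
  if (is.null(cfg$seed))
    stop("config error: a seed is mandatory", call. = FALSE)
  if (cfg$dmr$n_perm < 1)
    stop("config error: n_perm must be >= 1", call. = FALSE)
  if (is.null(cfg$simulate)) {
    for (p in c("beta_path", "manifest_path", "design_path")) {
      if (is.null(cfg[[p]]))
        stop(sprintf("config error: '%s' is required when not simulating",
                     p), call. = FALSE)
      if (!file.exists(cfg[[p]]))
        stop(sprintf("config error: %s '%s' does not exist", p, cfg[[p]]),
             call. = FALSE)
    }
  }
  cfg
}

.write_table <- function(tab, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes QC, optional cell-type adjustment, the per-CpG co-twin model
#' and bump hunting with permutation inference on every requested surface,
#' writing a DMP table, one DMR table and BED file per surface, a run log,
#' and a YAML snapshot of the effective configuration whose MD5 hash is
#' stamped into every table. Deterministic given the config seed.
#'
#' @param config List or YAML path accepted by [pipeline_config()].
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a list with the DMP table, the list of DMR tables,
#'   the paths written and the run log lines.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- pipeline_config(config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir))
    stop("config error: out_dir is required", call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  snapshot <- file.path(cfg$out_dir, "config.yaml")
  yaml::write_yaml(cfg, snapshot)
  # hash covers the analysis parameters, not where they are written
  hcfg <- cfg[setdiff(names(cfg), "out_dir")]
  hfile <- tempfile(fileext = ".yaml")
  yaml::write_yaml(hcfg, hfile)
  hash <- unname(tools::md5sum(hfile))
  unlink(hfile)
  say("config_hash %s", hash)
  say("seed %d", as.integer(cfg$seed))

  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    mani <- do.call(generate_manifest, c(sim$manifest,
                                         list(seed = cfg$seed)))
    design <- do.call(generate_pairs, c(sim$pairs,
                                        list(seed = cfg$seed + 1L)))
    spikes <- sim$spikes
    ds <- do.call(generate_dataset,
                  c(list(manifest = mani, design = design,
                         spikes = spikes, seed = cfg$seed + 2L),
                    sim$dataset))
    betas <- ds$betas; detp <- ds$detp
    say("simulated %d probes x %d samples", nrow(betas), ncol(betas))
  } else {
    betas <- read_beta_matrix(cfg$beta_path, cfg$na_token)
    mani <- read_manifest(cfg$manifest_path)
    design <- read_pair_design(cfg$design_path, cfg$na_token)
    detp <- if (!is.null(cfg$detp_path))
      as.matrix(utils::read.table(cfg$detp_path, header = TRUE, sep = "\t",
                                  row.names = 1, check.names = FALSE))
      else NULL
    say("loaded %d probes x %d samples", nrow(betas), ncol(betas))
  }
  check_design_samples(design, betas)

  # QC
  if (!is.null(detp)) {
    n_before <- sum(is.na(betas))
    betas <- mask_by_detection(betas, detp, cfg$qc$detection_threshold)
    say("detection masking: %d cell(s) newly missing",
        sum(is.na(betas)) - n_before)
  }
  flt <- filter_high_missing(betas, cfg$qc$max_missing_frac)
  say("missingness filter: %d probes in, %d dropped, %d out",
      nrow(betas), length(flt$dropped), nrow(flt$betas))
  betas <- flt$betas
  mani <- mani[match(rownames(betas), mani$probe_id), , drop = FALSE]
  mani <- manifest(mani)
  betas <- betas[mani$probe_id, , drop = FALSE]

  # cell-type adjustment
  if (!cfg$skip_celltype && !is.null(cfg$celltype_reference_path)) {
    ref <- as.matrix(utils::read.table(cfg$celltype_reference_path,
                                       header = TRUE, sep = "\t",
                                       row.names = 1, check.names = FALSE))
    props <- estimate_proportions(betas, ref)
    betas <- adjust_for_celltype(betas, props)
    say("cell-type adjustment applied (%d cell types)", ncol(ref))
  } else say("cell-type adjustment skipped")

  # per-CpG model and DMP table
  stats <- fit_pair_model(betas, design,
                          covariates = cfg$model$covariates,
                          min_pairs = cfg$model$min_pairs)
  dmps <- call_dmps(stats, cfg$model$fdr_threshold, cfg$model$suggestive_p)
  dmps <- cbind(dmps,
                chrom = mani$chrom[match(dmps$probe_id, mani$probe_id)],
                pos = mani$pos[match(dmps$probe_id, mani$probe_id)])
  dmp_path <- file.path(cfg$out_dir, "dmp_table.tsv")
  .write_table(dmps, dmp_path, hash)
  say("DMPs: %d tested, %d significant (FDR<%g), %d suggestive (p<%g)",
      sum(!is.na(dmps$alpha_p)), sum(dmps$significant),
      cfg$model$fdr_threshold, sum(dmps$suggestive), cfg$model$suggestive_p)

  # DMRs per surface
  dmr_tabs <- find_dmrs(betas, design, mani,
                        surfaces = cfg$dmr$surfaces,
                        covariates = cfg$model$covariates,
                        min_pairs = cfg$model$min_pairs,
                        n_perm = cfg$dmr$n_perm,
                        seed = cfg$seed + 10L,
                        maxgap = cfg$dmr$maxgap,
                        bandwidth = cfg$dmr$bandwidth,
                        quantile_level = cfg$dmr$quantile_level,
                        min_probes_loess = cfg$dmr$min_probes_loess)
  paths <- c(dmp = dmp_path)
  for (s in names(dmr_tabs)) {
    tab <- dmr_tabs[[s]]
    say("surface %s: %d putative DMRs, %d at FWER p<0.05",
        s, nrow(tab), sum(tab$fwer_p < 0.05))
    tp <- file.path(cfg$out_dir, sprintf("dmr_%s.tsv", s))
    keep <- setdiff(names(tab), c("index_start", "index_end"))
    .write_table(tab[, keep, drop = FALSE], tp, hash)
    bp <- file.path(cfg$out_dir, sprintf("dmr_%s.bed", s))
    write_bed(tab, bp, score = tab$area)
    paths[paste0("dmr_", s)] <- tp
  }

  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(list(dmps = dmps, dmrs = dmr_tabs, paths = paths,
                 log = log_lines, config = cfg, hash = hash))
}
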