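# deterministic TSV writer used by every pipeline artifact so reruns are
# byte-identical
.write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  utils::write.table(format(df, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_run_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stopifnot(is.list(config))
  known <- c("out_dir", "seed", "simulate", "inputs", "pedigree", "params")
  extra <- setdiff(names(config), known)
  if (length(extra)) stop("unknown config key(s): ",
                          paste(extra, collapse = ", "))
  params <- pigdiv_defaults()
  extra_params <- c("ld_max_pairs_per_chrom", "ne_max_pairs_per_window",
                    "ne_r2_correction")
  if (!is.null(config$params)) {
    bad <- setdiff(names(config$params), c(names(params), extra_params))
    if (length(bad)) stop("unknown parameter(s): ",
                          paste(bad, collapse = ", "))
    params[names(config$params)] <- config$params
  }
  if (is.null(params$ld_max_pairs_per_chrom))
    params$ld_max_pairs_per_chrom <- 20000L
  if (is.null(params$ne_max_pairs_per_window))
    params$ne_max_pairs_per_window <- 10000L
  if (is.null(params$ne_r2_correction))
    params$ne_r2_correction <- "none"
  config$params <- params
  if (is.null(config$seed)) config$seed <- 1L
  config
}

# resolve input datasets: either a simulator spec or PLINK file paths
.load_inputs <- function(config) {
  datasets <- list()
  pedigree <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- config$seed
    cfg <- do.call(sim_config, sim_args)
    if (is.null(cfg$split)) {
      res <- simulate_population(cfg)
      datasets[["P1"]] <- res$dataset
      truth <- res$truth
    } else {
      res <- split_populations(cfg)
      datasets[["P1"]] <- res$pop1
      datasets[["P2"]] <- res$pop2
      truth <- res$truth
    }
    pedigree <- truth$pedigree
    attr(datasets, "truth") <- truth
  } else if (!is.null(config$inputs)) {
    for (nm in names(config$inputs)) {
      spec <- config$inputs[[nm]]
      ds <- if (!is.null(spec$bed))
        read_plink_binary(spec$bed, spec$bim, spec$fam)
      else read_plink_text(spec$ped, spec$map)
      ds$samples$population <- nm
      datasets[[nm]] <- ds
    }
    if (!is.null(config$pedigree))
      pedigree <- read_pedigree(config$pedigree)
  } else stop("config needs either a 'simulate' spec or 'inputs' paths")
  list(datasets = datasets, pedigree = pedigree)
}

#' Run the full diversity pipeline
#'
#' Orchestrates QC, the three inbreeding estimators, ROH detection and
#' sharing, LD decay, adjacent/thinned LD, between-population phase
#' correlation and the Ne trajectory, writing every table as TSV under
#' `out_dir` together with a JSON manifest (package version, config hash,
#' input checksums). Between-population outputs are produced only when two
#' populations are present (a notice is logged otherwise). All stochastic
#' steps (pair subsampling, simulation) derive from the single config seed,
#' so reruns are byte-identical.
#'
#' @param config a named list or path to a JSON file with keys `out_dir`,
#'   `seed`, one of `simulate` (arguments to [sim_config()]) or `inputs`
#'   (per-population PLINK paths) plus optional `pedigree`, and optional
#'   `params` overriding [pigdiv_defaults()]. Unknown keys are rejected.
#' @return Invisibly, a list with the in-memory results per stage.
#' @export
run_full <- function(config) {
  config <- .read_run_config(config)
  p <- config$params
  out <- config$out_dir
  if (is.null(out)) stop("config$out_dir is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  inputs <- .load_inputs(config)
  datasets <- inputs$datasets
  results <- list()

  # frozen config copy + manifest scaffold
  cfg_path <- file.path(out, "config.json")
  jsonlite::write_json(config[setdiff(names(config), "params")],
                       cfg_path, auto_unbox = TRUE, pretty = TRUE)
  params_path <- file.path(out, "params.json")
  jsonlite::write_json(p, params_path, auto_unbox = TRUE, pretty = TRUE)

  all_segments <- list()
  populations <- character(0)
  ds_inb_by_pop <- list()
  for (nm in names(datasets)) {
    ds <- datasets[[nm]]
    populations <- c(populations,
                     stats::setNames(rep(nm, nrow(ds$samples)),
                                     ds$samples$sample_id))
    message("[", nm, "] sample QC (", nrow(ds$samples), " samples, ",
            nrow(ds$snps), " SNPs)")
    s_rep <- sample_qc(ds, call_rate_min = p$sample_call_rate_min,
                       het_sd = p$het_sd, dup_match_min = p$dup_match_min)
    .write_tsv(s_rep, file.path(out, paste0(nm, "_sample_qc.tsv")))
    prof_inb <- qc_profile("inbreeding")
    m_rep <- do.call(snp_qc, c(list(ds), prof_inb))
    .write_tsv(m_rep, file.path(out, paste0(nm, "_snp_qc_inbreeding.tsv")))
    qres <- apply_qc(ds, s_rep, m_rep)
    ds_inb <- qres$dataset
    ds_inb_by_pop[[nm]] <- ds_inb
    .write_tsv(qres$counts, file.path(out, paste0(nm, "_qc_counts.tsv")))

    # inbreeding estimators
    fsnp <- f_snp(ds_inb)
    segs <- detect_roh(ds_inb, min_snps = p$roh_min_snps,
                       min_length_kb = p$roh_min_length_kb,
                       window = p$roh_window,
                       max_het_per_window = p$roh_max_het_per_window,
                       max_missing_per_window = p$roh_max_missing_per_window)
    froh <- f_roh(segs, genome_length_kb = p$genome_length_kb,
                  sample_ids = ds_inb$samples$sample_id)
    inb <- data.frame(sample_id = ds_inb$samples$sample_id,
                      F_ROH = as.numeric(froh[ds_inb$samples$sample_id]),
                      F_SNP = as.numeric(fsnp[ds_inb$samples$sample_id]),
                      stringsAsFactors = FALSE)
    fx <- NULL
    if (!is.null(inputs$pedigree)) {
      fx <- wright_inbreeding(inputs$pedigree)
      inb$F_x <- as.numeric(fx[inb$sample_id])
      dep <- pedigree_depth(inputs$pedigree)
      .write_tsv(data.frame(statistic = c("mean_depth_equivalent",
                                          "mean_depth_max"),
                            value = c(dep$mean_equivalent, dep$mean_max)),
                 file.path(out, paste0(nm, "_pedigree_depth.tsv")))
    }
    .write_tsv(inb, file.path(out, paste0(nm, "_inbreeding.tsv")),
               comment = "F per sample; F_ROH total ROH bp / L")
    est_names <- intersect(c("F_x", "F_ROH", "F_SNP"), names(inb))
    cors <- list()
    for (a in est_names) for (b in est_names) if (a < b) {
      va <- inbreeding_vector(stats::setNames(inb[[a]], inb$sample_id),
                              "pedigree")
      vb <- inbreeding_vector(stats::setNames(inb[[b]], inb$sample_id),
                              "pedigree")
      cc <- tryCatch(suppressWarnings(compare_inbreeding(va, vb)),
                     error = function(e) list(r = NA_real_, n = NA))
      cors[[paste(a, b, sep = "_vs_")]] <-
        data.frame(pair = paste(a, b, sep = "_vs_"), r = cc$r,
                   n = cc$n, stringsAsFactors = FALSE)
    }
    if (length(cors))
      .write_tsv(do.call(rbind, cors),
                 file.path(out, paste0(nm, "_inbreeding_correlations.tsv")))

    .write_tsv(segs, file.path(out, paste0(nm, "_roh_segments.tsv")))
    smr <- summarize_roh(segs, boundary_bp = p$roh_short_long_boundary_bp)
    if (nrow(smr$per_sample)) {
      .write_tsv(smr$per_sample,
                 file.path(out, paste0(nm, "_roh_per_sample.tsv")))
      .write_tsv(smr$per_population,
                 file.path(out, paste0(nm, "_roh_population.tsv")))
    }
    all_segments[[nm]] <- segs

    # LD-profile QC within population, then LD statistics
    prof_ld <- qc_profile("ld")
    m_rep_ld <- do.call(snp_qc, c(list(ds), prof_ld))
    qld <- apply_qc(ds, s_rep, m_rep_ld)
    ds_ld <- qld$dataset
    adj <- adjacent_ld(ds_ld)
    thin <- thinned_ld(ds_ld, keep_every = p$ld_thin_keep_every)
    .write_tsv(data.frame(
      statistic = c("adjacent_mean_r2", "adjacent_frac_gt_0.2",
                    "adjacent_frac_gt_0.3", "adjacent_mean_distance_bp",
                    "adjacent_n_pairs", "thinned_mean_r2",
                    "thinned_n_pairs"),
      value = c(adj$mean_r2, adj$frac_gt_0.2, adj$frac_gt_0.3,
                adj$mean_distance_bp, adj$n_pairs, thin$mean_r2,
                thin$n_pairs)),
      file.path(out, paste0(nm, "_ld_adjacent.tsv")))
    decay <- ld_decay(ds_ld, max_dist_bp = p$ld_max_dist_bp,
                      bin_bp = p$ld_bin_bp,
                      max_pairs_per_chrom = p$ld_max_pairs_per_chrom,
                      seed = config$seed)
    .write_tsv(decay, file.path(out, paste0(nm, "_ld_decay.tsv")),
               comment = "bins bp half-open [lo,hi); mean_r2 = unweighted mean of per-chromosome means")
    ne <- ne_from_dataset(ds_ld, grid = p$ne_grid,
                          cm_per_mb = p$cm_per_mb,
                          max_pairs_per_window = p$ne_max_pairs_per_window,
                          seed = config$seed,
                          r2_correction = p$ne_r2_correction)
    .write_tsv(ne, file.path(out, paste0(nm, "_ne_trajectory.tsv")),
               comment = "c in Morgan; Ne_t = (1-r2)/(4 c r2) at c = 1/(2t)")
    results[[nm]] <- list(sample_qc = s_rep, snp_qc = m_rep,
                          qc_counts = qres$counts, inbreeding = inb,
                          segments = segs, roh_summary = smr,
                          adjacent = adj, thinned = thin, decay = decay,
                          ne = ne, ds_ld = ds_ld)
  }

  if (length(datasets) == 2) {
    segs_all <- do.call(rbind, all_segments)
    shared_between <- shared_roh(segs_all, populations, mode = "between",
                                 match = "exact")
    .write_tsv(shared_between$per_chromosome,
               file.path(out, "shared_roh_between_per_chromosome.tsv"))
    if (nrow(shared_between$regions))
      .write_tsv(shared_between$regions,
                 file.path(out, "shared_roh_between_regions.tsv"))
    shared_within <- shared_roh(segs_all, populations, mode = "within",
                                match = "exact")
    if (nrow(shared_within$regions))
      .write_tsv(shared_within$regions,
                 file.path(out, "shared_roh_within_regions.tsv"))
    pc <- phase_correlation(results[[1]]$ds_ld, results[[2]]$ds_ld,
                            max_dist_bp = p$ld_max_dist_bp,
                            bin_bp = p$ld_bin_bp,
                            headline_dist_bp = p$phase_headline_dist_bp,
                            max_pairs_per_chrom = p$ld_max_pairs_per_chrom,
                            seed = config$seed)
    .write_tsv(pc$bins, file.path(out, "phase_correlation.tsv"))
    .write_tsv(data.frame(statistic = c("headline_correlation",
                                        "headline_max_dist_bp", "n_pairs"),
                          value = c(pc$headline, p$phase_headline_dist_bp,
                                    pc$n_headline_pairs)),
               file.path(out, "phase_correlation_headline.tsv"))
    results$between <- list(shared = shared_between, phase = pc)
  } else {
    message("single population: between-population outputs omitted")
  }

  # manifest with checksums over every produced table
  files <- sort(setdiff(list.files(out), "manifest.json"))
  manifest <- list(
    package = "pigdiv",
    version = as.character(utils::packageVersion("pigdiv")),
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    params_md5 = unname(tools::md5sum(params_path)),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out, files))), files)))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
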