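# End-to-end orchestration: simulate -> screen -> annotate -> cgi ->
# categorize -> matrices -> methylation -> dynamics -> mixture, from one JSON
# (or in-memory list) configuration, with a machine-readable run report.

PIPELINE_KEYS <- c("seed", "outdir", "simulate", "generator", "inputs",
                   "params", "verbose")
PARAM_KEYS <- c("promoter_flank", "upstream_dist", "downstream_dist",
                "window", "bin_width", "k_background", "fdr_max", "fc_min",
                "min_coverage", "oe_min", "fpkm_threshold", "condition_stage")

default_params <- function() {
  list(promoter_flank = 1000, upstream_dist = 5000, downstream_dist = 5000,
       window = 3000, bin_width = 50, k_background = 2, fdr_max = 0.01,
       fc_min = 5, min_coverage = 1, oe_min = 1.0, fpkm_threshold = 10,
       condition_stage = NULL)
}

#' Validate and normalize a pipeline configuration
#'
#' @param config A list, or path to a JSON file. Unknown keys are rejected.
#' @return Normalized config list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("pipeline_config: no such file: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(config), PIPELINE_KEYS)
  if (length(unknown)) {
    stop("pipeline_config: unknown key(s): ", paste(unknown, collapse = ", "))
  }
  params <- utils::modifyList(default_params(),
                              as.list(config$params %||% list()))
  unknown <- setdiff(names(params), PARAM_KEYS)
  if (length(unknown)) {
    stop("pipeline_config: unknown params key(s): ",
         paste(unknown, collapse = ", "))
  }
  list(seed = config$seed %||% 1,
       outdir = config$outdir %||% tempfile("spermhist_run_"),
       simulate = isTRUE(config$simulate %||% TRUE),
       generator = as.list(config$generator %||% list()),
       inputs = as.list(config$inputs %||% list()),
       params = params,
       verbose = isTRUE(config$verbose %||% FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order on either a freshly simulated
#' dataset (`simulate = TRUE`, the default) or user-supplied input files, and
#' writes every output plus a JSON run report (with content hashes of all
#' outputs) under `outdir`. Re-running with an identical config and seed
#' reproduces every output byte for byte.
#'
#' @param config List or JSON path; see [pipeline_config()].
#' @return The run report (list), invisibly; also written as
#'   `<outdir>/report.json`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  pp <- cfg$params
  say <- function(...) if (cfg$verbose) message("[spermhist] ", ...)
  t0 <- proc.time()[["elapsed"]]
  report <- list(seed = cfg$seed, params = pp, stages = list())
  outfiles <- character(0)
  out <- function(name) {
    f <- file.path(cfg$outdir, name)
    outfiles[[name]] <<- f
    f
  }

  ## stage: data ---------------------------------------------------------------
  if (cfg$simulate) {
    say("simulate")
    gen <- do.call(generator_config, c(cfg$generator, list(seed = cfg$seed)))
    ds <- generate_dataset(gen)
    input_files <- write_dataset(ds, file.path(cfg$outdir, "inputs"))
    genes <- ds$genes; repeats <- ds$repeats; cgis <- ds$cgis
    peaks <- ds$peaks; coverage <- ds$coverage
    methylation <- ds$methylation; expr <- ds$expression
    chrom_sizes <- ds$chrom_sizes
    f_mix <- ds$config$hruncs_fraction
    report$stages$simulate <- list(
      n_genes = nrow(genes), n_hrcs_peaks = nrow(peaks$hrcs),
      n_total_peaks = nrow(peaks$total),
      planted_promoter_fraction = ds$truth$promoter_fraction)
  } else {
    need <- c("genes", "peaks_total", "peaks_hrcs")
    for (k in need) {
      if (is.null(cfg$inputs[[k]])) {
        stop("run_pipeline: simulate is disabled and required input '", k,
             "' is missing from the config")
      }
      if (!file.exists(cfg$inputs[[k]])) {
        stop("run_pipeline: input file for '", k, "' not found: ",
             cfg$inputs[[k]])
      }
    }
    grab <- function(k, reader) {
      f <- cfg$inputs[[k]]
      if (is.null(f)) return(NULL)
      if (!file.exists(f)) {
        stop("run_pipeline: input file for '", k, "' not found: ", f)
      }
      reader(f)
    }
    genes <- read_gene_table(cfg$inputs$genes)
    peaks <- list(hrcs = read_bed(cfg$inputs$peaks_hrcs),
                  total = read_bed(cfg$inputs$peaks_total))
    repeats <- grab("repeats", read_bed) %||%
      gintervals(character(), numeric(), numeric())
    cgis <- grab("cgis", read_bed)
    if (!is.null(cgis)) cgis$oe <- cgis$score
    coverage <- list(hrcs = grab("coverage_hrcs", read_bedgraph),
                     total = grab("coverage_total", read_bedgraph),
                     input = grab("coverage_input", read_bedgraph))
    methylation <- list(hrcs = grab("methylation_hrcs", read_methylation),
                        total = grab("methylation_total", read_methylation))
    expr <- grab("expression", read_expression)
    chrom_sizes <- cfg$inputs$chrom_sizes
    if (is.null(chrom_sizes)) {
      ends <- c(peaks$hrcs$end, peaks$total$end, genes$tes, genes$tss)
      chs <- c(peaks$hrcs$chrom, peaks$total$chrom, genes$chrom, genes$chrom)
      chrom_sizes <- vapply(split(ends, chs), max, numeric(1)) + 10000
    } else {
      chrom_sizes <- unlist(chrom_sizes)
    }
    f_mix <- 0.10
    report$stages$load <- list(n_hrcs_peaks = nrow(peaks$hrcs),
                               n_total_peaks = nrow(peaks$total))
  }

  ## stage: enrichment screen --------------------------------------------------
  if (!is.null(coverage$total) && !is.null(coverage$input)) {
    say("screen")
    screened <- enrichment_screen(coverage$total, coverage$input,
                                  fdr_max = pp$fdr_max, fc_min = pp$fc_min,
                                  sample_label = "total")
    write_bed(screened, out("screened_peaks_total.bed"))
    report$stages$screen <- list(n_screened_peaks = nrow(screened),
                                 fdr_max = pp$fdr_max, fc_min = pp$fc_min)
  }

  ## stage: compartments -------------------------------------------------------
  say("annotate")
  ann <- build_annotation(genes, repeats, chrom_sizes,
                          promoter_flank = pp$promoter_flank,
                          upstream_dist = pp$upstream_dist,
                          downstream_dist = pp$downstream_dist)
  part <- check_partition(ann)
  if (!part$ok) stop("run_pipeline: annotation failed to partition the genome")
  comp <- lapply(peaks, peak_compartment_table, ann = ann)
  for (sm in names(comp)) {
    utils::write.table(comp[[sm]], out(sprintf("compartments_%s.tsv", sm)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report$stages$compartments <- lapply(comp, function(d) {
    stats::setNames(as.list(round(d$fraction, 6)), d$class)
  })

  ## stage: CGI analysis -------------------------------------------------------
  if (!is.null(cgis) && "oe" %in% names(cgis)) {
    say("cgi")
    oecmp <- cgi_peak_oe_comparison(cgis, peaks$total, peaks$hrcs)
    dens <- chromosome_density(peaks$hrcs, cgis, chrom_sizes,
                               oe_min = pp$oe_min)
    utils::write.table(dens, out("chromosome_density_hrcs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$stages$cgi <- list(
      oe_median = lapply(oecmp$box, function(b) b$median),
      wilcoxon_p = as.list(oecmp$pvalues),
      n_overlap = as.list(oecmp$n_overlap))
  }

  ## stage: overlaps and categories --------------------------------------------
  say("categorize")
  osum <- overlap_summary(peaks, genes, flank = pp$promoter_flank)
  utils::write.table(osum, out("overlap_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report$stages$overlap <- lapply(seq_len(nrow(osum)), function(i) {
    as.list(osum[i, , drop = FALSE])
  })
  catalog <- NULL
  if (!is.null(coverage$hrcs)) {
    gt <- peaks_to_genes(peaks$total, genes, flank = pp$promoter_flank)
    gh <- peaks_to_genes(peaks$hrcs, genes, flank = pp$promoter_flank)
    catalog <- categorize_targets(gt, gh, coverage$hrcs, peaks$total, genes,
                                  k_background = pp$k_background,
                                  flank = pp$promoter_flank)
    utils::write.table(catalog, out("target_catalog.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sizes <- table(factor(catalog$category, levels = c("H", "PH", "TS")))
    report$stages$categories <- as.list(stats::setNames(as.integer(sizes),
                                                        names(sizes)))
  }

  ## stage: TSS matrices -------------------------------------------------------
  if (!is.null(coverage$hrcs) && !is.null(catalog)) {
    say("matrix")
    anchors <- data.frame(chrom = genes$chrom, pos = genes$tss,
                          strand = genes$strand, name = genes$gene_id,
                          stringsAsFactors = FALSE)
    anchors <- anchors[anchors$name %in% catalog$gene_id, , drop = FALSE]
    for (sm in intersect(c("total", "hrcs"), names(coverage))) {
      if (is.null(coverage[[sm]])) next
      m <- build_tss_matrix(coverage[[sm]], anchors, window = pp$window,
                            bin_width = pp$bin_width, sample_label = sm)
      write_matrix_tsv(export_heatmap_matrix(m), m$offsets,
                       out(sprintf("tss_matrix_%s.tsv", sm)))
      curve <- profile_curve(m)
      utils::write.table(curve, out(sprintf("profile_%s.tsv", sm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$stages$profiles[[sm]] <- list(
        n_anchors = nrow(m$values),
        center_mean_rpm = curve$mean_rpm[ncol(m$values) / 2 + 1])
    }
  }

  ## stage: methylation --------------------------------------------------------
  if (!is.null(methylation$hrcs) && !is.null(methylation$total) &&
      !is.null(cgis)) {
    say("methyl")
    lev_h <- region_methylation(methylation$hrcs, cgis,
                                min_coverage = pp$min_coverage)
    lev_t <- region_methylation(methylation$total, cgis,
                                min_coverage = pp$min_coverage)
    mc <- methylation_correlation(lev_h, lev_t)
    d <- data.frame(chrom = cgis$chrom, start = cgis$start, end = cgis$end,
                    level_hrcs = lev_h, level_total = lev_t)
    utils::write.table(d, out("region_methylation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$stages$methylation <- list(pearson_r = mc$r, n_regions = mc$n)
  }

  ## stage: expression dynamics ------------------------------------------------
  if (!is.null(expr) && !is.null(catalog)) {
    say("dynamics")
    cats <- stats::setNames(catalog$category, catalog$gene_id)
    dyn <- expression_dynamics(expr, cats, threshold = pp$fpkm_threshold,
                               condition_stage = pp$condition_stage)
    utils::write.table(dyn, out("expression_dynamics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    report$stages$dynamics <- lapply(split(dyn, dyn$category), function(d) {
      stats::setNames(as.list(round(d$fraction, 6)), as.character(d$stage))
    })
  }

  ## stage: mixture inversion --------------------------------------------------
  if (!is.null(coverage$total) && !is.null(coverage$hrcs)) {
    say("mixture")
    R_obs <- coverage$total$total_mapped_reads /
      coverage$hrcs$total_mapped_reads
    inv <- invert_ratio(f_mix, R_obs)
    report$stages$mixture <- list(f = f_mix, R_observed = R_obs,
                                  h_un_over_h_c = inv$h_un_over_h_c,
                                  contamination_share = inv$contamination_share)
  }

  ## report --------------------------------------------------------------------
  hashes <- as.list(tools::md5sum(unlist(outfiles)))
  names(hashes) <- names(outfiles)
  report$output_files <- hashes
  # the on-disk report carries only deterministic content; timing is attached
  # to the returned object afterwards
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  report$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 2)
  say("done in ", report$elapsed_s, " s")
  invisible(report)
}
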