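# End-to-end panel-design pipeline with validated configuration and a
# checksummed output manifest.

default_config <- function() {
  list(
    seed = 1L,
    output_dir = "panelsmith_out",
    simulate = list(
      enabled = TRUE,
      chrom_lengths = c(chr1 = 400000L, chr2 = 300000L, chr3 = 300000L),
      gc = 0.45,
      n_pops = 2L, samples_per_pop = 30L, n_snps = 600L,
      divergence_F = 0.1, maf_floor = 0.05, missing_rate = 0.02
    ),
    inputs = list(vcf = NULL, fasta = NULL, pops = NULL),
    qc = list(max_missing = 0.1, min_maf = 0.35, max_hobs = 0.5),
    probes = list(flank = 110L, gc_min = 0.3, gc_max = 0.7, max_hits = 5L),
    select = list(window = 100000L),
    fingerprint = list(enabled = FALSE, k = 384L, min_gap = 100000L)
  )
}

check_range <- function(x, name, lo, hi) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi)
    stop("config: `", name, "` must be a number in [", lo, ", ", hi, "]")
}

#' Validate a pipeline configuration
#'
#' Unknown keys are rejected; thresholds are checked against their
#' documented ranges. Missing sections inherit the defaults.
#'
#' @param config nested list (e.g. from [yaml::read_yaml()]), or a path to
#'   a YAML file.
#' @return the completed, validated config list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("config: unknown key(s): ", paste(unknown, collapse = ", "))
  for (sec in names(config)) {
    if (is.list(def[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
      if (length(bad))
        stop("config: unknown key(s) in `", sec, "`: ",
             paste(bad, collapse = ", "))
      def[[sec]][names(config[[sec]])] <- config[[sec]]
    } else {
      def[[sec]] <- config[[sec]]
    }
  }
  check_range(def$qc$max_missing, "qc.max_missing", 0, 1)
  check_range(def$qc$min_maf, "qc.min_maf", 0, 0.5)
  check_range(def$qc$max_hobs, "qc.max_hobs", 0, 1)
  check_range(def$probes$gc_min, "probes.gc_min", 0, 1)
  check_range(def$probes$gc_max, "probes.gc_max", 0, 1)
  if (def$probes$gc_min > def$probes$gc_max)
    stop("config: probes.gc_min exceeds probes.gc_max")
  check_range(def$probes$flank, "probes.flank", 1, 1e6)
  check_range(def$probes$max_hits, "probes.max_hits", 1, 1e6)
  check_range(def$select$window, "select.window", 1, 1e9)
  check_range(def$simulate$divergence_F, "simulate.divergence_F",
              0, 1 - 1e-9)
  def
}

#' Run the panel-design pipeline
#'
#' Stages: (optionally) simulate a genome and population, or load a
#' VCF/FASTA pair; per-site QC; probe GC/specificity screening; uniform
#' panel selection; characterization metrics. Every output file is
#' recorded in a manifest with its MD5 checksum, together with the config
#' snapshot and package version; a rerun with the same seed and config
#' reproduces identical checksums. Existing stage outputs are reused when
#' `resume = TRUE`.
#'
#' @param config list or YAML path accepted by [validate_config()].
#' @param resume reuse existing stage outputs if present (default FALSE).
#' @return the manifest (invisibly also written to
#'   `<output_dir>/manifest.json`).
#' @export
run_pipeline <- function(config = list(), resume = FALSE) {
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(cfg$output_dir, ...)
  stage_files <- character(0)

  fasta <- path("genome.fa")
  vcf <- path("cohort.vcf")
  if (isTRUE(cfg$simulate$enabled)) {
    if (!(resume && file.exists(fasta) && file.exists(vcf))) {
      sim_g <- simulate_genome(unlist(cfg$simulate$chrom_lengths),
                               gc = cfg$simulate$gc, seed = cfg$seed)
      Biostrings::writeXStringSet(sim_g$ref, fasta)
      sim_p <- simulate_population(
        unlist(cfg$simulate$chrom_lengths),
        n_pops = cfg$simulate$n_pops,
        samples_per_pop = cfg$simulate$samples_per_pop,
        n_snps = cfg$simulate$n_snps, F = cfg$simulate$divergence_F,
        maf_floor = cfg$simulate$maf_floor,
        missing_rate = cfg$simulate$missing_rate,
        seed = cfg$seed + 1L, genome = sim_g$ref)
      write_vcf(sim_p$geno, vcf,
                contig_lengths = unlist(cfg$simulate$chrom_lengths))
      write.table(data.frame(sample = names(sim_p$pops),
                             population = sim_p$pops),
                  path("populations.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      stage_files <- c(stage_files, path("populations.tsv"))
    }
  } else {
    if (is.null(cfg$inputs$vcf) || is.null(cfg$inputs$fasta))
      stop("stage `inputs` failed: vcf and fasta paths are required when ",
           "simulation is disabled")
    fasta <- cfg$inputs$fasta
    vcf <- cfg$inputs$vcf
  }
  stage_files <- c(stage_files, fasta, vcf)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE))
  }

  g <- run_stage("read", read_vcf(vcf))
  ref <- run_stage("read", read_reference(fasta))
  bad <- validate_inputs(g, ref)
  if (nrow(bad) > 0)
    stop("stage `validate` failed: ", nrow(bad), " inconsistent site(s)")

  stats <- run_stage("qc", site_stats(g))
  stats$qc_pass <- qc_filter(stats, cfg$qc$max_missing, cfg$qc$min_maf,
                             cfg$qc$max_hobs)
  write_site_stats(stats, path("site_stats.tsv"))

  cand <- stats[stats$qc_pass, , drop = FALSE]
  report <- run_stage("probes", probe_report(
    cand, ref, flank_len = cfg$probes$flank,
    gc_band = c(cfg$probes$gc_min, cfg$probes$gc_max),
    max_hits = cfg$probes$max_hits))
  write.table(report, path("probe_report.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  panel <- run_stage("select", select_uniform(
    report[report$overall_pass, , drop = FALSE],
    window = cfg$select$window))
  if (nrow(panel$sites) > 0) write_panel(panel, path("panel"))
  metrics <- if (nrow(panel$sites) > 0)
    panel_metrics(panel, ref_lengths(ref)) else NULL
  jsonlite::write_json(metrics, path("panel_metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (isTRUE(cfg$fingerprint$enabled) &&
      nrow(panel$sites) >= cfg$fingerprint$k) {
    fp <- select_fingerprint(panel, k = cfg$fingerprint$k,
                             min_gap = cfg$fingerprint$min_gap,
                             chrom_lengths = ref_lengths(ref))
    write.table(fp$loci, path("fingerprint.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    stage_files <- c(stage_files, path("fingerprint.tsv"))
  }

  stage_files <- unique(c(stage_files, path("site_stats.tsv"),
                          path("probe_report.tsv"),
                          if (nrow(panel$sites) > 0)
                            c(path("panel.bed"), path("panel.tsv")),
                          path("panel_metrics.json")))
  manifest <- list(
    tool = "panelsmith",
    version = as.character(utils::packageVersion("panelsmith")),
    config = cfg,
    files = lapply(stage_files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
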