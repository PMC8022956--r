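#' Pipeline run configuration
#'
#' @param seed Master seed; every stage derives its randomness from it.
#' @param outdir Output directory for stage artifacts and the manifest.
#' @param design Cohort design (default [wgs_panel_design()]).
#' @param scan_mode Concordance mode for the IBD scan.
#' @param sv_coverage,sv_region Read-simulation depth and
#'   [genomic_interval()] for the structural-variant stage.
#' @param min_support Minimum SV evidence support.
#' @return List of class `crest_config`.
#' @export
crest_config <- function(seed = 1L, outdir = "crestmap_run",
                         design = wgs_panel_design(),
                         scan_mode = "homozygous_ibd",
                         sv_coverage = 20,
                         sv_region = genomic_interval("chr33", 7578000L,
                                                      7598000L),
                         min_support = 3L) {
  structure(list(seed = as.integer(seed), outdir = outdir, design = design,
                 scan_mode = scan_mode, sv_coverage = sv_coverage,
                 sv_region = sv_region, min_support = min_support),
            class = "crest_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys: `seed`, `outdir`, `scan: mode`, `reads: coverage`,
#' `sv: min_support`. Omitted keys keep their defaults.
#'
#' @param path YAML file path.
#' @return A `crest_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- crest_config()
  if (!is.null(y$seed)) cfg$seed <- as.integer(y$seed)
  if (!is.null(y$outdir)) cfg$outdir <- y$outdir
  if (!is.null(y$scan$mode)) cfg$scan_mode <- y$scan$mode
  if (!is.null(y$reads$coverage)) cfg$sv_coverage <- y$reads$coverage
  if (!is.null(y$sv$min_support)) cfg$min_support <- as.integer(y$sv$min_support)
  cfg
}

#' Run the full discovery pipeline
#'
#' simulate -> IBD scan -> concordance filter -> SV detection -> diagnosis
#' -> report, writing stage artifacts and a JSON manifest under
#' `config$outdir`. A failing stage produces a partial manifest naming the
#' stage and an error.
#'
#' @param config A `crest_config`.
#' @return The manifest, invisibly (also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(config = crest_config()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("crestmap")),
                   stages = list())
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      manifest$failed_stage <<- name
      finish_manifest(manifest, config)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  ref <- stage("reference", function() build_reference(config$seed))
  cohort <- stage("simulate", function() {
    ch <- generate_cohort(ref, config$design, seed = config$seed)
    write_cohort(ch, config$outdir)
    ch
  })
  scan <- stage("scan", function() {
    if (!any(cohort$samples$phenotype != "non_crested")) {
      stop("no case samples in cohort; cannot scan for shared haplotype")
    }
    iv <- shared_interval_scan(cohort$matrix, crest_candidate_region(),
                               mode = config$scan_mode)
    write_ibd_bed(iv, ref$region$chrom,
                  file.path(config$outdir, "ibd_intervals.bed"))
    iv
  })
  candidates <- stage("filter", function() {
    top <- genomic_interval(ref$region$chrom, scan$start[1], scan$end[1])
    concordance_filter(cohort$matrix, top)
  })
  dup <- stage("detect_sv", function() {
    case_ids <- cohort$samples$sample_id[
      cohort$samples$phenotype != "non_crested" &
        cohort$samples$sample_kind == "individual"]
    haps <- cohort$haplotypes[[case_ids[1]]]
    aln <- simulate_alignments(ref, haps, coverage = config$sv_coverage,
                               region = config$sv_region,
                               seed = config$seed)
    write_sam(aln, file.path(config$outdir, "case_reads.sam"), ref)
    ev <- collect_evidence(aln, config$sv_region)
    call_tandem_dup(ev, ref, min_support = config$min_support)
  })
  diagnostics <- stage("diagnose", function() {
    res <- diagnose_cohort(cohort, ref)
    utils::write.table(res, file.path(config$outdir, "diagnostics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res
  })
  summary_tab <- stage("report", function() {
    tab <- cohort_summary(diagnostics, cohort$samples)
    utils::write.table(tab, file.path(config$outdir, "cohort_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tab
  })

  manifest$ibd_interval <- if (nrow(scan)) {
    list(start = scan$start[1], end = scan$end[1],
         length_bp = scan$length[1])
  }
  manifest$n_candidates <- nrow(candidates)
  manifest$candidates <- candidates$id
  manifest$dup_call <- if (nrow(dup)) {
    list(start = dup$start[1], end = dup$end[1],
         unit_length = dup$unit_length[1], genotype = dup$genotype[1],
         sr_support = dup$sr_support[1])
  }
  manifest$cohort_table <- file.path(config$outdir, "cohort_summary.tsv")
  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  finish_manifest(manifest, config)
  invisible(manifest)
}

finish_manifest <- function(manifest, config) {
  jsonlite::write_json(manifest,
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}
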