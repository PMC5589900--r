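# stage wrapper: any failure aborts with the stage name attached
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

.write_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  .write_tsv(df, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a run configuration
#'
#' YAML with keys `beta`, `segments`, `regions`, `anatomy`, `manifest`,
#' `controls` (file of sample ids, one per line), optional `tissue`,
#' `out_dir`, `min_probes` and a `thresholds` block overriding
#' [imprint_thresholds()] defaults. Relative paths are resolved against
#' the YAML's directory.
#'
#' @param path YAML file.
#' @return list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("beta", "segments", "regions", "anatomy", "manifest",
                "controls")) {
    .stop_if(is.null(cfg[[key]]), "run config missing '", key, "'")
    p <- cfg[[key]]
    if (!grepl("^/", p)) p <- file.path(base, p)
    .stop_if(!file.exists(p), "missing input file for '", key, "': ", p)
    cfg[[key]] <- p
  }
  cfg$tissue <- cfg$tissue %||% "cohort"
  cfg$min_probes <- cfg$min_probes %||% 2L
  cfg$thresholds <- do.call(imprint_thresholds,
                            cfg$thresholds %||% list())
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis from files
#'
#' Sequences probe QC, region averaging, control statistics, copy-state
#' assignment, CNA-predicted methylation, epimutation calling, state
#' classification, cnnLOH parent inference, context burden scoring and
#' per-region variance explained; writes every output table atomically
#' under `out_dir`. Reruns with identical inputs are byte-identical. Any
#' stage error aborts with the stage name.
#'
#' @param config a `"run_config"` (see [read_run_config()]), a YAML path,
#'   or an equivalent list.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return A `"run_report"`: per-stage record counts, probe-removal
#'   counts, cohort epimutation frequencies, per-region R^2, burden
#'   correlations, package version and the echoed config.
#' @export
run_analysis <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- out_dir %||% config$out_dir
  .stop_if(is.null(out_dir), "no output directory given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds %||% imprint_thresholds()

  bm <- .stage("read_beta", read_beta_matrix(config$beta))
  seg <- .stage("read_segments", read_segments(config$segments))
  reg <- .stage("read_regions", read_regions(config$regions))
  anatomy <- .stage("read_anatomy", read_anatomy(config$anatomy))
  manifest <- .stage("read_manifest",
                     utils::read.delim(config$manifest, sep = "\t"))
  controls <- .stage("read_controls", readLines(config$controls))

  bm_f <- .stage("filter_probes", filter_probes(bm, manifest, th))
  removal <- attr(bm_f, "removal")

  fit <- .stage("imprint_cna",
                imprint_cna(bm_f, seg, reg, anatomy, controls, manifest,
                            tissue = config$tissue %||% "cohort",
                            thresholds = th,
                            min_probes = config$min_probes %||% 2L))

  .stage("write_outputs", {
    .write_atomic(fit$calls, file.path(out_dir, "calls.tsv"))
    .write_atomic(fit$control_stats,
                  file.path(out_dir, "control_stats.tsv"))
    .write_atomic(fit$r_squared, file.path(out_dir, "region_r2.tsv"))
    .write_atomic(scatter_table(fit), file.path(out_dir, "scatter.tsv"))
    per_reg <- data.frame(
      region_id = as.character(
        names(fit$cohort$per_region_pct_independent)),
      pct_cna_independent =
        as.numeric(fit$cohort$per_region_pct_independent))
    .write_atomic(per_reg, file.path(out_dir, "region_summary.tsv"))
    if (!is.null(fit$context)) {
      sev <- fit$context$severity
      .write_atomic(data.frame(region_id = rownames(sev), sev,
                               check.names = FALSE),
                    file.path(out_dir, "context_severity.tsv"))
      for (kl in names(fit$context$burdens))
        .write_atomic(fit$context$burdens[[kl]],
                      file.path(out_dir,
                                paste0("context_burden_", kl, ".tsv")))
      if (!is.null(fit$context$correlations)) {
        co <- fit$context$correlations
        .write_atomic(data.frame(klass = rownames(co$coefficient),
                                 co$coefficient, check.names = FALSE),
                      file.path(out_dir, "burden_correlations.tsv"))
        .write_atomic(data.frame(klass = rownames(co$method), co$method,
                                 check.names = FALSE),
                      file.path(out_dir,
                                "burden_correlation_methods.tsv"))
      }
    }
  })

  report <- structure(list(
    stages = c(probes_in = nrow(bm$beta),
               probes_retained = as.integer(removal[["retained"]]),
               samples = ncol(bm$beta),
               regions = nrow(reg),
               calls = nrow(fit$calls),
               evaluable = fit$cohort$n_pairs_evaluable),
    probe_removal = removal,
    cohort = fit$cohort,
    r_squared = fit$r_squared,
    correlations = fit$context$correlations,
    version = as.character(utils::packageVersion("imprintCNA")),
    config = config, out_dir = out_dir), class = "run_report")
  yaml::write_yaml(list(
    version = report$version,
    stages = as.list(report$stages),
    probe_removal = as.list(removal),
    pct_pairs_cna_independent = fit$cohort$pct_pairs_cna_independent,
    mean_pct_dmrs_affected_per_sample =
      fit$cohort$mean_pct_dmrs_affected_per_sample),
    file.path(out_dir, "report.yaml"))
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report (imprintCNA", x$version, ")\n")
  print(x$stages)
  cat(sprintf("CNA-independent pairs: %.1f%%\n",
              x$cohort$pct_pairs_cna_independent))
  invisible(x)
}

#' Simulate a cohort and write it to disk
#'
#' Runs [simulate_cohort()] and [write_cohort()] (plus simulated RRBS
#' counts) so the files can be fed straight back through
#' [run_analysis()].
#'
#' @param cfg a [sim_config()].
#' @param out output directory.
#' @param force overwrite existing files.
#' @param rrbs also emit `rrbs.tsv`.
#' @return The `"imprint_sim"` object, invisibly.
#' @export
simulate_command <- function(cfg, out, force = FALSE, rrbs = FALSE) {
  sim <- simulate_cohort(cfg)
  write_cohort(sim, out, force = force)
  if (rrbs)
    .write_tsv(simulate_rrbs_counts(sim), file.path(out, "rrbs.tsv"))
  invisible(sim)
}
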