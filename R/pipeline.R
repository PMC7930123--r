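#' Run the multi-replica contact-mapping pipeline
#'
#' Orchestrates the full analysis behind a contact map: load each replica,
#' window it, compute per-residue contact metrics for all four chains,
#' aggregate over `4 x n_replicas` values, select hot spots, and write a
#' CSV/JSON bundle with a run manifest. The configuration is a YAML file
#' (or equivalent list) validated before any compute:
#'
#' ```yaml
#' species: CER6
#' cutoff: 6.0
#' window: [0.2, 1.0]
#' out_dir: results/wt_open
#' replicas:
#'   - {structure: rep1.gro, trajectory: rep1_traj.gro}
#'   - {structure: rep2.gro, trajectory: rep2_traj.gro}
#' ```
#'
#' @param config path to a YAML configuration or a list.
#' @return Invisibly, a list with `aggregated`, `hotspots`, `per_replica`
#'   and the paths written. Any stage failure leaves a `.failed` marker in
#'   `out_dir` and rethrows the error.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config))
      stopf("lc_config_error", "config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  for (field in c("species", "out_dir", "replicas"))
    if (is.null(config[[field]]))
      stopf("lc_config_error", "config lacks required field '%s'", field)
  if (length(config$replicas) < 1)
    stopf("lc_config_error", "config lists no replicas")
  for (r in config$replicas) {
    if (is.null(r$structure))
      stopf("lc_config_error", "replica entry lacks a structure path")
    for (p in c(r$structure, r$trajectory))
      if (!is.null(p) && !file.exists(p))
        stopf("lc_config_error", "input file not found: %s", p)
  }
  cutoff <- config$cutoff %||% 6
  window <- if (!is.null(config$window))
    analysis_window(config$window[[1]], config$window[[2]])
  else analysis_window()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(config$out_dir, ".failed")
  if (file.exists(marker)) unlink(marker)

  result <- tryCatch({
    per_replica <- purrr::imap(config$replicas, function(r, i) {
      message(sprintf("[replica %d] loading %s", i, r$structure))
      t0 <- Sys.time()
      traj <- load_trajectory(r$structure, r$trajectory,
                              topology_spec = config$topology_spec)
      cm <- contact_metrics(traj, config$species, cutoff = cutoff,
                            window = window, replica = i)
      message(sprintf("[replica %d] %d residue/chain metrics in %.1fs",
                      i, nrow(cm), as.numeric(Sys.time() - t0, units = "secs")))
      cm
    })
    agg <- aggregate_tetramer(per_replica)
    hs <- select_hotspots(agg)
    metrics_path <- file.path(config$out_dir, "contact_metrics.csv")
    write_metric_table(tidy(hs), metrics_path)
    raw_path <- file.path(config$out_dir, "contact_metrics_raw.csv")
    write_metric_table(attr(agg, "raw"), raw_path)
    report_path <- file.path(config$out_dir, "selection.json")
    jsonlite::write_json(list(
      thresholds = hs$thresholds,
      outliers = hs$outliers,
      upper_quartile = hs$upper_quartile,
      upper_quartile_only = hs$upper_quartile_only
    ), report_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest_path <- file.path(config$out_dir, "manifest.json")
    write_run_manifest(
      manifest_path,
      parameters = list(species = config$species, cutoff = cutoff,
                        n_replicas = length(config$replicas)),
      window = window,
      files = unlist(lapply(config$replicas, function(r)
        c(r$structure, r$trajectory))))
    list(aggregated = agg, hotspots = hs, per_replica = per_replica,
         paths = c(metrics = metrics_path, raw = raw_path,
                   selection = report_path, manifest = manifest_path))
  }, error = function(e) {
    writeLines(conditionMessage(e), marker)
    stop(e)
  })
  invisible(result)
}
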