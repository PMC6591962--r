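#' Run the whole analysis pipeline from a config
#'
#' Orchestrates simulate -> quantify -> differential -> markers ->
#' deconvolve -> evaluate from a single configuration (an R list or a YAML
#' file path), writing every intermediate artifact (TSV/BED/JSON) plus a
#' Markdown summary to `out_dir`. Runs are fully seeded: the same config
#' yields byte-identical artifacts. Omitting the `deconvolve` block stops
#' the pipeline after marker discovery and writes a partial report.
#'
#' Config blocks (all optional except `simulate`):
#' * `simulate`: arguments of [sim_config()], plus a `series` sub-block
#'   (`tissues`, `fraction_grid`, `replicates`, `total_reads`);
#' * `differential`: `fc_threshold`, `fdr_threshold`, `pseudocount`;
#' * `markers`: thresholds of [select_tissue_markers()];
#' * `deconvolve`: `swarm_size`, `iterations`, `n_runs`, `seed`, and
#'   `background` (`"defaults"`, `"estimate"`, or `"none"`).
#'
#' @param config Named list or path to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress stage messages.
#' @return (Invisibly) a bundle list: the panel, MePM tables, marker set,
#'   deconvolution results, recovery and detection-limit tables, and the
#'   paths of all written artifacts.
#' @export
run_pipeline <- function(config, out_dir = tempfile("cfdecon_"),
                         quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$simulate)) {
    abort("config must be a list (or YAML path) with a `simulate` block.",
          class = "cfdecon_config_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[cfdecon] ", sprintf(...))
  paths <- list()
  art <- function(name) {
    paths[[name]] <<- file.path(out_dir, name)
    paths[[name]]
  }

  ## -- simulate ------------------------------------------------------------
  sim <- config$simulate
  series_cfg <- sim$series
  sim$series <- NULL
  cfg <- do.call(sim_config, sim)
  say("simulate: generating reference panel (seed %d)", cfg$seed)
  panel <- generate_reference_panel(cfg)
  write_sites_bed(panel$sites, art("sites.bed"))
  jsonlite::write_json(
    list(tissues = panel$tissues,
         truth = tidyr::pivot_wider(panel$truth, names_from = "tissue",
                                    values_from = "true_mepm")),
    art("panel_truth.json"), digits = NA
  )

  series <- NULL
  if (!is.null(series_cfg)) {
    series_args <- c(list(panel = panel), series_cfg)
    if (is.null(series_args$seed)) series_args$seed <- cfg$seed + 1000
    series <- do.call(simulate_mixture_series, series_args)
    readr::write_tsv(series$truth, art("series_truth.tsv"))
    write_meta_tsv(series$meta, art("series_meta.tsv"))
  }

  ## -- quantify ------------------------------------------------------------
  say("quantify: computing MePM matrices")
  mk_pairs <- panel$markers[, c("site_id", "cpg_index")]
  wbc_mepm <- compute_mepm(panel$wbc_training$molecules,
                           panel$wbc_training$meta, panel$sites, mk_pairs)
  pairs_mepm <- compute_mepm(panel$wbc_plasma_pairs$molecules,
                             panel$wbc_plasma_pairs$meta, panel$sites,
                             mk_pairs)
  write_mepm_tsv(wbc_mepm, art("wbc_training_mepm.tsv"))
  write_mepm_tsv(pairs_mepm, art("pairs_mepm.tsv"))
  series_mepm <- NULL
  if (!is.null(series)) {
    series_mepm <- compute_mepm(series$molecules, series$meta, panel$sites,
                                mk_pairs)
    write_mepm_tsv(series_mepm, art("series_mepm.tsv"))
  }

  ## -- differential --------------------------------------------------------
  dm <- NULL
  if (!is.null(config$differential)) {
    say("differential: plasma vs WBC screen on the matched pairs")
    dm <- do.call(identify_dm_sites, c(
      list(mepm = pairs_mepm, meta = panel$wbc_plasma_pairs$meta),
      config$differential
    ))
    write_dm_tsv(dm, art("differential.tsv"))
  }

  ## -- markers -------------------------------------------------------------
  say("markers: tissue-specific marker selection")
  tissue_means <- panel$truth |>
    filter(.data$tissue != "WBC") |>
    rename(mean_mepm = "true_mepm")
  marker_set <- do.call(select_tissue_markers, c(
    list(tissue_means = tissue_means, wbc_mepm = wbc_mepm,
         marker_info = panel$markers),
    config$markers %||% list()
  ))
  readr::write_tsv(as_tibble(marker_set), art("marker_set.tsv"))
  write_marker_set_bed(marker_set, panel$markers, art("marker_set.bed"))

  bundle <- list(panel = panel, wbc_mepm = wbc_mepm, pairs_mepm = pairs_mepm,
                 series = series, series_mepm = series_mepm, dm = dm,
                 marker_set = marker_set, paths = paths)

  if (is.null(config$deconvolve)) {
    say("no deconvolve block: stopping after marker discovery")
    bundle$paths <- paths
    bundle$summary <- write_summary(art("summary.md"), bundle, partial = TRUE)
    return(invisible(bundle))
  }

  ## -- deconvolve + evaluate ----------------------------------------------
  if (is.null(series)) {
    abort("deconvolve block requires a simulate$series block.",
          class = "cfdecon_config_error")
  }
  say("deconvolve: PSO mixture solving on the spike-in series")
  dcfg <- config$deconvolve
  bg_mode <- dcfg$background %||% "defaults"
  dcfg$background <- NULL
  pcfg <- do.call(pso_config, dcfg[names(dcfg) %in%
                                     names(formals(pso_config))])
  if (is.null(pcfg$seed)) pcfg$seed <- cfg$seed + 2000
  background <- switch(bg_mode,
    defaults = wbc_background_model(),
    none = NULL,
    estimate = {
      wbc_ids <- panel$wbc_plasma_pairs$meta$sample_id[
        panel$wbc_plasma_pairs$meta$group == "WBC"]
      wbc_dc <- deconvolve(pairs_mepm[pairs_mepm$sample_id %in% wbc_ids, ],
                           marker_set, tissue_means, pcfg, background = NULL)
      estimate_wbc_background(
        rename(wbc_dc[, c("sample_id", "tissue", "raw_fraction")],
               fraction = "raw_fraction"))
    },
    abort("unknown background mode.", class = "cfdecon_config_error")
  )
  results <- deconvolve(series_mepm, marker_set, tissue_means, pcfg,
                        background = background)
  readr::write_tsv(as_tibble(results), art("deconvolution.tsv"))

  say("evaluate: recovery regression and detection limits")
  spiked_ids <- series$meta$sample_id[series$meta$group == "spiked"]
  null_ids <- series$meta$sample_id[series$meta$group == "wbc_only"]
  est <- rename(results[, c("sample_id", "tissue", "raw_fraction")],
                fraction = "raw_fraction")
  recovery <- evaluate_recovery(est[est$sample_id %in% spiked_ids, ],
                                series$truth)
  readr::write_tsv(as_tibble(recovery), art("recovery.tsv"))

  detection <- NULL
  if (length(null_ids) >= 2) {
    spiked_est <- est[est$sample_id %in% spiked_ids, ] |>
      left_join(rename(series$truth[, c("sample_id", "tissue", "fraction")],
                       level_fraction = "fraction"),
                by = c("sample_id", "tissue")) |>
      filter(.data$tissue %in% recovery$tissue)
    detection <- estimate_detection_limit(
      spiked_est, est[est$sample_id %in% null_ids, ])
    readr::write_tsv(attr(detection, "tests"), art("detection_tests.tsv"))
    readr::write_tsv(detection, art("detection_limits.tsv"))
  }

  bundle$results <- results
  bundle$recovery <- recovery
  bundle$detection <- detection
  bundle$paths <- paths
  bundle$summary <- write_summary(art("summary.md"), bundle, partial = FALSE)
  invisible(bundle)
}

# Markdown summary; every reported number points at the artifact file it
# was taken from.
write_summary <- function(path, bundle, partial) {
  md_table <- function(df) {
    df <- as_tibble(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |")))
  }
  lines <- c(
    "# cfDNA tissue-mapping pipeline summary", "",
    sprintf("Markers planted: %d (%d selected; see `marker_set.tsv`).",
            nrow(bundle$marker_set), sum(bundle$marker_set$selected)), ""
  )
  sel_tab <- bundle$marker_set |>
    filter(.data$selected) |>
    count(.data$source_tissue, name = "markers")
  lines <- c(lines, "## Selected markers per tissue (from `marker_set.tsv`)",
             "", md_table(sel_tab), "")
  if (!is.null(bundle$dm)) {
    lines <- c(lines,
               sprintf("Differential screen: %d significant loci (see `differential.tsv`).",
                       sum(bundle$dm$significant)), "")
  }
  if (!partial) {
    lines <- c(lines, "## Spike-in recovery (from `recovery.tsv`)", "",
               md_table(as_tibble(bundle$recovery)), "")
    if (!is.null(bundle$detection)) {
      lines <- c(lines,
                 "## Detection limits (from `detection_limits.tsv`)", "",
                 md_table(bundle$detection), "")
    }
  } else {
    lines <- c(lines, "_Partial run: pipeline stopped after marker discovery._")
  }
  writeLines(lines, path)
  path
}
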