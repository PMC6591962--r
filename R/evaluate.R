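#' Evaluate spike-in recovery by linear regression
#'
#' Ordinary least squares of the estimated against the true (spiked)
#' fraction, per spiked tissue. Accurate deconvolution gives slope near 1,
#' intercept near 0 and R-squared near 1.
#'
#' @param estimates Tibble (`sample_id`, `tissue`, `fraction`) of estimated
#'   fractions, e.g. `raw_fraction` from [deconvolve()].
#' @param truth Tibble (`sample_id`, `tissue`, `fraction`) of the true
#'   spiked fractions (a `cf_series` `truth` table works directly).
#' @param tissues Tissues to evaluate; default: every tissue whose true
#'   fraction varies.
#' @return A `cf_recovery` tibble: `tissue`, `slope`, `intercept`,
#'   `r_squared`, `n`; the per-point data are kept in the `"data"`
#'   attribute for plotting.
#' @export
evaluate_recovery <- function(estimates, truth, tissues = NULL) {
  dat <- inner_join(
    rename(estimates, estimate = "fraction"),
    rename(truth[, c("sample_id", "tissue", "fraction")], truth = "fraction"),
    by = c("sample_id", "tissue")
  )
  if (is.null(tissues)) {
    spread <- dat |>
      summarise(v = length(unique(.data$truth)), .by = "tissue")
    tissues <- spread$tissue[spread$v > 1]
  }
  res <- purrr::map_dfr(tissues, function(t) {
    d <- dat[dat$tissue == t, ]
    if (length(unique(d$truth)) < 3) {
      abort(sprintf("need >= 3 distinct true fractions for %s (R^2 undefined on constant truth).", t),
            class = "cfdecon_domain_error")
    }
    fit <- lm(estimate ~ truth, data = d)
    tibble(
      tissue = t,
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = summary(fit)$r.squared,
      n = nrow(d)
    )
  })
  class(res) <- c("cf_recovery", class(res))
  attr(res, "data") <- dat[dat$tissue %in% tissues, ]
  res
}

#' Detection limit of a spike-in series against the WBC-only null
#'
#' For each tissue and spike level, the estimated fractions of the level's
#' replicates are compared with the WBC-only replicates by a two-tailed
#' t test; the detection limit is the smallest level with P below `alpha`
#' (`NA` when no level separates from the null).
#'
#' @param estimates Tibble (`sample_id`, `tissue`, `level_fraction`,
#'   `fraction`) of spiked-sample estimates; `level_fraction` is the true
#'   spiked fraction of the sample's level.
#' @param null_estimates Tibble (`sample_id`, `tissue`, `fraction`) of
#'   WBC-only estimates; >= 2 replicates, as for each level.
#' @param alpha Significance level (default 0.05).
#' @return Tibble (`tissue`, `detection_limit`) with the per-level tests in
#'   the `"tests"` attribute (`tissue`, `level_fraction`, `p_value`).
#' @export
estimate_detection_limit <- function(estimates, null_estimates, alpha = 0.05) {
  tissues <- unique(estimates$tissue)
  tests <- purrr::map_dfr(tissues, function(t) {
    null_v <- null_estimates$fraction[null_estimates$tissue == t]
    if (length(null_v) < 2) {
      abort("need >= 2 WBC-only replicates (variance undefined otherwise).",
            class = "cfdecon_domain_error")
    }
    d <- estimates[estimates$tissue == t, ]
    purrr::map_dfr(sort(unique(d$level_fraction)), function(lv) {
      v <- d$fraction[d$level_fraction == lv]
      if (length(v) < 2) {
        abort("need >= 2 replicates per spike level.",
              class = "cfdecon_domain_error")
      }
      p <- tryCatch(
        t.test(v, null_v)$p.value,
        error = function(e) {
          # both groups essentially constant: distinct means are trivially
          # separated, identical means are not
          if (isTRUE(all.equal(mean(v), mean(null_v)))) 1 else 0
        }
      )
      tibble(tissue = t, level_fraction = lv, p_value = p)
    })
  })
  limits <- tests |>
    summarise(
      detection_limit = if (any(.data$p_value < alpha)) {
        min(.data$level_fraction[.data$p_value < alpha])
      } else NA_real_,
      .by = "tissue"
    )
  attr(limits, "tests") <- tests
  limits
}

#' Run the in-silico spike-in benchmark end to end
#'
#' The full accuracy/sensitivity experiment in one call: generates a
#' synthetic reference panel, simulates a spike-in dilution series with
#' matched WBC-only replicates, quantifies MePM, selects markers, runs the
#' PSO deconvolution on every sample, and evaluates recovery (OLS of
#' estimated versus true fraction) and the detection limit (two-tailed
#' t test against the WBC-only null).
#'
#' @param tissues Tissue(s) to spike (default liver).
#' @param fraction_grid Spike fractions (default 0.25--16% in doubling
#'   steps).
#' @param replicates Replicates per level and for the null (default 10).
#' @param total_reads Sequencing depth per sample (default 3e5).
#' @param seed Master seed for panel, series and solver.
#' @param config Panel [sim_config()]; defaults to the standard eight-tissue
#'   panel at `total_reads` depth.
#' @param pso A [pso_config()]; its seed is derived from `seed` when unset.
#' @return List: `recovery` (a `cf_recovery`), `detection` (per-tissue
#'   detection limits with per-level tests in the `"tests"` attribute),
#'   `estimates` (per-sample raw fractions), `truth`, `marker_set`,
#'   `panel`.
#' @export
spikein_benchmark <- function(tissues = "liver",
                              fraction_grid = c(0.0025, 0.005, 0.01, 0.02,
                                                0.04, 0.08, 0.16),
                              replicates = 10, total_reads = 3e5,
                              seed = 1, config = NULL,
                              pso = pso_config()) {
  config <- config %||% sim_config(total_mapped_reads = max(total_reads, 1e4),
                                   seed = seed)
  panel <- generate_reference_panel(config)
  series <- simulate_mixture_series(panel, tissues, fraction_grid,
                                    replicates = replicates,
                                    total_reads = total_reads,
                                    seed = seed + 1)
  mepm <- compute_mepm(series$molecules, series$meta, panel$sites,
                       panel$markers[, c("site_id", "cpg_index")])
  tissue_means <- rename(filter(panel$truth, .data$tissue != "WBC"),
                         mean_mepm = "true_mepm")
  wbc_mepm <- compute_mepm(panel$wbc_training$molecules,
                           panel$wbc_training$meta, panel$sites,
                           panel$markers[, c("site_id", "cpg_index")])
  marker_set <- select_tissue_markers(tissue_means, wbc_mepm, panel$markers)
  if (is.null(pso$seed)) pso$seed <- seed + 2
  results <- deconvolve(mepm, marker_set, tissue_means, config = pso,
                        background = NULL)
  est <- rename(results[, c("sample_id", "tissue", "raw_fraction")],
                fraction = "raw_fraction")
  spiked_ids <- series$meta$sample_id[series$meta$group == "spiked"]
  null_ids <- series$meta$sample_id[series$meta$group == "wbc_only"]
  recovery <- evaluate_recovery(est[est$sample_id %in% spiked_ids, ],
                                series$truth, tissues = tissues)
  spiked_est <- est[est$sample_id %in% spiked_ids, ] |>
    left_join(rename(series$truth[, c("sample_id", "tissue", "fraction")],
                     level_fraction = "fraction"),
              by = c("sample_id", "tissue")) |>
    filter(.data$tissue %in% tissues)
  detection <- estimate_detection_limit(spiked_est,
                                        est[est$sample_id %in% null_ids, ])
  list(recovery = recovery, detection = detection, estimates = est,
       truth = series$truth, marker_set = marker_set, panel = panel)
}
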