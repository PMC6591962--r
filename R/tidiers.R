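#' Tidy a PSO mixture fit
#'
#' @param x A `cf_pso_fit` from [pso_solve()].
#' @param ... Unused.
#' @return Tibble with one row per tissue: `tissue`, `fraction`, and the
#'   across-run spread `run_sd`.
#' @exportS3Method generics::tidy
tidy.cf_pso_fit <- function(x, ...) {
  tibble(
    tissue = names(x$fractions) %||% paste0("k", seq_along(x$fractions)),
    fraction = as.numeric(x$fractions),
    run_sd = apply(x$runs, 1, sd)
  )
}

#' @rdname tidy.cf_pso_fit
#' @return For `glance()`: a one-row tibble with the optimum residual,
#'   number of runs and swarm settings.
#' @exportS3Method generics::glance
glance.cf_pso_fit <- function(x, ...) {
  tibble(
    residual = x$residual, n_runs = x$config$n_runs,
    swarm_size = x$config$swarm_size, iterations = x$config$iterations
  )
}

#' Tidy spike-in recovery fits
#'
#' @param x A `cf_recovery` from [evaluate_recovery()].
#' @param ... Unused.
#' @return `tidy()`: the per-tissue slope/intercept/R-squared table.
#'   `glance()`: one row with the worst (minimum) R-squared across tissues.
#' @exportS3Method generics::tidy
tidy.cf_recovery <- function(x, ...) as_tibble(x)

#' @rdname tidy.cf_recovery
#' @exportS3Method generics::glance
glance.cf_recovery <- function(x, ...) {
  tibble(n_tissues = nrow(x), min_r_squared = min(x$r_squared),
         mean_slope = mean(x$slope))
}

#' Volcano plot of a differential methylation result
#'
#' @param object A `cf_dm` from [identify_dm_sites()].
#' @param ... Unused.
#' @return A ggplot: log2 fold change against -log10 q, significant loci
#'   highlighted.
#' @exportS3Method ggplot2::autoplot
autoplot.cf_dm <- function(object, ...) {
  df <- as_tibble(object)
  df$neg_log10_q <- -log10(pmax(df$q_value, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(.data$log2_fc, .data$neg_log10_q)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 1) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "thresholds")["fdr"]),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (MePM)", y = "-log10(q)",
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Bar plot of deconvolved tissue fractions
#'
#' @param object A `cf_deconv` from [deconvolve()].
#' @param corrected Plot corrected (default) or raw fractions.
#' @param ... Unused.
#' @return A ggplot of per-tissue fractions (percent), faceted by sample.
#' @exportS3Method ggplot2::autoplot
autoplot.cf_deconv <- function(object, corrected = TRUE, ...) {
  df <- as_tibble(object)
  df$value <- 100 * if (corrected) df$corrected_fraction else df$raw_fraction
  ggplot2::ggplot(df, ggplot2::aes(.data$tissue, .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~sample_id) +
    ggplot2::labs(x = NULL, y = "cfDNA fraction (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Estimated-versus-true plot of a spike-in series
#'
#' @param object A `cf_recovery` from [evaluate_recovery()].
#' @param ... Unused.
#' @return A ggplot of estimated against true fractions with the OLS line,
#'   faceted by tissue.
#' @exportS3Method ggplot2::autoplot
autoplot.cf_recovery <- function(object, ...) {
  dat <- attr(object, "data")
  ggplot2::ggplot(dat, ggplot2::aes(100 * .data$truth, 100 * .data$estimate)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "firebrick", linewidth = 0.6) +
    ggplot2::facet_wrap(~tissue, scales = "free") +
    ggplot2::labs(x = "spiked fraction (%)", y = "estimated fraction (%)") +
    ggplot2::theme_minimal()
}
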