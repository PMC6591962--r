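#' Particle swarm optimizer settings
#'
#' The mixture system is solved with particle swarm optimization (PSO)
#' under box constraints; the canonical constriction parameters are the
#' defaults, and the element-wise median of `n_runs` independent runs is
#' the readout.
#'
#' @param swarm_size Particles per run (>= 2, default 50).
#' @param iterations Iterations per run (default 500).
#' @param inertia,cognitive,social Velocity-update coefficients (defaults
#'   0.729 and 1.49445 / 1.49445, the constriction values).
#' @param n_runs Independent runs whose element-wise median is returned
#'   (default 10).
#' @param seed Optional integer seed; run r uses `seed + r`.
#' @return A `pso_config` object.
#' @export
pso_config <- function(swarm_size = 50, iterations = 500, inertia = 0.729,
                       cognitive = 1.49445, social = 1.49445, n_runs = 10,
                       seed = NULL) {
  if (swarm_size < 2 || iterations < 1 || n_runs < 1) {
    abort("need swarm_size >= 2, iterations >= 1, n_runs >= 1.",
          class = "cfdecon_config_error")
  }
  structure(
    list(swarm_size = as.integer(swarm_size),
         iterations = as.integer(iterations),
         inertia = inertia, cognitive = cognitive, social = social,
         n_runs = as.integer(n_runs), seed = seed),
    class = "pso_config"
  )
}

# One PSO run on min ||MT p - MP||^2 over [0,1]^d. Vectorized over the
# swarm. Bounds are reflecting (position mirrored, velocity reversed and
# damped): absorbing walls stagnate the swarm at the zero corner, where the
# true optima of low-fraction plasma samples live.
pso_run <- function(MT, MP, cfg) {
  d <- ncol(MT)
  n <- cfg$swarm_size
  X <- matrix(runif(d * n), d, n)
  V <- matrix(runif(d * n, -0.1, 0.1), d, n)
  obj <- function(X) colSums((MT %*% X - MP)^2)

  Fx <- obj(X)
  Pb <- X
  Fb <- Fx
  g <- which.min(Fb)
  G <- Pb[, g]
  Fg <- Fb[g]

  for (it in seq_len(cfg$iterations)) {
    R1 <- matrix(runif(d * n), d, n)
    R2 <- matrix(runif(d * n), d, n)
    V <- cfg$inertia * V + cfg$cognitive * R1 * (Pb - X) +
      cfg$social * R2 * (G - X)
    X <- X + V
    lo <- X < 0
    hi <- X > 1
    if (any(lo) || any(hi)) {
      X[lo] <- -X[lo]
      X[hi] <- 2 - X[hi]
      V[lo | hi] <- -0.5 * V[lo | hi]
      X[X < 0] <- 0  # overshoot beyond one reflection
      X[X > 1] <- 1
    }
    Fx <- obj(X)
    better <- Fx < Fb
    if (any(better)) {
      Pb[, better] <- X[, better]
      Fb[better] <- Fx[better]
      g <- which.min(Fb)
      if (Fb[g] < Fg) {
        G <- Pb[, g]
        Fg <- Fb[g]
      }
    }
  }
  list(p = G, value = Fg)
}

#' Solve the mixture system with particle swarm optimization
#'
#' Minimizes `sum_i (MP_i - sum_k MT_ik P_k)^2` subject to `0 <= P_k <= 1`
#' and returns the element-wise median of `n_runs` independent runs.
#'
#' @param MT Non-negative matrix of aggregated tissue-marker MePM values
#'   (equations x tissues).
#' @param MP Non-negative vector of the corresponding aggregated plasma
#'   MePM values.
#' @param config A [pso_config()].
#' @return A `cf_pso_fit`: list with `fractions` (named median solution),
#'   `runs` (tissues x n_runs matrix), `residual` (objective at the median
#'   solution), `config`.
#' @export
pso_solve <- function(MT, MP, config = pso_config()) {
  MT <- as.matrix(MT)
  MP <- as.numeric(MP)
  if (!all(is.finite(MT)) || !all(is.finite(MP))) {
    abort("`MT` and `MP` must be finite.", class = "cfdecon_domain_error")
  }
  if (any(MT < 0) || any(MP < 0)) {
    abort("`MT` and `MP` must be non-negative.",
          class = "cfdecon_domain_error")
  }
  if (nrow(MT) != length(MP)) {
    abort("`MP` length must match `nrow(MT)`.",
          class = "cfdecon_domain_error")
  }
  runs <- vapply(seq_len(config$n_runs), function(r) {
    seed_r <- if (is.null(config$seed)) NULL else config$seed + r
    with_seed(seed_r, pso_run(MT, MP, config))$p
  }, numeric(ncol(MT)))
  runs <- matrix(runs, nrow = ncol(MT))
  p <- apply(runs, 1, median)
  names(p) <- colnames(MT)
  rownames(runs) <- colnames(MT)
  structure(
    list(fractions = p, runs = runs,
         residual = sum((MP - as.numeric(MT %*% p))^2), config = config),
    class = "cf_pso_fit"
  )
}

#' Build the aggregated per-tissue mixture system
#'
#' For each tissue, its selected markers (minus the panel-strongest one,
#' see [aggregate_markers()]) are summed into a single combined marker,
#' both in the reference panel and in the plasma sample, giving one
#' equation per tissue: `MP_t = sum_k MT_tk P_k`. WBC is not a component
#' (the markers were selected to be silent in WBC). Tissues with no
#' retained markers are dropped with a warning.
#'
#' @param marker_set A `cf_marker_set`; only `selected` markers are used
#'   (restrict to `hcc_safe` markers first for HCC samples).
#' @param tissue_means Long tibble (`marker_id`, `tissue`, `mean_mepm`) of
#'   the reference panel.
#' @param plasma_mepm Tibble (`marker_id`, `mepm`) for one plasma sample,
#'   or a named numeric vector.
#' @return List with `MT` (tissues x tissues matrix), `MP` (named vector),
#'   `tissues`, and `dropped_markers` (the panel-strongest marker per
#'   tissue, excluded from the aggregate).
#' @export
build_system <- function(marker_set, tissue_means, plasma_mepm) {
  if (is.numeric(plasma_mepm)) {
    plasma_mepm <- tibble(marker_id = names(plasma_mepm),
                          mepm = as.numeric(plasma_mepm))
  }
  sel <- marker_set[marker_set$selected, ]
  tissues <- attr(marker_set, "tissues") %||% unique(tissue_means$tissue)
  tissues <- tissues[tissues %in% sel$source_tissue]
  empty <- setdiff(attr(marker_set, "tissues") %||% tissues, tissues)
  if (length(empty) > 0) {
    warn(sprintf("no retained markers for tissue(s) %s: equation(s) dropped.",
                 paste(empty, collapse = ", ")))
  }

  wide <- tidyr::pivot_wider(tissue_means, names_from = "tissue",
                             values_from = "mean_mepm")
  mp_all <- setNames(plasma_mepm$mepm, plasma_mepm$marker_id)

  MT <- matrix(0, length(tissues), length(tissues),
               dimnames = list(tissues, tissues))
  MP <- setNames(numeric(length(tissues)), tissues)
  dropped <- setNames(rep(NA_character_, length(tissues)), tissues)

  for (t in tissues) {
    ids <- sel$marker_id[sel$source_tissue == t]
    rows <- match(ids, wide$marker_id)
    if (any(is.na(rows)) || !all(ids %in% names(mp_all))) {
      abort(sprintf("panel or plasma values missing for %s markers.", t),
            class = "cfdecon_lookup_error")
    }
    drop_idx <- if (length(ids) > 1) which.max(wide[[t]][rows]) else NULL
    if (!is.null(drop_idx)) dropped[t] <- ids[drop_idx]
    for (k in tissues) {
      MT[t, k] <- aggregate_markers(wide[[k]][rows], drop_index = drop_idx)
    }
    MP[t] <- aggregate_markers(mp_all[ids], drop_index = drop_idx)
  }
  list(MT = MT, MP = MP, tissues = tissues, dropped_markers = dropped)
}

#' WBC background model for measured tissue fractions
#'
#' Deconvolving pure WBC samples yields small non-zero tissue fractions;
#' these are removed in two steps: measured fractions below the per-tissue
#' zeroing threshold (the WBC mean plus three standard deviations) are set
#' to zero, and the WBC mean background is subtracted from the survivors.
#' The defaults are the values estimated from fourteen paired healthy WBC
#' samples in the assay this package models (fractions, not percent):
#' means 0.015%, 0, 0.36%, 0, 0, 0, 0.066%, 0 and thresholds 0.11%, 0,
#' 2.0%, 0.082%, 0.036%, 0.023%, 0.57%, 0 for liver, lung, stomach, colon,
#' kidney, pancreas, muscle, skin.
#'
#' @param mean_background Named per-tissue mean background fractions.
#' @param threshold Named per-tissue zeroing thresholds (mean + 3 SD).
#' @return A `wbc_background_model` object.
#' @export
wbc_background_model <- function(
    mean_background = c(liver = 0.00015, lung = 0, stomach = 0.0036,
                        colon = 0, kidney = 0, pancreas = 0,
                        muscle = 0.00066, skin = 0),
    threshold = c(liver = 0.0011, lung = 0, stomach = 0.020,
                  colon = 0.00082, kidney = 0.00036, pancreas = 0.00023,
                  muscle = 0.0057, skin = 0)) {
  if (!identical(names(mean_background), names(threshold))) {
    abort("mean and threshold must cover the same tissues, same order.",
          class = "cfdecon_config_error")
  }
  if (any(mean_background < 0) || any(threshold < mean_background)) {
    abort("need thresholds >= means >= 0 tissue-wise.",
          class = "cfdecon_config_error")
  }
  structure(list(mean_background = mean_background, threshold = threshold),
            class = "wbc_background_model")
}

#' Estimate a WBC background model from deconvolved WBC samples
#'
#' Computes the per-tissue mean and mean + 3 SD of the measured fractions
#' across a cohort of pure WBC samples, the empirical analogue of the
#' default constants in [wbc_background_model()].
#'
#' @param wbc_fractions Tibble (`sample_id`, `tissue`, `fraction`) of raw
#'   deconvolved fractions of WBC-only samples.
#' @return A `wbc_background_model`.
#' @export
estimate_wbc_background <- function(wbc_fractions) {
  stats <- wbc_fractions |>
    summarise(m = mean(.data$fraction),
              s = sd(.data$fraction), .by = "tissue")
  wbc_background_model(
    mean_background = setNames(stats$m, stats$tissue),
    threshold = setNames(stats$m + 3 * ifelse(is.na(stats$s), 0, stats$s),
                         stats$tissue)
  )
}

#' Apply WBC background correction to measured tissue fractions
#'
#' Fractions below the tissue's zeroing threshold are set to zero; the
#' per-tissue mean background is subtracted from the survivors (floored at
#' zero). The threshold is tested on the measured (raw) fractions.
#'
#' @param fractions Named vector of raw tissue fractions in \[0, 1\].
#' @param model A [wbc_background_model()].
#' @return Named vector of corrected fractions.
#' @export
correct_background <- function(fractions, model = wbc_background_model()) {
  if (any(fractions < 0) || any(fractions > 1)) {
    abort("raw fractions must lie in [0, 1].", class = "cfdecon_domain_error")
  }
  tissues <- names(fractions) %||% names(model$mean_background)
  names(fractions) <- tissues
  mu <- model$mean_background[tissues]
  thr <- model$threshold[tissues]
  if (any(is.na(mu))) {
    abort("background model is missing some tissues.",
          class = "cfdecon_lookup_error")
  }
  out <- ifelse(fractions < thr, 0, pmax(0, fractions - mu))
  setNames(out, tissues)
}

#' Convert tissue fractions to absolute genomic equivalents per millilitre
#'
#' `GE/mL = P * cfdna_ng_per_ml * 1000 / pg_per_haploid_ge`: the sample's
#' cfDNA concentration expressed as haploid genome copies per millilitre of
#' plasma, attributed to each tissue by its fraction.
#'
#' @param fractions Tissue fractions (corrected).
#' @param cfdna_ng_per_ml Total cfDNA concentration (ng per mL plasma).
#' @param pg_per_haploid_ge Mass of one haploid genome in picograms
#'   (default 3.3).
#' @return Per-tissue haploid GE per mL plasma.
#' @export
absolute_ge <- function(fractions, cfdna_ng_per_ml, pg_per_haploid_ge = 3.3) {
  if (pg_per_haploid_ge <= 0) {
    abort("`pg_per_haploid_ge` must be positive.",
          class = "cfdecon_domain_error")
  }
  if (cfdna_ng_per_ml < 0) {
    abort("`cfdna_ng_per_ml` must be >= 0.", class = "cfdecon_domain_error")
  }
  fractions * cfdna_ng_per_ml * 1000 / pg_per_haploid_ge
}

#' Deconvolve plasma samples into per-tissue cfDNA fractions
#'
#' The user-facing wrapper: for each sample in `mepm`, builds the
#' aggregated mixture system from the marker set and reference panel,
#' solves it with PSO (median of `n_runs`), applies the WBC background
#' model, and optionally converts to absolute GE/mL.
#'
#' @param mepm Long MePM tibble (`marker_id`, `sample_id`, `mepm`).
#' @param marker_set A `cf_marker_set`.
#' @param tissue_means Reference panel, long tibble (`marker_id`, `tissue`,
#'   `mean_mepm`).
#' @param config A [pso_config()].
#' @param background A [wbc_background_model()], or `NULL` to skip
#'   correction.
#' @param meta Optional metadata with `cfdna_ng_per_ml` for the GE/mL
#'   conversion.
#' @param hcc_safe Use only the HCC-safe marker subset (requires
#'   [filter_hcc_safe_markers()] to have been applied).
#' @return A `cf_deconv` tibble: `sample_id`, `tissue`, `raw_fraction`,
#'   `corrected_fraction`, `ge_per_ml` (NA without concentration),
#'   `residual`.
#' @export
deconvolve <- function(mepm, marker_set, tissue_means,
                       config = pso_config(), background = wbc_background_model(),
                       meta = NULL, hcc_safe = FALSE) {
  if (hcc_safe) {
    if (!"hcc_safe" %in% names(marker_set)) {
      abort("run `filter_hcc_safe_markers()` before `hcc_safe = TRUE`.",
            class = "cfdecon_domain_error")
    }
    marker_set <- marker_set[marker_set$hcc_safe | !marker_set$selected, ]
  }
  samples <- unique(mepm$sample_id)
  res <- purrr::map_dfr(seq_along(samples), function(i) {
    sid <- samples[i]
    sys <- build_system(
      marker_set, tissue_means,
      mepm[mepm$sample_id == sid, c("marker_id", "mepm")]
    )
    cfg <- config
    if (!is.null(cfg$seed)) cfg$seed <- cfg$seed + (i - 1) * cfg$n_runs
    fit <- pso_solve(sys$MT, sys$MP, cfg)
    raw <- fit$fractions
    corr <- if (is.null(background)) raw else correct_background(raw, background)
    conc <- NA_real_
    if (!is.null(meta) && "cfdna_ng_per_ml" %in% names(meta)) {
      conc <- meta$cfdna_ng_per_ml[match(sid, meta$sample_id)]
    }
    tibble(
      sample_id = sid, tissue = sys$tissues,
      raw_fraction = as.numeric(raw),
      corrected_fraction = as.numeric(corr),
      ge_per_ml = if (is.na(conc)) NA_real_ else
        as.numeric(absolute_ge(corr, conc)),
      residual = fit$residual
    )
  })
  class(res) <- c("cf_deconv", class(res))
  res
}
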