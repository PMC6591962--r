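#' Tissue-specificity index (tau)
#'
#' `tau = sum(1 - x/max(x)) / (N - 1)` over the N per-tissue mean values:
#' 1 when a single tissue carries all the signal, 0 when the profile is
#' uniform.
#'
#' @param values Non-negative per-tissue mean MePM vector, length >= 2,
#'   with a positive maximum.
#' @return tau in \[0, 1\].
#' @export
tau_index <- function(values) {
  if (length(values) < 2 || any(values < 0)) {
    abort("`values` must be >= 0 with length >= 2.",
          class = "cfdecon_domain_error")
  }
  m <- max(values)
  if (m == 0) {
    abort("tau is undefined for an all-zero profile.",
          class = "cfdecon_domain_error")
  }
  sum(1 - values / m) / (length(values) - 1)
}

# Nearest-rank (type 1) quantile, so "90th percentile MePM = 0" is an exact
# equality test against a data value.
p90 <- function(x) quantile(x, 0.9, type = 1, names = FALSE)

#' Select tissue-specific hypermethylated markers
#'
#' Applies the five selection rules to every candidate marker: (v) the
#' marker CpG lies within `max_distance` bp of the CGCGCGG anchor; (iii)
#' the 90th-percentile MePM over the WBC training cohort equals 0; (ii)
#' MePM exceeds `min_source_mepm` in the most hypermethylated tissue; (i)
#' tau exceeds `tau_threshold`; (iv) mean liver MePM is below
#' `max_liver_mepm` when the most hypermethylated tissue is not the liver.
#' The rules are tested in that order and the first failing rule is
#' recorded, so every rejection is attributed deterministically. For
#' tissues in `fallback_tissues` (lung and muscle by default) that end up
#' with no markers, selection is re-run without the tau restriction.
#'
#' @param tissue_means Long tibble (`marker_id`, `tissue`, `mean_mepm`) of
#'   per-tissue mean MePM; at least two tissues.
#' @param wbc_mepm Long tibble (`marker_id`, `sample_id`, `mepm`) over the
#'   WBC training cohort (non-empty).
#' @param marker_info Tibble with `marker_id` and `distance_bp`.
#' @param tau_threshold,min_source_mepm,max_liver_mepm,max_distance,wbc_quantile_max
#'   The rule thresholds; defaults tau > 0.9, source MePM > 10, liver mean
#'   < 1, distance < 60 bp, WBC 90th percentile = 0
#'   (`wbc_quantile_max = 0`).
#' @param fallback_tissues Tissues allowed to drop the tau rule when they
#'   would otherwise have no markers.
#' @param tissue_order Tie-break order for the most hypermethylated tissue.
#' @return A `cf_marker_set` tibble: `marker_id`, `source_tissue`, `tau`,
#'   `max_mepm`, `wbc_p90`, `liver_mean`, `distance_bp`, `selected`,
#'   `rejected_by` (NA when selected), `fallback`.
#' @export
select_tissue_markers <- function(tissue_means, wbc_mepm, marker_info,
                                  tau_threshold = 0.9,
                                  min_source_mepm = 10,
                                  max_liver_mepm = 1,
                                  max_distance = 60,
                                  wbc_quantile_max = 0,
                                  fallback_tissues = c("lung", "muscle"),
                                  tissue_order = cf_tissues()) {
  tissues <- unique(tissue_means$tissue)
  if (length(tissues) < 2) {
    abort("need at least two tissues.", class = "cfdecon_domain_error")
  }
  if (nrow(wbc_mepm) == 0) {
    abort("WBC training set is empty.", class = "cfdecon_domain_error")
  }
  ord <- c(intersect(tissue_order, tissues), setdiff(tissues, tissue_order))

  wide <- tidyr::pivot_wider(tissue_means, names_from = "tissue",
                             values_from = "mean_mepm")
  mat <- as.matrix(wide[, ord])

  wbc_stats <- wbc_mepm |>
    summarise(wbc_p90 = p90(.data$mepm), .by = "marker_id")

  cand <- tibble(
    marker_id = wide$marker_id,
    source_tissue = ord[apply(mat, 1, which.max)],  # ties: first in order
    max_mepm = apply(mat, 1, max),
    tau = apply(mat, 1, function(x) if (max(x) == 0) NA_real_ else tau_index(x)),
    liver_mean = if ("liver" %in% ord) mat[, "liver"] else NA_real_
  ) |>
    left_join(wbc_stats, by = "marker_id") |>
    left_join(marker_info[, c("marker_id", "distance_bp")], by = "marker_id")
  if (any(is.na(cand$wbc_p90)) || any(is.na(cand$distance_bp))) {
    abort("every candidate needs WBC training values and a distance.",
          class = "cfdecon_lookup_error")
  }

  apply_rules <- function(df, use_tau) {
    reject <- rep(NA_character_, nrow(df))
    fail <- function(cur, cond, label) ifelse(is.na(cur) & cond, label, cur)
    reject <- fail(reject, df$distance_bp >= max_distance, "v_distance")
    reject <- fail(reject, df$wbc_p90 > wbc_quantile_max, "iii_wbc")
    reject <- fail(reject, df$max_mepm <= min_source_mepm, "ii_low_signal")
    if (use_tau) {
      reject <- fail(reject, is.na(df$tau) | df$tau <= tau_threshold, "i_tau")
    }
    reject <- fail(reject, df$source_tissue != "liver" &
                     df$liver_mean >= max_liver_mepm, "iv_liver")
    reject
  }

  cand$rejected_by <- apply_rules(cand, use_tau = TRUE)
  cand$fallback <- FALSE

  for (t in intersect(fallback_tissues, ord)) {
    idx <- cand$source_tissue == t
    if (!any(idx & is.na(cand$rejected_by))) {
      cand$rejected_by[idx] <- apply_rules(cand[idx, ], use_tau = FALSE)
      cand$fallback[idx] <- TRUE
    }
  }

  cand$selected <- is.na(cand$rejected_by)
  cand <- cand[, c("marker_id", "source_tissue", "tau", "max_mepm",
                   "wbc_p90", "liver_mean", "distance_bp", "selected",
                   "rejected_by", "fallback")]
  class(cand) <- c("cf_marker_set", class(cand))
  attr(cand, "tissues") <- ord
  cand
}

#' Aggregate a tissue's markers into one combined marker
#'
#' The per-tissue markers are combined by summing their MePM values after
#' leaving out the single strongest marker; a one-marker tissue keeps its
#' only value. By default the dropped marker is fixed by the reference
#' panel (the marker with the largest source-tissue mean), which keeps the
#' aggregate linear in the mixing fraction; passing `drop_index = NULL`
#' drops each sample's own maximum instead.
#'
#' @param values Numeric MePM values of one tissue's markers in one sample.
#' @param drop_index Index of the marker to leave out (panel-defined), or
#'   `NULL` to drop `which.max(values)`.
#' @return The aggregated scalar MePM.
#' @export
aggregate_markers <- function(values, drop_index = NULL) {
  if (length(values) == 0) {
    abort("no marker values to aggregate.", class = "cfdecon_domain_error")
  }
  if (length(values) == 1) return(values[[1]])
  drop_index <- drop_index %||% which.max(values)
  sum(values[-drop_index])
}

#' Restrict a marker set to markers safe in hepatocellular carcinoma
#'
#' Markers hypermethylated in liver tumors would confound liver-fraction
#' estimates in HCC patients. Liver markers are retained when a one-tailed
#' (tumor greater) MWW test of tumor versus adjacent non-cancerous liver
#' gives P > `alpha`; markers of other tissues are retained when the
#' tumor-tissue 90th-percentile MePM is below `p90_threshold`.
#'
#' @param marker_set A `cf_marker_set`.
#' @param tumor_mepm,adjacent_mepm Long tibbles (`marker_id`, `sample_id`,
#'   `mepm`) over tumor and adjacent-tissue cohorts; must cover every
#'   selected marker.
#' @param alpha MWW significance level (default 0.05).
#' @param p90_threshold Tumor 90th-percentile MePM bound for non-liver
#'   markers (default 10).
#' @return The marker set with an `hcc_safe` column; unselected markers
#'   keep `hcc_safe = FALSE`.
#' @export
filter_hcc_safe_markers <- function(marker_set, tumor_mepm, adjacent_mepm,
                                    alpha = 0.05, p90_threshold = 10) {
  sel <- marker_set$marker_id[marker_set$selected]
  missing <- setdiff(sel, intersect(unique(tumor_mepm$marker_id),
                                    unique(adjacent_mepm$marker_id)))
  if (length(missing) > 0) {
    abort(sprintf("tumor/adjacent values missing for marker(s): %s.",
                  paste(head(missing, 5), collapse = ", ")),
          class = "cfdecon_lookup_error")
  }
  safe <- vapply(seq_len(nrow(marker_set)), function(i) {
    if (!marker_set$selected[i]) return(FALSE)
    id <- marker_set$marker_id[i]
    tum <- tumor_mepm$mepm[tumor_mepm$marker_id == id]
    if (marker_set$source_tissue[i] == "liver") {
      adj <- adjacent_mepm$mepm[adjacent_mepm$marker_id == id]
      mww_test(tum, adj, alternative = "greater") > alpha
    } else {
      p90(tum) < p90_threshold
    }
  }, logical(1))
  marker_set$hcc_safe <- safe
  marker_set
}

#' Annotate markers inside intragenic regions of tissue-specific genes
#'
#' A gene is tissue specific when its expression z-score (computed across
#' tissues on log2(x + 1) means) exceeds `z_threshold` in some tissue. The
#' intragenic region runs from 300 bp downstream of the transcription start
#' site to 300 bp downstream of the transcription end site, strand-aware.
#' A marker is annotated when its CpG lies in the intragenic region of a
#' gene that is tissue specific in the marker's source tissue.
#'
#' @param marker_set A `cf_marker_set` (selected markers are annotated).
#' @param marker_info Tibble with `marker_id`, `chrom`, `cpg_pos`.
#' @param expression Long tibble (`gene`, `tissue`, `expr`) of expression
#'   means per tissue; tissue labels must cover the marker source tissues.
#' @param gene_models Tibble (`gene`, `chrom`, `start`, `end`, `strand`);
#'   `start < end`, strand "+" or "-".
#' @param z_threshold Expression z-score threshold (default 1.5).
#' @return Tibble of annotated markers: `marker_id`, `source_tissue`,
#'   `gene`, `expr_z` (z-score of the gene in the source tissue).
#' @export
annotate_intragenic_tissue_genes <- function(marker_set, marker_info,
                                             expression, gene_models,
                                             z_threshold = 1.5) {
  if (any(gene_models$start >= gene_models$end) ||
      !all(gene_models$strand %in% c("+", "-"))) {
    abort("malformed gene model (need start < end and strand +/-).",
          class = "cfdecon_domain_error")
  }
  z <- expression |>
    mutate(.l = log2(.data$expr + 1)) |>
    mutate(expr_z = (.data$.l - mean(.data$.l)) / sd(.data$.l),
           .by = "gene")

  # intragenic window in genomic coordinates, shifted 300 bp downstream in
  # the direction of transcription at both ends
  gm <- gene_models |>
    mutate(
      win_lo = ifelse(.data$strand == "+", .data$start + 300, .data$start - 300),
      win_hi = ifelse(.data$strand == "+", .data$end + 300, .data$end - 300)
    )

  sel <- marker_set[marker_set$selected, c("marker_id", "source_tissue")] |>
    left_join(marker_info[, c("marker_id", "chrom", "cpg_pos")],
              by = "marker_id")

  sel |>
    left_join(gm, by = "chrom", relationship = "many-to-many") |>
    filter(!is.na(.data$gene),
           .data$cpg_pos >= .data$win_lo, .data$cpg_pos < .data$win_hi) |>
    left_join(z[, c("gene", "tissue", "expr_z")],
              by = c("gene", "source_tissue" = "tissue")) |>
    filter(!is.na(.data$expr_z), .data$expr_z > z_threshold) |>
    select("marker_id", "source_tissue", "gene", "expr_z")
}
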