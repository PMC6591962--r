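#' Two-tailed Mann-Whitney-Wilcoxon test
#'
#' Thin wrapper with the conventions used throughout the package: the exact
#' null distribution when both groups have at most eight observations and
#' there are no ties, the normal approximation with tie correction
#' otherwise, and p = 1 when every observation in both groups is identical
#' (no rank separation at all).
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return The MWW p-value.
#' @export
mww_test <- function(a, b, alternative = "two.sided") {
  if (length(a) == 0 || length(b) == 0) {
    abort("both groups must be non-empty.", class = "cfdecon_domain_error")
  }
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) return(1)
  has_ties <- anyDuplicated(pooled) > 0
  exact <- !has_ties && length(a) <= 8 && length(b) <= 8
  suppressWarnings(
    wilcox.test(a, b, alternative = alternative, exact = exact,
                correct = !exact)$p.value
  )
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted q-values, monotone in p-value rank and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1].", class = "cfdecon_domain_error")
  }
  p.adjust(p, method = "BH")
}

#' Identify differentially methylated loci between two groups
#'
#' The plasma-versus-WBC screen: for every marker locus, group-mean MePM
#' values, the fold change of the means (with a pseudocount guarding
#' against zero denominators), a two-tailed MWW p-value, and BH q-values
#' across loci. A locus is flagged significant in a direction when the fold
#' change of that direction exceeds `fc_threshold` and q is below
#' `fdr_threshold`.
#'
#' @param mepm Long MePM tibble (`marker_id`, `sample_id`, `mepm`), e.g.
#'   from [compute_mepm()].
#' @param meta Metadata tibble mapping `sample_id` to `group`.
#' @param group_a,group_b The two group labels to compare (fold change is
#'   a over b); both need at least two samples.
#' @param fc_threshold Fold-change threshold (default 5).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @param pseudocount Added to both group means before the ratio
#'   (default 0.1 MePM).
#' @return A `cf_dm` tibble: `marker_id`, `mean_a`, `mean_b`,
#'   `fold_change`, `log2_fc`, `p_value`, `q_value`, `direction`
#'   (which group is hypermethylated), `significant`.
#' @export
identify_dm_sites <- function(mepm, meta, group_a = "plasma",
                              group_b = "WBC", fc_threshold = 5,
                              fdr_threshold = 0.05, pseudocount = 0.1) {
  groups <- setNames(meta$group, meta$sample_id)
  ids_a <- meta$sample_id[meta$group == group_a]
  ids_b <- meta$sample_id[meta$group == group_b]
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    abort("each group needs at least two samples.",
          class = "cfdecon_domain_error")
  }
  dat <- mepm[mepm$sample_id %in% c(ids_a, ids_b), ]

  res <- dat |>
    summarise(
      mean_a = mean(.data$mepm[.data$sample_id %in% ids_a]),
      mean_b = mean(.data$mepm[.data$sample_id %in% ids_b]),
      p_value = mww_test(.data$mepm[.data$sample_id %in% ids_a],
                         .data$mepm[.data$sample_id %in% ids_b]),
      .by = "marker_id"
    ) |>
    mutate(
      fold_change = (.data$mean_a + pseudocount) / (.data$mean_b + pseudocount),
      log2_fc = log2(.data$fold_change),
      q_value = bh_fdr(.data$p_value),
      direction = ifelse(.data$mean_a >= .data$mean_b, group_a, group_b),
      significant = .data$q_value < fdr_threshold &
        (.data$fold_change > fc_threshold |
           .data$fold_change < 1 / fc_threshold)
    )
  class(res) <- c("cf_dm", class(res))
  attr(res, "groups") <- c(group_a, group_b)
  attr(res, "thresholds") <- c(fc = fc_threshold, fdr = fdr_threshold)
  res
}
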