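#' Length of the fully methylated prefix of a molecule
#'
#' A molecule counts as a fully methylated molecule (FMM) at CpG index *j*
#' when every CpG from the CGCGCGG anchor through *j* is methylated, i.e.
#' when its methylated prefix is at least *j* long.
#'
#' @param states Character vector of 0/1 methylation-state strings.
#' @return Integer vector: number of leading "1"s of each string.
#' @keywords internal
fmm_prefix_len <- function(states) {
  bad <- grepl("[^01]", states)
  if (any(bad)) {
    abort("`meth_states` must contain only 0/1 characters.",
          class = "cfdecon_domain_error")
  }
  pos <- regexpr("0", states, fixed = TRUE)
  ifelse(pos == -1L, nchar(states), as.integer(pos) - 1L)
}

#' Count fully methylated molecules at one marker
#'
#' @param molecules Molecule tibble (`sample_id`, `site_id`, `meth_states`).
#' @param site_id CGCGCGG site identifier.
#' @param cpg_index Downstream CpG index, 1..10.
#' @param sites Optional site-definition tibble; when supplied, `site_id`
#'   is validated against it and `cpg_index` against the site's CpG count.
#' @return Number of molecules at `site_id` whose CpGs 1..`cpg_index` are
#'   all methylated (0 for an empty table).
#' @export
count_fmm <- function(molecules, site_id, cpg_index, sites = NULL) {
  if (!is.numeric(cpg_index) || cpg_index < 1 || cpg_index > 10) {
    abort("`cpg_index` must be in 1..10.", class = "cfdecon_domain_error")
  }
  if (!is.null(sites)) {
    row <- match(site_id, sites$site_id)
    if (is.na(row)) {
      abort(sprintf("unknown site '%s'.", site_id),
            class = "cfdecon_lookup_error")
    }
    if (cpg_index > sites$n_cpgs[row]) {
      abort(sprintf("site '%s' has only %d downstream CpGs.",
                    site_id, sites$n_cpgs[row]),
            class = "cfdecon_domain_error")
    }
  }
  hit <- molecules$site_id == site_id
  if (!any(hit)) return(0L)
  sum(fmm_prefix_len(molecules$meth_states[hit]) >= cpg_index)
}

#' Compute MePM values from molecule-level methylation calls
#'
#' Converts molecule records into methylated alleles per million mapped
#' reads (MePM): for each (site, CpG index) pair and sample, the FMM count
#' normalized by the sample's total uniquely mapped reads and scaled to one
#' million.
#'
#' @param molecules Molecule tibble (`sample_id`, `site_id`, `meth_states`).
#' @param meta Sample metadata tibble with `sample_id` and
#'   `total_mapped_reads` (> 0); every sample present in `molecules` must
#'   have a metadata row.
#' @param sites Site definitions (`site_id`, `n_cpgs`); rows of the result
#'   cover every (site, CpG index) pair they define.
#' @param markers Optional tibble (`site_id`, `cpg_index`) restricting the
#'   output to specific marker pairs.
#' @return Long tibble: `site_id`, `cpg_index`, `marker_id`, `sample_id`,
#'   `n_fmm`, `mepm`. Every sample in `meta` is represented at every pair
#'   (zero counts included).
#' @export
compute_mepm <- function(molecules, meta, sites, markers = NULL) {
  extra <- setdiff(unique(molecules$sample_id), meta$sample_id)
  if (length(extra) > 0) {
    abort(sprintf("no metadata for sample(s): %s.",
                  paste(extra, collapse = ", ")),
          class = "cfdecon_lookup_error")
  }
  if (any(meta$total_mapped_reads <= 0)) {
    abort("`total_mapped_reads` must be positive to compute MePM.",
          class = "cfdecon_domain_error")
  }
  pairs <- if (is.null(markers)) {
    tibble(site_id = rep(sites$site_id, sites$n_cpgs),
           cpg_index = unlist(lapply(sites$n_cpgs, seq_len), use.names = FALSE))
  } else {
    distinct(markers[, c("site_id", "cpg_index")])
  }

  counts <- molecules |>
    mutate(.prefix = fmm_prefix_len(.data$meth_states)) |>
    count(.data$sample_id, .data$site_id, .data$.prefix, name = ".n")

  grid <- tidyr::crossing(pairs, sample_id = meta$sample_id)
  fmm <- grid |>
    left_join(counts, by = c("site_id", "sample_id"),
              relationship = "many-to-many") |>
    mutate(.n = ifelse(is.na(.data$.n) | .data$.prefix < .data$cpg_index,
                       0L, .data$.n)) |>
    summarise(n_fmm = sum(.data$.n),
              .by = c("site_id", "cpg_index", "sample_id"))

  fmm |>
    left_join(meta[, c("sample_id", "total_mapped_reads")], by = "sample_id") |>
    mutate(
      marker_id = marker_id(.data$site_id, .data$cpg_index),
      mepm = .data$n_fmm * 1e6 / .data$total_mapped_reads
    ) |>
    select("site_id", "cpg_index", "marker_id", "sample_id", "n_fmm", "mepm") |>
    arrange(.data$site_id, .data$cpg_index, .data$sample_id)
}

#' Normalize a sample pair to a common duplication rate
#'
#' Matched plasma/WBC pairs are compared at the same effective PCR
#' duplication rate. The member with the higher rate is adjusted down to
#' the lower rate, either by seeded downsampling of its duplicate reads
#' (rows sharing a `molecule_id`; the count nature of the data is
#' preserved) or by a multiplicative rescaling of its MePM denominator.
#' In both modes the sample's `total_mapped_reads` is scaled by the rate
#' ratio so genome-wide and marker-local duplication stay coherent.
#'
#' @param molecules Molecule tibble holding the reads of both samples; in
#'   `"downsample"` mode duplicate reads of one molecule share a
#'   `molecule_id`.
#' @param meta Two-row metadata tibble with `duplication_rate` (>= 1).
#' @param mode `"downsample"` (default) or `"rescale"`.
#' @param seed Seed for the duplicate downsampling.
#' @return List with adjusted `molecules` and `meta`.
#' @export
normalize_duplication <- function(molecules, meta,
                                  mode = c("downsample", "rescale"),
                                  seed = NULL) {
  mode <- match.arg(mode)
  if (nrow(meta) != 2) {
    abort("`meta` must describe exactly two samples.",
          class = "cfdecon_domain_error")
  }
  if (any(meta$duplication_rate < 1)) {
    abort("`duplication_rate` must be >= 1.", class = "cfdecon_domain_error")
  }
  d <- meta$duplication_rate
  if (d[1] == d[2]) return(list(molecules = molecules, meta = meta))
  hi <- which.max(d)
  d_hi <- d[hi]
  d_lo <- min(d)
  hi_id <- meta$sample_id[hi]

  meta$duplication_rate[hi] <- d_lo

  if (mode == "rescale") {
    # reads untouched; inflating the denominator shrinks MePM by d_lo/d_hi
    meta$total_mapped_reads[hi] <-
      as.integer(round(meta$total_mapped_reads[hi] * d_hi / d_lo))
    return(list(molecules = molecules, meta = meta))
  }

  # duplicate reads removed from the numerator, so the genome-wide
  # denominator shrinks by the same rate ratio
  meta$total_mapped_reads[hi] <-
    as.integer(round(meta$total_mapped_reads[hi] * d_lo / d_hi))

  if (!"molecule_id" %in% names(molecules)) {
    abort("downsampling needs a `molecule_id` column grouping duplicate reads.",
          class = "cfdecon_domain_error")
  }
  with_seed(seed, {
    is_hi <- molecules$sample_id == hi_id
    hi_rows <- which(is_hi)
    first <- !duplicated(molecules$molecule_id[hi_rows])
    keepers <- hi_rows[first]
    dups <- hi_rows[!first]
    n_unique <- length(keepers)
    target_dups <- min(length(dups), round(n_unique * (d_lo - 1)))
    kept_dups <- if (target_dups > 0) sample(dups, target_dups) else integer(0)
    keep <- sort(c(which(!is_hi), keepers, kept_dups))
    list(molecules = molecules[keep, ], meta = meta)
  })
}
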