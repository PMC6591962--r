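#' Configuration for the synthetic MCTA-Seq-like data generator
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' The defaults emulate the study conditions the pipeline was designed for:
#' an eight-tissue reference panel (59/8/9/20/13/18/11/8 markers for
#' liver/lung/stomach/colon/kidney/pancreas/muscle/skin, 146 in total),
#' source-tissue methylation of 10--100 MePM, essentially unmethylated
#' white-blood-cell (WBC) background, and sequencing depth of about three
#' million uniquely mapped read pairs.
#'
#' @param n_tissues Number of tissues; must match `length(markers_per_tissue)`.
#' @param tissues Tissue labels, in canonical order.
#' @param markers_per_tissue Integer vector: number of tissue-specific
#'   markers planted per tissue.
#' @param source_mepm_range Interval the true source-tissue MePM of each
#'   marker is drawn from (uniform). The lower bound must exceed 10 so that
#'   the marker-selection rule "MePM > 10 in the most hypermethylated
#'   tissue" is satisfiable.
#' @param offtarget_mepm_max Upper bound of the (uniform) true MePM of a
#'   marker in tissues other than its source tissue; small relative to the
#'   source signal so planted markers are genuinely tissue specific.
#' @param wbc_leak_mepm Per-marker true MePM in WBC ("leak"); 0 by default,
#'   matching markers selected to have a WBC 90th-percentile MePM of 0.
#' @param background_mol_rate Rate (MePM units) of partially methylated
#'   background molecules emitted per marker site; these never count as
#'   fully methylated molecules at the marker's CpG index and exercise the
#'   FMM filter.
#' @param total_mapped_reads Default depth for simulated samples.
#' @param n_wbc_training Number of WBC training samples (marker selection).
#' @param n_wbc_plasma_pairs Number of matched WBC/plasma pairs.
#' @param pair_plasma_fractions Named tissue fractions used for the plasma
#'   member of each matched pair (plasma is a WBC-dominated mixture; the
#'   default plants a 1.3% liver fraction, the healthy-adult scale).
#' @param decoy_distance,decoy_shared,decoy_leaky Numbers of decoy markers
#'   to plant: CpG sites at >= 60 bp from the anchor motif, markers
#'   hypermethylated in two tissues (low specificity), and markers that
#'   leak into WBC, respectively. All default to 0.
#' @param decoy_leak_mepm True WBC MePM of "leaky" decoys.
#' @param seed Integer seed; every generator call is reproducible given the
#'   config seed.
#'
#' @return A `sim_config` object (a validated list).
#' @export
sim_config <- function(n_tissues = 8,
                       tissues = cf_tissues(),
                       markers_per_tissue = c(59, 8, 9, 20, 13, 18, 11, 8),
                       source_mepm_range = c(10, 100),
                       offtarget_mepm_max = 0.5,
                       wbc_leak_mepm = 0,
                       background_mol_rate = 1,
                       total_mapped_reads = 3e6,
                       n_wbc_training = 29,
                       n_wbc_plasma_pairs = 14,
                       pair_plasma_fractions = c(liver = 0.013),
                       decoy_distance = 0,
                       decoy_shared = 0,
                       decoy_leaky = 0,
                       decoy_leak_mepm = 5,
                       seed = 1L) {
  if (n_tissues != length(tissues) || n_tissues != length(markers_per_tissue)) {
    abort("`n_tissues`, `tissues` and `markers_per_tissue` must agree.",
          class = "cfdecon_config_error")
  }
  if (any(markers_per_tissue < 1)) {
    abort("every tissue needs at least one marker (`markers_per_tissue` >= 1).",
          class = "cfdecon_config_error")
  }
  if (total_mapped_reads < 1e4) {
    abort("`total_mapped_reads` must be at least 10,000.",
          class = "cfdecon_config_error")
  }
  if (length(source_mepm_range) != 2 || source_mepm_range[1] < 10 ||
      diff(source_mepm_range) < 0) {
    abort("`source_mepm_range` must be an increasing interval with lower bound >= 10.",
          class = "cfdecon_config_error")
  }
  if (wbc_leak_mepm < 0 || background_mol_rate < 0) {
    abort("rates must be non-negative.", class = "cfdecon_config_error")
  }
  structure(
    list(
      tissues = tissues,
      markers_per_tissue = setNames(as.integer(markers_per_tissue), tissues),
      source_mepm_range = source_mepm_range,
      offtarget_mepm_max = offtarget_mepm_max,
      wbc_leak_mepm = wbc_leak_mepm,
      background_mol_rate = background_mol_rate,
      total_mapped_reads = as.integer(total_mapped_reads),
      n_wbc_training = as.integer(n_wbc_training),
      n_wbc_plasma_pairs = as.integer(n_wbc_plasma_pairs),
      pair_plasma_fractions = pair_plasma_fractions,
      decoy_distance = as.integer(decoy_distance),
      decoy_shared = as.integer(decoy_shared),
      decoy_leaky = as.integer(decoy_leaky),
      decoy_leak_mepm = decoy_leak_mepm,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# Draw the site geometry for one marker. Real markers keep the marker CpG
# within 60 bp of the CGCGCGG anchor; "distance" decoys place it at >= 60 bp.
draw_site <- function(i, far = FALSE) {
  n_cpgs <- sample(4:10, 1)
  if (far) {
    offsets <- sort(c(sample(2:58, n_cpgs - 1), sample(60:120, 1)))
    cpg_index <- n_cpgs
  } else {
    offsets <- sort(sample(2:58, n_cpgs))
    cpg_index <- sample(seq_len(n_cpgs), 1)
  }
  chrom <- paste0("chr", (i - 1) %% 8 + 1)
  start <- 10000 * ((i - 1) %/% 8 + 1)
  list(
    site_id = sprintf("s%03d", i), chrom = chrom, start = start,
    end = start + 7L, strand = "+", n_cpgs = n_cpgs,
    cpg_offsets = offsets, cpg_index = cpg_index,
    distance_bp = offsets[cpg_index]
  )
}

#' Generate a synthetic tissue reference panel with WBC samples
#'
#' Builds the full synthetic study scaffold: site definitions (one CGCGCGG
#' locus per marker), the true per-tissue MePM of every marker (uniform in
#' `source_mepm_range` in the source tissue, near zero elsewhere and in
#' WBC), optional decoy markers, a WBC training cohort, and matched
#' WBC/plasma pairs with molecule counts sampled from the truth.
#'
#' @param config A [sim_config()].
#' @return A `cf_panel` object: a list with elements
#'   * `tissues` -- tissue labels;
#'   * `sites` -- tibble of CGCGCGG site definitions (`site_id`, `chrom`,
#'     `start`, `end`, `strand`, `n_cpgs`, `cpg_offsets` list-column);
#'   * `markers` -- tibble of marker loci (`marker_id`, `site_id`,
#'     `cpg_index`, `chrom`, `cpg_pos`, `distance_bp`, `source_tissue`,
#'     `decoy`);
#'   * `truth` -- long tibble of true MePM (`marker_id`, `tissue`,
#'     `true_mepm`), with `"WBC"` as an extra tissue level;
#'   * `wbc_training` -- list(molecules, meta) for the WBC training cohort;
#'   * `wbc_plasma_pairs` -- list(molecules, meta, truth_fractions) for the
#'     matched pairs (plasma simulated as a WBC-dominated mixture);
#'   * `config` -- the generating config.
#' @export
generate_reference_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    tissues <- config$tissues
    n_real <- sum(config$markers_per_tissue)
    n_total <- n_real + config$decoy_distance + config$decoy_shared +
      config$decoy_leaky

    source_tissue <- rep(tissues, times = config$markers_per_tissue)
    decoy <- c(
      rep(NA_character_, n_real),
      rep("distance", config$decoy_distance),
      rep("shared", config$decoy_shared),
      rep("leaky", config$decoy_leaky)
    )
    # decoys other than "shared" still have a nominal source tissue
    source_tissue <- c(source_tissue,
                       sample(tissues, n_total - n_real, replace = TRUE))

    geom <- purrr::map(seq_len(n_total),
                       ~ draw_site(.x, far = !is.na(decoy[.x]) && decoy[.x] == "distance"))

    sites <- purrr::map_dfr(geom, ~ tibble(
      site_id = .x$site_id, chrom = .x$chrom, start = .x$start,
      end = .x$end, strand = .x$strand, n_cpgs = .x$n_cpgs
    ))
    sites$cpg_offsets <- purrr::map(geom, "cpg_offsets")

    markers <- purrr::map_dfr(seq_len(n_total), function(i) {
      g <- geom[[i]]
      tibble(
        marker_id = marker_id(g$site_id, g$cpg_index),
        site_id = g$site_id, cpg_index = g$cpg_index, chrom = g$chrom,
        cpg_pos = g$start + g$distance_bp, distance_bp = g$distance_bp,
        source_tissue = source_tissue[i], decoy = decoy[i]
      )
    })

    truth <- purrr::map_dfr(seq_len(n_total), function(i) {
      src <- source_tissue[i]
      m <- runif(length(tissues), 0, config$offtarget_mepm_max)
      names(m) <- tissues
      m[src] <- runif(1, config$source_mepm_range[1], config$source_mepm_range[2])
      wbc <- config$wbc_leak_mepm
      if (!is.na(decoy[i])) {
        if (decoy[i] == "shared") {
          # a second tissue nearly as methylated as the source: tau <= 0.9
          other <- sample(setdiff(tissues, src), 1)
          m[other] <- m[src] * runif(1, 0.8, 1)
        } else if (decoy[i] == "leaky") {
          wbc <- config$decoy_leak_mepm
        }
      }
      tibble(
        marker_id = markers$marker_id[i],
        tissue = c(tissues, "WBC"),
        true_mepm = c(m, wbc)
      )
    })

    panel <- structure(
      list(tissues = tissues, sites = sites, markers = markers,
           truth = truth, config = config),
      class = "cf_panel"
    )

    wbc_training <- simulate_cohort(
      panel, n = config$n_wbc_training, prefix = "wbc_train",
      group = "WBC", fractions = NULL,
      total_reads = config$total_mapped_reads
    )

    pair_wbc <- simulate_cohort(
      panel, n = config$n_wbc_plasma_pairs, prefix = "pair_wbc",
      group = "WBC", fractions = NULL,
      total_reads = config$total_mapped_reads
    )
    pair_plasma <- simulate_cohort(
      panel, n = config$n_wbc_plasma_pairs, prefix = "pair_plasma",
      group = "plasma", fractions = config$pair_plasma_fractions,
      total_reads = config$total_mapped_reads
    )

    panel$wbc_training <- wbc_training
    panel$wbc_plasma_pairs <- list(
      molecules = bind_rows(pair_wbc$molecules, pair_plasma$molecules),
      meta = bind_rows(pair_wbc$meta, pair_plasma$meta),
      truth_fractions = pair_plasma$truth_fractions
    )
    panel
  })
}

# Simulate n samples with identical mixing fractions in the current RNG
# stream; fractions = NULL means pure WBC.
simulate_cohort <- function(panel, n, prefix, group, fractions, total_reads) {
  samples <- purrr::map(seq_len(n), function(i) {
    simulate_sample(panel, fractions = fractions, total_reads = total_reads,
                    sample_id = sprintf("%s_%02d", prefix, i), group = group)
  })
  list(
    molecules = bind_rows(purrr::map(samples, "molecules")),
    meta = bind_rows(purrr::map(samples, "meta")),
    truth_fractions = bind_rows(purrr::map(samples, "truth_fractions"))
  )
}

#' Simulate one sequencing sample from a synthetic panel
#'
#' Draws molecule-level data for a plasma-like mixture of tissues in a WBC
#' background. The fully-methylated-molecule (FMM) count of marker *i* is
#' Poisson with mean `total_reads/1e6 * sum_k fractions_k * M_ik`, where
#' `M_ik` is the marker's true MePM in tissue *k* and the unassigned
#' remainder of the mixture is WBC. Each FMM is emitted as a molecule
#' record whose CpGs are methylated through the marker's CpG index;
#' partially methylated background molecules are added at the config's
#' `background_mol_rate` and never satisfy the FMM criterion at the marker
#' index.
#'
#' @param panel A `cf_panel` from [generate_reference_panel()].
#' @param fractions Named numeric vector of tissue fractions (subset of the
#'   panel tissues), all >= 0 with sum <= 1; `NULL` means pure WBC.
#' @param total_reads Total uniquely mapped reads of the sample (the MePM
#'   denominator). A depth of 0 is accepted as a degenerate input: an empty
#'   molecule table is returned with a warning, and MePM is undefined.
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @param sample_id,group Sample identifier and group label for the
#'   metadata row.
#' @return List with `molecules` (tibble: `sample_id`, `site_id`,
#'   `molecule_id`, `meth_states` 0/1 string), `meta` (one-row tibble) and
#'   `truth_fractions` (long tibble of the generating fractions).
#' @export
simulate_sample <- function(panel, fractions = NULL, total_reads = NULL,
                            seed = NULL, sample_id = "sample_1",
                            group = "plasma") {
  stopifnot(inherits(panel, "cf_panel"))
  total_reads <- total_reads %||% panel$config$total_mapped_reads
  fractions <- normalize_fractions(fractions, panel$tissues)

  with_seed(seed, {
    truth_wide <- tidyr::pivot_wider(panel$truth, names_from = "tissue",
                                     values_from = "true_mepm")
    mt <- as.matrix(truth_wide[, panel$tissues])
    wbc <- truth_wide[["WBC"]]
    mix_mepm <- as.numeric(mt %*% fractions[panel$tissues]) +
      (1 - sum(fractions)) * wbc

    meta <- tibble(
      sample_id = sample_id, group = group,
      total_mapped_reads = as.integer(total_reads),
      duplication_rate = 1, cfdna_ng_per_ml = NA_real_
    )
    truth_fr <- tibble(sample_id = sample_id, tissue = panel$tissues,
                       fraction = as.numeric(fractions[panel$tissues]))

    if (total_reads == 0) {
      warn("`total_reads` is 0: empty molecule table, MePM undefined.")
      return(list(molecules = empty_molecules(), meta = meta,
                  truth_fractions = truth_fr))
    }

    scale <- total_reads / 1e6
    n_fmm <- rpois(length(mix_mepm), scale * mix_mepm)
    n_bg <- rpois(length(mix_mepm), scale * panel$config$background_mol_rate)

    mk <- panel$markers[match(truth_wide$marker_id, panel$markers$marker_id), ]
    n_cpgs <- panel$sites$n_cpgs[match(mk$site_id, panel$sites$site_id)]

    mols <- purrr::map_dfr(which(n_fmm + n_bg > 0), function(i) {
      j <- mk$cpg_index[i]
      nc <- n_cpgs[i]
      fmm_states <- paste(c(rep("1", j), rep("0", nc - j)), collapse = "")
      states <- rep(fmm_states, n_fmm[i])
      if (n_bg[i] > 0) {
        # methylated prefix strictly shorter than the marker CpG index
        states <- c(states, vapply(seq_len(n_bg[i]), function(b) {
          len <- sample(0:(j - 1), 1)
          rest <- sample(c("0", "1"), nc - len - 1, replace = TRUE)
          paste(c(rep("1", len), "0", rest), collapse = "")
        }, character(1)))
      }
      tibble(site_id = mk$site_id[i], meth_states = states)
    })
    if (nrow(mols) == 0) {
      mols <- empty_molecules()
      mols$sample_id <- character(0)
    } else {
      mols <- mols[sample.int(nrow(mols)), ]  # shuffle molecule order
      mols <- tibble(
        sample_id = sample_id, site_id = mols$site_id,
        molecule_id = sprintf("%s_m%05d", sample_id, seq_len(nrow(mols))),
        meth_states = mols$meth_states
      )
    }
    list(molecules = mols, meta = meta, truth_fractions = truth_fr)
  })
}

empty_molecules <- function() {
  tibble(sample_id = character(), site_id = character(),
         molecule_id = character(), meth_states = character())
}

normalize_fractions <- function(fractions, tissues) {
  out <- setNames(numeric(length(tissues)), tissues)
  if (is.null(fractions)) return(out)
  if (is.null(names(fractions)) || !all(names(fractions) %in% tissues)) {
    abort("`fractions` must be named with panel tissue labels.",
          class = "cfdecon_domain_error")
  }
  if (any(fractions < 0) || sum(fractions) > 1 + 1e-12) {
    abort("tissue fractions must be >= 0 and sum to at most 1.",
          class = "cfdecon_domain_error")
  }
  out[names(fractions)] <- fractions
  out
}

#' Simulate a spike-in dilution series
#'
#' Generates the in-silico mixing experiment used to establish accuracy and
#' detection limits: tissue DNA spiked into a WBC background over a grid of
#' fractions (default grid spans 0.25--16%), with replicate samples per
#' level and matched WBC-only (fraction 0) replicates for the null
#' comparison.
#'
#' @param panel A `cf_panel`.
#' @param tissues Character vector of one or more tissues to spike.
#' @param fraction_grid For one tissue, a numeric vector of fractions; for
#'   several tissues, a matrix/data frame with one column per tissue and
#'   one row per grid level.
#' @param replicates Replicates per grid level (and WBC-only replicates).
#' @param total_reads Depth per sample.
#' @param seed Seed for the whole series.
#' @param max_fraction Upper bound enforced on the grid (default 0.16).
#' @param include_null Also generate `replicates` WBC-only samples.
#' @return A `cf_series` object: list with `molecules`, `meta` (all samples,
#'   spiked samples grouped `"spiked"`, nulls `"wbc_only"`), `truth` (long
#'   tibble `sample_id`, `level`, `replicate`, `tissue`, `fraction`).
#' @export
simulate_mixture_series <- function(panel, tissues = "liver",
                                    fraction_grid = c(0.0025, 0.005, 0.01,
                                                      0.02, 0.04, 0.08, 0.16),
                                    replicates = 10,
                                    total_reads = NULL,
                                    seed = 1L,
                                    max_fraction = 0.16,
                                    include_null = TRUE) {
  stopifnot(inherits(panel, "cf_panel"))
  if (!all(tissues %in% panel$tissues)) {
    abort("unknown tissue in `tissues`.", class = "cfdecon_domain_error")
  }
  grid <- if (is.matrix(fraction_grid) || is.data.frame(fraction_grid)) {
    as.matrix(fraction_grid)
  } else {
    matrix(fraction_grid, ncol = 1)
  }
  if (nrow(grid) == 0) {
    abort("`fraction_grid` is empty.", class = "cfdecon_domain_error")
  }
  if (ncol(grid) != length(tissues)) {
    abort("`fraction_grid` must have one column per spiked tissue.",
          class = "cfdecon_domain_error")
  }
  if (any(grid < 0) || any(grid > max_fraction)) {
    abort(sprintf("grid fractions must lie in [0, %g].", max_fraction),
          class = "cfdecon_domain_error")
  }
  total_reads <- total_reads %||% panel$config$total_mapped_reads

  with_seed(seed, {
    out <- list()
    for (lv in seq_len(nrow(grid))) {
      fr <- setNames(grid[lv, ], tissues)
      for (r in seq_len(replicates)) {
        sid <- sprintf("spike_L%02d_r%02d", lv, r)
        s <- simulate_sample(panel, fractions = fr, total_reads = total_reads,
                             sample_id = sid, group = "spiked")
        s$truth_fractions$level <- lv
        s$truth_fractions$replicate <- r
        out[[sid]] <- s
      }
    }
    if (include_null) {
      for (r in seq_len(replicates)) {
        sid <- sprintf("null_r%02d", r)
        s <- simulate_sample(panel, fractions = NULL,
                             total_reads = total_reads,
                             sample_id = sid, group = "wbc_only")
        s$truth_fractions$level <- 0L
        s$truth_fractions$replicate <- r
        out[[sid]] <- s
      }
    }
    structure(
      list(
        molecules = bind_rows(purrr::map(out, "molecules")),
        meta = bind_rows(purrr::map(out, "meta")),
        truth = bind_rows(purrr::map(out, "truth_fractions"))
      ),
      class = "cf_series"
    )
  })
}
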