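test_that("tau index spans single-tissue to uniform profiles", {
  expect_equal(tau_index(c(1, 0, 0, 0, 0, 0, 0, 0)), 1)
  expect_equal(tau_index(rep(5, 8)), 0)
  # (7 * (1 - 0.1)) / 7 = 0.9 -- exactly at the strictly-greater threshold
  expect_equal(tau_index(c(10, 1, 1, 1, 1, 1, 1, 1)), 0.9)
  expect_error(tau_index(rep(0, 8)), class = "cfdecon_domain_error")
  expect_error(tau_index(5), class = "cfdecon_domain_error")

  # tau strictly decreases as a second tissue rises toward the max
  taus <- vapply(seq(0, 10, by = 1),
                 function(v) tau_index(c(10, v, 0, 0, 0, 0, 0, 0)),
                 numeric(1))
  expect_true(all(diff(taus) < 0))
  expect_true(all(taus >= 0 & taus <= 1))
})

# hand-built candidate table: one marker per row with controlled stats
toy_selection_fixture <- function() {
  tissues <- cf_tissues()
  mk <- tibble::tribble(
    ~marker_id, ~src,       ~src_mepm, ~others, ~dist, ~wbc,
    "good_liv", "liver",     12,        0,       40,    0,    # passes all
    "wbc_bad",  "liver",     50,        0,       40,    0.5,  # fails (iii)
    "liv_bad",  "pancreas",  80,        2,       40,    0,    # fails (iv): liver mean 2
    "far_bad",  "kidney",    60,        0,       80,    0,    # fails (v)
    "dim_bad",  "colon",      8,        0,       40,    0,    # fails (ii)
    "tau_bad",  "stomach",   40,        36,      40,    0     # fails (i)
  )
  means <- purrr::pmap_dfr(mk, function(marker_id, src, src_mepm, others,
                                        dist, wbc) {
    m <- setNames(rep(0, 8), tissues)
    m[src] <- src_mepm
    if (marker_id == "liv_bad") m["liver"] <- others
    if (marker_id == "tau_bad") m["colon"] <- others
    tibble::tibble(marker_id = marker_id, tissue = tissues,
                   mean_mepm = unname(m))
  })
  wbc <- tidyr::crossing(marker_id = mk$marker_id,
                         sample_id = sprintf("w%02d", 1:29)) |>
    dplyr::left_join(mk[, c("marker_id", "wbc")], by = "marker_id") |>
    dplyr::mutate(mepm = wbc, wbc = NULL)
  info <- tibble::tibble(marker_id = mk$marker_id, distance_bp = mk$dist)
  list(means = means, wbc = wbc, info = info)
}

test_that("selection applies the five criteria in the documented order", {
  fx <- toy_selection_fixture()
  ms <- select_tissue_markers(fx$means, fx$wbc, fx$info)
  get <- function(id, col) ms[[col]][ms$marker_id == id]
  expect_true(get("good_liv", "selected"))
  expect_equal(get("wbc_bad", "rejected_by"), "iii_wbc")
  expect_equal(get("liv_bad", "rejected_by"), "iv_liver")
  expect_equal(get("far_bad", "rejected_by"), "v_distance")
  expect_equal(get("dim_bad", "rejected_by"), "ii_low_signal")
  expect_equal(get("tau_bad", "rejected_by"), "i_tau")
  # tau = 0.9 exactly is NOT tissue specific (strictly greater threshold)
  expect_lte(get("tau_bad", "tau"), 0.9)
})

test_that("lung and muscle fall back to selection without the tau rule", {
  tissues <- cf_tissues()
  means <- purrr::map_dfr(c(lung = "lg1", colon = "cn1"), function(id) {
    tibble::tibble(marker_id = id, tissue = tissues, mean_mepm = 0)
  })
  # both markers shared with a second tissue -> tau ~ 0.87
  means$mean_mepm[means$marker_id == "lg1" & means$tissue == "lung"] <- 50
  means$mean_mepm[means$marker_id == "lg1" & means$tissue == "skin"] <- 45
  means$mean_mepm[means$marker_id == "cn1" & means$tissue == "colon"] <- 50
  means$mean_mepm[means$marker_id == "cn1" & means$tissue == "skin"] <- 45
  wbc <- tidyr::crossing(marker_id = c("lg1", "cn1"),
                         sample_id = sprintf("w%02d", 1:29)) |>
    dplyr::mutate(mepm = 0)
  info <- tibble::tibble(marker_id = c("lg1", "cn1"), distance_bp = 30)
  ms <- select_tissue_markers(means, wbc, info)
  expect_true(ms$selected[ms$marker_id == "lg1"])   # lung: tau rule waived
  expect_true(ms$fallback[ms$marker_id == "lg1"])
  expect_false(ms$selected[ms$marker_id == "cn1"])  # colon: no fallback
  expect_equal(ms$rejected_by[ms$marker_id == "cn1"], "i_tau")
})

test_that("planted markers are recovered and all decoys rejected", {
  panel <- cached("decoy_panel", generate_reference_panel(sim_config(
    markers_per_tissue = rep(3, 8), total_mapped_reads = 3e6,
    n_wbc_training = 29, n_wbc_plasma_pairs = 2,
    decoy_distance = 4, decoy_shared = 4, decoy_leaky = 4, seed = 202
  )))
  ms <- select_tissue_markers(panel_tissue_means(panel),
                              panel_wbc_mepm(panel), panel$markers)
  truth <- panel$markers[match(ms$marker_id, panel$markers$marker_id), ]
  expect_setequal(ms$marker_id[ms$selected],
                  truth$marker_id[is.na(truth$decoy)])
  rej <- ms[!ms$selected, ]
  rej_truth <- truth[!ms$selected, ]
  expect_equal(unname(rej$rejected_by[rej_truth$decoy == "distance"]),
               rep("v_distance", 4))
  expect_equal(unname(rej$rejected_by[rej_truth$decoy == "leaky"]),
               rep("iii_wbc", 4))
  expect_true(all(rej$rejected_by[rej_truth$decoy == "shared"] %in%
                    c("i_tau", "iv_liver")))
})

test_that("marker aggregation drops one maximum and keeps sums consistent", {
  expect_equal(aggregate_markers(c(7, 3, 2)), 5)
  expect_equal(aggregate_markers(4), 4)
  expect_equal(aggregate_markers(c(0, 0, 0)), 0)
  expect_equal(aggregate_markers(c(7, 3, 2), drop_index = 2), 9)
  expect_error(aggregate_markers(numeric(0)), class = "cfdecon_domain_error")

  set.seed(77)
  for (i in 1:20) {
    v <- runif(sample(2:10, 1), 0, 100)
    expect_equal(aggregate_markers(v) + max(v), sum(v))
  }
})

test_that("HCC-safe filtering removes tumor-hypermethylated markers", {
  fx <- toy_selection_fixture()
  ms <- select_tissue_markers(fx$means, fx$wbc, fx$info)
  # extend with a selected pancreas marker for the non-liver rule
  panc <- fx$means |>
    dplyr::filter(marker_id == "good_liv") |>
    dplyr::mutate(marker_id = "good_pan",
                  mean_mepm = ifelse(tissue == "liver", 0,
                                     ifelse(tissue == "pancreas", 20, 0)))
  means2 <- dplyr::bind_rows(fx$means, panc)
  wbc2 <- dplyr::bind_rows(
    fx$wbc, dplyr::mutate(dplyr::filter(fx$wbc, marker_id == "good_liv"),
                          marker_id = "good_pan"))
  info2 <- dplyr::bind_rows(fx$info,
                            tibble::tibble(marker_id = "good_pan",
                                           distance_bp = 30))
  ms <- select_tissue_markers(means2, wbc2, info2)
  expect_true(all(c("good_liv", "good_pan") %in% ms$marker_id[ms$selected]))

  long <- function(ids, vals) {
    tidyr::crossing(marker_id = ids, sample_id = sprintf("t%02d", 1:10)) |>
      dplyr::left_join(tibble::tibble(marker_id = ids, v = vals),
                       by = "marker_id") |>
      dplyr::mutate(mepm = v, v = NULL)
  }
  all_ids <- ms$marker_id
  # tumor == adjacent everywhere -> everything retained
  same <- long(all_ids, rep(5, length(all_ids)))
  f1 <- filter_hcc_safe_markers(ms, same, same)
  expect_true(all(f1$hcc_safe[f1$selected]))

  # planted tumor-hypermethylated liver marker (100 vs 0): one-sided exact
  # MWW p = 1/choose(20,10) < 0.05 -> removed
  tumor <- same
  tumor$mepm[tumor$marker_id == "good_liv"] <- 100 + seq_len(10)
  adjacent <- same
  adjacent$mepm[adjacent$marker_id == "good_liv"] <- seq_len(10) / 10
  # non-liver marker with tumor 90th percentile 25 -> removed
  tumor$mepm[tumor$marker_id == "good_pan"] <- 25
  f2 <- filter_hcc_safe_markers(ms, tumor, adjacent)
  expect_false(f2$hcc_safe[f2$marker_id == "good_liv"])
  expect_false(f2$hcc_safe[f2$marker_id == "good_pan"])

  expect_error(filter_hcc_safe_markers(ms, same[same$marker_id != "good_liv", ],
                                       same),
               class = "cfdecon_lookup_error")
})

test_that("intragenic annotation respects the 300-bp shifted window and z threshold", {
  tissues <- cf_tissues()
  ms <- tibble::tibble(
    marker_id = c("in_gene", "promoter", "far", "low_z"),
    source_tissue = c("liver", "liver", "liver", "lung"),
    tau = 1, max_mepm = 50, wbc_p90 = 0, liver_mean = 50,
    distance_bp = 20, selected = TRUE, rejected_by = NA_character_,
    fallback = FALSE
  )
  class(ms) <- c("cf_marker_set", class(ms))
  info <- tibble::tibble(
    marker_id = ms$marker_id, chrom = "chr1",
    cpg_pos = c(2000, 1100, 50000, 2500)
  )
  gene_models <- tibble::tibble(
    gene = c("G1", "G2"), chrom = "chr1",
    start = c(1000, 1000), end = c(5000, 5000), strand = "+"
  )
  # G1 liver specific (z > 1.5), G2 uniform
  expression <- tidyr::crossing(gene = c("G1", "G2"), tissue = tissues) |>
    dplyr::mutate(expr = ifelse(gene == "G1" & tissue == "liver", 1000, 5))
  ann <- annotate_intragenic_tissue_genes(ms, info, expression, gene_models)
  expect_equal(ann$marker_id, "in_gene")  # [1300, 5300) contains 2000 only
  expect_equal(ann$gene, "G1")
  expect_gt(ann$expr_z, 1.5)

  # minus-strand window is shifted the other way
  gm_minus <- dplyr::mutate(gene_models, strand = "-")
  ann2 <- annotate_intragenic_tissue_genes(ms, info, expression, gm_minus)
  expect_setequal(ann2$marker_id, c("in_gene", "promoter"))

  expect_error(
    annotate_intragenic_tissue_genes(ms, info, expression,
                                     dplyr::mutate(gene_models, strand = "*")),
    class = "cfdecon_domain_error"
  )
})
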