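quick_pso <- function(seed = 1) pso_config(n_runs = 3, seed = seed)

test_that("build_system aggregates one equation per tissue", {
  panel <- small_panel()
  ms <- select_tissue_markers(panel_tissue_means(panel),
                              panel_wbc_mepm(panel), panel$markers)
  tm <- panel_tissue_means(panel)

  # plasma constructed as an exact 2% liver mixture (no noise)
  truth_wide <- tidyr::pivot_wider(panel$truth, names_from = tissue,
                                   values_from = true_mepm)
  plasma <- tibble::tibble(marker_id = truth_wide$marker_id,
                           mepm = 0.02 * truth_wide$liver)
  sys <- build_system(ms, tm, plasma)
  expect_equal(dim(sys$MT), c(8, 8))
  expect_equal(length(sys$MP), 8)
  expect_equal(unname(sys$MP), unname(0.02 * sys$MT[, "liver"]))

  # pure WBC with zero leak: MP = 0
  zero <- tibble::tibble(marker_id = truth_wide$marker_id, mepm = 0)
  expect_equal(unname(build_system(ms, tm, zero)$MP), rep(0, 8))

  # a tissue with no retained markers drops its equation with a warning
  ms2 <- ms
  ms2$selected[ms2$source_tissue == "skin"] <- FALSE
  expect_warning(sys2 <- build_system(ms2, tm, plasma), "skin")
  expect_equal(dim(sys2$MT), c(7, 7))
})

test_that("PSO solves noiseless systems to the constrained optimum", {
  # zero right-hand side -> zero solution
  MT <- diag(8) * 100
  fit0 <- pso_solve(MT, rep(0, 8), quick_pso(2))
  expect_true(all(abs(fit0$fractions) < 1e-4))

  # known sparse solution, matched against the bounded least-squares oracle
  set.seed(41)
  sys <- random_mixture_system()
  p_star <- c(0.05, 0, 0.01, 0, 0, 0.002, 0, 0)
  MP <- as.numeric(sys$MT %*% p_star)
  fit <- pso_solve(sys$MT, MP, pso_config(seed = 5))
  expect_lt(max(abs(fit$fractions - p_star)), 2e-3)
  expect_lt(max(abs(fit$fractions - bounded_ls(sys$MT, MP))), 2e-3)

  # single-tissue construction
  panel <- small_panel()
  ms <- select_tissue_markers(panel_tissue_means(panel),
                              panel_wbc_mepm(panel), panel$markers)
  s <- build_system(ms, panel_tissue_means(panel), {
    tw <- tidyr::pivot_wider(panel$truth, names_from = tissue,
                             values_from = true_mepm)
    tibble::tibble(marker_id = tw$marker_id, mepm = 0.02 * tw$liver)
  })
  fit2 <- pso_solve(s$MT, s$MP, pso_config(seed = 7))
  expect_lt(abs(fit2$fractions["liver"] - 0.02), 1e-3)
  expect_true(all(fit2$fractions[names(fit2$fractions) != "liver"] < 1e-3))

  expect_error(pso_solve(matrix(c(1, NA, 1, 1), 2), c(1, 1)),
               class = "cfdecon_domain_error")
  expect_error(pso_solve(-MT, rep(1, 8)), class = "cfdecon_domain_error")
})

test_that("median of runs is within bounds and less variable than single runs", {
  set.seed(43)
  sys <- random_mixture_system()
  fit <- pso_solve(sys$MT, sys$MP, pso_config(seed = 11))
  expect_true(all(fit$fractions >= 0 & fit$fractions <= 1))
  expect_true(all(fit$runs >= 0 & fit$runs <= 1))

  # across repeated readouts, the median-of-10 spreads less than single runs
  singles <- vapply(1:12, function(i) {
    pso_solve(sys$MT, sys$MP, pso_config(n_runs = 1, seed = 100 + i))$fractions[1]
  }, numeric(1))
  medians <- vapply(1:12, function(i) {
    pso_solve(sys$MT, sys$MP, pso_config(n_runs = 10, seed = 1000 + 20 * i))$fractions[1]
  }, numeric(1))
  expect_lte(sd(medians), sd(singles) + 1e-12)
})

test_that("background correction thresholds then subtracts", {
  model <- wbc_background_model()
  raw <- setNames(rep(0, 8), cf_tissues())

  raw["liver"] <- 0.013  # above the 0.11% threshold
  corr <- correct_background(raw, model)
  expect_equal(unname(corr["liver"]), 0.013 - 0.00015)  # 1.285%

  raw2 <- raw
  raw2["liver"] <- 0
  raw2["stomach"] <- 0.015  # below the 2.0% threshold -> zeroed
  corr2 <- correct_background(raw2, model)
  expect_equal(unname(corr2["stomach"]), 0)

  expect_equal(unname(correct_background(setNames(rep(0, 8), cf_tissues()))),
               rep(0, 8))
  expect_error(correct_background(setNames(rep(-0.1, 8), cf_tissues())),
               class = "cfdecon_domain_error")

  # idempotent against a zero model once corrected
  zero_model <- wbc_background_model(
    mean_background = setNames(rep(0, 8), cf_tissues()),
    threshold = setNames(rep(0, 8), cf_tissues())
  )
  expect_equal(correct_background(corr, zero_model), corr)

  expect_error(wbc_background_model(threshold = setNames(rep(0, 8), cf_tissues())),
               class = "cfdecon_config_error")
})

test_that("absolute GE/mL conversion is linear in concentration and fraction", {
  expect_equal(absolute_ge(0, 10), 0)
  expect_equal(absolute_ge(0.013, 6.5), 6.5 * 1000 / 3.3 * 0.013,
               tolerance = 1e-12)
  expect_equal(round(absolute_ge(0.013, 6.5), 1), 25.6)
  expect_equal(absolute_ge(0.02, 12), 2 * absolute_ge(0.02, 6))
  expect_error(absolute_ge(0.1, 5, pg_per_haploid_ge = 0),
               class = "cfdecon_domain_error")
  expect_error(absolute_ge(0.1, -5), class = "cfdecon_domain_error")
})

test_that("recovery regression reproduces hand-computed OLS", {
  est <- tibble::tibble(
    sample_id = c("a", "b", "c"), tissue = "liver",
    fraction = c(0, 2, 4)
  )
  truth <- tibble::tibble(
    sample_id = c("a", "b", "c"), tissue = "liver",
    fraction = c(0, 1, 2)
  )
  rec <- suppressWarnings(evaluate_recovery(est, truth))
  expect_equal(rec$slope, 2)
  expect_equal(rec$intercept, 0)
  expect_equal(rec$r_squared, 1)

  # estimates identical to truth
  rec2 <- suppressWarnings(evaluate_recovery(truth, truth))
  expect_equal(rec2$slope, 1)
  expect_equal(rec2$r_squared, 1)

  # constant truth: R^2 undefined
  truth3 <- dplyr::mutate(truth, fraction = 0.5)
  expect_error(evaluate_recovery(est, truth3, tissues = "liver"),
               class = "cfdecon_domain_error")

  expect_equal(glance(rec)$min_r_squared, 1)
  expect_equal(tidy(rec)$slope, 2)
})

test_that("detection limit is the smallest level separated from the null", {
  set.seed(47)
  mk_level <- function(lv, mean, sd, n = 10) {
    tibble::tibble(
      sample_id = sprintf("s_%s_%d", lv, 1:n), tissue = "liver",
      level_fraction = lv, fraction = rnorm(n, mean, sd)
    )
  }
  est <- dplyr::bind_rows(mk_level(0.0025, 0.0024, 0.0002),
                          mk_level(0.005, 0.0049, 0.0004))
  null <- tibble::tibble(sample_id = sprintf("n%d", 1:10), tissue = "liver",
                         fraction = rnorm(10, 0, 0.0001))
  lim <- estimate_detection_limit(est, null)
  expect_equal(lim$detection_limit, 0.0025)

  # spiked estimates indistinguishable from the null -> not detected
  est_null <- dplyr::mutate(est, fraction = rep(null$fraction, 2))
  lim2 <- estimate_detection_limit(est_null, null)
  expect_true(is.na(lim2$detection_limit))

  expect_error(
    estimate_detection_limit(est, null[1, ]),
    class = "cfdecon_domain_error"
  )
  expect_error(
    estimate_detection_limit(est[c(1, 11), ], null),
    class = "cfdecon_domain_error"
  )
})

test_that("more replicates cannot worsen the detection limit at fixed effect", {
  limits <- vapply(c(4, 40), function(n) {
    withr::with_seed(53, {
      est <- dplyr::bind_rows(lapply(c(0.0025, 0.005, 0.01), function(lv) {
        tibble::tibble(sample_id = sprintf("s%g_%d", lv, 1:n),
                       tissue = "liver", level_fraction = lv,
                       fraction = rnorm(n, lv * 0.6, 0.004))
      }))
      null <- tibble::tibble(sample_id = sprintf("n%d", 1:n),
                             tissue = "liver",
                             fraction = rnorm(n, 0, 0.004))
      l <- estimate_detection_limit(est, null)$detection_limit
      if (is.na(l)) Inf else l
    })
  }, numeric(1))
  expect_lte(limits[2], limits[1])
})

test_that("deconvolve returns tidy per-sample fractions end to end", {
  panel <- small_panel()
  ms <- select_tissue_markers(panel_tissue_means(panel),
                              panel_wbc_mepm(panel), panel$markers)
  s <- simulate_sample(panel, c(liver = 0.08), total_reads = 3e6, seed = 71,
                       sample_id = "pl1")
  mep <- compute_mepm(s$molecules, s$meta, panel$sites,
                      panel_marker_pairs(panel))
  res <- deconvolve(mep, ms, panel_tissue_means(panel),
                    config = pso_config(seed = 3),
                    meta = dplyr::mutate(s$meta, cfdna_ng_per_ml = 6.5))
  expect_s3_class(res, "cf_deconv")
  expect_equal(nrow(res), 8)
  expect_lt(abs(res$raw_fraction[res$tissue == "liver"] - 0.08), 0.04)
  expect_true(all(res$corrected_fraction >= 0))
  expect_equal(
    res$ge_per_ml,
    res$corrected_fraction * 6.5 * 1000 / 3.3,
    tolerance = 1e-12
  )
})

test_that("two-tissue spikes recover both fractions within half a percentage point", {
  panel <- cached("full_panel_3e6",
                  generate_reference_panel(sim_config(seed = 303)))
  tm <- panel_tissue_means(panel)
  ms <- select_tissue_markers(tm, panel_wbc_mepm(panel), panel$markers)
  ests <- withr::with_seed(59, vapply(1:4, function(r) {
    s <- simulate_sample(panel, c(liver = 0.04, pancreas = 0.02),
                         total_reads = 3e6, sample_id = sprintf("mix%d", r))
    mep <- compute_mepm(s$molecules, s$meta, panel$sites,
                        panel_marker_pairs(panel))
    sys <- build_system(ms, tm, mep[, c("marker_id", "mepm")])
    pso_solve(sys$MT, sys$MP, pso_config(seed = 600 + r))$fractions
  }, numeric(8)))
  m <- rowMeans(ests)
  expect_lt(abs(m["liver"] - 0.04), 0.005)
  expect_lt(abs(m["pancreas"] - 0.02), 0.005)
  expect_true(all(m[!names(m) %in% c("liver", "pancreas")] < 0.005))
})
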