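# Shared fixtures and independent oracles. Panels are cached per option
# set so expensive generation happens once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# small eight-tissue panel: 4 markers per tissue, shallow depth
small_panel <- function() {
  cached("small_panel", generate_reference_panel(sim_config(
    markers_per_tissue = rep(4, 8), total_mapped_reads = 3e5,
    n_wbc_training = 29, n_wbc_plasma_pairs = 4, seed = 101
  )))
}

panel_tissue_means <- function(panel) {
  dplyr::rename(
    dplyr::filter(panel$truth, tissue != "WBC"),
    mean_mepm = "true_mepm"
  )
}

panel_marker_pairs <- function(panel) panel$markers[, c("site_id", "cpg_index")]

panel_wbc_mepm <- function(panel) {
  compute_mepm(panel$wbc_training$molecules, panel$wbc_training$meta,
               panel$sites, panel_marker_pairs(panel))
}

# molecule-table builder for hand-written cases
mol_tbl <- function(states, site_id = "s1", sample_id = "a",
                    molecule_id = NULL) {
  tibble::tibble(
    sample_id = sample_id, site_id = site_id,
    molecule_id = molecule_id %||% sprintf("m%03d", seq_along(states)),
    meth_states = states
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# --- independent oracles -----------------------------------------------------

# Exact two-tailed MWW p-value by full enumeration of rank assignments
# (tie-free data only).
mww_enumerate <- function(a, b) {
  n <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(pooled), n)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# Brute-force BH step-up on the sorted p-values
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * n / seq_len(n))))
  q <- numeric(n)
  q[o] <- pmin(1, q_sorted)
  q
}

# Box-constrained least squares on the same objective PSO minimizes,
# solved by multi-start L-BFGS-B
bounded_ls <- function(MT, MP) {
  fn <- function(p) sum((MP - MT %*% p)^2)
  gr <- function(p) as.numeric(-2 * t(MT) %*% (MP - MT %*% p))
  d <- ncol(MT)
  best <- NULL
  for (s in list(rep(0.5, d), rep(0.01, d), rep(0.99, d))) {
    o <- optim(s, fn, gr, method = "L-BFGS-B", lower = 0, upper = 1,
               control = list(maxit = 1000, factr = 1e3))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best$par
}

# Mixture system with the structure marker aggregation produces: a strong
# source-tissue diagonal and near-zero off-target entries
random_mixture_system <- function(d = 8) {
  MT <- matrix(runif(d * d, 0, 5), d, d)
  diag(MT) <- runif(d, 50, 500)
  p_true <- runif(d)
  list(MT = MT, MP = as.numeric(MT %*% p_true), p_true = p_true)
}
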